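# Panel / hidden-Markov likelihood machinery.
#
# The likelihood of intermittently observed data is computed under the
# standard piecewise-constant assumption: covariates are carried forward
# from the previous visit and the generator Q is treated as constant on the
# sub-intervals obtained by splitting every inter-visit gap at baseline
# cutpoints (and, for Weibull baselines, at an absolute grid of step
# `meta$time_step`, Q evaluated at sub-interval midpoints).  Transition
# matrices over gaps are ordered products of matrix exponentials; identical
# (generator, length) pairs are exponentiated once per evaluation.

covariates_used <- function(spec) {
  tc <- unique(unlist(lapply(spec$terms, names)))
  ec <- if (!is.null(spec$emission))
    setdiff(names(spec$emission$terms), "(Intercept)") else character()
  bc <- if (!is.null(spec$emission)) spec$emission$blocked %||% character()
  list(trans = tc %||% character(), emis = ec, blocked = bc)
}

#' Precompute the likelihood skeleton for a (spec, data) pair
#'
#' Splits every inter-visit gap into constant-generator segments, assigns
#' each segment a covariate/time pattern, groups identical (pattern, length)
#' pairs so each distinct matrix exponential is computed once per likelihood
#' evaluation, and parses observation records (single states, censoring
#' sets, \code{"*"}, exact-transition flags) into forward-algorithm weights.
#' Fitting functions call this once and reuse it for every evaluation.
#'
#' @param spec a \code{pm_spec}
#' @param data a \code{pm_panel} (or coercible data frame)
#' @param init \code{NULL} for the spec's default initial weighting, or a
#'   numeric prior over states applied at the first visit
#' @param condition number of leading visits to condition out of each
#'   series' likelihood (\code{NULL} = spec default)
#' @return an opaque object of class \code{pm_prep}
#' @export
pm_prepare <- function(spec, data, init = NULL, condition = NULL) {
  data <- pm_panel(data)
  ns <- spec$n_states
  use <- covariates_used(spec)
  miss <- setdiff(c(use$trans, use$emis), panel_cov_cols(data))
  if (length(miss))
    stop("panel data lacks covariate column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  cuts <- spec_cutpoints(spec)
  hw <- spec_has_weibull(spec)
  h <- spec$meta$time_step %||% 0.25
  init_cfg <- spec$meta$init
  use_pseudo <- is.null(init) && !is.null(init_cfg) &&
    identical(init_cfg$kind, "occupancy")
  if (is.null(condition)) {
    condition <- if (use_pseudo) {
      if (isFALSE(init_cfg$condition)) 0L else 2L
    } else if (isFALSE(spec$meta$condition_first)) 0L else 1L
  }
  init_vec <- if (!is.null(init)) {
    stopifnot(length(init) == ns)
    as.numeric(init)
  } else if (use_pseudo) {
    v <- numeric(ns); v[init_cfg$state] <- 1; v
  } else rep(1, ns)

  series <- panel_series(data)
  n_series <- length(series)
  n_visits <- integer(n_series)
  all_exact <- isTRUE(spec$meta$exact_times)
  gap_exact <- integer(0)
  gap_nseg <- integer(0)
  seg_dt <- numeric(0); seg_covkey <- character(0); seg_tkey <- character(0)
  seg_tmid <- numeric(0); seg_covrow <- integer(0)
  v_state <- list(); v_exact <- integer(0)
  cov_keys <- character(0); cov_rows <- list()
  absorb <- absorbing_states(spec)
  allcov <- c(use$trans, use$emis, use$blocked)
  allcov <- intersect(allcov, names(data))

  for (si in seq_len(n_series)) {
    rows <- series[[si]]
    tt <- data$time[rows]
    st <- data$state[rows]
    ex <- data$exact[rows]
    cv <- as.data.frame(data[rows, allcov, drop = FALSE])
    if (use_pseudo) {
      t0 <- init_cfg$time %||% 0
      if (tt[1] < t0 - 1e-12)
        stop("first observation precedes the initialization time",
             call. = FALSE)
      tt <- c(t0, tt); st <- c("*", st); ex <- c(0L, ex)
      cv <- rbind(cv[1, , drop = FALSE], cv)
    }
    nv <- length(tt)
    n_visits[si] <- nv
    for (v in seq_len(nv)) {
      if (ex[v] == 1L) {
        s <- parse_state(st[v], ns)
        if (length(s) != 1)
          stop("exact-transition records must name a single state",
               call. = FALSE)
        if (!(s %in% spec$transitions$to))
          stop(sprintf("state %d is not enterable by any transition", s),
               call. = FALSE)
        if (v == 1)
          stop("the first record of a series cannot be an exact transition",
               call. = FALSE)
        v_state[[length(v_state) + 1L]] <- integer(0)
        v_exact <- c(v_exact, s)
      } else {
        v_state[[length(v_state) + 1L]] <- parse_state(st[v], ns)
        v_exact <- c(v_exact, 0L)
      }
    }
    if (nv >= 2) for (g in seq_len(nv - 1)) {
      t0 <- tt[g]; t1 <- tt[g + 1]
      gap_exact <- c(gap_exact, as.integer(all_exact || ex[g + 1] == 1L))
      ck <- paste(vapply(cv[g, , drop = TRUE], format, "", digits = 15),
                  collapse = "\r")
      ci <- match(ck, cov_keys)
      if (is.na(ci)) {
        cov_keys <- c(cov_keys, ck)
        cov_rows[[length(cov_rows) + 1L]] <- as.list(cv[g, , drop = FALSE])
        ci <- length(cov_keys)
      }
      b <- c(t0, cuts[cuts > t0 + 1e-12 & cuts < t1 - 1e-12])
      if (hw && t1 > t0) {
        gr <- seq(ceiling(t0 / h - 1e-9), floor(t1 / h + 1e-9)) * h
        b <- c(b, gr[gr > t0 + 1e-12 & gr < t1 - 1e-12])
      }
      b <- sort(unique(c(b, t1)))
      mid <- (b[-length(b)] + b[-1]) / 2
      dts <- diff(b)
      if (hw) mid <- weibull_eval_times(spec, mid)
      tk <- if (hw) sprintf("%.9g", mid)
            else as.character(findInterval(mid, c(-Inf, cuts)))
      gap_nseg <- c(gap_nseg, length(dts))
      seg_dt <- c(seg_dt, dts)
      seg_covrow <- c(seg_covrow, rep(ci, length(dts)))
      seg_tkey <- c(seg_tkey, tk)
      seg_tmid <- c(seg_tmid, mid)
    }
  }
  # covariate/time patterns -> generator slices
  pat_key <- paste(seg_covrow, seg_tkey, sep = "\r")
  upat <- unique(pat_key)
  seg_pat <- match(pat_key, upat)
  first <- match(upat, pat_key)
  pat_covrow <- seg_covrow[first]
  pat_teval <- seg_tmid[first]
  # distinct (pattern, dt) exponentials
  key <- paste(seg_pat, sprintf("%.12g", seg_dt), sep = "\r")
  ukey <- unique(key)
  seg_key <- match(key, ukey)
  kfirst <- match(ukey, key)

  # static emission/indicator weights when there is no emission model
  E <- NULL
  if (is.null(spec$emission)) {
    E <- matrix(0, ns, length(v_state))
    for (v in seq_along(v_state)) {
      if (v_exact[v] > 0L) E[, v] <- 1 else E[v_state[[v]], v] <- 1
    }
  }
  emis_z <- NULL
  if (!is.null(spec$emission)) {
    zc <- c(use$emis, use$blocked)
    emis_z <- matrix(NA_real_, length(v_state), length(zc),
                     dimnames = list(NULL, zc))
    vi <- 0L
    for (si in seq_len(n_series)) {
      rows <- series[[si]]
      cv <- as.data.frame(data[rows, zc, drop = FALSE])
      if (use_pseudo) cv <- rbind(cv[1, , drop = FALSE], cv)
      for (r in seq_len(nrow(cv)))
        emis_z[vi + r, ] <- as.numeric(cv[r, ])
      vi <- vi + nrow(cv)
    }
  }
  structure(list(
    n_states = ns, series_id = names(series), n_series = n_series,
    n_visits = n_visits, gap_nseg = gap_nseg, gap_exact = gap_exact,
    seg_dt = seg_dt, seg_pat = seg_pat, seg_key = seg_key,
    key_pat = seg_pat[kfirst], key_dt = seg_dt[kfirst],
    pat_covrow = pat_covrow, pat_teval = pat_teval, cov_rows = cov_rows,
    v_state = v_state, v_exact = v_exact, E = E, emis_z = emis_z,
    init_vec = init_vec, cond_visits = as.integer(condition),
    pseudo = use_pseudo,
    series_subject = vapply(series, function(r) as.character(
      data$subject[r[1]]), "")),
    class = "pm_prep")
}

build_Q_cube <- function(spec, resolved, prep, u = 1) {
  npat <- length(prep$pat_teval)
  Q <- array(0, dim = c(prep$n_states, prep$n_states, npat))
  for (p in seq_len(npat)) {
    Q[, , p] <- intensity_matrix(spec,
                                 covariates = prep$cov_rows[[
                                   prep$pat_covrow[p]]],
                                 t = prep$pat_teval[p], frailty = u,
                                 resolved = resolved)
  }
  Q
}

build_E <- function(spec, prep, params) {
  if (!is.null(prep$E)) return(prep$E)
  em <- spec$emission
  ns <- prep$n_states
  M <- emission_prob_rows(em, params, prep$emis_z)  # n_visit x 3 hidden rows?
  E <- matrix(0, ns, length(prep$v_state))
  for (v in seq_along(prep$v_state)) {
    if (prep$v_exact[v] > 0L) { E[, v] <- 1; next }
    set <- prep$v_state[[v]]
    if (length(set) == ns) { E[, v] <- 1; next }
    for (o in set) E[, v] <- E[, v] + M[[o]][v, ]
  }
  E
}

#' Total panel log-likelihood
#'
#' Sums per-series forward-algorithm contributions.  Series whose observed
#' sequence has probability zero contribute \code{-Inf}.
#'
#' @param spec a \code{pm_spec}
#' @param data a \code{pm_panel} (ignored when \code{prep} is given)
#' @param params named natural-scale parameters
#' @param prep optional precomputed \code{\link{pm_prepare}} object
#' @param u frailty multiplier applied to all intensities
#' @param per_series return the vector of per-series contributions
#' @export
total_loglik <- function(spec, data = NULL, params, prep = NULL, u = 1,
                         per_series = FALSE) {
  if (is.null(prep)) {
    if (is.null(data) || nrow(data) == 0) return(0)
    prep <- pm_prepare(spec, data)
  }
  resolved <- resolve_parameters(spec, params)
  Q <- build_Q_cube(spec, resolved, prep, u = u)
  P <- cpp_expm_cube(Q, prep$key_pat, prep$key_dt)
  # numerical overflow in expm (very large rates) shows up as entries
  # outside [0, 1]: treat the whole evaluation as invalid
  if (!all(is.finite(P)) || any(P < -1e-8) || any(P > 1 + 1e-8)) {
    ll <- rep(-Inf, prep$n_series)
    return(if (per_series) ll else -Inf)
  }
  E <- build_E(spec, prep, params)
  init <- matrix(prep$init_vec, prep$n_states, prep$n_series)
  ll <- cpp_forward(P, Q, prep$seg_key, prep$seg_pat, prep$seg_dt,
                    prep$gap_exact, prep$gap_nseg, prep$n_visits, init, E,
                    prep$v_exact, prep$cond_visits)
  if (per_series) ll else sum(ll)
}

#' Log-likelihood contribution of one subject
#' @param records the subject's rows of a \code{pm_panel}
#' @inheritParams total_loglik
#' @export
subject_loglik <- function(spec, records, params, u = 1) {
  total_loglik(spec, pm_panel(records), params, u = u)
}

#' Forward-algorithm log-likelihood with an explicit initial distribution
#'
#' Computes \eqn{\log P(O_1, \ldots, O_n)} for one observed series under the
#' hidden-state model: the initial distribution is weighted by the first
#' visit's emission, then transition and emission weighting alternate.
#'
#' @inheritParams subject_loglik
#' @param init prior distribution over hidden states at the first visit
#'   (default: the spec's initialization rule)
#' @param condition number of leading visits to condition on (default 0)
#' @export
forward_loglik <- function(spec, records, params, init = NULL,
                           condition = 0L) {
  prep <- pm_prepare(spec, pm_panel(records), init = init,
                     condition = if (is.null(init)) NULL else condition)
  if (!is.null(init)) prep$cond_visits <- as.integer(condition)
  total_loglik(spec, params = params, prep = prep)
}

#' Transition probability matrix over an interval
#'
#' Ordered product of matrix exponentials over the sub-intervals on which
#' the generator is (taken as) constant.  Splitting an interval at an
#' arbitrary interior point leaves the result unchanged, and
#' \eqn{P(t_0,t_2) = P(t_0,t_1) P(t_1,t_2)} (Chapman-Kolmogorov).
#'
#' @inheritParams total_loglik
#' @param covariates named covariate values in force throughout the interval
#' @param t0,t1 interval endpoints, \code{t0 <= t1}
#' @param frailty positive multiplier on all intensities
#' @export
transition_probability <- function(spec, params, covariates = NULL, t0, t1,
                                   frailty = 1) {
  stopifnot(t0 <= t1)
  ns <- spec$n_states
  if (t1 == t0) return(diag(ns))
  resolved <- resolve_parameters(spec, params)
  b <- segment_breaks(spec, t0, t1)
  mid <- (b[-length(b)] + b[-1]) / 2
  if (spec_has_weibull(spec)) mid <- weibull_eval_times(spec, mid)
  P <- diag(ns)
  for (i in seq_len(length(b) - 1)) {
    Q <- intensity_matrix(spec, covariates = covariates, t = mid[i],
                          frailty = frailty, resolved = resolved)
    P <- P %*% cpp_expm(Q, b[i + 1] - b[i])
  }
  dimnames(P) <- list(spec$states, spec$states)
  P
}

# Canonical generator-evaluation time for a segment with midpoint `mid`
# under a Weibull (continuously time-varying) baseline: the midpoint of the
# absolute grid cell (step meta$time_step) intersected with the
# inter-cutpoint interval containing the segment.  Partial segments of the
# same cell share one generator, so splitting an interval anywhere leaves
# the transition probability exactly unchanged.
weibull_eval_times <- function(spec, mid) {
  h <- spec$meta$time_step %||% 0.25
  glo <- floor(mid / h + 1e-9) * h
  ghi <- glo + h
  cuts <- spec_cutpoints(spec)
  if (length(cuts)) {
    i <- findInterval(mid, cuts)
    clo <- ifelse(i > 0, cuts[pmax(i, 1)], 0)
    chi <- ifelse(i < length(cuts), cuts[pmin(i + 1, length(cuts))], Inf)
    glo <- pmax(glo, clo)
    ghi <- pmin(ghi, chi)
  }
  (pmax(glo, 0) + ghi) / 2
}

segment_breaks <- function(spec, t0, t1) {
  cuts <- spec_cutpoints(spec)
  b <- c(t0, cuts[cuts > t0 + 1e-12 & cuts < t1 - 1e-12])
  if (spec_has_weibull(spec)) {
    h <- spec$meta$time_step %||% 0.25
    gr <- seq(ceiling(t0 / h - 1e-9), floor(t1 / h + 1e-9)) * h
    b <- c(b, gr[gr > t0 + 1e-12 & gr < t1 - 1e-12])
  }
  sort(unique(c(b, t1)))
}

#' State-occupancy probabilities over a time grid
#'
#' @inheritParams transition_probability
#' @param initial_state 1-based starting state, or a distribution over states
#' @param times increasing time grid; occupancy is computed from
#'   \code{times[1]}
#' @return matrix (length(times) x n_states) of occupancy probabilities;
#'   rows sum to 1
#' @export
state_occupancy <- function(spec, params, covariates = NULL, initial_state,
                            times, frailty = 1) {
  stopifnot(!is.unsorted(times))
  ns <- spec$n_states
  p <- if (length(initial_state) == 1) {
    v <- numeric(ns); v[initial_state] <- 1; v
  } else as.numeric(initial_state)
  out <- matrix(NA_real_, length(times), ns,
                dimnames = list(NULL, spec$states))
  out[1, ] <- p
  for (i in seq_along(times)[-1]) {
    P <- transition_probability(spec, params, covariates, times[i - 1],
                                times[i], frailty = frailty)
    p <- as.numeric(p %*% P)
    out[i, ] <- p
  }
  out
}

#' Expected length of stay per state over [t0, t0 + horizon]
#'
#' Integrates the occupancy probabilities by composite Simpson quadrature
#' with grid doubling until the estimates change by less than \code{tol}
#' (relative to the horizon).  The components sum to the horizon.
#'
#' @inheritParams state_occupancy
#' @param horizon positive time horizon
#' @param t0 start of the integration window
#' @param tol relative tolerance of the quadrature
#' @export
length_of_stay <- function(spec, params, covariates = NULL, initial_state,
                           horizon, t0 = 0, tol = 1e-8) {
  stopifnot(horizon > 0)
  n <- 32L
  prev <- NULL
  repeat {
    times <- t0 + seq(0, horizon, length.out = n + 1L)
    occ <- state_occupancy(spec, params, covariates, initial_state, times)
    los <- apply(occ, 2, simpson, h = horizon / n)
    if (!is.null(prev) && max(abs(los - prev)) < tol * horizon) break
    if (n >= 4096L) break
    prev <- los
    n <- n * 2L
  }
  los
}
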