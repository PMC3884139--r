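# Five-state semi-competing-risks model with an unobservable state.
#
# States: H (healthy), NF (observed non-fatal event), LTF (lost to
# follow-up for the non-fatal process), NF_LTF (an unobservable non-fatal
# event after loss to follow-up), F (fatal event, absorbing).  Mortality is
# always observed; after loss to follow-up nothing is observed until death
# or administrative end of study.  Identifiability requires two structural
# assumptions: lambda3 = lambda7 (risk of death after a non-fatal event does
# not depend on loss to follow-up), and the ratio constraint
#   lambda1 / lambda2 = k * lambda5 / lambda6,
# so lambda5(t) = lambda1(t) lambda6(t) / (k lambda2(t)) with k > 0 a fixed,
# non-estimable sensitivity parameter.

WH_TRANS <- data.frame(
  from = c(1, 1, 2, 1, 3, 3, 4),
  to   = c(2, 5, 5, 3, 4, 5, 5))
WH_STATES <- c("H", "NF", "LTF", "NF_LTF", "F")

#' Build the five-state semi-competing-risks model
#'
#' Seven Weibull proportional intensities lambda1: H->NF, lambda2: H->F,
#' lambda3: NF->F, lambda4: H->LTF, lambda5: LTF->NF_LTF (derived),
#' lambda6: LTF->F, lambda7: NF_LTF->F (structurally equal to lambda3).
#'
#' @param k positive sensitivity constant (fixed, never estimated)
#' @param terms named list of covariate-term vectors for transitions
#'   \code{lam1}, \code{lam2}, \code{lam3}, \code{lam4}, \code{lam6}
#'   (each a named character vector covariate -> coefficient label);
#'   lambda7 shares lambda3's terms, lambda5's effects are derived
#' @param share_f_effects if TRUE, covariate labels supplied for
#'   \code{lam2} are reused for all transitions into F (lam3/lam7, lam6),
#'   so the explanatory-variable effects on mortality are common
#' @return a \code{pm_spec} with \code{meta$model == "whitehall"}
#' @export
build_whitehall_model <- function(k = 1, terms = list(),
                                  share_f_effects = FALSE) {
  if (!is.numeric(k) || length(k) != 1 || k <= 0)
    stop("k must be a positive number", call. = FALSE)
  gt <- function(nm) terms[[nm]] %||% character()
  t3 <- if (share_f_effects && length(gt("lam2"))) gt("lam2") else gt("lam3")
  t6 <- if (share_f_effects && length(gt("lam2"))) gt("lam2") else gt("lam6")
  wb <- function(i) bl_weibull(labels = c(paste0("a", i), paste0("b", i)))
  pm_spec(states = WH_STATES, transitions = WH_TRANS,
          baselines = list(wb(1), wb(2), wb(3), wb(4),
                           derived_ratio_product(num = c(1, 6), den = 2,
                                                 k = "k"),
                           wb(6), wb(3)),  # lambda7 shares lambda3's labels
          terms = list(gt("lam1"), gt("lam2"), t3, gt("lam4"),
                       character(), t6, t3),
          fixed = c(k = k),
          unobservable = "NF_LTF",
          meta = list(model = "whitehall", time_step = 0.125))
}

# classify each subject's record rows into one of the supported histories
wh_parse_subject <- function(tt, st, ex) {
  if (st[1] != "1" || ex[1] == 1L)
    stop("a history must start with an ordinary observation in H",
         call. = FALSE)
  n <- length(tt)
  # supported shapes: H only; H,NF[,F]; H,F; H,LTF[,F | ,"3,4"]
  out <- list(entry = tt[1])
  if (n == 1) { out$type <- "H_censored"; out$cens <- tt[1]; return(out) }
  s2 <- st[2]; e2 <- ex[2]; t2 <- tt[2]
  if (e2 == 0L && s2 == "1") {
    if (n > 2) stop("unsupported history", call. = FALSE)
    out$type <- "H_censored"; out$cens <- t2; return(out)
  }
  if (e2 == 1L && s2 == "5") {
    if (n > 2) stop("no events may follow death", call. = FALSE)
    out$type <- "death_from_H"; out$death <- t2; return(out)
  }
  if (e2 == 1L && s2 == "2") {
    out$nf <- t2
    if (n == 2) { out$type <- "NF_censored"; out$cens <- t2; return(out) }
    s3 <- st[3]; t3 <- tt[3]
    if (ex[3] == 1L && s3 == "5") { out$type <- "NF_death"; out$death <- t3 }
    else if (ex[3] == 0L && s3 == "2") { out$type <- "NF_censored"
      out$cens <- t3 }
    else stop("unsupported history after NF", call. = FALSE)
    if (n > 3) stop("unsupported history", call. = FALSE)
    return(out)
  }
  if (e2 == 1L && s2 == "3") {
    out$ltf <- t2
    if (n == 2) { out$type <- "LTF_end"; out$end <- t2; return(out) }
    s3 <- st[3]; t3 <- tt[3]
    if (ex[3] == 1L && s3 == "5") { out$type <- "LTF_death"
      out$death <- t3 }
    else if (ex[3] == 0L && s3 %in% c("3,4", "*")) { out$type <- "LTF_end"
      out$end <- t3 }
    else stop("unsupported history after LTF", call. = FALSE)
    if (n > 3) stop("unsupported history", call. = FALSE)
    return(out)
  }
  stop("unsupported history", call. = FALSE)
}

wh_multipliers <- function(spec, resolved, covrow) {
  vapply(seq_len(7), function(i) {
    cf <- resolved[[i]]$coefs
    if (!length(cf)) return(1)
    x <- unlist(covrow[names(cf)], use.names = FALSE)
    if (length(x) != length(cf) || anyNA(x))
      stop("missing covariate(s) for the semi-competing model",
           call. = FALSE)
    exp(sum(cf * x))
  }, 0)
}

# survival in LTF from l to s (no further event of either kind)
wh_SL <- function(bl5, bl6, m5, m6, l, s) {
  exp(-m5 * baseline_cumhaz(bl5, l, s) - m6 * baseline_cumhaz(bl6, l, s))
}

# marginal post-LTF quantities by Gauss-Legendre quadrature over the
# unobserved time of the non-fatal event
wh_post_ltf <- function(resolved, m, l, t, what = c("alive", "death"),
                        n_nodes = 25) {
  what <- match.arg(what)
  bl5 <- resolved[[5]]$baseline; bl6 <- resolved[[6]]$baseline
  bl7 <- resolved[[7]]$baseline
  m5 <- m[5]; m6 <- m[6]; m7 <- m[7]
  if (t <= l) return(if (what == "alive") 1 else 0)
  gl <- gauss_legendre(n_nodes, l, t)
  s <- gl$nodes
  f <- wh_SL(bl5, bl6, m5, m6, l, s) * m5 * baseline_hazard(bl5, s) *
    exp(-m7 * baseline_cumhaz(bl7, s, t))
  via_nf <- sum(gl$weights * f)
  if (what == "alive") {
    wh_SL(bl5, bl6, m5, m6, l, t) + via_nf
  } else {
    wh_SL(bl5, bl6, m5, m6, l, t) * m6 * baseline_hazard(bl6, t) +
      via_nf * m7 * baseline_hazard(bl7, t)
  }
}

# classify all subjects once; the per-evaluation work is then fully
# vectorized over subjects (and quadrature nodes for the post-LTF part)
wh_prepare <- function(spec, data) {
  data <- pm_panel(data)
  covcols <- panel_cov_cols(data)
  series <- panel_series(data)
  n <- length(series)
  type <- character(n)
  t_ev <- t_end <- rep(NA_real_, n)   # first-event time, final time
  covs <- vector("list", n)
  for (si in seq_len(n)) {
    rows <- series[[si]]
    hist <- wh_parse_subject(data$time[rows], data$state[rows],
                             data$exact[rows])
    type[si] <- hist$type
    t_ev[si] <- hist$nf %||% hist$ltf %||% NA_real_
    t_end[si] <- hist$cens %||% hist$death %||% hist$end
    covs[[si]] <- as.list(data[rows[1], covcols, drop = FALSE])
  }
  # per-transition design matrices for the covariate multipliers
  X <- lapply(seq_len(7), function(i) {
    nm <- names(spec$terms[[i]])
    if (i == 5) nm <- unique(unlist(lapply(spec$terms[c(1, 6, 2)], names)))
    if (!length(nm)) return(NULL)
    out <- do.call(rbind, lapply(covs, function(cv)
      unlist(cv[nm], use.names = FALSE)))
    colnames(out) <- nm
    out
  })
  list(type = type, t_ev = t_ev, t_end = t_end, X = X,
       terms5 = NULL, n = n)
}

wh_mult_matrix <- function(spec, resolved, prep) {
  m <- matrix(1, prep$n, 7)
  for (i in seq_len(7)) {
    cf <- resolved[[i]]$coefs
    if (!length(cf) || is.null(prep$X[[i]])) next
    Xi <- prep$X[[i]]
    beta <- cf[colnames(Xi)]
    if (anyNA(beta)) stop("covariate/coefficient mismatch", call. = FALSE)
    m[, i] <- exp(as.numeric(Xi %*% beta))
  }
  m
}

wh_eval <- function(spec, resolved, prep, n_nodes = 25) {
  bl <- lapply(resolved, `[[`, "baseline")
  m <- wh_mult_matrix(spec, resolved, prep)
  H <- function(i, t0, t1) baseline_cumhaz(bl[[i]], t0, t1)
  hz <- function(i, t) baseline_hazard(bl[[i]], t)
  ll <- numeric(prep$n)
  tp <- prep$type; te <- prep$t_ev; tn <- prep$t_end
  surv_H <- function(i, t) -(m[i, 1] * H(1, 0, t) + m[i, 2] * H(2, 0, t) +
                               m[i, 4] * H(4, 0, t))
  i <- tp == "H_censored"
  ll[i] <- surv_H(i, tn[i])
  i <- tp == "death_from_H"
  ll[i] <- surv_H(i, tn[i]) + log(m[i, 2] * hz(2, tn[i]))
  i <- tp %in% c("NF_censored", "NF_death")
  ll[i] <- surv_H(i, te[i]) + log(m[i, 1] * hz(1, te[i])) -
    m[i, 3] * H(3, te[i], tn[i])
  i <- tp == "NF_death"
  ll[i] <- ll[i] + log(m[i, 3] * hz(3, tn[i]))
  i <- which(tp %in% c("LTF_end", "LTF_death"))
  if (length(i)) {
    l <- te[i]; Tt <- tn[i]
    ll[i] <- surv_H(i, l) + log(m[i, 4] * hz(4, l))
    gl <- gauss_legendre(n_nodes)
    # nodes/weights mapped to [l, T] per subject: matrices (subject x node)
    s <- outer((Tt - l) / 2, gl$nodes) + (Tt + l) / 2
    w <- outer((Tt - l) / 2, gl$weights)
    SL <- function(a, b) exp(-m[i, 5] * (H(5, 0, b) - H(5, 0, a)) -
                               m[i, 6] * (H(6, 0, b) - H(6, 0, a)))
    integrand <- SL(l, s) * m[i, 5] * hz(5, s) *
      exp(-m[i, 7] * (H(7, 0, Tt) - H(7, 0, s)))
    via_nf <- rowSums(w * integrand)
    dead <- tp[i] == "LTF_death"
    p <- ifelse(dead,
                SL(l, Tt) * m[i, 6] * hz(6, Tt) +
                  via_nf * m[i, 7] * hz(7, Tt),
                SL(l, Tt) + via_nf)
    ll[i] <- ll[i] + log(p)
  }
  ll
}

#' Log-likelihood for the semi-competing-risks model
#'
#' Pre-loss-to-follow-up events (non-fatal event, death, loss to follow-up)
#' contribute exact-time hazard and survival terms in closed form; after an
#' exact loss to follow-up the subject's state is marginalized over
#' \{LTF, NF_LTF\} by Gauss-Legendre quadrature over the unobserved
#' non-fatal event time.  Administrative end of study contributes the
#' probability of being alive.
#'
#' @param spec a \code{\link{build_whitehall_model}} spec
#' @param data a \code{pm_panel} in the five-state encoding (states
#'   1=H, 2=NF, 3=LTF, 5=F; post-LTF administrative end recorded as the
#'   censoring set \code{"3,4"}); events carry \code{exact = 1}
#' @param params named natural-scale parameters
#' @param per_subject return per-subject contributions
#' @param prep optional precomputed \code{wh_prepare} skeleton
#' @export
whitehall_total_loglik <- function(spec, data, params,
                                   per_subject = FALSE, prep = NULL) {
  if (is.null(prep)) prep <- wh_prepare(spec, data)
  resolved <- resolve_parameters(spec, params)
  ll <- wh_eval(spec, resolved, prep)
  if (per_subject) ll else sum(ll)
}

#' @rdname whitehall_total_loglik
#' @param records one subject's rows
#' @export
whitehall_subject_loglik <- function(spec, records, params) {
  whitehall_total_loglik(spec, pm_panel(records), params)
}

#' Cumulative incidence of the first coronary event
#'
#' Probability that the first event of the disease process (entry into NF,
#' NF_LTF, or F directly from H) has occurred by each grid time: states H
#' and LTF are exactly the event-free states, so
#' \deqn{CIF(t) = 1 - p_H(t) - p_{LTF}(t).}
#'
#' @inheritParams whitehall_total_loglik
#' @param covariates named covariate values
#' @param grid increasing times starting at 0
#' @param n_nodes quadrature order for the LTF-occupancy integral
#' @export
chd_cumulative_incidence <- function(spec, params, covariates = NULL, grid,
                                     n_nodes = 40) {
  stopifnot(!is.unsorted(grid), grid[1] >= 0)
  resolved <- resolve_parameters(spec, params)
  bl <- lapply(resolved, `[[`, "baseline")
  m <- wh_multipliers(spec, resolved, as.list(covariates %||% list()))
  SH <- function(t) exp(-(m[1] * baseline_cumhaz(bl[[1]], 0, t) +
                            m[2] * baseline_cumhaz(bl[[2]], 0, t) +
                            m[4] * baseline_cumhaz(bl[[4]], 0, t)))
  p_ltf <- function(t) {
    if (t <= 0) return(0)
    gl <- gauss_legendre(n_nodes, 0, t)
    s <- gl$nodes
    f <- SH(s) * m[4] * baseline_hazard(bl[[4]], s) *
      exp(-m[5] * baseline_cumhaz(bl[[5]], s, t) -
            m[6] * baseline_cumhaz(bl[[6]], s, t))
    sum(gl$weights * f)
  }
  cif <- vapply(grid, function(t) 1 - SH(t) - p_ltf(t), 0)
  pmin(pmax(cif, 0), 1)
}

#' Five-state occupancy by Runge-Kutta integration
#'
#' Solves the Kolmogorov forward equations \eqn{p'(t) = p(t) Q(t)} with the
#' time-varying Weibull generator by classical fourth-order Runge-Kutta on a
#' fixed step; used for occupancy summaries and as a cross-check of the
#' quadrature-based marginalization.
#'
#' @inheritParams chd_cumulative_incidence
#' @param init initial distribution over the five states
#' @param n_steps number of RK4 steps per unit time
#' @export
whitehall_occupancy <- function(spec, params, covariates = NULL, grid,
                                init = c(1, 0, 0, 0, 0), n_steps = 64) {
  stopifnot(!is.unsorted(grid))
  resolved <- resolve_parameters(spec, params)
  Qf <- function(t) intensity_matrix(spec, covariates = covariates, t = t,
                                     resolved = resolved)
  p <- as.numeric(init)
  out <- matrix(NA_real_, length(grid), spec$n_states,
                dimnames = list(NULL, spec$states))
  out[1, ] <- p
  for (i in seq_along(grid)[-1]) {
    t0 <- grid[i - 1]; t1 <- grid[i]
    nh <- max(1L, ceiling((t1 - t0) * n_steps))
    hstep <- (t1 - t0) / nh
    for (s in seq_len(nh)) {
      tc <- t0 + (s - 1) * hstep
      k1 <- p %*% Qf(tc)
      k2 <- (p + hstep / 2 * k1) %*% Qf(tc + hstep / 2)
      k3 <- (p + hstep / 2 * k2) %*% Qf(tc + hstep / 2)
      k4 <- (p + hstep * k3) %*% Qf(tc + hstep)
      p <- p + hstep / 6 * as.numeric(k1 + 2 * k2 + 2 * k3 + k4)
    }
    out[i, ] <- p
  }
  out
}
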