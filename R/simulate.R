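# Seeded synthetic-data generators.  A single root seed fans out to
# per-subject substreams (substream_seed), so subject-level output is
# reproducible independently of generation order.

#' Simulate one continuous-time path of a multi-state process
#'
#' Competing-risks simulation: in each occupied state the exit time is drawn
#' by inverting the cumulative exit hazard (closed-form within the pieces
#' defined by baseline cutpoints and covariate-change times, root found by
#' bisection to 1e-10), and the destination is drawn proportionally to the
#' transition intensities at the jump time.
#'
#' @param spec a \code{pm_spec}
#' @param params named natural-scale parameters
#' @param init_state starting state (1-based)
#' @param t_max follow-up horizon
#' @param covariates either a named list (time-constant) or a data.frame
#'   with a \code{time} column giving a piecewise-constant trajectory
#' @param u frailty multiplier
#' @param t0 start time
#' @return data.frame with columns \code{time}, \code{state}: the initial
#'   record plus one row per jump
#' @export
simulate_path <- function(spec, params, init_state = 1, t_max,
                          covariates = NULL, u = 1, t0 = 0) {
  stopifnot(t_max > t0)
  resolved <- resolve_parameters(spec, params)
  tr <- spec$transitions
  cov_times <- 0
  cov_at <- function(t) covariates
  if (is.data.frame(covariates)) {
    cov_times <- covariates$time
    cov_at <- function(t) {
      i <- findInterval(t, cov_times)
      as.list(covariates[max(i, 1), setdiff(names(covariates), "time"),
                         drop = FALSE])
    }
  }
  cuts <- spec_cutpoints(spec)
  mult <- function(i, cv) {
    cf <- resolved[[i]]$coefs
    if (!length(cf)) return(1)
    exp(sum(cf * unlist(cv[names(cf)], use.names = FALSE)))
  }
  exit_cumhaz <- function(j, a, b) {
    if (b <= a) return(0)
    brk <- sort(unique(c(a, b, cuts[cuts > a & cuts < b],
                         cov_times[cov_times > a & cov_times < b])))
    tot <- 0
    which_tr <- which(tr$from == j)
    for (p in seq_len(length(brk) - 1)) {
      cv <- cov_at(brk[p])
      for (i in which_tr)
        tot <- tot + u * mult(i, cv) *
          baseline_cumhaz(resolved[[i]]$baseline, brk[p], brk[p + 1])
    }
    tot
  }
  times <- t0; states <- init_state
  s <- init_state; tcur <- t0
  # fast path: time-homogeneous generator and static covariates
  if (!is.data.frame(covariates) && !spec_has_weibull(spec) &&
      !length(cuts)) {
    repeat {
      cand <- which(tr$from == s)
      if (!length(cand)) break
      w <- vapply(cand, function(i) u * mult(i, covariates) *
                    resolved[[i]]$baseline$params[1], 0)
      tot <- sum(w)
      if (tot <= 0) break
      tcur <- tcur + stats::rexp(1, tot)
      if (tcur >= t_max) break
      s <- tr$to[cand[sample.int(length(cand), 1, prob = w)]]
      times <- c(times, tcur); states <- c(states, s)
    }
    return(data.frame(time = times, state = states))
  }
  repeat {
    if (!any(tr$from == s)) break  # absorbing
    E <- stats::rexp(1)
    if (exit_cumhaz(s, tcur, t_max) < E) break
    lo <- tcur; hi <- t_max
    while (hi - lo > 1e-10) {
      mid <- (lo + hi) / 2
      if (exit_cumhaz(s, tcur, mid) < E) lo <- mid else hi <- mid
    }
    tjump <- (lo + hi) / 2
    cv <- cov_at(tjump)
    cand <- which(tr$from == s)
    w <- vapply(cand, function(i) mult(i, cv) *
                  baseline_hazard(resolved[[i]]$baseline, tjump), 0)
    s <- tr$to[cand[sample.int(length(cand), 1, prob = w)]]
    tcur <- tjump
    times <- c(times, tjump); states <- c(states, s)
    if (tcur >= t_max) break
  }
  data.frame(time = times, state = states)
}

#' Read the state of a simulated path at given visit times
#'
#' @param path a \code{\link{simulate_path}} result
#' @param visit_times increasing observation times
#' @return data.frame with columns \code{time}, \code{state}
#' @export
observe_panel <- function(path, visit_times) {
  stopifnot(!is.unsorted(visit_times))
  i <- findInterval(visit_times, path$time)
  data.frame(time = visit_times, state = path$state[pmax(i, 1)])
}

# ---- scenario simulators ---------------------------------------------------

#' Simulate remission-style active-joint-count data
#'
#' Hidden three-state dynamics (active S1 -> early remission S2 ->
#' established remission S3 -> S1) with counts generated as: zero whenever
#' in remission (structural zero); in S1, a sampling zero with probability
#' \eqn{\mathrm{logit}^{-1}(\gamma_0 + \gamma_Z Z)} where Z = 1 at the first
#' zero of a run, except that a third consecutive zero is impossible in S1.
#'
#' @param n subjects
#' @param n_visits visits per subject (roughly annual, gamma-jittered)
#' @param params named rates \code{q12, q23, q31} and emission coefficients
#'   \code{gamma0, gammaZ}
#' @param entry_max uniform upper bound of the delayed-entry time (years
#'   after diagnosis)
#' @param seed root seed
#' @param mechanism \code{"counts"} draws active-joint counts
#'   mechanistically (zero whenever in remission) and returns a count table
#'   consumable by \code{\link{recode_zero_runs}}; \code{"model"} draws
#'   observed codes directly from the Model A emission law (the exact
#'   probability law the fit maximizes, used for parameter-recovery checks)
#'   and returns a model-ready \code{pm_panel}
#' @return data.frame subject, time, count (\code{mechanism = "counts"}) or
#'   a \code{pm_panel} with code states and emission covariates
#'   (\code{mechanism = "model"})
#' @export
sim_remission <- function(n = 400, n_visits = 12,
                          params = c(q12 = 0.15, q23 = 2.0, q31 = 0.25,
                                     gamma0 = -1, gammaZ = 2),
                          entry_max = 3, seed = 1,
                          mechanism = c("counts", "model")) {
  mechanism <- match.arg(mechanism)
  hid <- pm_spec(states = c("S1", "S2", "S3"),
                 transitions = data.frame(from = c(1, 2, 3), to = c(2, 3, 1)),
                 baselines = list(bl_constant(labels = "q12"),
                                  bl_constant(labels = "q23"),
                                  bl_constant(labels = "q31")))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(substream_seed(seed, i))
    entry <- stats::runif(1, 0, entry_max)
    gaps <- stats::rgamma(n_visits - 1, shape = 16, rate = 16)
    tt <- entry + c(0, cumsum(gaps))
    horizon <- max(tt) + 1
    path <- simulate_path(hid, params[c("q12", "q23", "q31")],
                          init_state = 1, t_max = horizon)
    st <- observe_panel(path, tt)$state
    if (mechanism == "counts") {
      counts <- integer(n_visits)
      run <- 0L
      for (v in seq_len(n_visits)) {
        if (st[v] != 1) {
          counts[v] <- 0L
        } else if (run >= 2L) {
          counts[v] <- 1L + stats::rpois(1, 2)
        } else {
          z <- as.numeric(run == 0L)
          p <- invlogit(params[["gamma0"]] + params[["gammaZ"]] * z)
          counts[v] <- if (stats::runif(1) < p) 0L
                       else 1L + stats::rpois(1, 2)
        }
        run <- if (counts[v] == 0L) run + 1L else 0L
      }
      out[[i]] <- data.frame(subject = i, time = tt, count = counts)
    } else {
      # draw codes from the emission law; run counts observed zero-like
      # codes (O2 or O3), so Z and the structural block are deterministic
      # functions of the observed past, exactly as the likelihood sees them
      code <- integer(n_visits); zf <- numeric(n_visits)
      bl <- integer(n_visits)
      run <- 0L
      for (v in seq_len(n_visits)) {
        zf[v] <- as.numeric(run == 0L)
        bl[v] <- as.integer(run >= 2L)
        code[v] <- if (st[v] == 1L) {
          p <- if (bl[v] == 1L) 0 else
            invlogit(params[["gamma0"]] + params[["gammaZ"]] * zf[v])
          if (stats::runif(1) < p) 2L else 1L
        } else if (st[v] == 2L) 2L else 3L
        run <- if (code[v] >= 2L) run + 1L else 0L
      }
      out[[i]] <- data.frame(subject = i, time = tt, state = code,
                             exact = 0L, Z = zf, blocked = bl)
    }
  }
  res <- do.call(rbind, out)
  if (mechanism == "model") pm_panel(res) else res
}

#' Simulate semi-competing-risks cohort data
#'
#' Exact non-fatal event, death and loss-to-follow-up times over a fixed
#' administrative horizon; after loss to follow-up only the death time (if
#' any) is recorded, otherwise the subject ends in the censoring set
#' \{LTF, NF_LTF\}.
#'
#' @param n subjects
#' @param params named Weibull parameters \code{a1,b1,...,a6,b6} (a3/b3
#'   shared with lambda7)
#' @param k sensitivity constant used for the generating lambda5
#' @param horizon administrative end of study
#' @param seed root seed
#' @return a \code{pm_panel} in the five-state encoding
#' @export
sim_whitehall <- function(n = 2000,
                          params = c(a1 = 0.004, b1 = 1.3, a2 = 0.0015,
                                     b2 = 1.4, a3 = 0.03, b3 = 1.1,
                                     a4 = 0.02, b4 = 1.1, a6 = 0.002,
                                     b6 = 1.4),
                          k = 1, horizon = 15, seed = 1) {
  spec <- build_whitehall_model(k = k)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(substream_seed(seed, i))
    path <- simulate_path(spec, params, init_state = 1, t_max = horizon)
    rec <- data.frame(subject = i, time = 0, state = "1", exact = 0L)
    ns <- nrow(path)
    add <- function(t, s, e) rbind(rec, data.frame(subject = i, time = t,
                                                   state = s, exact = e))
    if (ns == 1) {
      rec <- add(horizon, "1", 0L)
    } else if (path$state[2] == 5) {
      rec <- add(path$time[2], "5", 1L)
    } else if (path$state[2] == 2) {
      rec <- add(path$time[2], "2", 1L)
      if (ns >= 3 && path$state[3] == 5)
        rec <- add(path$time[3], "5", 1L)
      else rec <- add(horizon, "2", 0L)
    } else { # LTF
      rec <- add(path$time[2], "3", 1L)
      death <- path$time[path$state == 5]
      if (length(death)) rec <- add(death[1], "5", 1L)
      else rec <- add(horizon, "3,4", 0L)
    }
    out[[i]] <- rec
  }
  pm_panel(do.call(rbind, out))
}

#' Simulate jointly observed (Y, W) panel data
#'
#' The combined process evolves on the expanded m x n lattice; (Y, W) is
#' recorded jointly at protocol visits only.
#'
#' @param n subjects
#' @param space an \code{\link{expand_state_space}} result
#' @param params named parameters of the expanded model
#' @param visit_times shared protocol visit times
#' @param seed root seed
#' @return data.frame subject, time, Y, W
#' @export
sim_expanded <- function(n = 300, space = expand_state_space(3, 3), params,
                         visit_times = 0:9, seed = 1) {
  spec <- build_expanded_model(space)
  m <- space$m
  out <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(substream_seed(seed, i))
    w0 <- sample.int(space$n, 1)
    path <- simulate_path(spec, params,
                          init_state = space$index(1, w0),
                          t_max = max(visit_times) + 1e-9)
    st <- observe_panel(path, visit_times)$state
    out[[i]] <- data.frame(subject = i, time = visit_times,
                           Y = (st - 1) %% m + 1, W = (st - 1) %/% m + 1)
  }
  do.call(rbind, out)
}

#' Simulate clustered paired-joint damage data
#'
#' One gamma frailty per subject shared by all location processes; binary
#' activity/tenderness/effusion indicators evolve at visit level and are
#' piecewise constant between visits; damage states are read at visits.
#'
#' @param n subjects
#' @param n_loc joint locations per subject
#' @param params damage-model parameters (baselines, offsets, optional
#'   covariate effects)
#' @param theta frailty variance
#' @param visit_times shared visit schedule
#' @param spec the generating \code{\link{build_damage_model}} spec
#' @param seed root seed
#' @return a \code{pm_panel} with one unit per location
#' @export
sim_damage <- function(n = 300, n_loc = 14,
                       params = c(lam012 = 0.02, lam013 = 0.02,
                                  gamma24 = 1.0, gamma34 = 1.0),
                       theta = 0.5, visit_times = 0:10,
                       spec = build_damage_model(covariate_effects = FALSE),
                       seed = 1) {
  nv <- length(visit_times)
  tr <- spec$transitions
  out <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(substream_seed(seed, i))
    u <- if (theta > 0) stats::rgamma(1, 1 / theta, 1 / theta) else 1
    locs <- vector("list", n_loc)
    for (l in seq_len(n_loc)) {
      # visit-level activity processes per side (persistent, zero-inflated)
      act <- function() {
        a <- numeric(nv); a[1] <- stats::rbinom(1, 1, 0.3)
        for (v in seq_len(nv - 1))
          a[v + 1] <- stats::rbinom(1, 1, ifelse(a[v] == 1, 0.7, 0.25))
        a
      }
      A_L <- act(); A_R <- act()
      eff <- function(a) ifelse(a == 1, stats::rbinom(nv, 1, 0.4), 0)
      E_L <- eff(A_L); E_R <- eff(A_R)
      T_L <- A_L * (1 - E_L); T_R <- A_R * (1 - E_R)
      P_L <- cummax(A_L); P_R <- cummax(A_R)
      covs <- data.frame(A_L, A_R, T_L, T_R, E_L, E_R, P_L, P_R)
      resolved <- resolve_parameters(spec, params)
      st <- integer(nv); st[1] <- 1L
      s <- 1L
      for (v in seq_len(nv - 1)) {
        t0 <- visit_times[v]; t1 <- visit_times[v + 1]
        cv <- as.list(covs[v, ])
        tcur <- t0
        repeat {
          cand <- which(tr$from == s)
          if (!length(cand)) break
          rates <- vapply(cand, function(j) {
            cf <- resolved[[j]]$coefs
            lp <- if (length(cf))
              sum(cf * unlist(cv[names(cf)], use.names = FALSE)) else 0
            u * resolved[[j]]$baseline$params[1] * exp(lp)
          }, 0)
          if (sum(rates) <= 0) break
          wait <- stats::rexp(1, sum(rates))
          if (tcur + wait > t1) break
          tcur <- tcur + wait
          s <- tr$to[cand[sample.int(length(cand), 1, prob = rates)]]
        }
        st[v + 1] <- s
      }
      locs[[l]] <- cbind(data.frame(subject = i, unit = l,
                                    time = visit_times, state = st,
                                    exact = 0L), covs)
    }
    out[[i]] <- do.call(rbind, locs)
  }
  pm_panel(do.call(rbind, out))
}

#' Named library of simulation scenarios
#'
#' Each entry bundles the fitting spec, the generating (true) parameters
#' and a seeded \code{simulate(n, seed)} closure producing data in the
#' format its fitting route consumes.
#'
#' @export
scenario_library <- function() {
  exp_space <- expand_state_space(3, 3)
  exp_true <- c(
    lamY12_W1 = 0.15, lamY12_W2 = 0.30, lamY12_W3 = 0.60,
    lamY21_W1 = 0.25, lamY21_W2 = 0.25, lamY21_W3 = 0.25,
    lamY23_W1 = 0.10, lamY23_W2 = 0.20, lamY23_W3 = 0.40,
    lamY32_W1 = 0.30, lamY32_W2 = 0.30, lamY32_W3 = 0.30,
    lamW12 = 1.2, lamW21 = 1.0, lamW23 = 0.8, lamW32 = 1.0)
  list(
    remission = list(
      spec = build_remission_model(cutpoints = NULL),
      true = c(q12 = 0.15, q23 = 2.0, q31 = 0.25, gamma0 = -1, gammaZ = 2),
      simulate = function(n = 400, seed = 1)
        sim_remission(n = n, seed = seed)),
    whitehall = list(
      spec = build_whitehall_model(k = 1),
      true = c(a1 = 0.004, b1 = 1.3, a2 = 0.0015, b2 = 1.4, a3 = 0.03,
               b3 = 1.1, a4 = 0.02, b4 = 1.1, a6 = 0.002, b6 = 1.4),
      simulate = function(n = 2000, seed = 1)
        sim_whitehall(n = n, seed = seed)),
    expanded = list(
      space = exp_space,
      spec = build_expanded_model(exp_space),
      true = exp_true,
      simulate = function(n = 300, seed = 1)
        sim_expanded(n = n, space = exp_space, params = exp_true,
                     seed = seed)),
    damage = list(
      spec = build_damage_model(covariate_effects = FALSE),
      true = c(lam012 = 0.02, lam013 = 0.02, gamma24 = 1.0, gamma34 = 1.0,
               theta = 0.5),
      simulate = function(n = 300, seed = 1)
        sim_damage(n = n, theta = 0.5, seed = seed)))
}
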