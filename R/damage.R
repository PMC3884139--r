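# Four-state paired-organ damage model per joint location with a shared
# gamma frailty per subject.
#
# States per location: S1 = no damage, S2 = right joint damaged,
# S3 = left joint damaged, S4 = both damaged; transitions S1->S2, S1->S3,
# S2->S4, S3->S4 only (damage is irreversible, no simultaneous moves).
# Baselines are shared across the 14 hand-joint locations; symmetry is
# parameterized by the offsets lambda024 = lambda013 e^{gamma24} and
# lambda034 = lambda012 e^{gamma34}, so gamma24 > 0 and gamma34 > 0 indicate
# a symmetric damage pattern.  A unit-mean gamma frailty with variance theta
# is shared by all of a subject's location processes and multiplies every
# transition intensity.

#' Build the four-state paired-joint damage model
#'
#' Covariate effects follow the activity-process structure: on the
#' transitions out of S1, activity in the opposite joint (shared coefficient
#' \code{alpha}), tenderness and effusion in the transitive joint (shared
#' \code{tau1}, \code{eps1}); on the transitions into S4, tenderness and
#' effusion in the transitive (still undamaged) joint (shared \code{tau2},
#' \code{eps2}).  Optional past-activity indicators enter with coefficients
#' shared between hands (\code{phi_trans1}, \code{phi_opp} out of S1;
#' \code{phi_trans2} into S4, transitive joint only).  Expected covariate
#' columns: \code{A_L, A_R} (current activity), \code{T_L, T_R}
#' (tenderness), \code{E_L, E_R} (effusion), \code{P_L, P_R} (ever active),
#' all 0/1 and piecewise constant between visits.
#'
#' @param covariate_effects include the activity covariates (FALSE gives the
#'   baseline-only model used to estimate the symmetry offsets)
#' @param include_past include the past-activity indicators
#' @return a \code{pm_spec} with gamma frailty (\code{theta}) and
#'   \code{meta$model == "damage"}
#' @export
build_damage_model <- function(covariate_effects = TRUE,
                               include_past = TRUE) {
  t1 <- t2 <- t3 <- t4 <- character()
  if (covariate_effects) {
    t1 <- c(A_L = "alpha", T_R = "tau1", E_R = "eps1")
    t2 <- c(A_R = "alpha", T_L = "tau1", E_L = "eps1")
    t3 <- c(T_L = "tau2", E_L = "eps2")
    t4 <- c(T_R = "tau2", E_R = "eps2")
    if (include_past) {
      t1 <- c(t1, P_R = "phi_trans1", P_L = "phi_opp")
      t2 <- c(t2, P_L = "phi_trans1", P_R = "phi_opp")
      t3 <- c(t3, P_L = "phi_trans2")
      t4 <- c(t4, P_R = "phi_trans2")
    }
  }
  pm_spec(states = c("S1", "S2", "S3", "S4"),
          transitions = data.frame(from = c(1, 1, 2, 3), to = c(2, 3, 4, 4)),
          baselines = list(bl_constant(labels = "lam012"),
                           bl_constant(labels = "lam013"),
                           derived_exp_offset(source = 2, offset = "gamma24"),
                           derived_exp_offset(source = 1, offset = "gamma34")),
          terms = list(t1, t2, t3, t4),
          frailty = list(theta = "theta"),
          meta = list(model = "damage"))
}

#' Cluster log-likelihood conditional on the frailty value
#'
#' Sum over a subject's location processes of the panel log-likelihood with
#' every intensity multiplied by \code{u}.
#'
#' @param spec a \code{pm_spec} with a frailty component
#' @param panels the cluster's rows of a \code{pm_panel} (one unit per
#'   location)
#' @param params named natural-scale parameters (theta not used here)
#' @param u positive frailty value
#' @export
conditional_cluster_loglik <- function(spec, panels, params, u) {
  stopifnot(u > 0)
  total_loglik(spec, pm_panel(panels), params, u = u)
}

#' Marginal cluster log-likelihood under a gamma frailty
#'
#' \deqn{\log \int_0^\infty L(\mathrm{cluster} \mid u)\, dG(u;\theta)}
#' with \eqn{G} the unit-mean gamma with variance \eqn{\theta}, integrated
#' by generalized Gauss-Laguerre quadrature with log-sum-exp stabilization;
#' \eqn{\theta = 0} returns the conditional value at \eqn{u = 1}.
#'
#' @inheritParams conditional_cluster_loglik
#' @param data a \code{pm_panel} over one or more clusters (subjects)
#' @param theta frailty variance, >= 0
#' @param n_nodes quadrature order
#' @param per_cluster return per-cluster contributions
#' @export
marginal_cluster_loglik <- function(spec, data, params, theta,
                                    n_nodes = 30, per_cluster = FALSE) {
  stopifnot(theta >= 0)
  data <- pm_panel(data)
  prep <- pm_prepare(spec, data)
  cl <- factor(prep$series_subject, levels = unique(prep$series_subject))
  ll_at <- function(u) as.numeric(rowsum(
    total_loglik(spec, params = params, prep = prep, u = u,
                 per_series = TRUE), cl))
  out <- if (theta < 1e-8) ll_at(1)
         else gamma_marginal_tilted(ll_at, theta, n_nodes)
  if (per_cluster) out else sum(out)
}

# ---- fast closed-form likelihood for fitting -------------------------------
# The four-state chain is progressive and acyclic, so within a gap with
# constant rates r12, r13, r24, r34 the needed transition probabilities have
# closed forms (sums of exponentials); the frailty only rescales the rates,
# so the whole (gap x quadrature-node) array vectorizes.

prepare_damage <- function(spec, data) {
  data <- pm_panel(data)
  covcols <- panel_cov_cols(data)
  series <- panel_series(data)
  from <- integer(0); to <- integer(0); dt <- numeric(0)
  cluster <- character(0); covrows <- integer(0)
  rowidx <- integer(0)
  for (si in seq_along(series)) {
    rows <- series[[si]]
    st <- suppressWarnings(as.integer(data$state[rows]))
    if (anyNA(st) || any(st < 1 | st > 4))
      stop("damage panel states must be single codes 1..4", call. = FALSE)
    tt <- data$time[rows]
    ng <- length(rows) - 1L
    if (ng < 1) next
    from <- c(from, st[-length(st)])
    to <- c(to, st[-1])
    dt <- c(dt, diff(tt))
    cluster <- c(cluster, rep(as.character(data$subject[rows[1]]), ng))
    rowidx <- c(rowidx, rows[-length(rows)])
  }
  X <- lapply(seq_len(4), function(i) {
    trm <- spec$terms[[i]]
    if (!length(trm)) return(NULL)
    as.matrix(data[rowidx, names(trm), drop = FALSE])
  })
  ok <- (from == 1 & to %in% 1:4) | (from == 2 & to %in% c(2, 4)) |
    (from == 3 & to %in% c(3, 4)) | (from == 4 & to == 4)
  idx <- lapply(list(c(1, 1), c(1, 2), c(1, 3), c(1, 4), c(2, 2), c(2, 4),
                     c(3, 3), c(3, 4)),
                function(p) which(from == p[1] & to == p[2]))
  names(idx) <- c("i11", "i12", "i13", "i14", "i22", "i24", "i33", "i34")
  list(from = from, to = to, dt = dt, X = X,
       cluster = factor(cluster, levels = unique(cluster)),
       ok = ok, idx = idx)
}

damage_rates <- function(spec, prep, params) {
  p <- as.list(params)
  b12 <- p[[spec$baselines[[1]]$labels]]
  b13 <- p[[spec$baselines[[2]]$labels]]
  b24 <- b13 * exp(p[[spec$baselines[[3]]$rule$offset]])
  b34 <- b12 * exp(p[[spec$baselines[[4]]$rule$offset]])
  base <- c(b12, b13, b24, b34)
  lapply(seq_len(4), function(i) {
    lp <- 0
    if (!is.null(prep$X[[i]])) {
      beta <- vapply(spec$terms[[i]], function(l) p[[l]], 0)
      lp <- as.numeric(prep$X[[i]] %*% beta)
    }
    base[i] * exp(lp)
  })
}

# log transition probability per gap for frailty value u; each closed form
# is evaluated only on the subset of gaps with that (from, to) pair
damage_logP <- function(prep, r, u) {
  n <- length(prep$from)
  dt <- prep$dt
  r12 <- rep_len(r[[1]], n); r13 <- rep_len(r[[2]], n)
  r24 <- rep_len(r[[3]], n); r34 <- rep_len(r[[4]], n)
  q1 <- r12 + r13
  ix <- prep$idx
  out <- numeric(n)  # from == 4 stays 0
  p_1j <- function(i, r1j, rj4) {
    # P(1 -> intermediate damaged state) over dt under frailty u
    d <- rj4[i] - q1[i]
    small <- abs(d) < 1e-9 * (q1[i] + rj4[i] + 1e-12)
    v <- ifelse(small,
                u * r1j[i] * dt[i] * exp(-u * q1[i] * dt[i]),
                r1j[i] / ifelse(small, 1, d) *
                  (exp(-u * q1[i] * dt[i]) - exp(-u * rj4[i] * dt[i])))
    pmax(v, 0)
  }
  out[ix$i11] <- -u * q1[ix$i11] * dt[ix$i11]
  out[ix$i12] <- log(p_1j(ix$i12, r12, r24))
  out[ix$i13] <- log(p_1j(ix$i13, r13, r34))
  i <- ix$i14
  out[i] <- log(pmax(1 - exp(-u * q1[i] * dt[i]) - p_1j(i, r12, r24) -
                       p_1j(i, r13, r34), 0))
  out[ix$i22] <- -u * r24[ix$i22] * dt[ix$i22]
  out[ix$i24] <- log(-expm1(-u * r24[ix$i24] * dt[ix$i24]))
  out[ix$i33] <- -u * r34[ix$i33] * dt[ix$i33]
  out[ix$i34] <- log(-expm1(-u * r34[ix$i34] * dt[ix$i34]))
  out
}

damage_marginal_fast <- function(spec, prep, params, n_nodes = 30,
                                 per_cluster = FALSE) {
  theta <- as.list(params)[[spec$frailty$theta]]
  r <- damage_rates(spec, prep, params)
  if (any(!prep$ok)) return(if (per_cluster)
    rep(-Inf, nlevels(prep$cluster)) else -Inf)
  ll_at <- function(u) as.numeric(rowsum(damage_logP(prep, r, u),
                                         prep$cluster))
  out <- if (theta < 1e-8) ll_at(1)
         else gamma_marginal_tilted(ll_at, theta, n_nodes)
  if (per_cluster) out else sum(out)
}

#' Symmetry-offset estimates from a fitted damage model
#'
#' Point estimates and Wald intervals for the log-rate offsets
#' \eqn{\gamma_{24}} and \eqn{\gamma_{34}}; both positive indicates that a
#' joint's damage rate increases once its contralateral partner is damaged.
#'
#' @param fit a \code{pm_fit} of a \code{\link{build_damage_model}} spec
#' @param level confidence level
#' @export
symmetry_estimates <- function(fit, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  labs <- c(fit$spec$baselines[[3]]$rule$offset,
            fit$spec$baselines[[4]]$rule$offset)
  i <- match(labs, names(fit$working))
  est <- fit$working[i]
  se <- sqrt(diag(fit$vcov)[i])
  data.frame(parameter = labs, estimate = unname(est), se = unname(se),
             lower = unname(est - z * se), upper = unname(est + z * se))
}
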