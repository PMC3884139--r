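# Expanded m x n state space jointly modelling an ordinal outcome Y
# (adjacent-state reversible, m levels) and a rapidly fluctuating ordinal
# covariate W (n levels).  The combined state (j, r) has index
# j + m (r - 1); allowed moves change exactly one sub-process by one level
# (no simultaneous moves, no wrap-around between Y boundaries).

#' Expanded state space for a joint (Y, W) process
#'
#' @param m number of outcome (Y) states, >= 2
#' @param n number of covariate (W) levels, >= 2
#' @return list with the state labels, index maps and the allowed
#'   transition set (\code{2(m-1)n + 2(n-1)m} ordered pairs)
#' @export
expand_state_space <- function(m, n) {
  if (m < 2 || n < 2) stop("need m >= 2 and n >= 2", call. = FALSE)
  idx <- function(j, r) j + m * (r - 1)
  states <- character(m * n)
  for (r in seq_len(n)) for (j in seq_len(m))
    states[idx(j, r)] <- sprintf("Y%dW%d", j, r)
  from <- integer(0); to <- integer(0)
  kind <- character(0); yjk <- integer(0); wrs <- integer(0); lev <- integer(0)
  for (r in seq_len(n)) for (j in seq_len(m)) {
    for (dj in c(-1, 1)) {
      k <- j + dj
      if (k >= 1 && k <= m) {
        from <- c(from, idx(j, r)); to <- c(to, idx(k, r))
        kind <- c(kind, "Y"); yjk <- c(yjk, 10 * j + k)
        wrs <- c(wrs, NA); lev <- c(lev, r)
      }
    }
    for (dr in c(-1, 1)) {
      s <- r + dr
      if (s >= 1 && s <= n) {
        from <- c(from, idx(j, r)); to <- c(to, idx(j, s))
        kind <- c(kind, "W"); yjk <- c(yjk, NA)
        wrs <- c(wrs, 10 * r + s); lev <- c(lev, NA)
      }
    }
  }
  list(m = m, n = n, states = states,
       index = idx,
       unindex = function(i) c(j = (i - 1) %% m + 1, r = (i - 1) %/% m + 1),
       transitions = data.frame(from = from, to = to, kind = kind,
                                y_pair = yjk, w_pair = wrs, w_level = lev))
}

#' Build the constrained expanded joint model
#'
#' Free parameters: one baseline per (Y-transition, W-level) pair (these
#' encode the W effect on Y as log-ratios of baselines), regression
#' coefficients for the Y transitions shared across W levels (one per
#' Y-pair and covariate), and one baseline plus optional coefficients per
#' W-pair shared across Y states (the "marginal" model for W).
#'
#' @param space an \code{\link{expand_state_space}} result
#' @param y_terms character vector of covariate names entering the Y
#'   transitions (coefficients shared across W levels per Y-pair)
#' @param w_terms character vector of covariate names allowed to modify the
#'   W transition rates (shared across Y states per W-pair); default none
#' @return a \code{pm_spec}
#' @export
build_expanded_model <- function(space, y_terms = character(),
                                 w_terms = character()) {
  tr <- space$transitions
  baselines <- vector("list", nrow(tr))
  terms <- vector("list", nrow(tr))
  for (i in seq_len(nrow(tr))) {
    if (tr$kind[i] == "Y") {
      baselines[[i]] <- bl_constant(
        labels = sprintf("lamY%d_W%d", tr$y_pair[i], tr$w_level[i]))
      tt <- sprintf("beta%s_Y%d", y_terms, tr$y_pair[i])
      names(tt) <- y_terms
      terms[[i]] <- tt
    } else {
      baselines[[i]] <- bl_constant(labels = sprintf("lamW%d", tr$w_pair[i]))
      tt <- sprintf("beta%s_W%d", w_terms, tr$w_pair[i])
      names(tt) <- w_terms
      terms[[i]] <- tt
    }
  }
  pm_spec(states = space$states,
          transitions = tr[, c("from", "to")],
          baselines = baselines, terms = terms,
          meta = list(model = "expanded", m = space$m, n = space$n,
                      transition_info = tr))
}

#' Build the "misspecified" comparator model
#'
#' The m-state adjacent-reversible model for Y alone, with the W level
#' entering as last-value-carried-forward dummy covariates
#' \code{W2, ..., Wn} (free coefficient per Y transition and level), plus
#' any further covariates.
#'
#' @param m,n dimensions of the Y and W spaces
#' @param terms character vector of additional covariate names
#' @return a \code{pm_spec}
#' @export
build_misspecified_model <- function(m, n, terms = character()) {
  from <- integer(0); to <- integer(0)
  for (j in seq_len(m)) for (dj in c(-1, 1)) {
    k <- j + dj
    if (k >= 1 && k <= m) { from <- c(from, j); to <- c(to, k) }
  }
  wd <- sprintf("W%d", seq(2, n))
  baselines <- list(); trm <- list()
  for (i in seq_along(from)) {
    pair <- 10 * from[i] + to[i]
    baselines[[i]] <- bl_constant(labels = sprintf("lamY%d", pair))
    tt <- c(sprintf("alpha%d_Y%d", seq(2, n), pair),
            sprintf("beta%s_Y%d", terms, pair))
    names(tt) <- c(wd, terms)
    trm[[i]] <- tt
  }
  pm_spec(states = sprintf("Y%d", seq_len(m)),
          transitions = data.frame(from = from, to = to),
          baselines = baselines, terms = trm,
          meta = list(model = "misspecified", m = m, n = n))
}

#' W-level effects on the Y transitions from a fitted expanded model
#'
#' The activity effect of W level r on Y transition j->k is the log ratio
#' of baselines \eqn{\log(\lambda_{0jk,r} / \lambda_{0jk,1})}; on the
#' working (log-baseline) scale this is a difference of two parameters, so
#' delta-method Wald intervals follow from the fitted covariance.
#'
#' @param fit a \code{pm_fit} of a \code{\link{build_expanded_model}} spec
#' @param level confidence level
#' @return data.frame with the Y pair, W level, estimate, SE and CI
#' @export
activity_effects_from_baselines <- function(fit, level = 0.95) {
  spec <- fit$spec
  stopifnot(identical(spec$meta$model, "expanded"))
  info <- spec$meta$transition_info
  ypairs <- sort(unique(info$y_pair[info$kind == "Y"]))
  nlev <- spec$meta$n
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- NULL
  for (p in ypairs) for (r in seq(2, nlev)) {
    l1 <- sprintf("lamY%d_W%d", p, 1)
    lr <- sprintf("lamY%d_W%d", p, r)
    i1 <- match(l1, names(fit$working)); ir <- match(lr, names(fit$working))
    est <- fit$working[ir] - fit$working[i1]
    se <- sqrt(fit$vcov[ir, ir] + fit$vcov[i1, i1] - 2 * fit$vcov[ir, i1])
    out <- rbind(out, data.frame(
      y_pair = sprintf("%d->%d", p %/% 10, p %% 10), w_level = r,
      estimate = unname(est), se = se,
      lower = unname(est - z * se), upper = unname(est + z * se)))
  }
  out
}

#' Convert jointly observed (Y, W) visit data to panel data
#'
#' @param df data.frame with columns subject, time, Y, W plus covariates
#' @param space an \code{\link{expand_state_space}} result
#' @param model "expanded" (state = combined index; missing W becomes a
#'   censoring set over W levels at the observed Y) or "misspecified"
#'   (state = Y, W entering as carried-forward dummies)
#' @export
yw_to_panel <- function(df, space, model = c("expanded", "misspecified")) {
  model <- match.arg(model)
  m <- space$m; n <- space$n
  extra <- df[, setdiff(names(df), c("subject", "time", "Y", "W")),
              drop = FALSE]
  if (model == "expanded") {
    state <- ifelse(is.na(df$W),
                    vapply(df$Y, function(j)
                      paste(j + m * (seq_len(n) - 1), collapse = ","), ""),
                    as.character(df$Y + m * (df$W - 1)))
    out <- data.frame(subject = df$subject, time = df$time, state = state,
                      exact = 0L)
  } else {
    out <- data.frame(subject = df$subject, time = df$time,
                      state = as.character(df$Y), exact = 0L)
    for (r in seq(2, n)) out[[sprintf("W%d", r)]] <-
      as.integer(!is.na(df$W) & df$W == r)
  }
  pm_panel(cbind(out, extra))
}
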