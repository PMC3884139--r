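# Maximum-likelihood fitting shared by all model classes.  Optimization is
# quasi-Newton (BFGS, numerical gradients) on the unconstrained working
# scale; uncertainty comes from the observed information (numerical Hessian
# at the optimum).

#' Fit a multi-state model by maximum likelihood
#'
#' Dispatches on the model class: plain panel or hidden-Markov forward
#' likelihood for ordinary specs, the closed-form/quadrature semi-competing
#' likelihood for \code{meta$model == "whitehall"}, and the gamma-frailty
#' marginal likelihood (fast progressive-chain route for
#' \code{meta$model == "damage"}, generic quadrature otherwise) when the
#' spec carries a frailty component.
#'
#' @param spec a \code{pm_spec}
#' @param data model-ready data (a \code{pm_panel})
#' @param start optional named natural-scale starting values; defaults to
#'   crude occurrence/exposure rates, coefficients 0, Weibull shapes 1,
#'   frailty variance 0.1
#' @param method \code{\link[stats]{optim}} method
#' @param n_nodes quadrature order for frailty marginalization
#' @param control passed to \code{optim} (defaults: maxit 500, reltol 1e-10)
#' @return a \code{pm_fit}: working/natural estimates, observed-information
#'   covariance (working scale), maximized log-likelihood, convergence flag
#' @export
fit_msm <- function(spec, data, start = NULL, method = "BFGS",
                    n_nodes = 30, control = list()) {
  start <- default_start(spec, data, start)
  w0 <- pm_to_working(spec, start)
  labs <- names(w0)
  mt <- spec$meta$model %||% ""
  if (identical(mt, "whitehall")) {
    prep <- wh_prepare(spec, pm_panel(data))
    negll <- function(w) {
      p <- pm_from_working(spec, stats::setNames(w, labs))
      -whitehall_total_loglik(spec, NULL, p, prep = prep)
    }
  } else if (!is.null(spec$frailty) && identical(mt, "damage")) {
    prep <- prepare_damage(spec, data)
    negll <- function(w) {
      p <- pm_from_working(spec, stats::setNames(w, labs))
      -damage_marginal_fast(spec, prep, p, n_nodes = n_nodes)
    }
  } else if (!is.null(spec$frailty)) {
    data <- pm_panel(data)
    negll <- function(w) {
      p <- pm_from_working(spec, stats::setNames(w, labs))
      -marginal_cluster_loglik(spec, data, p,
                               theta = p[[spec$frailty$theta]],
                               n_nodes = n_nodes)
    }
  } else {
    prep <- pm_prepare(spec, pm_panel(data))
    negll <- function(w) {
      p <- pm_from_working(spec, stats::setNames(w, labs))
      -total_loglik(spec, params = p, prep = prep)
    }
  }
  safe <- function(w) {
    v <- tryCatch(negll(w), error = function(e) Inf)
    if (!is.finite(v)) 1e10 else v
  }
  if (!is.finite(negll(w0)))
    stop("log-likelihood not finite at the starting values", call. = FALSE)
  ctrl <- utils::modifyList(list(maxit = 500L, reltol = 1e-10), control)
  opt <- stats::optim(unname(w0), safe, method = method, control = ctrl)
  H <- tryCatch(stats::optimHess(opt$par, safe), error = function(e) NULL)
  vc <- NULL
  if (!is.null(H)) {
    vc <- tryCatch(solve(H), error = function(e) NULL)
    if (is.null(vc)) {
      ev <- eigen((H + t(H)) / 2, symmetric = TRUE)
      pos <- ev$values > 1e-10 * max(abs(ev$values))
      vc <- ev$vectors[, pos, drop = FALSE] %*%
        diag(1 / ev$values[pos], sum(pos)) %*%
        t(ev$vectors[, pos, drop = FALSE])
      warning("observed information singular; covariance is a pseudoinverse")
    }
    dimnames(vc) <- list(labs, labs)
  }
  working <- stats::setNames(opt$par, labs)
  natural <- pm_from_working(spec, working)
  info <- spec$par_info[spec$par_info$free, ]
  pos <- info$type == "positive"
  boundary <- any(working[pos] < log(1e-8))
  if (boundary)
    warning("estimate at or near the zero boundary for: ",
            paste(labs[pos][working[pos] < log(1e-8)], collapse = ", "),
            call. = FALSE)
  structure(list(working = working, natural = natural, vcov = vc,
                 loglik = -opt$value, convergence = opt$convergence == 0L,
                 npar = length(labs), boundary = boundary, spec = spec,
                 counts = opt$counts, method = method),
            class = "pm_fit")
}

default_start <- function(spec, data, start = NULL) {
  info <- spec$par_info[spec$par_info$free, ]
  out <- stats::setNames(numeric(nrow(info)), info$label)
  shape_labels <- unlist(lapply(spec$baselines, function(b)
    if (!is_derived(b) && b$kind == "weibull") b$labels[2] else NULL))
  crude <- crude_rates(spec, data)
  for (i in seq_len(nrow(info))) {
    l <- info$label[i]
    out[l] <- if (info$type[i] == "real") 0
    else if (!is.null(spec$frailty) && l == spec$frailty$theta) 0.1
    else if (l %in% shape_labels) 1
    else crude[[l]] %||% 0.1
  }
  if (!is.null(start)) out[names(start)] <- start
  out
}

# crude occurrence/exposure rates per baseline label
crude_rates <- function(spec, data) {
  out <- list()
  ok <- tryCatch({
    data <- pm_panel(data)
    st <- suppressWarnings(as.integer(data$state))
    key <- paste(data$subject, data$unit)
    n <- nrow(data)
    same <- c(key[-n] == key[-1], FALSE)
    from <- st[seq_len(n)]; to <- c(st[-1], NA)
    gap <- c(data$time[-1] - data$time[-n], NA)
    !all(is.na(st))
  }, error = function(e) FALSE)
  if (!ok) return(out)
  for (i in seq_len(nrow(spec$transitions))) {
    b <- spec$baselines[[i]]
    if (is_derived(b)) next
    j <- spec$transitions$from[i]; k <- spec$transitions$to[i]
    use <- same & !is.na(from) & !is.na(to)
    ev <- sum(use & from == j & to == k)
    expo <- sum(gap[use & from == j])
    r <- (ev + 0.5) / max(expo, 1)
    for (l in b$labels) if (is.null(out[[l]])) out[[l]] <- r
  }
  out
}

#' Likelihood-ratio test between nested fits
#'
#' @param fit_full,fit_reduced \code{pm_fit} objects, reduced nested in full
#' @param df degrees of freedom; defaults to the difference in free
#'   parameter counts and must match it when supplied
#' @export
lr_test <- function(fit_full, fit_reduced, df = NULL) {
  dnp <- fit_full$npar - fit_reduced$npar
  if (is.null(df)) df <- dnp
  if (df != dnp)
    stop(sprintf("df (%d) does not match the parameter-count difference (%d)",
                 df, dnp), call. = FALSE)
  if (df <= 0) stop("the reduced model must have fewer parameters",
                    call. = FALSE)
  stat <- 2 * (fit_full$loglik - fit_reduced$loglik)
  if (stat < -1e-6)
    warning("full model has lower likelihood than the reduced model; refit",
            call. = FALSE)
  stat <- max(stat, 0)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Wald estimates, standard errors and confidence intervals
#'
#' Intervals are est +/- z SE on the working scale, then mapped through the
#' requested transform (\code{"exp"} gives rate ratios for coefficients and
#' rates for log-rate parameters).
#'
#' @param fit a \code{pm_fit}
#' @param transform \code{"none"} or \code{"exp"}
#' @param level confidence level
#' @export
wald_summary <- function(fit, transform = c("none", "exp"), level = 0.95) {
  transform <- match.arg(transform)
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- if (is.null(fit$vcov)) rep(NA_real_, fit$npar) else
    sqrt(pmax(diag(fit$vcov), 0))
  est <- fit$working
  out <- data.frame(label = names(est), estimate = unname(est), se = se,
                    lower = unname(est - z * se),
                    upper = unname(est + z * se))
  if (transform == "exp") {
    out$rr <- exp(out$estimate)
    out$rr_lower <- exp(out$lower)
    out$rr_upper <- exp(out$upper)
  }
  rownames(out) <- NULL
  out
}

#' @export
print.pm_fit <- function(x, ...) {
  cat("Multi-state model fit\n")
  cat(sprintf("  log-likelihood: %.4f   free parameters: %d\n", x$loglik,
              x$npar))
  cat(sprintf("  converged: %s%s\n", x$convergence,
              if (isTRUE(x$boundary)) " (boundary estimate)" else ""))
  print(wald_summary(x), digits = 4)
  invisible(x)
}
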