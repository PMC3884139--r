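#' Baseline hazard families
#'
#' A baseline family describes the time part of a proportional transition
#' intensity.  Three families are supported:
#' \itemize{
#'   \item \code{constant}: hazard \eqn{\lambda};
#'   \item \code{piecewise}: right-continuous step hazard on the
#'     left-closed, right-open intervals defined by \code{cutpoints};
#'   \item \code{weibull}: hazard \eqn{a b t^{b-1}} with cumulative hazard
#'     \eqn{a t^b} (scale-rate \eqn{a > 0}, shape \eqn{b > 0}).
#' }
#' Either \code{params} (numeric values) or \code{labels} (parameter names
#' resolved later against a parameter vector) must be given.
#'
#' @param rate,levels,scale,shape numeric parameter values
#' @param cutpoints strictly increasing interior cutpoints (piecewise only)
#' @param labels character parameter labels used in a model specification
#' @return an object of class \code{pm_baseline}
#' @export
bl_constant <- function(rate = NULL, labels = NULL) {
  new_baseline("constant", NULL, params = rate, labels = labels, npar = 1L)
}

#' @rdname bl_constant
#' @export
bl_piecewise <- function(cutpoints, levels = NULL, labels = NULL) {
  cutpoints <- as.numeric(cutpoints)
  if (length(cutpoints) < 1 || is.unsorted(cutpoints, strictly = TRUE))
    stop("piecewise cutpoints must be strictly increasing", call. = FALSE)
  new_baseline("piecewise", cutpoints, params = levels, labels = labels,
               npar = length(cutpoints) + 1L)
}

#' @rdname bl_constant
#' @export
bl_weibull <- function(scale = NULL, shape = NULL, labels = NULL) {
  params <- if (!is.null(scale)) c(scale, shape) else NULL
  new_baseline("weibull", NULL, params = params, labels = labels, npar = 2L)
}

new_baseline <- function(kind, cutpoints, params, labels, npar) {
  if (!is.null(params)) {
    params <- as.numeric(params)
    if (length(params) != npar)
      stop(sprintf("baseline '%s' needs %d parameter(s)", kind, npar),
           call. = FALSE)
    if (any(params <= 0))
      stop("baseline parameters must be strictly positive", call. = FALSE)
  }
  if (!is.null(labels) && length(labels) != npar)
    stop(sprintf("baseline '%s' needs %d label(s)", kind, npar),
         call. = FALSE)
  structure(list(kind = kind, cutpoints = cutpoints, params = params,
                 labels = labels),
            class = "pm_baseline")
}

#' Evaluate a baseline hazard
#'
#' @param family a \code{pm_baseline} with numeric \code{params}
#' @param t nonnegative time(s)
#' @return hazard value(s); piecewise hazards are right-continuous at the
#'   cutpoints (left-closed, right-open interval convention)
#' @export
baseline_hazard <- function(family, t) {
  stopifnot(inherits(family, "pm_baseline"), !is.null(family$params))
  if (any(t < 0)) stop("negative time in baseline_hazard", call. = FALSE)
  p <- family$params
  switch(family$kind,
    constant = rep_len(p[1], length(t)),
    piecewise = p[findInterval(t, family$cutpoints) + 1L],
    weibull = p[1] * p[2] * t^(p[2] - 1),
    stop("unknown baseline kind"))
}

#' Cumulative baseline hazard over [t0, t1]
#' @inheritParams baseline_hazard
#' @param t0,t1 interval endpoints, 0 <= t0 <= t1
#' @export
baseline_cumhaz <- function(family, t0, t1) {
  stopifnot(inherits(family, "pm_baseline"), !is.null(family$params))
  if (any(t0 < 0) || any(t1 < t0))
    stop("need 0 <= t0 <= t1 in baseline_cumhaz", call. = FALSE)
  p <- family$params
  switch(family$kind,
    constant = p[1] * (t1 - t0),
    weibull = p[1] * (t1^p[2] - t0^p[2]),
    piecewise = {
      cuts <- family$cutpoints
      n <- max(length(t0), length(t1))
      t0 <- rep_len(t0, n); t1 <- rep_len(t1, n)
      H <- function(t) {
        # integral of the step hazard from 0 to t, vectorized
        b <- c(0, cuts)
        out <- numeric(length(t))
        for (i in seq_along(b)) {
          lo <- b[i]
          hi <- if (i < length(b)) b[i + 1] else Inf
          out <- out + p[i] * pmax(0, pmin(t, hi) - lo)
        }
        out
      }
      H(t1) - H(t0)
    },
    stop("unknown baseline kind"))
}

# Power-law form C * t^pow of a constant or Weibull hazard; used when
# resolving the ratio-product constraint lam5 = lam1 * lam6 / (k * lam2).
power_form <- function(family) {
  p <- family$params
  switch(family$kind,
    constant = c(C = p[1], pow = 0),
    weibull = c(C = p[1] * p[2], pow = p[2] - 1),
    stop("ratio-product constraints require constant or Weibull baselines",
         call. = FALSE))
}

# Back-convert a power-law hazard C * t^pow to a baseline family.
from_power_form <- function(C, pow) {
  if (C <= 0) stop("derived baseline has nonpositive rate", call. = FALSE)
  if (abs(pow) < 1e-12) return(bl_constant(rate = C))
  b <- pow + 1
  if (b <= 0)
    stop("derived baseline has nonpositive Weibull shape", call. = FALSE)
  bl_weibull(scale = C / b, shape = b)
}
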