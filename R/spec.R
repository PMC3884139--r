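#' Declarative multi-state model specification
#'
#' A \code{pm_spec} bundles the state graph, one intensity model per allowed
#' transition, parameter-sharing constraints, and optional misclassification
#' (emission) and frailty components.  Transition intensities have the
#' proportional form \eqn{\lambda_{jk}(t) = \lambda_{0jk}(t)\exp(\beta^T x)},
#' with \eqn{\lambda_{0jk}} a baseline family (see \code{\link{bl_constant}}).
#'
#' Equality constraints are expressed by giving two transitions the same
#' parameter label; identical labels always resolve to identical values.
#' Two kinds of derived baselines are supported:
#' \itemize{
#'   \item \code{derived_ratio_product(num, den, k)}: the target intensity is
#'     \eqn{\lambda_{n1}(t)\lambda_{n2}(t) / (k\,\lambda_d(t))}, with the
#'     regression coefficients combined accordingly (sum of the numerators'
#'     minus the denominator's);
#'   \item \code{derived_exp_offset(source, offset)}: the target baseline is
#'     the source baseline scaled by \eqn{e^{\gamma}} with \eqn{\gamma} a free
#'     parameter (used, e.g., for symmetry offsets in paired-organ models).
#' }
#'
#' @param states character vector of state labels, in order
#' @param transitions data.frame with columns \code{from}, \code{to}
#'   (state labels or 1-based indices)
#' @param baselines list, one \code{pm_baseline} (with \code{labels}) or
#'   derived rule per transition
#' @param terms list, one named character vector (covariate name ->
#'   coefficient label) per transition, or \code{NULL}
#' @param fixed named numeric vector of fixed parameters (e.g. a sensitivity
#'   constant)
#' @param emission optional emission model, see \code{\link{emission_remission}}
#' @param frailty optional \code{list(theta = "<label>")}: a unit-mean gamma
#'   frailty with variance \eqn{\theta} shared within a cluster and acting
#'   multiplicatively on all transition intensities
#' @param unobservable character vector of states never directly observed
#' @param meta free-form list of model metadata
#' @return an object of class \code{pm_spec}
#' @export
pm_spec <- function(states, transitions, baselines, terms = NULL,
                    fixed = NULL, emission = NULL, frailty = NULL,
                    unobservable = character(), meta = list()) {
  states <- as.character(states)
  if (anyDuplicated(states)) stop("duplicate state labels", call. = FALSE)
  tr <- as.data.frame(transitions)
  to_idx <- function(x) {
    if (is.numeric(x)) {
      i <- as.integer(x)
      i[i < 1 | i > length(states)] <- NA_integer_
      i
    } else match(as.character(x), states)
  }
  tr <- data.frame(from = to_idx(tr$from), to = to_idx(tr$to))
  if (anyNA(tr)) stop("transition references an unknown state", call. = FALSE)
  if (any(tr$from == tr$to))
    stop("transitions must connect distinct states", call. = FALSE)
  if (anyDuplicated(tr)) stop("duplicate transitions", call. = FALSE)
  nt <- nrow(tr)
  if (length(baselines) != nt)
    stop("need one baseline per transition", call. = FALSE)
  if (is.null(terms)) terms <- rep(list(character()), nt)
  if (length(terms) != nt) stop("need one terms entry per transition",
                                call. = FALSE)
  terms <- lapply(terms, function(x) {
    if (is.null(x)) character() else {
      if (is.null(names(x)) && length(x)) stop("terms must be named",
                                               call. = FALSE)
      vapply(x, as.character, "")
    }
  })
  spec <- structure(list(states = states, n_states = length(states),
                         transitions = tr, baselines = baselines,
                         terms = terms, fixed = fixed, emission = emission,
                         frailty = frailty,
                         unobservable = as.character(unobservable),
                         meta = meta),
                    class = "pm_spec")
  spec$par_info <- build_par_info(spec)
  validate_derived(spec)
  spec
}

#' @rdname pm_spec
#' @param num integer vector of the two numerator transition indices
#' @param den denominator transition index
#' @param k a positive number or the name of a fixed parameter
#' @export
derived_ratio_product <- function(num, den, k) {
  stopifnot(length(num) == 2, length(den) == 1)
  structure(list(kind = "derived",
                 rule = list(type = "ratio_product", num = as.integer(num),
                             den = as.integer(den), k = k)),
            class = "pm_derived")
}

#' @rdname pm_spec
#' @param source source transition index
#' @param offset label of the free log-scale offset parameter
#' @export
derived_exp_offset <- function(source, offset) {
  structure(list(kind = "derived",
                 rule = list(type = "exp_offset", source = as.integer(source),
                             offset = as.character(offset))),
            class = "pm_derived")
}

is_derived <- function(b) inherits(b, "pm_derived")

build_par_info <- function(spec) {
  lab <- character(); typ <- character()
  add <- function(l, t) {
    lab <<- c(lab, l); typ <<- c(typ, rep(t, length(l)))
  }
  for (i in seq_len(nrow(spec$transitions))) {
    b <- spec$baselines[[i]]
    if (is_derived(b)) {
      if (b$rule$type == "exp_offset") add(b$rule$offset, "real")
      if (b$rule$type == "ratio_product" && is.character(b$rule$k) &&
          !(b$rule$k %in% names(spec$fixed)))
        stop("ratio-product constant must be fixed", call. = FALSE)
    } else {
      if (is.null(b$labels))
        stop("non-derived baselines need parameter labels", call. = FALSE)
      add(b$labels, "positive")
    }
    add(unname(spec$terms[[i]]), "real")
  }
  if (!is.null(spec$emission)) add(unname(spec$emission$terms), "real")
  if (!is.null(spec$frailty)) add(spec$frailty$theta, "positive")
  keep <- !duplicated(lab)
  info <- data.frame(label = lab[keep], type = typ[keep],
                     stringsAsFactors = FALSE)
  for (l in unique(lab[duplicated(lab)])) {
    tt <- unique(typ[lab == l])
    if (length(tt) > 1)
      stop(sprintf("label '%s' used with conflicting scales", l),
           call. = FALSE)
  }
  info$free <- !(info$label %in% names(spec$fixed))
  info
}

validate_derived <- function(spec) {
  nt <- nrow(spec$transitions)
  for (i in seq_len(nt)) {
    b <- spec$baselines[[i]]
    if (!is_derived(b)) next
    deps <- if (b$rule$type == "ratio_product") c(b$rule$num, b$rule$den)
            else b$rule$source
    if (any(deps < 1 | deps > nt))
      stop("derived rule references an unknown transition", call. = FALSE)
    if (any(vapply(spec$baselines[deps], is_derived, TRUE)))
      stop("derived rules may not depend on other derived baselines",
           call. = FALSE)
    if (any(deps == i))
      stop("cyclic derived-baseline rule", call. = FALSE)
  }
  invisible(spec)
}

#' Free parameter labels of a specification
#' @param spec a \code{pm_spec}
#' @export
pm_free_labels <- function(spec) spec$par_info$label[spec$par_info$free]

#' Natural <-> working (unconstrained) parameter transforms
#'
#' Positive parameters (baseline rates, scales, shapes, frailty variance)
#' are log-transformed; regression and emission coefficients are untouched.
#' The round trip is the identity.
#'
#' @param spec a \code{pm_spec}
#' @param p named natural-scale parameter vector over the free labels
#' @export
pm_to_working <- function(spec, p) {
  info <- spec$par_info[spec$par_info$free, ]
  p <- p[info$label]
  if (anyNA(p)) stop("missing parameter(s): ",
                     paste(info$label[is.na(p)], collapse = ", "),
                     call. = FALSE)
  w <- as.numeric(p)
  pos <- info$type == "positive"
  w[pos] <- log(w[pos])
  names(w) <- info$label
  w
}

#' @rdname pm_to_working
#' @param w named working-scale vector
#' @export
pm_from_working <- function(spec, w) {
  info <- spec$par_info[spec$par_info$free, ]
  w <- w[info$label]
  p <- as.numeric(w)
  pos <- info$type == "positive"
  p[pos] <- exp(p[pos])
  names(p) <- info$label
  p
}

#' Resolve constraints to fully numeric per-transition parameters
#'
#' Applies fixed values, label sharing and derived-baseline rules, and
#' returns one numeric baseline plus named coefficient vector per
#' transition.  Resolution is idempotent and independent of rule order
#' (derived rules may only reference non-derived baselines, so the
#' dependency graph is trivially acyclic).
#'
#' @param spec a \code{pm_spec}
#' @param params named natural-scale values for the free labels
#' @return list with one \code{list(baseline, coefs)} per transition
#' @export
resolve_parameters <- function(spec, params) {
  full <- c(as.list(params), as.list(spec$fixed))
  getp <- function(l) {
    v <- full[[l]]
    if (is.null(v)) stop(sprintf("parameter '%s' missing", l), call. = FALSE)
    v
  }
  nt <- nrow(spec$transitions)
  out <- vector("list", nt)
  # pass 1: direct baselines
  for (i in seq_len(nt)) {
    b <- spec$baselines[[i]]
    coefs <- vapply(spec$terms[[i]], getp, 0)
    names(coefs) <- names(spec$terms[[i]])
    if (!is_derived(b)) {
      vals <- vapply(b$labels, getp, 0)
      rb <- switch(b$kind,
        constant = bl_constant(rate = vals[1]),
        piecewise = bl_piecewise(b$cutpoints, levels = vals),
        weibull = bl_weibull(scale = vals[1], shape = vals[2]))
      out[[i]] <- list(baseline = rb, coefs = coefs)
    } else {
      out[[i]] <- list(baseline = NULL, coefs = coefs, rule = b$rule)
    }
  }
  # pass 2: derived baselines (depend only on pass-1 results)
  for (i in seq_len(nt)) {
    r <- out[[i]]$rule
    if (is.null(r)) next
    if (r$type == "ratio_product") {
      k <- if (is.character(r$k)) getp(r$k) else r$k
      if (k <= 0) stop("ratio-product constant must be positive",
                       call. = FALSE)
      p1 <- power_form(out[[r$num[1]]]$baseline)
      p2 <- power_form(out[[r$num[2]]]$baseline)
      pd <- power_form(out[[r$den]]$baseline)
      out[[i]]$baseline <- from_power_form(p1["C"] * p2["C"] / (k * pd["C"]),
                                           p1["pow"] + p2["pow"] - pd["pow"])
      cc <- combine_coefs(out[[r$num[1]]]$coefs, out[[r$num[2]]]$coefs,
                          out[[r$den]]$coefs)
      out[[i]]$coefs <- c(out[[i]]$coefs, cc[setdiff(names(cc),
                                                     names(out[[i]]$coefs))])
      if (length(cc)) out[[i]]$coefs[names(cc)] <- cc
    } else if (r$type == "exp_offset") {
      src <- out[[r$source]]$baseline
      g <- getp(r$offset)
      out[[i]]$baseline <- switch(src$kind,
        constant = bl_constant(rate = src$params[1] * exp(g)),
        piecewise = bl_piecewise(src$cutpoints, levels = src$params * exp(g)),
        weibull = bl_weibull(scale = src$params[1] * exp(g),
                             shape = src$params[2]))
    }
    out[[i]]$rule <- NULL
  }
  out
}

combine_coefs <- function(c1, c2, cd) {
  nm <- unique(c(names(c1), names(c2), names(cd)))
  if (!length(nm)) return(numeric())
  g <- function(cc) ifelse(nm %in% names(cc), cc[nm], 0)
  out <- g(c1) + g(c2) - g(cd)
  names(out) <- nm
  out
}

#' Transition intensity matrix Q
#'
#' Off-diagonal entry (j, k) is
#' \eqn{u\,\lambda_{0jk}(t)\exp(\beta^T x)} for allowed transitions and 0
#' otherwise; each diagonal entry is minus its row sum, so rows sum to zero.
#'
#' @param spec a \code{pm_spec}
#' @param params named natural-scale parameter vector (ignored when
#'   \code{resolved} is supplied)
#' @param covariates named list/vector covering every covariate referenced by
#'   the transition models
#' @param t evaluation time
#' @param frailty positive multiplier applied to every intensity
#' @param resolved optional output of \code{\link{resolve_parameters}}
#' @export
intensity_matrix <- function(spec, params = NULL, covariates = NULL, t = 0,
                             frailty = 1, resolved = NULL) {
  if (is.null(resolved)) resolved <- resolve_parameters(spec, params)
  ns <- spec$n_states
  Q <- matrix(0, ns, ns, dimnames = list(spec$states, spec$states))
  for (i in seq_len(nrow(spec$transitions))) {
    tri <- resolved[[i]]
    lp <- 0
    if (length(tri$coefs)) {
      x <- unlist(covariates[names(tri$coefs)], use.names = FALSE)
      if (length(x) != length(tri$coefs) || anyNA(x))
        stop("missing covariate(s): ",
             paste(setdiff(names(tri$coefs), names(covariates)),
                   collapse = ", "), call. = FALSE)
      lp <- sum(tri$coefs * x)
    }
    Q[spec$transitions$from[i], spec$transitions$to[i]] <-
      frailty * baseline_hazard(tri$baseline, t) * exp(lp)
  }
  diag(Q) <- -rowSums(Q)
  Q
}

#' Absorbing states (no outgoing transitions)
#' @param spec a \code{pm_spec}
#' @export
absorbing_states <- function(spec) {
  setdiff(seq_len(spec$n_states), unique(spec$transitions$from))
}

spec_cutpoints <- function(spec) {
  sort(unique(unlist(lapply(spec$baselines, function(b) {
    if (is_derived(b)) NULL else b$cutpoints
  }))))
}

spec_has_weibull <- function(spec) {
  any(vapply(spec$baselines, function(b) {
    if (is_derived(b)) b$rule$type == "ratio_product" else b$kind == "weibull"
  }, TRUE))
}

#' @export
print.pm_spec <- function(x, ...) {
  cat("Multi-state model specification\n")
  cat("  states:", paste(x$states, collapse = ", "), "\n")
  if (length(x$unobservable))
    cat("  unobservable:", paste(x$unobservable, collapse = ", "), "\n")
  tr <- x$transitions
  for (i in seq_len(nrow(tr))) {
    b <- x$baselines[[i]]
    kind <- if (is_derived(b)) paste0("derived:", b$rule$type) else b$kind
    cat(sprintf("  %s -> %s  [%s]", x$states[tr$from[i]], x$states[tr$to[i]],
                kind))
    if (length(x$terms[[i]]))
      cat("  ~", paste(names(x$terms[[i]]), collapse = " + "))
    cat("\n")
  }
  if (!is.null(x$emission)) cat("  emission: ", x$emission$type, "\n")
  if (!is.null(x$frailty))
    cat("  frailty: gamma(1/theta, 1/theta), theta = '", x$frailty$theta,
        "'\n", sep = "")
  cat("  free parameters:", sum(x$par_info$free), "\n")
  invisible(x)
}
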