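# JSON model-configuration documents.  Schema (all other modules consume a
# pm_spec only through this structure):
# {
#   "states": [...], "unobservable": [...],
#   "transitions": [{"from": "...", "to": "...",
#                    "baseline": {"kind": "constant|piecewise|weibull",
#                                 "cutpoints": [...], "labels": [...]}
#                              | {"derived": "ratio_product",
#                                 "num": [i, j], "den": i, "k": "label"|num}
#                              | {"derived": "exp_offset", "source": i,
#                                 "offset": "label"},
#                    "terms": {"covariate": "label", ...}}, ...],
#   "constraints": {"fixed": {"label": value, ...}},
#   "emission": {"type": "remission", "terms": {...}, "blocked": "..."},
#   "frailty": {"theta": "label"},
#   "meta": {...}
# }
# Equality constraints are expressed by repeating a label.

#' Write / read a model specification as JSON
#' @param spec a \code{pm_spec}
#' @param path file path (for \code{spec_to_json}, \code{NULL} returns the
#'   JSON string)
#' @export
spec_to_json <- function(spec, path = NULL) {
  tr <- spec$transitions
  trans <- lapply(seq_len(nrow(tr)), function(i) {
    b <- spec$baselines[[i]]
    bj <- if (is_derived(b)) {
      r <- b$rule
      if (r$type == "ratio_product")
        list(derived = "ratio_product", num = r$num, den = r$den, k = r$k)
      else list(derived = "exp_offset", source = r$source, offset = r$offset)
    } else {
      out <- list(kind = b$kind, labels = as.list(b$labels))
      if (!is.null(b$cutpoints)) out$cutpoints <- b$cutpoints
      out
    }
    list(from = spec$states[tr$from[i]], to = spec$states[tr$to[i]],
         baseline = bj, terms = as.list(spec$terms[[i]]))
  })
  em <- spec$emission
  if (!is.null(em)) em$terms <- as.list(em$terms)  # keep covariate names
  doc <- list(states = spec$states, unobservable = spec$unobservable,
              transitions = trans,
              constraints = list(fixed = as.list(spec$fixed)),
              emission = em, frailty = spec$frailty,
              meta = spec$meta[setdiff(names(spec$meta), "transition_info")])
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' @rdname spec_to_json
#' @export
spec_from_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  nt <- length(doc$transitions)
  from <- character(nt); to <- character(nt)
  baselines <- vector("list", nt); terms <- vector("list", nt)
  for (i in seq_len(nt)) {
    tri <- doc$transitions[[i]]
    from[i] <- tri$from; to[i] <- tri$to
    b <- tri$baseline
    baselines[[i]] <- if (!is.null(b$derived)) {
      if (b$derived == "ratio_product")
        derived_ratio_product(unlist(b$num), b$den, b$k)
      else derived_exp_offset(b$source, b$offset)
    } else switch(b$kind,
      constant = bl_constant(labels = unlist(b$labels)),
      piecewise = bl_piecewise(unlist(b$cutpoints),
                               labels = unlist(b$labels)),
      weibull = bl_weibull(labels = unlist(b$labels)),
      stop("unknown baseline kind in config", call. = FALSE))
    terms[[i]] <- unlist(tri$terms) %||% character()
  }
  em <- doc$emission
  if (!is.null(em)) em <- list(type = em$type, terms = unlist(em$terms),
                               blocked = em$blocked)
  meta <- doc$meta %||% list()
  if (!is.null(meta$init)) meta$init <- as.list(meta$init)
  pm_spec(states = unlist(doc$states),
          transitions = data.frame(from = from, to = to),
          baselines = baselines, terms = terms,
          fixed = unlist(doc$constraints$fixed),
          emission = em,
          frailty = if (!is.null(doc$frailty)) as.list(doc$frailty),
          unobservable = unlist(doc$unobservable) %||% character(),
          meta = meta)
}
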