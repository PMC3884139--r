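# Hidden-state (misclassification) layer and the three-state remission
# model: active disease S1, early remission S2, established remission S3,
# with transitions S1->S2->S3->S1 and observed codes
#   O1: nonzero active-joint count at a visit,
#   O2: a zero count at the first or second visit of a zero run,
#   O3: the third or later consecutive zero-count visit.
# Only S1 can be misclassified: Pr(O2|S1) = invlogit(gamma' z), with the
# structural exception that a third consecutive zero is impossible under S1.

#' Recode active-joint counts into observed states
#'
#' Deterministically maps a per-visit count sequence to observed codes
#' O1/O2/O3, the first-zero indicator Z, and the observed state sequences
#' used by the two comparator models:
#' \itemize{
#'   \item Model B: remission exactly at the third and later visits of runs
#'     of >= 3 consecutive zero counts;
#'   \item Model C: remission at every visit of such runs (remission is
#'     assumed to start after the last preceding nonzero-count visit).
#' }
#' Runs of at most two zeros are active under both B and C.
#'
#' @param counts nonnegative integer active-joint counts, one per visit
#' @return data.frame with columns \code{count}, \code{code} (1/2/3),
#'   \code{O} ("O1"/"O2"/"O3"), \code{Z} (1 first zero, 0 second zero, NA
#'   otherwise), \code{zfirst} (the would-be Z at every visit, used as an
#'   emission covariate), \code{blocked} (1 when a zero count is
#'   structurally impossible under S1, i.e. at least two consecutive zeros
#'   precede the visit), \code{state_B}, \code{state_C} (1 active,
#'   2 remission)
#' @export
recode_zero_runs <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) < 1) stop("need at least one visit", call. = FALSE)
  if (any(counts < 0) || any(counts != floor(counts)) || anyNA(counts))
    stop("counts must be nonnegative integers", call. = FALSE)
  n <- length(counts)
  zero <- counts == 0
  prev_zeros <- integer(n)
  run <- 0L
  for (i in seq_len(n)) {
    prev_zeros[i] <- run
    run <- if (zero[i]) run + 1L else 0L
  }
  code <- ifelse(!zero, 1L, ifelse(prev_zeros <= 1L, 2L, 3L))
  Z <- ifelse(code == 2L, ifelse(prev_zeros == 0L, 1, 0), NA_real_)
  zfirst <- ifelse(prev_zeros == 0L, 1, 0)
  blocked <- as.integer(prev_zeros >= 2L)
  # run lengths of zero runs, for Model C
  runlen <- integer(n)
  i <- 1L
  while (i <= n) {
    if (zero[i]) {
      j <- i
      while (j < n && zero[j + 1L]) j <- j + 1L
      runlen[i:j] <- j - i + 1L
      i <- j + 1L
    } else i <- i + 1L
  }
  state_B <- ifelse(code == 3L, 2L, 1L)
  state_C <- ifelse(zero & runlen >= 3L, 2L, 1L)
  data.frame(count = counts, code = code,
             O = paste0("O", code), Z = Z, zfirst = zfirst,
             blocked = blocked, state_B = state_B, state_C = state_C)
}

#' Remission emission model
#'
#' Misclassification structure of the three-state remission model:
#' \deqn{\Pr(O_2|S_1) = \mathrm{logit}^{-1}(\gamma^T z), \quad
#'       \Pr(O_1|S_1) = 1 - \Pr(O_2|S_1), \quad \Pr(O_3|S_1) = 0,}
#' row S2 = (0, 1, 0) and row S3 = (0, 0, 1).  The emission covariates z are
#' visit-level (e.g. the first-zero indicator Z); the \code{blocked} column
#' forces \eqn{\Pr(O_2|S_1) = 0} where a sampling zero is structurally
#' impossible.  Emission parameters are time-constant.
#'
#' @param terms named character vector: covariate name -> coefficient label;
#'   use \code{"(Intercept)"} for the intercept
#' @param blocked name of the 0/1 structural-blocking covariate column
#' @export
emission_remission <- function(terms = c("(Intercept)" = "gamma0",
                                         Z = "gammaZ"),
                               blocked = "blocked") {
  list(type = "remission", terms = terms, blocked = blocked)
}

emission_p_misclass <- function(emission, params, z) {
  # z: matrix/df of visit-level covariates (may include the blocked column)
  nm <- names(emission$terms)
  lp <- 0
  for (j in seq_along(nm)) {
    g <- params[[emission$terms[j]]]
    if (is.null(g)) stop(sprintf("emission parameter '%s' missing",
                                 emission$terms[j]), call. = FALSE)
    xv <- if (nm[j] == "(Intercept)") 1 else z[, nm[j]]
    lp <- lp + g * xv
  }
  p <- invlogit(lp)
  bc <- emission$blocked
  if (!is.null(bc) && bc %in% colnames(z)) p <- p * (1 - z[, bc])
  p
}

#' Emission probability matrix at given visit covariates
#'
#' @param emission an \code{\link{emission_remission}} object
#' @param params named parameter values for the emission coefficients
#' @param z named vector (or 1-row data.frame) of visit covariates
#' @return 3x3 stochastic matrix, rows = hidden S1..S3, columns = O1..O3
#' @export
emission_matrix <- function(emission, params, z) {
  zm <- if (is.data.frame(z)) as.matrix(z) else
    matrix(z, 1, dimnames = list(NULL, names(z)))
  p <- emission_p_misclass(emission, as.list(params), zm)[1]
  m <- rbind(S1 = c(1 - p, p, 0), S2 = c(0, 1, 0), S3 = c(0, 0, 1))
  colnames(m) <- c("O1", "O2", "O3")
  m
}

# Per-code emission rows across all visits: list over observed codes o of
# (n_visit x n_hidden) matrices Pr(O = o | S = r).
emission_prob_rows <- function(emission, params, zmat) {
  p <- emission_p_misclass(emission, as.list(params), zmat)
  n <- length(p)
  list(cbind(1 - p, 0, 0), cbind(p, 1, 0),
       cbind(rep(0, n), 0, 1))
}

#' Build the three-state remission model (Model A)
#'
#' States S1 (active), S2 (early remission), S3 (established remission);
#' allowed transitions exactly S1->S2, S2->S3, S3->S1.  Baseline rates are
#' piecewise constant on the intervals split at \code{cutpoints} (default a
#' single cut at 15 years since diagnosis) or constant when
#' \code{cutpoints = NULL}.  The S1->S2 and S3->S1 rates may carry covariate
#' terms; S2->S3 is covariate-free.  Subjects occupy S1 at the diagnosis
#' time origin; observation may begin later (left truncation), in which case
#' the hidden-state distribution at the first visit is the occupancy row
#' from S1 and the likelihood conditions on the first observation.
#'
#' @param cutpoints baseline cutpoints, or NULL for constant rates
#' @param terms12,terms31 named character vectors (covariate -> label) for
#'   the S1->S2 and S3->S1 rates
#' @param emission an \code{\link{emission_remission}} object
#' @param condition_entry condition the likelihood on the first visit's
#'   observation (delayed-entry handling)
#' @return a \code{pm_spec}
#' @export
build_remission_model <- function(cutpoints = 15, terms12 = character(),
                                  terms31 = character(),
                                  emission = emission_remission(),
                                  condition_entry = TRUE) {
  bl <- function(stub) {
    if (is.null(cutpoints)) bl_constant(labels = stub)
    else bl_piecewise(cutpoints,
                      labels = paste0(stub, "_", seq_len(length(cutpoints)
                                                         + 1L)))
  }
  pm_spec(states = c("S1", "S2", "S3"),
          transitions = data.frame(from = c(1, 2, 3), to = c(2, 3, 1)),
          baselines = list(bl("q12"), bl("q23"), bl("q31")),
          terms = list(terms12, character(), terms31),
          emission = emission,
          meta = list(model = "remission",
                      state_groups = c(S1 = "active", S2 = "remission",
                                       S3 = "remission"),
                      init = list(kind = "occupancy", state = 1, time = 0,
                                  condition = condition_entry)))
}

#' Two-state alternating comparator models (Models B and C)
#'
#' Active (1) and remission (2) with transitions in both directions and no
#' misclassification; fitted by the plain panel likelihood on the recoded
#' state sequences from \code{\link{recode_zero_runs}}.
#'
#' @inheritParams build_remission_model
#' @export
build_remission_alt_model <- function(cutpoints = 15, terms12 = character(),
                                      terms21 = character()) {
  bl <- function(stub) {
    if (is.null(cutpoints)) bl_constant(labels = stub)
    else bl_piecewise(cutpoints,
                      labels = paste0(stub, "_", seq_len(length(cutpoints)
                                                         + 1L)))
  }
  pm_spec(states = c("active", "remission"),
          transitions = data.frame(from = c(1, 2), to = c(2, 1)),
          baselines = list(bl("q12"), bl("q21")),
          terms = list(terms12, terms21),
          meta = list(model = "remission_alt"))
}

#' Convert an active-joint-count table to model-ready panel data
#'
#' @param counts_df data.frame with columns \code{subject}, \code{time},
#'   \code{count}, plus any covariate columns
#' @param model "A" (observed codes plus emission covariates Z/blocked),
#'   "B" or "C" (recoded two-state sequences)
#' @return a \code{pm_panel}
#' @export
counts_to_panel <- function(counts_df, model = c("A", "B", "C")) {
  model <- match.arg(model)
  stopifnot(all(c("subject", "time", "count") %in% names(counts_df)))
  counts_df <- counts_df[order(counts_df$subject, counts_df$time), ]
  parts <- lapply(split(counts_df, counts_df$subject, drop = TRUE),
                  function(d) {
    rc <- recode_zero_runs(d$count)
    extra <- d[, setdiff(names(d), c("subject", "time", "count")),
               drop = FALSE]
    st <- switch(model, A = rc$code, B = rc$state_B, C = rc$state_C)
    out <- data.frame(subject = d$subject, time = d$time, state = st,
                      exact = 0L)
    if (model == "A") {
      out$Z <- rc$zfirst
      out$blocked <- rc$blocked
    }
    cbind(out, extra)
  })
  pm_panel(do.call(rbind, c(parts, list(make.row.names = FALSE))))
}

#' Posterior probability of active disease at an ambiguous zero-count visit
#'
#' Bayes' rule with \eqn{\Pr(O_2|S_2) = 1}:
#' \deqn{\Pr(S_1 | O_2) = \frac{p\,\pi_1}{p\,\pi_1 + \pi_2}}
#' where \eqn{p = \Pr(O_2|S_1)} and \eqn{\pi_1, \pi_2} are the occupancy
#' proportions of S1 and S2 (e.g. the proportions of expected length of stay
#' over a reporting period, renormalized over \{S1, S2\}).
#'
#' @param p_o2_s1 misclassification probability \eqn{\Pr(O_2|S_1)}
#' @param pi1,pi2 nonnegative occupancy weights of S1 and S2
#' @export
misclassification_posterior <- function(p_o2_s1, pi1, pi2) {
  if (any(pi1 < 0) || any(pi2 < 0) || any(pi1 + pi2 <= 0))
    stop("need pi1, pi2 >= 0 with pi1 + pi2 > 0", call. = FALSE)
  if (any(p_o2_s1 < 0 | p_o2_s1 > 1))
    stop("p_o2_s1 must be a probability", call. = FALSE)
  p_o2_s1 * pi1 / (p_o2_s1 * pi1 + pi2)
}
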