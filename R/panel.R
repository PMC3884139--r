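#' Panel data: intermittently observed subject histories
#'
#' A \code{pm_panel} is a long-format data frame with one row per
#' subject-visit and columns
#' \describe{
#'   \item{subject}{subject (cluster) identifier}
#'   \item{unit}{optional unit-process identifier within a subject (e.g. a
#'     joint location); omitted or constant for single-process models}
#'   \item{time}{nonnegative observation time, strictly increasing within a
#'     subject-unit series}
#'   \item{state}{observed state: a 1-based integer code, a comma-joined
#'     censoring set such as \code{"1,2"}, or \code{"*"} for fully unknown}
#'   \item{exact}{0/1 flag: 1 means the state was entered exactly at
#'     \code{time} (e.g. a death date)}
#' }
#' Any remaining columns are covariates, in force from the row's time until
#' the next visit (last value carried forward).
#'
#' @param df a data.frame in the layout above
#' @return the validated data frame with class \code{pm_panel}
#' @export
pm_panel <- function(df) {
  df <- as.data.frame(df)
  need <- c("subject", "time", "state")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("panel data lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (!"unit" %in% names(df)) df$unit <- 1L
  if (!"exact" %in% names(df)) df$exact <- 0L
  df$state <- as.character(df$state)
  df$time <- as.numeric(df$time)
  df$exact <- as.integer(df$exact)
  if (any(df$time < 0)) stop("negative observation time", call. = FALSE)
  if (!all(df$exact %in% c(0L, 1L))) stop("exact must be 0/1", call. = FALSE)
  ord <- order(df$subject, df$unit, df$time)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  key <- paste(df$subject, df$unit)
  for (k in unique(key)) {
    tt <- df$time[key == k]
    if (anyDuplicated(tt))
      stop(sprintf("duplicated (subject, time) rows for series '%s'", k),
           call. = FALSE)
  }
  covcols <- setdiff(names(df), c("subject", "unit", "time", "state",
                                  "exact"))
  structure(df, covariates = covcols, class = c("pm_panel", "data.frame"))
}

panel_cov_cols <- function(data) attr(data, "covariates") %||%
  setdiff(names(data), c("subject", "unit", "time", "state", "exact"))

# parse a state code into an integer vector of possible states
parse_state <- function(s, n_states) {
  if (identical(s, "*")) return(seq_len(n_states))
  v <- suppressWarnings(as.integer(strsplit(s, ",", fixed = TRUE)[[1]]))
  if (anyNA(v) || any(v < 1) || any(v > n_states))
    stop(sprintf("unknown state code '%s'", s), call. = FALSE)
  sort(unique(v))
}

#' Read / write panel data as CSV
#'
#' The CSV dialect is exactly the \code{\link{pm_panel}} layout; the round
#' trip read-write-read is bit-exact on the text representation.
#'
#' @param path file path
#' @export
read_panel_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = c(state = "character"),
                        check.names = FALSE)
  out <- tryCatch(pm_panel(df), error = function(e)
    stop(sprintf("invalid panel file '%s': %s", path, conditionMessage(e)),
         call. = FALSE))
  out
}

#' @rdname read_panel_csv
#' @param data a \code{pm_panel}
#' @export
write_panel_csv <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

# split a panel into per-series lists, in (subject, unit) order
panel_series <- function(data) {
  key <- paste(data$subject, data$unit, sep = "\r")
  idx <- split(seq_len(nrow(data)), factor(key, levels = unique(key)))
  idx
}
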