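# Open-format persistence: canonical trial CSV, norming-ratings CSV,
# posterior-draw CSV and JSON fit reports.

#' Read and write the canonical trial table
#'
#' The canonical schema has columns participant_id, task, trial_index,
#' word_id, group, response, rt_ms, timeout, correct; times in milliseconds.
#'
#' @param trials Trial data.frame.
#' @param path File path.
#' @return `read_trials` returns the trial data.frame.
#' @export
write_trials <- function(trials, path) {
  write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  tr <- read.csv(path, stringsAsFactors = FALSE)
  tr$timeout <- as.logical(tr$timeout)
  tr$correct <- as.logical(tr$correct)
  tr
}

#' Write norming ratings in long format
#'
#' One row per rater x word x scale: columns rater, word, scale, value.
#'
#' @param ratings Output of [generate_ratings()].
#' @param path File path.
#' @export
write_ratings <- function(ratings, path) {
  long <- function(m, scale) {
    data.frame(rater = rep(rownames(m), times = ncol(m)),
               word = rep(colnames(m), each = nrow(m)),
               scale = scale, value = as.vector(m))
  }
  write.csv(rbind(long(ratings$emotional, "emotional"),
                  long(ratings$moral, "moral")),
            path, row.names = FALSE)
  invisible(path)
}

#' Persist posterior draws as long-format CSV
#'
#' Columns: parameter, chain, iteration, value. Only group-level parameters
#' and the deviance are written (participant-level draws stay in the fit
#' object).
#'
#' @param fit A `ddm_fit`.
#' @param path File path.
#' @export
write_chains <- function(fit, path) {
  ch <- fit$chains
  long <- data.frame(
    parameter = rep(colnames(ch), each = nrow(ch)),
    chain = 1L,
    iteration = rep(seq_len(nrow(ch)), times = ncol(ch)),
    value = as.vector(ch)
  )
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Read posterior draws written by [write_chains()]
#'
#' @param path File path.
#' @return Iterations x parameters numeric matrix.
#' @export
read_chains <- function(path) {
  long <- read.csv(path, stringsAsFactors = FALSE)
  params <- unique(long$parameter)
  n <- max(long$iteration)
  m <- matrix(NA_real_, n, length(params), dimnames = list(NULL, params))
  for (p in params) m[, p] <- long$value[long$parameter == p]
  m
}
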