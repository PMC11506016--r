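# Trial-level filtering: the two exclusion rules applied before RT analyses.

#' Filter trials for analysis
#'
#' Applies the two standard exclusions in order: first timeout trials
#' (response slower than the deadline or no response), then incorrect
#' responses. The function is idempotent. The attached report gives counts
#' and percentages per task.
#'
#' @param trials Canonical trial table (see [simulate_dataset()]); needs
#'   columns `task`, `timeout`, `correct`, `rt_ms`.
#' @param deadline_ms Response deadline; trials with `rt_ms` above it are
#'   treated as timeouts even if not flagged (default 1600).
#' @return List with `trials` (kept rows) and `report` (per-task data.frame:
#'   n_total, n_timeout, n_error, n_kept and the matching percentages).
#' @examples
#' d <- generate_design(seed = 1, n_participants = 2)
#' tr <- generate_true_params(truth_scenario(), 2, seed = 1)
#' f <- filter_trials(simulate_dataset(d, tr, seed = 1))
#' f$report
#' @export
filter_trials <- function(trials, deadline_ms = 1600) {
  need <- c("task", "timeout", "correct", "rt_ms")
  if (!all(need %in% names(trials)))
    stop("trial table lacks columns: ", paste(setdiff(need, names(trials)), collapse = ", "))
  is_timeout <- trials$timeout | is.na(trials$correct) | trials$rt_ms > deadline_ms
  after_timeout <- trials[!is_timeout, , drop = FALSE]
  is_error <- !after_timeout$correct
  kept <- after_timeout[!is_error, , drop = FALSE]
  rownames(kept) <- NULL

  per_task <- function(tsk) {
    n_tot <- sum(trials$task == tsk)
    n_to <- sum(is_timeout & trials$task == tsk)
    n_err <- sum(is_error & after_timeout$task == tsk)
    n_keep <- n_tot - n_to - n_err
    data.frame(task = tsk, n_total = n_tot, n_timeout = n_to, n_error = n_err,
               n_kept = n_keep,
               pct_timeout = 100 * n_to / n_tot,
               pct_error = 100 * n_err / n_tot,
               pct_kept = 100 * n_keep / n_tot)
  }
  report <- do.call(rbind, lapply(unique(trials$task), per_task))
  rownames(report) <- NULL
  list(trials = kept, report = report)
}
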