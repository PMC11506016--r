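# Ground-truth scenarios and diffusion-based simulation of the full study.

#' Ground-truth scenario for the synthetic study
#'
#' Defines the group-level generating parameters for the twelve valence
#' groups, the shared starting point, and between-participant spreads. The
#' default `"study_pattern"` scenario encodes the qualitative effect
#' structure the package is built to detect: for moral words the drift rate
#' rises with emotional valence; for immoral words the boundary separation
#' falls with emotional valence; moral valence moves nothing; and the
#' starting point sits slightly below the midpoint (a negative/immoral
#' response bias). Values are round numbers chosen for desk-scale
#' recoverability, not estimates of any particular dataset.
#'
#' @param name One of `"study_pattern"` (z_rel 0.45), `"strong_bias"`
#'   (z_rel 0.35), `"no_bias"` (z_rel 0.5) or `"null"` (no valence effects).
#' @param z_rel Optional override of the group-level starting point.
#' @param sd_v,sd_a,sd_tau,sd_z Between-participant SDs.
#' @return A `truth_scenario` object: per-group v, a, tau plus z_rel and SDs.
#' @examples
#' truth_scenario("study_pattern")
#' @export
truth_scenario <- function(name = c("study_pattern", "strong_bias", "no_bias",
                                    "null"),
                           z_rel = NULL, sd_v = 0.3, sd_a = 0.2,
                           sd_tau = 0.05, sd_z = 0.05) {
  name <- match.arg(name)
  cells <- .cell_levels(.cell_labels())
  moral <- grepl("^moral", cells$label)
  v_by_emo <- c(`0` = 1.6, `1` = 2.4, `2` = 3.2)
  a_by_emo <- c(`0` = 1.7, `1` = 1.5, `2` = 1.3)
  if (name == "null") {
    v <- ifelse(moral, 2.2, -2.2)
    a <- rep(1.45, nrow(cells))
  } else {
    v <- ifelse(moral, v_by_emo[as.character(cells$emotional_level)], -2.0)
    a <- ifelse(moral, 1.4, a_by_emo[as.character(cells$emotional_level)])
  }
  z <- switch(name, study_pattern = 0.45, strong_bias = 0.35,
              no_bias = 0.5, null = 0.5)
  if (!is.null(z_rel)) z <- z_rel
  structure(list(
    name = name,
    group = data.frame(group = cells$label, v = as.numeric(v),
                       a = as.numeric(a), tau = 0.32, row.names = NULL),
    z_rel = z, sd_v = sd_v, sd_a = sd_a, sd_tau = sd_tau, sd_z = sd_z,
    # emotional-task non-decision shifts (seconds) giving that task's small
    # mean RT offsets relative to the moral task
    emo_task_tau_shift = c(moral = 0.007, immoral = -0.016)
  ), class = "truth_scenario")
}

#' @export
print.truth_scenario <- function(x, ...) {
  cat(sprintf("truth scenario '%s': z_rel = %.2f, SDs (v,a,tau,z) = %.2f/%.2f/%.2f/%.2f\n",
              x$name, x$z_rel, x$sd_v, x$sd_a, x$sd_tau, x$sd_z))
  print(x$group)
  invisible(x)
}

#' Draw participant-level true parameters from a scenario
#'
#' Participant parameters are group-level values plus Normal
#' between-participant deviations, redrawn when they fall outside validity
#' bounds (a > 0.3, tau > 0.05, z_rel in (0.05, 0.95)). The starting point is
#' drawn once per participant and shared across all twelve groups. An error
#' is raised if more than 5% of draws needed truncation, which would signal
#' a degenerate scenario.
#'
#' @param scenario A [truth_scenario()] object.
#' @param n_participants Number of participants (default 30).
#' @param seed Integer seed.
#' @return A long data.frame: participant_id x group with columns v, a, tau,
#'   z_rel.
#' @export
generate_true_params <- function(scenario, n_participants = 30, seed = 1) {
  if (!inherits(scenario, "truth_scenario")) stop("'scenario' must be a truth_scenario")
  .with_seed(seed, {
    g <- scenario$group
    n_redraw <- 0L
    n_total <- 0L
    draw_trunc <- function(n, mean, sd, lo, hi) {
      x <- rnorm(n, mean, sd)
      n_total <<- n_total + n
      bad <- which(x <= lo | x >= hi)
      while (length(bad) > 0L) {
        n_redraw <<- n_redraw + length(bad)
        x[bad] <- rnorm(length(bad), mean[bad], sd)
        bad <- bad[x[bad] <= lo | x[bad] >= hi]
      }
      x
    }
    pid <- sprintf("P%02d", seq_len(n_participants))
    out <- g[rep(seq_len(nrow(g)), times = n_participants), ]
    out$participant_id <- rep(pid, each = nrow(g))
    out$v <- draw_trunc(nrow(out), out$v, scenario$sd_v, -12, 12)
    out$a <- draw_trunc(nrow(out), out$a, scenario$sd_a, 0.3, 6)
    out$tau <- draw_trunc(nrow(out), out$tau, scenario$sd_tau, 0.05, 1.5)
    zp <- draw_trunc(n_participants, rep(scenario$z_rel, n_participants),
                     scenario$sd_z, 0.05, 0.95)
    out$z_rel <- rep(zp, each = nrow(g))
    if (n_redraw > 0.05 * n_total)
      stop("scenario produced > 5% invalid parameter draws")
    rownames(out) <- NULL
    out[, c("participant_id", "group", "v", "a", "tau", "z_rel")]
  })
}

#' Simulate the full trial table of the study
#'
#' Runs the diffusion simulator for every scheduled trial. In the moral
#' evaluation task the upper boundary is the "moral" response and the lower
#' the "immoral" response; in the emotional task the boundaries are
#' relabeled "positive"/"negative". Drift carries the word's sign (moral
#' words positive, immoral negative), so the correct response is the upper
#' boundary for moral words and the lower for immoral words in both tasks.
#' Responses slower than the deadline (and paths unabsorbed by it) are
#' timeout trials with no recorded choice.
#'
#' @param design Output of [generate_design()].
#' @param truth Output of [generate_true_params()] built from the same or a
#'   compatible scenario; the scenario's emotional-task tau shifts are taken
#'   from `scenario`.
#' @param scenario The [truth_scenario()] the truth was drawn from (for the
#'   emotional-task non-decision offsets); defaults to no offsets if NULL.
#' @param seed Integer seed.
#' @param deadline_ms Response deadline in milliseconds (default 1600).
#' @param dt Simulator step in seconds.
#' @return The canonical trial table: participant_id, task, trial_index,
#'   word_id, group, response, rt_ms, timeout, correct.
#' @examples
#' d <- generate_design(seed = 1, n_participants = 2)
#' tr <- generate_true_params(truth_scenario(), n_participants = 2, seed = 1)
#' head(simulate_dataset(d, tr, seed = 1))
#' @export
simulate_dataset <- function(design, truth, scenario = NULL, seed = 1,
                             deadline_ms = 1600, dt = 1e-4) {
  sched <- design$schedule
  stim <- design$stimuli
  key <- paste(truth$participant_id, truth$group)
  idx <- match(paste(sched$participant_id, sched$group), key)
  if (anyNA(idx)) stop("missing true parameters for some participant x group cell")
  wt <- stim$word_type[match(sched$word_id, stim$word_id)]
  shift <- if (is.null(scenario)) c(moral = 0, immoral = 0) else
    scenario$emo_task_tau_shift
  tau <- truth$tau[idx] + ifelse(sched$task == "emotional", shift[wt], 0)
  res <- sim_schedule_cpp(truth$v[idx], truth$a[idx], truth$z_rel[idx],
                          tau, dt, deadline_ms / 1000, as.double(seed))
  rt_ms <- res$rt * 1000
  timeout <- res$boundary < 0 | (!is.na(rt_ms) & rt_ms > deadline_ms)
  up <- res$boundary == 1 & !timeout
  pos_lab <- ifelse(sched$task == "moral", "moral", "positive")
  neg_lab <- ifelse(sched$task == "moral", "immoral", "negative")
  response <- ifelse(timeout, NA_character_, ifelse(up, pos_lab, neg_lab))
  correct <- ifelse(timeout, NA, up == (wt == "moral"))
  data.frame(
    participant_id = sched$participant_id,
    task = sched$task,
    trial_index = sched$trial_index,
    word_id = sched$word_id,
    group = sched$group,
    response = response,
    rt_ms = ifelse(timeout, deadline_ms, round(rt_ms, 1)),
    timeout = timeout,
    correct = correct,
    row.names = NULL
  )
}
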