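# Experimental design generator: the 96-word stimulus set filling the twelve
# valence-group cells, and per-participant trial schedules for the two
# evaluation tasks.

#' Generate the stimulus set and trial schedules
#'
#' Builds the canonical study design: 96 stimuli (48 moral, 48 immoral words)
#' filling the twelve populated cells of the emotional x moral valence grid
#' with 8 words each, plus per-participant trial schedules. Each participant
#' completes two tasks (emotional evaluation, moral evaluation) of 192 trials
#' each -- every word presented twice per task in freshly shuffled order.
#' Task order and response-key mapping are counterbalanced across
#' participants. Stimulus covariates (stroke count, frequency per million)
#' are drawn from the same distribution for moral and immoral words so that
#' the matching t-tests hold by construction.
#'
#' @param seed Integer seed.
#' @param n_participants Number of participants (default 30).
#' @return A list with `stimuli` (96-row data.frame: word_id, word_type,
#'   label, group, emotional/moral levels and mean ratings, strokes,
#'   frequency) and `schedule` (one row per scheduled trial: participant_id,
#'   task, task_position, trial_index, word_id, group, key_map).
#' @examples
#' d <- generate_design(seed = 1, n_participants = 2)
#' table(d$schedule$participant_id, d$schedule$task)
#' @export
generate_design <- function(seed = 1, n_participants = 30) {
  if (n_participants < 1) stop("'n_participants' must be >= 1")
  .with_seed(seed, {
    cells <- .cell_levels(.cell_labels())
    stim <- cells[rep(seq_len(nrow(cells)), each = 8L), ]
    n <- nrow(stim)  # 96
    word_type <- ifelse(grepl("^moral", stim$label), "moral", "immoral")
    lab <- sub("^(moral|immoral)_", "", stim$label)
    levels_int <- c(`0` = 1.0, `1` = 2.6, `2` = 3.6)
    sgn <- ifelse(word_type == "moral", 1, -1)
    stimuli <- data.frame(
      word_id = sprintf("W%03d", seq_len(n)),
      word_type = word_type,
      label = lab,
      group = stim$label,
      emotional_level = stim$emotional_level,
      moral_level = stim$moral_level,
      emotional_rating = 5 + sgn * (levels_int[as.character(stim$emotional_level)] +
                                      rnorm(n, 0, 0.1)),
      moral_rating = 5 + sgn * (levels_int[as.character(stim$moral_level)] +
                                  rnorm(n, 0, 0.1)),
      strokes = sample(5:18, n, replace = TRUE),
      frequency = round(exp(rnorm(n, 2, 0.8)), 2),
      row.names = NULL
    )

    tasks <- c("emotional", "moral")
    sched <- vector("list", n_participants * 2L)
    k <- 0L
    for (p in seq_len(n_participants)) {
      order_flip <- (p %% 2L) == 0L           # task order counterbalance
      key_map <- if (((p - 1L) %/% 2L) %% 2L == 0L) "F_pos_moral" else "J_pos_moral"
      task_seq <- if (order_flip) rev(tasks) else tasks
      for (ti in seq_along(task_seq)) {
        ord <- sample(rep(seq_len(n), 2L))     # each word twice, shuffled
        k <- k + 1L
        sched[[k]] <- data.frame(
          participant_id = sprintf("P%02d", p),
          task = task_seq[ti],
          task_position = ti,
          trial_index = seq_along(ord),
          word_id = stimuli$word_id[ord],
          group = stimuli$group[ord],
          key_map = key_map,
          row.names = NULL
        )
      }
    }
    list(stimuli = stimuli, schedule = do.call(rbind, sched))
  })
}
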