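# Synthetic stimulus norming study: a panel of raters scores candidate words
# on two 1-9 Likert scales (emotional and moral valence, 5 = neutral).

# run code with a local RNG state so callers' streams are untouched
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# true (signed) 1-9 scale scores for the designed word inventory:
# the first 96 words fill the twelve valence-group cells (8 words each) with
# intensity levels placed well inside the selection threshold; the remainder
# are near-neutral fillers that the selection rule should drop.
.norming_truth <- function(n_words, jitter_sd = 0.1) {
  levels_int <- c(`0` = 1.0, `1` = 2.6, `2` = 3.6)
  cells <- .cell_levels(.cell_labels())
  tgt <- cells[rep(seq_len(nrow(cells)), each = 8L), ]
  sign <- ifelse(grepl("^moral", tgt$label), 1, -1)
  emo_int <- levels_int[as.character(tgt$emotional_level)] +
    rnorm(nrow(tgt), 0, jitter_sd)
  mor_int <- levels_int[as.character(tgt$moral_level)] +
    rnorm(nrow(tgt), 0, jitter_sd)
  n_fill <- n_words - nrow(tgt)
  if (n_fill < 0) stop("'n_words' must be at least 96")
  data.frame(
    word_id = sprintf("W%03d", seq_len(n_words)),
    word_type = c(ifelse(sign > 0, "moral", "immoral"), rep("filler", n_fill)),
    cell = c(tgt$label, rep(NA_character_, n_fill)),
    true_emotional = 5 + c(sign * emo_int, runif(n_fill, -1.1, 1.1)),
    true_moral = 5 + c(sign * mor_int, runif(n_fill, -1.1, 1.1)),
    row.names = NULL
  )
}

#' Generate synthetic norming ratings
#'
#' Emulates a word-norming questionnaire: `n_raters` raters score `n_words`
#' candidate words on two 1-9 scales (emotional and moral valence, 5 =
#' neutral). Ratings are the word's true scale value plus a rater-severity
#' random effect plus trial noise, rounded to the Likert grid and clipped to
#' 1-9. The severity effect is what gives the questionnaire its inter-rater
#' consistency; the default noise scales are tuned so that Cronbach's alpha
#' (raters as cases, words as items) lands near 0.94-0.95 on both scales.
#'
#' @param n_raters Number of raters (>= 2), default 31.
#' @param n_words Number of candidate words (>= 96), default 230.
#' @param seed Integer seed.
#' @param rater_sd SD of per-rating noise (0 gives perfectly consistent
#'   raters up to their severity offsets, hence alpha = 1 when
#'   `discretize = FALSE`).
#' @param rater_bias_sd SD of the rater-severity random effect (0 gives
#'   independent ratings and alpha near 0).
#' @param discretize Round to the 1-9 Likert grid (default TRUE).
#' @return A list with components `emotional` and `moral` (numeric
#'   rater x word matrices) and `words` (data.frame of true scores and
#'   intended cell labels).
#' @examples
#' r <- generate_ratings(seed = 1)
#' cronbach_alpha(r$emotional)
#' @export
generate_ratings <- function(n_raters = 31, n_words = 230, seed = 1,
                             rater_sd = 1.2, rater_bias_sd = 0.36,
                             discretize = TRUE) {
  if (n_raters < 2 || n_words < 96) stop("need >= 2 raters and >= 96 words")
  .with_seed(seed, {
    words <- .norming_truth(n_words)
    one_scale <- function(true_scores) {
      bias <- rnorm(n_raters, 0, rater_bias_sd)
      m <- outer(bias, true_scores, `+`) +
        matrix(rnorm(n_raters * n_words, 0, rater_sd), n_raters, n_words)
      if (discretize) m <- round(m)
      m[m < 1] <- 1
      m[m > 9] <- 9
      dimnames(m) <- list(sprintf("R%02d", seq_len(n_raters)), words$word_id)
      m
    }
    list(emotional = one_scale(words$true_emotional),
         moral = one_scale(words$true_moral),
         words = words)
  })
}

#' Summarise norming ratings into per-word mean scores
#'
#' @param ratings Output of [generate_ratings()] (or a compatible list of two
#'   rater x word matrices).
#' @return A data.frame with one row per word: mean `emotional_rating` and
#'   `moral_rating` plus the truth columns when available.
#' @export
rating_means <- function(ratings) {
  out <- data.frame(
    word_id = colnames(ratings$emotional),
    emotional_rating = colMeans(ratings$emotional),
    moral_rating = colMeans(ratings$moral),
    row.names = NULL
  )
  if (!is.null(ratings$words)) {
    out <- merge(out, ratings$words, by = "word_id", sort = FALSE)
  }
  out[order(out$word_id), , drop = FALSE]
}
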