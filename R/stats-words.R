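# Word-level statistics: intensity transform, selection rule, valence-level
# binning, reliability and stimulus-matching tests.

#' Valence intensity transform
#'
#' Distance of a 1-9 Likert score from the neutral midpoint 5, giving a 0-4
#' intensity scale that puts moral and immoral (positive and negative) words
#' on a common footing.
#'
#' @param score Numeric scores in \[1, 9\].
#' @return `abs(score - 5)`.
#' @examples
#' intensity(c(5, 7, 1))  # 0 2 4
#' @export
intensity <- function(score) {
  if (!is.numeric(score) || any(!is.finite(score)))
    stop("'score' must be finite numeric")
  if (any(score < 1 | score > 9)) stop("'score' must lie in [1, 9]")
  abs(score - 5)
}

#' Select experimental words by valence intensity
#'
#' Keeps words whose intensity exceeds the threshold on the emotional OR the
#' moral dimension (strict inequality; boundary words are dropped).
#'
#' @param words Data.frame with columns `emotional_rating` and `moral_rating`
#'   (1-9 mean scores), e.g. from [rating_means()].
#' @param threshold Intensity threshold on the 0-4 scale (default 2).
#' @return The selected subset, with `emotional_intensity` and
#'   `moral_intensity` columns added.
#' @export
select_words <- function(words, threshold = 2) {
  words$emotional_intensity <- intensity(words$emotional_rating)
  words$moral_intensity <- intensity(words$moral_rating)
  keep <- words$emotional_intensity > threshold | words$moral_intensity > threshold
  out <- words[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign emotional and moral valence levels by binning intensities
#'
#' Splits each intensity dimension into three levels (0 = low, 1 = medium,
#' 2 = high). The default divides the observed range of each dimension into
#' three equal-width bins; `binning = "equal_freq"` uses tertiles instead. A
#' value landing exactly on an interior bin edge goes to the upper bin.
#' Cells outside the populated pattern of the design grid (e.g. a
#' low-emotional low-moral word) are flagged rather than silently kept.
#'
#' @param words Output of [select_words()] with a `word_type` column
#'   (`"moral"`/`"immoral"`).
#' @param binning `"equal_width"` (default) or `"equal_freq"`.
#' @return `words` with `emotional_level`, `moral_level` and `label` columns
#'   plus an attribute `"rejected"` holding rows whose cell is not part of
#'   the design grid.
#' @export
assign_valence_levels <- function(words, binning = c("equal_width", "equal_freq")) {
  binning <- match.arg(binning)
  if (nrow(words) == 0L) stop("'words' is empty")
  if (!all(c("emotional_intensity", "moral_intensity") %in% names(words)))
    words <- select_words(words, threshold = -1)  # just adds intensities
  bin3 <- function(x) {
    if (binning == "equal_width") {
      edges <- min(x) + (max(x) - min(x)) * c(1, 2) / 3
    } else {
      edges <- quantile(x, c(1, 2) / 3, names = FALSE)
    }
    (x >= edges[1]) + (x >= edges[2])  # exact edge -> upper bin
  }
  words$emotional_level <- bin3(words$emotional_intensity)
  words$moral_level <- bin3(words$moral_intensity)
  words$label <- paste0(words$emotional_level, "V", words$moral_level, "M")
  ok <- words$label %in% sub("^(moral|immoral)_", "", .cell_labels())
  out <- words[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- words[!ok, , drop = FALSE]
  out
}

#' Cronbach's alpha
#'
#' Internal-consistency reliability `k/(k-1) * (1 - sum(item variances) /
#' var(total score))` for a cases x items matrix. For norming ratings the
#' raters are the cases (rows) and the words the items (columns).
#'
#' @param x Numeric matrix, rows = cases, columns = items (>= 2 each).
#' @return Scalar alpha.
#' @examples
#' m <- matrix(rnorm(50), 10, 5)
#' cronbach_alpha(cbind(m, m))  # duplicated items push alpha up
#' @export
cronbach_alpha <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L || ncol(x) < 2L) stop("need >= 2 cases and >= 2 items")
  k <- ncol(x)
  total_var <- var(rowSums(x))
  if (total_var <= 0) stop("zero total-score variance; alpha undefined")
  k / (k - 1) * (1 - sum(apply(x, 2, var)) / total_var)
}

#' Stimulus matching t-tests between word groups
#'
#' Independent two-sample t-tests (pooled variance, df = n1 + n2 - 2)
#' comparing moral and immoral words on each matching covariate, with
#' Cohen's d (pooled SD). Used to verify that the two word groups differ
#' only in their nature, not in intensity or surface properties.
#'
#' @param words Data.frame with a `word_type` column (`"moral"`/`"immoral"`)
#'   and the covariate columns.
#' @param covariates Character vector of columns to test; defaults to the
#'   intensity and surface covariates present in `words`.
#' @return Data.frame with one row per covariate: t, df, p, cohens_d.
#' @export
match_stimuli_ttests <- function(words,
                                 covariates = intersect(
                                   c("moral_intensity", "emotional_intensity",
                                     "strokes", "frequency"), names(words))) {
  g1 <- words[words$word_type == "moral", , drop = FALSE]
  g2 <- words[words$word_type == "immoral", , drop = FALSE]
  if (nrow(g1) < 2L || nrow(g2) < 2L) stop("each word group needs >= 2 words")
  res <- lapply(covariates, function(cv) {
    x <- g1[[cv]]; y <- g2[[cv]]
    n1 <- length(x); n2 <- length(y)
    sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
    tval <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
    data.frame(covariate = cv, t = tval, df = df,
               p = 2 * pt(-abs(tval), df),
               cohens_d = (mean(x) - mean(y)) / sqrt(sp2))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
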