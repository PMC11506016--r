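# Repeated-measures ANOVA, simple effects, paired t-tests with FDR and the
# power-based sample-size computation.

.parse_cells <- function(cells) {
  cells <- as.matrix(cells)
  if (ncol(cells) != 4L) stop("'cells' must have exactly 4 columns")
  if (nrow(cells) < 2L) stop("need >= 2 participants")
  if (any(!is.finite(cells))) stop("missing cells are not allowed")
  cn <- colnames(cells)
  if (is.null(cn) || !all(grepl(":", cn))) {
    cn <- c("A1:B1", "A1:B2", "A2:B1", "A2:B2")
    colnames(cells) <- cn
  }
  lv <- do.call(rbind, strsplit(cn, ":", fixed = TRUE))
  list(y = cells, A = lv[, 1], B = lv[, 2])
}

#' Two-by-two repeated-measures ANOVA
#'
#' Classic within-subject sums-of-squares decomposition for a 2 x 2 fully
#' repeated design: each effect (factor A, factor B, A x B) is tested
#' against its own effect-by-subject interaction. Effect sizes are partial
#' eta squared, `SS_effect / (SS_effect + SS_error)`.
#'
#' @param cells Numeric participant x 4 matrix of cell means. Column names
#'   of the form `"<Alevel>:<Blevel>"` (e.g. `"emotional:moral"`) identify
#'   the design; columns must be ordered A1:B1, A1:B2, A2:B1, A2:B2 when
#'   names are absent.
#' @param factors Length-2 character vector naming the two factors (for the
#'   output labels only).
#' @return Data.frame of class `anova_rm` with one row per effect: F, df1,
#'   df2, p, partial_eta_sq.
#' @examples
#' set.seed(1)
#' y <- matrix(rnorm(120, 600, 50), 30, 4,
#'             dimnames = list(NULL, c("emo:mor", "emo:imm", "mor:mor", "mor:imm")))
#' rm_anova_2x2(y, factors = c("task", "word"))
#' @export
rm_anova_2x2 <- function(cells, factors = c("A", "B")) {
  p <- .parse_cells(cells)
  y <- p$y
  n <- nrow(y)
  gm <- mean(y)
  ms <- rowMeans(y)                      # subject means
  mA <- tapply(colMeans(y), p$A, mean)[unique(p$A)]
  mB <- tapply(colMeans(y), p$B, mean)[unique(p$B)]
  mAs <- sapply(unique(p$A), function(a) rowMeans(y[, p$A == a, drop = FALSE]))
  mBs <- sapply(unique(p$B), function(b) rowMeans(y[, p$B == b, drop = FALSE]))
  mAB <- colMeans(y)

  ss_A <- n * 2 * sum((mA - gm)^2)
  ss_AxS <- 2 * sum((mAs - outer(ms, rep(1, 2)) -
                       outer(rep(1, n), mA) + gm)^2)
  ss_B <- n * 2 * sum((mB - gm)^2)
  ss_BxS <- 2 * sum((mBs - outer(ms, rep(1, 2)) -
                       outer(rep(1, n), mB) + gm)^2)
  mab_eff <- mAB - mA[p$A] - mB[p$B] + gm
  ss_AB <- n * sum(mab_eff^2)
  resid <- y
  for (j in seq_len(4L)) {
    a <- p$A[j]; b <- p$B[j]
    resid[, j] <- y[, j] - mAB[j] - mAs[, match(a, unique(p$A))] -
      mBs[, match(b, unique(p$B))] + mA[a] + mB[b] + ms - gm
  }
  ss_ABxS <- sum(resid^2)

  one <- function(effect, ss_e, ss_err) {
    df1 <- 1; df2 <- n - 1
    Fv <- if (ss_err == 0) 0 else (ss_e / df1) / (ss_err / df2)
    data.frame(effect = effect, F = Fv, df1 = df1, df2 = df2,
               p = pf(Fv, df1, df2, lower.tail = FALSE),
               partial_eta_sq = if (ss_e + ss_err == 0) 0 else ss_e / (ss_e + ss_err))
  }
  out <- rbind(one(factors[1], ss_A, ss_AxS),
               one(factors[2], ss_B, ss_BxS),
               one(paste0(factors[1], " x ", factors[2]), ss_AB, ss_ABxS))
  rownames(out) <- NULL
  class(out) <- c("anova_rm", "data.frame")
  out
}

#' @export
print.anova_rm <- function(x, ...) {
  for (i in seq_len(nrow(x))) {
    cat(sprintf("%-16s F(%d,%d) = %.2f, p = %.4g, partial eta^2 = %.2f\n",
                x$effect[i], x$df1[i], x$df2[i], x$F[i], x$p[i],
                x$partial_eta_sq[i]))
  }
  invisible(x)
}

#' Simple effect of one within-subject factor at a level of the other
#'
#' One-way repeated-measures F test comparing the two cells that share the
#' given level of the other factor; with two cells this equals the squared
#' paired t statistic.
#'
#' @param cells As in [rm_anova_2x2()].
#' @param within Name of the factor whose effect is tested: `"A"`/`"B"` or
#'   its name in `factors`.
#' @param at Level of the *other* factor at which to test.
#' @param factors Length-2 character vector naming the two factors, matching
#'   [rm_anova_2x2()].
#' @return One-row data.frame: F, df1, df2, p, partial_eta_sq.
#' @export
simple_effects <- function(cells, within, at, factors = c("A", "B")) {
  p <- .parse_cells(cells)
  a_lv <- unique(p$A); b_lv <- unique(p$B)
  vary_b <- within %in% c("B", factors[2])
  vary_a <- within %in% c("A", factors[1])
  if (!vary_a && !vary_b) stop("unknown factor '", within, "'")
  if (vary_b && at %in% a_lv) {
    sel <- p$A == at
  } else if (vary_a && at %in% b_lv) {
    sel <- p$B == at
  } else {
    stop("unknown level '", at, "'")
  }
  y <- p$y[, sel, drop = FALSE]
  if (ncol(y) != 2L) stop("simple effect needs exactly two cells")
  n <- nrow(y)
  gm <- mean(y)
  mb <- colMeans(y)
  ms <- rowMeans(y)
  ss_eff <- n * sum((mb - gm)^2)
  ss_err <- sum((y - outer(rep(1, n), mb) - outer(ms, rep(1, 2)) + gm)^2)
  Fv <- if (ss_err == 0) 0 else ss_eff / (ss_err / (n - 1))
  data.frame(F = Fv, df1 = 1, df2 = n - 1,
             p = pf(Fv, 1, n - 1, lower.tail = FALSE),
             partial_eta_sq = if (ss_eff + ss_err == 0) 0 else
               ss_eff / (ss_eff + ss_err))
}

#' Paired t-tests with Benjamini-Hochberg FDR correction
#'
#' Runs two-sided paired t-tests for a family of comparisons and adjusts the
#' p-values with the Benjamini-Hochberg step-up procedure across the whole
#' family. Cohen's d is the mean paired difference over its SD.
#'
#' @param comparisons Named list; each element is a list or data.frame with
#'   two equal-length numeric components `x` and `y` (or the first two
#'   columns).
#' @return Data.frame: comparison, t, df, p_raw, p_fdr, cohens_d.
#' @examples
#' cmp <- list(a = list(x = rnorm(10), y = rnorm(10)),
#'             b = list(x = rnorm(10, 1), y = rnorm(10)))
#' paired_t_fdr(cmp)
#' @export
paired_t_fdr <- function(comparisons) {
  if (!is.list(comparisons) || length(comparisons) == 0L)
    stop("'comparisons' must be a non-empty list")
  nm <- names(comparisons)
  if (is.null(nm)) nm <- paste0("cmp", seq_along(comparisons))
  res <- lapply(seq_along(comparisons), function(i) {
    cc <- comparisons[[i]]
    x <- if (!is.null(cc$x)) cc$x else cc[[1]]
    y <- if (!is.null(cc$y)) cc$y else cc[[2]]
    if (length(x) != length(y)) stop("comparison '", nm[i], "': length mismatch")
    if (length(x) < 2L) stop("comparison '", nm[i], "': need >= 2 pairs")
    d <- x - y
    n <- length(d)
    # direct paired t; a zero-variance difference (identical vectors) is
    # reported as t = 0, p = 1 rather than an error
    if (sd(d) == 0) {
      tval <- 0; pval <- 1
    } else {
      tval <- mean(d) / (sd(d) / sqrt(n))
      pval <- 2 * pt(-abs(tval), n - 1)
    }
    data.frame(comparison = nm[i], t = tval, df = n - 1, p_raw = pval,
               cohens_d = if (sd(d) == 0) 0 else mean(d) / sd(d))
  })
  out <- do.call(rbind, res)
  out$p_fdr <- p.adjust(out$p_raw, method = "BH")
  rownames(out) <- NULL
  out[, c("comparison", "t", "df", "p_raw", "p_fdr", "cohens_d")]
}

#' Power of a within-subjects repeated-measures ANOVA effect
#'
#' Noncentral-F power following the G*Power "within factors" convention:
#' noncentrality `lambda = f^2 * n * m / (1 - rho)`, numerator df
#' `(m - 1) * eps`, denominator df `(n - 1) * (m - 1) * eps`.
#'
#' @param n Sample size (participants).
#' @param f Cohen's f effect size.
#' @param alpha Significance level.
#' @param m Number of repeated measurements.
#' @param rho Correlation among repeated measures.
#' @param eps Nonsphericity correction (1 = sphericity).
#' @return Power in (0, 1).
#' @export
rm_anova_power <- function(n, f, alpha = 0.05, m = 4, rho = 0.5, eps = 1) {
  lambda <- f^2 * n * m / (1 - rho)
  df1 <- (m - 1) * eps
  df2 <- (n - 1) * (m - 1) * eps
  crit <- qf(1 - alpha, df1, df2)
  pf(crit, df1, df2, ncp = lambda, lower.tail = FALSE)
}

#' Required sample size for a repeated-measures ANOVA
#'
#' Smallest `n` whose [rm_anova_power()] reaches the target power.
#'
#' @inheritParams rm_anova_power
#' @param power Target power in (0, 1).
#' @param n_max Upper search bound.
#' @return Integer sample size.
#' @examples
#' required_sample_size(f = 0.25, alpha = 0.05, power = 0.85)  # 26
#' @export
required_sample_size <- function(f, alpha = 0.05, power = 0.85, m = 4,
                                 rho = 0.5, eps = 1, n_max = 10000) {
  if (f <= 0) stop("'f' must be > 0")
  if (power <= 0 || power >= 1) stop("'power' must be in (0, 1)")
  if (m < 2) stop("'m' must be >= 2")
  if (rho < 0 || rho >= 1) stop("'rho' must be in [0, 1)")
  for (n in 3:n_max) {
    if (rm_anova_power(n, f, alpha, m, rho, eps) >= power) return(n)
  }
  stop("no n <= ", n_max, " reaches the requested power")
}
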