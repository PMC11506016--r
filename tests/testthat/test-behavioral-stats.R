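# Behavioral statistics: intensity/selection/binning, ANOVA, t-tests, FDR,
# reliability, power.

test_that("intensity transform and its domain checks", {
  expect_equal(intensity(c(5, 7, 1, 9)), c(0, 2, 4, 4))
  expect_error(intensity(10), "\\[1, 9\\]")
})

test_that("word selection uses the either-dimension rule with strict threshold", {
  w <- data.frame(word_id = c("a", "b", "c"),
                  emotional_rating = c(7.5, 7.0, 5.5),  # intensities 2.5, 2, .5
                  moral_rating = c(6.0, 3.0, 4.0))      # intensities 1, 2, 1
  sel <- select_words(w)
  expect_equal(sel$word_id, "a")   # b sits exactly on the boundary, dropped
})

test_that("equal-width binning places edges and ties as documented", {
  w <- data.frame(word_id = letters[1:7], word_type = "moral",
                  emotional_rating = 5 + c(1, 1.5, 2, 2.5, 3, 3.5, 4),
                  moral_rating = 5 + c(3, 3, 3, 3, 3, 3, 3))
  lv <- assign_valence_levels(select_words(w, threshold = -1))
  # recombine kept and grid-rejected rows to inspect the raw binning
  full <- rbind(lv, attr(lv, "rejected"))
  full <- full[order(full$word_id), ]
  # observed range [1, 4] -> edges at 2 and 3; a value exactly on an edge
  # goes to the upper bin
  expect_equal(full$emotional_level, c(0, 0, 1, 1, 2, 2, 2))
})

test_that("filter_trials reports counts and percentages correctly on a toy table", {
  toy <- data.frame(task = "moral",
                    timeout = c(TRUE, rep(FALSE, 9)),
                    correct = c(NA, FALSE, FALSE, rep(TRUE, 7)),
                    rt_ms = c(1600, rep(600, 9)))
  f <- filter_trials(toy)
  expect_equal(nrow(f$trials), 7)
  expect_equal(f$report$pct_timeout, 10)
  expect_equal(f$report$pct_error, 20)
  expect_equal(f$report$pct_kept, 70)
  all_good <- data.frame(task = "x", timeout = FALSE, correct = TRUE, rt_ms = 500)
  expect_equal(nrow(filter_trials(all_good)$trials), 1)
})

test_that("repeated-measures ANOVA matches the definitional oracle", {
  set.seed(42)
  for (rep in 1:5) {
    y <- matrix(rnorm(4 * 4, mean = 600, sd = 40), 4, 4)
    got <- rm_anova_2x2(y)
    want <- oracle_rm_anova(y)
    expect_equal(got$F, c(want$F_A, want$F_B, want$F_AB), tolerance = 1e-10)
    expect_equal(got$partial_eta_sq,
                 c(want$peta_A, want$peta_B, want$peta_AB), tolerance = 1e-10)
  }
})

test_that("ANOVA is exactly null for constant cells and location invariant", {
  y <- matrix(rep(rnorm(10, 500, 30), 4), 10, 4)  # all cells equal per subject
  got <- rm_anova_2x2(y)
  expect_equal(got$F, rep(0, 3))
  set.seed(9)
  y2 <- matrix(rnorm(40), 10, 4)
  expect_equal(rm_anova_2x2(y2)$F, rm_anova_2x2(y2 + 123.4)$F, tolerance = 1e-8)
  expect_error(rm_anova_2x2(y2[, 1:3]), "4 columns")
})

test_that("simple effects equal squared paired t and match the oracle", {
  set.seed(7)
  y <- matrix(rnorm(40, 550, 60), 10, 4,
              dimnames = list(NULL, c("emo:mor", "emo:imm", "mor:mor", "mor:imm")))
  tw <- c("task", "word")
  se <- simple_effects(y, within = "word", at = "mor", factors = tw)
  tt <- t.test(y[, "mor:mor"], y[, "mor:imm"], paired = TRUE)
  expect_equal(se$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(se$p, tt$p.value, tolerance = 1e-10)
  expect_error(simple_effects(y, within = "word", at = "nowhere", factors = tw),
               "unknown level")
  # identical columns give F = 0
  y0 <- y; y0[, 4] <- y0[, 3]
  expect_equal(simple_effects(y0, within = "word", at = "mor", factors = tw)$F, 0)
})

test_that("paired t-tests with BH adjustment reproduce the hand-worked case", {
  # construct four comparisons whose raw p-values are known to be ordered
  set.seed(11)
  base <- rnorm(20)
  cmp <- list(c1 = list(x = base + 2, y = base),
              c2 = list(x = base + 1, y = base),
              c3 = list(x = base + 0.5, y = base),
              c4 = list(x = base, y = base))
  res <- paired_t_fdr(cmp)
  expect_equal(res$p_fdr, oracle_bh(res$p_raw), tolerance = 1e-12)
  expect_equal(res$t[4], 0)
  expect_equal(res$p_raw[4], 1)
  # BH on the textbook vector
  expect_equal(oracle_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
})

test_that("BH adjustment equals the step-up definition on random p-vectors", {
  set.seed(13)
  for (i in 1:200) {
    p <- runif(sample(3:12, 1))^sample(1:3, 1)
    expect_equal(p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("Cronbach's alpha: duplication, Spearman-Brown identity, null case", {
  set.seed(3)
  item <- rnorm(50)
  dup <- cbind(item, item, item)
  expect_equal(cronbach_alpha(dup), 1, tolerance = 1e-12)
  # two standardized items: alpha equals the Spearman-Brown step-up of r
  x <- as.vector(scale(rnorm(200)))
  y <- as.vector(scale(0.6 * x + rnorm(200, 0, 0.8)))
  r <- cor(x, y)
  expect_equal(cronbach_alpha(cbind(x, y)), 2 * r / (1 + r), tolerance = 1e-10)
  # independent items: alpha near zero
  noise <- matrix(rnorm(4000 * 12), 4000, 12)
  expect_lt(abs(cronbach_alpha(noise)), 0.1)
  expect_error(cronbach_alpha(matrix(1, 4, 3)), "variance")
})

test_that("power computation reproduces the planned sample size", {
  expect_equal(required_sample_size(f = 0.25, alpha = 0.05, power = 0.85,
                                    m = 4, rho = 0.5, eps = 1), 26)
  # minimality and monotonicity at the returned n
  n <- 26
  expect_gte(rm_anova_power(n, 0.25, 0.05, 4, 0.5, 1), 0.85)
  expect_lt(rm_anova_power(n - 1, 0.25, 0.05, 4, 0.5, 1), 0.85)
  pw <- sapply(5:60, rm_anova_power, f = 0.25)
  expect_true(all(diff(pw) > 0))
  expect_error(required_sample_size(f = -1), "'f'")
})

test_that("stimulus matching t-tests use pooled df and match the direct formula", {
  d <- generate_design(seed = 77, n_participants = 1)
  st <- select_words(d$stimuli, threshold = -1)
  res <- match_stimuli_ttests(st)
  expect_true(all(res$df == 94))
  # direct-formula oracle on random vectors
  set.seed(19)
  w <- data.frame(word_type = rep(c("moral", "immoral"), each = 15),
                  xx = rnorm(30))
  r <- match_stimuli_ttests(w, covariates = "xx")
  x <- w$xx[1:15]; y <- w$xx[16:30]
  sp <- sqrt((14 * var(x) + 14 * var(y)) / 28)
  t_direct <- (mean(x) - mean(y)) / (sp * sqrt(2 / 15))
  expect_equal(r$t, t_direct, tolerance = 1e-12)
  expect_equal(r$cohens_d, (mean(x) - mean(y)) / sp, tolerance = 1e-12)
  # identical groups give t = 0
  w2 <- data.frame(word_type = rep(c("moral", "immoral"), each = 15),
                   xx = rep(1:15, 2))
  r2 <- match_stimuli_ttests(w2, covariates = "xx")
  expect_equal(r2$t, 0)
  expect_equal(r2$cohens_d, 0)
})
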