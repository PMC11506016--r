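# Shared fixtures and independent oracles used across the test files.
# Expensive objects are built once per test run and cached in this
# environment.

.fixtures <- new.env(parent = emptyenv())

# small synthetic cohort + fitted model, reused by several test files
small_cohort <- function() {
  if (is.null(.fixtures$cohort)) {
    scen <- truth_scenario()
    design <- generate_design(seed = 401, n_participants = 6)
    truth <- generate_true_params(scen, 6, seed = 402)
    trials <- simulate_dataset(design, truth, scenario = scen, seed = 403)
    .fixtures$cohort <- list(scenario = scen, design = design, truth = truth,
                             trials = trials)
  }
  .fixtures$cohort
}

small_fit <- function() {
  if (is.null(.fixtures$fit)) {
    co <- small_cohort()
    model <- build_model(co$trials, variant = "bias", include_errors = TRUE)
    .fixtures$fit <- suppressWarnings(
      sample_posterior(model, fit_config(1200, 300, seed = 77, thin = 1)))
  }
  .fixtures$fit
}

# --- independent oracles -------------------------------------------------

# textbook sums-of-squares decomposition of a 2x2 fully repeated design,
# computed from definitional loops over a long-format table
oracle_rm_anova <- function(y) {
  n <- nrow(y)
  long <- data.frame(
    s = rep(seq_len(n), 4),
    A = rep(c(1, 1, 2, 2), each = n),
    B = rep(c(1, 2, 1, 2), each = n),
    y = c(y[, 1], y[, 2], y[, 3], y[, 4])
  )
  gm <- mean(long$y)
  mA <- tapply(long$y, long$A, mean)
  mB <- tapply(long$y, long$B, mean)
  mS <- tapply(long$y, long$s, mean)
  mAB <- tapply(long$y, list(long$A, long$B), mean)
  mAS <- tapply(long$y, list(long$A, long$s), mean)
  mBS <- tapply(long$y, list(long$B, long$s), mean)
  ss <- function(idx, pred) sum((pred - gm)^2)
  ss_A <- 2 * n * sum((mA - gm)^2)
  ss_B <- 2 * n * sum((mB - gm)^2)
  ss_AxS <- 2 * sum((t(mAS) - outer(mS, mA, function(s, a) s + a - gm))^2)
  ss_BxS <- 2 * sum((t(mBS) - outer(mS, mB, function(s, b) s + b - gm))^2)
  ss_AB <- n * sum((mAB - outer(mA, mB, `+`) + gm)^2)
  res <- numeric(0)
  for (i in seq_len(nrow(long))) {
    r <- long[i, ]
    res <- c(res, r$y - mAB[r$A, r$B] - mAS[r$A, r$s] - mBS[r$B, r$s] +
               mA[r$A] + mB[r$B] + mS[r$s] - gm)
  }
  ss_ABxS <- sum(res^2)
  f <- function(ss_e, ss_err) (ss_e / 1) / (ss_err / (n - 1))
  list(F_A = f(ss_A, ss_AxS), F_B = f(ss_B, ss_BxS),
       F_AB = f(ss_AB, ss_ABxS),
       peta_A = ss_A / (ss_A + ss_AxS),
       peta_B = ss_B / (ss_B + ss_BxS),
       peta_AB = ss_AB / (ss_AB + ss_ABxS))
}

# Benjamini-Hochberg step-up from its definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# numeric CDF of the conditional upper-boundary decision-time distribution,
# built by trapezoid integration on a fine grid
analytic_rt_cdf <- function(params, t_max = 6, n_grid = 4000) {
  tg <- seq(1e-5, t_max, length.out = n_grid)
  d <- fpt_density(tg, "upper", params)
  cdf <- cumsum((d[-1] + d[-n_grid]) / 2 * diff(tg))
  cdf <- c(0, cdf) / prob_upper(params)
  function(t) approx(tg, pmin(cdf, 1), t, rule = 2)$y
}
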