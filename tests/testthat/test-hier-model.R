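# Hierarchical model: specification, sampler, inference, DIC, prediction.

test_that("model specification counts parameter families correctly", {
  co <- small_cohort()
  mb <- build_model(co$trials, variant = "bias")
  expect_s3_class(mb, "ddm_model_spec")
  expect_equal(mb$G, 12)
  expect_equal(mb$P, 6)
  expect_equal(mb$variant, "bias")
  mn <- build_model(co$trials, variant = "no_bias")
  expect_equal(mn$variant, "no_bias")
  # degenerate single-group dataset is rejected
  one_group <- co$trials[co$trials$group == "moral_1V1M", ]
  expect_error(build_model(one_group), "12 valence groups")
  bad <- co$trials
  idx <- which(bad$task == "moral" & !bad$timeout & bad$correct)[1]
  bad$group[idx] <- "moral_9V9M"
  expect_error(build_model(bad), "unknown valence group")
  expect_error(build_model(co$trials, variant = "nope"))
})

test_that("error-trial handling follows the include_errors flag", {
  co <- small_cohort()
  m_correct <- build_model(co$trials, include_errors = FALSE)
  m_all <- build_model(co$trials, include_errors = TRUE)
  n_errors <- sum(!co$trials$correct[co$trials$task == "moral"], na.rm = TRUE)
  expect_equal(nrow(m_all$data) - nrow(m_correct$data), n_errors)
  expect_true(all(m_correct$data$upper ==
                    (m_correct$data$cell < 6)))  # correct-only: moral cells up
})

test_that("sampling is bit-reproducible under a fixed seed", {
  co <- small_cohort()
  model <- build_model(co$trials, variant = "bias", include_errors = TRUE)
  cfg <- fit_config(400, 100, seed = 5, thin = 1)
  f1 <- suppressWarnings(sample_posterior(model, cfg))
  f2 <- suppressWarnings(sample_posterior(model, cfg))
  expect_identical(f1$chains, f2$chains)
  expect_identical(f1$indiv, f2$indiv)
  f3 <- suppressWarnings(sample_posterior(model, fit_config(400, 100, seed = 6,
                                                            thin = 1)))
  expect_false(identical(f1$chains, f3$chains))
})

test_that("prior-only sampling recovers the prior distributions", {
  pm <- prior_only_model(n_participants = 6, variant = "bias")
  fit <- suppressWarnings(
    sample_posterior(pm, fit_config(6000, 1000, seed = 2, thin = 2)))
  # direct prior simulation oracle
  set.seed(1)
  n <- 4e4
  mu_v_oracle <- rnorm(n, 0, 2)
  g <- rgamma(3 * n, shape = 1.5, rate = 0.75)
  mu_a_oracle <- g[g > 0.3][1:n]
  mu_z_oracle <- rbeta(n, 2, 2)
  mu_z_oracle <- mu_z_oracle[mu_z_oracle > 0.02 & mu_z_oracle < 0.98]
  # average over the 12 independent group families to sharpen the comparison
  vcols_g <- grep("^mu_v_", colnames(fit$chains))
  acols_g <- grep("^mu_a_", colnames(fit$chains))
  expect_lt(abs(mean(fit$chains[, vcols_g]) - mean(mu_v_oracle)), 0.25)
  expect_lt(abs(mean(fit$chains[, acols_g]) - mean(mu_a_oracle)), 0.2)
  expect_lt(abs(mean(fit$chains[, "mu_z"]) - mean(mu_z_oracle)), 0.06)
  # participant drifts are centered like their prior marginal
  vcols <- grep("^v_", colnames(fit$indiv))
  expect_lt(abs(mean(fit$indiv[, vcols])), 0.4)
})

test_that("difference distributions summarise location and mass correctly", {
  x <- rnorm(5000)
  d0 <- diff_distribution(x, x)
  expect_equal(d0$mean, 0)
  expect_equal(d0$pct_below_zero, 50)
  expect_false(d0$significant)
  d1 <- diff_distribution(x, x - 1)
  expect_equal(d1$mean, 1)
  expect_equal(d1$pct_below_zero, 0)
  expect_true(d1$significant)
  expect_error(diff_distribution(1:3, 1:4), "equal length")
  # two independent normal posteriors: overlap follows the closed form
  set.seed(8)
  da <- rnorm(1e5, 0.5, 1)
  db <- rnorm(1e5, 0, 1)
  dd <- diff_distribution(da, db)
  expect_lt(abs(dd$pct_above_zero - 100 * pnorm(0.5 / sqrt(2))), 1)
  expect_match(format_diff_summary(d1), "M = 1.00, 0.0% < 0 < 100.0% \\*")
})

test_that("DIC reduces to the point deviance for a degenerate posterior and matches a two-pass oracle", {
  fit <- small_fit()
  # brute-force two-pass deviance on the first 100 kept draws: rebuild the
  # deviance from participant-level draws with the R-level likelihood
  m <- fit$model
  d <- m$data
  n_or <- 100
  dev_oracle <- sapply(seq_len(n_or), function(s) {
    row <- fit$indiv[s, ]
    ll <- 0
    for (p in seq_len(m$P)) {
      for (g in seq_len(m$G)) {
        sel <- d$pid == p - 1 & d$cell == g - 1
        if (!any(sel)) next
        pref <- paste0("_", m$participants[p], "_", m$groups[g])
        pars <- ddm_params(row[paste0("v", pref)], row[paste0("a", pref)],
                           row[paste0("z_", m$participants[p])],
                           row[paste0("t0", pref)])
        tr <- data.frame(boundary = ifelse(d$upper[sel], "upper", "lower"),
                         rt = d$rt[sel])
        ll <- ll + loglik_trials(tr, pars)
      }
    }
    -2 * ll
  })
  expect_equal(dev_oracle, unname(fit$chains[seq_len(n_or), "deviance"]),
               tolerance = 1e-8)
  dic_val <- dic(fit)
  expect_equal(as.numeric(dic_val),
               attr(dic_val, "Dbar") + attr(dic_val, "pD"),
               ignore_attr = TRUE)
  # a zero-variance chain collapses pD to 0 and DIC to D(theta_bar)
  degen <- fit
  degen$chains <- fit$chains[rep(1, 50), ]
  degen$indiv <- fit$indiv[rep(1, 50), ]
  dd <- dic(degen)
  expect_equal(attr(dd, "pD"), 0, tolerance = 1e-6)
  expect_equal(as.numeric(dd), attr(dd, "D_at_mean"), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("DIC is stable under thinning within Monte-Carlo error", {
  fit <- small_fit()
  thinned <- fit
  keep <- seq(1, nrow(fit$chains), by = 3)
  thinned$chains <- fit$chains[keep, ]
  thinned$indiv <- fit$indiv[keep, ]
  expect_lt(abs(dic(fit) - dic(thinned)), 2)
})

test_that("posterior predictive checks cover self-generated data and flag gross misfit", {
  fit <- small_fit()
  pp <- posterior_predict(fit, n_rep = 60, seed = 3)
  expect_gte(pp$coverage, 0.9)
  expect_true(pp$coverage_ok)
  # deterministic under a fixed seed
  pp2 <- posterior_predict(fit, n_rep = 5, seed = 3)
  pp3 <- posterior_predict(fit, n_rep = 5, seed = 3)
  expect_identical(pp2$stats, pp3$stats)
  # grossly inflated boundaries cannot reproduce the data
  broken <- fit
  acols <- grep("^a_", colnames(broken$indiv))
  broken$indiv[, acols] <- pmin(broken$indiv[, acols] * 10, 5.9)
  ppb <- posterior_predict(broken, n_rep = 40, seed = 4)
  expect_false(ppb$coverage_ok)
  expect_error(posterior_predict(fit, n_rep = 0), "n_rep")
})

test_that("participant-level estimates shrink from the cell MLE toward the group mean", {
  fit <- small_fit()
  m <- fit$model
  d <- m$data
  set.seed(55)
  checks <- 0; between <- 0
  for (i in 1:12) {
    p <- sample(m$P, 1); g <- sample(m$G, 1)
    sel <- d$pid == p - 1 & d$cell == g - 1
    if (sum(sel) < 8) next
    tr <- data.frame(boundary = ifelse(d$upper[sel], "upper", "lower"),
                     rt = d$rt[sel])
    nll <- function(th) {
      if (th[2] < 0.2 || th[3] < 0.01 || th[3] > min(tr$rt) - 0.01) return(1e9)
      -loglik_trials(tr, ddm_params(th[1], th[2], 0.5, th[3]))
    }
    mle <- optim(c(1, 1.5, 0.8 * min(tr$rt)), nll)$par
    post_v <- mean(fit$indiv[, paste0("v_", m$participants[p], "_", m$groups[g])])
    group_v <- mean(fit$chains[, paste0("mu_v_", m$groups[g])])
    lo <- min(mle[1], group_v) - 0.05 * abs(mle[1] - group_v) - 0.02
    hi <- max(mle[1], group_v) + 0.05 * abs(mle[1] - group_v) + 0.02
    checks <- checks + 1
    if (post_v >= lo && post_v <= hi) between <- between + 1
  }
  expect_gte(checks, 6)
  expect_gte(between / checks, 0.75)
})
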