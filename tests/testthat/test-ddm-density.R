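# Wiener first-passage density and absorption probabilities.

test_that("parameter constructor validates its invariants", {
  expect_s3_class(ddm_params(1, 2, 0.5, 0.3), "ddm_params")
  expect_error(ddm_params(1, -1), "boundary")
  expect_error(ddm_params(1, 2, z_rel = 1), "z_rel")
  expect_error(ddm_params(1, 2, tau = -0.1), "tau")
  expect_error(ddm_params(Inf, 2), "finite")
})

test_that("absorption probability matches the gambler's-ruin formula and limits", {
  expect_equal(prob_upper(ddm_params(0, 2, 0.5)), 0.5)
  expect_equal(prob_upper(ddm_params(1, 2, 0.5)),
               (1 - exp(-2)) / (1 - exp(-4)), tolerance = 1e-12)
  # starting next to the upper boundary
  expect_gt(prob_upper(ddm_params(0.5, 2, 0.999)), 0.995)
  # zero-drift limit is continuous: tiny v agrees with v = 0
  expect_equal(prob_upper(ddm_params(1e-10, 2, 0.3)), 0.3, tolerance = 1e-6)
  # strong positive drift essentially guarantees the upper boundary
  expect_gt(prob_upper(ddm_params(50, 1, 0.5)), 0.999)
})

test_that("density vanishes at t -> 0+ and is symmetric when unbiased and driftless", {
  p <- ddm_params(0, 2, 0.5)
  expect_lt(fpt_density(1e-6, "upper", p), 1e-12)
  tt <- seq(0.05, 3, by = 0.05)
  expect_equal(fpt_density(tt, "upper", p), fpt_density(tt, "lower", p),
               tolerance = 1e-12)
  expect_error(fpt_density(-1, "upper", p), "positive")
  expect_error(fpt_density(1, "upper", p, tol = 0), "tol")
})

test_that("reflection identity holds pointwise", {
  tt <- seq(0.02, 4, by = 0.07)
  for (v in c(-2, 0.5, 1.5)) {
    for (z in c(0.3, 0.5, 0.7)) {
      f_up <- fpt_density(tt, "upper", ddm_params(v, 1.8, z))
      f_lo <- fpt_density(tt, "lower", ddm_params(-v, 1.8, 1 - z))
      expect_equal(f_up, f_lo, tolerance = 1e-10)
    }
  }
})

test_that("small-time and large-time expansions agree in the overlap region", {
  tt <- seq(0.05, 2, by = 0.05)
  for (v in c(-1.5, 0, 2)) {
    p <- ddm_params(v, 2, 0.4)
    expect_equal(fpt_density(tt, "upper", p, method = "small_time"),
                 fpt_density(tt, "upper", p, method = "large_time"),
                 tolerance = 1e-6)
  }
})

test_that("density integrates to the closed-form choice probability", {
  for (v in c(-2, 0, 1)) {
    for (z in c(0.3, 0.6)) {
      p <- ddm_params(v, 1.5, z)
      iu <- integrate(function(t) fpt_density(t, "upper", p), 0, Inf,
                      rel.tol = 1e-10)$value
      expect_equal(iu, prob_upper(p), tolerance = 1e-6)
    }
  }
})

test_that("defective densities of both boundaries sum to a proper distribution", {
  for (v in c(-3, -1, 0, 2)) {
    for (a in c(0.5, 1.5, 3)) {
      p <- ddm_params(v, a, 0.35)
      tot <- integrate(function(t) fpt_density(t, "upper", p) +
                         fpt_density(t, "lower", p),
                       0, Inf, rel.tol = 1e-9)$value
      expect_equal(tot, 1, tolerance = 1e-6)
    }
  }
})
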