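# Synthetic study generator: norming ratings, design, truth, simulation.

test_that("norming ratings hit the designed reliability band", {
  r <- generate_ratings(seed = 21)
  expect_equal(dim(r$emotional), c(31, 230))
  a_emo <- cronbach_alpha(r$emotional)
  a_mor <- cronbach_alpha(r$moral)
  expect_gt(min(a_emo, a_mor), 0.90)
  expect_lt(max(a_emo, a_mor), 0.98)
})

test_that("rater-noise extremes drive alpha to its limits", {
  # rater severity offsets only; the 1-9 clip leaves a sliver below 1
  perfect <- generate_ratings(seed = 3, rater_sd = 0, discretize = FALSE)
  expect_equal(cronbach_alpha(perfect$emotional), 1, tolerance = 1e-3)
  indep <- generate_ratings(seed = 4, rater_bias_sd = 0)
  expect_lt(abs(cronbach_alpha(indep$emotional)), 0.35)
})

test_that("selection round trip recovers roughly the designed 96 words", {
  r <- generate_ratings(seed = 31)
  sel <- select_words(rating_means(r))
  expect_gt(nrow(sel), 84)
  expect_lt(nrow(sel), 108)
  # the designed target words dominate the selection
  expect_gt(mean(sel$word_type %in% c("moral", "immoral")), 0.9)
  lv <- assign_valence_levels(sel)
  grid <- sub("^(moral|immoral)_", "", valddm:::.cell_labels())
  expect_true(all(unique(grid) %in% unique(lv$label)))
})

test_that("design has the canonical trial structure", {
  d <- generate_design(seed = 5, n_participants = 4)
  expect_equal(nrow(d$stimuli), 96)
  expect_equal(as.vector(table(d$stimuli$group)), rep(8, 12))
  counts <- table(d$schedule$participant_id, d$schedule$task)
  expect_true(all(counts == 192))
  # each word appears exactly twice per participant and task
  per_word <- table(d$schedule$participant_id, d$schedule$task, d$schedule$word_id)
  expect_true(all(per_word == 2))
  # each of the 12 cells contributes exactly 16 trials per task
  per_cell <- table(d$schedule$participant_id, d$schedule$task, d$schedule$group)
  expect_true(all(per_cell == 16))
  # counterbalancing: both task orders occur
  first_task <- with(d$schedule[d$schedule$task_position == 1, ],
                     tapply(task, participant_id, unique))
  expect_setequal(unique(first_task), c("emotional", "moral"))
})

test_that("true parameters follow the scenario and its spreads", {
  scen <- truth_scenario()
  tr0 <- generate_true_params(truth_scenario(sd_v = 0, sd_a = 0, sd_tau = 0,
                                             sd_z = 0), 5, seed = 1)
  expect_equal(length(unique(round(tr0$v[tr0$group == "moral_2V1M"], 10))), 1)
  tr1 <- generate_true_params(scen, 40, seed = 2)
  tr2 <- generate_true_params(scen, 40, seed = 3)
  expect_false(identical(tr1$v, tr2$v))
  gm1 <- tapply(tr1$v, tr1$group, mean)
  expect_equal(as.vector(gm1[scen$group$group]), scen$group$v, tolerance = 0.2)
  # study-pattern monotonicity holds at the group level by construction
  g <- scen$group
  vm <- setNames(g$v, g$group)
  expect_lt(vm["moral_0V1M"], vm["moral_1V1M"])
  expect_lt(vm["moral_1V1M"], vm["moral_2V1M"])
  am <- setNames(g$a, g$group)
  expect_gt(am["immoral_0V1M"], am["immoral_1V1M"])
  expect_gt(am["immoral_1V1M"], am["immoral_2V1M"])
  # z_rel is shared across groups within a participant
  expect_true(all(tapply(tr1$z_rel, tr1$participant_id,
                         function(x) length(unique(x))) == 1))
})

test_that("simulated dataset respects the deadline and labels correctness", {
  co <- small_cohort()
  tt <- co$trials
  expect_equal(nrow(tt), 6 * 2 * 192)
  expect_true(all(tt$rt_ms <= 1600))
  expect_true(all(is.na(tt$response[tt$timeout])))
  expect_true(all(!is.na(tt$correct[!tt$timeout])))
  # correctness is consistent with the response and word type
  stim <- co$design$stimuli
  wt <- stim$word_type[match(tt$word_id, stim$word_id)]
  ok <- !tt$timeout & tt$task == "moral"
  expect_equal(tt$correct[ok], (tt$response[ok] == "moral") == (wt[ok] == "moral"))
  # reproducible
  tt2 <- simulate_dataset(co$design, co$truth, scenario = co$scenario, seed = 403)
  expect_identical(tt, tt2)
})

test_that("filtering removes exactly the simulator-labeled timeout and error trials", {
  co <- small_cohort()
  f <- filter_trials(co$trials)
  expect_equal(nrow(f$trials),
               sum(!co$trials$timeout & co$trials$correct, na.rm = TRUE))
  expect_true(all(f$trials$correct))
  expect_true(all(!f$trials$timeout))
  # idempotent
  f2 <- filter_trials(f$trials)
  expect_identical(f2$trials, f$trials)
})
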