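test_that("initialization validates inputs and places the first trial", {
  expect_error(quest_init(0, -1), "positive")
  expect_error(quest_init(0, 1, gamma = 0.5, target_p = 0.4), "target_p")
  expect_error(quest_init(0, 1, delta = 0.02, target_p = 0.99), "target_p")
  ## flat prior: first recommendation sits at the prior mean's target point
  st <- quest_init(0.3, prior_sd = 100)
  off <- visreason:::weibull_offset(0.8, 3.5, 0.5, 0.02)
  expect_equal(quest_recommend(st), 0.3 + off, tolerance = 1e-6)
  ## physical-unit initializations (rho = 5.4, theta = 6)
  expect_equal(intensity_of(5.4, "rho"), -log10(5.4))
  expect_equal(physical_of(intensity_of(6, "theta"), "theta"), 6)
})

test_that("posterior updates move the recommendation the right way", {
  st <- quest_init(0, prior_sd = 0.5)
  x0 <- quest_recommend(st)
  st_up <- st
  for (i in 1:12) st_up <- quest_update(st_up, x0, correct = TRUE)
  expect_lt(quest_recommend(st_up), x0)   # run of corrects -> harder trials
  st_dn <- st
  for (i in 1:12) st_dn <- quest_update(st_dn, x0, correct = FALSE)
  expect_gt(quest_recommend(st_dn), x0)   # run of errors -> easier trials
  ## no posterior mass collapses to exactly zero
  st_ext <- st
  for (i in 1:200) st_ext <- quest_update(st_ext, st$grid[1], correct = FALSE)
  expect_true(all(is.finite(st_ext$log_posterior)))
  expect_equal(max(st_ext$log_posterior), 0)
})

test_that("recommendations are clamped to physical bounds", {
  st <- quest_init(0, prior_sd = 0.3, bounds = c(-0.2, 0.2))
  for (i in 1:60) st <- quest_update(st, quest_recommend(st), correct = TRUE)
  expect_gte(quest_recommend(st), -0.2)
  st2 <- quest_init(0, prior_sd = 0.3, bounds = c(-0.2, 0.2))
  for (i in 1:60) st2 <- quest_update(st2, quest_recommend(st2), correct = FALSE)
  expect_lte(quest_recommend(st2), 0.2)
})

test_that("the staircase converges to a simulated observer's threshold", {
  obs <- sim_observer(true_threshold = -0.6)
  target <- visreason:::observer_target_intensity(obs, 0.8)
  errs <- withr::with_seed(21, vapply(c(80, 640), function(n_trials) {
    st <- quest_init(-0.3, prior_sd = 0.5)
    for (i in seq_len(n_trials)) {
      x <- quest_recommend(st)
      r <- visreason:::observer_respond(obs, x)
      st <- quest_update(st, x, r$correct)
    }
    abs(quest_threshold(st) - obs$true_threshold)
  }, 0))
  expect_lt(errs[2], 0.08)
  expect_lt(errs[2], errs[1] + 0.02)      # error shrinks with trial count
})

test_that("sessions have the block structure of the experiment", {
  log <- run_session(sim_observer(intensity_of(8, "rho")),
                     sim_observer(intensity_of(3, "theta")), seed = 4L)
  expect_equal(nrow(log), 16 * 70)
  expect_equal(unique(log$task[log$block %% 2 == 1]), "SD")
  expect_equal(unique(log$task[log$block %% 2 == 0]), "SR")
  expect_equal(log$task[1], "SD")
  ## only the block's own parameter changes within a block
  for (b in c(2, 5, 10)) {
    d <- log[log$block == b, ]
    if (d$task[1] == "SD") expect_equal(length(unique(d$theta)), 1L)
    else expect_equal(length(unique(d$rho)), 1L)
  }
  ## the held parameter carries over from the preceding block
  b3 <- log[log$block == 3, ]
  b2 <- log[log$block == 2, ]
  expect_equal(unique(b3$theta), tail(b2$theta, 1))
  tr <- session_block_traces(log)
  expect_equal(nrow(tr), 16)
  expect_identical(run_session(sim_observer(-0.9), sim_observer(0.48),
                               seed = 4L)$correct[1:50],
                   run_session(sim_observer(-0.9), sim_observer(0.48),
                               seed = 4L)$correct[1:50])
})

test_that("a converged observer is held near 80% correct", {
  ## observer whose threshold equals the starting value: accuracy is on
  ## target from early on
  obs_sd <- sim_observer(intensity_of(5.4, "rho"))
  obs_sr <- sim_observer(intensity_of(6, "theta"))
  accs <- vapply(1:5, function(s)
    second_half_accuracy(run_session(obs_sd, obs_sr, seed = s)), 0)
  expect_true(all(accs > 0.74 & accs < 0.86))
})
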