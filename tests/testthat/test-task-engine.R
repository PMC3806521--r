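test_that("a perfect respondent makes no errors in any subtest", {
  task <- task_config()
  ideal <- agent_model()
  for (seed in c(14, 860)) {
    for (s in 1:5) {
      r <- run_subtest(s, task, ideal, seed)
      total <- r$false_positives + r$false_negatives +
        r$object_collisions + r$border_collisions
      expect_equal(total, 0L, info = sprintf("subtest %d seed %d", s, seed))
    }
  }
})

test_that("a fully lapsing respondent misses every target and nothing else", {
  task <- task_config(duration = 600, stim_rate = 0.5)
  agent <- agent_model(lapse_prob = 1, false_alarm_prob = 0)
  for (seed in 1:5) {
    r <- run_subtest(1, task, agent, seed)
    log <- event_log(r)
    k <- attr(log, "n_targets")
    expect_gt(k, 0)
    expect_equal(r$false_negatives, k)
    expect_equal(r$false_positives, 0L)
  }
})

test_that("half-lapse miss counts recover the binomial mean", {
  # ~200 expected targets per run; misses ~ Binomial(N, 0.5) with N Poisson
  task <- task_config(duration = 800, stim_rate = 0.5,
                      distractor_fraction = 0.5)
  agent <- agent_model(lapse_prob = 0.5)
  n_rep <- 500
  fn <- vapply(seq_len(n_rep), function(seed) {
    run_subtest(1, task, agent, seed)$false_negatives
  }, integer(1))
  mu <- 0.5 * task$stim_rate * task$duration * (1 - task$distractor_fraction)
  # Var(FN) = E[N] p(1-p) + Var(N) p^2 for N ~ Poisson
  v <- 200 * 0.25 + 200 * 0.25
  expect_lt(abs(mean(fn) - mu), 3 * sqrt(v / n_rep))
})

test_that("structural zeros hold: no collisions without steering, no detections without a peripheral task", {
  task <- task_config(duration = 60)
  noisy <- agent_model(steer_noise_sd = 0.2, reaction_delay = 0.5,
                       lapse_prob = 0.5, false_alarm_prob = 0.3,
                       speed_noise_sd = 4, degradation = 2)
  for (seed in 1:3) {
    r1 <- run_subtest(1, task, noisy, seed)
    r2 <- run_subtest(2, task, noisy, seed)
    r4 <- run_subtest(4, task, noisy, seed)
    r5 <- run_subtest(5, task, noisy, seed)
    expect_equal(r1$object_collisions + r1$border_collisions, 0L)
    expect_equal(r4$object_collisions + r4$border_collisions, 0L)
    expect_equal(r2$false_positives + r2$false_negatives, 0L)
    expect_equal(r5$false_positives + r5$false_negatives, 0L)
  }
})

test_that("counts are bounded by presented stimuli in the event log", {
  task <- task_config(duration = 120)
  agent <- agent_model(lapse_prob = 0.4, false_alarm_prob = 0.4)
  for (seed in 1:5) {
    r <- run_subtest(4, task, agent, seed)
    log <- event_log(r)
    expect_lte(r$false_negatives, attr(log, "n_targets"))
    expect_lte(r$false_positives, attr(log, "n_distractors"))
  }
})

test_that("impairment parameters do not decrease the errors they govern", {
  task <- task_config(duration = 90)
  seeds <- 1:40
  total_detect <- function(agent, subtest = 1) {
    sum(vapply(seeds, function(s) {
      r <- run_subtest(subtest, task, agent, s)
      r$false_positives + r$false_negatives
    }, integer(1)))
  }
  expect_lte(total_detect(agent_model(lapse_prob = 0.1)),
             total_detect(agent_model(lapse_prob = 0.5)))
  expect_lte(total_detect(agent_model(false_alarm_prob = 0.05)),
             total_detect(agent_model(false_alarm_prob = 0.4)))
  total_coll <- function(noise) {
    sum(vapply(seeds[1:12], function(s) {
      r <- run_subtest(2, task, agent_model(steer_noise_sd = noise), s)
      r$object_collisions + r$border_collisions
    }, integer(1)))
  }
  expect_lt(total_coll(0.03), total_coll(0.2))
})

test_that("divided attention degrades performance for a degradation-prone agent", {
  task <- task_config(duration = 45)
  base <- agent_model(steer_noise_sd = 0.08, lapse_prob = 0.15)
  degraded <- agent_model(steer_noise_sd = 0.08, lapse_prob = 0.15,
                          degradation = 2)
  seeds <- 1:80
  tot3 <- function(agent) {
    vapply(seeds, function(s) {
      r <- run_subtest(3, task, agent, s)
      r$false_positives + r$false_negatives + r$object_collisions +
        r$border_collisions
    }, integer(1))
  }
  a <- tot3(base); b <- tot3(degraded)
  mw <- mann_whitney_u(b, a, alternative = "greater")
  expect_lt(mw$p_value, 0.01)
})

test_that("battery runs are deterministic and expose the scoring error vector", {
  task <- task_config(duration = 45)
  agent <- agent_model(steer_noise_sd = 0.08, lapse_prob = 0.2,
                       false_alarm_prob = 0.1, speed_noise_sd = 2)
  b1 <- run_battery(task, agent, seed = 42)
  b2 <- run_battery(task, agent, seed = 42)
  expect_identical(b1$errors, b2$errors)
  expect_named(b1$errors, c("e1", "e2", "e3c", "e3p", "e4", "e5"))
  r3 <- b1$results[[3]]
  expect_equal(b1$errors[["e3c"]],
               r3$object_collisions + r3$border_collisions)
  expect_equal(b1$errors[["e3p"]],
               r3$false_positives + r3$false_negatives)
})

test_that("invalid task and agent configurations are rejected", {
  expect_error(task_config(dt = 2, response_window = 1), "response_window")
  expect_error(task_config(duration = -1), "positive")
  expect_error(agent_model(lapse_prob = 1.3), "\\[0, 1\\]")
  expect_error(agent_model(degradation = 0.5), ">= 1")
  expect_error(run_subtest(6, task_config(), agent_model(), 1), "1..5")
})
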