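test_that("cohort generation is deterministic given config and seed", {
  cfg <- cohort_config(seed = 123)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  d <- generate_cohort(cohort_config(seed = 124))
  expect_false(identical(a, d))
})

test_that("generator respects group sizes and record invariants", {
  co <- generate_cohort(cohort_config(seed = 5))
  expect_equal(unname(table(co$cohort)[c("young", "older_healthy",
                                         "older_impaired")]),
               c(26L, 44L, 10L), ignore_attr = TRUE)
  err <- as.matrix(co[, c("e1", "e2", "e3c", "e3p", "e4", "e5", "e_ds")])
  expect_true(all(err >= 0 & err == round(err)))
  expect_true(all(co$moca >= 0 & co$moca <= 30))
  expect_true(all(co$moca[co$cohort == "older_impaired"] < 26))
  expect_true(all(co$tmt_a > 0 & co$tmt_b > 0 & co$tug > 0))
  sec <- as.matrix(co[, c("speed_var", "lat_accel", "brake_time",
                          "dist_collision", "time_collision")])
  expect_true(all(sec > 0))
})

test_that("degenerate config (zero rates, zero ability SD) gives all-zero errors", {
  cfg <- cohort_config(
    ability_params = list(young = list(sd = 0), older_healthy = list(sd = 0),
                          older_impaired = list(sd = 0)),
    error_link = list(base = c(e1 = 0, e2 = 0, e3c = 0, e3p = 0, e4 = 0,
                               e5 = 0, e_ds = 0)),
    seed = 9
  )
  co <- generate_cohort(cfg)
  expect_true(all(co[, c("e1", "e2", "e3c", "e3p", "e4", "e5", "e_ds")] == 0))
})

test_that("covariate sample means recover their configured targets at large n", {
  cfg <- cohort_config(
    group_sizes = c(young = 26, older_healthy = 44, older_impaired = 10) * 50,
    seed = 31
  )
  co <- generate_cohort(cfg)
  for (g in c("young", "older_healthy", "older_impaired")) {
    target <- cfg$covariate_params[[g]]$moca[["mean"]]
    expect_lt(abs(mean(co$moca[co$cohort == g]) - target), 0.2)
    tgt_tug <- cfg$covariate_params[[g]]$tug[["mean"]]
    expect_lt(abs(mean(co$tug[co$cohort == g]) - tgt_tug), 0.3)
  }
})

test_that("raising the error-link rate strictly raises impaired error counts", {
  base <- cohort_config(group_sizes = c(older_impaired = 1000), seed = 77)
  high <- cohort_config(group_sizes = c(older_impaired = 1000),
                        error_link = list(base = cohort_config()$error_link$base * 2),
                        seed = 77)
  tot <- function(co) mean(rowSums(co[, c("e1", "e2", "e3c", "e3p", "e4",
                                          "e5", "e_ds")]))
  expect_gt(tot(generate_cohort(high)), tot(generate_cohort(base)))
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(group_sizes = c(young = -1)), "non-negative")
  expect_error(cohort_config(ability_params = list(young = list(sd = -1))),
               "SD")
  expect_error(cohort_config(error_link = list(base = c(e1 = -2))), "base rates")
  expect_error(generate_cohort(list()), "cohort_config")
})

test_that("covariate summary reports group moments in the expected layout", {
  co <- random_cohort(6, seed = 2)
  co$cohort <- "young"
  co[, c("moca", "tmt_a", "tmt_b", "cdt", "tug")] <-
    co[rep(1, 6), c("moca", "tmt_a", "tmt_b", "cdt", "tug")]
  s <- covariate_summary(co)
  expect_equal(nrow(s), 5)  # one row per covariate, single group
  expect_true(all(s$sd == 0))
  expect_true(all(s$defined))

  co2 <- random_cohort(2, seed = 3)
  co2$cohort <- c("young", "older_impaired")
  s2 <- covariate_summary(co2)
  moca_rows <- s2[s2$covariate == "moca", ]
  expect_equal(sort(moca_rows$mean), sort(as.numeric(co2$moca)))
  expect_equal(unique(s2$n), c(1L))

  # grouping by a driving-performance split instead of recruitment cohort
  co3 <- generate_cohort(cohort_config(seed = 8))
  sp <- split_by_mean_plus_sd(co3$e_ds)
  s3 <- covariate_summary(co3, split = sp)
  expect_setequal(unique(s3$group), c("good", "poor"))
  expect_equal(sum(s3$covariate == "moca"), 2)
})
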