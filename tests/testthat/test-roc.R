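make_labels <- function(n_good, n_poor) {
  group_split(c(rep("good", n_good), rep("poor", n_poor)))
}

test_that("empirical AUC equals pair counting in canonical cases", {
  r <- empirical_roc(c(0.9, 0.8, 0.3, 0.2), make_labels(2, 2))
  expect_equal(r$auc, 1)
  r2 <- empirical_roc(c(0.9, 0.6, 0.8, 0.5), make_labels(2, 2))
  expect_equal(r2$auc, 0.75)  # 3 of 4 pairs concordant
})

test_that("trapezoid AUC equals exhaustive tie-adjusted pair counting", {
  for (seed in 1:60) {
    set.seed(seed)
    n_g <- sample(2:15, 1); n_p <- sample(2:15, 1)
    scores <- c(rpois(n_g, 6), rpois(n_p, 4)) / 10   # ties guaranteed
    labels <- make_labels(n_g, n_p)
    r <- empirical_roc(scores, labels)
    expect_equal(r$auc, oracle_auc(scores[1:n_g], scores[-(1:n_g)]),
                 tolerance = 1e-12)
  }
})

test_that("operating points are monotone along the cutoff sweep", {
  for (seed in 1:10) {
    set.seed(seed)
    scores <- runif(30)
    labels <- make_labels(22, 8)
    pts <- empirical_roc(scores, labels)$points
    expect_true(all(diff(pts$cutoff) <= 0))
    expect_true(all(diff(pts$sensitivity) >= 0))
    expect_true(all(diff(pts$specificity) <= 0))
  }
})

test_that("swapping class labels maps AUC to its complement", {
  set.seed(7)
  scores <- rnorm(40)
  lab <- c(rep("good", 30), rep("poor", 10))
  a <- empirical_roc(scores, group_split(lab))$auc
  b <- empirical_roc(scores, group_split(ifelse(lab == "good", "poor",
                                                "good")))$auc
  expect_equal(a, 1 - b, tolerance = 1e-12)
})

test_that("shuffled labels give chance-level AUC on average", {
  set.seed(11)
  scores <- runif(30)
  aucs <- replicate(400, {
    lab <- sample(c(rep("good", 22), rep("poor", 8)))
    empirical_roc(scores, group_split(lab))$auc
  })
  se <- sd(aucs) / sqrt(length(aucs))
  expect_lt(abs(mean(aucs) - 0.5), 3 * se + 1e-3)
})

test_that("empirical AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  for (seed in 1:10) {
    set.seed(seed)
    scores <- c(rnorm(20, 1), rnorm(8))
    labels <- make_labels(20, 8)
    mine <- empirical_roc(scores, labels)$auc
    ref <- suppressMessages(
      as.numeric(pROC::auc(response = labels$labels, predictor = scores,
                           levels = c("poor", "good"), direction = "<"))
    )
    expect_equal(mine, ref, tolerance = 1e-12)
  }
})

test_that("Hanley-McNeil SE evaluates its closed form", {
  expect_equal(hanley_se(1, 10, 70), 0)
  expect_equal(hanley_se(0.5, 10, 10), oracle_hanley(0.5, 10, 10))
  expect_equal(hanley_se(0.5, 10, 10), 0.13229, tolerance = 1e-4)
  expect_equal(hanley_se(0.8, 10, 70), oracle_hanley(0.8, 10, 70))
  expect_equal(hanley_se(0.8, 10, 70), 0.0871, tolerance = 1e-3)
  for (a in seq(0.5, 0.95, by = 0.05)) {
    for (n1 in c(5, 10, 20)) {
      for (n2 in c(10, 40, 70)) {
        expect_equal(hanley_se(a, n1, n2), oracle_hanley(a, n1, n2))
        # SE shrinks as either group grows
        expect_lt(hanley_se(a, n1 + 5, n2), hanley_se(a, n1, n2))
        expect_lt(hanley_se(a, n1, n2 + 10), hanley_se(a, n1, n2))
      }
    }
  }
  expect_error(hanley_se(1.2, 10, 10), "\\[0, 1\\]")
})

test_that("ROC result carries a consistent CI and chance test", {
  set.seed(3)
  scores <- c(rnorm(30, 2.5), rnorm(10))
  r <- empirical_roc(scores, make_labels(30, 10))
  expect_true(r$ci[["lower"]] <= r$auc && r$auc <= r$ci[["upper"]])
  expect_true(r$ci[["lower"]] >= 0 && r$ci[["upper"]] <= 1)
  expect_lt(r$p_value, 0.05)
  expect_equal(r$se, hanley_se(r$auc, 10, 30))
})

test_that("binormal fit reproduces closed-form parameters and AUC", {
  set.seed(5)
  g <- rnorm(200, 1, 1); p <- rnorm(50, 1, 1)
  eq <- binormal_fit(c(g, p), make_labels(200, 50))
  expect_equal(eq$a, (mean(g) - mean(p)) / sd(g))
  expect_lt(abs(eq$auc - 0.5), 0.1)

  # unit-variance classes one mean apart: a = b = 1, AUC = pnorm(1/sqrt(2))
  good <- c(0, 1, 2); poor <- c(-1, 0, 1)
  fit <- binormal_fit(c(good, poor), make_labels(3, 3))
  expect_equal(fit$a, 1)
  expect_equal(fit$b, 1)
  expect_equal(fit$auc, pnorm(1 / sqrt(2)))
  expect_equal(fit$curve(pnorm(-1)), pnorm(0))  # TPR at t = Phi(a + b qnorm(t))
  expect_error(binormal_fit(c(1, 1, 0, 2), make_labels(2, 2)), "degenerate")
})

test_that("binormal AUC tracks the empirical AUC on truly normal scores", {
  set.seed(9)
  g <- rnorm(500, 0.8); p <- rnorm(500)
  labels <- make_labels(500, 500)
  emp <- empirical_roc(c(g, p), labels)$auc
  bin <- binormal_fit(c(g, p), labels)$auc
  expect_lt(abs(emp - bin), 0.02)
})

test_that("cutoff table matches direct counting and the efficiency identity", {
  tab <- cutoff_table(c(0.9, 0.8, 0.7, 0.4, 0.3), make_labels(3, 2),
                      cutoffs = 0.5)
  expect_equal(unlist(tab[1, c("sensitivity", "specificity", "efficiency")]),
               c(sensitivity = 1, specificity = 1, efficiency = 1))
  for (seed in 1:10) {
    set.seed(seed)
    n_g <- sample(5:40, 1); n_p <- sample(2:12, 1)
    scores <- round(runif(n_g + n_p), 2)
    labels <- make_labels(n_g, n_p)
    cuts <- sort(unique(c(scores, 0.5)))
    tab <- cutoff_table(scores, labels, cuts)
    for (i in seq_along(cuts)) {
      o <- oracle_operating_point(scores[1:n_g], scores[-(1:n_g)], cuts[i])
      expect_equal(tab$sensitivity[i], o[["sens"]])
      expect_equal(tab$specificity[i], o[["spec"]])
      expect_equal(tab$efficiency[i], o[["eff"]])
      expect_equal(tab$efficiency[i],
                   (n_g * tab$sensitivity[i] + n_p * tab$specificity[i]) /
                     (n_g + n_p))
    }
  }
})

test_that("reported rounding is half away from zero", {
  # 46/80 correct = 0.575, which must print as 0.58 (banker's rounding
  # would give 0.57): 37 of 70 good at/above the cutoff, 9 of 10 poor below
  scores <- c(rep(0.8, 37), rep(0.5, 33), rep(0.9, 1), rep(0.4, 9))
  tab <- cutoff_table(scores, make_labels(70, 10), cutoffs = 0.75)
  expect_equal(tab$efficiency, 0.575)
  expect_equal(tab$eff_print, 0.58)
  expect_equal(drivescreen:::round_half_away(0.575, 2), 0.58)
  expect_equal(drivescreen:::round_half_away(-0.575, 2), -0.58)
})

test_that("efficiency reconstruction bridges printed rates to counts", {
  expect_equal(efficiency_from_printed(0.83, 0.70, 70, 10), 0.81)
  expect_equal(efficiency_from_printed(0.94, 0.30, 70, 10), 0.86)
  # equal printed rates reproduce themselves when they resolve to integer
  # counts of correctly classified subjects
  for (s in c(0.25, 0.5, 0.90)) {
    expect_equal(efficiency_from_printed(s, s, 40, 40), s)
  }
})
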