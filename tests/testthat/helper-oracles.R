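# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# Rank score via explicit sorting: position of each value among the sorted
# raw values, ties averaged by hand.
oracle_rank_score <- function(raw, higher_is_worse = TRUE) {
  n <- length(raw)
  v <- if (higher_is_worse) raw else -raw
  sapply(v, function(x) {
    below <- sum(v < x)
    tied <- sum(v == x)
    r <- below + (tied + 1) / 2
    (n - r) / (n - 1)
  })
}

# AUC by exhaustive pair counting: P(good > poor) + 0.5 P(tie).
oracle_auc <- function(good, poor) {
  conc <- outer(good, poor, ">")
  ties <- outer(good, poor, "==")
  (sum(conc) + 0.5 * sum(ties)) / (length(good) * length(poor))
}

# U statistic by the same pair grid.
oracle_u <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# One-sided (greater) permutation p-value by full enumeration of group
# assignments; feasible for the small samples it is used with.
oracle_mwu_p_greater <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  obs <- oracle_u(x, y)
  idx <- utils::combn(length(pooled), n1)
  us <- apply(idx, 2, function(i) oracle_u(pooled[i], pooled[-i]))
  mean(us >= obs - 1e-12)
}

# Hanley-McNeil SE written out independently.
oracle_hanley <- function(a, n1, n2) {
  q1 <- a / (2 - a)
  q2 <- 2 * a * a / (1 + a)
  sqrt((a * (1 - a) + (n1 - 1) * (q1 - a * a) + (n2 - 1) * (q2 - a * a)) /
         (n1 * n2))
}

# Sensitivity/specificity/efficiency by direct counting in the orientation
# where a high score at/above the cutoff predicts good performance.
oracle_operating_point <- function(good, poor, cutoff) {
  sens <- sum(good >= cutoff) / length(good)
  spec <- sum(poor < cutoff) / length(poor)
  eff <- (sum(good >= cutoff) + sum(poor < cutoff)) /
    (length(good) + length(poor))
  c(sens = sens, spec = spec, eff = eff)
}

# A small random cohort data frame with the package's column set, built
# directly (not via the generator) so scoring tests are independent of it.
random_cohort <- function(n, seed) {
  set.seed(seed)
  data.frame(
    participant_id = sprintf("X%03d", seq_len(n)),
    cohort = sample(c("young", "older_healthy", "older_impaired"), n, TRUE),
    e1 = rpois(n, 3), e2 = rpois(n, 3), e3c = rpois(n, 2), e3p = rpois(n, 2),
    e4 = rpois(n, 3), e5 = rpois(n, 3), e_ds = rpois(n, 2),
    speed_var = rlnorm(n), lat_accel = rlnorm(n), brake_time = rlnorm(n, 2),
    dist_collision = rlnorm(n, 3), time_collision = rlnorm(n),
    moca = sample(20:30, n, TRUE), tmt_a = runif(n, 15, 60),
    tmt_b = runif(n, 40, 160), cdt = sample(3:7, n, TRUE),
    tug = runif(n, 4, 12),
    stringsAsFactors = FALSE
  )
}
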