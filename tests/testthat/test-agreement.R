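# explicit sums-of-squares ANOVA oracle for the two-way consistency ICC
icc_oracle <- function(x, y) {
  n <- length(x); k <- 2
  dat <- cbind(x, y)
  grand <- mean(dat)
  ss_tot <- sum((dat - grand)^2)
  ss_rows <- k * sum((rowMeans(dat) - grand)^2)
  ss_cols <- n * sum((colMeans(dat) - grand)^2)
  ms_rows <- ss_rows / (n - 1)
  ms_err <- (ss_tot - ss_rows - ss_cols) / ((n - 1) * (k - 1))
  (ms_rows - ms_err) / (ms_rows + (k - 1) * ms_err)
}

make_table <- function(v_tcd, v_sim, ...) {
  paired_velocity_table(sprintf("i%03d", seq_along(v_tcd)),
                        rep("L_MCA", length(v_tcd)), v_tcd, v_sim, ...)
}

test_that("consistency ICC is exact for identical and offset raters", {
  v <- c(30, 45, 60, 75, 90, 50, 66)
  expect_equal(icc_consistency(make_table(v, v))$icc, 1)
  # consistency form ignores a fixed systematic bias
  r <- icc_consistency(make_table(v, v + 10))
  expect_equal(r$icc, 1)
  expect_equal(c(r$ci_low, r$ci_high), c(1, 1))
  expect_error(icc_consistency(make_table(v[1:4], v[1:4])), "at least 5")
})

test_that("consistency ICC equals the explicit sums-of-squares oracle", {
  set.seed(31)
  for (i in 1:40) {
    n <- sample(8:40, 1)
    x <- exp(rnorm(n, log(50), 0.4))
    y <- x * exp(rnorm(n, 0.1, 0.25))
    r <- icc_consistency(make_table(x, y))
    expect_equal(r$icc, icc_oracle(x, y), tolerance = 1e-10)
    expect_true(r$ci_low <= r$icc && r$icc <= r$ci_high)
  }
})

test_that("consistency ICC is affine-invariant but is not the Pearson shortcut", {
  set.seed(32)
  x <- exp(rnorm(12, log(60), 0.3))
  y <- x * exp(rnorm(12, 0, 0.2))
  r0 <- icc_consistency(make_table(x, y))$icc
  r1 <- icc_consistency(make_table(3 * x + 7, 3 * y + 7))$icc
  expect_equal(r0, r1, tolerance = 1e-10)
  # a biased, unequal-variance table separates ICC(C,1) from Pearson r
  y2 <- 3 * x - 40
  r_icc <- icc_consistency(make_table(x, y2))$icc
  expect_equal(r_icc, icc_oracle(x, y2), tolerance = 1e-10)
  expect_gt(abs(r_icc - stats::cor(x, y2)), 0.05)
})

test_that("degenerate zero-variance tables give a defined ICC of 0", {
  v <- rep(50, 6)
  expect_warning(r <- icc_consistency(make_table(v, v)), "degenerate")
  expect_equal(r$icc, 0)
})

test_that("log Bland-Altman limits are multiplicative and scale-invariant", {
  v <- c(30, 45, 60, 75, 90)
  r <- log_bland_altman(make_table(v, v))
  expect_equal(c(r$lower_factor, r$upper_factor), c(1, 1))
  # exact 2x multiplicative bias: factors (2, 2), zero spread
  r2 <- log_bland_altman(make_table(v, 2 * v))
  expect_equal(r2$mean_log_diff, log10(2), tolerance = 1e-12)
  expect_equal(r2$sd_log_diff, 0)
  expect_equal(c(r2$lower_factor, r2$upper_factor), c(2, 2), tolerance = 1e-12)
  # 20-row table against direct formula evaluation
  set.seed(33)
  x <- exp(rnorm(20, log(50), 0.3))
  y <- x * exp(rnorm(20, 0.05, 0.2))
  r3 <- log_bland_altman(make_table(x, y))
  d <- log10(y) - log10(x)
  expect_equal(r3$lower_factor, 10^(mean(d) - 1.96 * stats::sd(d)),
               tolerance = 1e-12)
  expect_equal(r3$upper_factor, 10^(mean(d) + 1.96 * stats::sd(d)),
               tolerance = 1e-12)
  expect_equal(r3$percent_below, 1 - r3$lower_factor, tolerance = 1e-12)
  # exactly invariant to a common velocity rescaling
  r4 <- log_bland_altman(make_table(7 * x, 7 * y))
  expect_equal(r4$lower_factor, r3$lower_factor, tolerance = 1e-12)
  expect_equal(r4$upper_factor, r3$upper_factor, tolerance = 1e-12)
})

test_that("Wilcoxon signed-rank test matches exact sign-assignment enumeration", {
  # all-positive differences at n = 6: two-sided p = 2/2^6
  tab <- make_table(c(30, 40, 50, 60, 70, 80), c(31, 42, 53, 64, 75, 86))
  r <- paired_difference_test(tab)
  expect_equal(r$p_value, 2 / 64, tolerance = 1e-12)
  expect_identical(r$method, "exact")
  # enumeration oracle for random tables (no ties, n <= 10)
  set.seed(34)
  for (i in 1:10) {
    n <- sample(6:10, 1)
    x <- exp(rnorm(n, log(50), 0.3))
    d <- round(rnorm(n, 0.5, 2), 3)
    d <- d[d != 0]; n <- length(d)
    if (n < 6 || any(duplicated(abs(d)))) next
    y <- x[seq_len(n)] + d
    rk <- rank(abs(d))
    v_obs <- sum(rk[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    v_all <- signs %*% rk
    p_exact <- min(1, 2 * min(mean(v_all >= v_obs), mean(v_all <= v_obs)))
    r <- paired_difference_test(make_table(x[seq_len(n)], y))
    expect_equal(r$p_value, p_exact, tolerance = 1e-10)
  }
  # all differences zero: p = 1 by definition
  v <- c(30, 40, 50, 60, 70, 80)
  r0 <- paired_difference_test(make_table(v, v))
  expect_equal(r0$p_value, 1)
  # symmetric differences: no evidence against zero location
  rsym <- paired_difference_test(make_table(v, v + c(-3, 3, -2, 2, -1, 1)))
  expect_gt(rsym$p_value, 0.5)
})

test_that("subgroup agreement stratifies and flags CI overlap", {
  set.seed(35)
  x <- exp(rnorm(24, log(50), 0.4))
  y <- x * exp(rnorm(24, 0, 0.1))
  tab <- make_table(x, y, dci = rep(c("yes", "no"), each = 12))
  sg <- subgroup_agreement(tab, "dci")
  expect_named(sg$by_level, c("no", "yes"))
  # identical subtables: identical ICCs, overlapping CIs
  tab2 <- paired_velocity_table(
    c(sprintf("a%02d", 1:12), sprintf("b%02d", 1:12)),
    rep("L_MCA", 24), rep(x[1:12], 2), rep(y[1:12], 2),
    grp = rep(c("A", "B"), each = 12))
  sg2 <- subgroup_agreement(tab2, "grp")
  expect_equal(sg2$by_level$A$icc, sg2$by_level$B$icc)
  expect_true(sg2$overlap)
  # constructed low-noise vs high-noise groups: disjoint CIs
  set.seed(36)
  x3 <- exp(rnorm(80, log(50), 0.5))
  y3_lo <- x3 * exp(rnorm(80, 0, 0.02))
  y3_hi <- x3 * exp(rnorm(80, 0, 0.8))
  tab3 <- paired_velocity_table(
    sprintf("i%03d", 1:160), rep("L_MCA", 160),
    c(x3, x3), c(y3_lo, y3_hi), noise = rep(c("low", "high"), each = 80))
  sg3 <- subgroup_agreement(tab3, "noise")
  expect_false(sg3$overlap)
  # level relabelling does not change the per-level results
  tab4 <- tab3
  tab4$noise <- ifelse(tab3$noise == "low", "zzz", "aaa")
  sg4 <- subgroup_agreement(tab4, "noise")
  expect_equal(sg4$by_level$zzz$icc, sg3$by_level$low$icc)
  expect_identical(sg4$overlap, sg3$overlap)
  # small levels are excluded with a warning
  tab5 <- make_table(x[1:8], y[1:8], g = c(rep("big", 6), rep("small", 2)))
  expect_warning(sg5 <- subgroup_agreement(tab5, "g"), "excluded")
  expect_named(sg5$by_level, "big")
})

test_that("paired table construction enforces positivity and uniqueness", {
  expect_error(make_table(c(1, -2, 3, 4, 5), c(1, 2, 3, 4, 5)), "> 0")
  expect_error(
    paired_velocity_table(c("a", "a"), c("L_MCA", "L_MCA"), c(1, 2), c(1, 2)),
    "duplicated")
  tab <- make_table(c(30, 40, 50, 60, 70), c(31, 41, 51, 61, 71))
  expect_equal(unique(tab$artery_class), "MCA")
})
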