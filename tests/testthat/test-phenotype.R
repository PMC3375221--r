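test_that("max growth rate of a noiseless curve sits at the inflection", {
  gp <- simulateGrowthPair(t_inflection = 6, noise_sd = 0, seed = 1)
  t1 <- maxGrowthRateTime(gp$control$times, gp$control$od)
  expect_lt(abs(t1 - 6), 10 / 60)          # within one sampling interval
  # translation equivariance is exact on the sampling grid
  shifted <- maxGrowthRateTime(gp$control$times + 3, gp$control$od)
  expect_equal(shifted, t1 + 3)
})

test_that("noisy curves localize the max-rate time within half an hour", {
  nrep <- 100
  ok <- 0
  for (i in seq_len(nrep)) {
    gp <- simulateGrowthPair(t_inflection = 7, noise_sd = 0.01,
                             sampling_min = 10, seed = 1000 + i)
    ok <- ok + (abs(maxGrowthRateTime(gp$control$times, gp$control$od) - 7)
                <= 0.5)
  }
  expect_gte(ok, qbinom(0.005, nrep, 0.95))
})

test_that("input contracts are enforced", {
  gp <- simulateGrowthPair(seed = 2)
  expect_error(maxGrowthRateTime(rev(gp$control$times), gp$control$od),
               "increasing")
  expect_error(maxGrowthRateTime(gp$control$times, gp$control$od,
                                 smooth_window = 4), "odd")
  expect_error(maxGrowthRateTime(gp$control$times[1:5], gp$control$od[1:5]),
               "10 points")
  flat <- maxGrowthRateTime(gp$control$times,
                            rep(0.05, length(gp$control$times)) +
                              seq(0, 0.001, length.out =
                                    length(gp$control$times)))
  expect_true(is.na(flat))
  expect_equal(attr(flat, "reason"), "non_grower")
})

test_that("sulfite delay recovers a pure time shift and handles failures", {
  gp0 <- simulateGrowthPair(shift_hours = 0, noise_sd = 0, seed = 3)
  expect_equal(sulfiteDelay(gp0$sulfite, gp0$control)$delay_hours, 0)
  gp <- simulateGrowthPair(shift_hours = 3.05, noise_sd = 0, seed = 4)
  expect_lt(abs(sulfiteDelay(gp$sulfite, gp$control)$delay_hours - 3.05),
            10 / 60)
  flatod <- data.frame(times = gp$control$times,
                       od = rep(0.05, nrow(gp$control)))
  d <- sulfiteDelay(gp$sulfite, flatod)
  expect_true(is.na(d$delay_hours))
  expect_equal(d$reason, "control_failed")
  d2 <- sulfiteDelay(flatod, gp$control)
  expect_equal(d2$reason, "sulfite_failed")
})

test_that("delay is invariant to OD scaling and common time shifts", {
  gp <- simulateGrowthPair(shift_hours = 2, noise_sd = 0.005, seed = 6)
  base <- sulfiteDelay(gp$sulfite, gp$control)$delay_hours
  scaled <- sulfiteDelay(list(times = gp$sulfite$times,
                              od = 3.7 * gp$sulfite$od),
                         list(times = gp$control$times,
                              od = 3.7 * gp$control$od))$delay_hours
  expect_equal(scaled, base)
  shifted <- sulfiteDelay(list(times = gp$sulfite$times + 1.5,
                               od = gp$sulfite$od),
                          list(times = gp$control$times + 1.5,
                               od = gp$control$od))$delay_hours
  expect_equal(shifted, base)
})

test_that("delayTable pairs curves by strain, day and batch", {
  gp <- simulateGrowthPair(shift_hours = 2, noise_sd = 0, seed = 8)
  long <- rbind(
    data.frame(strain = "s1", treatment = "control", day = "d1",
               batch = "b1", time_h = gp$control$times, od = gp$control$od),
    data.frame(strain = "s1", treatment = "sulfite", day = "d1",
               batch = "b1", time_h = gp$sulfite$times, od = gp$sulfite$od))
  tab <- delayTable(long)
  expect_equal(nrow(tab), 1)
  expect_lt(abs(tab$delay_hours - 2), 10 / 60)
})

test_that("day-wise Z-scoring standardizes each day and is idempotent", {
  expect_equal(zscoreByDay(c(1, 2, 3), rep("d1", 3)), c(-1, 0, 1))
  v <- c(rnorm(5, 10, 2), rnorm(6, -3, 0.5))
  day <- rep(c("a", "b"), c(5, 6))
  z <- zscoreByDay(v, day)
  expect_equal(mean(z[day == "a"]), 0, tolerance = 1e-12)
  expect_equal(sd(z[day == "b"]), 1, tolerance = 1e-12)
  expect_equal(zscoreByDay(z, day), z, tolerance = 1e-12)
  expect_error(zscoreByDay(c(1, 1, 2), c("x", "x", "y")), "y")
})

test_that("Kruskal-Wallis matches direct rank computation and has power", {
  g <- list(c(1, 2, 3), c(4, 5, 6))
  kw <- kruskalWallis(g)
  # oracle: H computed from its rank-sum definition, no ties
  r <- rank(unlist(g))
  n <- 6
  H <- 12 / (n * (n + 1)) * (sum(r[1:3])^2 / 3 + sum(r[4:6])^2 / 3) -
    3 * (n + 1)
  expect_equal(kw$statistic, H, tolerance = 1e-12)
  expect_equal(kruskalWallis(list(c(2, 2), c(2, 2)))$p_value, 1)
  withr::with_seed(12, {
    a <- rnorm(20)
    b <- rnorm(20) + 10
    expect_lt(kruskalWallis(list(a, b))$p_value, 1e-3)
    # invariance to strictly monotone transforms
    expect_equal(kruskalWallis(list(exp(a), exp(b)))$p_value,
                 kruskalWallis(list(a, b))$p_value)
  })
})

test_that("Wilcoxon p-values match exhaustive enumeration, Bonferroni caps", {
  withr::with_seed(13, {
    a <- rnorm(5)
    b <- rnorm(4) + 1
    got <- wilcoxonBonferroni(list(list(a, b)), m = 1)
    # brute force over all assignments of ranks to group A
    pooled <- c(a, b)
    W_obs <- sum(rank(pooled)[1:5]) - 5 * 6 / 2
    combos <- combn(9, 5)
    Wall <- apply(combos, 2, function(ix) sum(rank(pooled)[ix]) - 15)
    p_exact <- mean(abs(Wall - 10) >= abs(W_obs - 10))  # mean W = n1*n2/2
    expect_equal(got$p_raw, p_exact, tolerance = 1e-12)
  })
  two <- wilcoxonBonferroni(list(list(1:5, 6:10), list(1:5, c(2:5, 7))),
                            m = 10)
  expect_equal(two$p_adjusted, pmin(1, 10 * two$p_raw))
  expect_error(wilcoxonBonferroni(list(list(1:3, numeric(0)))), "empty")
  expect_error(wilcoxonBonferroni(list(list(1, 2), list(3, 4)), m = 1),
               "m must")
})
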