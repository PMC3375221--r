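tableOneEffects <- c(-0.25, -1.19, -1.51, 0.04, 0.01)

test_that("with zero batch variance the ML fit equals ordinary least squares", {
  tab <- simulateChimeraTable(tableOneEffects, batch_sd = 0,
                              residual_sd = 0.3, reps = 3, seed = 7)
  fit <- fitRegionModel(tab)
  d <- tab
  for (r in paste0("region", 1:5)) d[[r]] <- as.numeric(d[[r]])
  ols <- stats::coef(stats::lm(delay_hours ~ region1 + region2 + region3 +
                                 region4 + region5, data = d))
  expect_equal(unname(fit@fixed_effects), unname(ols), tolerance = 1e-6)
  expect_equal(fit@n, 66L)
  expect_equal(fit@k, 8L)
})

test_that("additive effects on the published scale are recovered within 2 SE", {
  tab <- simulateChimeraTable(tableOneEffects, batch_sd = 0,
                              residual_sd = 0.3, reps = 3, seed = 17)
  fit <- fitRegionModel(tab)
  est <- fit@fixed_effects[paste0("region", 1:5)]
  se <- fit@se[paste0("region", 1:5)]
  expect_true(all(abs(est - tableOneEffects) < 2 * se))
})

test_that("batch variance is recovered within 50% with 30 batches", {
  tab <- simulateChimeraTable(tableOneEffects, batch_sd = 1,
                              residual_sd = 0.1, reps = 30, seed = 23)
  fit <- fitRegionModel(tab)
  expect_gt(fit@batch_variance, 0.5)
  expect_lt(fit@batch_variance, 1.5)
})

test_that("interaction estimates are near zero under an additive truth", {
  nrep <- 30
  within2 <- total <- 0
  for (i in seq_len(nrep)) {
    # 6 plates so the ML Wald standard errors are close to honest
    tab <- simulateChimeraTable(tableOneEffects, batch_sd = 0.3,
                                residual_sd = 0.4, reps = 6,
                                seed = 1300 + i)
    fit <- fitRegionModel(tab, "pairwise")
    ints <- grepl(":", names(fit@fixed_effects))
    within2 <- within2 + sum(abs(fit@fixed_effects[ints]) < 2 * fit@se[ints])
    total <- total + sum(ints)
  }
  expect_gte(within2 / total, 0.90)
})

test_that("the additive/epistatic LRT has 10 df and is calibrated when
           asymptotics apply", {
  tab <- simulateChimeraTable(tableOneEffects, batch_sd = 0.5,
                              residual_sd = 0.4, reps = 3, seed = 29)
  fa <- fitRegionModel(tab)
  fe <- fitRegionModel(tab, "pairwise")
  expect_equal(fa@k, 8L)
  expect_equal(fe@k, 18L)
  lr <- lrtCompare(fa, fe)
  expect_equal(lr$df, 10L)
  expect_gte(lr$stat, -1e-6)
  # identical fits: zero statistic, p = 1
  self <- lrtCompare(fa, new("LMMFit", fixed_effects = fa@fixed_effects,
                             se = fa@se, p_values = fa@p_values,
                             batch_variance = fa@batch_variance,
                             residual_variance = fa@residual_variance,
                             lnL = fa@lnL, n = fa@n, k = 18L,
                             interactions = "pairwise", model = NULL))
  expect_equal(self$stat, 0)
  expect_equal(self$p_value, 1)
  # type-I error at a panel replication where the chi-square approximation
  # is adequate (30 plates, n = 660); ML LRTs are anti-conservative at
  # small n, which is the vignette-documented reason for the permutation
  # check below
  nrep <- 150
  rej <- 0
  for (i in seq_len(nrep)) {
    t2 <- simulateChimeraTable(tableOneEffects, batch_sd = 0.5,
                               residual_sd = 0.4, reps = 30,
                               seed = 1400 + i)
    rej <- rej + (lrtCompare(fitRegionModel(t2),
                             fitRegionModel(t2, "pairwise"))$p_value < 0.05)
  }
  expect_gte(rej, qbinom(0.0025, nrep, 0.05))
  expect_lte(rej, qbinom(0.9975, nrep, 0.08))
})

test_that("rank-deficient designs name the offending region", {
  tab <- simulateChimeraTable(tableOneEffects, seed = 31)
  tab$region4 <- 0
  expect_error(fitRegionModel(tab), "region4")
})

test_that("flipping the species coding negates effects, predictions intact", {
  tab <- simulateChimeraTable(tableOneEffects, batch_sd = 0,
                              residual_sd = 0.2, reps = 3, seed = 37)
  fit <- fitRegionModel(tab)
  flipped <- tab
  for (r in paste0("region", 1:5)) flipped[[r]] <- 1 - flipped[[r]]
  fit2 <- fitRegionModel(flipped)
  expect_equal(unname(fit2@fixed_effects[-1]),
               unname(-fit@fixed_effects[-1]), tolerance = 1e-6)
  expect_equal(unname(fit2@fixed_effects[1]),
               unname(fit@fixed_effects[1] + sum(fit@fixed_effects[-1])),
               tolerance = 1e-6)
  expect_equal(fit2@lnL, fit@lnL, tolerance = 1e-6)
})

test_that("R-squared from the likelihood ratio behaves as advertised", {
  expect_equal(varianceExplained(0, 50), 0)
  expect_equal(varianceExplained(66 * log(4), 66), 0.75)
  expect_error(varianceExplained(-1, 10), ">= 0")
  x <- varianceExplained(c(1, 5, 20), 30)
  expect_true(all(diff(x) > 0))
  # noise -> 0 drives R^2 -> 1
  hi <- simulateChimeraTable(tableOneEffects, batch_sd = 0,
                             residual_sd = 0.01, reps = 3, seed = 41)
  fit <- fitRegionModel(hi)
  null <- suppressMessages(lme4::lmer(delay_hours ~ 1 + (1 | batch),
                                      data = hi, REML = FALSE))
  LR <- 2 * (fit@lnL - as.numeric(stats::logLik(null)))
  expect_gt(varianceExplained(LR, fit@n), 0.99)
})

test_that("percent contributions reproduce the published worked example", {
  pc <- percentContribution(c(-0.251, -1.189, -1.509, 0.039, 0.012), 3.05)
  expect_equal(round(pc[1:3], 1), c(8.2, 39.0, 49.5))
  expect_equal(percentContribution(0, 3.05), 0)
  expect_equal(percentContribution(3.05, 3.05), 100)
  expect_error(percentContribution(c(1, 2), 0), "nonzero")
})

test_that("permuted parametric p-values are uniform; output is seeded", {
  tab <- simulateChimeraTable(tableOneEffects, batch_sd = 0.4,
                              residual_sd = 0.4, reps = 6, seed = 47)
  pp <- permutationPvalues(tab, nperm = 150, seed = 5)
  expect_gt(pp$ks_p, 0.01)
  expect_lt(pp$observed_p, 1e-6)   # real effects are extreme...
  # ...yet permutation destroys them by construction
  expect_gt(mean(pp$permuted_p > 0.05), 0.8)
  pp2 <- permutationPvalues(tab, nperm = 150, seed = 5)
  expect_identical(pp$permuted_p, pp2$permuted_p)
  expect_error(permutationPvalues(tab, nperm = 50), ">= 100")
})
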