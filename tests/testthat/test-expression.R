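design <- standardExpressionDesign()

test_that("median normalization centers arrays, preserves order, idempotent", {
  m <- matrix(c(rep(5, 4), 1:4), nrow = 4)
  norm <- medianNormalize(m)
  expect_equal(unname(norm[, 1]), rep(0, 4))
  expect_equal(apply(norm, 2, median), c(0, 0))
  expect_equal(order(norm[, 2]), order(m[, 2]))
  expect_equal(medianNormalize(norm), norm)
  # arrays differing by an offset collapse to the same values
  m2 <- cbind(rnorm(10), 0)
  m2[, 2] <- m2[, 1] + 3
  n2 <- medianNormalize(m2)
  expect_equal(n2[, 1], n2[, 2])
  expect_error(medianNormalize(cbind(NA_real_, 1:3)), "no non-missing")
})

test_that("first-level ANOVA p-values are uniform under the null", {
  m <- simulateExpressionMatrix(1500, seed = 11)
  res <- geneAnova(m, design)
  ks <- suppressWarnings(stats::ks.test(res$p_allele, "punif"))
  expect_gt(ks$p.value, 0.01)
  ks2 <- suppressWarnings(stats::ks.test(res$p_allele_time, "punif"))
  expect_gt(ks2$p.value, 0.01)
  expect_true(all(is.na(res$source_class[res$p_allele >= 0.01 &
                                           res$p_allele_time >= 0.01])))
})

test_that("a constant gene yields p = 1, missing values are flagged", {
  m <- simulateExpressionMatrix(20, seed = 12)
  m[3, ] <- 7
  m[5, 1] <- NA
  res <- geneAnova(m, design)
  expect_equal(res$p_allele[3], 1)
  expect_equal(res$p_allele_time[3], 1)
  expect_true(res$flagged[5])
  expect_true(is.na(res$p_allele[5]))
  expect_false(any(res$flagged[-5]))
})

test_that("spiked effect sources are classified correctly", {
  m <- simulateExpressionMatrix(
    600, spikes = list(coding = c(40, 2), noncoding = c(40, 2),
                       cn_interaction = c(40, 3)), seed = 13)
  res <- geneAnova(m, design)
  truth <- attr(m, "truth")
  got <- res$source_class[match(truth$gene, res$gene)]
  for (cls in c("coding", "noncoding")) {
    agree <- mean(got[truth$class == cls] == cls, na.rm = TRUE)
    expect_gte(agree, 0.90)
  }
  agree_int <- mean(got[truth$class == "cn_interaction"] == "interaction",
                    na.rm = TRUE)
  expect_gte(agree_int, 0.80)
})

test_that("classification is invariant to which species is the reference", {
  m <- simulateExpressionMatrix(
    300, spikes = list(coding = c(30, 2), noncoding = c(30, 2)), seed = 14)
  res <- geneAnova(m, design)
  flipped <- design
  flipped$noncoding_origin <- 1 - flipped$noncoding_origin
  flipped$coding_origin <- 1 - flipped$coding_origin
  res2 <- geneAnova(m, flipped)
  expect_equal(res2$p_coding, res$p_coding, tolerance = 1e-9)
  expect_equal(res2$p_noncoding, res$p_noncoding, tolerance = 1e-9)
  expect_equal(res2$source_class, res$source_class)
})

test_that("time-dependent allele effects are decomposed on the response
           contrast", {
  m <- simulateExpressionMatrix(400,
                                spikes = list(allele_time = c(40, 3)),
                                seed = 15)
  res <- geneAnova(m, design)
  truth <- attr(m, "truth")
  hit <- res$p_allele_time[match(truth$gene, res$gene)] < 0.01
  expect_gte(mean(hit), 0.9)
  got <- res$source_class[match(truth$gene, res$gene)]
  expect_gte(mean(got[hit] == "coding", na.rm = TRUE), 0.85)
})

test_that("the permutation FDR is seeded, near 1 under the null, and small
           with strong spikes", {
  null_m <- simulateExpressionMatrix(800, seed = 16)
  f0 <- permutationFdr(null_m, design, alpha = 0.05, nperm = 25, seed = 3)
  expect_gt(f0$fdr, 0.5)   # observed ~ chance expectation
  f0b <- permutationFdr(null_m, design, alpha = 0.05, nperm = 25, seed = 3)
  expect_identical(f0$null_counts, f0b$null_counts)

  spiked <- simulateExpressionMatrix(
    2000, spikes = list(coding = c(100, 3), noncoding = c(60, 3),
                        allele_time = c(40, 3)), seed = 17)
  f1 <- permutationFdr(spiked, design, alpha = 0.01, nperm = 25, seed = 4)
  expect_lt(f1$fdr, 0.25)
  expect_gt(f1$n_observed, 150)
  expect_error(permutationFdr(spiked, design, nperm = 5), ">= 20")
})

test_that("fold-change sets use strict 2-fold boundaries and stay disjoint", {
  res <- data.frame(gene = c("a", "b", "c", "d"),
                    log2fc_sulfite = c(1.1, 1.0, -1.4, 2.0),
                    p_time = c(0.005, 0.005, 0.001, 0.5))
  sets <- foldChangeSets(res)
  expect_equal(sets$up, "a")        # b sits exactly at 2-fold: excluded
  expect_equal(sets$down, "c")      # d fails the p threshold
  expect_length(intersect(sets$up, sets$down), 0)
})

test_that("qPCR plate correction removes primer bias exactly and normalizes
           the heterozygote to 1", {
  # heterozygote measured with biased primers (the par primer over-reports
  # by 1.3x): apparent allele ratio != 1 before correction
  cal <- data.frame(plate = "p1", primer = c("cer", "par"),
                    ct_target = c(20, 20 - log2(1.3)), ct_reference = 15)
  rec <- data.frame(sample = c("h", "h"), gene = "FZF1",
                    primer = c("cer", "par"),
                    ct_target = c(20, 20 - log2(1.3)), ct_reference = 15,
                    plate = "p1", day = "d1", batch = "b1")
  out <- plateCorrectedRelativeExpression(rec, cal)
  expect_equal(out$rel_expr[1] / out$rel_expr[2], 1, tolerance = 1e-12)

  # a known 2-fold allele effect with primer bias 1.3 is recovered
  withr::with_seed(19, {
    n <- 50
    truth <- rep(c(1, 2), each = n)            # cer = 1x, par = 2x
    primer <- rep(c("cer", "par"), each = n)
    bias <- ifelse(primer == "par", 1.3, 1)
    ct_ref <- rnorm(2 * n, 15, 0.05)
    ct_t <- ct_ref - log2(truth * bias) + rnorm(2 * n, 0, 0.05)
    rec2 <- data.frame(sample = paste0("s", 1:(2 * n)), gene = "FZF1",
                       primer = primer, ct_target = ct_t,
                       ct_reference = ct_ref, plate = "p1", day = "d1",
                       batch = "b1")
    out2 <- plateCorrectedRelativeExpression(rec2, cal)
    fold <- mean(out2$rel_expr[primer == "par"]) /
      mean(out2$rel_expr[primer == "cer"])
    expect_lt(abs(fold - 2) / 2, 0.10)
  })
  # trivial identity: equal Cts, no allele-specific primer
  plain <- data.frame(sample = "s", gene = "SSU1", primer = NA,
                      ct_target = 17, ct_reference = 17, plate = "p2")
  expect_equal(plateCorrectedRelativeExpression(plain)$rel_expr, 1)
  # contract errors
  expect_error(plateCorrectedRelativeExpression(
    data.frame(sample = "s", gene = "g", primer = "cer", ct_target = 20,
               ct_reference = 15, plate = "p9")), "calibration")
  expect_error(plateCorrectedRelativeExpression(
    data.frame(sample = "s", gene = "g", ct_target = 20,
               ct_reference = NA, plate = "p1")), "reference")
})
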