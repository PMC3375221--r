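test_that("identical sequences give zero divergence", {
  r <- ng86Pairwise("ATGGCTAAA", "ATGGCTAAA")
  expect_equal(r@dS, 0)
  expect_equal(r@dN, 0)
  expect_equal(r@syn_diffs, 0)
})

test_that("TTT vs TTC is one synonymous difference, zero nonsynonymous", {
  r <- ng86Pairwise("TTT", "TTC")
  expect_equal(r@syn_diffs, 1)
  expect_equal(r@nonsyn_diffs, 0)
  # oracle: enumerate the nine single-base mutations of each codon
  gc_tab <- Biostrings::GENETIC_CODE
  synFrac <- function(cod) {
    s <- 0
    for (pos in 1:3) for (b in setdiff(c("A", "C", "G", "T"),
                                       substr(cod, pos, pos))) {
      alt <- cod
      substr(alt, pos, pos) <- b
      if (gc_tab[alt] == gc_tab[cod]) s <- s + 1 / 3
    }
    s
  }
  expect_equal(r@syn_sites, (synFrac("TTT") + synFrac("TTC")) / 2)
})

test_that("site counts conserve total length and the method is symmetric", {
  withr::with_seed(21, {
    for (rep in 1:15) {
      pr <- simulateCodonPair(40, dS = runif(1, 0, 0.6),
                              dN = runif(1, 0, 0.3), seed = 600 + rep)
      r <- ng86Pairwise(pr$a, pr$b)
      expect_equal(r@syn_sites + r@nonsyn_sites, 3 * r@codons,
                   tolerance = 1e-9)
      rev <- ng86Pairwise(pr$b, pr$a)
      expect_equal(r@syn_diffs, rev@syn_diffs)
      expect_equal(r@dN, rev@dN)
    }
  })
})

test_that("codons with gaps or stops are skipped, internal stops warn", {
  r <- ng86Pairwise("ATG---AAA", "ATGGCTAAA")
  expect_equal(r@codons, 2L)
  expect_warning(ng86Pairwise("ATGTAAAAA", "ATGGCTAAA"), "stop")
  term <- suppressWarnings(ng86Pairwise("ATGAAATAA", "ATGAAATGA"))
  expect_equal(term@codons, 2L)  # terminal stop pair dropped from counts
})

test_that("saturation is reported as undefined, never infinite", {
  a <- paste(rep("GCT", 4), collapse = "")
  b <- paste(rep("GCA", 4), collapse = "")  # every codon differs silently
  r <- ng86Pairwise(a, b)
  expect_true(r@saturated["dS"])
  expect_true(is.na(r@dS))
  expect_true(is.na(r@omega))
})

test_that("point estimates fall inside their Monte-Carlo CI as often as
           the parametric bootstrap promises", {
  truth <- c(dS = 0.4, dN = 0.1)
  nrep <- 50
  cover <- 0
  for (i in seq_len(nrep)) {
    pr <- simulateCodonPair(300, truth["dS"], truth["dN"], seed = 700 + i)
    r <- ng86Pairwise(pr$a, pr$b)
    ci <- mcConfidenceInterval(r, nsim = 100, seed = 800 + i)
    cover <- cover + (truth["dS"] >= ci$dS[1] && truth["dS"] <= ci$dS[2] &&
                        truth["dN"] >= ci$dN[1] && truth["dN"] <= ci$dN[2])
  }
  # both-rates joint coverage at a nominal ~90%, exact binomial 99% band
  expect_gte(cover, qbinom(0.005, nrep, 0.90))
})

test_that("Monte-Carlo CIs are deterministic and degenerate at zero", {
  r <- ng86Pairwise("ATGGCTAAA", "ATGGCTAAA")
  ci <- mcConfidenceInterval(r, codons = 100, nsim = 100, seed = 5)
  expect_equal(ci$dS, c(0, 0))
  expect_equal(ci$dN, c(0, 0))
  pr <- simulateCodonPair(120, 0.3, 0.1, seed = 9)
  r2 <- ng86Pairwise(pr$a, pr$b)
  ci1 <- mcConfidenceInterval(r2, nsim = 150, seed = 31)
  ci2 <- mcConfidenceInterval(r2, nsim = 150, seed = 31)
  expect_identical(ci1, ci2)
  expect_error(mcConfidenceInterval(r2, nsim = 50), ">= 100")
})

test_that("window scan tiles the gene; invariant windows are undefined", {
  a <- paste(rep("GCT", 60), collapse = "")
  sc <- slidingWindowDnds(a, a, window_size = 20, step = 10)
  expect_equal(sc@per_window$start_codon, seq(1, 41, by = 10))
  expect_true(all(is.na(sc@per_window$omega)))
  expect_equal(sc@per_window$dS, rep(0, 5))
  expect_error(slidingWindowDnds(a, a, window_size = 20, step = 0), "step")
  expect_error(slidingWindowDnds(a, a, window_size = 100), "window_size")
})

test_that("the whole-gene estimate pools sites and differences, not ratios", {
  pr <- simulateCodonPair(120, 0.5, 0.15, seed = 55)
  sc <- slidingWindowDnds(pr$a, pr$b, window_size = 40, step = 40)
  expect_equal(sum(sc@per_window$syn_diffs), sc@gene@syn_diffs)
  expect_equal(sum(sc@per_window$syn_sites), sc@gene@syn_sites,
               tolerance = 1e-9)
  pooled_pS <- sum(sc@per_window$syn_diffs) / sum(sc@per_window$syn_sites)
  expect_equal(sc@gene@dS, -0.75 * log(1 - 4 * pooled_pS / 3),
               tolerance = 1e-12)
})

test_that("a high-omega segment is localized by the max-omega window", {
  hits <- 0
  nrep <- 20
  for (i in seq_len(nrep)) {
    bg1 <- simulateCodonPair(150, 0.4, 0.08, seed = 900 + i)
    seg <- simulateCodonPair(100, 0.4, 0.8, seed = 950 + i)
    bg2 <- simulateCodonPair(150, 0.4, 0.08, seed = 990 + i)
    a <- paste0(bg1$a, seg$a, bg2$a)
    b <- paste0(bg1$b, seg$b, bg2$b)
    sc <- slidingWindowDnds(a, b, window_size = 100, step = 25)
    w <- sc@per_window[which.max(sc@per_window$omega), ]
    hits <- hits + (w$end_codon >= 151 && w$start_codon <= 250)
  }
  expect_gte(hits, qbinom(0.005, nrep, 0.95))
})
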