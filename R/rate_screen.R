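#' Insertion/deletion fraction filter
#'
#' A locus is dropped when the fraction of alignment columns containing at
#' least one gap character exceeds `threshold` ("more than" is strict: a
#' fraction exactly at the threshold is kept).  Column counting makes the
#' indel length commensurate with the alignment length whatever the gap
#' placement.
#'
#' @param aln a [NucAlignment-class]
#' @param threshold maximum tolerated gap-column fraction (default 0.15)
#' @return list with `keep` (logical), `fraction`, `threshold`
#' @examples
#' a <- nucAlignment(c(x = "AC-T", y = "ACGT"))
#' indelFractionFilter(a)$fraction  # 0.25
#' @export
indelFractionFilter <- function(aln, threshold = 0.15) {
  stopifnot(is(aln, "NucAlignment"))
  frac <- mean(apply(aln@seqs == "-", 2, any))
  list(keep = frac <= threshold, fraction = frac, threshold = threshold)
}

#' Chi-square upper tail probability
#'
#' P(X >= x) for X ~ chi-square(df); the reference distribution of every
#' likelihood ratio statistic in the package.
#'
#' @param x statistic, >= 0
#' @param df positive integer degrees of freedom
#' @return upper-tail probability
#' @examples
#' chiSquareSf(56.48, 10)  # ~1.7e-8
#' @export
chiSquareSf <- function(x, df) {
  if (any(df < 1) || any(df != round(df)))
    stop("df must be a positive integer")
  if (any(!is.finite(x)) || any(x < 0)) stop("statistic must be >= 0")
  stats::pchisq(x, df, lower.tail = FALSE)
}

# One bounded multi-start ML fit of rate ratios with fixed tree lengths.
# `free` gives the number of ratio parameters (1 = shared, nb = per-branch);
# kappa is optimized when `kappa` is NULL, else held fixed.
fitRatios <- function(pat, tr, pi, free, kappa = NULL,
                      starts = c(0.1, 1, 10), extra_start = NULL,
                      ratio_bounds = c(1e-6, 100)) {
  nb <- nrow(tr$edge)
  bl <- tr$edge.length
  estK <- is.null(kappa)
  negll <- function(par) {
    k <- if (estK) exp(par[1]) else kappa
    r <- exp(par[(1 + estK):(free + estK)])
    eff <- bl * (if (free == 1) rep(r, nb) else r)
    -pruningCore(pat, tr, hky85Params(k, pi), eff)
  }
  lo <- c(if (estK) log(0.05), rep(log(ratio_bounds[1]), free))
  hi <- c(if (estK) log(100), rep(log(ratio_bounds[2]), free))
  startList <- lapply(starts, function(s)
    c(if (estK) log(2), rep(log(s), free)))
  if (!is.null(extra_start))
    startList <- c(startList, list(c(if (estK) log(2), log(extra_start))))
  best <- NULL
  ok <- FALSE
  for (p0 in startList) {
    fit <- tryCatch(
      stats::optim(p0, negll, method = "L-BFGS-B", lower = lo, upper = hi,
                   control = list(factr = 1e7, maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) {  # retry from a perturbed start
      fit <- tryCatch(
        stats::optim(p0 + stats::runif(length(p0), -0.3, 0.3), negll,
                     method = "L-BFGS-B", lower = lo, upper = hi,
                     control = list(factr = 1e7, maxit = 500)),
        error = function(e) NULL)
    }
    if (is.null(fit)) next
    ok <- ok || fit$convergence == 0
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) return(NULL)
  estKn <- as.integer(estK)
  list(lnL = -best$value,
       kappa = if (estK) exp(best$par[1]) else kappa,
       ratios = exp(best$par[(1 + estKn):(free + estKn)]),
       converged = ok)
}

#' Fit constrained and unconstrained rate-ratio models to a locus
#'
#' The constrained model shares one rate ratio (locus rate relative to the
#' silent-site rate) across all branches; the unconstrained model gives each
#' branch its own.  Both use HKY85 with empirical base frequencies; kappa is
#' ML-estimated once (in the constrained fit) and then held fixed in the
#' unconstrained fit so the likelihood ratio isolates rate heterogeneity.
#' The unconstrained optimization starts from 0.1, 1, 10 and from the
#' constrained optimum, which also guarantees the nesting inequality.
#'
#' @param aln locus alignment, a [NucAlignment-class]
#' @param tree a [ScaledTree-class] with fixed silent-rate branch lengths
#' @param locus_id label for reporting
#' @param ratio_bounds box constraints for the ratio (default `[1e-6, 100]`;
#'   rate-ratio likelihoods can be flat near zero)
#' @return a [RateHetResult-class]
#' @export
fitRateModels <- function(aln, tree, locus_id = "locus",
                          ratio_bounds = c(1e-6, 100)) {
  stopifnot(is(aln, "NucAlignment"), is(tree, "ScaledTree"))
  tr <- tree@phylo
  if (!setequal(taxa(aln), tr$tip.label))
    stop("taxa mismatch between locus alignment and tree")
  pi <- empiricalBaseFreqs(aln)
  pat <- sitePatterns(aln)
  nb <- nrow(tr$edge)

  con <- fitRatios(pat, tr, pi, free = 1, ratio_bounds = ratio_bounds)
  if (is.null(con)) stop("constrained fit failed for locus ", locus_id)
  unc <- fitRatios(pat, tr, pi, free = nb, kappa = con$kappa,
                   extra_start = rep(con$ratios, nb),
                   ratio_bounds = ratio_bounds)
  if (is.null(unc)) stop("unconstrained fit failed for locus ", locus_id)

  stat <- 2 * (unc$lnL - con$lnL)
  df <- nb - 1L
  new("RateHetResult",
      locus_id = locus_id, lnL_constrained = con$lnL,
      lnL_unconstrained = unc$lnL, kappa = con$kappa,
      shared_ratio = con$ratios,
      branch_ratios = stats::setNames(unc$ratios, edgeLabelsPhylo(tr)),
      lrt_stat = stat, df = df,
      p_value = chiSquareSf(max(stat, 0), df),
      bonferroni_significant = NA, converged = con$converged && unc$converged)
}

#' @export
setMethod("show", "RateHetResult", function(object) {
  cat(sprintf("RateHetResult [%s]\n", object@locus_id))
  cat(sprintf("  lnL constrained   %12.4f  (shared ratio %.4g, kappa %.3g)\n",
              object@lnL_constrained, object@shared_ratio, object@kappa))
  cat(sprintf("  lnL unconstrained %12.4f\n", object@lnL_unconstrained))
  cat("  branch ratios:",
      paste(sprintf("%s=%.3g", names(object@branch_ratios),
                    object@branch_ratios), collapse = ", "), "\n")
  cat(sprintf("  2*dlnL = %.4f, df = %d, p = %.4g\n", object@lrt_stat,
              object@df, object@p_value))
})

#' Genome-wide rate-heterogeneity screen
#'
#' Applies the indel-fraction filter to each locus, fits surviving loci with
#' [fitRateModels()], and marks Bonferroni-corrected significance at per-test
#' level `alpha / n_tested` where `n_tested` counts loci actually fitted
#' (post-filter).  Loci named in `allowlist` are fitted even if they fail the
#' filter (an explicit override, mirroring a region kept for an already
#' initiated functional analysis) but still count toward `n_tested`.
#'
#' @param loci named list of [NucAlignment-class] objects
#' @param tree a [ScaledTree-class]
#' @param alpha family-wise significance level (default 0.05)
#' @param indel_max gap-column fraction threshold (default 0.15)
#' @param allowlist locus names exempt from the filter
#' @return a [ScreenReport-class]
#' @export
screenLoci <- function(loci, tree, alpha = 0.05, indel_max = 0.15,
                       allowlist = character()) {
  if (length(loci) < 1) stop("need at least one locus")
  if (is.null(names(loci)))
    names(loci) <- paste0("locus", seq_along(loci))
  frac <- vapply(loci, function(a) indelFractionFilter(a, indel_max)$fraction,
                 numeric(1))
  keep <- frac <= indel_max | names(loci) %in% allowlist
  if (!any(keep)) {
    warning("no loci pass the indel filter; empty report")
    return(new("ScreenReport", n_tested = 0L, n_significant = 0L,
               alpha = alpha, per_locus = list(),
               table = data.frame(locus = names(loci),
                                  fraction_indel = frac, tested = FALSE,
                                  lnL_constrained = NA_real_,
                                  lnL_unconstrained = NA_real_,
                                  shared_ratio = NA_real_,
                                  lrt_stat = NA_real_, df = NA_integer_,
                                  p_value = NA_real_, significant = FALSE)))
  }
  fits <- lapply(names(loci)[keep], function(id)
    fitRateModels(loci[[id]], tree, locus_id = id))
  names(fits) <- names(loci)[keep]
  n_tested <- length(fits)
  thr <- alpha / n_tested
  sig <- vapply(fits, function(f) f@p_value < thr, logical(1))
  fits <- lapply(fits, function(f) {
    f@bonferroni_significant <- f@p_value < thr
    f
  })
  tab <- data.frame(
    locus = names(loci), fraction_indel = frac, tested = keep,
    lnL_constrained = NA_real_, lnL_unconstrained = NA_real_,
    shared_ratio = NA_real_, lrt_stat = NA_real_, df = NA_integer_,
    p_value = NA_real_, significant = FALSE)
  for (id in names(fits)) {
    i <- match(id, tab$locus)
    f <- fits[[id]]
    tab$lnL_constrained[i] <- f@lnL_constrained
    tab$lnL_unconstrained[i] <- f@lnL_unconstrained
    tab$shared_ratio[i] <- f@shared_ratio
    tab$lrt_stat[i] <- f@lrt_stat
    tab$df[i] <- f@df
    tab$p_value[i] <- f@p_value
    tab$significant[i] <- f@bonferroni_significant
  }
  new("ScreenReport", n_tested = as.integer(n_tested),
      n_significant = as.integer(sum(sig)), alpha = alpha,
      per_locus = fits, table = tab)
}

#' Write a screen report to disk
#'
#' Writes the per-locus summary as a tab-separated table and, optionally,
#' the full per-locus detail (log-likelihoods, per-branch ratios, kappa,
#' convergence flags) as JSON.
#'
#' @param report a [ScreenReport-class]
#' @param tsv path for the per-locus summary table
#' @param json optional path for per-locus detail (requires \pkg{jsonlite})
#' @return invisibly, the report
#' @export
writeScreenReport <- function(report, tsv, json = NULL) {
  stopifnot(is(report, "ScreenReport"))
  utils::write.table(report@table, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(json)) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("jsonlite is required for JSON output")
    detail <- lapply(report@per_locus, function(f) list(
      locus = f@locus_id, lnL_constrained = f@lnL_constrained,
      lnL_unconstrained = f@lnL_unconstrained, kappa = f@kappa,
      shared_ratio = f@shared_ratio, branch_ratios = as.list(f@branch_ratios),
      lrt_stat = f@lrt_stat, df = f@df, p_value = f@p_value,
      bonferroni_significant = f@bonferroni_significant,
      converged = f@converged))
    jsonlite::write_json(list(n_tested = report@n_tested,
                              n_significant = report@n_significant,
                              alpha = report@alpha, loci = detail),
                         json, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}

#' @export
setMethod("show", "ScreenReport", function(object) {
  cat(sprintf(paste0("ScreenReport: %d loci tested, %d significant ",
                     "(alpha %.3g, Bonferroni per-test %.3g)\n"),
              object@n_tested, object@n_significant, object@alpha,
              if (object@n_tested > 0) object@alpha / object@n_tested
              else NA_real_))
})
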