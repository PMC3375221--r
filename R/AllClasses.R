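#' @import methods
NULL

ALN_ALPHABET <- c("A", "C", "G", "T", "-", "N")
NUC <- c("A", "C", "G", "T")

#' Aligned nucleotide sequences for a set of taxa
#'
#' A thin container for a gapped multiple alignment: a character matrix over
#' \code{A,C,G,T,-,N} with one row per taxon.  Gaps and \code{N} are treated
#' as missing data by the likelihood machinery (a partial-likelihood vector of
#' ones), never silently dropped, so the alignment length stays commensurate
#' with the insertion/deletion filter.
#'
#' @slot seqs character matrix, rows named by taxon.
#' @seealso [nucAlignment()], [readAlignment()]
#' @export
setClass("NucAlignment", representation(seqs = "matrix"))

setValidity("NucAlignment", function(object) {
  m <- object@seqs
  if (!is.character(m)) return("seqs must be a character matrix")
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    return("taxa (rownames) must be present and unique")
  if (nrow(m) < 1) return("at least one taxon required")
  bad <- setdiff(unique(as.vector(m)), ALN_ALPHABET)
  if (length(bad))
    return(paste0("disallowed alignment characters: ",
                  paste(bad, collapse = ", ")))
  TRUE
})

#' Phylogeny scaled to the fourfold-degenerate substitution rate
#'
#' Wraps an \pkg{ape} \code{phylo} tree whose branch lengths are genome-wide
#' substitutions/site at fourfold-degenerate (silent) third codon positions.
#' These lengths are the neutral yardstick: a noncoding region evolving
#' neutrally should accumulate substitutions at this rate (rate ratio 1), and
#' the rate-heterogeneity screen estimates per-branch multipliers against it.
#'
#' @slot phylo an \code{ape::phylo} object with \code{edge.length} set.
#' @slot metadata list; optimizer diagnostics when the tree was estimated
#'   (e.g. \code{converged}, \code{logLik}, \code{kappa}).
#' @seealso [scaledTree()], [estimateBranchLengths()]
#' @export
setClass("ScaledTree", representation(phylo = "ANY", metadata = "list"))

setValidity("ScaledTree", function(object) {
  tr <- object@phylo
  if (!inherits(tr, "phylo")) return("phylo slot must be an ape 'phylo' tree")
  if (is.null(tr$edge.length)) return("branch lengths are required")
  if (any(!is.finite(tr$edge.length)) || any(tr$edge.length < 0))
    return("branch lengths must be finite and non-negative")
  if (anyDuplicated(tr$tip.label)) return("tip labels must be unique")
  TRUE
})

#' HKY85 substitution model parameters
#'
#' @slot kappa transition/transversion rate ratio, > 0.
#' @slot pi stationary base frequencies in order A, C, G, T; strictly
#'   positive and summing to one.
#' @seealso [hky85Params()], [hky85TransitionProbs()]
#' @export
setClass("HKY85Params", representation(kappa = "numeric", pi = "numeric"))

setValidity("HKY85Params", function(object) {
  if (length(object@kappa) != 1 || !is.finite(object@kappa) ||
      object@kappa <= 0)
    return("kappa must be a single finite value > 0")
  p <- object@pi
  if (length(p) != 4 || any(!is.finite(p)) || any(p < 0))
    return("pi must be 4 finite non-negative frequencies")
  if (abs(sum(p) - 1) > 1e-12) return("pi must sum to 1 (within 1e-12)")
  TRUE
})

#' Branch-specific rate multipliers (dNC/dS)
#'
#' The ratio of the substitution rate in the region under test to the
#' fourfold-degenerate rate carried by the [ScaledTree-class].  In
#' \code{"constrained"} mode a single shared multiplier applies to every
#' branch; in \code{"unconstrained"} mode each branch carries its own, ordered
#' as [edgeLabels()] orders the branches of the tree they are applied to.
#'
#' @slot mode "constrained" or "unconstrained".
#' @slot ratios non-negative multipliers; exactly one when constrained.
#' @seealso [branchRates()]
#' @export
setClass("BranchRates", representation(mode = "character", ratios = "numeric"))

setValidity("BranchRates", function(object) {
  if (!object@mode %in% c("constrained", "unconstrained"))
    return("mode must be 'constrained' or 'unconstrained'")
  if (any(!is.finite(object@ratios)) || any(object@ratios < 0))
    return("ratios must be finite and >= 0")
  if (object@mode == "constrained" && length(object@ratios) != 1)
    return("constrained mode carries exactly one ratio")
  TRUE
})

#' Per-locus rate-heterogeneity test result
#'
#' Constrained (shared rate ratio) versus unconstrained (per-branch rate
#' ratios) maximum-likelihood fits and the likelihood ratio test between them.
#'
#' @slot locus_id label.
#' @slot lnL_constrained,lnL_unconstrained maximized log-likelihoods (ML).
#' @slot kappa transition/transversion ratio shared by both fits.
#' @slot shared_ratio the constrained-model rate ratio.
#' @slot branch_ratios named per-branch rate ratios (unconstrained model).
#' @slot lrt_stat 2(lnL_u - lnL_c).
#' @slot df free branch ratios minus one.
#' @slot p_value chi-square upper tail probability.
#' @slot bonferroni_significant logical, set by [screenLoci()].
#' @slot converged logical; FALSE flags persistent optimizer failure.
#' @export
setClass("RateHetResult", representation(
  locus_id = "character", lnL_constrained = "numeric",
  lnL_unconstrained = "numeric", kappa = "numeric", shared_ratio = "numeric",
  branch_ratios = "numeric", lrt_stat = "numeric", df = "integer",
  p_value = "numeric", bonferroni_significant = "logical",
  converged = "logical"))

setValidity("RateHetResult", function(object) {
  if (object@lrt_stat < -1e-6) return("lrt_stat must be >= -1e-6 (nesting)")
  if (object@p_value < 0 || object@p_value > 1) return("p_value not in [0,1]")
  if (object@df < 1L) return("df must be >= 1")
  TRUE
})

#' Genome-wide screen report
#'
#' @slot n_tested loci fitted after the indel filter.
#' @slot n_significant loci significant after Bonferroni correction.
#' @slot alpha family-wise significance level.
#' @slot per_locus list of [RateHetResult-class] objects.
#' @slot table per-locus summary data.frame (one row per input locus,
#'   including filtered ones).
#' @export
setClass("ScreenReport", representation(
  n_tested = "integer", n_significant = "integer", alpha = "numeric",
  per_locus = "list", table = "data.frame"))

setValidity("ScreenReport", function(object) {
  if (object@n_significant > object@n_tested)
    return("n_significant cannot exceed n_tested")
  TRUE
})

#' Pairwise NG86 divergence estimates
#'
#' Nei-Gojobori (1986) site and difference counts with Jukes-Cantor corrected
#' synonymous (dS) and nonsynonymous (dN) rates.  \code{omega} is \code{NA}
#' (undefined, never infinite) when dS is zero or saturated.
#'
#' @slot codons codon pairs actually compared (gap/stop codons skipped).
#' @slot syn_sites,nonsyn_sites expected site counts, averaged over the two
#'   sequences; they sum to 3 x codons.
#' @slot syn_diffs,nonsyn_diffs pathway-averaged difference counts.
#' @slot dS,dN Jukes-Cantor corrected rates; NA when saturated.
#' @slot omega dN/dS.
#' @slot saturated logical flags for dS and dN (p >= 3/4).
#' @export
setClass("PairwiseRates", representation(
  codons = "integer", syn_sites = "numeric", nonsyn_sites = "numeric",
  syn_diffs = "numeric", nonsyn_diffs = "numeric", dS = "numeric",
  dN = "numeric", omega = "numeric", saturated = "logical"))

setValidity("PairwiseRates", function(object) {
  if (object@codons > 0 &&
      abs(object@syn_sites + object@nonsyn_sites - 3 * object@codons) > 1e-9)
    return("syn_sites + nonsyn_sites must equal 3 x codons")
  TRUE
})

#' Linear mixed-model fit for chimeric-allele decomposition
#'
#' ML (not REML) fit of growth-delay phenotypes on per-region origin
#' indicators with a batch (96-well plate) random intercept.  The parameter
#' count convention is intercept + region terms (+ pairwise interactions) +
#' two variance components, giving k = 8 for the additive and k = 18 for the
#' pairwise-epistatic model with five regions.
#'
#' @slot fixed_effects named coefficient vector.
#' @slot se standard errors of the fixed effects.
#' @slot p_values Wald (z) p-values of the fixed effects.
#' @slot batch_variance,residual_variance variance components (>= 0).
#' @slot lnL maximized ML log-likelihood.
#' @slot n observations.
#' @slot k counted free parameters.
#' @slot interactions "none" or "pairwise".
#' @slot model the underlying \pkg{lme4} fit.
#' @export
setClass("LMMFit", representation(
  fixed_effects = "numeric", se = "numeric", p_values = "numeric",
  batch_variance = "numeric", residual_variance = "numeric", lnL = "numeric",
  n = "integer", k = "integer", interactions = "character", model = "ANY"))

setValidity("LMMFit", function(object) {
  if (object@batch_variance < 0) return("batch variance must be >= 0")
  if (object@residual_variance <= 0) return("residual variance must be > 0")
  TRUE
})
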