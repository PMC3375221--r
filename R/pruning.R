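#' Construct branch rate multipliers
#'
#' @param mode "constrained" (one shared dNC/dS multiplier) or
#'   "unconstrained" (one per branch, in [edgeLabels()] order)
#' @param ratios non-negative rate ratios
#' @return a [BranchRates-class]
#' @export
branchRates <- function(mode = c("constrained", "unconstrained"),
                        ratios = 1) {
  new("BranchRates", mode = match.arg(mode), ratios = as.numeric(ratios))
}

# Expand BranchRates to one multiplier per edge of `tr` (a phylo).
edgeRatios <- function(tr, rates) {
  nb <- nrow(tr$edge)
  if (rates@mode == "constrained") return(rep(rates@ratios, nb))
  if (length(rates@ratios) != nb)
    stop("unconstrained BranchRates needs one ratio per branch (", nb, ")")
  rates@ratios
}

# Likelihood core on precomputed site patterns.  `effLengths` are effective
# branch lengths (silent-rate length x rate ratio) in the ORIGINAL edge order
# of `tr`.  One eigendecomposition serves every branch.
pruningCore <- function(pat, tr, params, effLengths) {
  ntip <- length(tr$tip.label)
  ord <- match(tr$tip.label, pat$taxa)
  codes <- pat$patterns[ord, , drop = FALSE]
  npat <- ncol(codes)

  tr$edge.length <- effLengths
  po <- ape::reorder.phylo(tr, "postorder")
  eig <- hky85Eigen(params)

  partial <- vector("list", ntip + tr$Nnode)
  for (i in seq_len(ntip)) {
    tp <- matrix(0, 4, npat)
    obs <- codes[i, ] > 0L
    tp[cbind(codes[i, obs], which(obs))] <- 1
    tp[, !obs] <- 1        # gap/N: missing data, partial of ones
    partial[[i]] <- tp
  }
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]
    ch <- po$edge[e, 2]
    P <- hky85ProbsFromEigen(eig, po$edge.length[e])
    contrib <- P %*% partial[[ch]]
    partial[[p]] <- if (is.null(partial[[p]])) contrib
                    else partial[[p]] * contrib
  }
  root <- po$edge[nrow(po$edge), 1]
  L <- colSums(params@pi * partial[[root]])
  sum(pat$weights * log(L))
}

#' Phylogenetic log-likelihood by Felsenstein pruning
#'
#' Exact post-order dynamic-programming likelihood of an alignment on a fixed
#' tree under HKY85, with per-branch effective lengths equal to the tree's
#' silent-rate branch lengths multiplied by the [BranchRates-class] ratios.
#' Columns are independent, so the log-likelihood of concatenated alignments
#' adds.  Gap and N characters are missing data (partial-likelihood vector of
#' ones at the tip); an all-gap column contributes exactly zero.
#'
#' @param aln a [NucAlignment-class]; taxa must match the tree's tips
#' @param tree a [ScaledTree-class]
#' @param params an [HKY85Params-class]
#' @param rates a [BranchRates-class]; default: shared ratio 1 (the tree's
#'   own branch lengths)
#' @return log-likelihood (numeric scalar)
#' @export
pruningLogLik <- function(aln, tree, params,
                          rates = branchRates("constrained", 1)) {
  stopifnot(is(aln, "NucAlignment"), is(tree, "ScaledTree"),
            is(params, "HKY85Params"), is(rates, "BranchRates"))
  tr <- tree@phylo
  if (!setequal(taxa(aln), tr$tip.label))
    stop("taxa mismatch: alignment taxa {",
         paste(taxa(aln), collapse = ","), "} != tree tips {",
         paste(tr$tip.label, collapse = ","), "}")
  pat <- sitePatterns(aln)
  pruningCore(pat, tr, params, tr$edge.length * edgeRatios(tr, rates))
}
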