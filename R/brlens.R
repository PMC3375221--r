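#' Maximum-likelihood branch lengths at fourfold-degenerate sites
#'
#' Fits HKY85 branch lengths on a fixed topology to an alignment of silent
#' (fourfold-degenerate third codon position) sites, giving the scaled tree
#' against which noncoding rate ratios are measured.  Base frequencies are
#' empirical; kappa is estimated jointly by ML unless supplied.  Bounded
#' quasi-Newton (L-BFGS-B) optimization on log-transformed parameters.
#'
#' @param ff_sites a [NucAlignment-class] of fourfold-degenerate sites
#' @param topology an \code{ape::phylo} or [ScaledTree-class] giving the
#'   fixed topology (its branch lengths, if any, are ignored)
#' @param kappa optional fixed transition/transversion ratio
#' @return a [ScaledTree-class]; `metadata` carries `logLik`, `kappa` and a
#'   `converged` flag (non-convergence is flagged, never silent)
#' @export
estimateBranchLengths <- function(ff_sites, topology, kappa = NULL) {
  stopifnot(is(ff_sites, "NucAlignment"))
  if (nsites(ff_sites) < 1) stop("need at least one site")
  tr <- if (is(topology, "ScaledTree")) topology@phylo else topology
  if (!inherits(tr, "phylo")) stop("topology must be a phylo or ScaledTree")
  if (!setequal(taxa(ff_sites), tr$tip.label))
    stop("taxa mismatch between alignment and topology")
  pi <- empiricalBaseFreqs(ff_sites)
  pat <- sitePatterns(ff_sites)
  nb <- nrow(tr$edge)
  estK <- is.null(kappa)

  negll <- function(par) {
    k <- if (estK) exp(par[1]) else kappa
    bl <- exp(par[(1 + estK):(nb + estK)])
    -pruningCore(pat, tr, hky85Params(k, pi), bl)
  }
  p0 <- c(if (estK) log(2), rep(log(0.1), nb))
  lo <- c(if (estK) log(0.05), rep(log(1e-8), nb))
  hi <- c(if (estK) log(100), rep(log(10), nb))
  fit <- stats::optim(p0, negll, method = "L-BFGS-B", lower = lo,
                      upper = hi, control = list(factr = 1e7,
                                                 maxit = 500))
  khat <- if (estK) exp(fit$par[1]) else kappa
  tr$edge.length <- exp(fit$par[(1 + estK):(nb + estK)])
  scaledTree(tr, metadata = list(
    logLik = -fit$value, kappa = khat, converged = fit$convergence == 0,
    optim_message = fit$message %||% ""))
}
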