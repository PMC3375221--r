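#' Construct HKY85 model parameters
#'
#' @param kappa transition/transversion rate ratio (> 0)
#' @param pi base frequencies in order A, C, G, T; renormalized to sum to one
#'   exactly.  Zero frequencies are rejected: with a zero stationary
#'   frequency the rate matrix degenerates and the model is not supported.
#' @return an [HKY85Params-class]
#' @examples
#' hky85Params(kappa = 2, pi = c(0.3, 0.2, 0.2, 0.3))
#' @export
hky85Params <- function(kappa, pi = rep(0.25, 4)) {
  if (any(pi <= 0))
    stop("degenerate base frequencies (a zero entry) are not supported")
  pi <- pi / sum(pi)
  new("HKY85Params", kappa = kappa, pi = stats::setNames(pi, NUC))
}

#' @export
setMethod("show", "HKY85Params", function(object) {
  cat(sprintf("HKY85: kappa = %.4g, pi = (%.3f, %.3f, %.3f, %.3f)\n",
              object@kappa, object@pi[1], object@pi[2], object@pi[3],
              object@pi[4]))
})

# HKY85 generator, normalized to one expected substitution per site per unit
# time so that branch lengths are in substitutions/site.  Transitions are
# A<->G and C<->T.
hky85RateMatrix <- function(params) {
  k <- params@kappa
  p <- params@pi
  ts <- matrix(c(0, 1, k, 1,
                 1, 0, 1, k,
                 k, 1, 0, 1,
                 1, k, 1, 0), 4, 4, byrow = TRUE)
  Q <- ts * rep(p, each = 4)   # q_ij = a_ij * pi_j
  diag(Q) <- -rowSums(Q)
  mu <- -sum(p * diag(Q))
  Q <- Q / mu
  dimnames(Q) <- list(NUC, NUC)
  Q
}

# Eigendecomposition of the reversible generator through its symmetrized
# form D^1/2 Q D^-1/2 (numerically stable; real eigensystem guaranteed).
hky85Eigen <- function(params) {
  Q <- hky85RateMatrix(params)
  d <- sqrt(params@pi)
  S <- Q * (d %o% (1 / d))          # d_i q_ij / d_j
  S <- (S + t(S)) / 2               # clean residual asymmetry
  e <- eigen(S, symmetric = TRUE)
  list(values = e$values,
       right = e$vectors / d,       # D^-1/2 V  (columns)
       left = e$vectors * d)        # rows of V^T D^1/2 as columns
}

hky85ProbsFromEigen <- function(eig, t) {
  P <- (eig$right * rep(exp(eig$values * t), each = 4)) %*% t(eig$left)
  P[P < 0] <- 0
  dimnames(P) <- list(NUC, NUC)
  P
}

#' HKY85 transition probability matrix
#'
#' P(t) = exp(Qt) for the HKY85 generator normalized to one expected
#' substitution per site per unit time, computed by eigendecomposition of the
#' symmetrized reversible generator.  Rows are the ancestral base (A, C, G,
#' T), columns the descendant base.
#'
#' @param params an [HKY85Params-class]
#' @param t branch length in expected substitutions/site, >= 0
#' @return 4x4 row-stochastic matrix satisfying detailed balance
#' @examples
#' P <- hky85TransitionProbs(hky85Params(2), t = 0.1)
#' rowSums(P)
#' @export
hky85TransitionProbs <- function(params, t) {
  stopifnot(is(params, "HKY85Params"))
  validObject(params)
  if (!is.numeric(t) || length(t) != 1 || !is.finite(t) || t < 0)
    stop("branch length t must be a single finite value >= 0")
  hky85ProbsFromEigen(hky85Eigen(params), t)
}
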