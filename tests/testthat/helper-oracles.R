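# Independent oracles used by the tests.  These deliberately do not reuse
# any package internals: the rate matrix is rebuilt from its definition, the
# transition probabilities come from a generic matrix exponential, and the
# tree likelihood is brute-force enumeration over internal-node states.

oracleHkyQ <- function(kappa, pi) {
  rate <- matrix(1, 4, 4)
  rate[1, 3] <- rate[3, 1] <- kappa  # A<->G
  rate[2, 4] <- rate[4, 2] <- kappa  # C<->T
  Q <- rate * rep(pi, each = 4)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q / -sum(pi * diag(Q))
}

oracleHkyP <- function(kappa, pi, t) {
  as.matrix(Matrix::expm(oracleHkyQ(kappa, pi) * t))
}

# Brute-force likelihood: sum over every assignment of states to internal
# nodes, multiplying root prior and per-edge transition probabilities.
# Gap/N tip characters contribute a factor summed over tip states (= 1 by
# row-stochasticity, so the edge is simply skipped).
oracleLogLik <- function(seqs, tr, kappa, pi, eff) {
  nuc <- c("A", "C", "G", "T")
  Plist <- lapply(eff, function(t) oracleHkyP(kappa, pi, t))
  ntip <- length(tr$tip.label)
  combos <- as.matrix(expand.grid(rep(list(1:4), tr$Nnode)))
  tipcodes <- matrix(match(seqs[match(tr$tip.label, rownames(seqs)), ,
                                drop = FALSE], nuc),
                     nrow = ntip)
  total <- 0
  for (col in seq_len(ncol(seqs))) {
    Lcol <- 0
    for (k in seq_len(nrow(combos))) {
      st <- combos[k, ]
      stateOf <- function(n) if (n <= ntip) tipcodes[n, col]
                             else st[n - ntip]
      pr <- unname(pi[st[1]])  # node ntip+1 (the root) is internal node 1
      for (e in seq_len(nrow(tr$edge))) {
        ch <- stateOf(tr$edge[e, 2])
        if (is.na(ch)) next
        pr <- pr * Plist[[e]][stateOf(tr$edge[e, 1]), ch]
      }
      Lcol <- Lcol + pr
    }
    total <- total + log(Lcol)
  }
  total
}

# Random model parameters for property-style tests.
randomHkyParams <- function() {
  pi <- stats::runif(4, 0.1, 1)
  hky85Params(kappa = stats::runif(1, 0.5, 8), pi = pi / sum(pi))
}

randomAlignment <- function(taxa, ncols, gap_prob = 0) {
  chars <- sample(c("A", "C", "G", "T"), length(taxa) * ncols, replace = TRUE)
  if (gap_prob > 0) {
    g <- stats::runif(length(chars)) < gap_prob
    chars[g] <- "-"
  }
  m <- matrix(chars, nrow = length(taxa), dimnames = list(taxa, NULL))
  nucAlignment(m)
}
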