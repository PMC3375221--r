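# Synthetic-data generators.  Every generator is a pure function of its
# arguments and seed (bit-for-bit reproducible), and none calls into the
# analysis modules: sequence evolution here is simulated by exact
# continuous-time jump simulation with its own inline rate matrix, so the
# generators stay an independent route from the eigendecomposition-based
# likelihood machinery they are used to test.

# Inline HKY85 generator (duplicated from the analysis side on purpose).
simHkyQ <- function(kappa, pi) {
  ts <- matrix(c(0, 1, kappa, 1,
                 1, 0, 1, kappa,
                 kappa, 1, 0, 1,
                 1, kappa, 1, 0), 4, 4, byrow = TRUE)
  Q <- ts * rep(pi, each = 4)
  diag(Q) <- -rowSums(Q)
  Q / -sum(pi * diag(Q))
}

# Exact CTMC evolution of integer-coded states over time t (Gillespie,
# vectorized over sites).
evolveStates <- function(states, t, Q) {
  if (t <= 0) return(states)
  exit <- -diag(Q)
  jumpP <- Q / exit
  diag(jumpP) <- 0
  rem <- rep(t, length(states))
  active <- seq_along(states)
  while (length(active)) {
    w <- stats::rexp(length(active), exit[states[active]])
    jumped <- w < rem[active]
    idx <- active[jumped]
    if (!length(idx)) break
    rem[idx] <- rem[idx] - w[jumped]
    old <- states[idx]
    for (s in 1:4) {
      ii <- idx[old == s]
      if (length(ii))
        states[ii] <- sample.int(4, length(ii), replace = TRUE,
                                 prob = jumpP[s, ])
    }
    active <- idx
  }
  states
}

#' Simulate a nucleotide alignment on a tree under HKY85
#'
#' Sites evolve independently along the tree by exact stochastic simulation
#' of the HKY85 process, with effective branch lengths equal to the tree's
#' branch lengths times the [BranchRates-class] multipliers; root states are
#' drawn from the stationary frequencies.  Optional insertion/deletion runs
#' (geometric lengths, mean 5 columns) are placed in random taxa until the
#' target gap-column fraction is reached.
#'
#' @param tree a [ScaledTree-class]
#' @param params an [HKY85Params-class]
#' @param rates a [BranchRates-class] (default: shared ratio 1)
#' @param length number of sites, >= 1
#' @param indel_fraction target fraction of columns containing a gap, in
#'   `[0, 1)` (default 0: no gaps)
#' @param seed RNG seed
#' @return a [NucAlignment-class] with the tree's tip labels
#' @export
simulateAlignment <- function(tree, params, rates = branchRates(),
                              length = 1000, indel_fraction = 0, seed = 1) {
  stopifnot(is(tree, "ScaledTree"), is(params, "HKY85Params"))
  if (length < 1) stop("length must be >= 1")
  if (indel_fraction < 0 || indel_fraction >= 1)
    stop("indel_fraction must be in [0, 1)")
  tr <- tree@phylo
  tr$edge.length <- tr$edge.length * edgeRatios(tr, rates)
  tr <- ape::reorder.phylo(tr, "cladewise")  # parents precede children
  eff <- tr$edge.length
  Q <- simHkyQ(params@kappa, params@pi)
  ntip <- length(tr$tip.label)
  withSeed(seed, {
    states <- vector("list", ntip + tr$Nnode)
    root <- ntip + 1L
    states[[root]] <- sample.int(4, length, replace = TRUE,
                                 prob = params@pi)
    # parents always precede children in ape's cladewise edge order
    for (e in seq_len(nrow(tr$edge)))
      states[[tr$edge[e, 2]]] <- evolveStates(states[[tr$edge[e, 1]]],
                                              eff[e], Q)
    m <- do.call(rbind, lapply(seq_len(ntip), function(i)
      NUC[states[[i]]]))
    rownames(m) <- tr$tip.label
    if (indel_fraction > 0) {
      target <- round(indel_fraction * length)
      guard <- 0
      while (sum(apply(m == "-", 2, any)) < target && guard < 10000) {
        run <- stats::rgeom(1, 1 / 5) + 1
        start <- sample.int(length, 1)
        cols <- start:min(length, start + run - 1)
        m[sample.int(ntip, 1), cols] <- "-"
        guard <- guard + 1
      }
    }
    new("NucAlignment", seqs = m)
  })
}

# Local codon bookkeeping for the codon-pair generator (independent of the
# analysis-side NG86 tables).
simCodonInfo <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gc_tab <- Biostrings::GENETIC_CODE
      sense <- names(gc_tab)[gc_tab != "*"]
      syn <- vapply(names(gc_tab), function(cod) {
        if (gc_tab[cod] == "*") return(NA_real_)
        s <- 0
        for (pos in 1:3) {
          for (b in setdiff(c("A", "C", "G", "T"),
                            substr(cod, pos, pos))) {
            alt <- cod
            substr(alt, pos, pos) <- b
            if (gc_tab[alt] == gc_tab[cod]) s <- s + 1 / 3
          }
        }
        s
      }, numeric(1))
      cache <<- list(gc_tab = gc_tab, sense = sense, syn = syn)
    }
    cache
  }
})

#' Simulate a pair of coding sequences with known dS and dN
#'
#' Draws an ancestral sequence of random sense codons, then applies Poisson
#' numbers of synonymous and nonsynonymous single-base substitutions
#' (expected counts dS x synonymous sites and dN x nonsynonymous sites of
#' the ancestor) at uniformly random eligible positions to produce the
#' second sequence.  Multiple hits accumulate naturally, so corrected-rate
#' estimators can be exercised at realistic divergences.
#'
#' @param n_codons codons per sequence
#' @param dS,dN target synonymous / nonsynonymous substitution rates
#' @param seed RNG seed
#' @return list with character strings `a` and `b`
#' @export
simulateCodonPair <- function(n_codons, dS, dN, seed = 1) {
  if (n_codons < 1) stop("n_codons must be >= 1")
  if (dS < 0 || dN < 0) stop("rates must be >= 0")
  info <- simCodonInfo()
  withSeed(seed, {
    anc <- sample(info$sense, n_codons, replace = TRUE)
    S <- sum(info$syn[anc])
    N <- 3 * n_codons - S
    nS <- stats::rpois(1, dS * S)
    nN <- stats::rpois(1, dN * N)
    der <- anc
    applyMut <- function(der, synonymous) {
      for (tries in 1:1000) {
        j <- sample.int(length(der), 1)
        pos <- sample.int(3, 1)
        b <- sample(setdiff(c("A", "C", "G", "T"),
                            substr(der[j], pos, pos)), 1)
        alt <- der[j]
        substr(alt, pos, pos) <- b
        if (info$gc_tab[alt] == "*") next
        same <- info$gc_tab[alt] == info$gc_tab[der[j]]
        if (same == synonymous) {
          der[j] <- alt
          return(der)
        }
      }
      der
    }
    for (i in seq_len(nS)) der <- applyMut(der, TRUE)
    for (i in seq_len(nN)) der <- applyMut(der, FALSE)
    list(a = paste(anc, collapse = ""), b = paste(der, collapse = ""))
  })
}

#' The 22 chimeric-allele designs
#'
#' Two full-length parents, ten reciprocal single-region chimeras, and five
#' of the ten possible region pairs in both orientations: the cycle (1,2),
#' (2,3), (3,4), (4,5), (1,5), under which every region enters exactly two
#' pairwise chimeras and all ten pairwise interaction terms of the epistatic
#' model remain estimable (the design matrix has full rank 16).
#'
#' @return data.frame with `construct` and `region1`..`region5` (0/1)
#' @export
standardChimeraDesigns <- function() {
  rows <- list(rep(0, 5), rep(1, 5))
  for (r in 1:5) {
    x <- rep(0, 5); x[r] <- 1; rows <- c(rows, list(x))
    y <- rep(1, 5); y[r] <- 0; rows <- c(rows, list(y))
  }
  for (pr in list(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(1, 5))) {
    x <- rep(0, 5); x[pr] <- 1; rows <- c(rows, list(x))
    y <- rep(1, 5); y[pr] <- 0; rows <- c(rows, list(y))
  }
  m <- do.call(rbind, rows)
  colnames(m) <- REGIONS
  data.frame(construct = paste0("chim", seq_len(nrow(m))),
             m, stringsAsFactors = FALSE)
}

#' Simulate a chimeric-allele phenotype table
#'
#' delay = intercept + sum(region effects) + sum(pairwise interactions) +
#' batch random intercept + residual noise.  Each replicate of the construct
#' panel is one batch (one 96-well plate carrying every construct), and each
#' batch is one day.
#'
#' @param effects 5 per-region additive effects
#' @param interactions 10 pairwise interaction effects in the order
#'   (1,2),(1,3),(1,4),(1,5),(2,3),(2,4),(2,5),(3,4),(3,5),(4,5); default 0
#' @param batch_sd,residual_sd standard deviations, >= 0
#' @param constructs design data.frame (default [standardChimeraDesigns()])
#' @param reps replicate measurements (= batches) per construct, >= 1
#' @param intercept baseline delay of the all-reference parent
#' @param seed RNG seed
#' @return data.frame: construct, region1..5, day, batch, delay_hours
#' @export
simulateChimeraTable <- function(effects, interactions = rep(0, 10),
                                 batch_sd = 0, residual_sd = 0.5,
                                 constructs = standardChimeraDesigns(),
                                 reps = 3, intercept = 0, seed = 1) {
  if (batch_sd < 0 || residual_sd < 0) stop("sds must be >= 0")
  if (reps < 1) stop("reps must be >= 1")
  stopifnot(length(effects) == 5, length(interactions) == 10)
  X <- as.matrix(constructs[, REGIONS])
  pairs <- utils::combn(5, 2)
  XI <- sapply(seq_len(ncol(pairs)), function(j)
    X[, pairs[1, j]] * X[, pairs[2, j]])
  mu <- intercept + drop(X %*% effects) + drop(XI %*% interactions)
  withSeed(seed, {
    out <- do.call(rbind, lapply(seq_len(reps), function(b) {
      be <- stats::rnorm(1, 0, batch_sd)
      data.frame(construct = constructs$construct,
                 constructs[, REGIONS],
                 day = paste0("day", b), batch = paste0("plate", b),
                 delay_hours = mu + be +
                   stats::rnorm(nrow(constructs), 0, residual_sd),
                 stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
  })
}

#' Simulate a paired control/sulfite growth-curve experiment
#'
#' Shifted-logistic growth on the log(OD) scale: log OD rises as a logistic
#' with inflection at `t_inflection` (so the time of maximum specific growth
#' rate is exactly `t_inflection`), from a baseline OD of `od0` to a
#' carrying capacity `od_max`.  The sulfite curve is the control curve
#' delayed by `shift_hours`; i.i.d. Gaussian noise is added to the OD
#' readings.
#'
#' @param shift_hours sulfite-induced delay (either sign permitted)
#' @param t_inflection control-time of maximum growth rate, hours
#' @param noise_sd OD noise standard deviation
#' @param sampling_min sampling interval in minutes, > 0
#' @param duration_h total run length in hours
#' @param od0,od_max baseline and saturation OD
#' @param steepness logistic steepness (1/hours); the maximum specific
#'   growth rate is `log(od_max/od0) * steepness / 4`
#' @param seed RNG seed
#' @return list of two data.frames (`control`, `sulfite`) with `times`, `od`
#' @export
simulateGrowthPair <- function(shift_hours = 0, t_inflection = 6,
                               noise_sd = 0, sampling_min = 10,
                               duration_h = 20, od0 = 0.05, od_max = 1.5,
                               steepness = 1.2, seed = 1) {
  if (sampling_min <= 0) stop("sampling interval must be > 0")
  times <- seq(0, duration_h, by = sampling_min / 60)
  A <- log(od_max / od0)
  curve <- function(t0) od0 * exp(A / (1 + exp(-steepness * (times - t0))))
  withSeed(seed, {
    ctl <- pmax(curve(t_inflection) +
                  stats::rnorm(length(times), 0, noise_sd), 1e-4)
    sul <- pmax(curve(t_inflection + shift_hours) +
                  stats::rnorm(length(times), 0, noise_sd), 1e-4)
    list(control = data.frame(times = times, od = ctl),
         sulfite = data.frame(times = times, od = sul))
  })
}

#' The standard four-allele expression design
#'
#' Four alleles crossing the 5' noncoding and coding origins (CC, CP, PC,
#' PP: first letter = noncoding origin, second = coding; C = reference
#' species, P = alternate), two time points (0 and 15 minutes after sulfite
#' addition), three biological replicates, two technical (feature)
#' replicates per sample.
#'
#' @param times time points in minutes
#' @param bioreps biological replicates per allele and time
#' @param tech_reps technical replicates per biological sample
#' @return design data.frame, one row per matrix column
#' @export
standardExpressionDesign <- function(times = c(0, 15), bioreps = 3,
                                     tech_reps = 2) {
  alleles <- c("CC", "CP", "PC", "PP")
  d <- expand.grid(tech_rep = seq_len(tech_reps), biorep = seq_len(bioreps),
                   time = times, allele = alleles,
                   stringsAsFactors = FALSE)
  d$noncoding_origin <- as.integer(substr(d$allele, 1, 1) == "P")
  d$coding_origin <- as.integer(substr(d$allele, 2, 2) == "P")
  d$sample <- paste(d$allele, d$time, d$biorep, sep = "_")
  d[, c("sample", "allele", "noncoding_origin", "coding_origin", "time",
        "biorep", "tech_rep")]
}

#' Simulate an expression matrix with known effect spikes
#'
#' Background genes are pure Gaussian noise; spiked genes additionally carry
#' a coding-origin, noncoding-origin, coding-by-noncoding interaction,
#' time (sulfite treatment), or allele-by-time effect of the stated size (in
#' the same units as `noise_sd`).  The identities and classes of spiked
#' genes are returned as ground truth.
#'
#' @param n_genes total genes
#' @param design design data.frame (default [standardExpressionDesign()])
#' @param spikes named list of `c(n, size)` pairs; allowed names: `coding`,
#'   `noncoding`, `cn_interaction`, `time`, `allele_time`
#' @param noise_sd residual standard deviation
#' @param seed RNG seed
#' @return genes x samples matrix with attributes `design` and `truth`
#'   (data.frame gene/class/size)
#' @export
simulateExpressionMatrix <- function(n_genes,
                                     design = standardExpressionDesign(),
                                     spikes = list(), noise_sd = 1,
                                     seed = 1) {
  allowed <- c("coding", "noncoding", "cn_interaction", "time",
               "allele_time")
  if (length(spikes) && !all(names(spikes) %in% allowed))
    stop("spike classes must be among: ", paste(allowed, collapse = ", "))
  n_spiked <- sum(vapply(spikes, function(s) s[1], numeric(1)))
  if (n_spiked > n_genes) stop("more spikes than genes")
  ns <- nrow(design)
  t_hi <- design$time == max(design$time)
  pattern <- list(
    coding = function() design$coding_origin,
    noncoding = function() design$noncoding_origin,
    # pure interaction contrast: chimeric alleles shift relative to both
    # full-length parents, with no coding or noncoding main effect
    cn_interaction = function() as.numeric(xor(design$coding_origin,
                                               design$noncoding_origin)),
    time = function() as.numeric(t_hi),
    allele_time = function() design$coding_origin * as.numeric(t_hi))
  withSeed(seed, {
    m <- matrix(stats::rnorm(n_genes * ns, 0, noise_sd), n_genes, ns)
    rownames(m) <- sprintf("g%04d", seq_len(n_genes))
    colnames(m) <- design$sample
    truth <- data.frame(gene = character(0), class = character(0),
                        size = numeric(0), stringsAsFactors = FALSE)
    at <- 1L
    for (cls in names(spikes)) {
      n <- spikes[[cls]][1]
      size <- spikes[[cls]][2]
      if (n < 1) next
      rows <- at:(at + n - 1)
      m[rows, ] <- m[rows, ] + rep(size * pattern[[cls]](), each = n)
      truth <- rbind(truth, data.frame(gene = rownames(m)[rows],
                                       class = cls, size = size,
                                       stringsAsFactors = FALSE))
      at <- at + n
    }
    attr(m, "design") <- design
    attr(m, "truth") <- truth
    m
  })
}
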