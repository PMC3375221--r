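# NG86 codon bookkeeping, built once per session from the standard genetic
# code: per-codon expected synonymous site counts and pathway-averaged
# synonymous/nonsynonymous difference counts for every codon pair.
codonTables <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    gc_tab <- Biostrings::GENETIC_CODE
    codons <- names(gc_tab)
    aa <- unname(gc_tab)
    n <- length(codons)
    idx <- stats::setNames(seq_len(n), codons)

    # expected synonymous sites per codon: at each position, the fraction of
    # the three single-base changes that preserve the amino acid (changes to
    # a stop codon count as nonsynonymous), so S + N = 3 exactly
    syn_sites <- rep(NA_real_, n)
    mut1 <- function(cod, pos, base) {
      s <- strsplit(cod, "")[[1]]
      s[pos] <- base
      paste(s, collapse = "")
    }
    for (i in seq_len(n)) {
      if (aa[i] == "*") next
      s <- 0
      for (pos in 1:3) for (b in setdiff(NUC, substr(codons[i], pos, pos)))
        s <- s + (gc_tab[mut1(codons[i], pos, b)] == aa[i]) / 3
      syn_sites[i] <- s
    }

    # pathway averaging over orderings of the differing positions; paths
    # through stop codons are excluded (all-blocked pairs fall back to the
    # unrestricted average)
    perms <- list(`1` = matrix(1), `2` = rbind(c(1, 2), c(2, 1)),
                  `3` = rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                              c(2, 3, 1), c(3, 1, 2), c(3, 2, 1)))
    Sd <- Nd <- matrix(0, n, n, dimnames = list(codons, codons))
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i >= j || aa[i] == "*" || aa[j] == "*") next
      ci <- strsplit(codons[i], "")[[1]]
      cj <- strsplit(codons[j], "")[[1]]
      dpos <- which(ci != cj)
      k <- length(dpos)
      if (k == 0) next
      pm <- perms[[as.character(k)]]
      paths <- vector("list", nrow(pm))
      for (p in seq_len(nrow(pm))) {
        cur <- ci
        sy <- ns <- 0
        blocked <- FALSE
        for (step in pm[p, seq_len(k)]) {
          nxt <- cur
          nxt[dpos[step]] <- cj[dpos[step]]
          a1 <- gc_tab[paste(cur, collapse = "")]
          a2 <- gc_tab[paste(nxt, collapse = "")]
          if (a2 == "*" && !identical(nxt, cj)) blocked <- TRUE
          if (a1 == a2) sy <- sy + 1 else ns <- ns + 1
          cur <- nxt
        }
        paths[[p]] <- c(sy = sy, ns = ns, blocked = blocked)
      }
      pm_ok <- Filter(function(z) !z["blocked"], paths)
      if (!length(pm_ok)) pm_ok <- paths
      sy <- mean(vapply(pm_ok, `[`, numeric(1), "sy"))
      ns <- mean(vapply(pm_ok, `[`, numeric(1), "ns"))
      Sd[i, j] <- Sd[j, i] <- sy
      Nd[i, j] <- Nd[j, i] <- ns
    }
    cache <<- list(codons = codons, aa = aa, idx = idx,
                   syn_sites = syn_sites, Sd = Sd, Nd = Nd)
    cache
  }
})

splitCodons <- function(x) {
  x <- toupper(as.character(x))
  if (nchar(x) %% 3 != 0) stop("sequence length must be divisible by 3")
  substring(x, seq(1, nchar(x), 3), seq(3, nchar(x), 3))
}

# Jukes-Cantor multiple-hit correction; p >= 3/4 is saturated (NA).
jcCorrect <- function(p) {
  ifelse(p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

#' Pairwise dN and dS by the Nei-Gojobori (1986) method
#'
#' Counts expected synonymous and nonsynonymous sites (averaged over the two
#' sequences) and observed differences (averaged with equal weight over all
#' orderings of single-base steps for multi-difference codons, excluding
#' paths through stop codons), then applies the Jukes-Cantor correction
#' d = -(3/4) ln(1 - 4p/3).  Codon pairs containing gaps, Ns, or stop codons
#' are skipped; an internal stop raises a warning.
#'
#' @param codon_a,codon_b equal-length in-frame nucleotide sequences
#'   (character strings, `DNAString`s, or anything `as.character` coerces)
#' @return a [PairwiseRates-class]; `dS`/`dN` are `NA` and flagged
#'   `saturated` when the proportion of differences reaches 3/4
#' @examples
#' ng86Pairwise("TTTGCT", "TTCGCA")  # two synonymous differences
#' @export
ng86Pairwise <- function(codon_a, codon_b) {
  tb <- codonTables()
  ca <- splitCodons(codon_a)
  cb <- splitCodons(codon_b)
  if (length(ca) != length(cb)) stop("sequences must have equal length")

  clean <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb)
  ia <- tb$idx[ca[clean]]
  ib <- tb$idx[cb[clean]]
  stopA <- tb$aa[ia] == "*"
  stopB <- tb$aa[ib] == "*"
  if (any((stopA | stopB) & which(clean) < length(ca)))
    warning("internal stop codon(s) skipped")
  use <- !(stopA | stopB)
  ia <- ia[use]
  ib <- ib[use]
  ncod <- length(ia)
  if (ncod == 0)
    return(new("PairwiseRates", codons = 0L, syn_sites = 0, nonsyn_sites = 0,
               syn_diffs = 0, nonsyn_diffs = 0, dS = NA_real_, dN = NA_real_,
               omega = NA_real_, saturated = c(dS = FALSE, dN = FALSE)))

  S <- (sum(tb$syn_sites[ia]) + sum(tb$syn_sites[ib])) / 2
  N <- 3 * ncod - S
  Sd <- sum(tb$Sd[cbind(ia, ib)])
  Nd <- sum(tb$Nd[cbind(ia, ib)])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  dS <- jcCorrect(pS)
  dN <- jcCorrect(pN)
  omega <- if (is.na(dS) || is.na(dN) || dS == 0) NA_real_ else dN / dS
  new("PairwiseRates", codons = as.integer(ncod), syn_sites = S,
      nonsyn_sites = N, syn_diffs = Sd, nonsyn_diffs = Nd, dS = dS, dN = dN,
      omega = omega,
      saturated = c(dS = is.na(dS) && pS >= 0.75,
                    dN = is.na(dN) && pN >= 0.75))
}

#' @export
setMethod("show", "PairwiseRates", function(object) {
  cat(sprintf("PairwiseRates: %d codons, S=%.2f N=%.2f Sd=%.2f Nd=%.2f\n",
              object@codons, object@syn_sites, object@nonsyn_sites,
              object@syn_diffs, object@nonsyn_diffs))
  cat(sprintf("  dS=%.4g dN=%.4g dN/dS=%s%s\n", object@dS, object@dN,
              ifelse(is.na(object@omega), "undefined",
                     sprintf("%.4g", object@omega)),
              if (any(object@saturated)) " [saturated]" else ""))
})

#' Sliding-window scan result
#'
#' @slot window_size,step window geometry in codons.
#' @slot per_window data.frame of per-window NG86 estimates (and Monte-Carlo
#'   CI bounds when requested).
#' @slot gene whole-gene [PairwiseRates-class].
#' @export
setClass("WindowScan", representation(
  window_size = "integer", step = "integer", per_window = "data.frame",
  gene = "PairwiseRates"))

#' Sliding-window dN/dS scan of a pairwise codon alignment
#'
#' NG86 estimates in overlapping windows plus the whole-gene estimate.
#' Windows where dS is zero or saturated carry an undefined (NA) dN/dS,
#' never an infinity.  With `nsim > 0` a parametric Monte-Carlo confidence
#' interval is attached to each window (see [mcConfidenceInterval()]).
#'
#' @param codon_a,codon_b equal-length in-frame sequences
#' @param window_size window width in codons (default 150)
#' @param step offset between window starts in codons (default 25)
#' @param nsim Monte-Carlo replicates per window (0 = no CIs)
#' @param seed RNG seed for the Monte-Carlo CIs
#' @return a [WindowScan-class]
#' @export
slidingWindowDnds <- function(codon_a, codon_b, window_size = 150,
                              step = 25, nsim = 0, seed = 1) {
  if (step <= 0) stop("step must be a positive number of codons")
  ca <- splitCodons(codon_a)
  cb <- splitCodons(codon_b)
  ncod <- length(ca)
  if (window_size > ncod)
    stop("window_size (", window_size, ") exceeds gene length in codons (",
         ncod, ")")
  starts <- seq(1, ncod - window_size + 1, by = step)
  rows <- lapply(seq_along(starts), function(i) {
    s <- starts[i]
    idx <- s:(s + window_size - 1)
    r <- ng86Pairwise(paste(ca[idx], collapse = ""),
                      paste(cb[idx], collapse = ""))
    out <- data.frame(start_codon = s, end_codon = s + window_size - 1,
                      syn_sites = r@syn_sites, nonsyn_sites = r@nonsyn_sites,
                      syn_diffs = r@syn_diffs, nonsyn_diffs = r@nonsyn_diffs,
                      dS = r@dS, dN = r@dN, omega = r@omega)
    if (nsim > 0) {
      ci <- mcConfidenceInterval(r, codons = r@codons, nsim = nsim,
                                 seed = deriveSeed(seed, i))
      out$dS_lo <- ci$dS[1]; out$dS_hi <- ci$dS[2]
      out$dN_lo <- ci$dN[1]; out$dN_hi <- ci$dN[2]
      out$omega_lo <- ci$omega[1]; out$omega_hi <- ci$omega[2]
    }
    out
  })
  new("WindowScan", window_size = as.integer(window_size),
      step = as.integer(step), per_window = do.call(rbind, rows),
      gene = ng86Pairwise(codon_a, codon_b))
}

#' @export
setMethod("show", "WindowScan", function(object) {
  cat(sprintf("WindowScan: %d windows of %d codons (step %d)\n",
              nrow(object@per_window), object@window_size, object@step))
  cat("whole gene: ")
  show(object@gene)
})

#' Parametric Monte-Carlo confidence interval for pairwise rates
#'
#' Simulates `nsim` codon-sequence pairs at the estimated dS and dN (the
#' parametric bootstrap behind K-estimator-style intervals), re-estimates
#' each with [ng86Pairwise()], and returns empirical 2.5/97.5 percentiles
#' for dS, dN and dN/dS.  Deterministic given `seed`.
#'
#' @param rates a [PairwiseRates-class] point estimate
#' @param codons number of codons to simulate (usually `rates@codons`)
#' @param nsim number of replicates, >= 100
#' @param seed RNG seed
#' @return list with `dS`, `dN`, `omega` (each `c(lower, upper)`),
#'   `n_omega_defined`, and a `saturated` flag
#' @export
mcConfidenceInterval <- function(rates, codons = rates@codons, nsim = 1000,
                                 seed = 1) {
  stopifnot(is(rates, "PairwiseRates"))
  if (nsim < 100) stop("nsim must be >= 100")
  if (any(rates@saturated) || is.na(rates@dS) || is.na(rates@dN))
    return(list(dS = c(NA_real_, NA_real_), dN = c(NA_real_, NA_real_),
                omega = c(NA_real_, NA_real_), n_omega_defined = 0L,
                saturated = TRUE))
  sims <- lapply(seq_len(nsim), function(i) {
    pair <- simulateCodonPair(codons, dS = rates@dS, dN = rates@dN,
                              seed = deriveSeed(seed, i))
    r <- ng86Pairwise(pair$a, pair$b)
    c(dS = r@dS, dN = r@dN, omega = r@omega)
  })
  m <- do.call(rbind, sims)
  qs <- function(v) {
    if (all(is.na(v))) return(c(NA_real_, NA_real_))
    unname(stats::quantile(v, c(0.025, 0.975), na.rm = TRUE))
  }
  list(dS = qs(m[, "dS"]), dN = qs(m[, "dN"]), omega = qs(m[, "omega"]),
       n_omega_defined = sum(!is.na(m[, "omega"])), saturated = FALSE)
}
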