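# Codon-degeneracy bookkeeping derived once from the standard genetic code.
fourfoldPrefixes <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gc_tab <- Biostrings::GENETIC_CODE
      pre <- as.vector(outer(NUC, NUC, paste0))
      ff <- vapply(pre, function(d) {
        aa <- gc_tab[paste0(d, NUC)]
        length(unique(aa)) == 1 && !any(aa == "*")
      }, logical(1))
      cache <<- pre[ff]
    }
    cache
  }
})

#' Extract fourfold-degenerate third codon positions
#'
#' Keeps the third position of a codon column only when, in every taxon, the
#' codon is gap- and N-free and its first two bases define a fourfold
#' degenerate family (all four third-position bases encode the same amino
#' acid under the standard genetic code).  These sites are the conventional
#' proxy for neutral divergence and are what the [ScaledTree-class] branch
#' lengths are estimated from.
#'
#' @param codon_aln a [NucAlignment-class] of in-frame coding sequence
#' @param frame 1-based frame offset (1 = alignment starts on codon position
#'   1); positions before the frame start are ignored
#' @return a [NucAlignment-class] of the retained third positions (possibly
#'   zero columns)
#' @examples
#' aln <- nucAlignment(c(a = "GCTGCA", b = "GCCGCA"))
#' nsites(extractFourfoldSites(aln))  # both codons are Ala (GCN): 2 sites
#' @export
extractFourfoldSites <- function(codon_aln, frame = 1L) {
  stopifnot(is(codon_aln, "NucAlignment"))
  m <- codon_aln@seqs
  if (frame < 1 || frame > 3) stop("frame must be 1, 2 or 3")
  m <- m[, frame:ncol(m), drop = FALSE]
  if (ncol(m) %% 3 != 0)
    stop("frame error: alignment length (", ncol(m),
         ") is not divisible by 3")
  ncod <- ncol(m) %/% 3
  ff <- fourfoldPrefixes()
  keep <- logical(ncod)
  for (j in seq_len(ncod)) {
    cod <- m[, (3 * j - 2):(3 * j), drop = FALSE]
    ok <- !any(!(cod %in% NUC)) &&
      all(paste0(cod[, 1], cod[, 2]) %in% ff)
    keep[j] <- ok
  }
  sel <- 3 * which(keep)
  out <- m[, sel, drop = FALSE]
  rownames(out) <- rownames(codon_aln@seqs)
  new("NucAlignment", seqs = out)
}
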