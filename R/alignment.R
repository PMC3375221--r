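#' Construct a nucleotide alignment
#'
#' @param x either a character matrix (rows = taxa, columns = sites) or a
#'   named character vector of equal-length aligned sequences.  Lower case is
#'   accepted and folded to upper case; \code{U} is mapped to \code{T} and any
#'   IUPAC ambiguity code other than \code{N} is mapped to \code{N}.
#' @return a [NucAlignment-class]
#' @examples
#' aln <- nucAlignment(c(cer = "ACGT", par = "ACGA"))
#' nsites(aln)
#' @export
nucAlignment <- function(x) {
  if (is.character(x) && !is.matrix(x)) {
    if (is.null(names(x))) stop("sequences must be named by taxon")
    w <- unique(nchar(x))
    if (length(w) != 1) stop("aligned sequences must have equal length")
    m <- matrix(unlist(strsplit(x, "")), nrow = length(x), byrow = TRUE,
                dimnames = list(names(x), NULL))
  } else if (is.matrix(x)) {
    m <- x
  } else stop("x must be a character matrix or named character vector")
  if (ncol(m) < 1) stop("alignment must contain at least one column")
  m[] <- toupper(m)
  m[m == "U"] <- "T"
  m[!(m %in% ALN_ALPHABET)] <- "N"
  new("NucAlignment", seqs = m)
}

#' Read a FASTA alignment
#'
#' Thin wrapper over \code{Biostrings::readDNAStringSet}; all sequences must
#' have equal (aligned) width.
#'
#' @param path FASTA file
#' @return a [NucAlignment-class]
#' @export
readAlignment <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  nucAlignment(stats::setNames(as.character(ss),
                               sub("\\s.*$", "", names(ss))))
}

#' Write an alignment to FASTA
#' @param aln a [NucAlignment-class]
#' @param path output file
#' @return invisibly, `path`
#' @export
writeAlignment <- function(aln, path) {
  ss <- Biostrings::DNAStringSet(apply(aln@seqs, 1, paste, collapse = ""))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' @rdname taxa
#' @export
setMethod("taxa", "NucAlignment", function(x) rownames(x@seqs))

#' @rdname nsites
#' @export
setMethod("nsites", "NucAlignment", function(x) ncol(x@seqs))

#' @export
setMethod("show", "NucAlignment", function(object) {
  cat("NucAlignment:", nrow(object@seqs), "taxa x", ncol(object@seqs),
      "sites\n")
  for (i in seq_len(min(4, nrow(object@seqs)))) {
    s <- paste(object@seqs[i, seq_len(min(50, ncol(object@seqs)))],
               collapse = "")
    cat(sprintf("  %-12s %s%s\n", rownames(object@seqs)[i], s,
                if (ncol(object@seqs) > 50) "..." else ""))
  }
})

#' Character-matrix view of an alignment
#' @param x a [NucAlignment-class]
#' @param ... ignored
#' @return character matrix, rows named by taxon
#' @export
setMethod("as.matrix", "NucAlignment", function(x, ...) x@seqs)

# Integer-coded site patterns: A,C,G,T -> 1..4; gap/N -> 0 (missing).
# Collapsing identical columns makes likelihood evaluation cost independent
# of locus length for 4-taxon data (<= 5^4 distinct patterns).
sitePatterns <- function(aln) {
  code <- match(aln@seqs, NUC, nomatch = 0L)
  dim(code) <- dim(aln@seqs)
  key <- apply(code, 2, paste, collapse = ".")
  tab <- table(key)
  first <- match(names(tab), key)
  list(patterns = code[, first, drop = FALSE],
       weights = as.numeric(tab),
       taxa = rownames(aln@seqs))
}

#' Empirical base frequencies of an alignment
#'
#' Counts of A, C, G, T across the whole alignment, gaps and Ns excluded.
#' Used as the HKY85 stationary frequencies for per-locus fits (the common
#' default of likelihood engines; removes three free parameters per locus).
#'
#' @param aln a [NucAlignment-class]
#' @return frequency vector (A, C, G, T) summing to one
#' @export
empiricalBaseFreqs <- function(aln) {
  counts <- vapply(NUC, function(b) sum(aln@seqs == b), numeric(1))
  if (sum(counts) == 0) stop("alignment contains no unambiguous bases")
  p <- counts / sum(counts)
  # exact renormalization so downstream validity checks at 1e-12 hold
  p / sum(p)
}
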