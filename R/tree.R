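#' Construct a ScaledTree
#'
#' @param phylo an \code{ape::phylo} tree with branch lengths in
#'   fourfold-degenerate substitutions/site
#' @param metadata optional list of diagnostics
#' @return a [ScaledTree-class]
#' @export
scaledTree <- function(phylo, metadata = list()) {
  new("ScaledTree", phylo = phylo, metadata = metadata)
}

#' Read a ScaledTree from a Newick file or string
#'
#' Branch lengths are required: they are the genome-wide silent-site rates
#' that the rate-ratio screen measures against.
#'
#' @param x path to a Newick file, or a Newick string (contains ";")
#' @return a [ScaledTree-class]
#' @export
readScaledTree <- function(x) {
  tr <- if (grepl(";", x)) ape::read.tree(text = x) else ape::read.tree(x)
  if (is.null(tr$edge.length))
    stop("input tree must carry branch lengths")
  scaledTree(tr)
}

#' Write a ScaledTree to Newick
#' @param tree a [ScaledTree-class]
#' @param path output file
#' @return invisibly, `path`
#' @export
writeScaledTree <- function(tree, path) {
  ape::write.tree(tree@phylo, file = path)
  invisible(path)
}

#' The fixed four-species yeast topology
#'
#' Unrooted ((cerevisiae,paradoxus),mikatae,bayanus) topology used throughout;
#' default branch lengths are plausible genome-wide fourfold-degenerate rates
#' for these species and are replaceable via `lengths`.
#'
#' @param lengths branch lengths, either named by branch label
#'   (cer, par, mik, bay, internal2) or unnamed in [edgeLabels()] order
#' @return a [ScaledTree-class]
#' @export
yeastTree <- function(lengths = c(cer = 0.25, par = 0.25, mik = 0.45,
                                  bay = 0.60, internal2 = 0.15)) {
  tr <- ape::read.tree(text = "((cer:1,par:1):1,mik:1,bay:1);")
  st <- scaledTree(tr)
  labs <- edgeLabels(st)
  if (!is.null(names(lengths))) {
    if (!setequal(names(lengths), labs))
      stop("named lengths must cover: ", paste(labs, collapse = ", "))
    lengths <- lengths[labs]
  }
  branchLengths(st) <- unname(lengths)
  st
}

#' @rdname treePhylo
#' @export
setMethod("treePhylo", "ScaledTree", function(x) x@phylo)

#' @rdname edgeLabels
#' @export
setMethod("edgeLabels", "ScaledTree", function(x) edgeLabelsPhylo(x@phylo))

edgeLabelsPhylo <- function(tr) {
  child <- tr$edge[, 2]
  ntip <- length(tr$tip.label)
  ifelse(child <= ntip, tr$tip.label[child],
         paste0("internal", child - ntip))
}

#' @rdname branchLengths
#' @export
setMethod("branchLengths", "ScaledTree", function(x)
  stats::setNames(x@phylo$edge.length, edgeLabels(x)))

#' Replace branch lengths (in edge order)
#' @param x a [ScaledTree-class]
#' @param value numeric vector, one length per branch
#' @export
setGeneric("branchLengths<-", function(x, value)
  standardGeneric("branchLengths<-"))

#' @rdname branchLengths-set
#' @export
setMethod("branchLengths<-", "ScaledTree", function(x, value) {
  if (length(value) != nrow(x@phylo$edge))
    stop("need one branch length per edge")
  x@phylo$edge.length <- as.numeric(value)
  validObject(x)
  x
})

#' @export
setMethod("show", "ScaledTree", function(object) {
  bl <- branchLengths(object)
  cat("ScaledTree (fourfold-degenerate substitutions/site):\n")
  cat(" ", ape::write.tree(object@phylo), "\n")
  cat("  branches:", paste(sprintf("%s=%.4g", names(bl), bl),
                           collapse = ", "), "\n")
  if (length(object@metadata))
    cat("  metadata:", paste(names(object@metadata), collapse = ", "), "\n")
})
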