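#' Taxon labels of an alignment
#' @param x a [NucAlignment-class]
#' @return character vector of taxon labels
#' @export
setGeneric("taxa", function(x) standardGeneric("taxa"))

#' Number of aligned sites
#' @param x a [NucAlignment-class]
#' @return integer alignment length (columns)
#' @export
setGeneric("nsites", function(x) standardGeneric("nsites"))

#' Underlying ape tree of a ScaledTree
#' @param x a [ScaledTree-class]
#' @return the \code{ape::phylo} object
#' @export
setGeneric("treePhylo", function(x) standardGeneric("treePhylo"))

#' Branch lengths in canonical branch order
#' @param x a [ScaledTree-class]
#' @return named numeric vector, ordered as [edgeLabels()]
#' @export
setGeneric("branchLengths", function(x) standardGeneric("branchLengths"))

#' Canonical branch labels of a tree
#'
#' Branches are labelled by their child node: the tip name for terminal
#' branches and \code{internal<k>} for internal ones, in the order of the
#' tree's edge matrix.  Per-branch rate multipliers everywhere in the package
#' follow this order.
#'
#' @param x a [ScaledTree-class] or \code{phylo}
#' @return character vector, one label per branch
#' @export
setGeneric("edgeLabels", function(x) standardGeneric("edgeLabels"))

#' Effect-size table of a chimeric-allele model fit
#' @param x an [LMMFit-class]
#' @return data.frame with term, effect size, standard error and p-value,
#'   shaped like a per-region effect table
#' @export
setGeneric("effectTable", function(x) standardGeneric("effectTable"))
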