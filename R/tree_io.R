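#' @importFrom ape read.tree read.nexus write.tree keep.tip reorder.phylo
#'   is.rooted Ntip Nnode
#' @importFrom stats optimize runif rexp qpois dpois setNames pt lm cor
#'   cor.test t.test rbinom
#' @importFrom utils read.csv write.csv
NULL

#' Posterior tree samples
#'
#' A `tree_sample` bundles an ordered set of phylogenies over a shared taxon
#' namespace — typically a Bayesian posterior sample of language trees — with
#' the label of the language family it belongs to. All downstream change
#' counting averages over the sample rather than committing to a single tree,
#' which propagates topological and branch-length uncertainty into the trait
#' summaries. Branch lengths are in units of expected character change (for
#' lexically inferred language trees, units of linguistic change), not time.
#'
#' @param trees a `multiPhylo` (or list of `phylo`) with identical tip sets.
#' @param family character label for the family ("A", "Bantu", ...).
#' @return an object of class `tree_sample`: a list with elements `trees`
#'   (a `multiPhylo`), `family` and `taxa` (sorted tip namespace).
#' @seealso [read_tree_sample()], [prune_to_taxa()]
#' @examples
#' trs <- ape::read.tree(text = c("((A:1,B:1):1,C:2);", "((A:2,C:1):1,B:2);"))
#' tree_sample(trs, family = "demo")
#' @export
tree_sample <- function(trees, family = "unnamed") {
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- lapply(trees, validate_tree)
  if (length(trees) < 1L) stop("a tree sample needs at least one tree")
  taxa <- sort(trees[[1L]]$tip.label)
  for (i in seq_along(trees)) {
    if (!identical(sort(trees[[i]]$tip.label), taxa)) {
      stop("tree ", i, " has a different tip-label set from tree 1")
    }
  }
  class(trees) <- "multiPhylo"
  structure(list(trees = trees, family = as.character(family), taxa = taxa),
            class = "tree_sample")
}

validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  }
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    stop("tree has missing branch lengths; all non-root edges need one")
  }
  if (length(tree$edge.length) != nrow(tree$edge)) {
    stop("tree has ", nrow(tree$edge), " edges but ",
         length(tree$edge.length), " branch lengths")
  }
  if (any(tree$edge.length < 0)) stop("negative branch length")
  tree
}

#' Read a posterior tree sample from newick or NEXUS
#'
#' A sample file is either a multi-tree newick file (one tree per line) or a
#' NEXUS file with multiple TREE statements; NEXUS TRANSLATE tables are
#' resolved to full labels and square-bracket comments ignored (both handled
#' by \pkg{ape}'s readers). Every tree must carry branch lengths on all
#' non-root edges and all trees must share one tip-label set.
#'
#' @param file path to the tree file.
#' @param format `"auto"` (sniff for `#NEXUS`), `"newick"` or `"nexus"`.
#' @param family family label attached to the sample.
#' @return a [tree_sample()].
#' @export
read_tree_sample <- function(file, format = c("auto", "newick", "nexus"),
                             family = "unnamed") {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(file, n = 1L, warn = FALSE)
    format <- if (grepl("^\\s*#nexus", first, ignore.case = TRUE)) "nexus"
              else "newick"
  }
  trees <- switch(format,
    newick = ape::read.tree(file),
    nexus  = ape::read.nexus(file))
  if (is.null(trees)) stop("no trees could be parsed from ", file)
  if (inherits(trees, "phylo")) trees <- list(trees)
  tree_sample(trees, family = family)
}

#' Write a tree sample as multi-line newick
#'
#' @param sample a [tree_sample()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_tree_sample <- function(sample, file) {
  stopifnot(inherits(sample, "tree_sample"))
  ape::write.tree(sample$trees, file = file, digits = 15)
  invisible(file)
}

#' @export
print.tree_sample <- function(x, ...) {
  cat("Tree sample '", x$family, "': ", length(x$trees), " tree(s), ",
      length(x$taxa), " shared taxa\n", sep = "")
  invisible(x)
}

#' @export
length.tree_sample <- function(x) length(x$trees)

#' Prune a tree to a subset of taxa
#'
#' Drops all tips outside `keep`, suppressing the unifurcations this creates
#' by summing branch lengths, so that path lengths between every pair of
#' retained tips are unchanged. This is how missing trait data are handled
#' throughout: societies without a code for a trait are removed from the
#' phylogeny trait-by-trait before any change counting.
#'
#' @param tree a `phylo`.
#' @param keep character vector of tip labels to retain (at least 2).
#' @return the pruned `phylo`.
#' @export
prune_to_taxa <- function(tree, keep) {
  keep <- unique(as.character(keep))
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown)) {
    stop("unknown tip label(s): ", paste(unknown, collapse = ", "))
  }
  if (length(keep) < 2L) {
    stop_cultrates("fewer than 2 taxa to keep; trait is un-analysable",
                   "cultrates_unanalysable")
  }
  if (length(keep) == length(tree$tip.label)) return(tree)
  validate_tree(ape::keep.tip(tree, keep))
}

#' Total branch length of a tree
#'
#' @param tree a `phylo`.
#' @return the sum of all branch lengths.
#' @export
total_branch_length <- function(tree) {
  validate_tree(tree)
  sum(tree$edge.length)
}
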