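#' Maximum-parsimony change count for a discrete character
#'
#' Computes the minimum number of state changes needed on `tree` to explain
#' the observed tip states, under unit (unordered/Fitch) costs: the minimum,
#' over all assignments of states to internal nodes, of the number of edges
#' whose endpoints differ. Implemented as a Sankoff-style post-order dynamic
#' programme with 0/1 costs, which handles polytomies natively (the per-state
#' cost of a node is the sum over its children of the cheapest child option).
#' The score does not depend on the position of the root.
#'
#' @param tree a `phylo` (>= 2 tips); every tip must have a state.
#' @param states vector of tip states named by tip label (any atomic codes;
#'   `NA` is an error — prune uncoded tips first with [prune_to_taxa()]).
#' @return integer minimum change count.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
#' fitch_score(tr, c(A = 0, B = 0, C = 1, D = 1))  # 1
#' @export
fitch_score <- function(tree, states) {
  ntip <- length(tree$tip.label)
  if (ntip < 2L) stop("fitch_score needs at least 2 tips")
  s <- states[tree$tip.label]
  if (anyNA(s)) {
    stop("missing state for tip(s): ",
         paste(tree$tip.label[is.na(s)], collapse = ", "))
  }
  codes <- match(s, unique(s))
  k <- max(codes)
  if (k == 1L) return(0L)
  tree <- ape::reorder.phylo(tree, "postorder")
  nnode <- ntip + tree$Nnode
  cost <- matrix(0, nnode, k)
  cost[seq_len(ntip), ] <- Inf
  cost[cbind(seq_len(ntip), codes)] <- 0
  edge <- tree$edge
  for (i in seq_len(nrow(edge))) {
    cc <- cost[edge[i, 2L], ]
    cost[edge[i, 1L], ] <- cost[edge[i, 1L], ] + pmin(cc, min(cc) + 1)
  }
  as.integer(min(cost[edge[nrow(edge), 1L], ]))
}

#' Exhaustive parsimony oracle
#'
#' Enumerates every assignment of observed states to the internal nodes and
#' returns the minimum number of edges with differing endpoint states.
#' Exponential in the number of internal nodes — a brute-force reference for
#' [fitch_score()] on tiny instances, not a working implementation.
#'
#' @inheritParams fitch_score
#' @param max_internal,max_states instance-size guards (defaults 8 and 5).
#' @return integer minimum change count.
#' @export
brute_force_parsimony <- function(tree, states, max_internal = 8L,
                                  max_states = 5L) {
  ntip <- length(tree$tip.label)
  if (ntip < 2L) stop("need at least 2 tips")
  s <- states[tree$tip.label]
  if (anyNA(s)) stop("missing tip state")
  codes <- match(s, unique(s))
  k <- max(codes)
  nint <- tree$Nnode
  if (nint > max_internal || k > max_states) {
    stop("instance too large for exhaustive enumeration (",
         nint, " internal nodes, ", k, " states)")
  }
  if (k == 1L) return(0L)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), nint)))
  assign_all <- cbind(matrix(codes, nrow(grid), ntip, byrow = TRUE), grid)
  edge <- tree$edge
  changes <- rep(0L, nrow(grid))
  for (i in seq_len(nrow(edge))) {
    changes <- changes + (assign_all[, edge[i, 1L]] != assign_all[, edge[i, 2L]])
  }
  as.integer(min(changes))
}

#' Mean parsimony change count over a posterior tree sample
#'
#' For each tree in the sample, prunes to the societies coded for the trait,
#' computes the Fitch score, and returns the arithmetic mean over trees —
#' the "Pars" statistic of the comparative analysis. Deterministic: consumes
#' no randomness.
#'
#' @param sample a [tree_sample()].
#' @param v a [trait_variable()] over the sample's taxon namespace.
#' @return mean score (length-1 numeric) with attribute `per_tree`; `NA` with
#'   a warning if fewer than 2 societies are coded. A constant trait scores 0.
#' @export
mean_parsimony_changes <- function(sample, v) {
  stopifnot(inherits(sample, "tree_sample"), inherits(v, "trait_variable"))
  cov <- trait_coverage(v)
  if (!cov$analysable) {
    warning("trait ", v$id, ": fewer than 2 coded societies; un-analysable")
    return(NA_real_)
  }
  st <- v$states[cov$coded]
  per_tree <- vapply(sample$trees, function(tr) {
    as.double(fitch_score(prune_to_taxa(tr, cov$coded), st))
  }, 0)
  structure(mean(per_tree), per_tree = per_tree)
}
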