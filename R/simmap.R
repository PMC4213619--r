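# Endpoint-conditioned CTMC path sampling on a single branch, symmetric Mk.
#
# Primary sampler: forward-simulation rejection (with the first jump drawn
# from a truncated exponential when the endpoints differ, after Nielsen 2002),
# capped at `max_attempts`. Fallback: uniformization. With uniformization
# rate mu = k*r the jump chain of the symmetric Mk model is uniform over all
# k states (self-transitions included), so conditional on n virtual jumps the
# intermediate states are i.i.d. uniform and the jump times are uniform order
# statistics on (0, t); self-transitions are then discarded. Both samplers
# draw from the exact conditional path distribution.

sample_other <- function(from, k) {
  j <- sample.int(k - 1L, 1L)
  if (j >= from) j + 1L else j
}

sample_branch_path <- function(a, b, t, r, k, max_attempts = 1000L) {
  lam <- (k - 1) * r                     # total leaving rate
  if (lam * t < 1e-14) {
    if (a == b) return(list(times = numeric(0), states = integer(0)))
    if (lam == 0) stop("zero rate but differing branch endpoints")
    # fall through to uniformization for a near-degenerate branch
    return(uniformization_path(a, b, t, r, k))
  }
  pstay <- exp(-lam * t)
  for (att in seq_len(max_attempts)) {
    times <- numeric(0)
    sts <- integer(0)
    cur <- a
    tcur <- 0
    if (a != b) {                        # first jump truncated to (0, t)
      tcur <- -log(1 - stats::runif(1) * (1 - pstay)) / lam
      cur <- sample_other(a, k)
      times <- tcur
      sts <- cur
    }
    repeat {
      tcur <- tcur + stats::rexp(1, lam)
      if (tcur > t) break
      cur <- sample_other(cur, k)
      times <- c(times, tcur)
      sts <- c(sts, cur)
    }
    if (cur == b) return(list(times = times, states = sts))
  }
  uniformization_path(a, b, t, r, k)
}

uniformization_path <- function(a, b, t, r, k) {
  mu <- k * r
  if (mu * t < 1e-300) {
    if (a == b) return(list(times = numeric(0), states = integer(0)))
    stop("endpoint-conditioned path impossible at rate ~0 with a != b")
  }
  # P(N = n | a, b) propto dpois(n, mu t) * w_n, w_0 = [a == b], w_n = 1/k
  pab <- if (a == b) 1 / k + (k - 1) / k * exp(-mu * t) else
         (1 - exp(-mu * t)) / k
  u <- stats::runif(1) * pab
  n <- 0L
  cum <- if (a == b) stats::dpois(0, mu * t) else 0
  nmax <- stats::qpois(1 - 1e-14, mu * t) + 10L
  while (cum < u && n < nmax) {
    n <- n + 1L
    cum <- cum + stats::dpois(n, mu * t) / k
  }
  if (n == 0L) return(list(times = numeric(0), states = integer(0)))
  times <- sort(stats::runif(n, 0, t))
  sts <- c(if (n > 1L) sample.int(k, n - 1L, replace = TRUE), b)
  keep <- logical(n)
  cur <- a
  for (m in seq_len(n)) {
    if (sts[m] != cur) {
      keep[m] <- TRUE
      cur <- sts[m]
    }
  }
  list(times = times[keep], states = sts[keep])
}

# forward (unconditioned) simulation helper used by tests and the trait
# simulator: evolve a state along a branch, returning the full jump list
simulate_branch_forward <- function(a, t, r, k) {
  lam <- (k - 1) * r
  times <- numeric(0)
  sts <- integer(0)
  cur <- a
  tcur <- 0
  if (lam > 0) repeat {
    tcur <- tcur + stats::rexp(1, lam)
    if (tcur > t) break
    cur <- sample_other(cur, k)
    times <- c(times, tcur)
    sts <- c(sts, cur)
  }
  list(times = times, states = sts, end = cur)
}

#' Draw one stochastic character map
#'
#' Samples a complete history of a discrete character over the tree,
#' conditional on the observed tip states, under the symmetric Mk model at
#' rate `r`: internal-node states are drawn from their joint conditional
#' distribution (root from prior times root partials, then pre-order
#' conditional sampling using the stored pruning partials), and each branch
#' path is drawn conditional on its endpoint pair by rejection sampling with
#' a uniformization fallback. Self-transitions are never recorded, so the
#' number of events in the history is the number of real state changes.
#'
#' @inheritParams mk_log_likelihood
#' @param pruning optional precomputed result of the internal pruning pass
#'   (reused across repeated maps of the same trait/tree/rate).
#' @return an object of class `character_history`: list with `node_states`
#'   (sampled state per node, tips first in the order of the postorder tree's
#'   `tip.label`), `events` (data.frame `node` = child node of the branch,
#'   `time` = position along the branch from its parent end, `from`, `to`),
#'   `n_changes`, and the postorder `tree`.
#' @export
sample_stochastic_map <- function(tree, states, r, k = NULL, pruning = NULL) {
  levels <- NULL
  obs <- sort(unique(states[!is.na(states)]))
  if (is.null(k)) k <- length(obs)
  k <- as.integer(k)
  if (length(obs) > k) stop("k smaller than the number of observed states")
  if (max(obs) > k) {
    # compact arbitrary codes to 1..k, mapping sampled states back afterwards
    if (length(obs) < k) {
      stop("cannot compact state codes: k exceeds the observed state count ",
           "but codes exceed k; recode the states to 1..k first")
    }
    levels <- as.integer(obs)
    states <- stats::setNames(match(states, obs), names(states))
  }
  if (is.null(pruning)) pruning <- mk_pruning(tree, states, r, k)
  if (!is.finite(pruning$loglik)) {
    stop("tip data have zero probability at this rate; cannot sample a map")
  }
  tree <- pruning$tree
  partial <- pruning$partial
  edge <- tree$edge
  el <- tree$edge.length
  nE <- nrow(edge)
  ntip <- length(tree$tip.label)
  node_states <- integer(ntip + tree$Nnode)
  root <- edge[nE, 1L]
  w <- partial[root, ]
  node_states[root] <- sample.int(k, 1L, prob = w)
  for (i in rev(seq_len(nE))) {          # pre-order
    p <- edge[i, 1L]
    ch <- edge[i, 2L]
    e <- exp(-k * r * el[i])
    p_diff <- (1 - e) / k
    w <- p_diff * partial[ch, ]
    ps <- node_states[p]
    w[ps] <- w[ps] + e * partial[ch, ps]  # p_same = p_diff + e
    node_states[ch] <- sample.int(k, 1L, prob = w)
  }
  ev_node <- integer(0)
  ev_time <- numeric(0)
  ev_from <- integer(0)
  ev_to <- integer(0)
  for (i in seq_len(nE)) {
    a <- node_states[edge[i, 1L]]
    b <- node_states[edge[i, 2L]]
    path <- sample_branch_path(a, b, el[i], r, k)
    nev <- length(path$times)
    if (nev) {
      ev_node <- c(ev_node, rep.int(edge[i, 2L], nev))
      ev_time <- c(ev_time, path$times)
      ev_from <- c(ev_from, c(a, path$states[-nev]))
      ev_to <- c(ev_to, path$states)
    }
  }
  if (!is.null(levels)) {               # restore the caller's state codes
    node_states <- levels[node_states]
    ev_from <- levels[ev_from]
    ev_to <- levels[ev_to]
  }
  structure(list(
    node_states = node_states,
    events = data.frame(node = ev_node, time = ev_time,
                        from = ev_from, to = ev_to),
    n_changes = length(ev_time),
    tree = tree), class = "character_history")
}

#' @export
print.character_history <- function(x, ...) {
  cat("Character history: ", x$n_changes, " change(s) over ",
      nrow(x$tree$edge), " branches\n", sep = "")
  invisible(x)
}

#' Mean stochastic-character-mapping change count over a tree sample
#'
#' For each tree: prune to the coded societies, set the state space to the
#' number of distinct observed states, fit the Mk rate by maximum likelihood,
#' and draw `n_maps` conditional character histories at that rate; the
#' returned value is the grand mean event count over trees x maps — the
#' "SCM" statistic of the comparative analysis. A constant trait yields 0
#' (boundary rate, no events). With `seed` given, every (tree, map) pair runs
#' in its own deterministic RNG substream derived via [derive_seed()], so the
#' result is reproducible regardless of evaluation order.
#'
#' @inheritParams mean_parsimony_changes
#' @param n_maps character maps drawn per tree (default 20).
#' @param seed optional integer master seed for this trait.
#' @return mean count with attributes `per_tree` (mean per tree) and `rates`
#'   (per-tree ML rates); `NA` with a warning when fewer than 2 societies
#'   are coded.
#' @export
mean_scm_changes <- function(sample, v, n_maps = 20L, seed = NULL) {
  stopifnot(inherits(sample, "tree_sample"), inherits(v, "trait_variable"))
  if (n_maps < 1L) stop("n_maps must be >= 1")
  cov <- trait_coverage(v)
  if (!cov$analysable) {
    warning("trait ", v$id, ": fewer than 2 coded societies; un-analysable")
    return(NA_real_)
  }
  st <- v$states[cov$coded]
  if (cov$n_observed < 2L) {             # constant trait: boundary rate, 0
    return(structure(0, per_tree = rep(0, length(sample$trees)),
                     rates = rep(1e-8, length(sample$trees))))
  }
  # compact observed codes to 1..k (Mk is invariant under state relabelling)
  st <- stats::setNames(match(st, sort(unique(st))), names(st))
  per_tree <- numeric(length(sample$trees))
  rates <- numeric(length(sample$trees))
  for (i in seq_along(sample$trees)) {
    tr <- prune_to_taxa(sample$trees[[i]], cov$coded)
    fit <- fit_mk_rate(tr, st)
    rates[i] <- fit$rate
    pr <- mk_pruning(tr, st, fit$rate, fit$k)
    counts <- vapply(seq_len(n_maps), function(j) {
      with_seed(if (is.null(seed)) NULL else derive_seed(seed, i, j), {
        sample_stochastic_map(tr, st, fit$rate, fit$k, pruning = pr)$n_changes
      })
    }, 0L)
    per_tree[i] <- mean(counts)
  }
  structure(mean(per_tree), per_tree = per_tree, rates = rates)
}
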