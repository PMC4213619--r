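#' Transition probability matrix of the symmetric Mk model
#'
#' Under the k-state equal-rates Markov model ("Mk"), every off-diagonal
#' entry of the generator is `r` and the diagonal is `-(k-1) r`. Over a
#' branch of length `t` the transition probabilities have the closed form
#' `P(same) = 1/k + (k-1)/k * exp(-k r t)` and
#' `P(different) = 1/k - 1/k * exp(-k r t)`.
#'
#' @param r instantaneous per-pair rate (>= 0), per unit branch length.
#' @param k number of states (>= 2).
#' @param t branch length (>= 0).
#' @return a `k x k` stochastic matrix.
#' @examples
#' transition_matrix(1, 3, 0.5)
#' @export
transition_matrix <- function(r, k, t) {
  if (r < 0 || t < 0) stop("rate and branch length must be non-negative")
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  e <- exp(-k * r * t)
  p_diff <- (1 - e) / k
  P <- matrix(p_diff, k, k)
  diag(P) <- 1 / k + (k - 1) / k * e
  P
}

# Post-order pruning pass. Returns the postorder-reordered tree, the matrix of
# per-node conditional ("below") partial likelihoods — each row rescaled to
# max 1, relative values within a row exact — and the total log-likelihood
# under a uniform (= Mk stationary) root prior. `states` is a named integer
# vector in 1..k covering every tip.
mk_pruning <- function(tree, states, r, k) {
  ntip <- length(tree$tip.label)
  s <- as.integer(states[tree$tip.label])
  if (anyNA(s)) stop("uncoded tip(s) present; prune first")
  if (any(s < 1L | s > k)) stop("tip state outside 1..k")
  tree <- ape::reorder.phylo(tree, "postorder")
  nnode <- ntip + tree$Nnode
  partial <- matrix(1, nnode, k)
  partial[seq_len(ntip), ] <- 0
  partial[cbind(seq_len(ntip), s)] <- 1
  edge <- tree$edge
  el <- tree$edge.length
  logscale <- 0
  for (i in seq_len(nrow(edge))) {
    pc <- partial[edge[i, 2L], ]
    e <- exp(-k * r * el[i])
    p_diff <- (1 - e) / k
    contrib <- p_diff * sum(pc) + e * pc       # p_same - p_diff = e
    m <- max(contrib)
    if (m <= 0) {
      return(list(tree = tree, partial = partial, loglik = -Inf, k = k))
    }
    p <- edge[i, 1L]
    partial[p, ] <- partial[p, ] * (contrib / m)
    logscale <- logscale + log(m)
    pm <- max(partial[p, ])
    if (pm <= 0) {                             # data impossible at this rate
      return(list(tree = tree, partial = partial, loglik = -Inf, k = k))
    }
    if (pm < 1e-280) {                         # guard against underflow
      partial[p, ] <- partial[p, ] / pm
      logscale <- logscale + log(pm)
    }
  }
  root <- edge[nrow(edge), 1L]
  lik <- sum(partial[root, ]) / k
  list(tree = tree, partial = partial,
       loglik = if (lik > 0) log(lik) + logscale else -Inf,
       k = k, root = root)
}

#' Mk log-likelihood of tip data on a tree
#'
#' Felsenstein pruning recursion for the symmetric k-state Mk model with a
#' uniform root prior (the model's stationary distribution). Invariant under
#' relabelling of states and under rerooting.
#'
#' @param tree a `phylo`; every tip coded.
#' @param states named integer vector of tip states in `1..k`.
#' @param r instantaneous rate (>= 0).
#' @param k state-space size (>= number of distinct observed states).
#' @return the log-probability of the tip data (`-Inf` possible at `r = 0`
#'   with conflicting tips).
#' @export
mk_log_likelihood <- function(tree, states, r, k) {
  if (r < 0) stop("rate must be non-negative")
  k <- as.integer(k)
  obs <- unique(states[!is.na(states)])
  if (k < length(obs)) stop("k smaller than the number of observed states")
  mk_pruning(tree, states, r, k)$loglik
}

#' Maximum-likelihood Mk rate for one trait on one tree
#'
#' One-dimensional bounded search for the rate maximising
#' [mk_log_likelihood()], on the log-rate scale over `[1e-8, 1e3]` per unit
#' branch length (relative tolerance 1e-8). A constant character has a
#' likelihood that decreases monotonically in the rate, so it returns the
#' lower bound with `convergence = "boundary"`; any fit whose optimum sits
#' against either bound is flagged the same way.
#'
#' @inheritParams mk_log_likelihood
#' @param k state-space size; default the number of distinct observed states.
#' @param bounds rate search interval.
#' @return an object of class `mk_fit`: list with `rate`, `k`, `log_lik`,
#'   `convergence` (`"converged"` or `"boundary"`).
#' @export
fit_mk_rate <- function(tree, states, k = NULL,
                        bounds = c(1e-8, 1e3)) {
  states <- states[tree$tip.label]
  if (anyNA(states)) stop("uncoded tip(s) present; prune first")
  obs <- sort(unique(states))
  if (is.null(k)) k <- length(obs)
  k <- as.integer(k)
  if (length(obs) > k) stop("k smaller than the number of observed states")
  if (length(obs) >= 1L && max(obs) > k) {
    # compact arbitrary codes to 1..k; the likelihood is relabel-invariant
    states <- stats::setNames(match(states, obs), names(states))
  }
  if (length(obs) < 1L) stop("no coded states")
  if (length(obs) == 1L) {
    fit <- list(rate = bounds[1L], k = k,
                log_lik = mk_log_likelihood(tree, states, bounds[1L], k),
                convergence = "boundary")
    return(structure(fit, class = "mk_fit"))
  }
  nll <- function(logr) -mk_pruning(tree, states, exp(logr), k)$loglik
  opt <- stats::optimize(nll, interval = log(bounds), tol = 1e-8)
  if (!is.finite(opt$objective)) {
    stop("Mk rate optimisation failed: non-finite likelihood at optimum")
  }
  rate <- exp(opt$minimum)
  at_bound <- opt$minimum < log(bounds[1L]) + 1e-4 ||
              opt$minimum > log(bounds[2L]) - 1e-4
  structure(list(rate = rate, k = k, log_lik = -opt$objective,
                 convergence = if (at_bound) "boundary" else "converged"),
            class = "mk_fit")
}

#' @export
print.mk_fit <- function(x, ...) {
  cat("Mk fit: k = ", x$k, ", rate = ", signif(x$rate, 6),
      ", logLik = ", signif(x$log_lik, 6), " (", x$convergence, ")\n",
      sep = "")
  invisible(x)
}

# Enumeration oracle: sums prior x product of transition probabilities over
# every assignment of states to internal nodes. Tiny instances only.
mk_likelihood_enumeration <- function(tree, states, r, k) {
  ntip <- length(tree$tip.label)
  s <- as.integer(states[tree$tip.label])
  nint <- tree$Nnode
  stopifnot(nint <= 8L, k <= 5L)
  edge <- tree$edge
  el <- tree$edge.length
  Plist <- lapply(el, function(t) transition_matrix(r, k, t))
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), nint)))
  total <- 0
  for (g in seq_len(nrow(grid))) {
    assign_all <- c(s, grid[g, ])
    prob <- 1 / k   # uniform root prior
    for (i in seq_len(nrow(edge))) {
      prob <- prob * Plist[[i]][assign_all[edge[i, 1L]],
                                assign_all[edge[i, 2L]]]
    }
    total <- total + prob
  }
  log(total)
}
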