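#' Per-family trait change summary
#'
#' The "count" stage: for every variable in the trait matrix, computes its
#' coverage N, the codebook category count Cats, the number of distinct
#' observed states, and the mean parsimony and/or mean SCM change counts
#' over the posterior tree sample. Un-analysable variables (N < 2) get `NA`
#' counts and a note; constant variables (one observed state) score 0 under
#' both methods.
#'
#' @param sample a [tree_sample()].
#' @param traits a [trait_matrix()] over the same taxon namespace.
#' @param method `"both"` (default), `"pars"` or `"scm"`.
#' @param n_maps stochastic maps per tree for the SCM mean (default 20).
#' @param seed integer master seed for the SCM sampling; per-trait substreams
#'   are derived with [derive_seed()]. The parsimony path consumes no
#'   randomness.
#' @return data.frame with columns `variable`, `class`, `n`, `cats`,
#'   `k_observed`, `pars` and/or `scm`, `note`; attribute `family`.
#' @export
summarize_trait_changes <- function(sample, traits,
                                    method = c("both", "pars", "scm"),
                                    n_maps = 20L, seed = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(sample, "tree_sample"), inherits(traits, "trait_matrix"))
  extra <- setdiff(traits$societies, sample$taxa)
  if (length(extra)) {
    stop("societies not in the tree namespace: ",
         paste(utils::head(extra, 5L), collapse = ", "))
  }
  vars <- traits$variables
  out <- data.frame(
    variable = vapply(vars, `[[`, "", "id"),
    class = vapply(vars, `[[`, "", "class"),
    n = NA_integer_, cats = vapply(vars, function(v) v$n_categories, 1L),
    k_observed = NA_integer_, stringsAsFactors = FALSE)
  if (method %in% c("both", "pars")) out$pars <- NA_real_
  if (method %in% c("both", "scm")) out$scm <- NA_real_
  out$note <- ""
  for (i in seq_along(vars)) {
    v <- vars[[i]]
    cov <- trait_coverage(v)
    out$n[i] <- cov$n
    out$k_observed[i] <- cov$n_observed
    if (!cov$analysable) {
      out$note[i] <- "un-analysable: fewer than 2 coded societies"
      next
    }
    if (cov$n_observed < 2L) out$note[i] <- "constant"
    if (method %in% c("both", "pars")) {
      out$pars[i] <- suppressWarnings(as.numeric(mean_parsimony_changes(sample, v)))
    }
    if (method %in% c("both", "scm")) {
      trait_seed <- if (is.null(seed)) NULL else derive_seed(seed, 1000L + i)
      out$scm[i] <- suppressWarnings(
        as.numeric(mean_scm_changes(sample, v, n_maps = n_maps,
                                    seed = trait_seed)))
    }
  }
  rownames(out) <- NULL
  attr(out, "family") <- sample$family
  out
}
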