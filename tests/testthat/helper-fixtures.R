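# fixtures are built in code: small random trees (optionally with
# polytomies), random discrete tip states, and temp CSV writers

random_tree <- function(n_tips, polytomies = FALSE) {
  tr <- ape::rtree(n_tips)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.1, 2)
  if (polytomies && n_tips >= 4 && stats::runif(1) < 0.5) {
    # collapse the shortest internal edge(s) into polytomies
    internal <- tr$edge[, 2] > ape::Ntip(tr)
    if (any(internal)) {
      thr <- stats::quantile(tr$edge.length[internal], 0.3)
      tr$edge.length[internal & tr$edge.length <= thr] <- 0
      tr <- ape::di2multi(tr, tol = 1e-12)
      tr$edge.length[tr$edge.length == 0] <- 0.5
    }
  }
  tr
}

random_states <- function(tree, k) {
  stats::setNames(sample.int(k, ape::Ntip(tree), replace = TRUE),
                  tree$tip.label)
}

write_temp_csv <- function(df) {
  p <- tempfile(fileext = ".csv")
  utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
  p
}

# small codebook + trait table pair for loader tests
demo_trait_files <- function() {
  tab <- data.frame(society = c("s1", "s2", "s3"),
                    V1 = c("1", "2", "?"),
                    V2 = c("3", "1", "2"),
                    stringsAsFactors = FALSE)
  cb <- data.frame(id = c("V1", "V2"),
                   description = c("binary demo", "tristate demo"),
                   n_categories = c(2L, 3L),
                   class = c("eco", "social"),
                   recode = c("", ""),
                   stringsAsFactors = FALSE)
  list(table = write_temp_csv(tab), codebook = write_temp_csv(cb))
}

# tiny synthetic spec used by pipeline-level tests (kept small for speed)
tiny_spec <- function(seed = 11L) {
  synthetic_spec(n_taxa = c(12L, 15L), n_trees = 3L, n_traits = 8L,
                 n_eco = 3L, missing_range = c(0, 0.3), seed = seed)
}
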