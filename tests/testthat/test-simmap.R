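test_that("a near-zero rate with constant tips yields an event-free history", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  st <- c(A = 1L, B = 1L, C = 1L)
  set.seed(1)
  h <- sample_stochastic_map(tr, st, r = 1e-8, k = 2)
  expect_s3_class(h, "character_history")
  expect_identical(h$n_changes, 0L)
  expect_equal(nrow(h$events), 0L)
})

test_that("sampled histories satisfy their structural invariants", {
  set.seed(77)
  for (rep in 1:20) {
    tr <- random_tree(sample(5:12, 1), polytomies = TRUE)
    k <- sample(2:4, 1)
    st <- random_states(tr, k)
    fit <- fit_mk_rate(tr, st)
    h <- sample_stochastic_map(tr, st, fit$rate, fit$k)
    ptree <- h$tree
    ntip <- ape::Ntip(ptree)
    # tip end-states equal the observed data
    expect_identical(h$node_states[seq_len(ntip)],
                     unname(st[ptree$tip.label]))
    # per-branch event lists are position-sorted within (0, branch length)
    # and chain from the parent state to the child state
    for (i in seq_len(nrow(ptree$edge))) {
      ch <- ptree$edge[i, 2L]
      ev <- h$events[h$events$node == ch, ]
      if (nrow(ev)) {
        expect_true(all(diff(ev$time) > 0))
        expect_true(all(ev$time > 0 & ev$time < ptree$edge.length[i]))
        expect_identical(ev$from[1], h$node_states[ptree$edge[i, 1L]])
        expect_identical(ev$to[nrow(ev)], h$node_states[ch])
        expect_true(all(ev$from != ev$to))
        if (nrow(ev) > 1) {
          expect_identical(ev$from[-1], ev$to[-nrow(ev)])
        }
      } else {
        expect_identical(h$node_states[ptree$edge[i, 1L]],
                         h$node_states[ch])
      }
    }
    # any realization of the data needs at least the parsimony minimum
    expect_gte(h$n_changes, fitch_score(tr, st))
  }
})

test_that("unconditioned single-branch event count matches the Mk leaving rate", {
  set.seed(404)
  k <- 3L; r <- 0.7; t <- 1.3
  n <- 1e4
  counts <- vapply(seq_len(n), function(i) {
    length(cultrates:::simulate_branch_forward(sample.int(k, 1), t, r, k)$times)
  }, 0L)
  expected <- (k - 1) * r * t   # leaving rate of the symmetric Mk chain
  se <- stats::sd(counts) / sqrt(n)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("rejection and uniformization samplers agree in distribution", {
  set.seed(505)
  k <- 3L; r <- 0.8; t <- 1.2; a <- 1L; b <- 2L
  n <- 1e4
  rej <- vapply(seq_len(n), function(i) {
    length(cultrates:::sample_branch_path(a, b, t, r, k)$times)
  }, 0)
  uni <- vapply(seq_len(n), function(i) {
    length(cultrates:::sample_branch_path(a, b, t, r, k,
                                          max_attempts = 0L)$times)
  }, 0)
  se <- sqrt(stats::var(rej) / n + stats::var(uni) / n)
  expect_lt(abs(mean(rej) - mean(uni)), 3 * se)
  # both samplers only ever produce paths compatible with the endpoints
  expect_true(all(rej >= 1))  # a != b forces at least one change
})

test_that("mean SCM count is reproducible under a fixed seed", {
  set.seed(3)
  trees <- lapply(1:3, function(i) random_tree(12))
  for (i in 1:3) trees[[i]]$tip.label <- sprintf("t%02d", 1:12)
  ts <- tree_sample(trees, "s")
  st <- setNames(sample.int(3, 12, replace = TRUE), sprintf("t%02d", 1:12))
  v <- trait_variable("x", st, 4L)
  m1 <- mean_scm_changes(ts, v, n_maps = 6, seed = 91L)
  m2 <- mean_scm_changes(ts, v, n_maps = 6, seed = 91L)
  expect_identical(m1, m2)
  m3 <- mean_scm_changes(ts, v, n_maps = 6, seed = 92L)
  expect_false(identical(as.numeric(m1), as.numeric(m3)))
  # constant trait: boundary rate, zero events
  vc <- trait_variable("c", setNames(rep(2L, 12), names(st)), 3L)
  expect_equal(as.numeric(mean_scm_changes(ts, vc, n_maps = 3, seed = 1L)), 0)
})

test_that("per-trait mean SCM count dominates mean parsimony count", {
  ds <- generate_paired_families(tiny_spec(seed = 23L))
  s <- summarize_trait_changes(ds$samples$A, ds$traits$A, n_maps = 4,
                               seed = 7L)
  ok <- !is.na(s$pars)
  expect_true(all(s$scm[ok] >= s$pars[ok]))
})
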