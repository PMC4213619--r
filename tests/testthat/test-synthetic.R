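test_that("pure-birth trees have the right shape and unit depth", {
  set.seed(61)
  tr2 <- simulate_yule_tree(2)
  expect_equal(ape::Ntip(tr2), 2L)
  d <- ape::node.depth.edgelength(tr2)[1:2]
  expect_lt(max(abs(d - 1)), 1e-9)
  tr <- simulate_yule_tree(100)
  expect_equal(ape::Ntip(tr), 100L)
  expect_equal(tr$Nnode, 99L)
  expect_equal(nrow(tr$edge), 198L)
  depths <- ape::node.depth.edgelength(tr)[1:100]
  expect_lt(abs(mean(depths) - 1), 1e-9)
})

test_that("forward trait evolution: frozen at rate ~0, uniform when saturated", {
  set.seed(62)
  tr <- simulate_yule_tree(50)
  st <- evolve_discrete_trait(tr, 4L, 1e-12)
  expect_equal(length(unique(st)), 1L)
  # saturation: accumulated tip states are uniform over k
  k <- 4L
  tipstates <- integer(0)
  while (length(tipstates) < 1e4) {
    tipstates <- c(tipstates, evolve_discrete_trait(tr, k, 1e3))
  }
  gof <- stats::chisq.test(tabulate(tipstates, k))
  expect_gt(gof$p.value, 0.01)
})

test_that("generator ground truth is complete and eco labels track slow rates", {
  ds <- generate_paired_families(tiny_spec(seed = 63L))
  spec <- ds$spec
  expect_identical(ds$truth$id, ds$codebook$id)
  expect_equal(nrow(ds$truth), spec$n_traits)
  expect_true(all(ds$truth$true_rate > 0))
  # default rule: the n_eco slowest traits carry the eco label
  eco_rates <- ds$truth$true_rate[ds$truth$class == "eco"]
  soc_rates <- ds$truth$true_rate[ds$truth$class == "social"]
  expect_equal(length(eco_rates), spec$n_eco)
  expect_lt(max(eco_rates), min(soc_rates))
  # matrices validate and share the generator's taxa
  for (fam in spec$families) {
    expect_identical(sort(ds$traits[[fam]]$societies),
                     ds$samples[[fam]]$taxa)
    for (v in ds$traits[[fam]]$variables) {
      cov <- trait_coverage(v)
      expect_gte(cov$n, 2L)
      expect_lte(cov$n_observed, v$n_categories)
    }
  }
})

test_that("same seed reproduces byte-identical dataset files", {
  d1 <- tempfile(); d2 <- tempfile()
  generate_paired_families(tiny_spec(seed = 64L), dir = d1)
  generate_paired_families(tiny_spec(seed = 64L), dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  d3 <- tempfile()
  generate_paired_families(tiny_spec(seed = 65L), dir = d3)
  expect_false(identical(readLines(file.path(d1, "trees_A.nwk")),
                         readLines(file.path(d3, "trees_A.nwk"))))
})

test_that("missingness masks entries without corrupting the coded ones", {
  # single-trait specs let the pre-mask RNG streams coincide, so family A's
  # coded entries must be identical with and without masking
  base <- synthetic_spec(n_taxa = c(20L, 20L), n_trees = 1L, n_traits = 1L,
                         n_eco = 0L, missing_range = c(0, 0), seed = 66L)
  masked <- synthetic_spec(n_taxa = c(20L, 20L), n_trees = 1L, n_traits = 1L,
                           n_eco = 0L, missing_range = c(0.4, 0.4), seed = 66L)
  v0 <- generate_paired_families(base)$traits$A$variables[[1]]
  v1 <- generate_paired_families(masked)$traits$A$variables[[1]]
  expect_gt(sum(is.na(v1$states)), 0L)
  coded <- !is.na(v1$states)
  expect_identical(v1$states[coded], v0$states[coded])
  expect_equal(trait_coverage(v1)$n, sum(coded))
})

test_that("clustered missingness removes a clade's tips", {
  spec <- synthetic_spec(n_taxa = c(30L, 30L), n_trees = 2L, n_traits = 2L,
                         n_eco = 0L, missing_range = c(0.4, 0.4),
                         missing_mode = "clustered", seed = 67L)
  ds <- generate_paired_families(spec)
  v <- ds$traits$A$variables[[1]]
  miss <- names(v$states)[is.na(v$states)]
  expect_gt(length(miss), 0L)
  # the missing tips form a contiguous block of the tree's postorder tip
  # ordering, i.e. they are phylogenetically clustered
  ord <- cultrates:::clade_order(ds$samples$A$trees[[1]])
  expect_identical(sort(match(miss, ord)), seq_along(miss))
})

test_that("true rates explain the parsimony counts within a family", {
  ds <- generate_paired_families(tiny_spec(seed = 68L))
  s <- summarize_trait_changes(ds$samples$A, ds$traits$A, method = "pars")
  rho <- cor(ds$truth$true_rate, s$pars, method = "spearman",
             use = "complete.obs")
  expect_gt(rho, 0.5)  # small instance; the full-size condition is stronger
})
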