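test_that("trait loader validates codes and maps the missing code to NA", {
  fx <- demo_trait_files()
  tm <- load_trait_matrix(fx$table, fx$codebook, family = "demo")
  expect_s3_class(tm, "trait_matrix")
  expect_length(tm$variables, 2L)
  v1 <- tm$variables[["V1"]]
  expect_identical(unname(v1$states), c(1L, 2L, NA))
  cov <- trait_coverage(v1)
  expect_equal(cov$n, 2L)
  expect_setequal(cov$coded, c("s1", "s2"))

  # code outside [1, n_categories]
  bad <- utils::read.csv(fx$table, colClasses = "character")
  bad$V1[1] <- "11"
  expect_error(load_trait_matrix(write_temp_csv(bad), fx$codebook),
               "outside \\[1, 2\\]")

  # variable absent from the codebook
  bad2 <- utils::read.csv(fx$table, colClasses = "character")
  names(bad2)[3] <- "V9"
  expect_error(load_trait_matrix(write_temp_csv(bad2), fx$codebook),
               "absent from codebook")
})

test_that("societies outside the tree namespace are dropped with a warning", {
  fx <- demo_trait_files()
  expect_warning(
    tm <- load_trait_matrix(fx$table, fx$codebook, taxa = c("s1", "s3")),
    "dropping 1 societies")
  expect_identical(tm$societies, c("s1", "s3"))
})

test_that("recoding collapses categories and respects its contracts", {
  v <- trait_variable("slavery", c(a = 1L, b = 2L, c = 3L, d = 4L, e = NA),
                      n_categories = 4L, class = "social")
  # typed categories collapse to presence/absence
  b <- recode_variable(v, c("1" = 1L, "2" = 2L, "3" = 2L, "4" = 2L))
  expect_equal(b$n_categories, 2L)
  expect_identical(unname(b$states), c(1L, 2L, 2L, 2L, NA))
  # identity map leaves states unchanged
  idm <- setNames(1:4, 1:4)
  expect_identical(recode_variable(v, idm)$states, v$states)
  # collapse-all gives a constant, un-analysable variable
  allone <- recode_variable(v, setNames(rep(1L, 4), 1:4))
  expect_equal(trait_coverage(allone)$n_observed, 1L)
  # non-total and non-contiguous maps are rejected
  expect_error(recode_variable(v, c("1" = 1L, "2" = 2L)), "does not cover")
  expect_error(recode_variable(v, c("1" = 1L, "2" = 3L, "3" = 3L, "4" = 3L)),
               "contiguous")
})

test_that("recode invariants: observed states never increase, N unchanged", {
  set.seed(5)
  for (rep in 1:20) {
    k <- sample(3:6, 1)
    st <- sample.int(k, 12, replace = TRUE)
    st[sample.int(12, 3)] <- NA
    v <- trait_variable("x", setNames(st, paste0("s", 1:12)), k)
    cov0 <- trait_coverage(v)
    expect_lte(cov0$n_observed, v$n_categories)
    newk <- sample.int(k, 1)
    map <- setNames(sample.int(newk, k, replace = TRUE), 1:k)
    # make targets contiguous from 1
    map[seq_len(newk)] <- seq_len(newk)
    v2 <- recode_variable(v, map)
    cov2 <- trait_coverage(v2)
    expect_lte(cov2$n_observed, cov0$n_observed)
    expect_equal(cov2$n, cov0$n)
  }
})

test_that("codebook recode maps are applied at load time", {
  tab <- data.frame(society = c("s1", "s2", "s3", "s4"),
                    V1 = c("1", "2", "3", "4"))
  cb <- data.frame(id = "V1", description = "typed slavery",
                   n_categories = 4L, class = "social",
                   recode = "1:1;2:2;3:2;4:2")
  tm <- load_trait_matrix(write_temp_csv(tab), write_temp_csv(cb))
  expect_equal(tm$variables[["V1"]]$n_categories, 2L)
  expect_identical(unname(tm$variables[["V1"]]$states), c(1L, 2L, 2L, 2L))
})

test_that("a written trait matrix loads back losslessly", {
  ds <- generate_paired_families(tiny_spec())
  d <- tempfile()
  write_synthetic_dataset(ds, d)
  tm <- load_trait_matrix(file.path(d, "traits_B.csv"),
                          file.path(d, "codebook.csv"), family = "B")
  orig <- ds$traits$B
  expect_identical(tm$societies, orig$societies)
  for (id in names(orig$variables)) {
    expect_identical(tm$variables[[id]]$states, orig$variables[[id]]$states)
    expect_identical(tm$variables[[id]]$n_categories,
                     orig$variables[[id]]$n_categories)
    expect_identical(tm$variables[[id]]$class, orig$variables[[id]]$class)
  }
})
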