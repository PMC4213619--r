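test_that("residualize: centring, exact fits, and the normal-equations oracle", {
  set.seed(8)
  y <- rnorm(20)
  expect_equal(residualize(y, NULL), y - mean(y))
  X <- cbind(rnorm(20), rnorm(20))
  y_lin <- 2 + 3 * X[, 1] - X[, 2]
  expect_lt(max(abs(residualize(y_lin, X))), 1e-10)
  # random 28 x 2 design against an explicit (X'X)^-1 X'y solve
  X2 <- cbind(rnorm(28), rnorm(28))
  y2 <- rnorm(28)
  M <- cbind(1, X2)
  beta <- solve(t(M) %*% M, t(M) %*% y2)
  expect_equal(residualize(y2, X2), as.numeric(y2 - M %*% beta),
               tolerance = 1e-10)
  r <- residualize(y2, X2)
  expect_lt(abs(sum(r)), 1e-8)
  expect_lt(max(abs(t(M) %*% r)), 1e-8)
  expect_error(residualize(y2, cbind(X2, X2[, 1])), "rank deficient")
})

test_that("partial correlation: reductions, symmetry and the matrix oracle", {
  set.seed(16)
  x <- rnorm(28); y <- rnorm(28); Z <- matrix(rnorm(28 * 3), ncol = 3)
  # empty control set reduces to plain Pearson
  plain <- partial_correlation(x, y)
  ref <- cor.test(x, y)
  expect_equal(plain$estimate, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(plain$p.value, ref$p.value, tolerance = 1e-12)
  # y = x gives r = 1 regardless of controls
  expect_equal(partial_correlation(x, x + 0, Z)$estimate, 1, tolerance = 1e-12)
  # inverse-correlation-matrix oracle
  pc <- partial_correlation(x, y, Z)
  Om <- solve(cor(cbind(x, y, Z)))
  expect_equal(pc$estimate, -Om[1, 2] / sqrt(Om[1, 1] * Om[2, 2]),
               tolerance = 1e-10)
  expect_equal(pc$df, 28L - 3L - 2L)
  # symmetry in the two variables
  pc2 <- partial_correlation(y, x, Z)
  expect_equal(pc$estimate, pc2$estimate, tolerance = 1e-12)
  expect_equal(pc$p.value, pc2$p.value, tolerance = 1e-12)
})

test_that("spearman mode rank-transforms with average ranks for ties", {
  x <- c(1, 2, 2, 5, 7, 7, 7, 10)
  y <- c(2, 1, 4, 4, 6, 9, 8, 12)
  sp <- partial_correlation(x, y, method = "spearman")
  ref <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  expect_equal(sp$estimate, unname(ref$estimate), tolerance = 1e-12)
})

test_that("eco/social contrast: sign convention, label swap, R^2 identity", {
  set.seed(24)
  classes <- rep(c("eco", "social"), c(10, 18))
  res <- rnorm(28) + ifelse(classes == "social", 1, 0)
  out <- eco_social_test(res, classes)
  expect_equal(out$df, 26)
  expect_gt(out$t, 0)            # social mean above eco mean
  # swapping the labels negates t, leaves p and R^2 unchanged
  swapped <- ifelse(classes == "eco", "social", "eco")
  out2 <- eco_social_test(res, swapped)
  expect_equal(out2$t, -out$t, tolerance = 1e-12)
  expect_equal(out2$p.value, out$p.value, tolerance = 1e-12)
  expect_equal(out2$r_squared, out$r_squared, tolerance = 1e-12)
  # algebraic identity for a binary predictor
  expect_equal(out$r_squared, out$t^2 / (out$t^2 + out$df),
               tolerance = 1e-10)
  # identical group means give t = 0, R^2 = 0
  out0 <- eco_social_test(c(rep(c(-1, 1), 5), rep(c(-1, 1), 9)),
                          rep(c("eco", "social"), c(10, 18)))
  expect_lt(abs(out0$t), 1e-12)
  expect_lt(out0$r_squared, 1e-12)
})

test_that("run_comparison on a duplicated family gives perfect correlation", {
  set.seed(40)
  s <- data.frame(variable = sprintf("V%02d", 1:14),
                  class = rep(c("eco", "social"), 7),
                  n = sample(40:100, 14), cats = sample(2:8, 14, TRUE),
                  pars = runif(14, 1, 40))
  s$scm <- s$pars * 1.3
  res <- run_comparison(s, s)
  expect_equal(res$pearson$estimate, 1, tolerance = 1e-12)
  expect_equal(res$partial$estimate, 1, tolerance = 1e-10)
  expect_equal(res$mp_scm_spearman$family_a$estimate, 1, tolerance = 1e-12)
  # per-family residuals sum to ~0 (OLS with intercept)
  expect_lt(abs(sum(res$table$res_a)), 1e-8)
  expect_lt(abs(sum(res$table$res_b)), 1e-8)
})

test_that("statistics are invariant to the ordering of the variables", {
  set.seed(41)
  mk <- function() data.frame(variable = sprintf("V%02d", 1:16),
                              class = rep(c("eco", "social"), each = 8),
                              n = sample(30:90, 16),
                              cats = sample(2:9, 16, TRUE),
                              pars = runif(16, 1, 30),
                              scm = runif(16, 1, 40))
  a <- mk(); b <- mk()
  b$class <- a$class; b$cats <- a$cats
  r1 <- run_comparison(a, b)
  perm <- sample.int(16)
  r2 <- run_comparison(a[perm, ], b[sample.int(16), ])
  expect_equal(r1$partial$estimate, r2$partial$estimate, tolerance = 1e-12)
  expect_equal(r1$spearman$estimate, r2$spearman$estimate, tolerance = 1e-12)
  expect_equal(r1$eco_social$family_a$t, r2$eco_social$family_a$t,
               tolerance = 1e-12)
  # mismatched variable sets are rejected
  a2 <- a; a2$variable[1] <- "VXX"
  expect_error(run_comparison(a2, b), "same variable set")
})
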