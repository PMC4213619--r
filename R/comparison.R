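#' OLS residuals against a covariate set
#'
#' Ordinary least-squares residuals of `y` on `X` plus an intercept — the
#' "unstandardized residuals" used both for the per-family residual rate
#' column (change count adjusted for coverage N and category count Cats) and
#' inside [partial_correlation()]. Residuals sum to zero and are orthogonal
#' to every covariate.
#'
#' @param y numeric response vector.
#' @param X numeric covariate matrix/data.frame (no intercept column), or
#'   `NULL` for intercept-only centring.
#' @return numeric residual vector.
#' @export
residualize <- function(y, X = NULL) {
  y <- as.numeric(y)
  if (is.null(X) || NCOL(X) == 0L) return(y - mean(y))
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("rows(X) must equal length(y)")
  M <- cbind(1, X)
  if (qr(M)$rank < ncol(M)) stop("covariate matrix is rank deficient")
  stats::lm.fit(M, y)$residuals
}

#' Partial correlation with two-tailed t-test
#'
#' Pearson correlation between `x` and `y` after residualizing both on the
#' covariates `Z`; the p-value comes from `t = r * sqrt(df / (1 - r^2))`
#' with `df = n - ncol(Z) - 2`, two-tailed. With empty `Z` this is the plain
#' Pearson correlation test. With `method = "spearman"` all three of `x`,
#' `y` and the covariate columns are rank-transformed first (average ranks
#' for ties), giving the non-parametric mirror of the analysis.
#'
#' @param x,y numeric vectors of equal length.
#' @param Z covariate matrix or `NULL`.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return list with `estimate`, `statistic` (t), `df`, `p.value`, `n`.
#' @export
partial_correlation <- function(x, y, Z = NULL,
                                method = c("pearson", "spearman")) {
  method <- match.arg(method)
  x <- as.numeric(x)
  y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  nz <- if (is.null(Z)) 0L else NCOL(Z)
  if (n <= nz + 2L) stop("too few observations for ", nz, " covariates")
  if (method == "spearman") {
    x <- rank(x)
    y <- rank(y)
    if (nz > 0L) Z <- apply(as.matrix(Z), 2L, rank)
  }
  if (nz > 0L) {
    # drop linearly redundant controls (e.g. identical coverage vectors when
    # comparing a family with itself); the projection space is unchanged
    Z <- as.matrix(Z)
    qz <- qr(cbind(1, Z))
    keep <- qz$pivot[seq_len(qz$rank)] - 1L
    keep <- keep[keep > 0L]
    Z <- Z[, sort(keep), drop = FALSE]
    nz <- ncol(Z)
    if (nz == 0L) Z <- NULL
  }
  rx <- residualize(x, Z)
  ry <- residualize(y, Z)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("degenerate (zero-variance) residuals")
  }
  r <- stats::cor(rx, ry)
  df <- n - nz - 2L
  tt <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  list(estimate = r, statistic = tt, df = df,
       p.value = 2 * stats::pt(-abs(tt), df), n = n)
}

#' Ecological-vs-social contrast on residual change counts
#'
#' Pooled-variance two-sample t-test of the residual change counts between
#' the two trait classes (positive t means the social mean exceeds the eco
#' mean; df = n - 2, two-tailed p), plus the R-squared of an OLS regression
#' of the residuals on the binary class indicator — the effect-size summary
#' of how much of the residual rate variation the eco/social distinction
#' explains.
#'
#' @param res numeric residual vector (one value per trait).
#' @param classes character/factor vector of `"eco"`/`"social"` labels.
#' @param welch use Welch's unequal-variance t instead of pooled (default
#'   `FALSE`; the R-squared is unaffected).
#' @return list with `t`, `df`, `p.value`, `r_squared`, `mean_eco`,
#'   `mean_social`.
#' @export
eco_social_test <- function(res, classes, welch = FALSE) {
  classes <- as.character(classes)
  if (!all(classes %in% c("eco", "social"))) {
    stop("classes must be 'eco' or 'social'")
  }
  res_e <- res[classes == "eco"]
  res_s <- res[classes == "social"]
  if (length(res_e) < 2L || length(res_s) < 2L) {
    stop("each class needs at least 2 traits")
  }
  tt <- stats::t.test(res_s, res_e, var.equal = !welch)
  ind <- as.integer(classes == "social")
  fit <- stats::lm(res ~ ind)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p.value = tt$p.value,
       r_squared = summary(fit)$r.squared,
       mean_eco = mean(res_e), mean_social = mean(res_s))
}

#' Cross-family comparison of per-trait change counts
#'
#' Takes the per-family trait summaries (one row per trait: coverage `n`,
#' codebook category count `cats`, mean parsimony count `pars`, mean SCM
#' count `scm`, class label) and computes the full comparative analysis for
#' the chosen change measure:
#' \itemize{
#'   \item Pearson and Spearman correlations of the raw per-trait counts
#'     across the two families;
#'   \item the partial correlation controlling jointly for the per-family
#'     coverages \eqn{N_A, N_B} and the category count Cats (Cats enters
#'     once — it is a property of the variable, identical in both families);
#'   \item per-family residual counts from separate OLS regressions of the
#'     count on that family's N and on Cats (the tabulated "Res" column);
#'   \item per-family eco/social contrasts on those residuals
#'     ([eco_social_test()]);
#'   \item per-family Spearman rank agreement between the parsimony and SCM
#'     counts (when both are present).
#' }
#'
#' @param summary_a,summary_b data.frames with columns `variable`, `class`,
#'   `n`, `cats` and the count column(s) `pars` and/or `scm`; same variable
#'   set in both.
#' @param method which change measure to compare: `"pars"` or `"scm"`.
#' @param nonparametric rank-transform everything (Spearman mirror of the
#'   whole analysis).
#' @param welch Welch t-test instead of pooled for the class contrast.
#' @return an object of class `comparison_result`: list with `pearson`,
#'   `spearman`, `partial` (each `estimate`/`statistic`/`df`/`p.value`),
#'   `eco_social` (per family), `mp_scm_spearman` (per family, `NA` when a
#'   count column is absent), `table` (the combined per-trait table, sorted
#'   by increasing family-A residual), `method`, `families`, `n_traits`.
#' @export
run_comparison <- function(summary_a, summary_b, method = c("pars", "scm"),
                           nonparametric = FALSE, welch = FALSE) {
  method <- match.arg(method)
  need <- c("variable", "class", "n", "cats", method)
  for (nm in need) {
    if (!nm %in% names(summary_a) || !nm %in% names(summary_b)) {
      stop("summaries must contain column '", nm, "'")
    }
  }
  if (!setequal(summary_a$variable, summary_b$variable)) {
    stop("the two families do not share the same variable set")
  }
  b <- summary_b[match(summary_a$variable, summary_b$variable), ]
  a <- summary_a
  if (!identical(as.character(a$class), as.character(b$class))) {
    stop("class labels disagree between families")
  }
  if (!identical(as.numeric(a$cats), as.numeric(b$cats))) {
    stop("category counts disagree between families")
  }
  keep <- !is.na(a[[method]]) & !is.na(b[[method]])
  if (any(!keep)) {
    warning(sum(!keep), " un-analysable trait(s) dropped from the comparison")
    a <- a[keep, ]
    b <- b[keep, ]
  }
  nv <- nrow(a)
  if (nv < 10L) warning("only ", nv, " traits; statistics will be unstable")
  ya <- a[[method]]
  yb <- b[[method]]
  pm <- if (nonparametric) "spearman" else "pearson"
  pearson <- partial_correlation(ya, yb, NULL, method = pm)
  spearman <- partial_correlation(ya, yb, NULL, method = "spearman")
  partial <- partial_correlation(ya, yb,
                                 cbind(n_a = a$n, n_b = b$n, cats = a$cats),
                                 method = pm)
  rnk <- function(z) if (nonparametric) rank(z) else z
  res_a <- residualize(rnk(ya), cbind(rnk(a$n), rnk(a$cats)))
  res_b <- residualize(rnk(yb), cbind(rnk(b$n), rnk(b$cats)))
  eco <- list(
    family_a = eco_social_test(res_a, a$class, welch = welch),
    family_b = eco_social_test(res_b, b$class, welch = welch))
  rank_agree <- function(s) {
    if (!all(c("pars", "scm") %in% names(s)) ||
        anyNA(s$pars) || anyNA(s$scm)) return(list(estimate = NA_real_,
                                                   p.value = NA_real_))
    partial_correlation(s$pars, s$scm, NULL, method = "spearman")
  }
  tab <- data.frame(variable = a$variable, class = a$class, cats = a$cats,
                    n_a = a$n, count_a = ya, res_a = res_a,
                    n_b = b$n, count_b = yb, res_b = res_b,
                    stringsAsFactors = FALSE)
  if (all(c("pars", "scm") %in% names(a))) {
    tab$pars_a <- a$pars; tab$scm_a <- a$scm
    tab$pars_b <- b$pars; tab$scm_b <- b$scm
  }
  tab <- tab[order(tab$res_a), ]
  structure(list(
    method = method, nonparametric = nonparametric,
    families = c(attr(summary_a, "family") %||% "A",
                 attr(summary_b, "family") %||% "B"),
    n_traits = nv,
    pearson = pearson, spearman = spearman, partial = partial,
    eco_social = eco,
    mp_scm_spearman = list(family_a = rank_agree(a), family_b = rank_agree(b)),
    table = tab), class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  f <- function(v) formatC(v, digits = 3, format = "g")
  cat("Cross-family comparison of per-trait change counts (",
      toupper(x$method), if (x$nonparametric) ", non-parametric", ")\n",
      "  families: ", x$families[1L], " vs ", x$families[2L],
      "  (", x$n_traits, " traits)\n",
      "  Pearson r  = ", f(x$pearson$estimate),
      "  (p = ", f(x$pearson$p.value), ")\n",
      "  Spearman rho = ", f(x$spearman$estimate),
      "  (p = ", f(x$spearman$p.value), ")\n",
      "  partial r  = ", f(x$partial$estimate),
      "  (controls N_A, N_B, Cats; df = ", x$partial$df,
      ", p = ", f(x$partial$p.value), ")\n", sep = "")
  for (fam in c("family_a", "family_b")) {
    e <- x$eco_social[[fam]]
    cat("  eco/social ", fam, ": t(", e$df, ") = ", f(e$t),
        ", p = ", f(e$p.value), ", R^2 = ", f(e$r_squared), "\n", sep = "")
    m <- x$mp_scm_spearman[[fam]]
    if (!is.na(m$estimate)) {
      cat("  MP~SCM rank rho ", fam, ": ", f(m$estimate),
          " (p = ", f(m$p.value), ")\n", sep = "")
    }
  }
  invisible(x)
}
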