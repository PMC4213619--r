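#' Discrete trait variables and trait matrices
#'
#' A `trait_variable` holds one discrete cultural character: per-society
#' category codes (integers `1..n_categories`, `NA` for missing data), plus
#' codebook metadata — a description, the number of categories the source
#' database distinguishes (`n_categories`, the "Cats" covariate used in the
#' comparative statistics), and a class label, `"eco"` for traits tied to the
#' external environment (subsistence, dwellings, settlements) or `"social"`
#' for norms and institutions of social organization. Codes are treated as
#' nominal (unordered) throughout.
#'
#' @param id variable identifier.
#' @param states named integer vector, society -> code in `[1, n_categories]`
#'   or `NA`.
#' @param n_categories number of categories in the codebook (>= 2).
#' @param class `"eco"` or `"social"`.
#' @param description free-text description.
#' @return an object of class `trait_variable`.
#' @export
trait_variable <- function(id, states, n_categories,
                           class = c("social", "eco"), description = "") {
  class <- match.arg(class)
  n_categories <- as.integer(n_categories)
  if (is.na(n_categories) || n_categories < 2L) {
    stop("variable ", id, ": n_categories must be an integer >= 2")
  }
  if (is.null(names(states)) || anyDuplicated(names(states))) {
    stop("variable ", id, ": states must be uniquely named by society")
  }
  st <- as.integer(states)
  names(st) <- names(states)
  bad <- !is.na(st) & (st < 1L | st > n_categories)
  if (any(bad)) {
    stop("variable ", id, ": state code(s) ",
         paste(unique(st[bad]), collapse = ", "),
         " outside [1, ", n_categories, "]")
  }
  structure(list(id = as.character(id), description = as.character(description),
                 n_categories = n_categories, class = class, states = st),
            class = "trait_variable")
}

#' @export
print.trait_variable <- function(x, ...) {
  cov <- trait_coverage(x)
  cat("Trait '", x$id, "' (", x$class, "): ", x$n_categories,
      " categories, coded for ", cov$n, "/", length(x$states),
      " societies, ", cov$n_observed, " state(s) observed\n", sep = "")
  invisible(x)
}

#' Construct a trait matrix
#'
#' @param variables list of [trait_variable()]s sharing one society set.
#' @param family family label.
#' @return an object of class `trait_matrix`: list with `family`, `societies`
#'   and `variables` (named by variable id).
#' @export
trait_matrix <- function(variables, family = "unnamed") {
  if (length(variables) < 1L) stop("a trait matrix needs at least 1 variable")
  stopifnot(all(vapply(variables, inherits, TRUE, "trait_variable")))
  soc <- names(variables[[1L]]$states)
  for (v in variables) {
    if (!identical(names(v$states), soc)) {
      stop("variable ", v$id, ": society list differs from the first variable")
    }
  }
  names(variables) <- vapply(variables, `[[`, "", "id")
  structure(list(family = as.character(family), societies = soc,
                 variables = variables),
            class = "trait_matrix")
}

#' @export
print.trait_matrix <- function(x, ...) {
  cat("Trait matrix '", x$family, "': ", length(x$variables), " variables x ",
      length(x$societies), " societies\n", sep = "")
  invisible(x)
}

#' Load a trait matrix and codebook from CSV
#'
#' The trait table is a CSV with a `society` identifier column and one column
#' per variable; the codebook CSV has columns `id`, `description`,
#' `n_categories`, `class` (`eco`/`social`) and an optional `recode` column
#' with entries of the form `"old1:new1;old2:new2;..."` which, when
#' non-empty, is applied via [recode_variable()] at load time (this is how
#' e.g. a typed slavery variable collapses to presence/absence). Entries equal
#' to `missing_code` become `NA`. Societies absent from `taxa` are dropped
#' with a warning — they cannot be placed on the trees.
#'
#' @param table path to the trait CSV.
#' @param codebook path to the codebook CSV.
#' @param missing_code string marking missing data (default `"?"`).
#' @param taxa optional character vector: the tree tip namespace to validate
#'   societies against.
#' @param family family label.
#' @param apply_recode apply codebook recode maps (default `TRUE`).
#' @return a [trait_matrix()].
#' @export
load_trait_matrix <- function(table, codebook, missing_code = "?",
                              taxa = NULL, family = "unnamed",
                              apply_recode = TRUE) {
  tab <- utils::read.csv(table, check.names = FALSE,
                         colClasses = "character")
  cb <- utils::read.csv(codebook, check.names = FALSE,
                        colClasses = "character")
  soc_col <- if ("society" %in% names(tab)) "society" else names(tab)[1L]
  societies <- tab[[soc_col]]
  if (anyDuplicated(societies)) stop("duplicate society ids in ", table)
  var_cols <- setdiff(names(tab), soc_col)
  missing_cb <- setdiff(var_cols, cb$id)
  if (length(missing_cb)) {
    stop("variable(s) absent from codebook: ",
         paste(missing_cb, collapse = ", "))
  }
  if (!is.null(taxa)) {
    drop <- setdiff(societies, taxa)
    if (length(drop)) {
      warning("dropping ", length(drop),
              " societies absent from the tree namespace: ",
              paste(utils::head(drop, 5L), collapse = ", "),
              if (length(drop) > 5L) ", ..." else "")
      keep <- societies %in% taxa
      tab <- tab[keep, , drop = FALSE]
      societies <- societies[keep]
    }
  }
  vars <- lapply(var_cols, function(vc) {
    row <- cb[match(vc, cb$id), ]
    raw <- tab[[vc]]
    raw[raw == missing_code | raw == "" | is.na(raw)] <- NA
    st <- suppressWarnings(as.integer(raw))
    if (any(is.na(st) & !is.na(raw))) {
      stop("variable ", vc, ": non-integer state code(s)")
    }
    names(st) <- societies
    v <- trait_variable(vc, st, n_categories = row$n_categories,
                        class = match.arg(row$class, c("social", "eco")),
                        description = row$description %||% "")
    rc <- if ("recode" %in% names(row)) row$recode else ""
    if (apply_recode && !is.na(rc) && nzchar(rc)) {
      v <- recode_variable(v, parse_recode(rc))
    }
    v
  })
  trait_matrix(vars, family = family)
}

parse_recode <- function(spec) {
  pairs <- strsplit(strsplit(spec, ";", fixed = TRUE)[[1L]], ":", fixed = TRUE)
  if (any(lengths(pairs) != 2L)) stop("malformed recode spec: ", spec)
  map <- as.integer(vapply(pairs, `[`, "", 2L))
  names(map) <- vapply(pairs, `[`, "", 1L)
  map
}

#' Write a trait matrix and codebook back to CSV
#'
#' Inverse of [load_trait_matrix()] (without re-applying recodes).
#'
#' @param tm a [trait_matrix()].
#' @param table,codebook output paths.
#' @param missing_code string written for `NA` states.
#' @return invisibly, `c(table, codebook)`.
#' @export
write_trait_matrix <- function(tm, table, codebook, missing_code = "?") {
  stopifnot(inherits(tm, "trait_matrix"))
  df <- data.frame(society = tm$societies, check.names = FALSE,
                   stringsAsFactors = FALSE)
  for (v in tm$variables) {
    col <- as.character(v$states)
    col[is.na(col)] <- missing_code
    df[[v$id]] <- col
  }
  utils::write.csv(df, table, row.names = FALSE, quote = FALSE)
  cb <- data.frame(
    id = vapply(tm$variables, `[[`, "", "id"),
    description = vapply(tm$variables, `[[`, "", "description"),
    n_categories = vapply(tm$variables, function(v) v$n_categories, 1L),
    class = vapply(tm$variables, `[[`, "", "class"),
    recode = "", check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(cb, codebook, row.names = FALSE, quote = FALSE)
  invisible(c(table, codebook))
}

#' Recode a trait variable
#'
#' Maps observed category codes onto a new, contiguous code set starting at 1
#' (e.g. collapsing a typed multistate variable to presence/absence). The map
#' must cover every observed non-missing code; missing entries are preserved;
#' `n_categories` becomes the number of distinct target codes.
#'
#' @param v a [trait_variable()].
#' @param recode_map named integer vector, `old code -> new code`.
#' @return the recoded [trait_variable()]; if all observed states collapse to
#'   one code the result has `n_categories = 2` nominally but a single
#'   observed state, and is flagged un-analysable downstream.
#' @export
recode_variable <- function(v, recode_map) {
  stopifnot(inherits(v, "trait_variable"))
  old <- as.integer(names(recode_map))
  new <- as.integer(recode_map)
  observed <- unique(v$states[!is.na(v$states)])
  uncovered <- setdiff(observed, old)
  if (length(uncovered)) {
    stop("variable ", v$id, ": recode map does not cover observed code(s) ",
         paste(uncovered, collapse = ", "))
  }
  targets <- sort(unique(new))
  if (!identical(targets, seq_along(targets))) {
    stop("variable ", v$id,
         ": recode target codes must be contiguous from 1, got ",
         paste(targets, collapse = ", "))
  }
  st <- new[match(v$states, old)]
  names(st) <- names(v$states)
  trait_variable(v$id, st, n_categories = max(2L, length(targets)),
                 class = v$class, description = v$description)
}

#' Coverage of a trait variable
#'
#' Reports which societies carry a code, how many (`n`, the per-variable
#' effective sample size used as the "N" covariate in all comparative
#' statistics), and how many distinct states are actually observed.
#'
#' @param v a [trait_variable()].
#' @return list with `coded` (society names), `n`, `n_observed` (distinct
#'   non-missing codes) and `analysable` (`n >= 2`).
#' @export
trait_coverage <- function(v) {
  stopifnot(inherits(v, "trait_variable"))
  coded <- names(v$states)[!is.na(v$states)]
  n_obs <- length(unique(v$states[!is.na(v$states)]))
  list(coded = coded, n = length(coded), n_observed = n_obs,
       analysable = length(coded) >= 2L)
}
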