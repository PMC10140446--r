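#' Clean a cognitive score matrix: exclusion then mean imputation
#'
#' Applies the battery's cleaning rule: subjects missing more than
#' `max_missing` of the test scores are excluded; remaining missing cells are
#' replaced by the column mean computed over the observed values of the
#' retained subjects. Observed cells are never modified.
#'
#' @param matrix numeric matrix (subjects x tests), `NA` for missing; row
#'   names taken as subject ids when present.
#' @param max_missing maximum number of missing scores a retained subject may
#'   have (default 5); must be smaller than the number of tests.
#' @return list with `values` (complete matrix) and `excluded_ids`
#'   (character vector of removed subjects).
#' @export
impute_cognitive <- function(matrix, max_missing = 5L) {
  m <- as.matrix(matrix)
  if (max_missing >= ncol(m)) {
    stop("max_missing must be smaller than the number of tests")
  }
  ids <- rownames(m)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(m)))
  n_miss <- rowSums(is.na(m))
  drop <- n_miss > max_missing
  excluded <- ids[drop]
  m <- m[!drop, , drop = FALSE]
  col_all_na <- colSums(!is.na(m)) == 0
  if (any(col_all_na)) {
    stop("column(s) entirely missing after exclusion: ",
         paste(colnames(m)[col_all_na], collapse = ", "))
  }
  mu <- colMeans(m, na.rm = TRUE)
  na_idx <- which(is.na(m), arr.ind = TRUE)
  if (nrow(na_idx)) m[na_idx] <- mu[na_idx[, 2]]
  list(values = m, excluded_ids = excluded)
}

#' Principal component analysis of the cognitive battery
#'
#' Correlation-scale PCA (columns standardized to unit variance): returns the
#' loadings, the per-component explained-variance proportions and the
#' per-test contributions to each component, defined as
#' `100 * loading^2 / sum(loading^2)` within the component (the usual
#' factor-map "contribution").
#'
#' @param matrix complete numeric matrix (subjects x tests).
#' @return object of class `cog_pca`: list with `loadings` (tests x K),
#'   `explained_variance` (length K), `contributions` (tests x K, percent),
#'   `center`, `scale`, `scores` (subjects x K) and `test_names`.
#' @export
fit_cognition_pca <- function(matrix) {
  m <- as.matrix(matrix)
  if (anyNA(m)) stop("fit_cognition_pca: matrix contains missing values; impute first")
  if (nrow(m) <= ncol(m)) stop("fit_cognition_pca: need more subjects than tests")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance column(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "))
  }
  pc <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  contrib <- 100 * sweep(pc$rotation^2, 2, colSums(pc$rotation^2), "/")
  structure(list(
    loadings = pc$rotation,
    explained_variance = ev,
    contributions = contrib,
    center = pc$center,
    scale = pc$scale,
    scores = pc$x,
    test_names = colnames(m)
  ), class = "cog_pca")
}

#' @export
print.cog_pca <- function(x, ...) {
  cat("<cog_pca>", length(x$test_names), "tests; PC1 explains",
      sprintf("%.1f%%", 100 * x$explained_variance[1]), "of the variance\n")
  invisible(x)
}

#' Extract the general-cognition factor (g) from a fitted PCA
#'
#' Scores each subject on the first principal component, orients the axis so
#' that it correlates positively with a designated anchor test (by default the
#' achievement-test column, the battery's top PC1 contributor), and
#' standardizes to mean 0, SD 1.
#'
#' @param model a `cog_pca` fit.
#' @param matrix the complete matrix the model was fitted on (or new data on
#'   the same tests).
#' @param anchor_test column name used to fix the sign of g.
#' @return object of class `g_scores`: list with `g` (named standardized
#'   scores) and `anchor_test`.
#' @export
extract_g <- function(model, matrix, anchor_test = "wrat") {
  stopifnot(inherits(model, "cog_pca"))
  m <- as.matrix(matrix)
  if (!anchor_test %in% colnames(m)) {
    stop("anchor_test '", anchor_test, "' not found among test columns")
  }
  ms <- scale(m[, model$test_names, drop = FALSE],
              center = model$center, scale = model$scale)
  g <- drop(ms %*% model$loadings[, 1])
  r <- stats::cor(g, m[, anchor_test])
  if (!is.finite(r) || r == 0) {
    stop("orientation undefined: g is uncorrelated with the anchor test")
  }
  if (r < 0) g <- -g
  g <- (g - mean(g)) / stats::sd(g)
  names(g) <- rownames(m)
  structure(list(g = g, anchor_test = anchor_test), class = "g_scores")
}
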