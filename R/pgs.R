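#' Default grid of GWAS p-value thresholds
#'
#' A uniform grid of `n` thresholds from genome-wide significance (5e-8) to
#' 0.5, matching the dense-thresholding approach in which a polygenic score is
#' computed at every threshold and the resulting score matrix is collapsed by
#' PCA instead of picking one threshold.
#'
#' @param n number of thresholds (default 6002).
#' @return increasing numeric vector of length `n` spanning `[5e-8, 0.5]`.
#' @export
prs_thresholds <- function(n = 6002L) {
  seq(5e-8, 0.5, length.out = n)
}

#' Polygenic score matrix over a threshold grid
#'
#' For each threshold `t`, the score of subject `i` is
#' `sum over SNPs j with p_j <= t of beta_j * dosage_ij`. Columns are nested:
#' raising the threshold only adds SNPs.
#'
#' @param dosages subjects x SNPs numeric matrix with dosages in `[0, 2]`;
#'   column names are SNP ids.
#' @param stats data.frame with columns `snp_id`, `beta`, `p_value`; must
#'   cover every dosage column.
#' @param thresholds increasing vector of p-value thresholds.
#' @return object of class `prs_matrix`: list with `scores` (subjects x T,
#'   columns named by threshold) and `thresholds`.
#' @export
compute_prs_matrix <- function(dosages, stats, thresholds = prs_thresholds()) {
  d <- as.matrix(dosages)
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop("thresholds must be strictly increasing")
  }
  snps <- colnames(d)
  if (is.null(snps)) stop("dosage matrix must have SNP ids as column names")
  missing <- setdiff(snps, stats$snp_id)
  if (length(missing)) {
    stop("SNP(s) in dosages without summary statistics: ",
         paste(utils::head(missing, 10), collapse = ", "),
         if (length(missing) > 10) sprintf(" (and %d more)", length(missing) - 10))
  }
  if (anyDuplicated(stats$snp_id)) stop("duplicate snp_id in summary statistics")
  if (any(stats$p_value <= 0 | stats$p_value > 1)) {
    stop("p_value must lie in (0, 1]")
  }
  st <- stats[match(snps, stats$snp_id), ]
  ord <- order(st$p_value)
  # cumulative weighted-dosage sums over SNPs sorted by p-value
  wd <- sweep(d[, ord, drop = FALSE], 2, st$beta[ord], "*")
  cum <- if (ncol(wd)) t(apply(wd, 1, cumsum)) else wd
  if (nrow(d) == 1) cum <- matrix(cum, nrow = 1)
  k <- findInterval(thresholds, st$p_value[ord])
  scores <- cbind(0, cum)[, k + 1, drop = FALSE]
  if (nrow(d) == 0) scores <- matrix(0, 0, length(thresholds))
  colnames(scores) <- format(thresholds, digits = 6, trim = TRUE)
  rownames(scores) <- rownames(d)
  structure(list(scores = scores, thresholds = thresholds),
            class = "prs_matrix")
}

#' Collapse a polygenic score matrix to its first principal component
#'
#' Centers and scales the threshold columns (constant columns — typically the
#' genome-wide-significance end of the grid when no SNP passes — are dropped
#' with a message) and returns each subject's score on the first principal
#' component together with its explained-variance proportion.
#'
#' @param matrix a `prs_matrix` or plain subjects x thresholds matrix.
#' @return object of class `pgs_component`: list with `score` (length n,
#'   standardized), `explained_variance`, `n_columns_used`.
#' @export
prs_pca <- function(matrix) {
  m <- if (inherits(matrix, "prs_matrix")) matrix$scores else as.matrix(matrix)
  sds <- apply(m, 2, stats::sd)
  keep <- sds > 0
  if (sum(keep) < 2) stop("prs_pca: need at least 2 non-constant columns")
  if (any(!keep)) {
    message("prs_pca: dropping ", sum(!keep), " constant column(s)")
  }
  pc <- stats::prcomp(m[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  score <- pc$x[, 1]
  score <- (score - mean(score)) / stats::sd(score)
  names(score) <- rownames(m)
  structure(list(score = score,
                 explained_variance = pc$sdev[1]^2 / sum(pc$sdev^2),
                 n_columns_used = sum(keep)),
            class = "pgs_component")
}

#' @export
print.pgs_component <- function(x, ...) {
  cat(sprintf("<pgs_component> first PC over %d threshold columns explains %.1f%% of the variance\n",
              x$n_columns_used, 100 * x$explained_variance))
  invisible(x)
}
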