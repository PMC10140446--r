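# Decomposition of ordinal clinical items into independent symptom components.
#
# fit_ica() is a fixed-point (FastICA-style) negentropy-maximizing ICA with
# symmetric decorrelation, wrapped in a restart-clustering scheme: the
# algorithm is run from many seeded starts, estimated components are clustered
# by absolute loading correlation, and each cluster's centrotype is returned
# together with a cluster-compactness stability index (the Icasso recipe).

#' Nearest-neighbor imputation of ordinal clinical items
#'
#' For each subject with missing items, finds the complete-data subject
#' minimizing the mean squared difference over the recipient's observed items
#' (computed on standardized items so that items on different prevalence
#' scales are comparable) and copies that donor's raw values into the missing
#' cells. Subjects with no observed items at all are excluded and reported.
#' Ties are broken by the lowest donor row index. The operation is idempotent.
#'
#' @param items numeric matrix (subjects x items) with `NA` for missing.
#' @return list with `values` (complete matrix) and `excluded_ids`.
#' @export
knn_impute <- function(items) {
  m <- as.matrix(items)
  ids <- rownames(m)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(m)))
  all_missing <- rowSums(!is.na(m)) == 0
  excluded <- ids[all_missing]
  m <- m[!all_missing, , drop = FALSE]
  ids <- ids[!all_missing]

  complete <- which(rowSums(is.na(m)) == 0)
  if (length(complete) == 0) stop("knn_impute: no complete donor row available")
  need <- which(rowSums(is.na(m)) > 0)
  if (length(need)) {
    mu <- colMeans(m, na.rm = TRUE)
    sdv <- apply(m, 2, stats::sd, na.rm = TRUE)
    sdv[sdv == 0 | is.na(sdv)] <- 1
    ms <- sweep(sweep(m, 2, mu), 2, sdv, "/")
    donors <- ms[complete, , drop = FALSE]
    for (i in need) {
      obs <- !is.na(m[i, ])
      # mean squared distance over the recipient's observed items
      diff <- sweep(donors[, obs, drop = FALSE], 2, ms[i, obs])
      d <- rowMeans(diff^2)
      best <- complete[which.min(d)]   # which.min takes the first minimum
      m[i, !obs] <- m[best, !obs]
    }
  }
  rownames(m) <- ids
  list(values = m, excluded_ids = excluded)
}

# one symmetric fixed-point ICA run on whitened data Z (n x k).
# Returns the k x k orthogonal unmixing matrix W with sources S = Z %*% t(W).
fastica_core <- function(Z, W0, max_iter = 200, tol = 1e-6, alpha = 1) {
  n <- nrow(Z)
  sym_decorrelate <- function(W) {
    e <- eigen(W %*% t(W), symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12)),
                       length(e$values)) %*% t(e$vectors) %*% W
  }
  W <- sym_decorrelate(W0)
  for (it in seq_len(max_iter)) {
    U <- Z %*% t(W)                    # n x k projections
    G <- tanh(alpha * U)               # logcosh nonlinearity
    gp <- alpha * colMeans(1 - G^2)
    W1 <- t(G) %*% Z / n - diag(gp, ncol(W)) %*% W
    W1 <- sym_decorrelate(W1)
    delta <- max(abs(abs(rowSums(W1 * W)) - 1))
    W <- W1
    if (delta < tol) break
  }
  list(W = W, iterations = it, converged = delta < tol)
}

#' Independent component analysis with restart-clustering stability
#'
#' Standardizes the item columns, whitens to `k` dimensions by PCA, and runs
#' fixed-point negentropy-maximizing ICA from `n_restarts` seeded random
#' rotations. Components from all runs are matched by the absolute correlation
#' of their item loadings and clustered (average-linkage) into `k` clusters;
#' each cluster's centrotype — the member most correlated with its own
#' cluster — is returned. The stability index per component is the mean
#' within-cluster absolute correlation minus the mean correlation to points
#' outside the cluster (in `[0, 1]` for compact, well-separated clusters).
#'
#' Components are sign-oriented so each component score correlates positively
#' with the sum of its strongly loaded items (positive = more symptoms, since
#' items are coded higher = more symptomatic), and component scores are
#' standardized.
#'
#' @param items complete numeric matrix (subjects x items).
#' @param k number of components (default 7).
#' @param n_restarts number of seeded ICA runs (default 20).
#' @param seed integer seed.
#' @param stability_min clusters with stability index below this are not
#'   counted as stable; fewer than `k` stable clusters is an error.
#' @return object of class `ica_model`: list with `mixing` (items x k),
#'   `unmixing` (k x items), `scores` (subjects x k, standardized),
#'   `stability_index` (length k), `restarts`, `center`, `scale`.
#' @export
fit_ica <- function(items, k = 7L, n_restarts = 20L, seed = 1L,
                    stability_min = 0.5) {
  X <- as.matrix(items)
  if (anyNA(X)) stop("fit_ica: items contain missing values; impute first")
  n <- nrow(X); p <- ncol(X)
  if (n <= 10 * k) stop("fit_ica: need more than 10*k subjects")
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  if (any(sdv == 0)) {
    stop("fit_ica: zero-variance item(s): ",
         paste(colnames(X)[sdv == 0], collapse = ", "))
  }
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")

  # whiten to k dimensions: Z = Xs E_k diag(1/sqrt(lambda_k))
  eg <- eigen(stats::cov(Xs), symmetric = TRUE)
  if (eg$values[k] < 1e-10) stop("fit_ica: data rank below k")
  Ek <- eg$vectors[, seq_len(k), drop = FALSE]
  lam <- eg$values[seq_len(k)]
  Wwhite <- Ek %*% diag(1 / sqrt(lam), k)        # p x k
  Dewhite <- diag(sqrt(lam), k) %*% t(Ek)        # k x p
  Z <- Xs %*% Wwhite

  set.seed(as.integer(seed))
  runs <- vector("list", n_restarts)
  for (r in seq_len(n_restarts)) {
    W0 <- matrix(stats::rnorm(k * k), k)
    runs[[r]] <- fastica_core(Z, W0)$W
  }

  # loadings in item space for every estimated component: A = t(W %*% Dewhite)
  load_all <- do.call(cbind, lapply(runs, function(W) t(W %*% Dewhite)))
  ncomp <- ncol(load_all)                        # k * n_restarts
  sim <- abs(stats::cor(load_all))
  hc <- stats::hclust(stats::as.dist(1 - sim), method = "average")
  cl <- stats::cutree(hc, k = k)

  mixing <- matrix(0, p, k)
  unmix_white <- matrix(0, k, k)                 # rows of W per centrotype
  stab <- numeric(k)
  for (j in seq_len(k)) {
    members <- which(cl == j)
    within <- sim[members, members, drop = FALSE]
    outside <- sim[members, -members, drop = FALSE]
    stab[j] <- mean(within) -
      if (length(outside)) mean(outside) else 0
    cent <- members[which.max(rowMeans(within))]
    run_id <- (cent - 1) %/% k + 1
    row_id <- (cent - 1) %% k + 1
    unmix_white[j, ] <- runs[[run_id]][row_id, ]
    mixing[, j] <- load_all[, cent]
  }
  n_stable <- sum(stab >= stability_min)
  if (n_stable < k) {
    stop("fit_ica: only ", n_stable, " of ", k,
         " component clusters are stable (stability >= ", stability_min, ")")
  }

  S <- Z %*% t(unmix_white)                      # n x k sources
  # sign convention: positive = more symptoms. Items code higher = more
  # symptomatic, so each component is flipped (if needed) so its score
  # correlates positively with the sum of its strongly loaded items
  for (j in seq_len(k)) {
    a <- mixing[, j]
    strong <- abs(a) >= 0.5 * max(abs(a))
    r <- stats::cor(S[, j], rowSums(Xs[, strong, drop = FALSE]))
    if (is.finite(r) && r < 0) {
      S[, j] <- -S[, j]
      mixing[, j] <- -mixing[, j]
      unmix_white[j, ] <- -unmix_white[j, ]
    }
  }
  S <- scale(S)
  colnames(S) <- colnames(mixing) <- sprintf("IC%d", seq_len(k))
  rownames(mixing) <- colnames(X)
  unmixing <- unmix_white %*% t(Wwhite)          # k x p, applies to scaled X
  rownames(unmixing) <- sprintf("IC%d", seq_len(k))

  structure(list(
    mixing = mixing, unmixing = unmixing, scores = S,
    stability_index = stab, restarts = n_restarts,
    center = mu, scale = sdv
  ), class = "ica_model")
}

#' @export
print.ica_model <- function(x, ...) {
  cat("<ica_model>", ncol(x$mixing), "components from", x$restarts,
      "restarts; stability:",
      paste(sprintf("%.2f", x$stability_index), collapse = " "), "\n")
  invisible(x)
}

#' Component scores plus the general-psychopathology proxy
#'
#' Bundles the standardized component scores with their arithmetic row mean,
#' used downstream as a proxy for general psychopathology.
#'
#' @param model an `ica_model`.
#' @return object of class `clinical_components`: list with `scores`
#'   (subjects x k) and `general` (row means).
#' @export
clinical_components <- function(model) {
  stopifnot(inherits(model, "ica_model"))
  s <- model$scores
  structure(list(scores = s, general = general_psychopathology(s)),
            class = "clinical_components")
}

#' General-psychopathology proxy: mean across component scores
#'
#' @param scores subjects x k matrix of component scores.
#' @return numeric vector of row means.
#' @export
general_psychopathology <- function(scores) {
  rowMeans(as.matrix(scores))
}
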