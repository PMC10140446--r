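test_that("knn_impute copies the nearest complete donor's values", {
  m <- rbind(A = c(1, 2, 3), B = c(1, 2, NA), C = c(9, 9, 9))
  res <- knn_impute(m)
  expect_equal(unname(res$values["B", 3]), 3)           # A is nearest on observed dims
  expect_identical(res$excluded_ids, character(0))
  expect_identical(res$values[c("A", "C"), ], m[c("A", "C"), ])

  # identity on complete data, idempotence on imputed data
  expect_identical(knn_impute(res$values)$values, res$values)

  # all-missing rows are excluded and reported
  m2 <- rbind(m, D = c(NA, NA, NA))
  res2 <- knn_impute(m2)
  expect_identical(res2$excluded_ids, "D")
  expect_false("D" %in% rownames(res2$values))

  expect_error(knn_impute(rbind(a = c(1, NA), b = c(NA, 2))),
               "no complete donor")
})

test_that("knn_impute matches a brute-force donor search", {
  set.seed(21)
  m <- matrix(sample(0:2, 30 * 10, replace = TRUE), 30, 10)
  rownames(m) <- paste0("s", 1:30)
  m[cbind(sample(1:15, 10), sample(1:10, 10, replace = TRUE))] <- NA
  res <- knn_impute(m)
  mu <- colMeans(m, na.rm = TRUE)
  sdv <- apply(m, 2, sd, na.rm = TRUE); sdv[sdv == 0] <- 1
  ms <- scale(m, center = mu, scale = sdv)
  complete <- which(rowSums(is.na(m)) == 0)
  for (i in which(rowSums(is.na(m)) > 0)) {
    obs <- which(!is.na(m[i, ]))
    d <- sapply(complete, function(j) mean((ms[j, obs] - ms[i, obs])^2))
    donor <- complete[which.min(d)]
    expect_identical(unname(res$values[i, -obs]), unname(m[donor, -obs]),
                     label = sprintf("row %d donor", i))
  }
})

make_two_source <- function(n = 3000, seed = 31) {
  set.seed(seed)
  S <- cbind(runif(n, -sqrt(3), sqrt(3)), rexp(n) - 1)   # non-Gaussian
  A <- matrix(rnorm(129 * 2), 129, 2)
  X <- S %*% t(A) + matrix(rnorm(n * 129, sd = 0.3), n)
  list(X = X, S = S, A = A)
}

test_that("two non-Gaussian sources are recovered (Amari index)", {
  d <- make_two_source()
  fit <- fit_ica(d$X, k = 2, n_restarts = 8, seed = 41)
  # map unmixing back to raw-item scale for the oracle comparison
  W_raw <- sweep(fit$unmixing, 2, apply(d$X, 2, sd), "/")
  expect_lt(amari_index(W_raw, d$A), 0.05)
  expect_true(all(fit$stability_index > 0.9))
  # recovered scores match the true sources up to permutation
  r <- abs(cor(fit$scores, d$S))
  expect_true(all(apply(r, 1, max) > 0.95))
})

test_that("component scores are standardized and k components are returned", {
  d <- make_two_source(n = 1200, seed = 51)
  fit <- fit_ica(d$X, k = 2, n_restarts = 6, seed = 52)
  expect_identical(ncol(fit$mixing), 2L)
  expect_equal(unname(colMeans(fit$scores)), c(0, 0), tolerance = 1e-6)
  expect_equal(unname(apply(fit$scores, 2, sd)), c(1, 1), tolerance = 1e-6)
  # sign convention: positive correlation with the strongly loaded item sum
  Xs <- scale(d$X)
  for (j in 1:2) {
    strong <- abs(fit$mixing[, j]) >= 0.5 * max(abs(fit$mixing[, j]))
    expect_gt(cor(fit$scores[, j], rowSums(Xs[, strong, drop = FALSE])), 0)
  }
})

test_that("default cohort decomposes into 7 components recovering the truth", {
  co <- generate_cohort(cohort_config(n_subjects = 2500, n_snps = 2,
                                      cognitive_missing_rate = 0,
                                      item_missing_rate = 0.02, seed = 61))
  imp <- knn_impute(co$clinical_items)
  fit <- fit_ica(imp$values, k = 7, n_restarts = 10, seed = 62)
  expect_identical(ncol(fit$scores), 7L)
  truth <- as.matrix(co$truth[, paste0("factor_", 1:7)])
  r <- abs(cor(fit$scores, truth))
  # each recovered component matches a distinct truth factor
  best <- apply(r, 1, which.max)
  hits <- apply(r, 1, max) >= 0.7
  expect_gte(sum(hits), 6)
  expect_gte(length(unique(best[hits])), 6)
  # orientation: matched components point toward more symptoms, i.e. they
  # correlate positively with their truth factor (items load positively)
  rs <- cor(fit$scores, truth)
  for (j in which(hits)) expect_gt(rs[j, best[j]], 0)
})

test_that("general psychopathology is the arithmetic row mean", {
  s <- rbind(a = rep(0, 7), b = 1:7)
  expect_equal(unname(general_psychopathology(s)), c(0, 4))
  d <- make_two_source(n = 1200, seed = 71)
  comp <- clinical_components(fit_ica(d$X, k = 2, n_restarts = 6, seed = 72))
  expect_equal(comp$general, rowMeans(comp$scores))
})

test_that("fit_ica rejects degenerate input", {
  d <- make_two_source(n = 500, seed = 81)
  X <- d$X; X[3, 7] <- NA
  expect_error(fit_ica(X, k = 2), "missing")
  expect_error(fit_ica(d$X[1:15, ], k = 2), "10\\*k")
  Xc <- d$X; Xc[, 5] <- 1
  expect_error(fit_ica(Xc, k = 2, n_restarts = 2, seed = 1), "zero-variance")
})
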