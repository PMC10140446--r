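# Gaussian-process normative model of g on (age, sex).
#
# Kernel: k(x, x') = s2 * exp(-(a - a')^2 / (2 l^2)) + v2 * sex * sex' + n2 * I
# with age standardized internally. Hyperparameters are optimized on the exact
# log marginal likelihood (L-BFGS-B on log parameters, analytic gradients,
# multiple seeded restarts). A small fixed jitter keeps Cholesky factorizations
# stable independently of the fitted noise level.

GP_JITTER <- 1e-8

gp_kernel <- function(age1, sex1, age2, sex2, hp, diag_noise = FALSE) {
  d2 <- outer(age1, age2, "-")^2
  K <- hp["s2"] * exp(-0.5 * d2 / hp["l"]^2) + hp["v2"] * outer(sex1, sex2)
  if (diag_noise) K <- K + diag(hp["n2"] + GP_JITTER, nrow(K))
  K
}

# negative log marginal likelihood and gradient wrt log hyperparameters;
# shares one Cholesky between value and gradient via a closure cache
gp_nlml_factory <- function(age, sex, y) {
  n <- length(y)
  d2 <- outer(age, age, "-")^2
  ss <- outer(sex, sex)
  cache <- new.env(parent = emptyenv())
  cache$par <- NULL

  compute <- function(lp) {
    hp <- exp(lp)
    names(hp) <- c("s2", "l", "v2", "n2")
    Krbf <- hp["s2"] * exp(-0.5 * d2 / hp["l"]^2)
    K <- Krbf + hp["v2"] * ss + diag(hp["n2"] + GP_JITTER, n)
    ch <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(ch)) {
      return(list(value = 1e10, grad = rep(0, 4)))
    }
    alpha <- backsolve(ch, backsolve(ch, y, transpose = TRUE))
    nlml <- 0.5 * sum(y * alpha) + sum(log(diag(ch))) + 0.5 * n * log(2 * pi)
    Kinv <- chol2inv(ch)
    # d(nlml)/d(theta) = -0.5 tr((alpha alpha' - Kinv) dK/dtheta)
    A <- tcrossprod(alpha) - Kinv
    g <- c(
      s2 = -0.5 * sum(A * Krbf),
      l  = -0.5 * sum(A * (Krbf * d2 / hp["l"]^2)),
      v2 = -0.5 * sum(A * ss) * hp["v2"],
      n2 = -0.5 * sum(diag(A)) * hp["n2"]
    )
    list(value = as.numeric(nlml), grad = g)
  }
  get <- function(lp) {
    if (is.null(cache$par) || !identical(cache$par, lp)) {
      cache$res <- compute(lp)
      cache$par <- lp
    }
    cache$res
  }
  list(fn = function(lp) get(lp)$value,
       gr = function(lp) get(lp)$grad)
}

#' Fit the Gaussian-process normative model
#'
#' Regresses a target (the general-cognition factor) on age and sex with a
#' squared-exponential kernel over standardized age, a linear kernel over sex
#' and additive white noise. Hyperparameters `(signal variance, length-scale,
#' sex variance, noise variance)` maximize the log marginal likelihood from
#' `n_restarts` seeded starting points; the best restart is kept.
#'
#' For training sets larger than `max_opt_n`, hyperparameters are optimized on
#' a seeded subsample of that size (prediction still conditions on the full
#' training set); this bounds the cubic cost of the optimizer at large n.
#'
#' @param covariates two-column matrix or data.frame `(age, sex)`; sex coded
#'   0/1.
#' @param targets numeric vector, same length as rows of `covariates`.
#' @param n_restarts number of optimizer restarts (>= 1).
#' @param seed integer seed for the restart draws and subsample.
#' @param max_opt_n optimizer subsample cap.
#' @param init optional length-4 vector of log hyperparameters used as the
#'   first restart (warm start).
#' @return object of class `normative_gp` with elements `hyperparams`
#'   (named: s2, l, v2, n2 on the original scale), `age_center`, `age_scale`,
#'   `y_mean`, `train` (covariates/targets), `optimizer_trace` (per-restart
#'   convergence record) and cached Cholesky factors for prediction.
#' @export
fit_gp <- function(covariates, targets, n_restarts = 3L, seed = 1L,
                   max_opt_n = 2000L, init = NULL) {
  cv <- as.matrix(covariates)
  if (ncol(cv) != 2) stop("fit_gp: covariates must have exactly 2 columns (age, sex)")
  age_raw <- as.numeric(cv[, 1]); sex <- as.numeric(cv[, 2])
  y_raw <- as.numeric(targets)
  n <- length(y_raw)
  if (n < 20) stop("fit_gp: need at least 20 observations")
  if (!all(is.finite(age_raw)) || !all(is.finite(y_raw))) {
    stop("fit_gp: non-finite covariates or targets")
  }
  if (!all(sex %in% c(0, 1))) stop("fit_gp: sex must be coded 0/1")

  age_center <- mean(age_raw); age_scale <- stats::sd(age_raw)
  if (age_scale == 0) age_scale <- 1
  age <- (age_raw - age_center) / age_scale
  y_mean <- mean(y_raw)
  y <- y_raw - y_mean
  vy <- stats::var(y)

  set.seed(as.integer(seed))
  idx <- seq_len(n)
  if (n > max_opt_n) idx <- sort(sample.int(n, max_opt_n))
  fac <- gp_nlml_factory(age[idx], sex[idx], y[idx])

  # n_restarts counts total starting points: the warm start (when given),
  # then a deterministic default, then seeded log-uniform draws
  starts <- list()
  if (!is.null(init)) starts[[length(starts) + 1]] <- init
  if (length(starts) < n_restarts) {
    starts[[length(starts) + 1]] <-
      log(c(s2 = max(vy, 1e-3), l = 1, v2 = 0.1 * max(vy, 1e-3),
            n2 = 0.5 * max(vy, 1e-3)))
  }
  while (length(starts) < n_restarts) {
    starts[[length(starts) + 1]] <- stats::runif(4, log(1e-4), log(10))
  }

  trace <- list(); best <- NULL
  for (i in seq_along(starts)) {
    fit <- tryCatch(
      stats::optim(starts[[i]], fn = fac$fn, gr = fac$gr,
                   method = "L-BFGS-B", lower = log(1e-10), upper = log(1e4),
                   control = list(maxit = 200)),
      error = function(e) NULL)
    ok <- !is.null(fit) && is.finite(fit$value) && fit$value < 1e9
    trace[[i]] <- list(start = unname(starts[[i]]),
                       value = if (ok) fit$value else NA_real_,
                       converged = ok && fit$convergence %in% c(0, 1))
    if (ok && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) {
    stop("fit_gp: optimizer failed on all restarts; trace: ",
         paste(vapply(trace, function(t) format(t$value), ""), collapse = ", "))
  }
  hp <- exp(best$par)
  names(hp) <- c("s2", "l", "v2", "n2")

  K <- gp_kernel(age, sex, age, sex, hp, diag_noise = TRUE)
  ch <- chol(K)
  alpha <- backsolve(ch, backsolve(ch, y, transpose = TRUE))

  structure(list(
    hyperparams = hp,
    age_center = age_center, age_scale = age_scale, y_mean = y_mean,
    train = list(age = age, sex = sex, y = y),
    chol = ch, alpha = alpha,
    nlml = best$value,
    optimizer_trace = trace
  ), class = "normative_gp")
}

#' @export
print.normative_gp <- function(x, ...) {
  hp <- x$hyperparams
  cat(sprintf(
    "<normative_gp> n=%d  signal var=%.3g  length-scale=%.3g (std-age units)  sex var=%.3g  noise var=%.3g\n",
    length(x$train$y), hp["s2"], hp["l"], hp["v2"], hp["n2"]))
  invisible(x)
}

#' Posterior predictive distribution of a fitted normative GP
#'
#' Standard GP posterior predictive mean and SD at new `(age, sex)` points.
#' The predictive SD includes the fitted noise variance, so it is the
#' uncertainty of a new observation — the scale on which deviation z-scores
#' are defined.
#'
#' @param model a `normative_gp`.
#' @param covariates m x 2 matrix `(age, sex)`; zero rows allowed.
#' @return list with numeric vectors `mean` and `sd` of length m.
#' @export
predict_gp <- function(model, covariates) {
  stopifnot(inherits(model, "normative_gp"))
  cv <- as.matrix(covariates)
  if (nrow(cv) == 0) return(list(mean = numeric(0), sd = numeric(0)))
  if (ncol(cv) != 2) stop("predict_gp: covariates must have 2 columns")
  if (!all(is.finite(cv))) stop("predict_gp: non-finite covariates")
  age <- (as.numeric(cv[, 1]) - model$age_center) / model$age_scale
  sex <- as.numeric(cv[, 2])
  hp <- model$hyperparams
  Ks <- gp_kernel(age, sex, model$train$age, model$train$sex, hp)
  mu <- model$y_mean + drop(Ks %*% model$alpha)
  V <- backsolve(model$chol, t(Ks), transpose = TRUE)
  kss <- hp["s2"] + hp["v2"] * sex^2
  var_f <- pmax(kss - colSums(V^2), 0)
  list(mean = mu, sd = sqrt(var_f + hp["n2"]))
}

#' Pooled out-of-sample fit metrics for a normative model
#'
#' Given observed targets and per-subject out-of-sample predictive means and
#' SDs, computes explained variance `EV = 1 - SSE/SST` (SST about the overall
#' target mean), `RMSE`, `SMSE = MSE / var(targets)` and the mean standardized
#' log loss `MSLL`: the mean negative log predictive density minus the mean
#' negative log density under a per-fold baseline Gaussian fitted to that
#' fold's *training* targets. A model no better than the trivial
#' mean-and-variance predictor has MSLL near 0; negative is better.
#'
#' @param y observed targets.
#' @param mean,sd out-of-sample predictive means and SDs.
#' @param fold_id integer fold labels per subject.
#' @param baseline data.frame with columns `fold_id`, `mean`, `sd`: the
#'   Gaussian fitted to each fold's training targets.
#' @return list with `explained_variance`, `msll`, `rmse`, `smse`.
#' @export
deviation_metrics <- function(y, mean, sd, fold_id, baseline) {
  err2 <- (y - mean)^2
  sse <- sum(err2)
  sst <- sum((y - base::mean(y))^2)
  mse <- base::mean(err2)
  b <- baseline[match(fold_id, baseline$fold_id), ]
  nlpd_model <- -stats::dnorm(y, mean, sd, log = TRUE)
  nlpd_base <- -stats::dnorm(y, b$mean, b$sd, log = TRUE)
  list(explained_variance = 1 - sse / sst,
       msll = base::mean(nlpd_model - nlpd_base),
       rmse = sqrt(mse),
       smse = mse / stats::var(y))
}

#' Deviation z-scores under k-fold cross-validated normative modeling
#'
#' Partitions subjects into `k` seeded equal-size folds, fits the GP on each
#' training split, scores the held-out fold, and returns per-subject deviation
#' z-scores `z = (observed - predicted mean) / predictive SD` together with
#' pooled out-of-sample fit metrics. Every subject is scored exactly once, by
#' the model that never saw it.
#'
#' Folds after the first warm-start the optimizer from the first fold's
#' optimum (plus fresh restarts), which speeds convergence without sharing any
#' data across folds.
#'
#' @inheritParams fit_gp
#' @param k number of folds (default 10).
#' @return object of class `deviation_scores`: list with `z`, `fold_id`,
#'   `predicted_mean`, `predicted_sd`, `metrics` (see [deviation_metrics()])
#'   and `models` (the per-fold hyperparameters).
#' @export
crossval_normative <- function(covariates, targets, k = 10L, seed = 1L,
                               n_restarts = 3L, max_opt_n = 2000L) {
  cv <- as.matrix(covariates)
  y <- as.numeric(targets)
  n <- length(y)
  if (k < 2) stop("crossval_normative: k must be >= 2")
  if (n < 10 * k) stop("crossval_normative: need at least 10*k observations")
  set.seed(as.integer(seed))
  fold <- sample(rep(seq_len(k), length.out = n))

  mu <- sdv <- numeric(n)
  baseline <- data.frame(fold_id = seq_len(k), mean = NA_real_, sd = NA_real_)
  hps <- vector("list", k)
  warm <- NULL
  for (f in seq_len(k)) {
    tr <- fold != f
    # fold 1 runs the full restart schedule; later folds start from its
    # optimum plus the deterministic default (their optima are near-identical)
    m <- fit_gp(cv[tr, , drop = FALSE], y[tr],
                n_restarts = if (f == 1) n_restarts else min(n_restarts, 2L),
                seed = seed + f,
                max_opt_n = max_opt_n, init = warm)
    if (f == 1) warm <- log(m$hyperparams)
    pr <- predict_gp(m, cv[!tr, , drop = FALSE])
    mu[!tr] <- pr$mean
    sdv[!tr] <- pr$sd
    baseline$mean[f] <- mean(y[tr])
    baseline$sd[f] <- stats::sd(y[tr])
    hps[[f]] <- m$hyperparams
  }
  z <- (y - mu) / sdv
  structure(list(
    z = z, fold_id = fold, predicted_mean = mu, predicted_sd = sdv,
    metrics = deviation_metrics(y, mu, sdv, fold, baseline),
    models = hps
  ), class = "deviation_scores")
}

#' @export
print.deviation_scores <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "<deviation_scores> n=%d  EV=%.3f  MSLL=%.3f  RMSE=%.3f  SMSE=%.3f\n",
    length(x$z), m$explained_variance, m$msll, m$rmse, m$smse))
  invisible(x)
}

#' Plot the normative trajectory with predictive bands
#'
#' Draws the fitted mean and +/-1, +/-2 predictive-SD bands against age for
#' each sex, with the observed targets overplotted.
#'
#' @param model a `normative_gp`.
#' @param covariates,targets the data to overplot (typically the training
#'   set).
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the grid used for the curves.
#' @export
plot_normative_trajectory <- function(model, covariates, targets, ...) {
  cv <- as.matrix(covariates)
  ages <- seq(min(cv[, 1]), max(cv[, 1]), length.out = 100)
  graphics::plot(cv[, 1], targets, pch = 16, cex = 0.3,
                 col = grDevices::grey(0.6, 0.4),
                 xlab = "age (years)", ylab = "g", ...)
  cols <- c("#1b6ca8", "#c0392b")
  grid <- list()
  for (s in 0:1) {
    pr <- predict_gp(model, cbind(ages, s))
    graphics::lines(ages, pr$mean, col = cols[s + 1], lwd = 2)
    for (w in c(1, 2)) {
      graphics::lines(ages, pr$mean + w * pr$sd, col = cols[s + 1], lty = 2)
      graphics::lines(ages, pr$mean - w * pr$sd, col = cols[s + 1], lty = 2)
    }
    grid[[s + 1]] <- data.frame(age = ages, sex = s,
                                mean = pr$mean, sd = pr$sd)
  }
  graphics::legend("bottomright", legend = c("sex=0", "sex=1"),
                   col = cols, lwd = 2, bty = "n")
  invisible(do.call(rbind, grid))
}
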