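# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# Amari index between a true mixing matrix A (p x k) and an estimated
# unmixing W (k x p): permutation- and scale-invariant, 0 = perfect recovery.
amari_index <- function(W, A) {
  P <- abs(W %*% A)
  k <- nrow(P)
  r <- sum(rowSums(P / apply(P, 1, max)) - 1)
  c <- sum(colSums(sweep(P, 2, apply(P, 2, max), "/")) - 1)
  (r + c) / (2 * k * (k - 1))
}

# brute-force correlation-PCA explained variances via eigen()
eigen_ev_oracle <- function(m) {
  ev <- eigen(stats::cor(m), symmetric = TRUE, only.values = TRUE)$values
  ev / sum(ev)
}

# naive GP posterior via a dense direct solve (no Cholesky reuse)
gp_posterior_oracle <- function(age_tr, sex_tr, y, age_te, sex_te, hp,
                                y_mean = mean(y)) {
  k <- function(a1, s1, a2, s2) {
    hp["s2"] * exp(-0.5 * outer(a1, a2, "-")^2 / hp["l"]^2) +
      hp["v2"] * outer(s1, s2)
  }
  K <- k(age_tr, sex_tr, age_tr, sex_tr) +
    diag(hp["n2"] + 1e-8, length(y))
  Ks <- k(age_te, sex_te, age_tr, sex_tr)
  Kss <- k(age_te, sex_te, age_te, sex_te)
  Kinv <- solve(K)
  mu <- y_mean + drop(Ks %*% Kinv %*% (y - y_mean))
  V <- Kss - Ks %*% Kinv %*% t(Ks)
  list(mean = mu, sd = sqrt(pmax(diag(V), 0) + hp["n2"]))
}

# brute-force Savage-Dickey BF01 for a single-predictor linear model by 2-D
# grid integration over (beta, sigma), prior beta ~ N(0, prior_sd^2) and
# Jeffreys p(sigma) ~ 1/sigma. BF01 = p(y | beta = 0) / p(y).
bf01_grid_oracle <- function(y, x, prior_sd = 0.5,
                             n_beta = 601, n_sigma = 301) {
  y <- (y - mean(y)) / stats::sd(y)
  x <- (x - mean(x)) / stats::sd(x)
  n <- length(y)
  betas <- seq(-4 * prior_sd, 4 * prior_sd, length.out = n_beta)
  sigmas <- exp(seq(log(0.05), log(5), length.out = n_sigma))
  yty <- sum(y^2); xty <- sum(x * y); xtx <- sum(x^2)
  rss <- yty - 2 * betas * xty + betas^2 * xtx      # residual SS per beta
  # log joint over the (beta, log sigma) grid; integration over log sigma
  # makes the Jeffreys 1/sigma prior an unweighted sum
  lj <- outer(-rss / 2, 1 / sigmas^2) +
    matrix(rep(-n * log(sigmas), each = n_beta), n_beta) +
    stats::dnorm(betas, 0, prior_sd, log = TRUE)
  lse <- function(v) {
    m <- max(v)
    m + log(sum(exp(v - m)))
  }
  db <- diff(betas[1:2]); dls <- diff(log(sigmas[1:2]))
  log_marg <- lse(as.vector(lj)) + log(db) + log(dls)
  l0 <- -yty / (2 * sigmas^2) - n * log(sigmas)
  log_null <- lse(l0) + log(dls)
  # BF01 = p(y | beta = 0) / p(y): the prior density at 0 cancels out of the
  # Savage-Dickey ratio
  exp(log_null - log_marg)
}

# config-implied corr(g, age) for ages U(lo, hi), g = a + b log(age) + c sex
# + eps, by dense numeric integration
implied_cor_g_age <- function(cfg) {
  lo <- cfg$age_range[1]; hi <- cfg$age_range[2]
  a <- seq(lo, hi, length.out = 20001)
  f <- cfg$g_growth[2] * log(a)
  cov_fa <- mean(f * a) - mean(f) * mean(a)
  var_a <- mean(a^2) - mean(a)^2
  pf <- cfg$female_fraction
  var_g <- (mean(f^2) - mean(f)^2) +
    cfg$g_growth[3]^2 * pf * (1 - pf) + cfg$residual_sd[1]^2
  cov_fa / sqrt(var_a * var_g)
}

# two columns with an exact given sample correlation (for PCA closed forms)
make_cor_pair <- function(n, r, seed = 1) {
  set.seed(seed)
  x <- stats::rnorm(n)
  e <- stats::rnorm(n)
  x <- (x - mean(x)) / stats::sd(x)
  e <- stats::residuals(stats::lm(e ~ x))
  e <- (e - mean(e)) / stats::sd(e)
  cbind(a = x, b = r * x + sqrt(1 - r^2) * e)
}
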