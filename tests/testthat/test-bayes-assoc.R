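test_that("standardize: hand case, idempotence, degenerate input", {
  expect_equal(standardize(c(1, 2, 3)), c(-1, 0, 1))
  z <- standardize(rnorm(50))
  expect_equal(standardize(z), z, tolerance = 1e-12)
  expect_error(standardize(rep(2, 10)), "constant")
})

test_that("conjugate closed form with known sigma", {
  # single centered predictor engineered so X'X = 100 and X'y = 18.2
  x <- c(rep(sqrt(100 / 8), 4), rep(-sqrt(100 / 8), 4))
  y <- 18.2 * x / 100 + c(1, -1, 1, -1, 1, -1, 1, -1) * 0.3
  y <- y - mean(y)
  y <- y + (18.2 - sum(x * y)) * x / 100   # adjust to exact X'y
  expect_equal(sum(x * x), 100)
  expect_equal(sum(x * y), 18.2)
  fit <- fit_bayes_linear(y, cbind(b = x), prior_sd = 0.5,
                          standardize = FALSE, sigma = 1)
  expect_equal(unname(fit$beta_mean), 18.2 / 104, tolerance = 1e-10)
  expect_equal(unname(fit$beta_sd), sqrt(1 / 104), tolerance = 1e-10)
  expect_lt(fit$ci95[1, 1], fit$ci95[1, 2])
})

test_that("the shrinkage prior always pulls toward zero", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 40
    X <- cbind(a = rnorm(n), b = rnorm(n))
    y <- 0.4 * X[, 1] + rnorm(n)
    fit <- fit_bayes_linear(y, X)
    ols <- coef(lm(standardize(y) ~ apply(X, 2, standardize) - 1))
    expect_true(all(abs(fit$beta_mean) <= abs(ols) + 1e-12),
                label = paste("seed", seed))
  }
})

test_that("null predictor at large n gives a near-zero posterior mean", {
  set.seed(201)
  n <- 5000
  X <- cbind(predictor = rnorm(n), age = runif(n), sex = rbinom(n, 1, 0.5))
  y <- 0.3 * X[, "age"] + rnorm(n)
  fit <- fit_bayes_linear(y, X)
  expect_lt(abs(fit$beta_mean["predictor"]), 0.03)
  expect_error(fit_bayes_linear(y[1:4], X[1:4, ]), "n >")
  expect_error(fit_bayes_linear(y, cbind(X, X[, 1])), "singular")
})

test_that("Savage-Dickey closed forms", {
  # posterior identical to the prior -> BF01 = 1 exactly
  prior_like <- list(beta_mean = 0, beta_sd = 0.5, prior_sd = 0.5)
  expect_identical(savage_dickey(prior_like)$bf01, 1)
  expect_identical(savage_dickey(prior_like)$category, "equipoise")
  # posterior N(0, 0.25) vs prior N(0, 0.5): ratio of densities at 0 = 2
  expect_equal(savage_dickey(list(beta_mean = 0, beta_sd = 0.25),
                             prior_sd = 0.5)$bf01, 2, tolerance = 1e-12)
  # posterior N(1, 0.1): astronomically small BF01, extreme evidence
  bf <- savage_dickey(list(beta_mean = 1, beta_sd = 0.1), prior_sd = 0.5)
  expect_lt(bf$bf01, 1e-15)
  expect_identical(bf$category, "extreme (alternative)")
  expect_error(savage_dickey(list(beta_mean = 0, beta_sd = 0),
                             prior_sd = 0.5), "posterior SD")
})

test_that("evidence categories follow the printed scale", {
  expect_identical(categorize_bf(19.37), "strong (null)")
  expect_identical(categorize_bf(2.654), "anecdotal (null)")
  expect_identical(categorize_bf(0.002), "extreme (alternative)")
  expect_identical(categorize_bf(0.5), "anecdotal (alternative)")
  expect_identical(categorize_bf(0.15), "moderate (alternative)")
  expect_identical(categorize_bf(0.05), "strong (alternative)")
  expect_identical(categorize_bf(0.02), "very strong (alternative)")
  expect_identical(categorize_bf(5), "moderate (null)")
  expect_identical(categorize_bf(50), "very strong (null)")
  expect_identical(categorize_bf(200), "extreme (null)")
  expect_error(categorize_bf(-1), "> 0")
})

test_that("BF01 is strictly decreasing in |posterior mean| at fixed SD", {
  means <- seq(0, 1, by = 0.05)
  bfs <- sapply(means, function(m) {
    savage_dickey(list(beta_mean = m, beta_sd = 0.1), prior_sd = 0.5)$bf01
  })
  expect_true(all(diff(bfs) < 0))
})

test_that("analytic BF01 agrees with the grid-integration oracle", {
  # smaller version of the acceptance sweep: 5 seeded n=50 datasets
  for (seed in 1:5) {
    set.seed(seed + 300)
    x <- rnorm(50)
    y <- runif(1, -0.4, 0.4) * x + rnorm(50)
    fit <- fit_bayes_linear(y, cbind(b = x))
    bf <- savage_dickey(fit, "b")$bf01
    orc <- bf01_grid_oracle(y, x)
    expect_lt(abs(bf - orc) / orc, 0.05, label = paste("seed", seed))
  }
})

test_that("association table carries the generated sign convention", {
  # higher symptom load generated with poorer-than-expected cognition
  set.seed(401)
  n <- 4000
  resid <- rnorm(n)                     # z: higher = better than expected
  symptom <- -0.17 * resid + sqrt(1 - 0.17^2) * (rexp(n) - 1)
  age <- runif(n, 8, 21); sex <- rbinom(n, 1, 0.5)
  assoc <- associate_deviations(resid, data.frame(symptom = symptom),
                                age, sex)
  expect_identical(nrow(assoc), 1L)
  expect_lt(assoc$beta_mean, -0.1)
  expect_lt(assoc$bf01, 0.01)
  expect_identical(assoc$category, "extreme (alternative)")
  expect_named(assoc, c("predictor", "beta_mean", "beta_sd", "ci_low",
                        "ci_high", "bf01", "category"))
})
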