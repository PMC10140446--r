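test_that("empty and deterministic cohorts", {
  cfg <- cohort_config(n_subjects = 0, n_snps = 5, seed = 7)
  co <- generate_cohort(cfg)
  expect_identical(nrow(co$demographics), 0L)
  expect_identical(nrow(co$cognition), 0L)
  expect_identical(nrow(co$clinical_items), 0L)
  expect_identical(nrow(co$genotypes), 0L)
  expect_identical(nrow(co$truth), 0L)

  cfg2 <- cohort_config(n_subjects = 120, n_snps = 50, seed = 11)
  expect_identical(generate_cohort(cfg2), generate_cohort(cfg2))
})

test_that("config validation rejects bad values", {
  expect_error(cohort_config(age_range = c(21, 8)), "min < max")
  expect_error(cohort_config(female_fraction = 1.2), "proportions")
  expect_error(cohort_config(g_growth = c(0, NA, 0)), "non-finite")
  expect_error(cohort_config(symptom_effect = rep(1.5, 7)), "symptom_effect")
})

test_that("noise-free cohorts are strictly monotone in age within sex", {
  cfg <- cohort_config(n_subjects = 300, residual_sd = c(0, 0),
                       test_noise_sd = rep(0, 17),
                       cognitive_missing_rate = 0, item_missing_rate = 0,
                       seed = 5)
  co <- generate_cohort(cfg)
  for (s in 0:1) {
    sel <- co$demographics$sex == s
    ord <- order(co$demographics$age[sel])
    for (j in c(1, 9, 17)) {
      expect_true(all(diff(co$cognition[sel, j][ord]) > 0),
                  label = sprintf("test %d strictly increasing, sex %d", j, s))
    }
  }
})

test_that("default cohort matches the stated world", {
  co <- generate_cohort(cohort_config(n_snps = 10, seed = 2))
  expect_identical(nrow(co$demographics), 6481L)
  expect_true(all(co$demographics$age >= 8 & co$demographics$age <= 21))
  expect_identical(ncol(co$cognition), 17L)
  expect_identical(ncol(co$clinical_items), 129L)
  expect_true(all(co$genotypes >= 0 & co$genotypes <= 2, na.rm = TRUE))
  expect_true(all(co$summary_stats$p_value > 0 & co$summary_stats$p_value <= 1))
  expect_true(all(co$clinical_items %in% c(0:2, NA)))
})

test_that("marginal and effect-size calibration", {
  cfg <- cohort_config(n_subjects = 6000, n_snps = 5,
                       cognitive_missing_rate = 0, item_missing_rate = 0,
                       seed = 13)
  co <- generate_cohort(cfg)
  expect_lt(abs(cor(co$truth$g, co$demographics$age) - implied_cor_g_age(cfg)),
            0.05)
  for (k in seq_along(cfg$symptom_effect)) {
    r <- cor(co$truth[[paste0("factor_", k)]],
             scale(co$truth$g_resid)[, 1])
    expect_lt(abs(r - cfg$symptom_effect[k]), 0.04,
              label = sprintf("factor %d effect", k))
  }
})

test_that("inject_missingness hits the requested rates and leaves truth intact", {
  cfg <- cohort_config(n_subjects = 6481, n_snps = 5,
                       cognitive_missing_rate = 0, item_missing_rate = 0,
                       seed = 17)
  co <- generate_cohort(cfg)
  expect_identical(inject_missingness(co, 0, 0, seed = 1), co)

  co2 <- inject_missingness(co, cognitive_rate = 0.025, item_rate = 0.07,
                            seed = 19)
  expect_lt(abs(mean(is.na(co2$cognition)) - 0.025), 0.005)
  per_item <- colMeans(is.na(co2$clinical_items))
  expect_true(all(per_item <= 0.10))
  expect_identical(co2$truth, co$truth)
  obs <- !is.na(co2$cognition)
  expect_identical(co2$cognition[obs], co$cognition[obs])

  expect_error(inject_missingness(co, cognitive_rate = 1), "\\[0, 1\\)")
})

test_that("cohort TSV round trip preserves the blocks", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(cohort_config(n_subjects = 40, n_snps = 8, seed = 23))
  write_cohort(co, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "demographics.tsv", "cognition.tsv", "clinical_items.tsv",
    "genotypes.tsv", "summary_stats.tsv", "truth.tsv", "config.yaml")))))
  back <- read_cohort(dir)
  expect_equal(back$demographics$age, co$demographics$age, tolerance = 1e-10)
  expect_equal(unname(back$cognition), unname(co$cognition), tolerance = 1e-10)
  expect_identical(unname(is.na(back$cognition)), unname(is.na(co$cognition)))
  expect_equal(unname(back$genotypes), unname(co$genotypes))
})
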