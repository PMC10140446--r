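#' Configuration for a synthetic developmental cohort
#'
#' Builds the full parameter set for [generate_cohort()]. Defaults describe a
#' cohort of 6481 youths aged 8-21 with a latent general-cognition factor `g`
#' that improves with (log) age, a small sex offset and heteroscedastic
#' residuals; 17 test scores loading on `g`; 129 ordinal clinical items driven
#' by 7 latent symptom factors whose correlations with the age-adjusted `g`
#' residual are small (|r| around 0.1-0.2); and independent SNP dosages with a
#' null GWAS summary-statistics table.
#'
#' @param n_subjects number of subjects.
#' @param age_range numeric length-2, min < max, in years.
#' @param female_fraction probability that `sex == 1` (female).
#' @param g_growth numeric length-3 `(intercept, log-age slope, sex offset)`
#'   for the latent mean `a + b*log(age) + c*sex`, on the standardized g scale.
#' @param residual_sd numeric length-2 `(base, slope)`: residual SD of `g` at
#'   age `a` is `base + slope * (a - mean(age_range))`; slope 0 gives a
#'   homoscedastic cohort.
#' @param n_tests number of cognitive scores (default 17: 16 battery scores
#'   plus a WRAT-like achievement score used as the orientation anchor).
#' @param test_loadings length-`n_tests` loadings of each test on standardized
#'   latent g; defaults decay from 0.72 so the first (anchor) test contributes
#'   most to PC1 and PC1 explains roughly a third of the battery variance.
#' @param test_noise_sd length-`n_tests` specific-noise SDs; default
#'   `sqrt(1 - test_loadings^2)` so each test has unit variance.
#' @param cognitive_missing_rate per-cell MCAR rate for the cognitive block.
#' @param n_items number of ordinal clinical items.
#' @param item_loadings `n_items x 7` sparse loading matrix; default assigns
#'   each item a 0.8 loading on one of the 7 symptom factors, in contiguous
#'   blocks.
#' @param item_levels number of ordinal levels per item (default 3).
#' @param item_cut_quantiles cumulative probabilities cutting the latent item
#'   score into levels; defaults `c(0.7, 0.9)` emulate rare symptom
#'   endorsement (70% score 0, 20% score 1, 10% score 2).
#' @param item_missing_rate per-cell MCAR rate for the clinical block.
#' @param symptom_effect length-7 standardized correlations between each
#'   latent symptom factor and the g residual. Convention: higher z = better
#'   than expected cognition, higher symptom score = more symptoms, so the
#'   domains associated with poorer performance carry negative values.
#' @param n_snps number of independent SNPs.
#' @param maf_range minor-allele-frequency range for simulated dosages.
#' @param seed integer seed; fully determines the cohort.
#' @return an object of class `cohort_config` (a validated list).
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_subjects = 6481,
                          age_range = c(8, 21),
                          female_fraction = 3377 / 6481,
                          g_growth = c(intercept = -5.27,
                                       log_age_slope = 2.0,
                                       sex_offset = 0.2),
                          residual_sd = c(base = 0.53, slope = 0),
                          n_tests = 17,
                          test_loadings = NULL,
                          test_noise_sd = NULL,
                          cognitive_missing_rate = 0.01,
                          n_items = 129,
                          item_loadings = NULL,
                          item_levels = 3,
                          item_cut_quantiles = c(0.7, 0.9),
                          item_missing_rate = 0.02,
                          symptom_effect = c(attention = -0.167,
                                             anxiety = -0.117,
                                             norm_violating = -0.133,
                                             psychosis = -0.171,
                                             depression = 0.055,
                                             mania = 0.015,
                                             ocd = 0.030),
                          n_snps = 1000,
                          maf_range = c(0.05, 0.5),
                          seed = 1L) {
  if (is.null(test_loadings)) {
    test_loadings <- seq(0.72, 0.40, length.out = n_tests)
  }
  if (is.null(test_noise_sd)) {
    test_noise_sd <- sqrt(pmax(0, 1 - test_loadings^2))
  }
  if (is.null(item_loadings)) {
    item_loadings <- default_item_loadings(n_items, length(symptom_effect))
  }
  cfg <- structure(list(
    n_subjects = as.integer(n_subjects),
    age_range = as.numeric(age_range),
    female_fraction = female_fraction,
    g_growth = g_growth,
    residual_sd = residual_sd,
    n_tests = as.integer(n_tests),
    test_loadings = test_loadings,
    test_noise_sd = test_noise_sd,
    cognitive_missing_rate = cognitive_missing_rate,
    n_items = as.integer(n_items),
    item_loadings = as.matrix(item_loadings),
    item_levels = as.integer(item_levels),
    item_cut_quantiles = item_cut_quantiles,
    item_missing_rate = item_missing_rate,
    symptom_effect = symptom_effect,
    n_snps = as.integer(n_snps),
    maf_range = as.numeric(maf_range),
    seed = as.integer(seed)
  ), class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

# block-diagonal sparse loadings: item i loads 0.8 on factor ceiling(i/size)
default_item_loadings <- function(n_items, k) {
  block <- rep(seq_len(k), length.out = n_items)
  block <- sort(block)
  L <- matrix(0, n_items, k)
  L[cbind(seq_len(n_items), block)] <- 0.8
  L
}

validate_cohort_config <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  num_fields <- c("age_range", "female_fraction", "g_growth", "residual_sd",
                  "test_loadings", "test_noise_sd", "cognitive_missing_rate",
                  "item_loadings", "item_cut_quantiles", "item_missing_rate",
                  "symptom_effect", "maf_range")
  for (f in num_fields) {
    if (!all(is.finite(cfg[[f]]))) {
      stop("cohort_config: non-finite values in field '", f, "'")
    }
  }
  if (cfg$n_subjects < 0) stop("cohort_config: n_subjects must be >= 0")
  if (length(cfg$age_range) != 2 || cfg$age_range[1] >= cfg$age_range[2]) {
    stop("cohort_config: age_range must satisfy min < max")
  }
  props <- c(cfg$female_fraction, cfg$cognitive_missing_rate,
             cfg$item_missing_rate, cfg$maf_range)
  if (any(props < 0 | props > 1)) {
    stop("cohort_config: proportions must lie in [0, 1]")
  }
  if (length(cfg$test_loadings) != cfg$n_tests ||
      length(cfg$test_noise_sd) != cfg$n_tests) {
    stop("cohort_config: test_loadings/test_noise_sd length must equal n_tests")
  }
  if (nrow(cfg$item_loadings) != cfg$n_items ||
      ncol(cfg$item_loadings) != length(cfg$symptom_effect)) {
    stop("cohort_config: item_loadings must be n_items x length(symptom_effect)")
  }
  if (any(abs(cfg$symptom_effect) >= 1)) {
    stop("cohort_config: symptom_effect entries must lie in (-1, 1)")
  }
  if (any(rowSums(cfg$item_loadings^2) > 1)) {
    stop("cohort_config: item_loadings rows must have squared norm <= 1")
  }
  if (cfg$item_levels < 2) stop("cohort_config: item_levels must be >= 2")
  if (length(cfg$item_cut_quantiles) != cfg$item_levels - 1 ||
      is.unsorted(cfg$item_cut_quantiles, strictly = TRUE) ||
      any(cfg$item_cut_quantiles <= 0 | cfg$item_cut_quantiles >= 1)) {
    stop("cohort_config: item_cut_quantiles must be item_levels - 1 strictly ",
         "increasing probabilities in (0, 1)")
  }
  invisible(cfg)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Simulates demographics, cognitive test scores, ordinal clinical items,
#' SNP dosages and a GWAS summary-statistics table from the generative model
#' described in [cohort_config()]. The latent general-cognition factor is
#' `g = a + b*log(age) + c*sex + eps` with `eps ~ N(0, sd(age)^2)`; tests are
#' noisy linear functions of standardized g; symptom factors are skewed
#' (centered-exponential) variates correlated with the standardized g residual
#' at the configured effect sizes; items are ordinalized latent combinations
#' of the symptom factors; dosages are independent Binomial(2, maf).
#'
#' All latent quantities are kept in the `truth` block for parameter-recovery
#' tests. The seed in `config` fully determines the output.
#'
#' @param config a [cohort_config()] object.
#' @return an object of class `synthetic_cohort`: a list with elements
#'   `demographics` (data.frame: subject_id, age, sex), `cognition` (n x
#'   n_tests matrix), `clinical_items` (n x n_items integer matrix),
#'   `genotypes` (n x n_snps dosage matrix), `summary_stats` (data.frame:
#'   snp_id, beta, p_value), `truth` (data.frame: subject_id, g, g_resid,
#'   one column per symptom factor) and `config`.
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  cfg <- config
  n <- cfg$n_subjects
  k <- length(cfg$symptom_effect)
  set.seed(cfg$seed)

  age <- stats::runif(n, cfg$age_range[1], cfg$age_range[2])
  sex <- stats::rbinom(n, 1L, cfg$female_fraction)
  sd_age <- cfg$residual_sd[1] +
    cfg$residual_sd[2] * (age - mean(cfg$age_range))
  if (any(sd_age < 0)) stop("residual_sd spec yields negative SD at some age")
  eps <- stats::rnorm(n, 0, sd_age)
  g <- cfg$g_growth[1] + cfg$g_growth[2] * log(age) +
    cfg$g_growth[3] * sex + eps

  # tests load on the (sample-)standardized latent factor so that default
  # unit-variance noise yields roughly unit-variance scores
  g_std <- if (n > 1 && stats::sd(g) > 0) (g - mean(g)) / stats::sd(g) else g * 0
  tests <- outer(g_std, cfg$test_loadings) +
    matrix(stats::rnorm(n * cfg$n_tests), n, cfg$n_tests) *
      rep(cfg$test_noise_sd, each = n)
  colnames(tests) <- test_names(cfg$n_tests)

  # symptom factors: share the standardized residual at the configured
  # correlation; the independent part is a centered exponential (skewed, so
  # the factors are non-Gaussian and ICA-identifiable, like real symptom
  # load distributions)
  eps_std <- if (n > 1 && stats::sd(eps) > 0) (eps - mean(eps)) / stats::sd(eps) else eps * 0
  uniq <- matrix(stats::rexp(n * k) - 1, n, k)
  s <- cfg$symptom_effect
  fac <- eps_std %*% t(s) + uniq %*% diag(sqrt(1 - s^2), k)
  colnames(fac) <- symptom_names(k)

  lat <- fac %*% t(cfg$item_loadings)
  item_noise_sd <- sqrt(pmax(0, 1 - rowSums(cfg$item_loadings^2)))
  lat <- lat + matrix(stats::rnorm(n * cfg$n_items), n, cfg$n_items) *
    rep(item_noise_sd, each = n)
  cuts <- stats::qnorm(cfg$item_cut_quantiles)
  items <- matrix(0L, n, cfg$n_items)
  if (n > 0) {
    for (cut in cuts) items <- items + (lat > cut)
  }
  storage.mode(items) <- "integer"
  colnames(items) <- item_names_default(cfg$n_items)

  maf <- stats::runif(cfg$n_snps, cfg$maf_range[1], cfg$maf_range[2])
  geno <- matrix(stats::rbinom(n * cfg$n_snps, 2L, rep(maf, each = n)), n, cfg$n_snps)
  snp_ids <- sprintf("rs%06d", seq_len(cfg$n_snps))
  colnames(geno) <- snp_ids
  sumstats <- data.frame(
    snp_id = snp_ids,
    beta = stats::rnorm(cfg$n_snps, 0, 0.1),
    p_value = pmax(stats::runif(cfg$n_snps), .Machine$double.xmin),
    stringsAsFactors = FALSE
  )
  if (cfg$n_snps == 0) sumstats <- sumstats[0, ]

  ids <- sprintf("S%05d", seq_len(n))
  demo <- data.frame(subject_id = ids, age = age, sex = sex,
                     stringsAsFactors = FALSE)
  rownames(tests) <- rownames(items) <- rownames(geno) <- ids
  truth <- data.frame(subject_id = ids, g = g, g_resid = eps,
                      stringsAsFactors = FALSE)
  truth <- cbind(truth, as.data.frame(fac))

  cohort <- structure(list(
    demographics = demo, cognition = tests, clinical_items = items,
    genotypes = geno, summary_stats = sumstats, truth = truth, config = cfg
  ), class = "synthetic_cohort")

  if (cfg$cognitive_missing_rate > 0 || cfg$item_missing_rate > 0) {
    cohort <- inject_missingness(cohort,
                                 cognitive_rate = cfg$cognitive_missing_rate,
                                 item_rate = cfg$item_missing_rate,
                                 seed = cfg$seed + 1L)
  }
  cohort
}

test_names <- function(n_tests) {
  c("wrat", sprintf("cnb_%02d", seq_len(max(0, n_tests - 1)) + 1L))[seq_len(n_tests)]
}
symptom_names <- function(k) sprintf("factor_%d", seq_len(k))
item_names_default <- function(n_items) sprintf("item_%03d", seq_len(n_items))

#' Set cells missing completely at random
#'
#' Masks cells of the cognitive and clinical blocks independently at the given
#' per-cell rates. The truth block is never touched, so recovery tests can
#' still compare against the latent values.
#'
#' @param cohort a `synthetic_cohort`.
#' @param cognitive_rate,item_rate per-cell missingness probabilities in
#'   `[0, 1)`.
#' @param seed integer seed for the masks.
#' @return the cohort with `NA`s injected.
#' @export
inject_missingness <- function(cohort, cognitive_rate = 0, item_rate = 0,
                               seed = 1L) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  rates <- c(cognitive_rate, item_rate)
  if (any(!is.finite(rates)) || any(rates < 0) || any(rates >= 1)) {
    stop("missingness rates must lie in [0, 1)")
  }
  set.seed(as.integer(seed))
  mask_block <- function(m, rate) {
    if (rate > 0 && length(m) > 0) {
      m[stats::runif(length(m)) < rate] <- NA
    }
    m
  }
  cohort$cognition <- mask_block(cohort$cognition, cognitive_rate)
  items <- mask_block(cohort$clinical_items, item_rate)
  storage.mode(items) <- "integer"
  cohort$clinical_items <- items
  cohort
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>", nrow(x$demographics), "subjects,",
      ncol(x$cognition), "cognitive scores,",
      ncol(x$clinical_items), "clinical items,",
      ncol(x$genotypes), "SNPs\n")
  invisible(x)
}

#' Write a cohort to a directory of TSV files
#'
#' Writes `demographics.tsv`, `cognition.tsv`, `clinical_items.tsv`,
#' `genotypes.tsv`, `summary_stats.tsv`, `truth.tsv` and a `config.yaml`
#' snapshot. Missing values are encoded as empty fields.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, file) {
    data.table::fwrite(df, file.path(dir, file), sep = "\t", na = "",
                       quote = FALSE)
  }
  wr(cohort$demographics, "demographics.tsv")
  wr(mat_to_df(cohort$cognition, cohort$demographics$subject_id),
     "cognition.tsv")
  wr(mat_to_df(cohort$clinical_items, cohort$demographics$subject_id),
     "clinical_items.tsv")
  wr(mat_to_df(cohort$genotypes, cohort$demographics$subject_id),
     "genotypes.tsv")
  wr(cohort$summary_stats, "summary_stats.tsv")
  wr(cohort$truth, "truth.tsv")
  cfg <- cohort$config
  cfg$item_loadings <- apply(cfg$item_loadings, 1, paste, collapse = ",")
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}

mat_to_df <- function(m, ids) {
  df <- as.data.frame(m)
  cbind(data.frame(subject_id = ids, stringsAsFactors = FALSE), df)
}

df_to_mat <- function(df) {
  ids <- df$subject_id
  m <- as.matrix(df[, setdiff(names(df), "subject_id"), drop = FALSE])
  rownames(m) <- ids
  m
}

#' Read a cohort directory written by [write_cohort()]
#'
#' Only the blocks present on disk are loaded; `truth.tsv` and `config.yaml`
#' are optional.
#'
#' @param dir directory path.
#' @return a `synthetic_cohort` (config slot may be `NULL`).
#' @export
read_cohort <- function(dir) {
  rd <- function(file) {
    path <- file.path(dir, file)
    if (!file.exists(path)) return(NULL)
    as.data.frame(data.table::fread(path, sep = "\t", na.strings = ""))
  }
  demo <- rd("demographics.tsv")
  if (is.null(demo)) stop("read_cohort: no demographics.tsv in ", dir)
  out <- list(
    demographics = demo,
    cognition = df_to_mat(rd("cognition.tsv")),
    clinical_items = df_to_mat(rd("clinical_items.tsv")),
    genotypes = if (!is.null(g <- rd("genotypes.tsv"))) df_to_mat(g) else NULL,
    summary_stats = rd("summary_stats.tsv"),
    truth = rd("truth.tsv"),
    config = NULL
  )
  structure(out, class = "synthetic_cohort")
}
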