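# End-to-end orchestration: synthesize -> cognition -> normative ->
# clinical / pgs -> associate -> enrich. Every stage reads its inputs from and
# writes its outputs to the run directory, so stages can also be run one at a
# time from the CLI. All tabular I/O is TSV with a header; metrics and the
# manifest are JSON.

default_pipeline_config <- function() {
  list(
    seed = 1L,
    outdir = "normdev_run",
    stages = list(synthesize = TRUE, cognition = TRUE, normative = TRUE,
                  clinical = TRUE, pgs = TRUE, associate = TRUE,
                  enrich = TRUE),
    synthesize = list(),
    cognition = list(max_missing = 5, anchor_test = "wrat"),
    normative = list(k = 10, n_restarts = 3, max_opt_n = 2000),
    clinical = list(k = 7, n_restarts = 20),
    pgs = list(n_thresholds = 6002),
    associate = list(prior_sd = 0.5),
    enrich = list(thresholds_sd = c(1, 1.5, 2, 3), correction = FALSE)
  )
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Load and normalize a pipeline configuration
#'
#' @param config path to a YAML file, a list, or `NULL` for defaults.
#' @param outdir,seed optional overrides.
#' @return a complete config list.
#' @export
load_pipeline_config <- function(config = NULL, outdir = NULL, seed = NULL) {
  user <- if (is.character(config)) yaml::read_yaml(config)
          else if (is.list(config)) config
          else list()
  cfg <- merge_config(default_pipeline_config(), user)
  if (!is.null(outdir)) cfg$outdir <- outdir
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  # per-stage seeds derive from the global seed by fixed offsets when unset
  offsets <- c(synthesize = 0L, cognition = 100L, normative = 200L,
               clinical = 300L, pgs = 400L, associate = 500L, enrich = 600L)
  for (st in names(offsets)) {
    if (is.null(cfg[[st]]$seed)) cfg[[st]]$seed <- cfg$seed + offsets[[st]]
  }
  cfg
}

pipe_read <- function(outdir, file, required = TRUE) {
  path <- file.path(outdir, file)
  if (!file.exists(path)) {
    if (required) stop("required input '", file, "' not found in ", outdir)
    return(NULL)
  }
  as.data.frame(data.table::fread(path, sep = "\t", na.strings = ""))
}

pipe_write <- function(df, outdir, file) {
  data.table::fwrite(df, file.path(outdir, file), sep = "\t", na = "",
                     quote = FALSE)
  file
}

pipe_png <- function(outdir, file, expr) {
  grDevices::png(file.path(outdir, file), width = 900, height = 650)
  on.exit(grDevices::dev.off())
  force(expr)
  file
}

stage_synthesize <- function(cfg, outdir) {
  args <- cfg$synthesize
  args$seed <- cfg$synthesize$seed
  cohort <- generate_cohort(do.call(cohort_config, args))
  write_cohort(cohort, outdir)
  c("demographics.tsv", "cognition.tsv", "clinical_items.tsv",
    "genotypes.tsv", "summary_stats.tsv", "truth.tsv", "config.yaml")
}

stage_cognition <- function(cfg, outdir) {
  cog <- df_to_mat(pipe_read(outdir, "cognition.tsv"))
  imp <- impute_cognitive(cog, max_missing = cfg$cognition$max_missing)
  pca <- fit_cognition_pca(imp$values)
  g <- extract_g(pca, imp$values, anchor_test = cfg$cognition$anchor_test)
  files <- c(
    pipe_write(data.frame(subject_id = rownames(imp$values), g = g$g),
               outdir, "g_scores.tsv"),
    local({
      jsonlite::write_json(list(
        explained_variance = pca$explained_variance,
        contributions_pc1 = as.list(stats::setNames(
          pca$contributions[, 1], pca$test_names)),
        excluded_ids = imp$excluded_ids
      ), file.path(outdir, "pca_summary.json"), auto_unbox = TRUE, digits = NA)
      "pca_summary.json"
    }),
    pipe_png(outdir, "scree.png", {
      graphics::barplot(100 * pca$explained_variance,
                        names.arg = seq_along(pca$explained_variance),
                        xlab = "component", ylab = "% explained variance")
    })
  )
  files
}

stage_normative <- function(cfg, outdir) {
  gdf <- pipe_read(outdir, "g_scores.tsv")
  demo <- pipe_read(outdir, "demographics.tsv")
  demo <- demo[match(gdf$subject_id, demo$subject_id), ]
  cv <- cbind(age = demo$age, sex = demo$sex)
  dev <- crossval_normative(cv, gdf$g, k = cfg$normative$k,
                            seed = cfg$normative$seed,
                            n_restarts = cfg$normative$n_restarts,
                            max_opt_n = cfg$normative$max_opt_n)
  model <- fit_gp(cv, gdf$g, n_restarts = cfg$normative$n_restarts,
                  seed = cfg$normative$seed,
                  max_opt_n = cfg$normative$max_opt_n,
                  init = log(dev$models[[1]]))
  c(
    pipe_write(data.frame(subject_id = gdf$subject_id, z = dev$z,
                          fold_id = dev$fold_id),
               outdir, "z_scores.tsv"),
    local({
      jsonlite::write_json(dev$metrics, file.path(outdir, "metrics.json"),
                           auto_unbox = TRUE, digits = NA)
      "metrics.json"
    }),
    pipe_png(outdir, "normative_trajectory.png",
             plot_normative_trajectory(model, cv, gdf$g))
  )
}

stage_clinical <- function(cfg, outdir) {
  items <- df_to_mat(pipe_read(outdir, "clinical_items.tsv"))
  imp <- knn_impute(items)
  ica <- fit_ica(imp$values, k = cfg$clinical$k,
                 n_restarts = cfg$clinical$n_restarts,
                 seed = cfg$clinical$seed)
  comp <- clinical_components(ica)
  df <- data.frame(subject_id = rownames(imp$values), comp$scores,
                   general = comp$general, check.names = FALSE)
  c(
    pipe_write(df, outdir, "clinical_components.tsv"),
    local({
      jsonlite::write_json(list(
        mixing = as.data.frame(ica$mixing),
        stability_index = ica$stability_index,
        restarts = ica$restarts,
        excluded_ids = imp$excluded_ids
      ), file.path(outdir, "ica_model.json"), digits = NA)
      "ica_model.json"
    })
  )
}

stage_pgs <- function(cfg, outdir) {
  geno <- df_to_mat(pipe_read(outdir, "genotypes.tsv"))
  stats_df <- pipe_read(outdir, "summary_stats.tsv")
  prs <- compute_prs_matrix(geno, stats_df,
                            prs_thresholds(cfg$pgs$n_thresholds))
  comp <- prs_pca(prs)
  c(
    pipe_write(data.frame(subject_id = rownames(geno), score = comp$score),
               outdir, "pgs_component.tsv"),
    local({
      jsonlite::write_json(list(
        explained_variance = comp$explained_variance,
        n_columns_used = comp$n_columns_used,
        n_thresholds = length(prs$thresholds)
      ), file.path(outdir, "pgs_summary.json"), auto_unbox = TRUE, digits = NA)
      "pgs_summary.json"
    })
  )
}

stage_associate <- function(cfg, outdir) {
  zdf <- pipe_read(outdir, "z_scores.tsv")
  demo <- pipe_read(outdir, "demographics.tsv")
  demo <- demo[match(zdf$subject_id, demo$subject_id), ]
  comp <- pipe_read(outdir, "clinical_components.tsv")
  comp <- comp[match(zdf$subject_id, comp$subject_id), ]
  preds <- comp[, setdiff(names(comp), "subject_id"), drop = FALSE]
  pgs <- pipe_read(outdir, "pgs_component.tsv", required = FALSE)
  if (!is.null(pgs)) {
    preds$pgs <- pgs$score[match(zdf$subject_id, pgs$subject_id)]
  }
  keep <- stats::complete.cases(preds, zdf$z, demo$age, demo$sex)
  assoc <- associate_deviations(zdf$z[keep], preds[keep, , drop = FALSE],
                                demo$age[keep], demo$sex[keep],
                                prior_sd = cfg$associate$prior_sd)
  c(
    pipe_write(assoc, outdir, "associations.tsv"),
    pipe_png(outdir, "associations.png", plot_associations(assoc))
  )
}

stage_enrich <- function(cfg, outdir) {
  zdf <- pipe_read(outdir, "z_scores.tsv")
  comp <- pipe_read(outdir, "clinical_components.tsv")
  comp <- comp[match(zdf$subject_id, comp$subject_id), ]
  dec <- assign_deciles(zdf$z)
  domains <- setdiff(names(comp), "subject_id")
  enr <- do.call(rbind, lapply(domains, function(d) {
    cbind(domain = d,
          risk_proportions(dec, comp[[d]], cfg$enrich$thresholds_sd))
  }))
  ors <- do.call(rbind, lapply(domains, function(d) {
    cbind(domain = d,
          enrichment_odds_ratios(dec, comp[[d]], cfg$enrich$thresholds_sd,
                                 correction = cfg$enrich$correction))
  }))
  c(
    pipe_write(enr, outdir, "enrichment.tsv"),
    pipe_write(ors, outdir, "or_table.tsv"),
    pipe_png(outdir, "enrichment.png",
             plot_enrichment(enr[enr$domain == "general", ]))
  )
}

#' Run the full normative-deviation pipeline
#'
#' Executes the enabled stages in dependency order (synthesize, cognition,
#' normative, clinical, pgs, associate, enrich) and writes a
#' `manifest.json` recording the configuration hash, per-stage seeds, output
#' files and package version. A stage failure aborts the run, retains partial
#' outputs and leaves a `FAILED` marker naming the stage.
#'
#' @param config path to a YAML config, a config list, or `NULL` for
#'   defaults. See the package vignette for the schema.
#' @param outdir,seed optional overrides of the config.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = NULL, outdir = NULL, seed = NULL) {
  cfg <- load_pipeline_config(config, outdir, seed)
  outdir <- cfg$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  snap <- file.path(outdir, "pipeline_config.yaml")
  yaml::write_yaml(cfg, snap)

  runners <- list(synthesize = stage_synthesize, cognition = stage_cognition,
                  normative = stage_normative, clinical = stage_clinical,
                  pgs = stage_pgs, associate = stage_associate,
                  enrich = stage_enrich)
  manifest <- list(config_hash = unname(tools::md5sum(snap)),
                   seed = cfg$seed,
                   package_version = as.character(utils::packageVersion("normdev")),
                   stages = list())
  for (st in names(runners)) {
    if (!isTRUE(cfg$stages[[st]])) next
    message(sprintf("[normdev] stage %-10s seed=%d", st, cfg[[st]]$seed))
    files <- tryCatch(runners[[st]](cfg, outdir), error = function(e) {
      writeLines(paste0("stage ", st, ": ", conditionMessage(e)),
                 file.path(outdir, "FAILED"))
      stop("pipeline stage '", st, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[st]] <- list(seed = cfg[[st]]$seed, outputs = files)
  }
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Command-line entry point
#'
#' Subcommands: `synthesize`, `cognition`, `normative`, `clinical`, `pgs`,
#' `associate`, `enrich`, `all`. Common flags: `--config`, `--outdir`,
#' `--seed`, `--verbose`. Single-stage subcommands read their inputs from
#' `--outdir`, so a run can be resumed or repeated stage by stage.
#'
#' @param args character vector of command-line arguments (default: the
#'   process's trailing arguments).
#' @return exit status, invisibly (0 on success).
#' @export
normdev_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  stages <- c("synthesize", "cognition", "normative", "clinical", "pgs",
              "associate", "enrich")
  usage <- paste0("usage: normdev <", paste(c(stages, "all"), collapse = "|"),
                  "> [--config FILE] [--outdir DIR] [--seed INT] [--verbose]")
  if (length(args) == 0 || args[1] %in% c("-h", "--help")) {
    cat(usage, "\n")
    return(invisible(0L))
  }
  cmd <- args[1]
  if (!cmd %in% c(stages, "all")) stop(usage, call. = FALSE)
  parser <- optparse::OptionParser(option_list = list(
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--outdir", type = "character", default = NULL),
    optparse::make_option("--seed", type = "integer", default = NULL),
    optparse::make_option("--verbose", action = "store_true", default = FALSE)
  ))
  opt <- optparse::parse_args(parser, args = args[-1])
  cfg <- load_pipeline_config(opt$config, opt$outdir, opt$seed)
  if (cmd != "all") {
    cfg$stages <- stats::setNames(as.list(stages %in% cmd), stages)
  }
  if (!opt$verbose) {
    suppressMessages(run_pipeline(cfg))
  } else {
    run_pipeline(cfg)
  }
  invisible(0L)
}
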