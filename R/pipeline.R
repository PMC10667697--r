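#' Run the full trial-analysis pipeline
#'
#' Orchestrates every analysis stage on either a phenotype file or a
#' synthetic trial, writing the standard report set to `outdir`:
#'
#' * `phenotypes.csv` — the analysed table (always written for synthetic
#'   input, so a run is self-contained);
#' * `anova_rcbd.tsv` — per-environment RCBD ANOVA lines for every trait x
#'   year x regime; `anova_combined.tsv` — the combined multi-environment
#'   ANOVA per trait (when the design supports it);
#' * `genetic_summary.tsv` — mean, variance components, GCV/PCV,
#'   heritability, GA, GAM per trait x year x regime;
#' * `correlations_<regime>.tsv` — paired phenotypic/genotypic trait
#'   correlations per regime (years pooled);
#' * `stepwise_<regime>_<response>.tsv` — stepwise regression of each yield
#'   response on the remaining traits, on genotype means per regime;
#' * `cluster_groups_<regime>.tsv` — accession group assignments;
#' * `manifest.json` — package version, seed, configuration hash, stage
#'   log with row counts and output files.
#'
#' Any stage failure aborts the run with a stage-named error.
#'
#' @param config A `run_config` (see [as_run_config()]), a plain named
#'   list, or the path to a YAML configuration file.
#' @return Invisibly, a list with `artifacts` (named file paths), `manifest`
#'   and the analysed `table`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- read_trial_config(config)
  } else if (!inherits(config, "run_config")) {
    config <- as_run_config(config)
  }
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- list()
  log <- list()
  note <- function(stage, what, rows) {
    log[[length(log) + 1]] <<- list(stage = stage, output = what, rows = rows)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("stage '", stage, "' failed: ", conditionMessage(e)),
            class = "forageQG_pipeline_error", parent = e)
    })
  }
  out_path <- function(...) file.path(config$outdir, paste0(...))

  # ---- load ----
  table <- run_stage("load", {
    if (!is.null(config$synthetic)) {
      spec <- config_synthetic_spec(config)
      tab <- generate_trial(spec)
      artifacts$phenotypes <- write_phenotypes(tab, out_path("phenotypes.csv"))
      tab
    } else {
      read_phenotypes(config$input, design = config_design(config))
    }
  })
  note("load", "phenotypes", nrow(table))
  traits <- unique(table$trait)
  years <- unique(table$year)
  regimes <- unique(table$regime)

  if ("anova" %in% config$stages) {
    run_stage("anova", {
      rows <- list()
      for (tr in traits) for (yr in years) for (rg in regimes) {
        a <- rcbd_anova(table, tr, yr, rg)
        rows[[length(rows) + 1]] <- mutate(a$anova, trait = tr, year = yr,
                                           regime = rg, .before = 1)
      }
      rcbd_all <- bind_rows(rows)
      readr::write_tsv(rcbd_all, out_path("anova_rcbd.tsv"))
      artifacts$anova_rcbd <- out_path("anova_rcbd.tsv")
      note("anova", "anova_rcbd", nrow(rcbd_all))
      if (length(years) >= 2 && length(regimes) >= 2) {
        comb <- bind_rows(lapply(traits, function(tr)
          mutate(combined_anova(table, tr)$anova, trait = tr, .before = 1)))
        readr::write_tsv(comb, out_path("anova_combined.tsv"))
        artifacts$anova_combined <- out_path("anova_combined.tsv")
        note("anova", "anova_combined", nrow(comb))
      }
    })
  }

  if ("genparams" %in% config$stages) {
    run_stage("genparams", {
      gs <- genetic_summary(table, k = config$k, sd_scale = config$sd_scale)
      artifacts$genetic_summary <- write_genetic_summary(
        gs, out_path("genetic_summary.tsv"))
      note("genparams", "genetic_summary", nrow(gs))
    })
  }

  if ("corr" %in% config$stages) {
    run_stage("corr", {
      for (rg in regimes) {
        cm <- trait_correlations(table, regime = rg)
        p <- out_path("correlations_", gsub("[^A-Za-z0-9]+", "_", rg), ".tsv")
        artifacts[[paste0("correlations_", rg)]] <- write_correlations(cm, p)
        note("corr", basename(p), length(cm$traits))
      }
    })
  }

  if ("stepwise" %in% config$stages) {
    run_stage("stepwise", {
      responses <- intersect(c("FY", "DY"), traits)
      if (length(responses) == 0) responses <- traits[1]
      for (rg in regimes) {
        gm <- genotype_means(table, regime = rg)
        for (resp in responses) {
          predictors <- setdiff(traits, responses)
          sw <- stepwise_regression(gm[[resp]], gm[predictors],
                                    alpha_enter = config$alpha_enter,
                                    alpha_stay = config$alpha_stay)
          p <- out_path("stepwise_", gsub("[^A-Za-z0-9]+", "_", rg),
                        "_", resp, ".tsv")
          artifacts[[paste0("stepwise_", rg, "_", resp)]] <- write_stepwise(sw, p)
          note("stepwise", basename(p), nrow(sw$steps))
        }
      }
    })
  }

  if ("cluster" %in% config$stages) {
    run_stage("cluster", {
      for (rg in regimes) {
        gm <- genotype_means(table, regime = rg)
        cl <- cluster_accessions(gm, n_groups = config$n_groups)
        p <- out_path("cluster_groups_", gsub("[^A-Za-z0-9]+", "_", rg), ".tsv")
        artifacts[[paste0("cluster_", rg)]] <- write_cluster_groups(cl, p, regime = rg)
        note("cluster", basename(p), nrow(cl$groups))
      }
    })
  }

  manifest <- list(
    package = "forageQG",
    version = as.character(utils::packageVersion("forageQG")),
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    stages = config$stages,
    log = log,
    artifacts = lapply(artifacts, basename)
  )
  jsonlite::write_json(manifest, out_path("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  artifacts$manifest <- out_path("manifest.json")
  invisible(list(artifacts = artifacts, manifest = manifest, table = table))
}
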