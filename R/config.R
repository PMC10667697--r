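#' Read a trial/run configuration from YAML
#'
#' The configuration names the design sizes, trait list, regime labels,
#' analysis parameters and (optionally) a synthetic-trial section. All
#' analysis parameters are optional and default to the package defaults:
#' `k = 2.063`, `alpha_enter = alpha_stay = 0.15`, `n_groups = 3`,
#' `seed = 1`.
#'
#' Recognised top-level keys: `design` (`n_genotypes`, `n_blocks`, `years`,
#' `regimes`, `control`, `traits`), `input` (path to a phenotype CSV/TSV),
#' `synthetic` (`trait_params` rows and optional `regime_shift`,
#' `genetic_cor`), `stages`, `outdir`, `seed`, `k`, `sd_scale`,
#' `alpha_enter`, `alpha_stay`, `n_groups`.
#'
#' @param path Path to a YAML file.
#' @return A named list of class `run_config` with defaults filled in.
#' @export
read_trial_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("config file not found: ", path), class = "forageQG_format_error")
  }
  raw <- yaml::read_yaml(path)
  as_run_config(raw)
}

#' Build a run configuration from a list
#'
#' @param x Named list of configuration entries (see [read_trial_config()]).
#' @return A `run_config` list.
#' @export
as_run_config <- function(x) {
  defaults <- list(
    stages = c("anova", "genparams", "corr", "stepwise", "cluster"),
    outdir = ".", seed = 1L, k = 2.063, sd_scale = "phenotypic",
    alpha_enter = 0.15, alpha_stay = 0.15, n_groups = 3L,
    input = NULL, design = NULL, synthetic = NULL
  )
  cfg <- modifyList(defaults, x, keep.null = TRUE)
  known <- c("anova", "genparams", "corr", "stepwise", "cluster")
  bad <- setdiff(cfg$stages, known)
  if (length(bad) > 0) {
    abort(paste0("unknown stage(s): ", paste(bad, collapse = ", "),
                 " (known: ", paste(known, collapse = ", "), ")"),
          class = "forageQG_config_error")
  }
  if (is.null(cfg$input) && is.null(cfg$synthetic)) {
    abort("config must provide either `input` (a phenotype file) or `synthetic`.",
          class = "forageQG_config_error")
  }
  if (!is.null(cfg$input) && !file.exists(cfg$input)) {
    abort(paste0("input file not found: ", cfg$input),
          class = "forageQG_config_error")
  }
  structure(cfg, class = "run_config")
}

# materialize the design / synthetic spec sections of a config
config_design <- function(cfg) {
  d <- cfg$design
  if (is.null(d)) return(NULL)
  trial_design(
    n_genotypes = d$n_genotypes, n_blocks = d$n_blocks,
    years = d$years, regimes = d$regimes, traits = d$traits,
    control = if (is.null(d$control)) d$regimes[[1]] else d$control
  )
}

config_synthetic_spec <- function(cfg) {
  s <- cfg$synthetic
  if (is.null(s)) return(NULL)
  if (isTRUE(s$paper_defaults) || is.null(s$trait_params)) {
    args <- s[intersect(names(s), c("n_genotypes", "n_blocks",
                                    "interaction_fraction"))]
    args$seed <- cfg$seed
    return(do.call(paper_trial_spec, args))
  }
  design <- config_design(cfg)
  if (is.null(design)) {
    abort("a `design` section is required with custom `synthetic.trait_params`.",
          class = "forageQG_config_error")
  }
  tp <- bind_rows(lapply(s$trait_params, as_tibble))
  shift <- if (!is.null(s$regime_shift)) do.call(rbind, s$regime_shift) else NULL
  gc <- if (!is.null(s$genetic_cor)) do.call(rbind, s$genetic_cor) else NULL
  synthetic_trial_spec(design, tp, regime_shift = shift, genetic_cor = gc,
                       seed = cfg$seed)
}
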