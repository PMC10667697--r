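#' Define the layout of a multi-environment RCBD trial
#'
#' A trial design records the dimensions of a randomized complete block
#' design repeated over years and irrigation regimes: `g` genotypes appear
#' once in each of `r` blocks within every year x regime combination.
#'
#' @param n_genotypes Number of genotypes (accessions), `g >= 2`.
#' @param n_blocks Number of blocks (replicates) per environment, `r >= 2`.
#' @param years Character or numeric vector of year labels.
#' @param regimes Character vector of irrigation regime labels. The first is
#'   taken as the control (well-watered) level unless `control` says
#'   otherwise; remaining levels are stress levels.
#' @param traits Character vector of unique trait names.
#' @param genotypes Optional genotype labels; defaults to `"G001"...`.
#' @param control Label of the control regime. Must be one of `regimes`.
#'
#' @return An object of class `trial_design`: a list with fields
#'   `n_genotypes`, `n_blocks`, `genotypes`, `blocks`, `years`, `regimes`,
#'   `control`, `traits`.
#' @examples
#' trial_design(10, 2, years = c(2018, 2019),
#'              regimes = c("non-stress", "drought"),
#'              traits = c("FY", "DY"))
#' @export
trial_design <- function(n_genotypes, n_blocks, years, regimes, traits,
                         genotypes = NULL, control = regimes[[1]]) {
  if (!is.numeric(n_genotypes) || n_genotypes < 2) {
    abort("`n_genotypes` must be an integer >= 2.", class = "forageQG_design_error")
  }
  if (!is.numeric(n_blocks) || n_blocks < 2) {
    abort("`n_blocks` must be an integer >= 2.", class = "forageQG_design_error")
  }
  if (length(years) < 1) abort("at least one year is required.", class = "forageQG_design_error")
  if (length(regimes) < 1) abort("at least one regime is required.", class = "forageQG_design_error")
  if (!control %in% regimes) {
    abort("`control` must be one of `regimes`.", class = "forageQG_design_error")
  }
  if (anyDuplicated(traits)) {
    abort("trait names must be unique.", class = "forageQG_design_error")
  }
  g <- as.integer(n_genotypes)
  r <- as.integer(n_blocks)
  if (is.null(genotypes)) {
    genotypes <- sprintf("G%03d", seq_len(g))
  } else if (length(genotypes) != g || anyDuplicated(genotypes)) {
    abort("`genotypes` must be `n_genotypes` unique labels.", class = "forageQG_design_error")
  }
  structure(
    list(
      n_genotypes = g, n_blocks = r,
      genotypes = as.character(genotypes),
      blocks = sprintf("B%d", seq_len(r)),
      years = as.character(years),
      regimes = as.character(regimes),
      control = as.character(control),
      traits = as.character(traits)
    ),
    class = "trial_design"
  )
}

#' @export
print.trial_design <- function(x, ...) {
  cat("<trial_design> ", x$n_genotypes, " genotypes x ", x$n_blocks,
      " blocks x ", length(x$years), " year(s) x ", length(x$regimes),
      " regime(s)\n", sep = "")
  cat("  regimes:", paste(x$regimes, collapse = ", "),
      sprintf("(control: %s)\n", x$control))
  cat("  traits: ", paste(x$traits, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# all (genotype, year, regime, block, trait) keys the design implies
design_keys <- function(design) {
  expand_grid(
    genotype = design$genotypes,
    year = design$years,
    regime = design$regimes,
    block = design$blocks,
    trait = design$traits
  )
}
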