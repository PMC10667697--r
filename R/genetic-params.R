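#' Variance components from an RCBD ANOVA
#'
#' Solves the expected mean squares of the per-environment RCBD:
#' `E(MS_genotype) = sigma_e^2 + r * sigma_g^2`, `E(MS_error) = sigma_e^2`,
#' giving `sigma_g^2 = (MS_g - MS_e) / r`, `sigma_e^2 = MS_e` and the
#' phenotypic variance `sigma_p^2 = sigma_g^2 + sigma_e^2`. Method-of-moments
#' estimates can go negative; negative genotypic variance is truncated to 0
#' and flagged.
#'
#' @param a An [rcbd_anova()] result, or a list with `ms_genotype`,
#'   `ms_error`, `n_blocks`.
#' @return An object of class `variance_components`: list with `sigma_g2`,
#'   `sigma_e2`, `sigma_p2`, `negative_truncated`, `n_blocks`.
#' @export
variance_components <- function(a) {
  r <- a$n_blocks
  if (is.null(r) || r < 1) abort("`n_blocks` must be >= 1.", class = "forageQG_design_error")
  sigma_g2 <- (a$ms_genotype - a$ms_error) / r
  truncated <- sigma_g2 < 0
  if (truncated) sigma_g2 <- 0
  sigma_e2 <- a$ms_error
  structure(
    list(sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
         sigma_p2 = sigma_g2 + sigma_e2,
         negative_truncated = truncated, n_blocks = r),
    class = "variance_components"
  )
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("<variance_components> sigma_g2 = %.6g, sigma_e2 = %.6g, sigma_p2 = %.6g%s\n",
              x$sigma_g2, x$sigma_e2, x$sigma_p2,
              if (x$negative_truncated) " (negative estimate truncated to 0)" else ""))
  invisible(x)
}

#' Phenotypic and genotypic coefficients of variation
#'
#' `PCV = 100 * sigma_p / mu` and `GCV = 100 * sigma_g / mu`: the phenotypic
#' and genotypic standard deviations as percentages of the trait mean, the
#' standard unit-free measures of variability in breeding trials.
#'
#' @param vc A [variance_components()] object.
#' @param mu Trait mean (> 0).
#' @return A list with `pcv` and `gcv` (percent); `gcv <= pcv` always.
#' @export
coefficients_of_variation <- function(vc, mu) {
  if (!(mu > 0)) abort("`mu` must be > 0.", class = "forageQG_domain_error")
  list(pcv = 100 * sqrt(vc$sigma_p2) / mu,
       gcv = 100 * sqrt(vc$sigma_g2) / mu)
}

#' Broad-sense heritability
#'
#' `h^2 = 100 * sigma_g^2 / sigma_p^2` (percent): the share of phenotypic
#' variance attributable to total genotypic effects. Identically equals
#' `100 * (GCV / PCV)^2`.
#'
#' @param vc A [variance_components()] object.
#' @return Heritability in percent, in `[0, 100]`.
#' @export
heritability <- function(vc) {
  if (!(vc$sigma_p2 > 0)) {
    abort("heritability undefined: phenotypic variance is zero.",
          class = "forageQG_domain_error")
  }
  100 * vc$sigma_g2 / vc$sigma_p2
}

#' Genetic advance under truncation selection
#'
#' Expected gain per selection cycle, `GA = k * sigma_p * h^2 / 100`: the
#' selection differential on the phenotypic-SD scale times heritability.
#' `k = 2.063` is the standardized selection differential for selecting the
#' top 5%. `sd_scale = "error"` instead multiplies k by the error (residual)
#' standard deviation; that variant circulates in some texts but is not
#' consistent with the selection-theory derivation and is provided for
#' strict cross-checking only.
#'
#' @param vc A [variance_components()] object.
#' @param h2 Heritability in percent; computed from `vc` when omitted.
#' @param k Selection intensity (default 2.063, top-5% truncation).
#' @param sd_scale `"phenotypic"` (default) or `"error"`.
#' @return Genetic advance in trait units.
#' @export
genetic_advance <- function(vc, h2 = NULL, k = 2.063,
                            sd_scale = c("phenotypic", "error")) {
  sd_scale <- match.arg(sd_scale)
  if (is.null(h2)) h2 <- heritability(vc)
  s <- if (sd_scale == "phenotypic") sqrt(vc$sigma_p2) else sqrt(vc$sigma_e2)
  k * s * h2 / 100
}

#' Genetic advance as percent of the trait mean
#'
#' `GAM = 100 * GA / mu`, enabling comparison of expected selection response
#' across traits measured in different units.
#'
#' @param ga Genetic advance (trait units).
#' @param mu Trait mean (> 0).
#' @return GAM in percent.
#' @export
genetic_advance_percent <- function(ga, mu) {
  if (!(mu > 0)) abort("`mu` must be > 0.", class = "forageQG_domain_error")
  100 * ga / mu
}

#' Percent reduction of a trait under stress
#'
#' Relative loss of a trait mean under a stress treatment. The default
#' expresses the loss relative to the *stress* mean,
#' `100 * (control - stress) / stress`; `denominator = "control"` gives the
#' more common `100 * (control - stress) / control`.
#'
#' @param mean_control Trait mean under the control regime.
#' @param mean_stress Trait mean under the stress regime (> 0; for the
#'   control denominator, control must be > 0).
#' @param denominator `"stress"` (default) or `"control"`.
#' @return Percent reduction.
#' @export
percent_reduction <- function(mean_control, mean_stress,
                              denominator = c("stress", "control")) {
  denominator <- match.arg(denominator)
  den <- if (denominator == "stress") mean_stress else mean_control
  if (!(den > 0)) {
    abort("denominator mean must be > 0.", class = "forageQG_domain_error")
  }
  100 * (mean_control - mean_stress) / den
}

#' Classify a coefficient of variation as low, moderate or high
#'
#' Conventional breeding-literature bands: `< 10%` low, `10-20%` moderate,
#' `> 20%` high.
#'
#' @param cv Coefficient of variation in percent.
#' @param thresholds Numeric length-2 vector of band edges.
#' @return Character vector of `"low"`, `"moderate"`, `"high"`.
#' @export
classify_cv <- function(cv, thresholds = c(10, 20)) {
  stopifnot(length(thresholds) == 2, diff(thresholds) > 0)
  cut(cv, breaks = c(-Inf, thresholds, Inf),
      labels = c("low", "moderate", "high"), right = FALSE) |>
    as.character()
}

#' Genetic-variability summary per trait, year and regime
#'
#' Runs the per-environment pipeline — RCBD ANOVA, variance components,
#' PCV/GCV, broad-sense heritability, genetic advance and GAM — for every
#' trait x year x regime combination, producing the standard
#' genetic-variability summary table of a breeding-trial report.
#'
#' @param table A balanced `phenotype_table`.
#' @param traits,years,regimes Subsets to analyse; default all present.
#' @param k Selection intensity (default 2.063, top-5% truncation).
#' @param sd_scale Passed to [genetic_advance()].
#' @return A tibble of class `genetic_summary` with one row per trait x
#'   year x regime: `mean`, `se`, `sigma_g2`, `sigma_e2`, `sigma_p2`,
#'   `gcv`, `pcv`, `h2`, `ga`, `gam`, `negative_truncated`.
#' @export
genetic_summary <- function(table, traits = NULL, years = NULL, regimes = NULL,
                            k = 2.063, sd_scale = c("phenotypic", "error")) {
  sd_scale <- match.arg(sd_scale)
  d <- as_tibble(table)
  if (is.null(traits)) traits <- unique(d$trait)
  if (is.null(years)) years <- unique(d$year)
  if (is.null(regimes)) regimes <- unique(d$regime)
  grid <- expand_grid(trait = traits, year = years, regime = regimes)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    tr <- grid$trait[i]; yr <- grid$year[i]; rg <- grid$regime[i]
    a <- rcbd_anova(table, tr, yr, rg)
    vc <- variance_components(a)
    mu <- a$grand_mean
    sub <- environment_subset(table, tr, yr, rg)
    cv <- coefficients_of_variation(vc, mu)
    h2 <- heritability(vc)
    ga <- genetic_advance(vc, h2, k = k, sd_scale = sd_scale)
    tibble(
      trait = tr, year = yr, regime = rg,
      mean = mu, se = sd(sub$value) / sqrt(nrow(sub)),
      sigma_g2 = vc$sigma_g2, sigma_e2 = vc$sigma_e2, sigma_p2 = vc$sigma_p2,
      gcv = cv$gcv, pcv = cv$pcv, h2 = h2,
      ga = ga, gam = genetic_advance_percent(ga, mu),
      negative_truncated = vc$negative_truncated
    )
  })
  out <- bind_rows(rows)
  class(out) <- c("genetic_summary", class(out))
  attr(out, "k") <- k
  attr(out, "sd_scale") <- sd_scale
  out
}

#' Write a genetic summary as TSV
#'
#' @param x A [genetic_summary()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genetic_summary <- function(x, path) {
  readr::write_tsv(as_tibble(x), path)
  invisible(path)
}
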