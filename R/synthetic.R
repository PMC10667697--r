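#' Specify a synthetic multi-environment RCBD trial
#'
#' Ground truth for the generator: per-trait grand means and variance
#' components for the linear model
#' `value = mu + regime shift + year + genotype + GxY + GxR + block(regime, year) + error`,
#' with genotype main effects drawn jointly across traits from a
#' multivariate normal whose correlation matrix is the true genetic
#' correlation. All other effect draws are independent across traits.
#'
#' @param design A [trial_design()].
#' @param trait_params Data frame with one row per design trait and columns
#'   `trait`, `mu`, `sigma_g2`, `sigma_e2`, and optionally `sigma_y2`,
#'   `sigma_gxy2`, `sigma_gxr2`, `sigma_block2` (default 0).
#' @param regime_shift Traits x regimes matrix of fixed mean shifts
#'   (default all 0); rows ordered as `design$traits`, columns as
#'   `design$regimes`.
#' @param genetic_cor True between-trait genetic correlation matrix
#'   (symmetric, unit diagonal, positive semidefinite); default identity.
#' @param seed Integer RNG seed; generation is deterministic given the spec.
#' @return An object of class `synthetic_trial_spec`.
#' @export
synthetic_trial_spec <- function(design, trait_params, regime_shift = NULL,
                                 genetic_cor = NULL, seed = 1L) {
  stopifnot(inherits(design, "trial_design"))
  tp <- as_tibble(trait_params)
  needed <- c("trait", "mu", "sigma_g2", "sigma_e2")
  if (!all(needed %in% names(tp))) {
    abort(paste0("`trait_params` needs columns: ", paste(needed, collapse = ", ")),
          class = "forageQG_spec_error")
  }
  for (optional in c("sigma_y2", "sigma_gxy2", "sigma_gxr2", "sigma_block2")) {
    if (!optional %in% names(tp)) tp[[optional]] <- 0
  }
  if (!setequal(tp$trait, design$traits) || nrow(tp) != length(design$traits)) {
    abort("`trait_params` must have exactly one row per design trait.",
          class = "forageQG_spec_error")
  }
  tp <- tp[match(design$traits, tp$trait), ]
  varcols <- c("sigma_g2", "sigma_e2", "sigma_y2", "sigma_gxy2",
               "sigma_gxr2", "sigma_block2")
  if (any(as.matrix(tp[varcols]) < 0)) {
    abort("all variance components must be >= 0.", class = "forageQG_spec_error")
  }
  nt <- length(design$traits); nm <- length(design$regimes)
  if (is.null(regime_shift)) {
    regime_shift <- matrix(0, nt, nm, dimnames = list(design$traits, design$regimes))
  }
  regime_shift <- as.matrix(regime_shift)
  stopifnot(dim(regime_shift) == c(nt, nm))
  dimnames(regime_shift) <- list(design$traits, design$regimes)
  if (is.null(genetic_cor)) genetic_cor <- diag(nt)
  genetic_cor <- as.matrix(genetic_cor)
  if (!isTRUE(all.equal(genetic_cor, t(genetic_cor))) ||
      !isTRUE(all.equal(unname(diag(genetic_cor)), rep(1, nt)))) {
    abort("`genetic_cor` must be symmetric with unit diagonal.",
          class = "forageQG_spec_error")
  }
  if (min(eigen(genetic_cor, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    abort("`genetic_cor` must be positive semidefinite.",
          class = "forageQG_spec_error")
  }
  dimnames(genetic_cor) <- list(design$traits, design$traits)
  structure(
    list(design = design, trait_params = tp, regime_shift = regime_shift,
         genetic_cor = genetic_cor, seed = as.integer(seed)),
    class = "synthetic_trial_spec"
  )
}

#' @export
print.synthetic_trial_spec <- function(x, ...) {
  cat("<synthetic_trial_spec> seed ", x$seed, "\n", sep = "")
  print(x$design)
  print(as.data.frame(x$trait_params), row.names = FALSE)
  invisible(x)
}

#' Default trial specification emulating the bluegrass drought study
#'
#' A ready-made [synthetic_trial_spec()] matching the study conditions of
#' the 100-ecotype Kentucky bluegrass trial this package is built around:
#' 100 genotypes x 2 blocks x 2 years (2018, 2019) x 2 irrigation regimes
#' (non-stress control, 50% deficit drought), seven traits (FY, DY, A, g_s,
#' T_r, Chl, Fv/Fm). Per-trait means and genotypic/error variances are
#' back-solved from the published 2018 non-stress summary statistics
#' (mean, GCV, PCV; see [bluegrass_summary()]); drought shifts reproduce
#' the published control-stress mean gaps (so e.g. FY drops by about 43% of
#' the stress mean); year-effect SD is a quarter of the published 2018-2019
#' mean jump, large enough to produce year swings of the reported magnitude
#' while keeping simulated environment means strictly positive; genotype x
#' year and genotype x regime variances default to
#' 25% of the genotypic variance; block variance to a quarter of the error
#' variance; and the genetic correlation matrix is anchored at the published
#' genotypic correlations (FY-DY 0.91, g_s-T_r 0.75, ...).
#'
#' @param n_genotypes,n_blocks Design sizes (defaults 100 and 2).
#' @param seed RNG seed.
#' @param interaction_fraction G x year and G x regime variance as a
#'   fraction of the genotypic variance (default 0.25).
#' @param sigma_y2 Optional named numeric vector overriding per-trait
#'   year-effect variances (e.g. set to 0 for recovery experiments).
#' @return A `synthetic_trial_spec`.
#' @export
paper_trial_spec <- function(n_genotypes = 100, n_blocks = 2, seed = 1L,
                             interaction_fraction = 0.25, sigma_y2 = NULL) {
  pub <- bluegrass_summary()
  traits <- unique(pub$trait)
  design <- trial_design(
    n_genotypes, n_blocks,
    years = c("2018", "2019"),
    regimes = c("non-stress", "drought"),
    traits = traits
  )
  base <- filter(pub, .data$year == "2018", .data$regime == "non-stress")
  base <- base[match(traits, base$trait), ]
  sg <- base$gcv * base$mean / 100
  sp <- base$pcv * base$mean / 100
  gap_mat <- pivot_wider(pub[c("trait", "year", "regime", "mean")],
                         names_from = c("year", "regime"), values_from = "mean")
  gap_mat <- gap_mat[match(traits, gap_mat$trait), ]
  year_gap <- (abs(gap_mat$`2019_non-stress` - gap_mat$`2018_non-stress`) +
               abs(gap_mat$`2019_drought` - gap_mat$`2018_drought`)) / 2
  tp <- tibble(
    trait = traits,
    mu = base$mean,
    sigma_g2 = sg^2,
    sigma_e2 = sp^2 - sg^2,
    sigma_y2 = (year_gap / 4)^2,
    sigma_gxy2 = interaction_fraction * sg^2,
    sigma_gxr2 = interaction_fraction * sg^2,
    sigma_block2 = (sp^2 - sg^2) / 4
  )
  if (!is.null(sigma_y2)) {
    stopifnot(all(names(sigma_y2) %in% traits))
    tp$sigma_y2[match(names(sigma_y2), tp$trait)] <- sigma_y2
  }
  drought <- filter(pub, .data$year == "2018", .data$regime == "drought")
  drought <- drought[match(traits, drought$trait), ]
  shift <- cbind(`non-stress` = rep(0, length(traits)),
                 drought = drought$mean - base$mean)
  rownames(shift) <- traits
  # anchored at the published genotypic correlations; completed to a PSD
  # matrix (min eigenvalue ~0.09)
  R <- matrix(c(
    1.00, 0.91, 0.55, 0.60, 0.55, 0.40, 0.35,
    0.91, 1.00, 0.55, 0.60, 0.55, 0.40, 0.35,
    0.55, 0.55, 1.00, 0.75, 0.75, 0.70, 0.60,
    0.60, 0.60, 0.75, 1.00, 0.75, 0.77, 0.55,
    0.55, 0.55, 0.75, 0.75, 1.00, 0.70, 0.66,
    0.40, 0.40, 0.70, 0.77, 0.70, 1.00, 0.55,
    0.35, 0.35, 0.60, 0.55, 0.66, 0.55, 1.00
  ), 7, 7, dimnames = list(traits, traits))
  synthetic_trial_spec(design, tp, regime_shift = shift,
                       genetic_cor = R, seed = seed)
}

#' Generate a synthetic phenotype table
#'
#' Draws a balanced multi-environment RCBD trial from the Gaussian effects
#' model of a [synthetic_trial_spec()]. Generation is deterministic: the
#' same spec and seed produce a bit-identical table, and the caller's RNG
#' state is left untouched.
#'
#' @param spec A `synthetic_trial_spec`.
#' @return A balanced `phenotype_table` with the spec's design attached.
#' @export
generate_trial <- function(spec) {
  stopifnot(inherits(spec, "synthetic_trial_spec"))
  des <- spec$design
  tp <- spec$trait_params
  g <- des$n_genotypes; r <- des$n_blocks
  years <- des$years; regimes <- des$regimes; traits <- des$traits
  nt <- length(traits); ny <- length(years); nm <- length(regimes)

  withr::with_seed(spec$seed, {
    # genotype main effects, correlated across traits
    sg <- sqrt(tp$sigma_g2)
    sigma <- diag(sg, nt) %*% spec$genetic_cor %*% diag(sg, nt)
    geno <- MASS::mvrnorm(g, mu = rep(0, nt), Sigma = sigma)
    dimnames(geno) <- list(des$genotypes, traits)
    # per-trait independent effects
    year_eff <- matrix(rnorm(nt * ny, 0, rep(sqrt(tp$sigma_y2), ny)),
                       nt, ny, dimnames = list(traits, years))
    gxy <- array(rnorm(g * ny * nt, 0,
                       rep(sqrt(tp$sigma_gxy2), each = g * ny)),
                 dim = c(g, ny, nt), dimnames = list(des$genotypes, years, traits))
    gxr <- array(rnorm(g * nm * nt, 0,
                       rep(sqrt(tp$sigma_gxr2), each = g * nm)),
                 dim = c(g, nm, nt), dimnames = list(des$genotypes, regimes, traits))
    blk <- array(rnorm(ny * nm * r * nt, 0,
                       rep(sqrt(tp$sigma_block2), each = ny * nm * r)),
                 dim = c(ny, nm, r, nt),
                 dimnames = list(years, regimes, des$blocks, traits))

    grid <- expand_grid(
      genotype = des$genotypes, year = years, regime = regimes,
      block = des$blocks, trait = traits
    )
    gi <- match(grid$genotype, des$genotypes)
    yi <- match(grid$year, years)
    mi <- match(grid$regime, regimes)
    ri <- match(grid$block, des$blocks)
    ti <- match(grid$trait, traits)
    value <- tp$mu[ti] +
      spec$regime_shift[cbind(ti, mi)] +
      year_eff[cbind(ti, yi)] +
      geno[cbind(gi, ti)] +
      gxy[cbind(gi, yi, ti)] +
      gxr[cbind(gi, mi, ti)] +
      blk[cbind(yi, mi, ri, ti)] +
      rnorm(nrow(grid), 0, sqrt(tp$sigma_e2)[ti])
    grid$value <- value
  })
  phenotype_table(grid, design = des)
}

# effective per-environment truths implied by a spec: within one
# year x regime subset the GxY and GxR draws act as genotype effects
effective_truth <- function(spec) {
  tp <- spec$trait_params
  sg2_eff <- tp$sigma_g2 + tp$sigma_gxy2 + tp$sigma_gxr2
  mu_env <- tp$mu + spec$regime_shift[, spec$design$control]
  tibble(
    trait = tp$trait,
    sigma_g2 = sg2_eff,
    sigma_e2 = tp$sigma_e2,
    h2 = 100 * sg2_eff / (sg2_eff + tp$sigma_e2),
    gcv = 100 * sqrt(sg2_eff) / mu_env,
    mu = mu_env
  )
}

effective_rg <- function(spec, t1, t2) {
  tp <- spec$trait_params
  i <- match(t1, tp$trait); j <- match(t2, tp$trait)
  num <- spec$genetic_cor[i, j] * sqrt(tp$sigma_g2[i] * tp$sigma_g2[j])
  eff <- tp$sigma_g2 + tp$sigma_gxy2 + tp$sigma_gxr2
  num / sqrt(eff[i] * eff[j])
}

#' Parameter-recovery experiment on synthetic trials
#'
#' Repeatedly generates trials from a spec (seed incremented per
#' replicate), runs the per-environment estimation pipeline on the first
#' year of the control regime, and compares the Monte-Carlo distribution of
#' the estimators with the truth the spec implies. Because a single
#' year x regime subset cannot separate genotype main effects from G x year
#' and G x regime interactions, truths are the *effective* per-environment
#' values (genotypic variance plus both interaction variances); genotypic
#' correlations are attenuated accordingly.
#'
#' @param spec A `synthetic_trial_spec`.
#' @param n_replicates Number of replicate trials (>= 2).
#' @param traits Traits to track (default: all).
#' @param rg_pair Length-2 trait vector for the genotypic-correlation
#'   estimator (default: first two traits); set NULL to skip.
#' @return A tibble of class `recovery_report`: one row per estimator x
#'   trait with `truth`, `mean_est`, `bias`, `sd`, `mc_se`, `within_2se`
#'   (is the Monte-Carlo mean within 2 MC standard errors of the truth),
#'   and `truncation_freq` for the genotypic variance.
#' @export
recovery_experiment <- function(spec, n_replicates, traits = NULL,
                                rg_pair = spec$design$traits[1:2]) {
  stopifnot(inherits(spec, "synthetic_trial_spec"), n_replicates >= 2)
  des <- spec$design
  if (is.null(traits)) traits <- des$traits
  year <- des$years[[1]]; regime <- des$control

  est <- vector("list", n_replicates)
  for (i in seq_len(n_replicates)) {
    sp_i <- spec
    sp_i$seed <- spec$seed + i
    tab <- generate_trial(sp_i)
    per_trait <- lapply(traits, function(tr) {
      a <- rcbd_anova(tab, tr, year, regime)
      vc <- variance_components(a)
      cv <- coefficients_of_variation(vc, a$grand_mean)
      tibble(trait = tr, sigma_g2 = vc$sigma_g2, h2 = heritability(vc),
             gcv = cv$gcv, truncated = vc$negative_truncated)
    })
    res <- bind_rows(per_trait)
    if (!is.null(rg_pair)) {
      cpc <- cross_product_components(tab, traits = rg_pair, year = year,
                                      regime = regime)
      cm <- correlation_matrices(cpc)
      res$r_g <- c(cm$r_g[rg_pair[1], rg_pair[2]], rep(NA, nrow(res) - 1))
    }
    est[[i]] <- res
  }
  est <- bind_rows(est, .id = "replicate")
  truth <- effective_truth(spec)

  summarise_est <- function(values, truth_value, extra = NULL) {
    truth_value <- unname(truth_value)
    m <- mean(values); s <- sd(values)
    tibble(truth = truth_value, mean_est = m, bias = m - truth_value,
           sd = s, mc_se = s / sqrt(length(values)),
           within_2se = abs(m - truth_value) <= 2 * s / sqrt(length(values)))
  }
  out <- list()
  for (tr in traits) {
    e <- filter(est, .data$trait == tr)
    tt <- filter(truth, .data$trait == tr)
    for (param in c("sigma_g2", "h2", "gcv")) {
      row <- summarise_est(e[[param]], tt[[param]])
      row$estimator <- param; row$trait <- tr
      row$truncation_freq <- if (param == "sigma_g2") mean(e$truncated) else NA_real_
      out[[length(out) + 1]] <- row
    }
  }
  if (!is.null(rg_pair)) {
    rg <- est$r_g[!is.na(est$r_g)]
    row <- summarise_est(rg, effective_rg(spec, rg_pair[1], rg_pair[2]))
    row$estimator <- "r_g"
    row$trait <- paste(rg_pair, collapse = ":")
    row$truncation_freq <- NA_real_
    out[[length(out) + 1]] <- row
  }
  report <- select(bind_rows(out), "estimator", "trait", "truth", "mean_est",
                   "bias", "sd", "mc_se", "within_2se", "truncation_freq")
  class(report) <- c("recovery_report", class(report))
  attr(report, "n_replicates") <- n_replicates
  report
}
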