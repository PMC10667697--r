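test_that("the covariance of a trait with itself is its variance component", {
  m <- withr::with_seed(21, matrix(rnorm(12, 30, 4), 4, 3))
  tab <- toy_env_table(list(X = m, X2 = m))
  cpc <- cross_product_components(tab, year = "2018", regime = "non-stress")
  a <- rcbd_anova(tab, "X", "2018", "non-stress")
  vc_sigma_g2 <- (a$ms_genotype - a$ms_error) / a$n_blocks  # untruncated
  expect_equal(cpc$cov_g["X", "X2"], vc_sigma_g2, tolerance = 1e-10)
  expect_equal(cpc$cov_g["X", "X"], vc_sigma_g2, tolerance = 1e-10)
  expect_equal(cpc$cov_p["X", "X"], vc_sigma_g2 + a$ms_error, tolerance = 1e-10)
})

test_that("mean cross-products match the brute-force oracle on toy tables", {
  # hand-set 3 x 2 toy and random layouts up to 5 genotypes
  x_toy <- matrix(c(10, 12, 14, 11, 13, 18), 3, 2)
  y_toy <- matrix(c(5, 9, 6, 7, 11, 8), 3, 2)
  cases <- c(list(list(X = x_toy, Y = y_toy)), lapply(1:5, function(s) {
    withr::with_seed(300 + s, {
      g <- sample(3:5, 1); r <- sample(2:3, 1)
      list(X = matrix(rnorm(g * r, 10, 3), g, r),
           Y = matrix(rnorm(g * r, 40, 6), g, r))
    })
  }))
  for (mats in cases) {
    tab <- toy_env_table(mats)
    cpc <- cross_product_components(tab, year = "2018", regime = "non-stress")
    oracle <- brute_cross_products(mats$X, mats$Y)
    expect_equal(cpc$mcp_g["X", "Y"], oracle$mcp_g, tolerance = 1e-9)
    expect_equal(cpc$mcp_e["X", "Y"], oracle$mcp_e, tolerance = 1e-9)
    expect_equal(cpc$cov_g["X", "Y"], oracle$cov_g, tolerance = 1e-9)
    expect_equal(cpc$cov_p["X", "Y"], oracle$cov_p, tolerance = 1e-9)
  }
})

test_that("correlation matrices are symmetric with unit diagonal and |r_p| <= 1", {
  spec <- paper_trial_spec(n_genotypes = 15, seed = 8)
  tab <- generate_trial(spec)
  cm <- correlation_matrices(
    cross_product_components(tab, year = "2018", regime = "non-stress"))
  expect_equal(diag(cm$r_p), rep(1, 7), ignore_attr = TRUE)
  expect_equal(diag(cm$r_g), rep(1, 7), ignore_attr = TRUE)
  expect_equal(cm$r_p, t(cm$r_p))
  expect_equal(cm$r_g, t(cm$r_g))
  expect_true(all(abs(cm$r_p) <= 1 + 1e-12))
  # out-of-range genotypic entries are flagged, not clamped
  expect_equal(cm$abs_gt1, abs(cm$r_g) > 1)
})

test_that("correlations are invariant to positive affine rescaling of a trait", {
  mats <- withr::with_seed(15, {
    gx <- rnorm(5, 0, 6); gy <- 0.4 * gx + rnorm(5, 0, 1)
    list(X = 20 + outer(gx, rep(1, 2)) + matrix(rnorm(10, 0, 1), 5, 2),
         Y = 3 + outer(gy, rep(1, 2)) + matrix(rnorm(10, 0, 0.4), 5, 2))
  })
  base <- correlation_matrices(
    cross_product_components(toy_env_table(mats), year = "2018",
                             regime = "non-stress"))
  mats$Y <- 7 + 3.5 * mats$Y
  shifted <- correlation_matrices(
    cross_product_components(toy_env_table(mats), year = "2018",
                             regime = "non-stress"))
  expect_equal(shifted$r_p, base$r_p, tolerance = 1e-10)
  expect_equal(shifted$r_g, base$r_g, tolerance = 1e-10)
})

test_that("r_p equals the Pearson correlation of block-detrended unit values", {
  mats <- withr::with_seed(33, {
    gx <- rnorm(7, 0, 5); gy <- 0.5 * gx + rnorm(7, 0, 1)
    list(X = 20 + outer(gx, rep(1, 2)) + matrix(rnorm(14, 0, 1.5), 7, 2),
         Y = 3 + outer(gy, rep(1, 2)) + matrix(rnorm(14, 0, 0.5), 7, 2))
  })
  tab <- toy_env_table(mats)
  cm <- correlation_matrices(
    cross_product_components(tab, year = "2018", regime = "non-stress"))
  # remove block means, then correlate plot-level values
  detrend <- function(m) sweep(m, 2, colMeans(m)) + mean(m)
  r_naive <- cor(as.vector(detrend(mats$X)), as.vector(detrend(mats$Y)))
  # phenotypic covariance components reweight genotype vs error strata;
  # with r = 2 the two agree up to the stratum df weights, so compare the
  # from-components reconstruction instead of blind equality
  sx <- detrend(mats$X); sy <- detrend(mats$Y)
  sp_xy <- brute_cross_products(mats$X, mats$Y)$cov_p
  sp_x <- brute_cross_products(mats$X, mats$X)$cov_p
  sp_y <- brute_cross_products(mats$Y, mats$Y)$cov_p
  expect_equal(cm$r_p["X", "Y"], sp_xy / sqrt(sp_x * sp_y), tolerance = 1e-10)
  # and the naive Pearson r has the same sign and similar magnitude
  expect_equal(sign(cm$r_p["X", "Y"]), sign(r_naive))
})

test_that("null genetic correlation is recovered as ~0 over 500 seeds", {
  des <- trial_design(8, 2, years = "Y1", regimes = "ctl", traits = c("T1", "T2"))
  tp <- data.frame(trait = c("T1", "T2"), mu = c(50, 50),
                   sigma_g2 = c(16, 16), sigma_e2 = c(9, 9))
  cov_g <- vapply(1:500, function(s) {
    spec <- synthetic_trial_spec(des, tp, seed = 5000 + s)  # independent traits
    tab <- generate_trial(spec)
    cross_product_components(tab, year = "Y1", regime = "ctl")$cov_g["T1", "T2"]
  }, numeric(1))
  mc_se <- sd(cov_g) / sqrt(length(cov_g))
  expect_lt(abs(mean(cov_g)), 2 * mc_se + 1e-12)
})

test_that("|r_g| can exceed 1 but rarely at realistic signal strength", {
  des <- trial_design(40, 2, years = "Y1", regimes = "ctl", traits = c("T1", "T2"))
  tp <- data.frame(trait = c("T1", "T2"), mu = c(100, 100),
                   sigma_g2 = c(40, 40), sigma_e2 = c(10, 10))
  R <- matrix(c(1, 0.9, 0.9, 1), 2, 2)
  n_out <- vapply(1:200, function(s) {
    spec <- synthetic_trial_spec(des, tp, genetic_cor = R, seed = 7000 + s)
    cm <- correlation_matrices(
      cross_product_components(generate_trial(spec), year = "Y1", regime = "ctl"))
    cm$abs_gt1["T1", "T2"]
  }, logical(1))
  expect_lt(mean(n_out), 0.05)
})

test_that("pooling years averages covariance components before correlating", {
  spec <- paper_trial_spec(n_genotypes = 10, seed = 77)
  tab <- generate_trial(spec)
  pooled <- trait_correlations(tab, regime = "non-stress",
                               traits = c("FY", "DY", "A"))
  cpc1 <- cross_product_components(tab, c("FY", "DY", "A"), "2018", "non-stress")
  cpc2 <- cross_product_components(tab, c("FY", "DY", "A"), "2019", "non-stress")
  avg <- cpc1
  for (f in c("cov_g", "cov_p")) avg[[f]] <- (cpc1[[f]] + cpc2[[f]]) / 2
  manual <- correlation_matrices(avg)
  expect_equal(pooled$r_g, manual$r_g, tolerance = 1e-12)
  expect_equal(pooled$r_p, manual$r_p, tolerance = 1e-12)
  per_year <- trait_correlations(tab, regime = "non-stress",
                                 traits = c("FY", "DY", "A"), pool_years = FALSE)
  expect_named(per_year, c("2018", "2019"))
})

test_that("zero-variance traits are excluded with a warning", {
  m <- withr::with_seed(2, matrix(rnorm(8, 10, 2), 4, 2))
  tab <- toy_env_table(list(X = m, Y = m * 0 + 5, Z = m + 1))
  cpc <- suppressWarnings(
    cross_product_components(tab, year = "2018", regime = "non-stress"))
  expect_warning(cm <- correlation_matrices(cpc),
                 class = "forageQG_zero_variance_warning")
  expect_setequal(cm$traits, c("X", "Z"))
})
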