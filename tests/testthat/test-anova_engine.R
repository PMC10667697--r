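test_that("constant data yields zero sums of squares everywhere", {
  m <- matrix(7, 4, 2)
  tab <- toy_env_table(m)
  # (aov warns that F-tests on a perfect fit are unreliable; SS are exact)
  a <- suppressWarnings(rcbd_anova(tab, "Y", "2018", "non-stress"))
  expect_equal(a$anova$ss, rep(0, 3))
  expect_equal(a$grand_mean, 7)
})

test_that("RCBD sums of squares match the brute-force mean-contrast oracle", {
  # hand-built 3 x 2 toy plus random balanced layouts up to 5 genotypes
  toy <- matrix(c(10, 12, 14, 11, 13, 18), nrow = 3)
  cases <- c(list(toy), lapply(1:6, function(s) {
    withr::with_seed(100 + s, {
      g <- sample(3:5, 1); r <- sample(2:4, 1)
      matrix(rnorm(g * r, 20, 5), nrow = g, ncol = r)
    })
  }))
  for (m in cases) {
    a <- rcbd_anova(toy_env_table(m), "Y", "2018", "non-stress")
    oracle <- brute_rcbd_ss(m)
    expect_equal(a$anova$ss[a$anova$source == "genotype"], oracle$genotype,
                 tolerance = 1e-9)
    expect_equal(a$anova$ss[a$anova$source == "block"], oracle$block,
                 tolerance = 1e-9)
    expect_equal(a$anova$ss[a$anova$source == "error"], oracle$error,
                 tolerance = 1e-9)
    expect_equal(sum(a$anova$ss), oracle$total, tolerance = 1e-9)
    expect_equal(a$anova$df, c(ncol(m) - 1, nrow(m) - 1,
                               (ncol(m) - 1) * (nrow(m) - 1)))
  }
})

test_that("SS are invariant to genotype relabelling and shifts, scale as c^2", {
  m <- withr::with_seed(9, matrix(rnorm(10, 50, 8), 5, 2))
  base <- rcbd_anova(toy_env_table(m), "Y", "2018", "non-stress")$anova$ss
  perm <- rcbd_anova(toy_env_table(m[c(3, 1, 5, 2, 4), ]),
                     "Y", "2018", "non-stress")$anova$ss
  expect_equal(perm, base, tolerance = 1e-12)
  shifted <- rcbd_anova(toy_env_table(m + 100), "Y", "2018", "non-stress")$anova$ss
  expect_equal(shifted, base, tolerance = 1e-9)
  scaled <- rcbd_anova(toy_env_table(3 * m), "Y", "2018", "non-stress")$anova$ss
  expect_equal(scaled, 9 * base, tolerance = 1e-9)
})

test_that("under a null genotype effect MS_g and MS_e agree on average", {
  # E(MS_g) = sigma_e^2 + r sigma_g^2 with sigma_g^2 = 0 -> both estimate
  # sigma_e^2; the mean difference over seeds is ~0
  diffs <- vapply(1:500, function(s) {
    m <- withr::with_seed(2000 + s, matrix(rnorm(12, 10, 2), 6, 2))
    a <- rcbd_anova(toy_env_table(m), "Y", "2018", "non-stress")
    a$ms_genotype - a$ms_error
  }, numeric(1))
  mc_se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 2 * mc_se + 1e-12)
})

test_that("unbalanced or degenerate subsets are refused", {
  tab <- random_trial(3, 2, regimes = "ctl", traits = "Y", seed = 2)
  broken <- suppressWarnings(phenotype_table(as.data.frame(tab)[-1, ]))
  expect_error(rcbd_anova(broken, "Y", "2018", "ctl"),
               class = "forageQG_design_error")
  expect_error(rcbd_anova(tab, "Y", "2018", "missing-regime"),
               class = "forageQG_design_error")
})

test_that("combined ANOVA df match the full factorial bookkeeping", {
  # the study layout: g = 100, r = 2, 2 years, 2 regimes
  tab <- random_trial(100, 2, years = c("2018", "2019"),
                      regimes = c("ctl", "str"), traits = "Y", seed = 77)
  ca <- combined_anova(tab, "Y")
  expect_equal(ca$anova$source,
               c("Ir", "Error I", "G", "Ir x G", "Error II",
                 "Y", "Y x Ir", "Y x G", "Y x G x Ir", "Residual"))
  expect_equal(ca$anova$df, c(1, 2, 99, 99, 198, 1, 1, 99, 99, 200))
  expect_equal(sum(ca$anova$df), 2 * 2 * 2 * 100 - 1)
  # SS decomposition is exhaustive and non-negative
  expect_true(all(ca$anova$ss >= 0))
  mu <- mean(tab$value[tab$trait == "Y"])
  expect_equal(sum(ca$anova$ss), sum((tab$value[tab$trait == "Y"] - mu)^2),
               tolerance = 1e-9)
})

test_that("combined ANOVA on constant data is all-zero and errors without 2 years/regimes", {
  des <- trial_design(3, 2, years = c("Y1", "Y2"), regimes = c("ctl", "str"),
                      traits = "Y")
  grid <- tidyr::expand_grid(
    genotype = des$genotypes, year = des$years, regime = des$regimes,
    block = des$blocks, trait = des$traits)
  grid$value <- 5
  tab <- phenotype_table(grid)
  ca <- combined_anova(tab, "Y")
  expect_equal(ca$anova$ss, rep(0, 10), tolerance = 1e-20)

  one_year <- phenotype_table(grid[grid$year == "Y1", ])
  expect_error(combined_anova(one_year, "Y"), class = "forageQG_design_error")
})

test_that("combined ANOVA stratum SS agree with per-stratum brute sums", {
  tab <- random_trial(4, 3, years = c("Y1", "Y2"), regimes = c("ctl", "str"),
                      traits = "Y", seed = 31)
  d <- as.data.frame(tab)
  ca <- combined_anova(tab, "Y")$anova
  mu <- mean(d$value)
  # regime main effect from regime means
  ss_ir <- 2 * 3 * 4 * sum((tapply(d$value, d$regime, mean) - mu)^2)
  expect_equal(ca$ss[ca$source == "Ir"], ss_ir, tolerance = 1e-9)
  # genotype main effect from genotype means
  ss_g <- 2 * 2 * 3 * sum((tapply(d$value, d$genotype, mean) - mu)^2)
  expect_equal(ca$ss[ca$source == "G"], ss_g, tolerance = 1e-9)
  # Error I: block-within-regime means around their regime mean
  mr <- tapply(d$value, list(d$regime, d$block), mean)
  m_reg <- tapply(d$value, d$regime, mean)
  ss_e1 <- 2 * 4 * sum((mr - matrix(m_reg, 2, 3))^2)
  expect_equal(ca$ss[ca$source == "Error I"], ss_e1, tolerance = 1e-9)
})
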