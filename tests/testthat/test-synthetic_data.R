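test_that("generation is deterministic under the spec seed", {
  spec <- paper_trial_spec(n_genotypes = 8, seed = 123)
  t1 <- generate_trial(spec)
  t2 <- generate_trial(spec)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  spec2 <- paper_trial_spec(n_genotypes = 8, seed = 124)
  expect_false(identical(t1$value, generate_trial(spec2)$value))
  # the caller's RNG stream is untouched
  withr::with_seed(55, r_before <- rnorm(1))
  withr::with_seed(55, { invisible(generate_trial(spec)); r_after <- rnorm(1) })
  expect_identical(r_before, r_after)
})

test_that("all-zero variances reproduce the fixed effects exactly", {
  des <- trial_design(3, 2, years = c("Y1", "Y2"), regimes = c("ctl", "str"),
                      traits = c("T1", "T2"))
  tp <- data.frame(trait = c("T1", "T2"), mu = c(100, 10),
                   sigma_g2 = 0, sigma_e2 = 0)
  shift <- rbind(T1 = c(0, -40), T2 = c(0, -3))
  spec <- synthetic_trial_spec(des, tp, regime_shift = shift, seed = 2)
  tab <- as.data.frame(generate_trial(spec))
  expect_equal(tab$value[tab$trait == "T1" & tab$regime == "ctl"],
               rep(100, 12))
  expect_equal(tab$value[tab$trait == "T1" & tab$regime == "str"],
               rep(60, 12))
  expect_equal(tab$value[tab$trait == "T2" & tab$regime == "str"],
               rep(7, 12))
})

test_that("invalid specs are rejected", {
  des <- trial_design(3, 2, years = "Y1", regimes = "ctl", traits = c("T1", "T2"))
  tp <- data.frame(trait = c("T1", "T2"), mu = 10, sigma_g2 = 1, sigma_e2 = 1)
  bad_cor <- matrix(c(1, 2, 2, 1), 2, 2)  # not PSD
  expect_error(synthetic_trial_spec(des, tp, genetic_cor = bad_cor),
               class = "forageQG_spec_error")
  tp_neg <- tp; tp_neg$sigma_e2 <- -1
  expect_error(synthetic_trial_spec(des, tp_neg),
               class = "forageQG_spec_error")
  expect_error(synthetic_trial_spec(des, tp[1, ]),
               class = "forageQG_spec_error")
})

test_that("simulated genotype effects converge to the specified variance", {
  des <- trial_design(2000, 2, years = "Y1", regimes = "ctl", traits = "T1")
  tp <- data.frame(trait = "T1", mu = 50, sigma_g2 = 36, sigma_e2 = 4)
  spec <- synthetic_trial_spec(des, tp, seed = 31)
  tab <- as.data.frame(generate_trial(spec))
  geno_means <- tapply(tab$value, tab$genotype, mean)
  # Var(genotype mean) = sigma_g2 + sigma_e2 / r
  expect_equal(var(geno_means), 36 + 4 / 2, tolerance = 0.05)
})

test_that("the default spec reproduces the study-scale drought losses", {
  # FY drought shift was calibrated so that the control-vs-stress gap
  # is ~43% of the stress mean; averaged over seeds the generated tables
  # reproduce it
  reductions <- vapply(1:25, function(s) {
    spec <- paper_trial_spec(n_genotypes = 40, seed = 1000 + s)
    spec$trait_params$sigma_y2 <- 0  # isolate the regime contrast
    tab <- as.data.frame(generate_trial(spec))
    fy <- tab[tab$trait == "FY" & tab$year == "2018", ]
    percent_reduction(mean(fy$value[fy$regime == "non-stress"]),
                      mean(fy$value[fy$regime == "drought"]))
  }, numeric(1))
  expect_equal(mean(reductions), 43.1, tolerance = 0.05)
})

test_that("genotype effects carry the specified cross-trait correlation", {
  des <- trial_design(1500, 2, years = "Y1", regimes = "ctl",
                      traits = c("T1", "T2"))
  tp <- data.frame(trait = c("T1", "T2"), mu = c(100, 50),
                   sigma_g2 = c(25, 16), sigma_e2 = c(1, 1))
  R <- matrix(c(1, 0.8, 0.8, 1), 2, 2)
  spec <- synthetic_trial_spec(des, tp, genetic_cor = R, seed = 77)
  tab <- as.data.frame(generate_trial(spec))
  gm1 <- tapply(tab$value[tab$trait == "T1"], tab$genotype[tab$trait == "T1"], mean)
  gm2 <- tapply(tab$value[tab$trait == "T2"], tab$genotype[tab$trait == "T2"], mean)
  # genotype means carry error noise sigma_e2 / r, attenuating the
  # correlation to 0.8 * 20 / sqrt(25.5 * 16.5) = 0.780
  attenuated <- 0.8 * sqrt(25 * 16) / sqrt((25 + 0.5) * (16 + 0.5))
  expect_equal(cor(gm1, gm2), attenuated, tolerance = 0.03)
})

test_that("recovery_experiment reports unbiased estimates and truncation under the null", {
  # no genotypic signal: MS_g < MS_e about half the time
  des <- trial_design(20, 2, years = "Y1", regimes = "ctl", traits = "T1")
  tp <- data.frame(trait = "T1", mu = 50, sigma_g2 = 0, sigma_e2 = 9)
  spec <- synthetic_trial_spec(des, tp, seed = 40)
  rep0 <- recovery_experiment(spec, n_replicates = 400, rg_pair = NULL)
  tf <- rep0$truncation_freq[rep0$estimator == "sigma_g2"]
  expect_gt(tf, 0.4)
  expect_lt(tf, 0.6)

  # strong genotypic correlation is recovered
  des2 <- trial_design(80, 2, years = "Y1", regimes = "ctl",
                       traits = c("T1", "T2"))
  tp2 <- data.frame(trait = c("T1", "T2"), mu = c(100, 60),
                    sigma_g2 = c(40, 30), sigma_e2 = c(10, 8))
  R <- matrix(c(1, 0.95, 0.95, 1), 2, 2)
  spec2 <- synthetic_trial_spec(des2, tp2, genetic_cor = R, seed = 50)
  rep2 <- recovery_experiment(spec2, n_replicates = 150)
  rg <- rep2[rep2$estimator == "r_g", ]
  expect_equal(rg$truth, 0.95)
  expect_lt(abs(rg$bias), 3 * rg$mc_se + 0.01)
})

test_that("effective per-environment truths account for interaction variance", {
  des <- trial_design(10, 2, years = c("Y1", "Y2"), regimes = c("ctl", "str"),
                      traits = c("T1", "T2"))
  tp <- data.frame(trait = c("T1", "T2"), mu = c(100, 50),
                   sigma_g2 = c(30, 20), sigma_e2 = c(10, 10),
                   sigma_gxy2 = c(6, 4), sigma_gxr2 = c(3, 2))
  spec <- synthetic_trial_spec(des, tp, seed = 3)
  truth <- forageQG:::effective_truth(spec)
  expect_equal(truth$sigma_g2, c(39, 26))
  expect_equal(truth$h2, 100 * c(39, 26) / c(49, 36))
  # r_g attenuated by the uncorrelated interaction variance
  expect_equal(forageQG:::effective_rg(spec, "T1", "T2"), 0)
  spec$genetic_cor <- matrix(c(1, 0.9, 0.9, 1), 2, 2,
                             dimnames = list(c("T1", "T2"), c("T1", "T2")))
  expect_equal(forageQG:::effective_rg(spec, "T1", "T2"),
               0.9 * sqrt(30 * 20) / sqrt(39 * 26))
})
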