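# Peak-decay fitting, protection free energies, hyperprotection, regime
# classification, and survivor counting.

test_that("noiseless single-exponential input is recovered to high precision", {
  t <- seq(0, 600, by = 10)
  for (k in c(0.2, 0.01, 5e-4)) {
    f <- fit_decay(t, exp(-k * t))
    expect_lt(abs(f$k_HDX - k) / k, 1e-8)
    expect_lt(abs(f$amplitude - 1), 1e-8)
    expect_false(f$hyperprotected)
  }
})

test_that("decay fitting validates its inputs", {
  expect_error(fit_decay(c(0, 10), c(1, 0.5)), "3 time points")
  expect_error(fit_decay(c(0, 10, 5), c(1, 0.9, 0.8)), "increasing")
  expect_error(fit_decay(c(0, 10, 20), c(0, 0, 0)), "all-zero")
  expect_error(fit_decay(c(0, 10, 20), c(1, -0.1, 0.2)), "non-negative")
})

test_that("a flat series over a month is flagged hyperprotected", {
  t <- seq(10, 40320, length.out = 60)   # 10 min to 28 days
  f <- fit_decay(t, rep(1, 60))
  expect_true(f$hyperprotected)
  expect_true(is.na(f$k_HDX))
  expect_equal(f$resolvable_lower_bound, log(1 / 0.8) / 40320)
  # a clearly decaying series is never hyperprotected
  expect_false(fit_decay(t, exp(-1e-4 * t))$hyperprotected)
})

test_that("noisy rate recovery is accurate in the median over replicates", {
  t <- seq(10, 1000, by = 10)
  k <- 0.005
  errs <- vapply(1:100, function(s) {
    set.seed(s)
    h <- pmax(exp(-k * t) * (1 + rnorm(length(t), sd = 0.02)), 0)
    abs(fit_decay(t, h)$k_HDX - k) / k
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})

test_that("protection free energies follow -RT ln K with R in kcal/mol/K", {
  # unprotected limit
  p0 <- protection_energy(0.3, 0.3, 298.15)
  expect_equal(p0$K_unfold, 1)
  expect_equal(p0$dG_local, 0)
  # frozen values from direct evaluation of -RT ln(1e-5)
  expect_equal(round(protection_energy(1e-5, 1, 298.15)$dG_local, 2), 6.82)
  expect_equal(round(protection_energy(1e-5, 1, 323.15)$dG_local, 2), 7.39)
  expect_error(protection_energy(-1, 1, 298), "positive")
  # strictly decreasing in K_unfold
  Ks <- 10^seq(-6, -1, by = 0.5)
  dG <- protection_energy(Ks, 1, 298.15)$dG_local
  expect_true(all(diff(dG) < 0))
})

test_that("regime labels follow the log-shift decision bands", {
  expect_equal(classify_regime(1e-3, 1e-2, 1)$label, "EX2")
  expect_equal(classify_regime(1e-3, 1e-2, 1)$log_rate_shift, 1)
  expect_equal(classify_regime(2e-4, 2e-4, 1)$label, "EX1")
  expect_equal(classify_regime(1e-3, 10^(-3 + 0.5), 1)$label, "intermediate")
  # hyperprotected estimates cannot be classified
  t <- seq(10, 40320, length.out = 40)
  hyper <- fit_decay(t, rep(1, 40))
  expect_error(classify_regime(hyper, 1e-3, 1), "hyperprotected")
})

test_that("EX2- and EX1-simulated residues are labeled correctly at 2% noise", {
  p <- acp_study_preset()
  dG <- p$dG_local[as.character(c(11, 12, 14, 30, 31, 47, 50, 70, 74))]
  ex2 <- simulate_hdx(p$sequence, dG, pD = c(5.5, 6.5), noise_sd = 0.02,
                      times = p$times, seed = 101)
  f2 <- fit_hdx_rates(ex2)
  lab2 <- vapply(unique(f2$residue_index), function(r) {
    classify_regime(f2$k_HDX[f2$residue_index == r & f2$pD == 5.5],
                    f2$k_HDX[f2$residue_index == r & f2$pD == 6.5], 1)$label
  }, character(1))
  expect_gte(mean(lab2 == "EX2"), 0.95)

  ku <- setNames(rep(1e-4, length(dG)), names(dG))
  mech <- setNames(rep("EX1", length(dG)), names(dG))
  ex1 <- simulate_hdx(p$sequence, dG, pD = c(5.5, 6.5), noise_sd = 0.02,
                      times = p$times, mechanism = mech, k_unfold = ku,
                      seed = 102)
  f1 <- fit_hdx_rates(ex1)
  lab1 <- vapply(unique(f1$residue_index), function(r) {
    classify_regime(f1$k_HDX[f1$residue_index == r & f1$pD == 5.5],
                    f1$k_HDX[f1$residue_index == r & f1$pD == 6.5], 1)$label
  }, character(1))
  expect_gte(mean(lab1 == "EX1"), 0.95)
})

test_that("survivor counting interpolates heights against the threshold", {
  pt <- small_peak_table()
  expect_equal(count_survivors(pt, 25, threshold = 0), 2L)
  expect_equal(count_survivors(NULL, 10), 0L)
  expect_equal(count_survivors(pt[0, ], 10), 0L)
  # residue 6 decays with k = 0.05: height at 25 min ~ 0.29
  expect_equal(count_survivors(pt, 25, threshold = 0.5), 1L)
  expect_error(count_survivors(pt, 500), "outside")
})

test_that("fitted rates and intrinsic rates reproduce the simulated energies", {
  # pipeline equivalence on a noiseless subset: simulate at one pD, fit, and
  # convert back through the same intrinsic-rate profile
  p <- acp_study_preset()
  dG <- p$dG_local[as.character(c(26, 46, 50, 63, 69, 75))]
  peaks <- simulate_hdx(p$sequence, dG, pD = 5.5, noise_sd = 0,
                        times = p$times, seed = 1)
  fits <- fit_hdx_rates(peaks)
  kp <- krc_profile(p$sequence, exchange_conditions(5.5, 298.15))
  krc <- kp$k_rc[match(fits$residue_index, kp$position)]
  rec <- protection_energy(fits$k_HDX, krc, 298.15)$dG_local
  expect_equal(rec, unname(dG[as.character(fits$residue_index)]),
               tolerance = 1e-6)
})
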