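# Generators: forward-model correctness and seeded reproducibility.

test_that("generators are bit-reproducible under a seed", {
  p <- acp_study_preset()
  a <- simulate_hdx(p$sequence, p$dG_local[1:5], pD = 5.5, noise_sd = 0.02,
                    seed = 99)
  b <- simulate_hdx(p$sequence, p$dG_local[1:5], pD = 5.5, noise_sd = 0.02,
                    seed = 99)
  expect_identical(a, b)
  expect_identical(simulate_denaturation(8, 2, noise_sd = 50, seed = 1),
                   simulate_denaturation(8, 2, noise_sd = 50, seed = 1))
  expect_identical(simulate_thermogram(95, 100, noise_sd = 0.1, seed = 1),
                   simulate_thermogram(95, 100, noise_sd = 0.1, seed = 1))
  e1 <- simulate_helix_bundle_ensemble(3, 0.2, seed = 4)
  e2 <- simulate_helix_bundle_ensemble(3, 0.2, seed = 4)
  expect_identical(e1$models[[2]]$x, e2$models[[2]]$x)
  # the generator does not disturb the global RNG stream
  set.seed(10); before <- rnorm(1)
  set.seed(10); invisible(simulate_denaturation(8, 2, noise_sd = 1, seed = 3))
  expect_identical(rnorm(1), before)
})

test_that("EX2 exchange rates invert the protection free energy exactly", {
  p <- acp_study_preset()
  # free energy chosen so that K_unfold is exactly 1e-5 at 298.15 K
  dG <- c(`46` = 1.987e-3 * 298.15 * log(1e5))
  peaks <- simulate_hdx(p$sequence, dG, pD = 6.5, temperature = 298.15,
                        noise_sd = 0)
  truth <- attr(peaks, "truth")
  kp <- krc_profile(p$sequence, exchange_conditions(6.5, 298.15))
  k_expected <- 1e-5 * kp$k_rc[kp$position == 46]
  expect_equal(truth$k_true, k_expected, tolerance = 1e-10)
})

test_that("EX2 rates shift tenfold between pD 5.5 and 6.5; EX1 rates do not", {
  p <- acp_study_preset()
  dG <- c(`46` = 5, `63` = 4)
  ex2 <- attr(simulate_hdx(p$sequence, dG, pD = c(5.5, 6.5)), "truth")
  for (r in c(46, 63)) {
    ks <- ex2$k_true[ex2$residue_index == r]
    expect_equal(log10(ks[2] / ks[1]), 1, tolerance = 0.01)
  }
  ex1 <- simulate_hdx(p$sequence, dG, pD = c(5.5, 6.5),
                      mechanism = c(`46` = "EX1", `63` = "EX1"),
                      k_unfold = c(`46` = 1e-4, `63` = 2e-4))
  lo <- ex1[ex1$pD == 5.5, c("residue_index", "time_min", "height")]
  hi <- ex1[ex1$pD == 6.5, c("residue_index", "time_min", "height")]
  expect_equal(lo, hi, ignore_attr = TRUE)
})

test_that("hyperprotected residues are emitted with constant unit height", {
  p <- acp_study_preset()
  peaks <- simulate_hdx(p$sequence, c(`46` = 5), hyperprotected = 15,
                        pD = 5.5, noise_sd = 0)
  h15 <- peaks$height[peaks$residue_index == 15]
  expect_true(all(h15 == 1))
})

test_that("denaturation generator hits the baselines in its limits", {
  cur <- simulate_denaturation(12, 2, denaturant = seq(0, 8.5, 0.25))
  # far below the midpoint the signal sits on the native baseline
  expect_equal(cur$signal[1], -12000, tolerance = 1e-6)
  fN <- attr(cur, "f_N_true")
  expect_equal(fN[1], 1, tolerance = 1e-8)
})

test_that("thermogram peak sits at T_m and baseline-only input is flat", {
  th <- simulate_thermogram(90, 120, baseline = c(0, 0))
  expect_lt(abs(th$temp_C[which.max(th$signal)] - 90), 0.2 + 1e-9)
  flat <- simulate_thermogram(90, 120, scale = 0, baseline = c(1, 0.02))
  bc <- baseline_correct(flat$temp_C, flat$signal, degree = 1)
  expect_lt(max(abs(bc$corrected)), 1e-9)
})

test_that("preset reproduces the designed count structure", {
  p <- acp_study_preset()
  expect_length(p$observed, 60L)
  expect_length(p$dG_local, 59L)
  expect_equal(p$hyperprotected, 15L)
  expect_equal(sum(p$dG_local > 5), 15L)  # plus hyperprotected I15 = 16
  expect_equal(p$global_regime_residues, c(15L, 75L, 76L))
  peaks <- simulate_hdx(p$sequence, p$dG_local,
                        hyperprotected = p$hyperprotected, pD = 5.5,
                        times = p$times, noise_sd = p$noise_sd, seed = 31)
  expect_equal(count_survivors(peaks, 10, p$survivor_threshold), 46L)
})
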