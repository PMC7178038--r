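# Intrinsic (random-coil) exchange rates: reference rates, neighbor
# corrections, temperature scaling, and the per-sequence profile.

test_that("alanine context reproduces the uncorrected poly-DL-alanine rate", {
  cond <- exchange_conditions(pD = 6, temperature = 293)
  r <- krc_base("A", "A", "A", cond)
  # direct evaluation of the reference channel formulas (all factors zero)
  expect_equal(unname(r$channels["acid"]), 10^(1.62 - 6))
  expect_equal(unname(r$channels["base"]), 10^(10.05 + 6 - 15.05))
  expect_equal(unname(r$channels["water"]), 10^(-1.5))
  expect_equal(r$k_rc, sum(r$channels))
})

test_that("base-catalyzed channel scales tenfold per pD unit", {
  r55 <- krc_base("A", "L", "V", exchange_conditions(5.5))
  r65 <- krc_base("A", "L", "V", exchange_conditions(6.5))
  expect_equal(unname(r65$channels["base"] / r55$channels["base"]), 10)
  # water channel is pD-independent
  expect_equal(unname(r65$channels["water"]), unname(r55$channels["water"]))
})

test_that("Gly-Gly context matches an independent table-lookup calculation", {
  # oracle: read the packaged factor table directly and evaluate the
  # channel formulas by hand for the amide of G preceded by G at pD 6, 293 K
  tab <- read.delim(system.file("extdata", "polyala_neighbor_factors.tsv",
                                package = "acpstab", mustWork = TRUE),
                    comment.char = "#")
  g <- tab[tab$res == "G", ]
  acid <- 10^(1.62 + g$acid_left + g$acid_right - 6)
  base <- 10^(10.05 + g$base_left + g$base_right + 6 - 15.05)
  water <- 10^(-1.5 + g$base_left + g$base_right)
  r <- krc_base("G", "G", "G", exchange_conditions(pD = 6))
  expect_equal(r$k_rc, acid + base + water, tolerance = 1e-12)
})

test_that("invalid residue contexts are rejected", {
  cond <- exchange_conditions(6)
  expect_error(krc_base("B", "A", "A", cond), "unknown residue")
  expect_error(krc_base("P", "A", "A", cond), "proline")
})

test_that("meter-reading flag applies the +0.4 pD correction", {
  expect_equal(exchange_conditions(6.0, from_meter_reading = TRUE)$pD, 6.4)
})

test_that("temperature correction follows the Arrhenius factor", {
  cond <- exchange_conditions(6, temperature = 298)
  expect_equal(temperature_correct(1, cond, Ea_over_R = 8500),
               exp(-8500 * (1 / 298 - 1 / 293)))
  # reference temperature and zero activation energy leave rates unchanged
  cond293 <- exchange_conditions(6, temperature = 293)
  expect_equal(temperature_correct(2.5, cond293, Ea_over_R = 8500), 2.5)
  expect_equal(temperature_correct(2.5, cond, Ea_over_R = 0), 2.5)
  expect_error(temperature_correct(-1, cond), "positive")
  # monotone increasing in T for positive activation energy
  ks <- vapply(seq(283, 323, by = 10), function(T.)
    temperature_correct(1, exchange_conditions(6, temperature = T.)),
    numeric(1))
  expect_true(all(diff(ks) > 0))
})

test_that("profile skips residue 1 and prolines and matches krc_base", {
  cond <- exchange_conditions(6, temperature = 298)
  p <- krc_profile("AAAAA", cond)
  expect_equal(p$position, 2:5)
  # interior alanines share an identical context; the second and last
  # residues additionally feel the terminal groups
  expect_equal(p$k_rc[2], p$k_rc[3])
  expect_gt(p$k_rc[1], p$k_rc[2])   # N-terminal ammonium accelerates (base)
  expect_true(all(p$k_rc > 0))

  pp <- krc_profile("AAPA", cond)
  expect_false(3 %in% pp$position)   # proline has no amide proton
  expect_true(all(c(2, 4) %in% pp$position))
  expect_error(krc_profile("A", cond), "at least 2")

  # composition oracle: profile equals krc_base + temperature_correct
  seqs <- "MSTIEERVKKIIGEQLG"
  prof <- krc_profile(seqs, cond)
  res <- strsplit(seqs, "")[[1]]
  i <- 5L
  manual <- temperature_correct(
    krc_base(res[i], res[i - 1], res[i + 1], cond,
             n_terminal = FALSE, c_terminal = FALSE), cond)
  expect_equal(prof$k_rc[prof$position == i], manual$k_rc, tolerance = 1e-12)
})

test_that("log10 rate shift is one unit across the pD 5-7 base regime", {
  seqs <- acp_reference_sequence()
  for (pd in c(5.5, 6.0)) {
    lo <- krc_profile(seqs, exchange_conditions(pd, temperature = 298))
    hi <- krc_profile(seqs, exchange_conditions(pd + 1, temperature = 298))
    shift <- log10(hi$k_rc) - log10(lo$k_rc)
    base_frac <- lo$k_base / lo$k_rc
    # within 0.01 log units for every interior context (the base channel
    # itself shifts exactly tenfold; acid and water catalysis contribute
    # about a percent at pD 5.5). The C-terminal amide gains extra acid
    # catalysis from the carboxylate and is allowed a wider band.
    last <- which.max(lo$position)
    expect_true(all(abs(shift[-last] - 1) < 0.01))
    expect_lt(abs(shift[last] - 1), 0.05)
    expect_true(all(base_frac > 0.9))
  }
})
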