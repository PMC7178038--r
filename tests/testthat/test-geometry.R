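# Superposition, ensemble precision, distances, contacts, salt bridges,
# charge census and the RDC quality factor.

test_that("superposition is exact for identical and rigidly moved copies", {
  set.seed(1)
  A <- matrix(rnorm(45, sd = 4), 15)
  m <- toy_model(A)
  self <- superpose(m, m, selection = "calpha")
  expect_lt(self$rmsd, 1e-12)
  expect_equal(self$rotation, diag(3), tolerance = 1e-9)

  R <- random_rotation_fixture()
  moved <- toy_model(A %*% R + matrix(c(3, -7, 2), 15, 3, byrow = TRUE))
  fit <- superpose(moved, m, selection = "calpha")
  expect_lt(fit$rmsd, 1e-10)
  # symmetry of the RMSD in its arguments
  expect_equal(superpose(m, moved, selection = "calpha")$rmsd, fit$rmsd,
               tolerance = 1e-9)
})

test_that("Kabsch RMSD matches a brute-force rotational search", {
  set.seed(7)
  A <- matrix(rnorm(30, sd = 3), 10)
  B <- A + matrix(rnorm(30, sd = 0.8), 10)
  got <- superpose(toy_model(A), toy_model(B), selection = "calpha")$rmsd
  oracle <- grid_superpose_rmsd(A, B)
  expect_lt(abs(got - oracle), 1e-3)
  expect_error(superpose(toy_model(A[1:2, , drop = FALSE]),
                         toy_model(B[1:2, , drop = FALSE]),
                         selection = "calpha"), "3 matched")
})

test_that("ensemble RMSD-to-mean behaves like the jitter ground truth", {
  # identical models give zero
  m <- toy_model(matrix(rnorm(60), 20))
  expect_lt(ensemble_rmsd_to_mean(structure_ensemble(list(m, m, m)),
                                  selection = "calpha"), 1e-10)
  # rigid transforms alone are removed by superposition
  ens0 <- simulate_helix_bundle_ensemble(6, jitter_sd = 0, seed = 5)
  expect_lt(ensemble_rmsd_to_mean(ens0), 1e-9)
  # isotropic jitter: expectation sigma * sqrt(3) * sqrt((n-1)/n)
  ens <- simulate_helix_bundle_ensemble(20, jitter_sd = 0.3, seed = 11)
  expected <- 0.3 * sqrt(3) * sqrt(19 / 20)
  expect_lt(abs(ensemble_rmsd_to_mean(ens) - expected) / expected, 0.15)
})

test_that("two-model ensemble with one displaced atom follows the closed form", {
  set.seed(3)
  base <- matrix(rnorm(300, sd = 6), 100)
  shifted <- base
  d <- 0.4
  shifted[1, 1] <- shifted[1, 1] + d
  ens <- structure_ensemble(list(toy_model(base), toy_model(shifted)))
  # each model sits d/2 from the mean at one atom: RMSD = d / (2 sqrt(N))
  expect_equal(ensemble_rmsd_to_mean(ens, selection = "calpha"),
               d / (2 * sqrt(100)), tolerance = 0.02, ignore_attr = TRUE)
})

test_that("entrance distances report labeled pairs and obey the triangle inequality", {
  xyz <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0))
  m <- toy_model(xyz, resno = c(43, 63, 67))
  ed <- entrance_distances(m, c(43, 63, 67))
  expect_equal(unname(ed$distances), c(1, 1, 1))
  expect_equal(names(ed$distances), c("43-63", "43-67", "63-67"))
  set.seed(8)
  for (i in 1:5) {
    mm <- toy_model(matrix(rnorm(9, sd = 5), 3), resno = c(1, 2, 3))
    dd <- sort(entrance_distances(mm, c(1, 2, 3))$distances)
    expect_lte(dd[3], dd[1] + dd[2] + 1e-12)
  }
  expect_error(entrance_distances(m, c(43, 63, 99)), "missing C-alpha")
})

test_that("closest proton contacts use side-chain hydrogens", {
  atoms <- data.frame(
    atom = c("CB", "HB1", "CB", "HB1"),
    element = c("C", "H", "C", "H"),
    resno = c(10, 10, 20, 20), resid = "LEU", chain = "A",
    x = c(0, 0, 2.6, 2.1), y = 0, z = 0)
  m <- structure_model(atoms)
  d <- closest_proton_contact(m, 10, 20)
  expect_equal(as.numeric(d), 2.1)
  expect_equal(attr(d, "atoms"), c("HB1", "HB1"))
  expect_error(closest_proton_contact(m, 10, 10), "itself")
  # heavy-atom fallback warns when protons are absent
  mh <- structure_model(atoms[c(1, 3), ])
  expect_warning(dh <- closest_proton_contact(mh, 10, 20), "heavy")
  expect_equal(as.numeric(dh), 2.6)
})

test_that("salt-bridge detection respects the cutoff and clusters bridges", {
  atoms <- data.frame(
    atom = c("NZ", "OD1", "NH1", "OE1"),
    element = c("N", "O", "N", "O"),
    resno = c(10, 22, 4, 28),
    resid = c("LYS", "ASP", "ARG", "GLU"), chain = "A",
    x = c(0, 3, 10, 13.5), y = 0, z = 0)
  m <- structure_model(atoms)
  sb <- detect_salt_bridges(m, cutoff = 4)
  expect_equal(nrow(sb$bridges), 2L)
  expect_true("LYS10" %in% sb$bridges$basic)
  expect_equal(length(sb$clusters), 2L)
  # tighter cutoff removes the 3.5 A pair, then everything
  expect_equal(nrow(detect_salt_bridges(m, cutoff = 3.2)$bridges), 1L)
  expect_equal(nrow(detect_salt_bridges(m, cutoff = 2.5)$bridges), 0L)
  # monotone non-decreasing in the cutoff
  ns <- vapply(c(2, 3, 3.6, 4, 6),
               function(co) nrow(detect_salt_bridges(m, co)$bridges),
               integer(1))
  expect_true(all(diff(ns) >= 0))
})

test_that("charge census counts and pI match independent evaluation", {
  cc <- charge_census("EK")
  expect_equal(cc$acidic, 1L)
  expect_equal(cc$basic, 1L)
  # bisection agrees with a fine-grid scan of the net charge
  for (s in c("GGGGG", "EKDRH", acp_reference_sequence())) {
    grid <- seq(0, 14, by = 1e-4)
    z <- net_charge(grid, s)
    scan_pi <- grid[which.min(abs(z))]
    expect_lt(abs(isoelectric_point(s) - scan_pi), 1e-3)
  }
  expect_error(charge_census("AXZ"), "invalid residue")
})

test_that("RDC quality factor matches its definition", {
  expect_equal(rdc_q_factor(c(3, -5, 8), c(3, -5, 8)), 0)
  expect_equal(rdc_q_factor(c(3, -5, 8), c(0, 0, 0)), 1)
  expect_equal(round(rdc_q_factor(1:3, c(1, 1, 3)), 4), 0.2673)
  expect_error(rdc_q_factor(c(0, 0), c(1, 1)), "all-zero")
  expect_error(rdc_q_factor(1:3, 1:2), "equal length")
})

test_that("PDB files round-trip through the reader", {
  lines <- c(
    "MODEL        1",
    sprintf("ATOM  %5d  %-3s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
            1, "N", "ALA", 1, 1.0, 2.0, 3.0, "N"),
    sprintf("ATOM  %5d  %-3s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
            2, "CA", "ALA", 1, 2.5, 2.0, 3.0, "C"),
    sprintf("ATOM  %5d  %-3s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
            3, "C", "ALA", 1, 3.5, 3.0, 3.0, "C"),
    "ENDMDL",
    "MODEL        2",
    sprintf("ATOM  %5d  %-3s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
            1, "N", "ALA", 1, 1.1, 2.0, 3.0, "N"),
    sprintf("ATOM  %5d  %-3s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
            2, "CA", "ALA", 1, 2.6, 2.0, 3.0, "C"),
    sprintf("ATOM  %5d  %-3s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
            3, "C", "ALA", 1, 3.6, 3.0, 3.0, "C"),
    "ENDMDL",
    "END")
  path <- tempfile(fileext = ".pdb")
  on.exit(unlink(path))
  writeLines(lines, path)
  ens <- read_structure(path)
  expect_s3_class(ens, "structure_ensemble")
  expect_length(ens$models, 2L)
  expect_equal(ens$models[[1]]$x, c(1.0, 2.5, 3.5))
  one <- read_structure(path, model = 2)
  expect_s3_class(one, "structure_model")
  expect_equal(one$x[2], 2.6)
  expect_error(read_structure(path, model = 5), "not present")
})
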