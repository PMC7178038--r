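# Seeded synthetic-data generators. Every input the analysis modules consume
# can be generated here with known ground truth, which is what the test suite
# and the acceptance script exercise: exchange-peak decays with pD-dependent
# intrinsic rates, sigmoidal denaturation curves with sloping baselines,
# two-state DSC peaks on polynomial baselines, and jittered helix-bundle
# coordinate ensembles.

#' Simulate H/D exchange peak-decay series
#'
#' Forward model of the exchange experiment. For EX2 residues the observed
#' rate is `k = exp(-dG_local/RT) * k_rc(context, pD, T)`; for EX1 residues
#' `k = k_unfold`, independent of pD. Heights follow
#' `exp(-k t) * (1 + eps)` with multiplicative Gaussian noise of standard
#' deviation `noise_sd`. Hyperprotected residues are emitted with `k = 0`.
#'
#' @param sequence amino-acid string supplying the exchange contexts.
#' @param dG_local named numeric vector of local unfolding free energies
#'   (kcal/mol); names are 1-based residue positions. Only these residues are
#'   simulated.
#' @param hyperprotected integer vector of positions emitted with no decay.
#' @param pD one or more pD values; one series set per value.
#' @param temperature kelvin (default 298.15).
#' @param times exchange times in minutes, increasing (default every 10 min
#'   to 1000 min plus 3/7/14/21/28-day points).
#' @param noise_sd multiplicative noise fraction (default 0).
#' @param mechanism optional named character vector, `"EX2"` (default) or
#'   `"EX1"` per position.
#' @param k_unfold named numeric vector of opening rates (per minute) for
#'   EX1 positions.
#' @param seed integer seed for reproducibility.
#' @return Long-format data frame with columns `residue_index`, `residue`,
#'   `time_min`, `height`, `pD`, `temperature_K`. True rates are attached as
#'   attribute `"truth"` (data frame `residue_index`, `pD`, `k_true`).
#' @export
simulate_hdx <- function(sequence, dG_local, hyperprotected = integer(0),
                         pD = c(5.5, 6.5), temperature = 298.15,
                         times = c(seq(10, 1000, by = 10),
                                   c(3, 7, 14, 21, 28) * 1440),
                         noise_sd = 0, mechanism = NULL, k_unfold = NULL,
                         seed = NULL) {
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  if (any(diff(times) <= 0)) stop("`times` must be increasing", call. = FALSE)
  res <- split_sequence(sequence)
  pos <- as.integer(names(dG_local))
  if (any(is.na(pos)))
    stop("`dG_local` must be named by residue position", call. = FALSE)
  hyper <- as.integer(hyperprotected)
  all_pos <- sort(unique(c(pos, hyper)))
  mech <- setNames(rep("EX2", length(all_pos)), all_pos)
  if (!is.null(mechanism)) mech[names(mechanism)] <- mechanism

  with_seed(seed, {
    out <- list(); truth <- list()
    for (p in pD) {
      cond <- exchange_conditions(pD = p, temperature = temperature)
      kp <- krc_profile(sequence, cond)
      for (r in all_pos) {
        k <- if (r %in% hyper) 0
        else if (mech[[as.character(r)]] == "EX1") {
          if (is.null(k_unfold) || is.na(k_unfold[as.character(r)]))
            stop("EX1 residue ", r, " needs `k_unfold`", call. = FALSE)
          unname(k_unfold[as.character(r)])
        } else {
          krc <- kp$k_rc[kp$position == r]
          if (!length(krc))
            stop("residue ", r, " has no observable amide", call. = FALSE)
          dg_to_K(dG_local[[as.character(r)]], temperature) * krc
        }
        h <- exp(-k * times)
        if (noise_sd > 0)
          h <- pmax(h * (1 + rnorm(length(times), sd = noise_sd)), 0)
        out[[length(out) + 1L]] <- data.frame(
          residue_index = r, residue = res[r], time_min = times, height = h,
          pD = p, temperature_K = temperature)
        truth[[length(truth) + 1L]] <- data.frame(residue_index = r, pD = p,
                                                  k_true = k)
      }
    }
    peaks <- do.call(rbind, out)
    rownames(peaks) <- NULL
    attr(peaks, "truth") <- do.call(rbind, truth)
    peaks
  })
}

#' Simulate a two-state chemical denaturation curve
#'
#' `f_N(D) = 1 / (1 + exp(-(dG - m D)/RT))`; the signal interpolates between
#' sloping native and unfolded baselines with additive Gaussian noise.
#'
#' @param dG_global free energy of global unfolding at zero denaturant,
#'   kcal/mol.
#' @param m_value slope of the free energy in denaturant, kcal/mol/M (> 0).
#' @param native_baseline,unfolded_baseline `c(intercept, slope)` in signal
#'   units vs molar denaturant.
#' @param denaturant denaturant grid in M (must span the transition).
#' @param noise_sd additive noise standard deviation, signal units.
#' @param temperature kelvin.
#' @param seed integer seed.
#' @return Data frame `denaturant`, `signal`; the true fraction native is in
#'   attribute `"f_N_true"`.
#' @export
simulate_denaturation <- function(dG_global = 8.47, m_value = 1.85,
                                  native_baseline = c(-12000, 100),
                                  unfolded_baseline = c(-3000, -100),
                                  denaturant = seq(0, 8.5, by = 0.25),
                                  noise_sd = 0, temperature = 298.15,
                                  seed = NULL) {
  if (m_value <= 0) stop("`m_value` must be positive", call. = FALSE)
  midpoint <- dG_global / m_value
  if (midpoint <= min(denaturant) || midpoint >= max(denaturant))
    stop("denaturant grid does not span the transition midpoint",
         call. = FALSE)
  with_seed(seed, {
    fN <- 1 / (1 + exp(-(dG_global - m_value * denaturant) /
                         (R_KCAL * temperature)))
    sig <- fN * line_at(native_baseline, denaturant) +
      (1 - fN) * line_at(unfolded_baseline, denaturant)
    if (noise_sd > 0) sig <- sig + rnorm(length(sig), sd = noise_sd)
    out <- data.frame(denaturant = denaturant, signal = sig)
    attr(out, "f_N_true") <- fN
    out
  })
}

#' Simulate a DSC thermogram
#'
#' Two-state excess heat capacity ([dsc_two_state_cp()]) plus a polynomial
#' baseline in temperature and additive Gaussian noise.
#'
#' @param T_m melting temperature, degrees Celsius, inside the grid.
#' @param dH_vH van't Hoff enthalpy, kcal/mol.
#' @param scale amplitude factor.
#' @param baseline polynomial coefficients (increasing powers of
#'   `temp_C - min(temp_C)`).
#' @param temp_C temperature grid, degrees Celsius (default 50-120 at 0.2).
#' @param noise_sd additive noise standard deviation, signal units.
#' @param seed integer seed.
#' @return Data frame `temp_C`, `signal`.
#' @export
simulate_thermogram <- function(T_m = 101.4, dH_vH = 100, scale = 1,
                                baseline = c(0, 0),
                                temp_C = seq(50, 120, by = 0.2),
                                noise_sd = 0, seed = NULL) {
  if (T_m <= min(temp_C) || T_m >= max(temp_C))
    stop("`T_m` must lie inside the temperature grid", call. = FALSE)
  with_seed(seed, {
    tc <- temp_C - min(temp_C)
    base <- drop(outer(tc, seq_along(baseline) - 1L, `^`) %*% baseline)
    sig <- dsc_two_state_cp(celsius_to_kelvin(temp_C),
                            celsius_to_kelvin(T_m), dH_vH, scale) + base
    if (noise_sd > 0) sig <- sig + rnorm(length(sig), sd = noise_sd)
    data.frame(temp_C = temp_C, signal = sig)
  })
}

# idealized alpha-helix backbone along +z: N, CA, C per residue
.ideal_helix <- function(n_res, rise = 1.5, twist = 100 * pi / 180) {
  rows <- lapply(seq_len(n_res), function(i) {
    th <- i * twist
    z <- i * rise
    data.frame(
      atom = c("N", "CA", "C"),
      element = c("N", "C", "C"),
      x = c(1.46 * cos(th - 0.49), 2.30 * cos(th), 1.64 * cos(th + 0.47)),
      y = c(1.46 * sin(th - 0.49), 2.30 * sin(th), 1.64 * sin(th + 0.47)),
      z = c(z - 0.90, z, z + 0.55))
  })
  do.call(rbind, rows)
}

# uniform random rotation matrix
.random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3L))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1L] <- -R[, 1L]
  R
}

#' Simulate a four-helix-bundle coordinate ensemble
#'
#' Builds an idealized poly-alanine four-helix bundle backbone (N, CA, C),
#' then emits `n_models` copies, each perturbed by isotropic Gaussian jitter
#' of standard deviation `jitter_sd` and placed in a random rigid frame.
#' Useful as ground truth for superposition and ensemble-precision code: the
#' expected RMSD-to-mean is close to
#' `jitter_sd * sqrt(3) * sqrt((n-1)/n)`.
#'
#' @param n_models number of models (>= 2).
#' @param jitter_sd per-coordinate jitter in angstrom (>= 0).
#' @param n_res_per_helix residues per helix (default 12).
#' @param seed integer seed.
#' @return A [structure_ensemble()].
#' @export
simulate_helix_bundle_ensemble <- function(n_models = 20, jitter_sd = 0.3,
                                           n_res_per_helix = 12,
                                           seed = NULL) {
  if (n_models < 2) stop("`n_models` must be at least 2", call. = FALSE)
  if (jitter_sd < 0) stop("`jitter_sd` must be non-negative", call. = FALSE)
  offsets <- list(c(-5.5, -5.5), c(5.5, -5.5), c(5.5, 5.5), c(-5.5, 5.5))
  helices <- lapply(seq_along(offsets), function(h) {
    hx <- .ideal_helix(n_res_per_helix)
    if (h %% 2L == 0L) hx$z <- max(hx$z) + min(hx$z) - hx$z  # antiparallel
    hx$x <- hx$x + offsets[[h]][1L]
    hx$y <- hx$y + offsets[[h]][2L]
    hx$resno_local <- rep(seq_len(n_res_per_helix), each = 3L)
    hx$helix <- h
    hx
  })
  ref <- do.call(rbind, helices)
  ref$resno <- (ref$helix - 1L) * (n_res_per_helix + 3L) + ref$resno_local
  ref$resid <- "ALA"
  ref$chain <- "A"
  ref <- ref[c("atom", "element", "resno", "resid", "chain", "x", "y", "z")]

  with_seed(seed, {
    models <- lapply(seq_len(n_models), function(i) {
      xyz <- as.matrix(ref[, c("x", "y", "z")])
      xyz <- xyz + matrix(rnorm(length(xyz), sd = jitter_sd), ncol = 3L)
      R <- .random_rotation()
      xyz <- xyz %*% R + matrix(runif(3, -10, 10), nrow(xyz), 3L,
                                byrow = TRUE)
      m <- ref
      m$x <- xyz[, 1L]; m$y <- xyz[, 2L]; m$z <- xyz[, 3L]
      structure_model(m, model_id = i)
    })
    structure_ensemble(models, source = "synthetic four-helix bundle")
  })
}
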