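# Differential scanning calorimetry: polynomial baseline correction and the
# scaled two-state van't Hoff fit of the excess heat capacity.

#' Two-state excess heat capacity model
#'
#' `Cp(T) = scale * dH^2 K / (R T^2 (1 + K)^2)` with
#' `K = exp(-(dH/R)(1/T - 1/Tm))`, temperatures in kelvin and `dH` the van't
#' Hoff enthalpy in kcal/mol. The free amplitude `scale` absorbs instrument
#' units and concentration, so only `Tm` and `dH` carry physical meaning.
#'
#' @param temp_K temperatures in kelvin.
#' @param Tm_K melting temperature in kelvin.
#' @param dH_vH van't Hoff enthalpy, kcal/mol.
#' @param scale amplitude factor (default 1).
#' @return Excess heat capacity (arbitrary units x kcal/mol/K).
#' @export
dsc_two_state_cp <- function(temp_K, Tm_K, dH_vH, scale = 1) {
  K <- exp(-(dH_vH / R_KCAL) * (1 / temp_K - 1 / Tm_K))
  scale * dH_vH^2 * K / (R_KCAL * temp_K^2 * (1 + K)^2)
}

#' Polynomial baseline correction of a thermogram
#'
#' Fits a polynomial of degree <= 3 to the pre- and post-transition flanks of
#' the scan (the outer `flank_fraction` of the temperature range on each
#' side) and subtracts it.
#'
#' @param temp_C strictly increasing temperature grid, degrees Celsius.
#' @param signal heat signal on that grid (arbitrary heat-capacity units).
#' @param degree polynomial degree, 0-3 (default 1).
#' @param flank_fraction fraction of the scanned range treated as transition
#'   free on each side (default 0.2).
#' @return A list with `temp_C`, `corrected`, `baseline` (fitted values) and
#'   `coefficients` (increasing powers of temperature).
#' @export
baseline_correct <- function(temp_C, signal, degree = 1,
                             flank_fraction = 0.2) {
  if (length(temp_C) != length(signal))
    stop("`temp_C` and `signal` must have equal length", call. = FALSE)
  if (any(diff(temp_C) <= 0))
    stop("`temp_C` must be strictly increasing", call. = FALSE)
  if (degree > 3 || degree < 0)
    stop("`degree` must be between 0 and 3", call. = FALSE)
  rng <- range(temp_C)
  span <- diff(rng)
  if (flank_fraction <= 0 || flank_fraction >= 0.5)
    stop("`flank_fraction` must be in (0, 0.5)", call. = FALSE)
  flank <- temp_C <= rng[1L] + flank_fraction * span |
    temp_C >= rng[2L] - flank_fraction * span
  if (sum(flank) <= degree + 1L)
    stop("transition occupies the whole scan; no baseline flanks",
         call. = FALSE)
  # guard: the flanks must be flat relative to the central excursion
  tc <- temp_C - mean(temp_C)            # centred for conditioning
  fit <- if (degree == 0) lm(signal[flank] ~ 1)
  else lm(signal[flank] ~ poly(tc[flank], degree, raw = TRUE))
  base <- if (degree == 0) rep(coef(fit)[[1L]], length(temp_C))
  else drop(cbind(1, outer(tc, seq_len(degree), `^`)) %*% coef(fit))
  list(temp_C = temp_C, corrected = signal - base, baseline = base,
       coefficients = unname(coef(fit)))
}

#' Scaled two-state fit of a baseline-corrected thermogram
#'
#' Nonlinear least-squares fit of [dsc_two_state_cp()] to a corrected excess
#' heat signal. Start values come from the peak position (Tm), and from the
#' standard width relation `dH ~ 4 R Tm^2 Cp_max / area`.
#'
#' @param temp_C strictly increasing temperature grid, degrees Celsius.
#' @param corrected baseline-corrected heat signal.
#' @return An object of class `dsc_fit`: `T_m` (deg C), `dH_vH` (kcal/mol),
#'   `scale`, `fitted`, `fit_quality` (residual norm).
#' @export
dsc_two_state_fit <- function(temp_C, corrected) {
  if (length(temp_C) < 50L)
    stop("at least 50 scan points are required", call. = FALSE)
  pk <- which.max(corrected)
  if (corrected[pk] <= 3 * sd(corrected[c(seq_len(5L),
                                          length(corrected) - 0:4)]))
    stop("no transition peak above noise", call. = FALSE)
  TK <- celsius_to_kelvin(temp_C)
  Tm0 <- TK[pk]
  area <- sum(diff(TK) * (head(corrected, -1) + tail(corrected, -1)) / 2)
  dH0 <- max(4 * R_KCAL * Tm0^2 * corrected[pk] / max(area, 1e-12), 10)
  s0 <- max(area, 1e-12) / dH0
  df <- data.frame(TK = TK, y = corrected)
  fit <- minpack.lm::nlsLM(
    y ~ s * dH^2 * exp(-(dH / R_KCAL) * (1 / TK - 1 / Tm)) /
      (R_KCAL * TK^2 * (1 + exp(-(dH / R_KCAL) * (1 / TK - 1 / Tm)))^2),
    data = df, start = list(Tm = Tm0, dH = dH0, s = s0),
    lower = c(min(TK), 1, 0),
    control = minpack.lm::nls.lm.control(maxiter = 500,
                                         ftol = 1e-14, ptol = 1e-14))
  cf <- coef(fit)
  if (cf[["Tm"]] < min(TK) || cf[["Tm"]] > max(TK))
    warning("fitted T_m outside the scanned range")
  structure(list(T_m = kelvin_to_celsius(cf[["Tm"]]), dH_vH = cf[["dH"]],
                 scale = cf[["s"]], fitted = predict(fit),
                 fit_quality = sqrt(sum(stats::resid(fit)^2))),
            class = "dsc_fit")
}

#' @export
print.dsc_fit <- function(x, ...) {
  cat(sprintf("Two-state DSC fit: T_m = %.2f degC, dH_vH = %.1f kcal/mol\n",
              x$T_m, x$dH_vH))
  invisible(x)
}

#' Baseline-correct and fit a raw thermogram
#'
#' Convenience wrapper: [baseline_correct()] followed by
#' [dsc_two_state_fit()], or by a sum of `n_components` two-state components
#' when a complex profile must be deconvolved.
#'
#' @inheritParams baseline_correct
#' @param n_components number of two-state components (default 1).
#' @param joint_refine after the correct-then-fit pass, refit baseline and
#'   transition parameters jointly on the raw signal (default `TRUE`). This
#'   removes the bias of flank-window baselines when the transition tails
#'   reach the ends of the scan, as they do for melting temperatures near
#'   the boiling point.
#' @return For one component, a `dsc_fit` (plus `baseline_coefficients`).
#'   For several, a list with per-component `T_m`, `dH_vH`, `scale`.
#' @export
dsc_fit <- function(temp_C, signal, degree = 1, flank_fraction = 0.2,
                    n_components = 1, joint_refine = TRUE) {
  bc <- baseline_correct(temp_C, signal, degree, flank_fraction)
  if (n_components == 1) {
    out <- dsc_two_state_fit(temp_C, bc$corrected)
    if (joint_refine) {
      TK <- celsius_to_kelvin(temp_C)
      tc <- temp_C - mean(temp_C)
      start <- list(Tm = celsius_to_kelvin(out$T_m), dH = out$dH_vH,
                    s = out$scale)
      bnames <- paste0("b", 0:degree)
      # baseline start values from the flank fit, re-expressed on tc
      bstart <- setNames(as.list(rep(0, degree + 1L)), bnames)
      bstart$b0 <- mean(signal - bc$corrected)
      start <- c(start, bstart)
      poly_terms <- paste(vapply(0:degree, function(p)
        if (p == 0) "b0" else sprintf("b%d * tc^%d", p, p),
        character(1)), collapse = " + ")
      form <- stats::as.formula(paste(
        "y ~ s * dH^2 * exp(-(dH / R_) * (1/TK - 1/Tm)) /",
        "(R_ * TK^2 * (1 + exp(-(dH / R_) * (1/TK - 1/Tm)))^2) +",
        poly_terms))
      jfit <- minpack.lm::nlsLM(
        form, data = data.frame(TK = TK, tc = tc, y = signal, R_ = R_KCAL),
        start = start, lower = c(min(TK), 1, 0, rep(-Inf, degree + 1L)),
        control = minpack.lm::nls.lm.control(maxiter = 500,
                                             ftol = 1e-14, ptol = 1e-14))
      cf <- coef(jfit)
      out <- structure(list(T_m = kelvin_to_celsius(cf[["Tm"]]),
                            dH_vH = cf[["dH"]], scale = cf[["s"]],
                            fitted = predict(jfit),
                            fit_quality = sqrt(sum(stats::resid(jfit)^2))),
                       class = "dsc_fit")
      out$baseline_coefficients <- unname(cf[bnames])
      return(out)
    }
    out$baseline_coefficients <- bc$coefficients
    return(out)
  }
  # seed components at the n largest well-separated local maxima
  TK <- celsius_to_kelvin(temp_C)
  y <- bc$corrected
  pk <- order(y, decreasing = TRUE)
  picks <- pk[1L]
  for (i in pk) {
    if (length(picks) >= n_components) break
    if (all(abs(TK[i] - TK[picks]) > 5)) picks <- c(picks, i)
  }
  if (length(picks) < n_components)
    stop("could not locate ", n_components, " separated peaks", call. = FALSE)
  start <- list()
  for (j in seq_len(n_components)) {
    start[[paste0("Tm", j)]] <- TK[picks[j]]
    start[[paste0("dH", j)]] <- 100
    start[[paste0("s", j)]] <- sum(diff(TK) * (head(y, -1) + tail(y, -1)) / 2) /
      (100 * n_components)
  }
  terms <- paste(vapply(seq_len(n_components), function(j) sprintf(
    "s%d * dH%d^2 * exp(-(dH%d / %.6g) * (1/TK - 1/Tm%d)) / (%.6g * TK^2 * (1 + exp(-(dH%d / %.6g) * (1/TK - 1/Tm%d)))^2)",
    j, j, j, R_KCAL, j, R_KCAL, j, R_KCAL, j), character(1)),
    collapse = " + ")
  fit <- minpack.lm::nlsLM(stats::as.formula(paste("y ~", terms)),
                           data = data.frame(TK = TK, y = y), start = start,
                           control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- coef(fit)
  comps <- data.frame(
    component = seq_len(n_components),
    T_m = kelvin_to_celsius(unname(cf[paste0("Tm", seq_len(n_components))])),
    dH_vH = unname(cf[paste0("dH", seq_len(n_components))]),
    scale = unname(cf[paste0("s", seq_len(n_components))]))
  list(components = comps[order(comps$T_m), ],
       baseline_coefficients = bc$coefficients)
}
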