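# Fitting of HSQC peak-decay series, protection free energies, and the
# EX1/EX2 regime diagnosis from paired-pD measurements.

#' Fit a single-exponential decay to a peak-height series
#'
#' Models the decay of a normalized HSQC cross-peak height after transfer to
#' D2O as `I(t) = A exp(-k t)` (no floating baseline: a fully exchanged amide
#' peak vanishes; an optional plateau term is available via `plateau = TRUE`).
#' A residue is flagged hyperprotected when the 95% confidence interval of
#' `k` includes zero and the final/first height ratio exceeds
#' `hyper_height_ratio` over the whole observation window; in that case only
#' a resolvable lower bound on a detectable rate,
#' `log(1/hyper_height_ratio)/t_max`, is reported.
#'
#' @param times observation times in minutes, strictly increasing, >= 3 points.
#' @param heights peak heights; normalized to the first point unless
#'   `normalize = FALSE`.
#' @param normalize divide heights by the first height (default `TRUE`).
#' @param plateau add a constant offset term `c` to the decay model.
#' @param hyper_height_ratio final/first height ratio above which a flat
#'   series is called hyperprotected (default 0.8).
#' @param conf confidence level for the rate interval (default 0.95).
#' @return An object of class `hdx_fit`: `k_HDX` (per minute; `NA` when
#'   hyperprotected), `amplitude`, `conf_int`, `fit_quality` (residual norm),
#'   `hyperprotected`, `resolvable_lower_bound`, `n_points`.
#' @export
fit_decay <- function(times, heights, normalize = TRUE, plateau = FALSE,
                      hyper_height_ratio = 0.8, conf = 0.95) {
  if (length(times) != length(heights))
    stop("`times` and `heights` must have equal length", call. = FALSE)
  if (length(times) < 3L)
    stop("at least 3 time points are required", call. = FALSE)
  if (any(diff(times) <= 0) || times[1L] < 0)
    stop("`times` must be non-negative and strictly increasing", call. = FALSE)
  if (any(heights < 0))
    stop("`heights` must be non-negative", call. = FALSE)
  if (all(heights == 0))
    stop("degenerate input: all-zero heights", call. = FALSE)
  if (isTRUE(normalize) && heights[1L] > 0) heights <- heights / heights[1L]

  # log-linear start values from the positive part of the series
  pos <- heights > 0
  sl <- if (sum(pos) >= 2L)
    coef(lm(log(heights[pos]) ~ times[pos]))[[2L]] else -1e-3
  k0 <- max(-sl, 1e-9)
  a0 <- max(heights[1L], 1e-6)

  df <- data.frame(t = times, I = heights)
  # Peaks that vanish into the noise floor before the second spectrum leave
  # the exponential fit without curvature information; fall back to weighted
  # log-linear regression on the positive heights in that case.
  loglinear_fallback <- function() {
    sel <- heights > 0
    if (sum(sel) < 3L)
      stop("too few positive heights for a rate estimate", call. = FALSE)
    lf <- lm(log(heights[sel]) ~ times[sel])
    k <- max(-coef(lf)[[2L]], 0)
    se <- sqrt(vcov(lf)[2L, 2L])
    A <- exp(coef(lf)[[1L]])
    list(k = k, A = A, se = se, dfree = sum(sel) - 2L,
         resid_norm = sqrt(sum((heights - A * exp(-k * times))^2)))
  }
  fit <- if (plateau) {
    minpack.lm::nlsLM(I ~ A * exp(-k * t) + c0, data = df,
                      start = list(A = a0, k = k0, c0 = 0),
                      lower = c(0, 0, -Inf), upper = c(Inf, Inf, Inf),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 200, ftol = 1e-14, ptol = 1e-14))
  } else {
    tryCatch(
      minpack.lm::nlsLM(I ~ A * exp(-k * t), data = df,
                        start = list(A = a0, k = k0),
                        lower = c(0, 0),
                        control = minpack.lm::nls.lm.control(
                          maxiter = 200, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
  }
  if (is.null(fit)) {
    fb <- loglinear_fallback()
    k <- fb$k; se_k <- fb$se; dfree <- fb$dfree
    amp <- fb$A
    resid_norm <- fb$resid_norm
  } else {
    est <- coef(fit)
    k <- unname(est["k"])
    amp <- unname(est["A"])
    se_k <- tryCatch(sqrt(vcov(fit)["k", "k"]), error = function(e) NA_real_)
    dfree <- length(times) - length(est)
    resid_norm <- sqrt(sum(stats::resid(fit)^2))
  }
  tq <- qt(1 - (1 - conf) / 2, dfree)
  ci <- if (is.finite(se_k)) c(k - tq * se_k, k + tq * se_k)
  else c(NA_real_, NA_real_)

  # Hyperprotection: the series stays flat over the whole window and no
  # decay is detected. Detection demands the rate to clear 3.5 standard
  # errors, so a truly constant peak is almost never misread as decaying
  # while even a 10-20% decay over the window (enormous t-statistic at
  # percent-level noise) is still resolved.
  flat <- heights[length(heights)] / heights[1L] > hyper_height_ratio
  detected <- is.finite(se_k) && se_k > 0 && (k / se_k) >= 3.5
  hyper <- flat && !detected
  bound <- log(1 / hyper_height_ratio) / max(times)

  structure(list(
    k_HDX = if (hyper) NA_real_ else k,
    amplitude = amp,
    conf_int = ci,
    fit_quality = resid_norm,
    hyperprotected = hyper,
    resolvable_lower_bound = if (hyper) bound else NA_real_,
    n_points = length(times)
  ), class = "hdx_fit")
}

#' @export
print.hdx_fit <- function(x, ...) {
  if (x$hyperprotected) {
    cat(sprintf("hdx_fit: hyperprotected (resolvable k < %.3g /min)\n",
                x$resolvable_lower_bound))
  } else {
    cat(sprintf("hdx_fit: k_HDX = %.4g /min  [%.3g, %.3g]  (n = %d)\n",
                x$k_HDX, x$conf_int[1], x$conf_int[2], x$n_points))
  }
  invisible(x)
}

#' Fit peak decays for every residue of a long-format peak table
#'
#' @param peaks data frame with columns `residue_index`, `residue`,
#'   `time_min`, `height`, and optionally `pD` and `temperature_K` (one series
#'   per residue_index x pD combination).
#' @param ... passed on to [fit_decay()].
#' @return A data frame with one row per series: `residue_index`, `residue`,
#'   `pD`, `k_HDX`, `k_lo`, `k_hi`, `hyperprotected`,
#'   `resolvable_lower_bound`, `fit_quality`.
#' @export
fit_hdx_rates <- function(peaks, ...) {
  needed <- c("residue_index", "residue", "time_min", "height")
  miss <- setdiff(needed, names(peaks))
  if (length(miss))
    stop("peak table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!"pD" %in% names(peaks)) peaks$pD <- NA_real_
  keys <- unique(peaks[c("residue_index", "residue", "pD")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- peaks$residue_index == keys$residue_index[i] &
      (is.na(keys$pD[i]) | peaks$pD == keys$pD[i])
    s <- peaks[sel, , drop = FALSE]
    s <- s[order(s$time_min), , drop = FALSE]
    f <- fit_decay(s$time_min, s$height, ...)
    data.frame(residue_index = keys$residue_index[i],
               residue = keys$residue[i], pD = keys$pD[i],
               k_HDX = f$k_HDX, k_lo = f$conf_int[1L], k_hi = f$conf_int[2L],
               hyperprotected = f$hyperprotected,
               resolvable_lower_bound = f$resolvable_lower_bound,
               fit_quality = f$fit_quality)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Local unfolding free energy from observed and intrinsic rates
#'
#' Under EX2 exchange the opening equilibrium constant is approximated by
#' `K_unfold = k_HDX / k_rc`, and the local unfolding free energy is
#' `dG_local = -RT ln(K_unfold)` with R = 1.987e-3 kcal/mol/K.
#'
#' @param k_HDX observed exchange rate(s), per minute, > 0.
#' @param k_rc intrinsic random-coil rate(s), per minute, > 0.
#' @param temperature kelvin.
#' @return A data frame with `K_unfold` (dimensionless), `dG_local` (kcal/mol)
#'   and `temperature`.
#' @examples
#' protection_energy(1e-5, 1, 298.15)  # dG_local = 6.82 kcal/mol
#' @export
protection_energy <- function(k_HDX, k_rc, temperature) {
  if (any(!is.finite(k_HDX)) || any(k_HDX <= 0))
    stop("`k_HDX` must be positive", call. = FALSE)
  if (any(!is.finite(k_rc)) || any(k_rc <= 0))
    stop("`k_rc` must be positive", call. = FALSE)
  if (temperature <= 0) stop("`temperature` must be positive", call. = FALSE)
  K <- k_HDX / k_rc
  data.frame(K_unfold = K, dG_local = -R_KCAL * temperature * log(K),
             temperature = temperature)
}

#' Classify the exchange regime from a paired-pD measurement
#'
#' In the base-catalyzed regime an EX2 amide shifts its log10 exchange rate
#' one-for-one with pD, while an EX1 amide (rate-limited by the opening rate)
#' is pD-independent. The log10 rate shift between the two conditions is
#' compared with `delta_pD` (EX2 limit) and 0 (EX1 limit) within `tolerance`
#' log units; anything else, including exact ties of the two bands, is
#' labeled `intermediate`.
#'
#' @param estimate_low_pD,estimate_high_pD rates per minute (numeric) or
#'   [fit_decay()] results at the lower/higher pD.
#' @param delta_pD pD difference between the two measurements, > 0.
#' @param tolerance half-width of the decision bands in log10 units
#'   (default 0.3).
#' @return A list with `log_rate_shift` and `label`
#'   (`"EX2"`, `"EX1"` or `"intermediate"`).
#' @export
classify_regime <- function(estimate_low_pD, estimate_high_pD, delta_pD = 1,
                            tolerance = 0.3) {
  getk <- function(x, who) {
    if (inherits(x, "hdx_fit")) {
      if (x$hyperprotected)
        stop("cannot classify a hyperprotected residue (", who, ")",
             call. = FALSE)
      x$k_HDX
    } else x
  }
  k_lo <- getk(estimate_low_pD, "low pD")
  k_hi <- getk(estimate_high_pD, "high pD")
  if (!is.finite(k_lo) || !is.finite(k_hi) || k_lo <= 0 || k_hi <= 0)
    stop("both rate estimates must be positive and resolvable", call. = FALSE)
  if (delta_pD <= 0) stop("`delta_pD` must be positive", call. = FALSE)
  shift <- log10(k_hi) - log10(k_lo)
  in_ex2 <- abs(shift - delta_pD) <= tolerance
  in_ex1 <- abs(shift) <= tolerance
  label <- if (in_ex2 && !in_ex1) "EX2"
  else if (in_ex1 && !in_ex2) "EX1"
  else "intermediate"
  list(log_rate_shift = shift, label = label)
}

#' Count peaks surviving at a given exchange time
#'
#' @param peaks long-format peak table (see [fit_hdx_rates()]); heights are
#'   interpolated linearly onto `at_time` per residue.
#' @param at_time time in minutes, inside each residue's observed range.
#' @param threshold normalized-height survival threshold (default 0.1).
#' @return Integer count of residues with interpolated height >= threshold.
#' @export
count_survivors <- function(peaks, at_time, threshold = 0.1) {
  if (is.null(peaks) || nrow(peaks) == 0L) return(0L)
  ids <- unique(peaks$residue_index)
  surv <- vapply(ids, function(id) {
    s <- peaks[peaks$residue_index == id, , drop = FALSE]
    s <- s[order(s$time_min), , drop = FALSE]
    if (at_time < min(s$time_min) || at_time > max(s$time_min))
      stop("`at_time` outside the observed range for residue ", id,
           call. = FALSE)
    h <- approx(s$time_min, s$height, xout = at_time, ties = "ordered")$y
    h >= threshold
  }, logical(1))
  sum(surv)
}
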