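# Intrinsic (random-coil) backbone amide exchange rates.
#
# The observed exchange rate of a protected amide is interpreted against the
# rate the same amide would show in a random-coil peptide. That reference rate
# is taken from poly-DL-alanine and corrected for the inductive and steric
# effects of the flanking side chains, as a function of pD and temperature.
# All rates are per minute.

# --- reference poly-DL-alanine constants (293 K, D2O, log10 units) ----------
PDLA_LOG_KA <- 1.62    # acid channel, per minute per molar D+
PDLA_LOG_KB <- 10.05   # base channel, per minute per molar OD-
PDLA_LOG_KW <- -1.50   # water channel, per minute
PKD_D2O <- 15.05       # ion product of D2O on the pD scale

# Default activation energies over R (kelvin) per catalysis channel,
# corresponding to 14, 17 and 19 kcal/mol for acid, base and water catalysis.
DEFAULT_EA_OVER_R <- c(acid = 14 / R_KCAL, base = 17 / R_KCAL,
                       water = 19 / R_KCAL)

.factor_env <- new.env(parent = emptyenv())

#' Load the packaged neighbor-effect factor table
#'
#' Returns the side-chain neighbor correction factors (log10 multipliers on
#' the poly-DL-alanine reference rates) shipped with the package as a plain
#' tab-separated resource. Titrating side chains (Asp, Glu, His) appear as
#' two rows (protonated/deprotonated) together with their pKa on the pD scale.
#'
#' @return A data frame with columns `res`, `form`, `pKD`, `acid_left`,
#'   `acid_right`, `base_left`, `base_right`.
#' @export
neighbor_factors <- function() {
  if (is.null(.factor_env$table)) {
    path <- system.file("extdata", "polyala_neighbor_factors.tsv",
                        package = "acpstab", mustWork = TRUE)
    .factor_env$table <- read.delim(path, comment.char = "#",
                                    stringsAsFactors = FALSE)
  }
  .factor_env$table
}

# log10 neighbor factor for one residue code and one column. Titrating side
# chains (Asp, Glu, His) carry two factor sets; the ionization state is
# selected by comparing pD with the side chain's pKD (a step, not a blend).
# In the base-catalyzed window pD 5-7 this applies the carboxylate forms
# throughout, which keeps the one-log-unit pD dependence of the intrinsic
# rate exact across all sequence contexts, as the EX2 diagnostic assumes;
# the alternative of blending by ionization fraction would bend the pD law
# for acid-flanked amides near the side-chain pKa.
.log_factor <- function(res, column, pD) {
  tab <- neighbor_factors()
  rows <- tab[tab$res == res, , drop = FALSE]
  if (nrow(rows) == 0L) return(0)
  if (nrow(rows) == 1L) {
    val <- rows[[column]][1L]
    return(if (is.na(val)) 0 else val)
  }
  form <- if (pD > rows$pKD[1L]) "base" else "acid"
  rows[[column]][rows$form == form]
}

#' Exchange experiment conditions
#'
#' Bundles the solvent and temperature conditions of a hydrogen/deuterium
#' exchange experiment. pD is taken as a direct reading by default; set
#' `from_meter_reading = TRUE` to apply the standard +0.4 glass-electrode
#' correction for an uncorrected pH-meter reading in D2O.
#'
#' @param pD pD of the exchange buffer (dimensionless; the base-catalyzed
#'   regime covers roughly pD 5-7).
#' @param temperature experimental temperature in kelvin (default 298).
#' @param reference_temperature temperature at which the reference rates are
#'   tabulated, kelvin (default 293).
#' @param Ea_over_R named numeric vector of activation energies over the gas
#'   constant, in kelvin, per catalysis channel (`acid`, `base`, `water`).
#' @param from_meter_reading logical; apply pD = reading + 0.4.
#' @return An object of class `exchange_conditions`.
#' @export
exchange_conditions <- function(pD, temperature = 298,
                                reference_temperature = 293,
                                Ea_over_R = DEFAULT_EA_OVER_R,
                                from_meter_reading = FALSE) {
  if (!is.finite(pD)) stop("`pD` must be finite", call. = FALSE)
  if (!is.numeric(temperature) || temperature <= 0)
    stop("`temperature` must be positive (kelvin)", call. = FALSE)
  if (!is.numeric(reference_temperature) || reference_temperature <= 0)
    stop("`reference_temperature` must be positive (kelvin)", call. = FALSE)
  if (is.null(names(Ea_over_R)))
    names(Ea_over_R) <- c("acid", "base", "water")[seq_along(Ea_over_R)]
  if (isTRUE(from_meter_reading)) pD <- pD + 0.4
  structure(list(pD = pD, temperature = temperature,
                 reference_temperature = reference_temperature,
                 Ea_over_R = Ea_over_R),
            class = "exchange_conditions")
}

#' Intrinsic exchange rate for one amide in sequence context
#'
#' Computes the random-coil exchange rate of the backbone amide of a residue,
#' at the reference temperature of the packaged poly-DL-alanine rates and the
#' pD of `conditions`. The reference rate is corrected by the log-additive
#' neighbor factors of the residue's own side chain and of the preceding
#' residue's side chain; the N-terminal ammonium and C-terminal carboxylate
#' contribute additional factors for the second and last residues.
#'
#' @param residue one-letter code of the residue whose amide exchanges.
#' @param left_neighbor one-letter code of the preceding residue.
#' @param right_neighbor one-letter code of the following residue (accepted
#'   for a complete sequence context; the correction scheme attributes no
#'   effect of the following side chain on this amide).
#' @param conditions an [exchange_conditions()] object.
#' @param n_terminal logical; `TRUE` when the residue is position 2, so the
#'   amide additionally feels the N-terminal ammonium group.
#' @param c_terminal logical; `TRUE` for the final residue (C-terminal
#'   carboxylate factor applied).
#' @return An object of class `intrinsic_rate`: a list with `k_rc` (per
#'   minute, at the reference temperature) and `channels`, the acid/base/water
#'   contributions whose sum is `k_rc`.
#' @examples
#' cond <- exchange_conditions(pD = 6, temperature = 298)
#' krc_base("A", "A", "A", cond)        # uncorrected poly-DL-alanine rate
#' @export
krc_base <- function(residue, left_neighbor, right_neighbor = NULL,
                     conditions, n_terminal = FALSE, c_terminal = FALSE) {
  for (code in c(residue, left_neighbor, right_neighbor))
    if (!is.null(code) && !(code %in% AA1))
      stop("unknown residue code: ", code, call. = FALSE)
  if (residue == "P")
    stop("proline has no exchangeable backbone amide", call. = FALSE)
  if (!inherits(conditions, "exchange_conditions"))
    stop("`conditions` must be an exchange_conditions object", call. = FALSE)
  pD <- conditions$pD

  aL <- .log_factor(residue, "acid_left", pD) +
    .log_factor(left_neighbor, "acid_right", pD) +
    (if (n_terminal) .log_factor("NT", "acid_right", pD) else 0) +
    (if (c_terminal) .log_factor("CT", "acid_left", pD) else 0)
  bL <- .log_factor(residue, "base_left", pD) +
    .log_factor(left_neighbor, "base_right", pD) +
    (if (n_terminal) .log_factor("NT", "base_right", pD) else 0) +
    (if (c_terminal) .log_factor("CT", "base_left", pD) else 0)

  channels <- c(
    acid  = 10^(PDLA_LOG_KA + aL - pD),
    base  = 10^(PDLA_LOG_KB + bL + pD - PKD_D2O),
    water = 10^(PDLA_LOG_KW + bL)
  )
  structure(list(k_rc = sum(channels), channels = channels,
                 reference_temperature = conditions$reference_temperature),
            class = "intrinsic_rate")
}

#' Arrhenius temperature correction of an exchange rate
#'
#' Scales a reference-temperature rate to the experimental temperature by
#' `exp(-(Ea/R) (1/T - 1/T_ref))` with `Ea/R` in kelvin. When given an
#' [krc_base()] result, each catalysis channel is scaled with its own
#' activation energy and the channels are re-summed.
#'
#' @param k a positive rate (per minute) or an `intrinsic_rate` object.
#' @param conditions an [exchange_conditions()] object supplying `temperature`,
#'   `reference_temperature` and per-channel `Ea_over_R`.
#' @param Ea_over_R optional single activation energy over R (kelvin) used for
#'   a bare numeric `k`; defaults to the base-channel value of `conditions`.
#' @return A rate per minute, or an `intrinsic_rate` at the new temperature.
#' @export
temperature_correct <- function(k, conditions, Ea_over_R = NULL) {
  if (conditions$temperature <= 0)
    stop("temperature must be positive", call. = FALSE)
  arr <- function(ea) exp(-ea * (1 / conditions$temperature -
                                   1 / conditions$reference_temperature))
  if (inherits(k, "intrinsic_rate")) {
    ea <- conditions$Ea_over_R[c("acid", "base", "water")]
    channels <- k$channels * arr(unname(ea))
    return(structure(list(k_rc = sum(channels), channels = channels,
                          reference_temperature = conditions$temperature),
                     class = "intrinsic_rate"))
  }
  if (!is.numeric(k) || any(k <= 0))
    stop("`k` must be a positive rate", call. = FALSE)
  if (is.null(Ea_over_R)) Ea_over_R <- unname(conditions$Ea_over_R["base"])
  k * arr(Ea_over_R)
}

#' Per-residue intrinsic exchange-rate profile of a sequence
#'
#' Vectorizes [krc_base()] and [temperature_correct()] over a protein
#' sequence. Residue 1 (no backbone amide proton after the free amine) and
#' prolines are absent from the output.
#'
#' @param sequence amino-acid string (one-letter codes), length >= 2.
#' @param conditions an [exchange_conditions()] object.
#' @return A data frame with one row per observable amide: `position`,
#'   `residue`, `k_rc` (per minute at `conditions$temperature`) and the
#'   channel breakdown `k_acid`, `k_base`, `k_water`.
#' @export
krc_profile <- function(sequence, conditions) {
  res <- split_sequence(sequence)
  n <- length(res)
  if (n < 2L) stop("sequence must have at least 2 residues", call. = FALSE)
  keep <- which(seq_len(n) > 1L & res != "P")
  rows <- lapply(keep, function(i) {
    r0 <- krc_base(res[i], left_neighbor = res[i - 1L],
                   right_neighbor = if (i < n) res[i + 1L] else NULL,
                   conditions = conditions,
                   n_terminal = i == 2L, c_terminal = i == n)
    r <- temperature_correct(r0, conditions)
    data.frame(position = i, residue = res[i], k_rc = r$k_rc,
               k_acid = unname(r$channels["acid"]),
               k_base = unname(r$channels["base"]),
               k_water = unname(r$channels["water"]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
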