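# acpstab

Stability thermodynamics and structural geometry for small helical
proteins, built around the analysis workflow used for hyperthermophilic
bacterial acyl carrier proteins (ACPs): per-residue hydrogen/deuterium
exchange (HDX) thermodynamics from NMR peak decays, two-state chemical
denaturation by the linear extrapolation model, two-state DSC melting
fits, the global-vs-local unfolding regime rule, and coordinate-level
geometry, plus seeded synthetic-data generators for every input.

## The models at the core

**HDX protection.** Under EX2 exchange an amide's observed rate relates to
its intrinsic random-coil rate through the local opening equilibrium,

    k_HDX = K_unfold * k_rc,      dG_local = -RT ln(K_unfold),

with R = 1.987e-3 kcal/mol/K. Intrinsic rates come from poly-DL-alanine
reference rates corrected for neighboring side chains, pD and temperature
(per acid/base/water catalysis channel). In the base-catalyzed window
(pD 5–7) log10(k_HDX) rises one-for-one with pD for EX2 residues and not
at all for EX1 residues — the basis of `classify_regime()`. A peak that
never decays over the observation window is *hyperprotected*: its k_HDX
cannot be measured, only bounded.

**Chemical denaturation.** CD ellipticity at 222 nm is converted to
fraction native between sloping baselines; per-point free energies
`-RT ln((1-fN)/fN)` are fitted as a line in denaturant,

    dG(D) = dG_global - m [D],      [D]_1/2 = dG_global / m,

and the headline free energy is reported as `m × midpoint`.

**DSC.** The melting transition is the scaled two-state van't Hoff excess
heat capacity `Cp(T) = s dH² K / (R T² (1+K)²)` on a polynomial baseline,
yielding T_m and dH_vH.

**Regime rule.** A residue whose dG_local strictly exceeds 85% of
dG_global unfolds only through the global unfolding event; hyperprotected
residues are always in that regime.

## Worked example

Simulate the study-like preset (60 observed amides, one hyperprotected,
46 surviving peaks at 10 min), fit every stage, and classify the regime:

```r
library(acpstab)
preset <- acp_study_preset()

peaks <- simulate_hdx(preset$sequence, preset$dG_local,
                      hyperprotected = preset$hyperprotected,
                      pD = c(5.5, 6.5), times = preset$times,
                      noise_sd = 0.02, seed = 1)
fits <- fit_hdx_rates(peaks[peaks$pD == 5.5, ])

cur <- simulate_denaturation(8.47, 1.85, noise_sd = 180, seed = 2)
fit <- lem_fit(cur$denaturant, cur$signal)
fit
#> Two-state LEM fit (two_step): dG_global = 8.577 kcal/mol, m = 1.882 kcal/mol/M, midpoint = 4.558 M

th <- simulate_thermogram(101.4, 100, baseline = c(0.5, 0.01),
                          noise_sd = 0.09, seed = 3)
dsc_fit(th$temp_C, th$signal)
#> Two-state DSC fit: T_m = 101.39 degC, dH_vH = 100.1 kcal/mol

kp <- krc_profile(preset$sequence,
                  exchange_conditions(pD = 5.5, temperature = 298.15))
ok <- !fits$hyperprotected
dG <- rep(NA_real_, nrow(fits))
dG[ok] <- protection_energy(fits$k_HDX[ok],
                            kp$k_rc[match(fits$residue_index[ok], kp$position)],
                            298.15)$dG_local
classify_global_regime(dG, fit$dG_global,
                       hyperprotected = fits$hyperprotected,
                       residue_index = fits$residue_index)
#> Global unfolding regime (dG_local > 0.85 x 8.58 kcal/mol): 3 residue(s)
#>  residue_index dG_local hyperprotected in_global_regime
#>             15 8.577402           TRUE             TRUE
#>             75 7.572425          FALSE             TRUE
#>             76 7.435997          FALSE             TRUE
```

The denaturation fit recovers the generating stability (8.47 kcal/mol,
midpoint 4.58 M) within the 2% noise; the melting fit lands on the
generating T_m of 101.4 °C; and the regime report flags residue 15 (the
hyperprotected amide, assigned the global free energy) together with
residues 75 and 76, whose local free energies sit above 85% of the global
value — the designed triplet.

Composition-level statistics come from the packaged synthetic ACP-like
reference sequence:

```r
charge_census(acp_reference_sequence())
#> Acidic (Glu/Asp): 21 (10/11)
#> Basic (Arg/Lys): 9 (1/8)
#> pI: 4.13
#> His (0) excluded from the basic total
```

`run_pipeline(list(out_dir = "out", seed = 1))` runs all of the above end
to end and writes `peaks.tsv`, `residues.csv` and `summary.json`; reruns
under the same seed are byte-identical.

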