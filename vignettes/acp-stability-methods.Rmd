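---
title: "Stability thermodynamics of a hyperthermophilic acyl carrier protein: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stability thermodynamics of a hyperthermophilic acyl carrier protein: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acpstab)
```

## The scientific problem

Acyl carrier proteins (ACPs) are small, acidic four-helix bundles that
shuttle growing acyl chains through the fatty-acid synthesis machinery via a
phosphopantetheine arm on a conserved serine. Hyperthermophilic bacteria
express ACPs that stay folded near the boiling point of water, and the
questions a stability study of such a protein asks are quantitative: how
large is the free energy separating the folded and unfolded states, which
residues unfold only when the whole protein does, and which structural
features (ionic clusters, hydrophobic packing, pocket geometry) carry the
extra stability?

`acpstab` implements the complete quantitative layer of such a study:

* per-residue **hydrogen/deuterium exchange (HDX)** thermodynamics measured
  by NMR peak decay,
* **chemical denaturation** by the two-state linear extrapolation model
  (LEM) from circular dichroism (CD) data,
* **differential scanning calorimetry (DSC)** two-state melting fits,
* the **global-unfolding regime rule** connecting the per-residue and global
  free energies,
* **coordinate-level geometry** (ensemble precision, pocket-entrance
  distances, side-chain contacts, salt bridges, charge census, RDC quality
  factor), and
* a **synthetic-data generator** that produces every input with known ground
  truth, so the whole pipeline is testable without access to raw spectra.

## H/D exchange thermodynamics

An amide proton exchanges with solvent deuterium only from an "open" state.
In the EX2 limit the observed rate is

$$k_\mathrm{HDX} = K_\mathrm{unfold}\, k_\mathrm{rc},$$

where $K_\mathrm{unfold}$ is the equilibrium constant of the local opening
reaction and $k_\mathrm{rc}$ is the intrinsic rate the same amide would show
in a random coil. The local unfolding free energy follows as

$$\Delta G_\mathrm{local} = -RT\,\ln K_\mathrm{unfold},
\qquad R = 1.987\times10^{-3}\ \mathrm{kcal\,mol^{-1}K^{-1}}.$$

### Intrinsic rates

`krc_base()` evaluates the poly-DL-alanine reference rates per catalysis
channel (acid, base, water; log reference constants 1.62, 10.05, −1.5 at
293 K in D2O, pK of D2O 15.05) and corrects them with the log-additive
side-chain neighbor factors shipped in
`inst/extdata/polyala_neighbor_factors.tsv`. The factor table was
transcribed by hand from the published correction scheme; its file header
records the provenance and version. In the base-catalyzed window (pD 5–7)
the base channel carries ≥ 95% of the rate, which is what makes the EX2
diagnostic work: raising pD by one unit multiplies $k_\mathrm{rc}$, and
hence $k_\mathrm{HDX}$, by ten.

Three numerical choices deserve mention:

* **Arrhenius correction.** Rates are moved from the 293 K reference to the
  experimental temperature with $\exp(-(E_a/R)(1/T - 1/T_\mathrm{ref}))$,
  with $E_a/R$ configurable per channel (defaults correspond to 14, 17 and
  19 kcal/mol for acid, base and water catalysis). The exponent is
  dimensionless only when the activation energy is divided by the gas
  constant, so that is the quantity the API exposes, in kelvin.
* **Titrating side chains.** Asp, Glu and His carry two factor sets. The
  package selects the form by comparing pD with the side-chain pK (a step),
  rather than blending by ionization fraction. Blending would bend the
  one-log-unit pD law for acid-flanked amides near the side-chain pK (shifts
  as low as 0.87 between pD 5.5 and 6.5), contradicting the EX2 limit that
  the paired-pD experiment relies on; applying the carboxylate forms
  throughout pD 5–7 keeps the law exact to about 0.005 log units for
  interior residues. The C-terminal amide is the one deliberate exception
  (its carboxylate adds acid catalysis) and is documented as such.
* **Termini.** Residue 1 has no observable amide; residue 2 additionally
  feels the N-terminal ammonium factor and the final residue the C-terminal
  carboxylate factor. pD is taken as a direct reading; an optional flag
  applies the +0.4 correction for uncorrected meter readings.

### Peak-decay fitting and hyperprotection

`fit_decay()` fits $I(t) = A e^{-kt}$ by nonlinear least squares (no
floating baseline: a fully exchanged peak vanishes in D2O; a plateau term is
available behind a flag). When a peak has already dropped into the noise
floor by the second spectrum the exponential problem is degenerate and the
routine falls back to log-linear regression on the positive heights.

A residue is **hyperprotected** when its series stays flat over the whole
observation window (final/first height > 0.8) *and* no decay is detected.
Detection requires the fitted rate to exceed 3.5 standard errors. A plain
95% interval turned out to misread a truly constant peak as decaying in
roughly 2.5% of noise realizations (the one-sided $k \ge 0$ fit produces
spurious small positive rates), while a genuine 10–20% decay over a
month-long window is detected with a t-statistic above 50 at percent-level
noise — so the stricter threshold separates the two cases cleanly. For a
hyperprotected residue only a resolvable lower bound
$\ln(1/0.8)/t_\mathrm{max}$ is reported; its free energy cannot be measured
by exchange and is set to the global value in the regime analysis.

### EX1/EX2 diagnosis

`classify_regime()` compares the log10 rate shift between two pD conditions
with the pD difference (EX2 limit) and zero (EX1 limit) inside a ±0.3 log
unit band; anything else is `intermediate`. The band is a package default —
the underlying plot-based diagnostic draws the two limiting lines without a
numeric tolerance — and is configurable.

## Chemical denaturation (LEM)

CD ellipticity at 222 nm tracks helix content. After conversion to mean
residue ellipticity (`mean_residue_ellipticity()`, $n-1$ peptide-bond
convention), `lem_fit()` analyses a guanidine-HCl titration under the
two-state model:

$$f_N(D) = \frac{1}{1+\exp(-( \Delta G - mD)/RT)},\qquad
\Delta G(D) = \Delta G_\mathrm{global} - mD,\qquad
[D]_{1/2} = \Delta G_\mathrm{global}/m.$$

The default route follows the classical two-step procedure: estimate
baselines, convert to fraction native, compute per-point free energies
$-RT\ln((1-f_N)/f_N)$ for $0.05 \le f_N \le 0.95$, and fit the line in $D$.
Two refinements make this route exact on noiseless model data and efficient
on noisy data:

* baselines are refined by a **joint six-parameter nonlinear fit** (two
  sloping baselines plus $\Delta G$ and $m$) seeded by the flanking-20%
  window estimates. Fixed flanking windows bias the baselines whenever the
  transition encroaches on them — for a destabilized variant with a 2.9 M
  midpoint the "native" window already contains 2–3% unfolded protein;
* the per-point free-energy line is **weighted by $(f(1-f))^2$** (the delta
  method gives $\mathrm{sd}(\Delta G) \propto 1/(f(1-f))$), with the
  weights taken from the model fraction rather than the noisy observed one.

A pure `method = "global"` route reports the joint fit directly; on
noiseless data the two routes agree to machine precision, and the package
asserts agreement to 0.1%. The headline free energy is always reported as
$m \times [D]_{1/2}$, which ties the two printed quantities together
exactly.

## DSC melting fits

`dsc_two_state_cp()` is the scaled two-state van't Hoff excess heat
capacity,

$$C_p(T) = s\,\frac{\Delta H_{vH}^2}{R T^2}\frac{K}{(1+K)^2},\qquad
K = \exp\!\left(-\frac{\Delta H_{vH}}{R}\left(\frac1T - \frac1{T_m}\right)\right),$$

with a free amplitude $s$ absorbing instrument units and concentration, no
$\Delta C_p$ term, temperatures in kelvin internally and Celsius at the
interface. `baseline_correct()` fits a polynomial (degree ≤ 3) to the
pre- and post-transition flanks and subtracts it. Because a melting
temperature near 101 °C on a 50–120 °C scan leaves the post-transition
flank inside the transition (the van't Hoff width of a 100 kcal/mol
transition is ~11 °C), `dsc_fit()` refits baseline and transition jointly
after the flank-window pass; that removes a ~0.1 °C bias in $T_m$ and a
~18% bias in $\Delta H_{vH}$ at these study conditions. Multi-component
profiles can be deconvolved as sums of two-state components.

## The global-unfolding regime

Residues whose local opening costs nearly as much as complete unfolding can
only exchange through the global unfolding event. Following the convention
of protection-factor studies, `classify_global_regime()` labels a residue
as in the global regime when $\Delta G_\mathrm{local} >
0.85\,\Delta G_\mathrm{global}$, with a strict inequality at the boundary
(the rule is worded "higher than 85%"). Hyperprotected residues are always
in the regime and are assigned $\Delta G_\mathrm{global}$. An optional flag
requires the lower confidence bound to clear the threshold instead of the
point estimate.

## Structure geometry

Superposition uses the Kabsch SVD solution, written in-package and
cross-checked in the test suite against an independent rotational search
and against `bio3d`'s fitting routine. Ensemble precision
(`ensemble_rmsd_to_mean()`) iterates superpose-to-mean until the mean
coordinates move less than 10⁻⁶ Å, then averages the per-model RMSD over
the backbone (N, Cα, C′) or any other selection — the statistic quoted for
NMR ensembles. Pocket-entrance sizes are the three pairwise Cα distances of
the outermost entrance residues; packing contacts are the minimum
side-chain proton–proton distances (falling back to heavy atoms, with a
warning, for crystal structures); salt bridges pair Arg/Lys side-chain
nitrogens with Asp/Glu carboxylate oxygens at a 4 Å heavy-atom cutoff
(community convention; configurable) and are clustered into connected
components. The charge census counts Glu/Asp and Arg/Lys (His reported
separately, following comparative ACP tables) and computes the isoelectric
point by bisection of the Henderson–Hasselbalch net charge under the
Bjellqvist/ProtParam pK set. `rdc_q_factor()` is
$\mathrm{rms}(D_\mathrm{meas}-D_\mathrm{calc})/\mathrm{rms}(D_\mathrm{meas})$.

File parsing (PDB/mmCIF) is delegated to `bio3d`; deposited entries can be
fetched with `fetch_pdb()` where a network is available.

## What the synthetic generator emulates — and what it does not

`simulate_hdx()`, `simulate_denaturation()`, `simulate_thermogram()` and
`simulate_helix_bundle_ensemble()` generate the exact forward models above
with seeded noise: multiplicative Gaussian noise on peak heights, additive
Gaussian noise on CD/DSC signals, isotropic coordinate jitter plus random
rigid frames for ensembles. `acp_study_preset()` assembles one
deterministic "study-like" parameter set on top of the packaged synthetic
81-residue ACP-like sequence: 60 observed amides, 14 of which exchange out
before the first spectrum at 10 min (so 46 peaks survive), sixteen residues
above 5 kcal/mol, one hyperprotected amide (I15), exactly two finite
free energies above 85% of the 8.47 kcal/mol global value (Y75 at 7.60 and
I76 at 7.45 kcal/mol), a destabilized-variant curve (5.18 kcal/mol,
1.80 kcal/mol/M) and a 101.4 °C melting transition. Default noise levels
are 2% on peak heights, 2% of the CD amplitude and 1% of the DSC peak —
typical of well-behaved modern instruments.

The generator reproduces the *structure* of real data, not its pathologies:
no peak overlap or spectral artifacts, no baseline drift between spectra,
no EX1/EX2 mixtures, no aggregation or irreversibility in melts, and
noise is uncorrelated across points. Passing the recovery tests therefore
demonstrates correctness of the estimators under the stated models, not
robustness to every experimental artifact.

The packaged sequence is a constructed stand-in, not a deposited database
sequence: it carries the residue identities and helix boundaries named in
the underlying study and the published charge composition (10 Glu/11 Asp,
1 Arg/8 Lys), which is what the composition-level statistics (census, pI)
depend on. Its file and accessor documentation say so explicitly.

## Problem sizes and reproducibility

The test suite and the acceptance script run entirely from the generators:
105-point exchange series for 60 residues at two pD values, 35-point
denaturation curves (200 noisy replicates for the recovery statistic),
351-point thermograms (100 noisy replicates), and 20-model jittered
ensembles — sizes chosen to match the corresponding experiments while
keeping a full run in well under a minute. Every stochastic step takes an
explicit integer seed, generators save and restore the global RNG state,
and `run_pipeline()` reruns byte-identically under the same configuration;
outputs carry the package version, the seed, and an MD5 fingerprint of the
analysis parameters.

## Known limitations

* The neighbor-factor table is a hand transcription of the published
  correction scheme; an independent machine-readable cross-check was not
  available when the package was assembled.
* Geometry against deposited PDB entries requires those coordinate files
  (local copies or a network connection for `fetch_pdb()`); the package
  does not redistribute them.
* Exchange analysis covers the EX2/EX1 limits and a three-way label; no
  mixture modeling between the limits.
* The DSC model has no $\Delta C_p$ term and no scan-rate (kinetic)
  effects; the LEM analysis is strictly two-state at 222 nm.
* Isoelectric points use the composition-only Bjellqvist model, as the
  standard web tool does; structure-aware pK shifts are out of scope.
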