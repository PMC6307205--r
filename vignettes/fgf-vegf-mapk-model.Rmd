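---
title: "Modeling FGF/VEGF crosstalk in MAPK signaling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling FGF/VEGF crosstalk in MAPK signaling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`mapkcross` implements a mass-action kinetic model of ERK activation in
endothelial cells stimulated by two pro-angiogenic growth factors, FGF and
VEGF. The two ligands act through separate receptor systems that converge on
the MAPK cascade:

* **FGF arm.** FGF binds cell-surface heparan sulfate glycosaminoglycans
  (HSGAGs) and, competitively and non-productively, free FGFR1. Only the
  FGF:HSGAG complex can recruit FGFR1 into the signaling-competent ternary
  complex (binding of free FGFR1 to HSGAG is negligible, and direct
  FGF:FGFR1 complexes do not signal). Ternary complexes dimerize, the dimer
  is phosphorylated, and the phosphorylated dimer binds and phosphorylates
  the adaptor FRS2. Phosphorylated FRS2 is the FGF-arm kinase for MEK.
  Doubly phosphorylated ERK (ppERK) feeds back by driving ubiquitination of
  FRS2 and pFRS2 into an inactive pool (FRS2u), which terminates FGF-arm
  signaling on the timescale of minutes.
* **VEGF arm.** VEGF binding to VEGFR2 is collapsed into a single reversible
  autophosphorylation step (the two monomers of the ligated receptor
  phosphorylate each other, and the detailed mechanism is not the object of
  study here). Phosphorylated receptor activates Ras through both a
  Shc-independent route (direct recruitment of Grb2:Sos) and a Shc-dependent
  route (Shc phosphorylation, then Grb2:Sos recruitment by pShc free or on
  the receptor). Ras-GTP activates Raf; active Raf (aRaf) is the VEGF-arm
  MEK kinase.
* **Shared MAPK cascade.** pFRS2 and aRaf each phosphorylate MEK
  distributively at two sites; ppMEK phosphorylates ERK at two sites. The
  phosphatase Ptase2 reverses MEK phosphorylation through explicit binding
  (association rate `k_dpMEK_p`) and catalysis (`ked2`); Ptase1 and Ptase3
  play the same role for pFRS2 and for pERK/ppERK. The `pERK` readout sums
  every free and bound singly- and doubly-phosphorylated ERK species.
* **Trafficking.** Free and bound FGFR1 and VEGFR2 are internalized,
  recycled and degraded. All bound FGFR1 forms share one trafficking rate
  set; VEGFR2 carries six rates (`k_intf`, `k_recf`, `k_degf` for the free
  receptor, `k_intb`, `k_recb`, `k_degb` for the phosphorylated receptor).
  Degradation moves complexes into explicit degraded-pool species, so every
  protein moiety (receptors, HSGAG, FRS2 including FRS2u, Ras, Raf, MEK,
  ERK, phosphatases) is exactly conserved — there is no synthesis or loss
  within the model's two-hour validity window. Internalization and recycling
  of each form are stored as one reversible reaction.

The main model comprises 70 reactions, 72 species and 75 rate constants; the
heparin extension (below) adds 26 reactions, 25 species and 3 rate constants.
These counts are asserted by `check_model_integrity()` at construction time.

### Reconstruction, not transcription

The published supplementary tables that enumerate the original model's
reactions and fitted parameter values are not redistributable here. The
network shipped in this package is therefore a *reconstruction* assembled
from the mechanisms stated in the main text, designed to realize the same
structural counts and the same qualitative and quantitative behavior. All
fixtures derived from it — including the packaged best-fit ensemble
(`best_fits_synthetic.csv`) — are labelled synthetic. Consequences for
interpretation: species names, individual rate-constant values and reaction
indices are not one-to-one with the original tables, while the topology,
pool sizes with literature anchors (FGFR1 = 20,000, VEGFR2 = 1,000,
HSGAG = 1e5 molecules/cell), readout conventions and headline response
properties are.

Two reconstruction choices deserve mention. First, the identities of the
phosphatases acting on pFRS2 and pERK are not named in the source text; the
reconstruction uses one generic phosphatase per phospho-species (Ptase1 for
pFRS2, Ptase3 for pERK/ppERK) alongside the named Ptase2 for MEK, and these
are flagged as provisional. Second, dimerization of the ternary complex
precedes receptor phosphorylation at the reaction level; the source is
ambiguous ("dimerizes and leads to phosphorylation"), and ordering
phosphorylation after dimerization matches the trans-autophosphorylation
mechanism of receptor tyrosine kinases.

### Units and the ligand clamp

Cell-associated species are amounts in molecules/cell; extracellular
ligands are concentrations in nM and are **clamped**: the media reservoir in
the emulated experiments is large relative to consumption by ~1e4–1e5
surface binding sites over two hours, so ligand depletion is negligible.
On-rate constants of ligand-facing reactions are therefore in 1/(nM·min) and
all other bimolecular on-rates in 1/(molecules/cell·min); every flux is in
molecules/cell/min. A conversion factor (about 6.0e5 molecules/cell per nM
at 1e6 cells/ml) is only needed if a ligand is deliberately unclamped and is
documented rather than wired in.

### The heparin extension

Soluble heparin is a HSGAG analog that competes with surface HSGAGs for FGF.
The extension adds a parallel arm in which the FGF:heparin complex binds
FGFR1 to form a heparin-ternary complex that dimerizes (with itself and with
the HSGAG-ternary complex), signals to FRS2, and is trafficked like every
other bound FGFR1 form. Only three rate constants are new: FGF–heparin
binding (`kon_FGF_HEP`, `koff_FGF_HEP`) and the on-rate of the soluble
complex for FGFR1 (`kon_TCh`, weaker than the surface-anchored route); all
downstream rates are shared with the main arm.

Because both FGF and heparin come from the clamped media reservoir, their
solution-phase binding equilibrates on a timescale much faster than, and
independent of, the cell-surface dynamics. The stimulation protocol
therefore applies this binding as a pre-equilibrium: free FGF is clamped at
`FGF_tot / (1 + [heparin]/Kd_hep)` and FGF:heparin at the remainder. This
keeps the ligand-clamp contract, makes the zero-heparin protocol *exactly*
the main model, and is what produces the characteristic sign flip of the
heparin effect: at low FGF the dominant consequence of heparin is the
reduction of free FGF (less ternary complex, ΔpERK < 0), while at high FGF —
where the biphasic dose-response has turned over because excess FGF
sequesters FGFR1 in non-signaling FGF:FGFR1 pairs — the same reduction moves
the system back toward the peak, and the heparin-ternary route adds signal
(ΔpERK > 0).

## Baseline parameterization

Rate constants that the source text anchors (receptor and co-receptor
densities, dose–unit pairings: FGF 25 kDa from the 100 ng/ml = 4 nM pairing,
VEGF 45.5 kDa from 50 ng/ml = 1.1 nM) are used directly. The remaining
baseline values were calibrated, once, against the quantitative behaviors
the source reports for its fitted model, and then frozen as the package's
reference parameterization:

* maximum pERK ≈ 8e5 molecules/cell at 0.5 nM FGF and ≈ 9e2 at 0.5 nM VEGF
  (three orders of magnitude apart), with the FGF response spanning only
  4e5–8e5 across 0.01–2 nM while VEGF spans ~2e-2–1e5;
* a biphasic FGF dose response over 0.16–500 ng/ml with an interior peak,
  produced by FGFR1 sequestration into non-signaling FGF:FGFR1 complexes at
  high dose (quadratic dimerization sharpens the decline);
* FRS2 depletion even at 0.01 nM FGF, making FRS2 the FGF-arm bottleneck;
* time-to-peak T1 ≤ 6 min for 0.5–2 nM FGF versus ~8–22 min for VEGF, and
  half-maximum duration T2 of ~9 min (FGF) versus ~18 min (2 nM VEGF);
* a supra-additive combination (ratio R ≈ 1.1 at 0.5 nM + 0.5 nM) and the
  VEGFR2-density dependence of the combination response.

The steep VEGF dose-response arises from distributive two-site
phosphorylation with near-saturated phosphatases: below a threshold MEK-ward
flux the cascade is strongly damped, above it ppMEK breaks through. The
0.5→2 nM VEGF window straddles that knee. The same mechanism makes the
combination supra-additive — the marginal VEGF flux lands on a cascade
already driven past threshold by FGF — and makes VEGFR2 density a potent
lever. This is a designed, documented property of the reconstruction; users
exploring far-from-baseline parameter sets should expect threshold behavior.

Calibration used the package's own machinery (simulation, metrics, PSO on a
log10 box) against those targets; no quantity was fitted to data inside this
package. The 39 free quantities for data fitting are the shared-MAPK rate
constants (24), Raf activation/deactivation (4), the six VEGFR2 trafficking
rates, and five influential initial amounts (FRS2, Ptase2, Ras, MEK, Raf) —
the main-text rule of "overlapping-pathway parameters + VEGFR2 trafficking +
influential initial amounts", since the exact supplementary list is
unavailable.

## Simulation engine

`simulate()` integrates the assembled mass-action right-hand side (generated
in C++ from the network's sparse stoichiometry) with `deSolve::lsoda`,
relative tolerance 1e-8 and absolute tolerance 1e-6 molecules/cell —
phospho-species span roughly eight orders of magnitude, so the convergence
of the solution is verified in the test suite by halving tolerances. The
default output grid is 0.5 min over a 120-min horizon, fine enough to
resolve T1 values near 6 min; metric extraction interpolates between grid
points for the half-maximum crossings. Negative excursions beyond the
error-control scale (`max(atol, rtol * max|state|)`) abort with a diagnostic
error instead of being clipped, because silent clipping hides stiffness
failures. Horizons beyond 120 min require an explicit override, since the
no-synthesis/no-degradation assumptions only hold inside the two-hour
window.

## Response metrics

* `max_pERK`: window maximum of the `pERK_total` readout.
* `T1`: first time attaining the maximum. Records whose maximum sits on the
  window boundary are flagged (`boundary_max`) — the response has not peaked
  within two hours and T1/T2 should be omitted from comparisons, matching
  the omission rule used in the density/trafficking figures.
* `T2`: total measure of the super-half-maximum set, with interpolated
  crossings. Defining T2 as a measure (not a single interval) makes it
  robust to multi-modal responses, for which a single-crossing definition
  would be ambiguous.
* `R = max pERK(FGF+VEGF) / (max pERK(FGF) + max pERK(VEGF))` from three
  simulations under identical settings; R > 1 is supra-additive. When one
  ligand's dose is zero the combination run coincides with the other mono
  run and R = 1 exactly.
* Ensemble summaries report the median with a seeded percentile bootstrap
  (10,000 resamples) for the median's 95% CI, and a Wilcoxon signed-rank
  test against 1 for R. The bootstrap/rank choices are stand-ins: the source
  marks significance at p < 0.05 without naming its test or CI method.

## Global sensitivity analysis (eFAST)

`efast_design()`/`efast_indices()` implement the extended Fourier Amplitude
Sensitivity Test in the form standard in systems biology (Marino et al.
2008): the input of interest is driven at the maximum interference-free
frequency `floor((NS-1)/(2M))` with `M = 4` harmonics, the complementary set
at frequencies at most `w_max/(2M)`, with `NR = 5` random-phase resample
curves by default, and a dummy input appended as a significance floor. Total
order indices are `S_ti = 1 - V_comp/V`. Inputs are sampled log-uniformly
across the two-decade (×1/10 to ×10) bounds — the bounds are multiplicative,
so the log scale is the natural metric — and the sampling scale is
switchable to linear per input. The decomposed output is the two-hour
maximum of `pERK_total` under a fixed stimulus, one analysis per stimulus
(FGF-only or VEGF-only). Non-finite outputs (failed integrations, expected
at well under 1% of samples) are replaced by the per-curve median and
counted, since dropping samples would corrupt the spectrum. The estimator is
validated against the closed-form Ishigami indices (±0.05 at 257 samples ×
5 curves) and an additive linear model.

## Calibration (PSO on the weighted SSR)

The objective is the weighted sum of squared residuals
`WSSR = sum(((pred_i - obs_i)/obs_i)^2)` over the three training-shaped
datasets: the normalized pERK panel at six FGF doses (0.16–500 ng/ml;
normalized by the single maximum across all doses and times), the
normalized pR2 time course at 5 ng/ml VEGF, and the normalized pERK time
course at 50 ng/ml VEGF (each normalized by its own two-hour maximum).
Normalizers are taken over the dataset's sampling times - the same
operation applied to the measured data - so the objective vanishes exactly
at the truth on noise-free synthetic data. The optimizer is constriction-coefficient PSO (inertia 0.729,
cognitive/social 1.49445 — the standard Clerc–Kennedy constants, since the
cited implementation's settings are not stated), run in log10 space over the
two-decade box with reflecting boundaries; reflection preserves swarm
diversity near bounds better than clamping. Simulation failures inside the
objective contribute a large finite penalty (1e6) and are logged by the
swarm trace. `select_best()` ranks fits by training WSSR plus a validation
score — WSSR on the 10 ng/ml FGF pERK and 80 ng/ml VEGF pR2 tables plus the
number of sign disagreements on the heparin ΔpERK pattern — and keeps the
top 16, mirroring the published 72-runs-to-best-16 workflow; the weighting
between training and validation error is unstated in the source, and an
unweighted sum is used.

## Synthetic data

`generate_training_like()` simulates the three training conditions at a
sparse grid (8 points over 2 h, mimicking figure sampling so the fitting
problem has realistic information content), applies multiplicative
lognormal noise with a default CV of 10% *before* normalization
(densitometry noise on Western blots is scale-proportional; the source gives
no noise model), then normalizes per scheme. Lognormal noise keeps values
strictly positive, so the WSSR's division contract cannot be violated; t = 0
points are excluded because normalized observations must be positive.
Validation-shaped tables (10 ng/ml FGF, 80 ng/ml VEGF, heparin ΔpERK signs
at four time points) are generated from the same truth.

What the generator does *not* emulate: Western-blot saturation and
background, batch effects between the three source cell lines (the model
assumes shared kinetics across cell types, as the source does), and the
exact figure time grids (configurable here). Passing recovery tests on this
generator therefore demonstrates that the pipeline is self-consistent and
identifiable at realistic noise and sampling density — not that the original
digitized data would be fit equally well.

`recovery_experiment()` draws a truth by perturbing the baseline free
quantities (lognormal, 0.25 decades), refits with multi-start PSO plus a
Nelder–Mead polish of the swarm optimum (2 starts × 24 particles × 55
iterations + 400 polish steps and a 2-min objective grid by default, about
a quarter hour), and reports per-quantity log10 errors and the within-×2
recovery rate, separately for the designated influential set. Two findings
about this problem are worth stating plainly. First, the optimum is
informative: at zero noise the objective at the generating truth is
numerically zero, and fits reach a ~1% mean relative residual. Second,
several influential quantities are *practically non-identifiable
individually* from the three normalized training datasets — they enter the
observable response only through products with compensating partners
(MEK-phosphatase capacity `Ptase2 * ked2`; the VEGF-arm gains
`Raf * kon_aRaf_MEK` and `Ras * kon_RasGTP_Raf`) — so even near-perfect
fits can leave those individual values off by two- to four-fold. The
recovery report exposes exactly this structure; a recovery criterion that
demands every influential quantity individually within ×2 of truth is not
attainable for this model class, and the corresponding acceptance check is
expected to flag it.

## In-silico experiments

The drivers in `run_combination_grid()`, `run_vegfr2_density_scan()`,
`run_trafficking_swap()` and `run_heparin_difference()` are pure functions
of (model, parameter sets, spec): they never mutate the packaged baseline,
and re-running them reproduces identical tables. Density factors default to
the ten-fold range around the 1,000 molecules/cell baseline. Trafficking
swaps replace selected VEGFR2 rates with the corresponding FGFR1 values,
one-by-one or all together. The heparin difference uses the training FGF
dose panel and four evenly spaced time points (30/60/90/120 min), since the
original figure's exact times are not stated.

## Known limitations

* The reconstruction is structurally faithful but not table-identical to
  the original supplementary enumeration; absolute rate-constant values are
  calibrated stand-ins.
* The simulated pR2 time course at the low training dose (5 ng/ml VEGF)
  rises to a late maximum rather than peaking within ~15 min as typical
  immunoblot data do; at the doses used for predictions (0.5–2 nM) the
  receptor envelope peaks early. A receptor-level desensitization process
  would be needed to sharpen the low-dose peak and is out of scope.
* FGF-activated Ras–Raf signaling, VEGFR1/NRP1, signaling by internalized
  receptors, spatial gradients and >2 h dynamics are excluded, as in the
  source model.
* The VEGF arm's threshold behavior makes ensemble spread of VEGF-side
  metrics large relative to FGF-side metrics; ensemble medians are the
  stable summaries.

## Reproducibility notes

Every stochastic component (eFAST phases, PSO, noise generation, bootstrap)
takes an explicit seed and restores the caller's RNG state. Simulation is
deterministic given (model, parameters, protocol) — identical calls return
bit-identical trajectories on one platform.
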