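---
title: "Minimal PBPK modelling of lung and trachea exposure: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimal PBPK modelling of lung and trachea exposure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minipbpk)
```

## The model and its assumptions

The package implements a minimal PBPK model: the target tissues of a
respiratory indication — lung and trachea — are explicit compartments, and
all nontarget tissues are lumped into a single rest-of-body compartment.
Five states describe one analyte (oral absorption depot, blood, lung,
trachea, rest of body); a parent–metabolite model appends four metabolite
states fed by conversion of the parent in blood.

The structural assumptions, and where they matter:

* **Perfusion rate-limited distribution.** Each tissue equilibrates with
  blood instantaneously at a fixed partition coefficient; the return flux is
  `C_tissue · Q / K_tissue`. This is appropriate for small lipophilic
  molecules (pyronaridine) and is the reported disposition regime for
  artesunate and dihydroartemisinin (DHA). It cannot describe
  permeability-limited uptake, so the partition coefficients absorb any
  membrane kinetics.
* **Direct lung–trachea exchange.** First-order transfer in both directions
  (`k_lt`, `k_tl`) on amounts, in addition to perfusion. This is what lets
  the trachea — with only 2.1% of cardiac output — carry exposures far above
  its perfusion share.
* **Blood outflow as written.** The blood compartment loses
  `C_blood · (Q_co + Q_trachea + Q_rest + CL/F)`: the lung receives the full
  cardiac output *and* the trachea and rest-of-body flows leave blood
  separately, so the total outflow exceeds cardiac output. We keep this
  structure deliberately: it is internally mass-conserving (every outflow
  term has a matching tissue gain), and it is the structure to which the
  disposition parameters belong. "Correcting" it would silently invalidate
  the parameter values.
* **Complete metabolic conversion.** Artesunate is treated as a prodrug:
  its entire blood clearance term is the DHA formation rate. The
  parent–metabolite model therefore must run in molar units (nmol,
  nmol/L), and `dose_schedule()` converts administered mg through the molar
  mass (384.42 g/mol for artesunate; constants in `molar_masses`, all
  overridable). No salt-to-free-base correction is applied by default
  (`salt_factor = 1`), since none is defined for these dose levels.
* **Linearity.** All processes are first order, so profiles are proportional
  to dose and multiple-dose profiles superpose. Both properties are enforced
  by tests, and both mean that dimensionless ratios (tissue-to-blood,
  accumulation) are dose-invariant.

### The metabolite trachea equation

The DHA trachea balance is provided in two forms, selected by
`metabolite_trachea_form` in `pbpk_model()`:

* `"as_printed"` (default): the trachea's return flux to blood is
  `C_lung,m · Q_trachea / K_lung,m` — the *lung* concentration over the
  *lung* partition coefficient. This couples the trachea's loss term to the
  lung state and makes the metabolite block non-conserving: summing the
  metabolite derivatives leaves a residue
  `Q_trachea · (C_trachea,m/K_trachea,m − C_lung,m/K_lung,m)` (the blood
  gain and trachea loss no longer cancel). The derivative tests assert this
  residue exactly.
* `"mass_balanced"`: the conventional `C_trachea,m · Q_trachea / K_trachea,m`,
  which restores conservation.

We default to `as_printed` because that is the fitted model behind the DHA
disposition parameters, and because it reproduces the reported DHA
trachea-to-blood AUC ratio regime (≈ 0.14) while the mass-balanced form
gives ≈ 1.06. The lung-to-blood ratio is insensitive to the choice (0.3400
vs 0.3401), which is why the headline DHA lung ratio is robust. The printed
`C_trachea,m = A_trachea/V_trachea` definition is treated as a subscript
slip and implemented as `A_trachea,m/V_trachea`; a parent amount inside the
metabolite block would mix analytes.

## Parameters, units, defaults

Canonical internal units: volumes mL, flows mL/h, time h; amounts ng
(mass mode, pyronaridine) or nmol (molar mode, artesunate/DHA), so
concentrations are ng/mL or nmol/mL internally, with nmol/L (×1000) at the
I/O boundary. `CL_F` is accepted in L/h and converted to mL/h internally —
this matches how clearances are conventionally reported while keeping the
ODE in one unit system.

The reference parameterization (`hamster_physiology()`,
`pyronaridine_model()`, `artesunate_model()`) is the fitted hamster model:
102.01 mL total body volume, 7.20 mL blood, 0.48 mL lung, 0.06 mL trachea,
cardiac output 1181.28 mL/h with 2.1% tracheal perfusion; rest-of-body
volume and flow are derived, not entered. The same values ship as editable
YAML configs (`example_config()`), parsed strictly: any unknown key is an
error, because `K_lung` vs `K_lung_m` typos are otherwise silent.

## Numerical choices

* **Stiff integration.** `lsoda` with `rtol = 1e-8` and an absolute
  tolerance of `1e-10 ×` the dose amount. The artesunate blood pool turns
  over at ≈ 3.5 × 10⁵ /h (CL/F = 2517.7 L/h over 7.2 mL), and pyronaridine's
  near-zero `K_rest` (5.25 × 10⁻⁷) drives the rest compartment at ≈ 2 × 10⁷
  /h; explicit methods are hopeless here.
* **Dose events.** Doses are instantaneous additions to the depot at the
  scheduled times (integration restarts at each event). After every dose the
  output grid is refined geometrically (offsets `h·2⁻¹²` … `h`) so the
  absorption transient — which for artesunate rises on a microsecond-of-hours
  timescale — is resolved by the trapezoidal AUC. Without this, uniform
  grids under-integrate the first interval by ~1%.
* **Output grids.** Default spacing 0.1 h for single-analyte models, 0.02 h
  for parent–metabolite models (the 0.4 h half-life implies sub-hour peaks).
  Halving the step moves interval AUCs by < 0.05% (tested).
* **Negative states.** Solutions are clipped at zero after checking that no
  state undershoots beyond `10 × atol`; a deeper excursion raises an error
  instead of being hidden.
* **Terminal-slope window.** The half-life regression window defaults to
  "last dose + 4 h → end of series" and is always reported alongside the
  estimate. The estimate is genuinely window-sensitive: with `k_a = 0.03`/h,
  a late window drifts toward the absorption limit ln 2/k_a = 23.1 h,
  while windows spanning 4–24 h post-dose sit near 20 h. We therefore treat
  the window as an explicit, logged analysis choice rather than a hidden
  default.
* **Tie-breaks and BLQ.** T_max ties resolve to the earliest time. BLQ
  records are excluded from pooling and regression.

## Estimation

Destructive sampling yields at most a few samples per animal, so there are
no individual profiles: all records are pooled into one weighted least
squares problem (naive pooling), with arithmetic-mean pooling also used
before NCA. Choices:

* **Weighting** defaults to `1/pred²` (relative residuals): concentrations
  span > 3 orders of magnitude across blood, lung and trachea, and uniform
  weighting would fit only the lung peaks. Uniform and `1/pred` are
  available.
* **Log-parameter space, box bounds,** Levenberg–Marquardt (minpack.lm).
  Multi-start (default 8, log-uniform within bounds, seeded) guards against
  local minima in the exchange-rate constants; the demo pipeline and the
  recovery tests use single starts from displaced initial values, which the
  round-trip tests show is sufficient for the reference design.
* **Identifiability flagging.** After the fit, each free parameter is
  perturbed ×1.2 and ÷1.2; a locally flat objective flags the parameter as
  poorly identifiable. The canonical case is `K_rest` ≈ 5 × 10⁻⁷: at that
  magnitude the rest compartment holds nothing, so the objective carries no
  information about it.
* **Per-group fitting** is the natural default for this design (the
  reported per-group exposures are not dose-proportional, indicating
  group-specific fits); the problem object takes any subset of groups.

## The synthetic-data generator

`default_design()` encodes the study the package is built around: two dose
groups (180/360 mg/kg pyronaridine or 60/120 mg/kg artesunate), three daily
oral doses, 22 blood sampling times over 0–72 h, 13 lung/trachea times,
4 animals per time point, destructive tissue sampling (lung and trachea of a
record share an animal; blood animals serve up to three consecutive time
points).

The error model is proportional lognormal,
`obs = pred · exp(σZ − σ²/2)` with `σ² = log(1 + cv²)`, so `E[obs] = pred`
— the mean correction makes arithmetic-mean pooling unbiased, which the
generator tests verify on 10⁴ draws. Default CV 20%, a typical bioanalytical
magnitude; the parameter-recovery study uses 15%. Additive and combined
error are available; censoring below a configurable LLOQ flags records BLQ
(no default LLOQ — assay limits for these compounds are not established
here). Tissue concentrations are emitted as homogenate-corrected tissue
concentrations directly from the model, with no dilution factor: homogenate
dilution is a bioanalytical step assumed already corrected in any real
dataset this emulates.

What passing on synthetic data shows — and what it does not: the generator
draws from the same model family that is fitted, so recovery tests establish
the *estimator* works (no structural bias, tolerable variance under the
design's sparsity) but cannot detect model misspecification, between-animal
parameter variability, or assay artifacts, none of which the generator
emulates.

## Problem sizes used in the tests

The suite simulates at the design's own scale: 14 × 24 h pyronaridine runs
at 0.1 h output resolution, 48–72 h artesunate runs at 0.02 h, and the
recovery study uses 20 replicate datasets of the single-group design with
four free parameters — sizes chosen to exercise the pipeline at the study's
realistic dimensions while keeping the full suite in the minutes range.

## Known limitations

* Absolute concentration predictions inherit everything the partition
  coefficients absorbed; only dimensionless ratios and half-lives are
  design-independent outputs of the reference parameter sets.
* No lag time or transit absorption, no IV route, no enterohepatic
  recirculation, no protein-binding submodel, no interspecies scaling.
* The sensitivity module is local (1% forward perturbation, as defined);
  it does not replace global sensitivity analysis.
* The accumulation ratio and half-life of slowly absorbed compounds depend
  on the analysis windows; both are reported with their windows for that
  reason.
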