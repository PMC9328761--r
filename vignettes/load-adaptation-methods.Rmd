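---
title: "Methods: load adaptation in branched actin networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: load adaptation in branched actin networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actinload)
```

This vignette documents the models, parameter choices and numerical
decisions behind `actinload`, in the spirit of a methods section: what each
stage assumes, which knobs matter, and what the synthetic-data tests do and
do not establish about real measurements.

## The physical picture

A branched actin network grows from nucleation-promoting factors (NPFs)
immobilised on a surface, pushing against a load that an AFM force clamp
holds at a constant compressive stress σ (Pa ≡ pN/µm²). Three coupled
reactions set the steady state at the growth surface:

* **Nucleation** of new filaments by NPF-activated Arp2/3, at a maximal
  per-NPF rate suppressed by the fraction φ of NPF WH2 domains occupied by
  filament barbed ends ("barbed-end interference").
* **Elongation** of uncapped filaments by profilin–actin addition.
* **Capping**, which permanently terminates a filament's growth.

At stationarity the network-wide capping and nucleation fluxes balance,
`k_cap [CP] E = R_nucleate`, fixing the free-barbed-end density `E`
(`barbed_end_density_steady_state()`).

### Brownian-Ratchet rate laws

Insertion of a protein of gap size δ at a surface-pressed filament end is
slowed by `exp(−f δ sinθ / k_B T)` (`boltzmann_step_factor()`), with:

* `f` — force per filament: the external stress divided equally over the
  free ends (`force_per_filament()`), plus an additive internal tethering
  force from transient NPF–barbed-end links. We apply the tether
  identically at all loads, including zero: it is a friction-like force
  present whenever the network moves, and treating it as extra attachment
  kinetics would add parameters the data cannot constrain.
* `sinθ` — a single effective filament contact angle,
  `E / (C_A · 602.2 µm⁻³µM⁻¹ · 0.0027 µm)` (`sin_theta_from_network()`).
  This treats the orientation distribution as one representative angle; a
  full distribution model is out of scope. A ratio above 1 (more ends per
  area than the filament length density can present) is a hard geometric
  error, not a clamp — it signals inconsistent inputs.
* `k_B T` fixed at 4.114 pN·nm (298 K), configurable via
  `physical_constants()`.

Gap sizes: monomeric actin and wildtype capping protein both require
δ = 2.7 nm. The bulky (GST-fused) capping-protein variant needs a larger
gap; its exact value is not structurally determined, so the default is the
placeholder δ_bulky = 5.4 nm (2× wildtype), configurable in
`ratchet_params()`.

### The tethering-force fit

`wt_bulky_ratio()` predicts the load dependence of the normalised
wildtype:bulky incorporation ratio with everything fixed except the tether
force; `fit_tether_force()` estimates that one parameter by least squares
on log ratios. Two numerical choices matter:

* **Unweighted log-scale misfit by default.** Multiplicative measurement
  noise is homoscedastic on the log scale, and inverse-variance weights
  estimated from a handful of replicates are noisy enough to inflate the
  estimator variance; `weighted = TRUE` restores error-bar weighting.
* **t-interval on the residual-bootstrap spread.** With eight loads a
  plain percentile interval of a residual bootstrap undercovers; residuals
  are inflated by √(n/(n−1)) and the interval is
  `est ± t(n−1) · sd(boot)`, truncated at zero.

Identifiability requires the contact angle to differ between the reference
and loaded states — with a constant angle the tether cancels from every
ratio. The experiment's reference is the adjacent unloaded network, so the
ratio fit defaults to `reference_stress = 0` (the flux pipeline keeps the
25 Pa flux reference).

## The stochastic simulator

`simulate_network()` runs an exact Gillespie simulation over
{nucleate, elongate-by-one, cap} with propensities

* `R_nuc = k_nuc_max · npf_density · area · (1 − φ)`,
  `φ = E·K_be / (1 + E·K_be)`;
* per-filament elongation `k_on0 · B(f_eff, δ_actin)` and capping
  `k_cap0 · B(f_eff, δ_cap)`, with `f_eff = σ·area/n + f_tether`.

The inner loop is C++ (via Rcpp) with propensities recomputed after every
event; R's RNG is used throughout, so `set.seed()` makes runs exactly
reproducible. Height advances by `subunit_rise · sinθ / n` per elongation
event — the growth surface moves at the *per-filament* elongation speed,
not the summed one.

Because the package deliberately has no spatial filament representation,
the polymer concentration entering `sinθ` cannot be derived geometrically;
it is parameterised as `C_A = polymer_conc0 · (E/e_ref)^b`. The default
`b = 1.8 > 1` makes the network densify faster than the end density grows,
so the effective angle falls under load; `b = 0` fixes `C_A`, decoupling
the angle — the configuration used when comparing against the mean-field
oracle. `mean_field_barbed_ends()` solves the deterministic fixed point of
the same rate laws by scalar root finding and also initialises simulations
near stationarity.

Default rates are desk-scale study conditions: `k_nuc_max = 0.037 s⁻¹`
per NPF and `npf_density = 1850 µm⁻²` (the unloaded single-molecule
estimates), `k_on0 = 50 s⁻¹` (giving ~7 µm/min unloaded growth at an
effective angle near 1), `k_cap0 = 0.25 s⁻¹` (mean length ~200 subunits,
~0.5 µm), pattern area 0.25 µm². `K_be` is calibrated at construction so
the unloaded steady-state WH2 occupancy is 7%; the saturating form of φ is
a modelling choice — the measurements establish the occupancy values, not
the functional form. Mother-filament availability is assumed non-limiting.
An optional, deliberately force-independent early-failure hazard for young
branches (`abortive_hazard`) is off by default. Edge case: if capping
empties the network while σ > 0, the boundary carries the stress, force
coupling pauses, and the episode is counted in `paused_episodes`.

`steady_state_summary()` reports window averages with batch-means standard
errors for `E` (the raw samples are strongly autocorrelated, so both the
SE and the stationarity trend test use batch means; trend significance at
5% flags the window), Poisson standard errors for event fluxes, and the
flux-balance residual `|R_cap − R_nuc|/R_nuc`. Only steady states are
quantitatively tested; adaptation transients are reproduced by the
generators but not matched to any quantitative structure.

## Flux analysis

`find_steady_segments()` splits a force-clamp trace into near-constant
stress epochs (running-median criterion) and trims each epoch's transient
head until the height–time fit reaches `r2_min`. Defaults —
`min_duration = 60 s`, `r2_min = 0.99`, `stress_tol` of 2% of the setpoint
floored at 10 Pa (so clamp noise at low setpoints, including the 0 Pa
clamp, does not shred epochs) — are package choices; the measurement
protocol specifies no thresholds. A window with numerically zero height
variance counts as perfectly linear, so a stalled network is a valid
zero-velocity segment. Velocities are µm/min externally, µm/s internally;
stress is Pa throughout.

Per-network rates are density × velocity normalised to the 25 Pa reference
load; per-filament rates divide by the relative barbed-end density, with
nearest-stress matching (within 5% or 5 Pa) because segment stresses are
noisy-trace medians. NPF-bound background is removed by
`subtract_baseline()` using a user-specified pre-nucleation lag window.

`fit_decay()` fits one- or two-component exponentials with ≥5 log-spaced
multi-starts; the two decay constants are returned in ascending order to
resolve the label-swap degeneracy, and both shared- and free-amplitude
uses are possible since channels are fit independently. A constant
response is a degenerate-fit error (the decay constant is unbounded).

`mesh_size()` implements ζ = 1.47/√C_A (C_A in µM, ζ in µm) literally.
Direct evaluation at ~1250 µM gives ≈ 41.6 nm, whereas 45 nm is the
conventionally quoted value for such networks; the discrepancy is in the
source formula's typeset form, so no test pins the 45 nm figure and
`diffusion_threshold()` (0.4·ζ) accepts any mesh value.

## Single-molecule stage

Productive molecules leave the evanescent field with the network, so their
intensity decays with transit time τ = depth/velocity; the generator's
default depth (0.15 µm) is a typical TIRF value, a synthetic-data
parameter only. Classification replaces image-level tracking and trained
classifiers with three transparent thresholds on track tables: decay-fit
r² ≥ 0.9, ≥ 80% intensity drop (upper quartiles of the first/last frames,
robust to blinking), and positional drift below 0.2 µm. Tracks shorter
than 5 frames are ineligible; dwell is time from first frame to intensity
< 5% of fitted I₀ (or track end); a final intensity above 10% of I₀ marks
premature loss (the abortive signature). The generator draws abortive
failure times from an exponential hazard conditioned on the observable
window (final intensity ≥ 20% of I₀): later detachments are physically
indistinguishable from completed transits, so ground-truth labels remain
recoverable. Whether the failure hazard depends on force is left open by
the measurements; the parameter carries no claimed default.

`nucleation_rate_per_npf()` divides the observed productive event rate by
the labelled fraction and the NPF surface density — exactly homogeneous of
degree −1 in both.

## FRET occupancy stage

The quench model has two donor populations: unprotected WH2 domains
quenched at `k1`, protected ones lost only to bleaching at `k2`, giving
`I(t) = (1−p)·e^(−k1 t) + p·e^(−k2 t)`. `fit_quench()` clamps `k2` to its
independently measured value and fits `(i_fret, k1, i_bleach)` with
non-negative amplitudes via Levenberg–Marquardt from multiple `k1` starts.
Bleaching of the fast population during the fast phase is neglected
(k1 ≫ k2 assumed; the fit warns when the curve spans less than 3/k1). The
protected fraction is computed from *amplitudes*, not plateaus, so finite
acquisition windows do not bias it; estimates outside [0,1] are clipped
with a warning. A material fast amplitude whose rate fails to exceed the
fixed `k2` raises a phase-separation error, while a near-zero fast
amplitude (a fully protected curve) is legitimate. Bootstrap intervals
come from residual resampling (`protected_fraction_ci()`).

The printed unloaded occupancy ("~7%") and fold-change ("~3.7-fold to
27%") are rounded inconsistently (27/7 = 3.86); recovery tests therefore
use generator ground truth, with the unloaded value taken as the unrounded
0.27/3.7 where the fold-change itself is the target.

## What the generators emulate — and what they do not

`generator_config()` encodes smooth parametric force-response curves:
per-network flux declining linearly to 50% at 1200 Pa; TIRF component
densities rising (saturating exponent 0.7, ~2× at the stall scale);
velocity defined as flux/density so the pipeline's linearity is exact by
construction; relative barbed-end density rising linearly to 3.3× at
1020 Pa; local polymer concentration rising from 150 µM toward ~1250 µM
with a concave shape (exponent 0.6) — densification steep at low load,
then saturating — which makes the effective contact angle drop early and
stay low, the regime in which the tether force is identifiable. The
absolute unloaded end density (230 µm⁻²) sets sinθ ≈ 0.94 at zero load.
These shapes are stand-ins with the right qualitative structure, not fits
to any measured curve, and all recovery tests compare against generator
ground truth or worked-example numbers only.

Consequently, passing tests establish that each analysis stage inverts
data with the statistical structure it assumes — exponential decays,
Gaussian/log-normal noise, piecewise-steady clamp protocols. They do not
establish robustness to drift, non-exponential bleaching, correlated
noise, segmentation artefacts or any other failure mode of real
microscopy data. The ratio-dataset generator mirrors the measurement
protocol's replicate structure (4 independent replicates per load, means
with SEM).

## Problem sizes and determinism

The test suite runs at desk scale: simulator checks use 0.1–1 µm² patches
for 20–300 s (10⁴–10⁶ events; the C++ core executes ~10⁷ events/s), the
mean-field comparison spans a 12-point parameter grid, classification
tests use up to 1000 tracks, and the acceptance script's single-molecule
stream covers a 50 µm² pattern for 600 s at the 1:5000 labelling ratio
(~400 events). Every stochastic path flows through R's RNG, so a single
seed reproduces any run bit-for-bit; generator outputs record their seed.

## Known limitations

* No spatial or elastic network representation: no filament orientation
  distribution, excluded volume, buckling, severing or pointed-end
  dynamics (profilin blocks pointed ends in this system).
* One effective contact angle; the `C_A(E)` power law stands in for
  unmodelled densification geometry.
* The WH2-occupancy feedback form (saturating in `E`) and the additive
  tether are modelling decisions constrained only by endpoint
  measurements.
* Classification thresholds are sensible defaults, not trained values;
  with heavy blinking plus noise, borderline tracks fall into
  `unclassified` rather than being forced into a class.
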