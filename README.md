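# actinload

Quantitative analysis and modelling of **load adaptation in branched
(dendritic) actin networks**. Branched networks nucleated by surface-bound
WASP-family proteins (NPFs) push against membranes and probes; when a
growing network is compressed under an AFM force clamp it does not simply
stall — it adapts, growing denser and slower while keeping its average
filament length constant. This package implements the analysis chain that
dissects that adaptation:

* **Flux balance.** At steady state the network-wide rates of filament
  nucleation and capping must balance,
  `R_cap = k_cap [CP] E = R_nucleate`, so the density of free barbed ends
  is `E = R_nucleate / (k_cap [CP])`. Rising `E` under load must come from
  slower per-filament capping, faster nucleation, or both.
* **Brownian-Ratchet force laws.** A protein that binds a filament end
  pressed against a surface must wait for a thermal gap of size δ, so its
  rate carries the factor `exp(−f δ sinθ / k_B T)`, with `f` the force per
  filament (external stress shared equally over free ends, plus a small
  internal tethering force from NPF–barbed-end links) and θ the filament
  contact angle, estimated as `sinθ = E / (C_A · 602.2 · 0.0027 µm)` from
  the end density and polymeric actin concentration `C_A` (µM). Actin
  monomers and wildtype capping protein both need δ ≈ 2.7 nm; an engineered
  bulky capping protein needs a larger gap, so its capping rate falls
  faster with load. Fitting the predicted wildtype/bulky incorporation
  ratio to data with every other parameter fixed yields the single free
  parameter, the tethering force.
* **A stochastic simulator** (exact SSA, Rcpp core) of network growth under
  a force clamp: nucleation suppressed by WH2-domain occupancy ("barbed-end
  interference"), ratchet-modulated elongation and capping, equal load
  sharing — reproducing the flux-balance algebra at stationarity.
* **Single-molecule analysis** of Arp2/3 incorporation tracks: exponential
  transit-time fits, productive/abortive/unproductive classification by
  deterministic feature rules, per-NPF nucleation rates, dwell-time excess.
* **FRET occupancy estimation**: two-exponential donor-quench fits with a
  fixed bleaching rate; the protected (barbed-end-bound) WH2 fraction from
  relative fast-phase amplitudes.
* **Synthetic data generators** for every input (force-clamp traces, TIRF
  densities, molecule tracks, quench curves, ratio datasets), seeded and
  exactly invertible at zero noise, so the whole chain is testable without
  any external data.

Everything takes and returns tibbles, composes with the pipe, and fitted
objects support `tidy()`, `glance()` and `autoplot()`.

## Worked example

Generate a synthetic force-clamp experiment (setpoints 25 → 600 → 1200 Pa),
detect steady-growth segments, and compute normalised per-network
incorporation rates:

```r
library(actinload)
library(dplyr)

cfg <- generator_config(
  seed = 42,
  stress_steps = tibble::tibble(
    stress_pa = c(25, 600, 1200), hold_s = c(400, 400, 400)
  )
)
trace    <- gen_afm_trace(cfg)
segments <- find_steady_segments(trace, min_duration = 60)
segments
#> # A tibble: 3 × 6
#>   t_start t_end stress velocity r_squared n_points
#>     <dbl> <dbl>  <dbl>    <dbl>     <dbl>    <int>
#> 1       0   399   24.9     6.77     1.000      400
#> 2     400   799  600.      3.44     0.999      400
#> 3     800  1199 1200.      1.85     1.000      400

intensity <- gen_intensity_traces(cfg) |> filter(network == "loaded")
segment_densities(intensity, segments) |>
  per_network_rate(reference_stress = 25)
#> # A tibble: 9 × 3
#>   stress channel per_network_rate
#>    <dbl> <chr>              <dbl>
#> 1   24.9 Arp2/3             1
#> 2   24.9 CP                 1
#> 3   24.9 actin              1
#> 4  600.  Arp2/3             0.756
#> 5  600.  CP                 0.753
#> 6  600.  actin              0.755
#> 7 1200.  Arp2/3             0.507
#> 8 1200.  CP                 0.506
#> 9 1200.  actin              0.506
```

Growth velocity falls from 6.8 to 1.9 µm/min across the stress ladder while
component densities rise, and the per-network fluxes (density × velocity,
normalised to the 25 Pa reference) decline to ~50% near 1200 Pa for every
channel — nucleation, elongation and capping all slow together at the
network level.

Fit the tethering force from a synthetic wildtype/bulky capping-protein
ratio dataset (ground truth 0.3 pN, 5% replicate noise):

```r
states <- network_states(cfg, c(0, 150, 350, 510, 765, 1020, 1150, 1300))
params <- ratchet_params(f_tether = 0.3, reference_stress = 0)
ratios <- gen_ratio_dataset(states, params, noise_sd = 0.05, seed = 42)
fit    <- fit_tether_force(ratios, states, params)
fit
#> <tether_fit>
#>   f_tether = 0.288 pN  [95% CI 0.199, 0.377]  (n = 8 loads)
autoplot(fit)
```

The one free parameter of the ratchet model is recovered within its
bootstrap interval; `tidy(fit)` returns the estimate and interval as a
tibble.

A thin command-line wrapper over the same functions lives at
`inst/cli/actinload.R` (subcommands `gen-data`, `simulate`, `analyze-flux`,
`analyze-sm`, `analyze-fret`, `fit-tether`).

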