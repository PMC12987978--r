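# rodphase

Grand-canonical Monte Carlo simulation of hard-rod assembly on surfaces
with three-fold binding symmetry, plus the liquid-crystal order-parameter
analysis needed to tell nematic from smectic arrangements — both for
simulated configurations and for frame-indexed rod detections such as the
output of particle-tracking pipelines on high-speed AFM movies.

## The problem

Designed protein nanorods adsorb onto the potassium sublattice of mica
(001) along three symmetry-equivalent directions (0°, 60°, 120°). Whether
the adsorbed film ends up three-fold disordered, nematic (co-aligned), or
smectic (co-aligned *and* organized into periodic rows) depends on the
chemical potential driving deposition, the rods' surface mobility, and any
energetic bias that breaks the three-fold degeneracy — as the striped
second hydration layer of muscovite does. `rodphase` is for researchers
who want to explore that phase behavior with a minimal model and to
quantify order in either simulated or experimentally tracked rod
configurations.

## Model and statistics

Rods are hard `ℓ × 1` rectangles (no interaction except excluded volume)
in a periodic square box, orientation index `k ∈ {0,1,2}` with adsorption
energy `E_k = bias_k × (−2 kT)`. Each Monte Carlo step attempts one
bounded translation per rod (components uniform in `[−mobility·L,
mobility·L]`, accepted iff collision-free) followed by a fixed number of
grand-canonical exchanges: depositions accepted when
`RAND[0,1) ≤ A·e^{β(μ−E)}/(n+1)` (after a hard-core check) and
evaporations when `RAND[0,1) ≤ n/(A·e^{β(μ−E)})`.

Order parameters:

- **nematic** — maximum eigenvalue of the traceless orientation tensor
  `N = (1/n) Σ_i [[2cos²θ_i − 1, 2sinθ_icosθ_i], [2sinθ_icosθ_i,
  2sin²θ_i − 1]]`; 0 isotropic, 1 aligned.
- **smectic** — rod centers are rasterized onto a 500×500 image (5×5 pixel
  blocks, periodic wrap), the magnitude FFT is normalized to a maximum of
  one, and the row-spacing Bragg peak is located by a peak search in three
  10-pixel strips through the spectrum center at 0°, 60° and 120° (or, for
  frame series, as the maximum in a fixed 20×20 window around a known peak
  position). The reported value is the ratio of that peak to the central
  (rod-count) peak.

See the vignette (`vignettes/hard-rod-assembly.Rmd`) for assumptions,
parameter semantics, numerical conventions, and what the synthetic
fixtures do and do not emulate.

## Worked example

Reference configurations with known order, then a pair of desk-scale
simulations showing the effect of a two-fold orientational bias:

```r
library(rodphase)
set.seed(1)
configs <- list(
  smectic = perfect_smectic(10, 12, 10, 100/12),  # 10 rows of 12 co-aligned rods
  nematic = nematic_no_rows(150),                 # aligned, no row structure
  hdd     = hdd_config(300))                      # three-fold disordered
for (nm in names(configs)) {
  st <- configs[[nm]]
  cat(nm, nrow(st$rods), "rods: nematic",
      round(nematic_order(orientation_angle(st$rods[, 3])), 3), "smectic",
      round(smectic_order(st$rods[, 1], st$rods[, 2], 100), 3), "\n")
}
```

```
    kind n_rods nematic smectic
 smectic    120   1.000   0.984
 nematic    150   1.000   0.206
     hdd    300   0.046   0.142
```

The perfect lattice scores 0.984 — the exact analytic value for a
commensurate row comb rasterized with 5×5 blocks (the padding's form
factor caps the Bragg peak just below 1) — while disordered configurations
sit at the desk-scale noise floor near 0.2.

```r
run <- function(bias) {
  p <- sim_params(mu = 3, mobility = 1, bias = bias, aspect_ratio = 7,
                  box_side = 50, n_steps = 2e4,
                  exchange_attempts_per_step = 500, record_every = 2e3,
                  snapshot_every = 1e9, seed = 7)
  tail(run_simulation(p, keep_snapshots = FALSE)$records, 1)
}
run(c(1, 1, 1))   # three-fold symmetric
run(c(2, 1, 1))   # orientation 0 twice as favorable
```

```
unbiased (mu = 3):
  step n_rods frac0 frac1 frac2 nematic smectic
 20000    208 0.365 0.327 0.308   0.051    0.22

two-fold bias on orientation 0:
  step n_rods frac0 frac1 frac2 nematic smectic
 20000    220 0.577 0.200 0.223   0.366   0.281
```

Without bias the three orientations stay near 1/3 and the film is
disordered; the two-fold bias enriches the favored orientation (0.58 after
2×10⁴ steps, approaching ~0.88 by 10⁵ steps) and raises the nematic order.
At higher chemical potential the same enrichment requires far longer runs,
because orientations change only through the increasingly rare
evaporation/redeposition channel — see the vignette.

A thin CLI wraps the same functions (`exec/rodphase`): `simulate`,
`sweep`, `synth`, `analyze`, `render`, each writing a JSON metadata
sidecar with full parameters and seed.

```sh
Rscript exec/rodphase synth --kind smectic --seed 1 --out movie.csv
Rscript exec/rodphase analyze --in movie.csv --box 100 --out series.csv
```

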