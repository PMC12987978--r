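---
title: "Hard-rod assembly on three-fold surfaces: model, order parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hard-rod assembly on three-fold surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rodphase)
```

## The model

`rodphase` simulates the adsorption and in-plane ordering of rigid,
rod-shaped particles — e.g. designed protein nanorods binding to the
potassium sublattice of a mica (001) face — as hard rectangles on a
periodic square surface. The surface's hexagonal symmetry restricts rods to
three orientations, 0°, 60° and 120° (index $k \in \{0,1,2\}$); positions
are continuous ("free placement"). Rods interact only through hard-core
exclusion: configurations with overlapping open interiors are forbidden,
exact edge contact is allowed.

Sampling is grand-canonical Monte Carlo. One step consists of

1. **Translations** — each rod present at the start of the step receives
   one proposed displacement, with each component drawn uniformly from
   $[-m L, +m L]$, where $m \in [0,1]$ is the *mobility* and $L$ the box
   side. The move is accepted iff the displaced rod overlaps nothing;
   orientation never changes during translation.
2. **Exchanges** — a fixed number of deposition/evaporation attempts
   (2000 per step at production scale). Each attempt picks deposition or
   evaporation with probability 1/2. A deposition draws a uniform position
   and a uniform orientation, is rejected outright on overlap, and is
   otherwise accepted when
   $\mathrm{RAND}[0,1) \le A e^{\beta(\mu - E)}/(n+1)$, with $A = L^2$ the
   box area, $\mu$ the chemical potential, $E$ the rod's adsorption energy
   and $n$ the current rod count. An evaporation removes a uniformly chosen
   rod when $\mathrm{RAND}[0,1) \le n / (A e^{\beta(\mu - E)})$. The product
   of the two thresholds across $n \to n+1 \to n$ is identically 1
   (detailed balance of the symmetric proposal), which the suite checks.

Each orientation carries an energy $E_k = b_k \cdot E_0$ with baseline
$E_0 = -2\,k_BT$ and positive bias factors $b_k$. A bias of
$(2,1,1)$ makes horizontal rods twice as favorable ($-4\,k_BT$), the
two-fold perturbation that a muscovite-like hydration structure imposes on
an otherwise three-fold symmetric binding lattice. With $b = 1.5$ the
energy is $-3\,k_BT$. Rotations happen only indirectly: a rod may evaporate
and a differently oriented rod may be deposited in the freed space, so at
high coverage the bias acts through the slow evaporation channel.

Simulations start from an empty box. Production-scale settings are a
$100 \times 100$ box (lengths in rod widths), $10^7$ steps, 2000 exchange
attempts per step, records every $10^3$ steps and configuration snapshots
every $10^5$ steps; rod aspect ratios of interest are 3, 5, 7 and 10.

### Mobility semantics

The parameter governing translation is described in two ways in informal
accounts of such models: as a maximum move distance and as free relocation.
We reconcile them as a per-axis uniform displacement bounded by $mL$, so
$m = 1$ proposes anywhere in the box and $m = 0$ freezes all rods; an
alternative mode (`translation_mode = "relocation"`), where a rod relocates
uniformly with probability $m$, is provided behind a switch. The cap is
per-axis rather than Euclidean; at the two ends of the range ($m = 0$,
$m = 1$), where the phase behavior is read off, the two conventions
coincide.

## Order parameters

**Nematic.** For orientations $\theta_i$ the $2 \times 2$ tensor
$$N = \frac{1}{n}\sum_i
\begin{pmatrix} 2\cos^2\theta_i - 1 & 2\sin\theta_i\cos\theta_i\\
2\sin\theta_i\cos\theta_i & 2\sin^2\theta_i - 1\end{pmatrix}$$
is traceless by construction; its maximum eigenvalue is 0 for an isotropic
sample and 1 for perfect alignment, and is invariant under global rotations
and under $\theta \to \theta + 180^\circ$.

**Smectic.** Smectic order — co-aligned rods organized into periodic rows —
is read from the Fourier transform of a *center image*: each rod center
marks the pixel $\lfloor x \cdot \mathrm{grid}/L \rfloor$ of a
$500 \times 500$ image and is padded to a $5 \times 5$ block (wrapped
periodically). The magnitude spectrum is centered and normalized so its
maximum — the zero-frequency peak, whose pre-normalization magnitude is the
lit-pixel mass and hence proportional to the rod count — equals one. The
row spacing of a smectic arrangement produces a Bragg peak along the rod
axis; because rods only point along the three lattice directions, the
search is restricted to three 10-pixel-wide strips through the spectrum
center at 0°, 60° and 120°. Along each strip we form a profile of
per-position maxima across the strip width, exclude positions within 3
pixels of the center, and report the largest local maximum (a position not
below either neighbor and above at least one) over the three strips. Since
the spectrum is normalized, this *is* the ratio of the row-spacing peak to
the center peak. For frame series from experimental-style detections,
where the peak position is fixed but jitters by a few pixels, the
alternative `smectic_order_window()` reports the maximum intensity in a
$20 \times 20$ window around a fixed peak location, auto-detected on the
average spectrum or supplied manually.

### Numerical conventions worth knowing

- **Exact contact is not overlap.** The separating-axis test uses strict
  inequalities, so touching rectangles (a measure-zero event) are legal;
  acceptance behavior is insensitive to this convention.
- **Overlap cutoff and acceleration grid.** Two rectangles of length
  $\ell$ and width $w$ can overlap only if their centers are closer than
  $\sqrt{\ell^2 + w^2}$ (crossed orientations can touch near corners at
  distances slightly beyond $\ell$), so the engine's uniform bin grid uses
  cells of at least that diagonal, making the 3×3 neighborhood query exact;
  the suite checks it against an exhaustive scan. Boxes smaller than twice
  the cutoff fall back to testing all nine periodic images.
- **Binary rasterization.** Pixels are 0/1; for hard-core configurations at
  the default resolution blocks of distinct rods rarely collide, so binary
  and additive accumulation agree up to a small mass deficit from crossed
  near-contact pairs.
- **The Bragg value of a perfect lattice is the block form factor, not 1.**
  A commensurate lattice with rows every $P$ pixels has its first-order
  peak multiplied by the $5$-pixel block's Dirichlet factor
  $\sin(5\pi/P)/(5\sin(\pi/P))$; at the reference geometry (rows every 50
  px) this is $0.98428$, and the implementation reproduces it to machine
  precision. Only unpadded single-pixel centers would score exactly 1.
- **Degenerate inputs.** Fewer than two rods give smectic order 0 by
  convention; an empty sample has no nematic order (error from
  `nematic_order()`, missing value in frame series); a flat spectrum has no
  non-DC local maximum and scores 0.
- **Angle snapping.** For orientation fractions of noisy detections, angles
  snap to the nearest lattice direction modulo 180°, ties toward the lower
  index; the nematic order always uses the raw angles.
- **Determinism.** The engine uses its own 64-bit generator seeded from
  `sim_params(seed=)`; identical parameters and seed give byte-identical
  trajectories. R-level generators (fixtures, reference moves) use R's RNG
  under `set.seed()`. Sweeps derive an independent stream per cell, so
  results do not depend on execution order.

## Synthetic detections

The `fixtures` generators produce configurations of known order so the
analysis path is testable without microscopy data: `perfect_smectic()`
(rows of co-aligned rods on a rectangular lattice), `nematic_no_rows()`
(random sequential adsorption of co-aligned rods — aligned but without row
structure), `hdd_config()` (random sequential adsorption with uniform
orientations, the high-density disordered reference), and
`random_centers()` (a uniform point process, the noise-floor control).
`detection_noise()` turns a configuration into one detection frame the way
a rod-recognition pipeline on AFM movies would report it: Gaussian center
jitter, Gaussian angle jitter, per-rod dropout, shuffled order.
`filling_series()` emulates an assembling surface with nested random
subsets of a target configuration growing along a sigmoidal fill curve.

Two caveats on what these fixtures do *not* emulate: there is no tip
convolution, scan-line noise, or systematic segmentation bias, so passing
tests demonstrate correctness of the order-parameter pipeline, not
robustness to real AFM artifacts; and the noise model (isotropic Gaussian +
independent dropout) is deliberate scaffolding, not a claim about the error
structure of any instrument.

A useful measured fact about the statistic itself: at desk scale the
smectic noise floor is not zero. Uniform-random 150-point configurations
score about 0.19 in median, and the *aligned hard-core liquid*
(`nematic_no_rows(150)`) scores 0.20–0.27 across seeds, because lateral
exclusion creates genuine structure-factor features along the rod axis.
The floor decays roughly as $1/\sqrt{n}$, which is why production-scale
configurations (800+ rods) read "near zero" while 150–250-rod desk-scale
configurations hover near 0.2. The fixture-classification rule used in the
tests therefore places the smectic cut at 0.5 — between the lattice Bragg
value (0.98) and every disordered floor we measure — rather than at the
noise floor itself.

## Desk-scale profile and what it can show

Tests and examples run a scaled profile: box 50, aspect ratio 7, $10^5$
steps, 500 exchange attempts per step (about half a minute per run on one
CPU), versus the production profile above. The scaling preserves the
deposition-dominated phenomenology — filling to a dense disordered state,
kinetic trapping at zero mobility, orientation fractions near 1/3 without
bias — but it shortens the *exchange turnover* drastically. At $\mu = 8$
the evaporation acceptance is $\sim n/(A e^{10})$, giving each rod only
$\approx 0.45$ expected evaporation events over the whole desk-scale run
(versus $\approx 45$ at production scale). Since orientations change only
via evaporation/redeposition, bias-driven orientation enrichment and the
smectic ordering that follows it cannot equilibrate at $\mu = 8$ within
this budget, no matter how correct the engine is. The same engine at
$\mu = 3$, where turnover is $\sim e^5$ times faster, reaches a favored
fraction of about 0.88 and nematic order above 0.8 within the same number
of steps under a $(2,1,1)$ bias — this is the regime the bias-sensitivity
tests use. Reproducing the full high-$\mu$ smectic annealing requires the
production schedule.

## Known limitations

- Orientations are restricted to the three lattice directions inside the
  simulator; the analysis path accepts continuous angles but snaps them
  only for occupancy counting.
- No attractive or soft interactions, no cluster moves, no parallel
  tempering; equilibration at high coverage relies on single-particle
  moves and is correspondingly slow.
- The smectic statistic reports a single peak ratio; peak widths and
  lateral-spacing peaks are discarded.
- The local-maximum rule (plateau-excluding, 3-pixel DC exclusion) is one
  reasonable operationalization of "peak finding" on a discrete spectrum;
  other rules shift disordered scores by a few hundredths but leave the
  ordered/disordered separation intact.
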