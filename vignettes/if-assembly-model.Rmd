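---
title: "The bead-bond model of intermediate filament assembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The bead-bond model of intermediate filament assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ifsim)
```

## The assembly problem

Cytoplasmic intermediate filaments (IFs) such as vimentin, desmin and
keratin K8/K18 assemble in a distinctive two-phase process. Within seconds
of raising the ionic strength, tetramers associate laterally into
full-width "unit-length filaments" (ULFs) of about 60 nm. Elongation then
proceeds exclusively by *end-to-end annealing*: ULFs and short filaments
fuse longitudinally, the joining ends interdigitating by roughly 17 nm so
that each additional ULF adds a 42.7 nm axial repeat. Subunit dissociation
and filament breakage are negligible on the relevant time scales, so the
process is an irreversible binary coalescence driven by diffusion.

While filaments are much shorter than their persistence length
(`lp` ~ 1 micrometre for vimentin), treating them as rigid rods works well
and analytical rate models describe the first minutes of assembly. After
hours, however, filaments are several `lp` long and their flexibility
dominates the diffusion and the encounter geometry of the reacting ends.
`ifsim` implements a coarse-grained Monte Carlo (MC) model of this regime:
filaments are bead-bond chains moving in continuous space inside a fully
periodic box, and every quantity of interest — mean length in ULF units
`<l_n>`, length histograms, persistence-length calibration curves,
elongation constants — is computed from the simulated or traced length
distributions.

## The bead-bond filament model

A ULF is four consecutive spherical beads of diameter `d = 11` nm. A
filament of `i` ULFs is a chain of `4 i` beads with two hard geometric
constraints:

* each bond length must stay within `[0.8, 1.2] d` (a lattice-free analogue
  of bond-fluctuation models; the acceptance interval keeps the average
  bond near one bead diameter, `1.026 d`, so the contour length per ULF is
  stable), and
* the bending angle between consecutive bond vectors must not exceed a
  maximal bond angle `alpha`; torsion is completely free.

There are no energies: a trial configuration is accepted or rejected purely
by these geometric criteria. Excluded volume is deliberately absent. For
the stiffness and length regime simulated here (`lc` far below
`lp^3 / d^2`, about `8e6` nm for vimentin), self-avoidance does not alter
chain statistics appreciably, and ideal chains keep the model fast.

One MC *sweep* attempts a single trial move for every bead, in a fresh
random permutation each sweep. A trial move displaces one bead by a vector
of uniformly random direction and magnitude drawn uniformly from
`[0, 0.1 d]`. With the default geometry about 62 % of moves are accepted,
in line with the roughly two-thirds acceptance the scheme was designed
for. Matching the center-of-mass diffusion of chains against
Brownian-dynamics reference simulations puts one sweep at roughly 1 ns of
physical time (`sweep_time_s`, used only to convert sweep counts to
seconds; hydrodynamic interactions are neglected throughout).

### The stationary angle measure

With hard constraints and symmetric proposals, the chain samples the
uniform configurational measure: bond lengths get the radial density
`p(r) ~ r^2` on `[0.8, 1.2] d` (mean `1.0263 d`), and bond directions are
uniform *within the solid-angle cone* around the preceding bond, giving
`<cos theta> = (1 + cos alpha) / 2`. This purely geometric scheme is the
package default (`angle_measure = "solid_angle"`).

Because the phrase "fluctuate freely within an angle alpha" can also be
read as the bending angle itself being uniform on `[0, alpha]`, the engine
additionally implements that measure (`angle_measure = "uniform_theta"`)
through a Jacobian factor `sin(theta_old)/sin(theta_new)` in the move
acceptance — still geometry, no energy scale. It produces stiffer chains at
equal `alpha` (tangent-correlation `lp` of ~990 nm versus ~660 nm at 15
degrees), but its acceptance rate drops to ~0.51 and angles near zero
become sticky, slowing decorrelation badly. Since the documented acceptance
rate and mean bond length single out the hard-cutoff scheme, it is the
default, and all results below use it.

## Worm-like-chain calibration of the persistence length

The stiffness parameter `alpha` has no direct experimental counterpart; it
is calibrated against the persistence length through the closed-form
worm-like-chain (WLC) result implemented in `wlc_rg2()`:

$$\langle R_g^2 \rangle = \frac{l_c l_p}{3} - l_p^2 + \frac{2 l_p^3}{l_c}
  - \frac{2 l_p^4}{l_c^2}\left(1 - e^{-l_c/l_p}\right).$$

For `lc/lp < 0.01` the expression is evaluated by its series expansion
`(lc^2/12)(1 - x/5 + x^2/30 - x^3/210)`, `x = lc/lp`, because the closed
form loses about seven digits to cancellation there.

`calibrate_lp()` simulates isolated filaments of 2-64 ULFs (8-256 beads)
at a given `alpha`, estimates the time-averaged bead `Rg^2` per filament
length, and `fit_lp()` least-squares fits `lp` with per-point standard
errors as weights. Two estimator choices matter:

* **Replicates instead of one long trajectory.** Single-bead moves
  decorrelate global chain properties only diffusively; worse, adjacent
  bonds change in an anti-correlated way under a bead move, so the total
  contour length behaves like a conserved density that relaxes over
  ~`1e5` sweeps even for a 32-bead chain. Each calibration point is
  therefore averaged over hundreds of *independent replicate chains* drawn
  from the exact equilibrium measure (which factorizes over bonds and can
  be sampled directly; `init_shape = "equilibrium"` exposes the same
  sampler), each followed by a short MC stretch. Replicate means are
  independent, so the quoted standard errors are valid regardless of the
  autocorrelation inside one trajectory. The direct sampler doubles as an
  independent oracle in the test suite: MC time averages must agree with it
  within combined errors.
* **Continuum formula versus discrete beads.** The mean squared distance of
  `N` discrete beads from their centroid exceeds the continuum `Rg^2` of a
  rod of the same contour length by `(N+1)/(N-1)` — +28 % for a 2-ULF
  filament. Fitting the continuum WLC directly to the bead averages (the
  default, and the conventional way such calibration curves are compared)
  therefore lands above the tangent-correlation `lp`: about 870 nm at
  `alpha = 15` degrees and about 300 nm at 25 degrees, matching the nominal
  calibration values of 1000 nm (vimentin/desmin) and 333 nm (keratin)
  within 15 %. `fit_lp(..., discrete_correction = TRUE)` divides the factor
  out first and then recovers the tangent-correlation `lp` (~660 / ~235 nm)
  — the two protocols answer slightly different questions, and the package
  keeps both explicit rather than hiding the discrepancy.

```{r calibration, eval = FALSE}
curve <- calibrate_lp(15, n_replicates = 400, seed = 1)
fit_lp(curve)          # ~870 nm: continuum fit of the bead averages
fit_lp(curve, discrete_correction = TRUE)   # ~660 nm: tangent lp
```

## Assembly kinetics

`init_system()` scatters `n0` straight ULFs uniformly (positions and
orientations) in a cubic periodic box; `box_for_concentration()` sizes the
box so that `n0` ULFs match a protein mass concentration, using a ULF mass
of `2.85e-18` g (32 vimentin monomers of ~53.7 kDa — the constant makes
concentration, box volume and ULF count mutually consistent to within 3 %
across the reference run conditions exercised in the tests).
Coordinates are stored unwrapped — radii of gyration and contour lengths
must never see the box — and the minimum-image convention is applied only
when distances between filament ends are measured.

`run_assembly()` alternates sweeps with annealing passes:

1. collect the two terminal beads of every filament, wrap them into the
   box, and find all pairs of ends of distinct filaments closer than the
   reaction distance `1.2 d`. A periodic cell list with cell size at least
   `1.2 d` makes this `O(ends)`; it falls back to an all-pairs scan when
   the box holds fewer than three cells per axis, and the test suite checks
   the two routes against each other.
2. attempt the candidate merges in random order, each end reacting at most
   once per pass. A merge creates one new bond equal to the minimum-image
   gap vector; it is accepted only if that bond lies in `[0.8, 1.2] d` and
   both junction angles are within the reaction angle (equal to `alpha`,
   which preserves the mechanical continuity of the new filament). Bead
   positions are not adjusted — a rejected merge may succeed in a later
   pass once diffusion has improved the geometry. Ring closure
   (self-annealing) is forbidden. The absorbed filament is translated into
   the periodic image adjacent to its partner so the merged chain stays
   unwrapped.

Annealing passes run once per sweep by default (`react_every`); this is far
finer than the diffusional encounter time of ends, so making checks even
more frequent would not change the kinetics, only the cost.

ULF number is conserved, the filament count never increases, and
`<l_n> = n0 / n_filaments` grows monotonically; all three are asserted
along recorded trajectories in the tests, as is constraint validity of
every filament after sweeps and merges.

### Problem sizes and what the desk-scale runs show

The engine sustains about `2e7` bead-move attempts per second on one core,
so the package's routine experiments are run at reduced particle numbers
and elevated concentrations, exploiting two invariances that the model
itself establishes (and that the test suite re-verifies):

* **Concentration-time scaling.** The number of sweeps to reach a given
  `<l_n>` scales as `1/c`; `c * sweeps_10` is constant within ~15 % between
  17.8 g/l and 53.4 g/l at `n0 = 128` (the mean ULF spacing at 53.4 g/l,
  ~38 nm, is still well above the 13.2 nm reaction distance, so the
  annealing stays diffusion-limited). At 17.8 g/l the model needs
  ~`1.5e6` sweeps to reach `<l_n> = 5`, the same magnitude as full-scale
  runs of this model at thousands of ULFs.
* **Shape invariance.** At fixed `<l_n>`, normalized length distributions
  from different concentrations coincide (checked with a two-sample
  Kolmogorov-Smirnov distance across seeds).

Against this backdrop the package reproduces the central kinetic
observation: at equal concentration, raising the bond and reaction angles
from 15 to 25 degrees — i.e. dropping `lp` to roughly a third — reaches the
same mean length in about four times fewer sweeps (measured ratio ~4.0 at
`n0 = 256`, 53.4 g/l, four seeds per angle).

## Length-distribution analytics

Traced filament lengths (EM/AFM for short filaments, TIRFM for long ones)
are converted to ULF units by `i = (L - 60)/42.7 + 1` (`length_to_ulfs()`;
kept as real numbers internally, rounded only in reports). On top of a
`length_distribution` container the package provides number-weighted
histograms (`number_histogram()`; left-closed bins starting at 1 ULF),
mass-weighted histograms (`mass_weighted_histogram()`; each bin weighted by
its total polymer length, which shifts weight dramatically toward long
filaments whenever lengths are heterogeneous), binning in multiples of the
persistence length (`lp_normalized_fractions()`), and the
concentration-and-time-normalized elongation constant
`(<l_n> - 1)/(c t)` (`elongation_constant()`), which makes vimentin, desmin,
keratin and simulated kinetics directly comparable.

The mass-weighted histogram convention here is length-weighted; weighting
by integer ULF counts instead differs only by discretization (at most one
part in ~40 for the bins in question) and would not change any reported
fraction at the precision quoted here.

## Synthetic data

`make_traced_lengths()` generates tracing-like datasets from a
constant-kernel stochastic coalescence process — repeatedly merging
uniformly chosen cluster pairs from `n * target` monomers down to `n`
clusters — which mimics the statistics of end-to-end annealing well enough
to exercise every analysis path in milliseconds. It makes no claim about
experimental noise: tracing error, surface-deposition bias and imaging
artefacts are not modelled, so tests passing on these fixtures validate the
analytics, not the microscopy. `make_calibration_points()` produces exact
or noisy WLC curves for fitter validation (noise-free curves must be
recovered to machine precision), and `make_reactive_pair()` builds
two-ULF systems with prescribed gap and junction angle for annealing unit
tests.

## Numerical choices and limitations

* All randomness flows from R's RNG: `set.seed()` (or the `seed` arguments)
  makes every run bit-reproducible. Hot loops use an xoshiro256++ generator
  seeded from R's stream at each entry point.
* Angle checks compare squared dot products, avoiding square roots in the
  hot path; ties at the wrap boundary resolve to the positive half-open
  interval `(-edge/2, edge/2]`.
* Merge bookkeeping reverses bead order as needed so chains remain simple
  doubly-linked paths; stale candidate pairs (ends already consumed in the
  same pass) are skipped silently, matching the one-reaction-per-end rule.
* Not modelled: excluded volume, hydrodynamics, bending energetics,
  filament polarity, subunit exchange, breakage, lateral association
  (bundling) — the model is built for dilute in vitro elongation kinetics,
  and concentrations are best kept in the regime where the mean ULF spacing
  stays above the reaction distance.
* The nominal `lp` calibration values (1000/333 nm) are protocol-dependent:
  see the calibration
  section for how the fitted value depends on the discreteness convention.
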