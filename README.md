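# ifsim — Monte Carlo simulation of intermediate filament assembly

`ifsim` is an R package for simulating and analysing the *in vitro*
assembly kinetics of cytoplasmic intermediate filaments (IFs) such as
vimentin, desmin and keratin K8/K18. It is aimed at biophysicists and
quantitative cell biologists who work with filament length distributions
from EM/AFM/TIRFM tracing, or who want a fast, reproducible simulator of
diffusion-driven end-to-end annealing beyond the rigid-rod regime.

## The model

IF elongation proceeds by irreversible **end-to-end annealing**: ~60 nm
unit-length filaments (ULFs) fuse longitudinally, each added ULF
contributing a 42.7 nm axial repeat, so a traced length `L` (nm) converts
to ULF units as

```
i = (L − 60) / 42.7 + 1
```

Filaments are modelled as **bead-bond chains**: four beads of diameter
`d = 11` nm per ULF, bond lengths restricted to `[0.8, 1.2] d`, bending
angles capped at a maximal bond angle `α` (15° for vimentin/desmin, 25° for
keratin), torsion free, no energies — trial moves are accepted or rejected
by purely geometric criteria. Chains diffuse by single-bead displacements
(uniform direction, magnitude uniform on `[0, 0.1 d]`; one attempt per bead
per sweep, 1 sweep ≈ 1 ns) in a fully periodic cubic box, and two filament
ends closer than `1.2 d` anneal whenever the new bond and both junction
angles satisfy the same geometric constraints.

The stiffness is calibrated through the worm-like-chain (WLC) radius of
gyration

```
⟨Rg²⟩ = lc·lp/3 − lp² + 2lp³/lc − (2lp⁴/lc²)(1 − exp(−lc/lp))
```

by fitting simulated single-filament `Rg²(lc)` curves over `lp`
(`calibrate_lp()` + `fit_lp()`). Length-distribution analytics cover
number- and mass-weighted histograms, persistence-length-normalized
binning, concentration conversions, and the elongation constant
`(⟨l_n⟩ − 1)/(c·t)` that puts experiments and simulations on one scale.

## A worked example

Assemble 128 ULFs at an equivalent protein concentration of 17.8 g/l until
the mean filament length reaches 5 ULFs:

```r
library(ifsim)

p   <- if_params()                                  # vimentin geometry, α = 15°
sys <- init_system(128, box_for_concentration(128, 17.8, p), p, seed = 1)
sys
#> IF assembly system: 128 ULFs in 128 filaments (<l_n> = 1), 0 sweeps
#> Cubic periodic box: edge 273.7 nm (volume 0.02049 um^3)

run <- run_assembly(sys, target_mean_ulf = 5, max_sweeps = 1e7,
                    record_every = 2.5e5, seed = 2)
run
#> Assembly run: 1,536,026 sweeps, 128 -> 25 filaments (<l_n> 1 -> 5.12)

tail(run$trajectory, 4)
#>    sweep n_filaments  mean_ln acceptance
#>  1000000          42 3.047619  0.6575221
#>  1250000          34 3.764706  0.6517133
#>  1500000          27 4.740741  0.6408587
#>  1536026          25 5.120000  0.6348893
```

About 1.5 × 10⁶ sweeps (≈ 1.5 ms of real time at 1 ns/sweep) merge the 128
ULFs into 25 filaments; roughly 63 % of trial moves are accepted. The final
state converts directly into tracing-style statistics:

```r
d <- system_length_distribution(run$system)
summarize_lengths(d)
#> $n            25
#> $mean_length_um  0.235924
#> $mean_ulf        5.12
#> $sd_ulf          3.929801

head(mass_weighted_histogram(d, 5), 3)
#>  bin_lo_ulf bin_hi_ulf total_length_nm  fraction
#>           1          6          2112.9 0.3582340
#>           6         11          2068.0 0.3506214
#>          11         16          1717.2 0.2911446
```

so at ⟨l_n⟩ ≈ 5 about a third of the polymer mass already sits in filaments
longer than 10 ULFs. The same functions accept measured tracing tables
(`read_lengths()`), and `elongation_constant()` compares the simulated
speed with experimental assembly regimes.

A thin command-line wrapper over the same functions is installed at
`inst/cli/ifsim` (subcommands `simulate`, `calibrate-lp`, `analyze`,
`fixtures`), with YAML run configurations validated by `load_config()`.

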