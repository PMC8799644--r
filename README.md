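# restime

Trajectory-analysis toolkit for dissecting the molecular determinants of
protein–ligand **residence time** (τ = 1/k_off). Structurally similar kinase
inhibitors can share low-nanomolar IC₅₀ values yet differ by orders of
magnitude in how long they stay bound; the difference lives not in a single
interaction but in the behaviour of the whole complex over long timescales.
`restime` implements the analysis stages needed to quantify that behaviour
from molecular-dynamics output:

- **Interaction fingerprints** — frame-wise detection of hydrogen bonds
  (H···acceptor ≤ 2.5 Å, donor angle ≥ 120°, acceptor angle ≥ 90°), π–cation
  (≤ 4.5 Å), π–π stacking (face-to-face / edge-to-face), water bridges
  (relaxed criteria 2.8 Å / 110° / 90°) and salt bridges (≤ 4.0 Å), tabulated
  as occurrence frequencies with a strict >15 % display filter.
- **Ligand surface decomposition** — Shrake–Rupley solvent-accessible area
  (1.4 Å probe), a numerical solvent-excluded (molecular) surface, polar
  (N/O) shares, and the derived buried area (MolSA − SASA) and buried polar
  area (PSA − SAPSA), per 1-ns frame.
- **Solvent exposure** — per-residue sidechain water counts (≥ 1 water
  oxygen within 3 Å ⇒ exposed).
- **Markov state models** — backbone-torsion featurization, VAMP-2 scoring,
  TICA (lag 40 ns, 2 components), √n k-means microstates, reversible
  maximum-likelihood transition matrices, implied timescales
  t_i(τ) = −τ/ln λ_i(τ), Chapman–Kolmogorov validation, PCCA++
  coarse-graining into metastable states with equilibrium probabilities
  π_i, and deterministic representative-structure selection.
- **Resolvation scoring** — hydration-site clustering inside a 10 Å shell,
  overlap factors (site displaced when overlap > 0.5), ligand score
  −Σ ΔG over displaced sites, and the π_i-weighted average across
  metastable states: Σ π_i s_i / Σ π_i.
- **Metadynamics dissociation counting** — the ligand/binding-site
  centre-of-mass collective variable, the inclusive 15 Å dissociation rule,
  and per-state count tables.
- **Synthetic-data generators** — planted metastable kinetics, exact
  interaction geometries, water ensembles with planted hydration sites, and
  a toy 1-D well-tempered metadynamics integrator, each returning its ground
  truth so the full pipeline is testable end to end.

## Worked example

Recover a planted three-state partition from 100,000 frames of synthetic
feature trajectory, then combine per-state resolvation scores with the
equilibrium probabilities:

```r
library(restime)

g   <- gen_metastable_trajectory(n_frames = 100000,
                                 pi = c(0.43, 0.32, 0.25), seed = 1)
fit <- fit_msm(g$features, lag_ns = 40, n_states = 3, seed = 2022)
fit
#> MSM fit: lag 40 ns, 316 microstates, 3 metastable states
#>   equilibrium probabilities: 0.25, 0.435, 0.314

summary(fit$msm)
#> Markov state model (mle_reversible)
#>   microstates: 316  lag: 40 ns
#>   slowest implied timescales (ns): 46.6, 25.7, 15.7
```

The recovered equilibrium probabilities (0.435/0.314/0.25) match the planted
0.43/0.32/0.25 split within sampling error, and the slowest implied
timescale (46.6 ns) matches the generator's true relaxation time (46.5 ns).
Weighting per-state displaced-water scores (kcal/mol) by those
probabilities:

```r
ws <- weighted_state_score(c(-50, -45.2, -60), pi = c(0.08, 0.07, 0.85))
ws$plain_average     #> -51.73333
ws$weighted_average  #> -58.164
```

A dominant state (π = 0.85) with strongly favourable water displacement
pulls the weighted resolvation score well below the plain mean — the kind of
asymmetry that separates long- from short-residence-time inhibitors.

## Testing

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "restime",
                               load_package = "installed")'
```

## Command line

A thin CLI over the same functions is installed with the package:

```sh
Rscript $(Rscript -e 'cat(system.file("scripts/restime", package="restime"))') \
    metadyn --out traces --seed 7
```

See `vignettes/residence-time-analysis.Rmd` for the full account of the
models, parameters and numerical choices.
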