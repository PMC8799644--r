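---
title: "Analysing residence-time determinants from MD trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing residence-time determinants from MD trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(restime)
```

## The problem

The residence time of a protein–ligand complex, τ = 1/k_off, often
correlates better with cellular efficacy than equilibrium affinity does.
Two inhibitors of the same kinase can be near-identical in IC₅₀ yet differ
ten- to a hundred-fold in τ. Explaining such differences requires looking
past the static complex at (i) which interactions persist over microseconds,
(ii) how much ligand surface stays shielded from water, (iii) how stable the
protein's conformational ensemble is, and (iv) how costly it is for water to
refill the binding site when the ligand leaves (the resolvation barrier).
`restime` implements one tested, reusable pipeline for all four readouts
plus the metadynamics book-keeping used to sanity-check unbinding barriers.

This vignette records the models, their assumptions, the tunable parameters,
and the numerical decisions — including the places where the conventions in
the literature are ambiguous and we had to pick one.

## Interaction fingerprints

Each frame is scanned with purely geometric criteria (all cutoffs inclusive
at equality):

| interaction | criterion | default |
|---|---|---|
| hydrogen bond | H···A distance; D–H···A angle; H···A–X angle | 2.5 Å; ≥120°; ≥90° |
| π–cation | charged centre → ring centroid | ≤4.5 Å |
| π–π face-to-face | centroid distance; interplanar angle | ≤4.4 Å; ≤30° |
| π–π edge-to-face | centroid distance; interplanar angle | ≤5.5 Å; 60–120° |
| water bridge | relaxed H-bond both to ligand and protein | 2.8 Å; ≥110°; ≥90° |
| salt bridge | charged-group N/O heavy-atom pair | ≤4.0 Å |

Decisions worth recording:

- The hydrogen-bond distance is **hydrogen→acceptor**. A 2.5 Å heavy–heavy
  donor–acceptor distance is sterically impossible, so the published value
  only makes sense in the hydrogen-to-acceptor convention used by the
  standard simulation-interaction-diagram tools. The cutoff is configurable.
- π–π thresholds are not standardised anywhere; the defaults follow the
  common face-to-face/edge-to-face convention and are exposed in
  `interaction_criteria()`. The interplanar angle is folded into [0°, 90°].
- Salt bridges have no published cutoff in this context; 4.0 Å between
  charged heavy atoms is the field's usual choice, configurable.
- A pair "interacts in a frame" when ≥1 event of that kind exists — multiple
  simultaneous geometries (e.g. two waters bridging the same pair) collapse
  to one pair-frame. Water bridges are therefore counted **per pair**, not
  per water; the alternative would inflate frequencies where two waters
  alternate.
- Frequency tables filter at **strictly** greater than the threshold
  (default 0.15): a pair present in exactly 15 of 100 frames is dropped.
- Boundary comparisons carry a 1e-9 tolerance so geometries constructed
  exactly at a cutoff are classified as satisfying it despite floating-point
  rounding.

## Ligand surface decomposition

Per frame (1 ns stride) we report SASA, MolSA, their polar shares
(SAPSA, PSA) and the derived quantities buried = MolSA − SASA and
buried polar = PSA − SAPSA, all with a 1.4 Å probe.

- **SASA** is Shrake–Rupley on a deterministic golden-spiral point set
  (default 960 points/atom), evaluated in the context of protein + ligand;
  waters never occlude, because the solvent defines the probe. Van der
  Waals radii come from a fixed internal Bondi table so areas are
  reproducible bit-for-bit across machines (overridable per element).
- **MolSA** is the solvent-excluded (Connolly) surface of the *isolated*
  ligand conformer, computed numerically: convex contact patches
  (probe-placement-filtered sphere points, scaled from the expanded to the
  vdW sphere) plus toroidal reentrant strips integrated along the
  accessible part of each pairwise probe-centre circle, with spindle cusps
  clamped at the rotation axis. Concave triple-probe vertex patches are
  **omitted**; for drug-sized molecules they are a small correction, and
  the two-sphere fixtures used in testing agree with an independent
  meridian-profile oracle to better than 1 %. This is a known limitation
  for very concave ligands.
- Whether the original MolSA/PSA used the in-complex or isolated conformer
  is not documented; we use the isolated conformer, which makes
  buried = MolSA − SASA a property of burial rather than of conformational
  strain. Buried areas are reported exactly as computed and may be slightly
  negative for an essentially isolated molecule.
- Polar area is the share contributed by N, O and (by default) hydrogens
  bonded to them; a flag restricts it to heavy N/O only.

## Solvent exposure

A residue counts as exposed in a frame when ≥1 water molecule lies within
3 Å of its sidechain. Counting is per water molecule (not per atom contact),
measured from the water **oxygen** to sidechain **heavy atoms**; both
conventions are arguments because monitoring scripts differ on whether
hydrogens participate. Traces summarise to the exposed-frame fraction and
the median water count.

## Markov state models

The MSM stage follows the standard build: backbone φ/ψ torsions encoded as
(cos, sin) pairs → VAMP-2 to compare featurizations → TICA at lag 40 ns
with 2 retained components → k-means with k = round(√n) microstates →
reversible maximum-likelihood transition matrix at lag 40 ns → implied
timescales and Chapman–Kolmogorov validation → PCCA++ into 3 metastable
states with equilibrium probabilities π_i → 3 representative frames per
state.

Numerical decisions:

- Transition counting uses a **sliding window**, the standard
  recommendation; counts are restricted to the largest strongly connected
  microstate set before estimation.
- The reversible estimator is the classic fixed-point iteration on
  symmetric flows, run to 1e-12; detailed balance holds to 1e-8 by
  construction and is asserted in tests.
- TICA uses symmetrised covariances (reversible assumption) without
  kinetic-map scaling; rank-deficient covariances are ridge-regularised.
  VAMP-2 includes the constant singular function, so white noise scores ≈ 1
  and an exact two-state chain with eigenvalue λ₂ scores 1 + λ₂².
- k-means is seeded with k-means++ under a fixed seed (default 2022) and
  refined with Lloyd iterations; duplicate/empty clusters are pruned. The
  full stack is reproducible bit-for-bit for a fixed seed.
- √n rounding: published cluster counts in this setting differ by ±1 from
  any fixed rounding of √n, so k is `round(sqrt(n))` by default and
  overridable.
- PCCA++ memberships come from the inner-simplex vertex search on the top
  right eigenvectors, clipped to [0, 1] and row-renormalised; crisp states
  take the argmax and π_i sums the stationary mass of crisp members.
  Nearly degenerate eigenvalues trigger a warning rather than an error.
- The Chapman–Kolmogorov test works at the metastable-set level — estimate
  the coarse transition matrix at τ, predict kτ by matrix power, re-estimate
  at kτ — so factor 1 is exact by construction. Bands are bootstrap
  percentiles over trajectories (long single trajectories are first split
  into contiguous blocks).
- Point estimates of π_i come from the **MLE**; the Bayesian mode
  (multinomial count resampling and re-estimation, 100 samples) supplies
  error bars only. Which convention published π values used is generally
  unstated; MLE is the reproducible choice.
- Cross-structure Cα-distance measurements superpose on backbone atoms of
  residues common to both structures **excluding** the activation loop
  (residues 170–185) and glycine-rich loop (30–38), since loop displacement
  must be measured against the stable kinase core. Published analyses of
  this kind rarely state their reference frame; ours is configurable.

## Hydration sites and resolvation scoring

Water-oxygen observations within 10 Å of the ligand are clustered greedily:
take the observation with the most neighbours within 1 Å, found a site at
the members' centroid, remove them, repeat while any observation has at
least `min_occupancy` neighbours (default: twice the bulk expectation for
the clustering sphere, floor 5). Site free energies ΔG (kcal/mol, relative
to bulk) are primarily an input table, because proper hydration-site
thermodynamics requires inhomogeneous solvation theory; the built-in
inverse-Boltzmann estimator ΔG = −kT ln(ρ_site/ρ_bulk) with kT =
0.616 kcal/mol (310 K) is explicitly labelled an approximation.

The **overlap factor** of a site is the fraction of its member observations
lying within (vdW + 1.4 Å) of any ligand heavy atom — positions a water
centre could not occupy with the ligand present. No published definition
exists; this displaced-observation fraction is the natural choice and the
1.4 Å offset is configurable. A site is displaced when overlap is
**strictly** greater than 0.5. The ligand score is −Σ ΔG over displaced
sites — displacing unstable (positive-ΔG) water is favourable, giving the
negative scores conventionally printed — counting each displaced site in
full rather than weighting by partial overlap. Per-state scores (means over
each state's representative structures) combine as Σ π_i s_i / Σ π_i.

## Metadynamics dissociation analysis

The collective variable is the distance between mass-weighted centroids of
the ligand and of the binding-site residues Val38, Ala51, Leu75, Ile84,
Thr106, Met109. A replica counts as dissociated when its CV **reaches**
15 Å (inclusive — "reached" decides the boundary). Trace files are
two-column (time, distance) text with `#` comments and an optional header.
Count tables report per-start-state dissociated/bound counts with compound
totals; classification is monotone in the threshold by construction.

## What the generators emulate — and what they do not

- `gen_metastable_trajectory` plants a reversible Markov chain built from
  symmetric exchange flows (so the stationary law is exactly the requested
  π, default 0.43/0.32/0.25) with Gaussian emissions around well-separated
  centres. Defaults: exchange flows (0.006, 0.0025, 0.0015) per step giving
  a slowest relaxation of ≈47 frames, and emission σ = 0.85 on centres 4
  apart, i.e. ≈2 % basin misassignment. The flows are chosen so that at
  10⁵ frames the chain's own occupancy fluctuations stay well inside the
  ±0.03 recovery band — a slower chain would make the *planted* π
  unrecoverable by any estimator; the emission noise keeps state recovery
  nontrivial without letting discretisation error dominate the implied
  timescale. What it does not emulate: non-Markovian memory, overlapping
  anisotropic basins, and the featurization step itself (it emits features
  directly).
- `gen_interaction_fixture` builds minimal atom sets realizing one
  interaction geometry exactly and toggles it in a prescribed fraction of
  frames. It exercises the detectors' geometry and counting, not force-field
  realism.
- `gen_water_ensemble` scatters site observations with σ = 0.3 Å plus
  uniform bulk noise; real hydration sites are anisotropic and correlated
  between frames.
- `gen_metad_traces` runs overdamped Langevin dynamics (1 ps steps,
  0.3 Å diffusive steps) on a 1-D double well (bound minimum at 3 Å,
  dissociated at 15 Å, default barrier 6.5 kcal/mol, reflecting wall at
  35 Å) with well-tempered deposition: height h₀ e^(−V_bias/kTemp) with
  h₀ = 0.2 kcal/mol, width 0.03 Å, kTemp = 3.4, accumulated on a 0.01 Å
  grid. Its purpose is validating trace parsing, the inclusive 15 Å rule
  and the well-tempered update (heights at a revisited grid point never
  increase); it is not a physics engine. The barrier default makes
  unbiased escape rare and biased escape common within 8,000 steps, so the
  paired-seed comparison is informative at 20 replicas.

Passing tests on these generators therefore demonstrates correctness of the
analysis machinery under known ground truth — not agreement with any
particular experimental system, which would require the original
multi-microsecond trajectories.

## Problem sizes used by the test-suite

The standard validation runs use 10⁵ frames for MSM parameter recovery,
10⁶ Monte-Carlo samples for surface-area oracles, 200-frame water ensembles
with four planted sites, and 20 paired replicas of 8,000-step toy
metadynamics — sizes at which every recovery band in the suite is stable
across seeds while the whole suite stays desk-scale.

## Known limitations

- The molecular-surface algorithm omits concave triple-probe vertex patches
  (see above) and is quadratic in atom count — fine for ligands, slow for
  whole proteins.
- Ligand role annotation requires a sidecar file; there is no topology
  perception (bond orders, protonation), and mmCIF input is not supported.
- Periodic-boundary imaging is assumed already done.
- The Bayesian MSM mode resamples counts about the MLE rather than sampling
  the full reversible posterior; its spread is an error bar, not a
  posterior distribution.
- Water-bridge geometry considers only polar atoms within 4 Å of the water
  for speed; extremely distorted bridge geometries beyond that prefilter
  would be missed.
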