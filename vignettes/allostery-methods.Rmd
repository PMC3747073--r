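---
title: "Methods: coarse-grained allostery analysis with allosteer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coarse-grained allostery analysis with allosteer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allosteer)
```

This vignette documents the models behind the package, the parameters that
matter, the numerical conventions, and the choices made where the design was
genuinely open. It is the reference a maintainer should read before changing
a default.

## The coarse residue model

Every analysis operates on one node per residue, anchored at the Cα atom,
with side-chain heavy atoms retained for contact networks. PDB input is
reduced accordingly: HETATM records, waters, hydrogens and alternate
locations other than blank/`A` are discarded (a deterministic
single-conformer model); residues lacking a Cα are dropped with a warning;
insertion codes are part of the author-numbering key so the author-to-serial
map is bijective. Author-numbering gaps — unresolved loops in crystal
structures — are simply compressed into the consecutive 0-based serial
indexing used by all matrices, and reported as messages. No loop rebuilding
is attempted: structures are analysed as given, and gap compression means a
chain break can silently shorten the sequence-separation filters; that is a
known limitation to weigh when interpreting networks across unresolved
regions. Ligands and nucleotides are invisible to every network, which
under-connects binding-site residues relative to an all-molecule model.

## Elastic network model

Residue pairs within `cutoff_rc` of each other are joined by springs of
uniform force constant `spring_gamma`. Defaults:

| parameter | default | units | why |
|---|---|---|---|
| `cutoff_rc` | 7.0 | Å | the standard Cα Gaussian-network cutoff; first coordination shell |
| `spring_gamma`, `kBT` | 1 | arbitrary | only relative fluctuations matter anywhere downstream |
| `n_modes` presets | 1 / 3 / 10 / 20 | — | slowest-mode, few-mode and broad low-frequency views of collective motions |
| zero-mode tolerance | 1e-8 × λ_max | — | robust component counting without an absolute scale |

The distance criterion is *inclusive* (`≤ cutoff_rc`), fixed for
reproducibility and matching common implementations. The Kirchhoff matrix is
the graph Laplacian; its zero modes count connected components. Eigenvector
signs are made deterministic by forcing the largest-magnitude component of
each mode positive, so serialized matrices are byte-stable across platforms.

Mean-square fluctuations over a mode selection are
`msf_i = (3 kBT/γ) Σ_k λ_k⁻¹ u_k[i]²`; over all nonzero modes this equals the
diagonal of the Moore–Penrose pseudo-inverse (times `3 kBT/γ`), which the
test suite verifies against an SVD oracle on random connected networks.
Normalized profiles (NMSF) divide by the maximum by default, so profiles live
in [0, 1]; unit-sum normalization is available where relative weights across
residues are wanted. Both are exposed because no single convention is
canonical in the literature.

Stationary points of an NMSF profile are called with a depth filter
(`site_band`, default 0.1 of the profile range): a local minimum only counts
as a hinge candidate if it lies near the global floor of the profile, and
symmetrically for flexible-site maxima. Near-rigid regions always carry
shallow numerical ripples; without the filter every domain interior sprouts
spurious "hinges". The filter value is a presentation choice, not physics,
and is exposed as an argument.

Cross-correlation maps can be computed on truncated mode sets, where a
residue can have exactly zero self-variance (it does not move in those
modes). Its normalized correlations are then undefined; they are reported as
0 and flagged in a logical mask rather than silently dropped or NaN.

## Commute-time communication

The commute time between residues is the expected round-trip step count of a
random walk on the spring network, `C = 2|E| · r_ij`, with `r_ij` the
resistance distance from the pseudo-inverse of the Kirchhoff matrix. A
second normalization (`3 kBT/γ`, giving the mean-square inter-residue
distance fluctuation) is provided; the two give identical pair rankings, so
the choice only matters for the units in reports. Commute times are a metric
(they satisfy the triangle inequality) and shrink when springs are added —
both properties are under test.

Effective communicators are pairs at spatial separation
`min_separation_A ≥ 20 Å` whose commute time falls below a threshold. The
threshold defaults to the 5th percentile of commute times over all pairs
meeting the separation criterion (`cp_quantile = 0.05`), with an absolute
`cp_threshold` override. A quantile was chosen because a fixed number is not
transferable across systems of different size and connectivity, while "the
fastest few percent of long-range pairs" preserves the intended semantics.
Clusters are formed by single linkage over shared residues among qualifying
pairs — the simplest deterministic aggregation; it can chain distinct
functional sites together through a shared residue, which a reader of the
cluster report should keep in mind.

## Protein structure networks

Interaction strength between residues i and j is
`I_ij = 100 · n_ij / √(N_i N_j)` with `n_ij` the number of side-chain atom
pairs within `contact_distance_A = 4.5 Å`. The per-type normalization values
`N_i` shipped in `psn_normalization()` come from the classical PSN lineage;
they are a configurable asset, and a `"raw"` mode (`N = 100`, so `I = n_ij`)
exists for fixtures and for users who want unnormalized counts. Glycine,
having no side chain, contributes its Cα — the standard fallback that keeps
it visible to the network. Sequence neighbours (|Δresno| < 2 within a chain)
are excluded so covalently forced contacts do not dominate.

Edges require *strictly* `I > i_min` (default 3.0 %, in the empirically
useful 2–4 % range), and ensemble persistence requires *strictly* more than
`min_fraction = 0.75` of frames — both boundaries deliberately exclusive, and
both pinned by boundary tests (a clique intact in 8 of 10 frames is kept;
7 of 10 is dropped).

k-clique communities use k = 3 and overlap rule `k−2` by default (two
triangles sharing one node percolate); both are configurable, and `k−1` is
the stricter alternative. The implementation enumerates k-cliques via igraph
and percolates by connected components of the clique-overlap graph; a
brute-force enumeration oracle (all k-subsets, transitive closure) confirms
it on hundreds of random graphs. Candidate cliques for persistence filtering
are enumerated from the union network over frames, then scored per frame —
equivalent to enumerating per frame, but one enumeration instead of many.

## Local frustration

The frustration of a native contact is a Z-score of its native energy
against decoys: `F = (mean(decoys) − E_native) / sd(decoys)`, positive when
the native pair is more stabilizing than chance. Decoys randomize both the
residue identities (drawn from the structure's own composition) and the
contact distance (drawn from the 20-bin empirical histogram of native
contact distances, discretized to bin midpoints so small alphabets can be
enumerated exhaustively in tests). Classification: `F ≥ 0.78` minimally
frustrated (boundary inclusive), `F < −1` highly frustrated (boundary
exclusive), neutral between. The `≥ +0.78` reading — rather than
`|F| ≥ 0.78` — follows the established frustratometer convention and is
configurable through the `thresholds` argument.

Native contacts are Cα pairs within 8.0 Å at sequence separation ≥ 3,
matching common frustration practice; both values are arguments. The default
energy function is a hydrophobicity-derived quasi-chemical matrix,
`e(a,b) = −(h_a + h_b)/2` on the Kyte–Doolittle scale, modulated by a
distance well (full weight inside 6.5 Å, linear taper to zero at the 8 Å
cutoff). This potential was chosen because it is exactly reproducible from a
published 20-value scale, has a unique most-stabilizing pair (Ile–Ile) and a
unique most-destabilizing pair (Arg–Arg) — properties the synthetic designer
relies on — and because the frustration *procedure* (decoys, Z-score,
thresholds), not any particular force field, is the subject of this module.
Any symmetric 20×20 matrix can be plugged in via `contact_potential()`.
Consequently, absolute frustration categories from the default potential
should be read as hydrophobic-burial frustration, not as AWSEM-grade
energetics.

Frustration density attributes each contact to the residues whose Cα lies
within `radius_A = 5 Å` of the contact midpoint — the midpoint being the
package's definition of "where a contact is", chosen because it treats both
partners symmetrically.

All stochastic stages require an explicit seed and restore the caller's RNG
state; profiles are bit-reproducible.

## Synthetic data: what it emulates and what it does not

The generators produce the study conditions for every test:

* `make_chain()` — bead paths and rings with closed-form Laplacian spectra
  (`4 sin²(πk/N)` for rings), the ENM ground truth.
* `make_dumbbell()` — two mirror-symmetric compact domains (grid spacing
  4.5 Å) joined by an extended linker (3.8 Å steps): slowest-mode
  anticorrelation between domains, hinge minima in the linker.
* `make_persistence_ensemble()` — frames in which candidate side-chain
  contacts are realized independently per frame with probability `p_stable`
  inside a designed block (default 0.95) and `p_background` (default 0.3)
  elsewhere. Contacts are realized geometrically: each scheduled edge gets
  two pseudo-atoms per residue pointing at the partner with a ~3.2 Å
  atom–atom gap, so the same PSN code path users run is exercised. In dense
  blocks, atoms serving different edges can incidentally fall within the
  contact distance and inflate an off-edge's strength; fixtures for exact
  arithmetic therefore use wide-angle geometries where this cannot happen,
  and the planted-block recovery test asserts containment, not equality.
* `make_frustration_design()` — an ideal helix (radius 2.3 Å, rise 1.5 Å,
  100°/residue) whose native contacts are exactly the (i, i+3) and (i, i+4)
  pairs at 5.05 Å and 6.21 Å. Background residues cycle through four types
  of near-identical hydropathy, with the rare planted extremes providing the
  distribution's tails; this makes the decoy energy distribution leptokurtic,
  so a native pair drawn at random scores |F| < 1 about 90 % of the time at
  the default size (n = 80) and planted optimal/frustrated pairs separate by
  several standard deviations.

What passing these tests shows: the mathematics (spectra, pseudo-inverse
identities, commute metrics, percolation, threshold arithmetic, Z-scores) is
implemented correctly, and the pipeline's qualitative signatures (hinges,
anticorrelation, rigidification, contact enrichment) appear where they are
planted. What it does not show: realistic protein geometry, side-chain
packing, sequence statistics or force-field quality — real structures bring
all of those, and conclusions about a real complex should rest on the usual
domain judgement, not on the fixtures.

## Comparative pipeline

Differences are always complex − unbound, computed once on the shared
residue mapping (matched on chain, author number, insertion code and type),
so self-comparison returns exact zeros rather than floating-point dust.
Communicator pairs are re-expressed in mapping coordinates before the
gained/lost set difference. `run_config()` consumes a YAML file whose keys
are exactly the parameter names above (unknown keys are an error naming
them), writes every table as TSV plus a JSON summary, logs all parameters
and seeds, and is byte-deterministic given the same configuration.

## Problem sizes in the shipped checks

The test suite and the acceptance script run entirely on generated inputs:
random connected networks up to 50 residues (100 instances) for the
pseudo-inverse oracle, 200 random graphs up to 15 nodes for the percolation
oracle, 50,000-walk simulations on graphs up to 8 nodes for the commute
oracle, 100-frame ensembles for persistence, and 1000-decoy profiles on
80-residue helices for frustration. These sizes give the statistical checks
high power while keeping a full run in the tens of seconds; all scale
linearly upward if larger evidence is wanted.

## Known limitations

* Cα-only elastic networks have no directional (anisotropic) information;
  mode shapes are scalar participation, not 3-D displacement vectors.
* The crystal→serial renumbering compresses gaps; analyses spanning
  unresolved loops inherit that distortion.
* The commute-time threshold is a per-structure quantile, so communicator
  sets from different structures are comparable in spirit but not in
  absolute commute units unless an absolute `cp_threshold` is fixed.
* The shipped PSN normalization table and contact potential are defaults of
  convenience with documented provenance, not fitted to any particular
  system; both are pluggable.
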