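# allosteer

Coarse-grained analysis of allosteric regulation in proteins and their
complexes, at one node per residue. The package targets the standard question
of chaperone and signalling biology: when a partner protein binds — a
cochaperone docking onto a multi-domain chaperone dimer, for example — how do
the collective motions, the long-range communication routes, the structurally
stable residue blocks and the local energetic frustration of the receptor
change? It is written for structural bioinformaticians who want these four
views of allostery, plus their unbound-versus-complex differences, from plain
PDB input.

## What it computes

**Elastic network (Gaussian network model) dynamics.** Residues (Cα atoms)
within a cutoff `r_c` (default 7.0 Å) are joined by springs of uniform force
constant γ. The Kirchhoff (graph Laplacian) matrix Γ has `Γ_ij = −1` for
contacts and the coordination number on the diagonal. Its eigendecomposition
`Γ = U Λ Uᵀ` gives N−1 nonzero modes; per-residue mean-square fluctuations
and cross-correlations follow as

    ⟨ΔR_i · ΔR_j⟩ = (3 k_B T / γ) Σ_k λ_k⁻¹ [u_k]_i [u_k]_j

summed over selected low-frequency modes (presets: 1, 3, 10, 20 modes).
Normalized profiles (NMSF) locate flexible sites at local maxima and hinge
candidates at local minima.

**Commute-time communication propensities.** The commute time
`C(i,j) = 2|E| · (Γ⁺_ii + Γ⁺_jj − 2 Γ⁺_ij)` is the expected round-trip step
count of a random walk on the spring network — equivalently, up to scale, the
mean-square fluctuation of the inter-residue distance. Residue pairs that are
far apart in space (≥ 20 Å) yet have short commute times are *effective
communicators*; qualifying pairs are aggregated into clusters by single
linkage over shared residues.

**Protein structure networks (PSN).** Residues are connected when their
side-chain interaction strength `I_ij = 100 · n_ij / √(N_i N_j)` exceeds a
cutoff (default 3.0 %), where `n_ij` counts side-chain atom pairs within
4.5 Å and `N_i` is a per-residue-type normalization. On that graph the
package finds hubs (degree > 3), k-cliques, and k-clique percolation
communities; over a conformational ensemble only cliques intact in more than
75 % of frames are kept.

**Local frustration.** Every native contact (Cα distance ≤ 8 Å, sequence
separation ≥ 3) is scored by a Z-score of its native pair energy against
~1000 decoys with randomized residue identities and contact distances:
`F ≥ 0.78` minimally frustrated, `F < −1` highly frustrated, otherwise
neutral. Per-residue frustration densities count contacts of each category
within 5 Å.

A comparative pipeline (`compare_structures()`, `run_config()`) runs any
subset of these on an unbound structure and its complex and reports
differences with the fixed sign convention complex − unbound. Synthetic
generators (`make_chain()`, `make_dumbbell()`, `make_persistence_ensemble()`,
`make_frustration_design()`) produce structures with closed-form spectra and
planted ground truth, so every stage is testable without downloads.

## Worked example

A two-domain dumbbell with a flexible linker is the minimal allosteric
system: two rigid bodies whose anticorrelated motions pivot about the linker
hinge. Binding ten extra beads against one domain mimics a bound partner.

```r
library(allosteer)

db  <- make_dumbbell()                  # 2 x 12 beads + 4-bead linker
net <- build_network(db)                # 7.0 A cutoff
net
#> Elastic network: 28 residues, 71 springs, cutoff 7.0 A

prof <- nmsf_profile(decompose(net), n_modes = 3)
prof$hinge_candidates
#> [1] 14                                # mid-linker residue (0-based serial)

cp <- effective_pairs(commute_times(net), db, quantile = 0.05)
cp
#> Communicator report: 8 pair(s) in 4 cluster(s) (C <= 541.4, separation >= 20.0 A)
head(cp$pairs[, c("resno_i", "resno_j", "commute", "distance")], 3)
#>   resno_i resno_j commute distance
#> 1       7      15 436.183 20.36688
#> 2      14      22 436.183 20.36688
#> 3      13      27 526.573 20.20742

gt    <- attr(db, "ground_truth")
extra <- db$xyz[gt$domain2 + 1, ][1:10, ] + matrix(c(0, 0, 5.5), 10, 3, byrow = TRUE)
cplx  <- coarse_structure(rbind(db$xyz, extra),
                          chain = c(rep("A", 28), rep("B", 10)),
                          resno = c(db$residues$resno, 1:10),
                          label = "dumbbell-bound")
cmp <- compare_structures(db, cplx, analyses = "gnm", config = list(n_modes = 3))
cmp
#> Comparison report: dumbbell-bound vs dumbbell (28 shared residues; analyses: gnm)
#>   mobility delta (complex - unbound): mean -0.2928, range [-0.6898, 0.02223]
round(tapply(cmp$mobility_delta, rep(c("domain1", "linker", "domain2"), c(12, 4, 12)), mean), 3)
#> domain1 domain2  linker
#>   0.002  -0.615  -0.211
```

Reading: the linker residue 14 is the hinge; the fastest long-range
communicators are pairs bridging the two domains through the hinge
(commute time 436 steps at > 20 Å separation); and binding rigidifies the
bound domain (mobility delta −0.615) while barely touching the distal one
(+0.002) — the basic signature of one-sided allosteric stabilization.

Real structures enter through `read_structure("file.pdb")` (single- or
multi-MODEL); per-residue results can be written for molecular viewers with
`write_mobility_pdb()`.

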