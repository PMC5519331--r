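# chapdock

Characterizing transient, low-affinity protein–protein complexes — the
Hsp70/Hsp40 (DnaK/DnaJ) chaperone pair being the motivating case — by two
complementary computational routes:

1. **Coarse-grained rigid-body docking.** One bead per residue at the
   Cα position; interaction energy = statistical contact potential +
   Debye–Hückel electrostatics,
   `u(r) = u_c(r) + C q_i q_j exp(-r/λ_D)/(ε_r r)`. The two-body system
   is sampled by replica-exchange Monte Carlo in a periodic box;
   bound conformations (≥1 bead pair within 8 Å and total energy
   ≤ −2 k_BT) are extracted, and the dissociation constant follows from
   the bound fraction, `K_d = (1 − P_b)² / (P_b N_A V)`, averaged over
   increasing box volumes. The bound ensemble is analyzed in the
   receptor's inertia frame (spherical/Euler angles
   `Θ = asin(I₁ᴶ·I₂ᴷ)` …), as 2-D free-energy surfaces
   `F = −k_BT ln p̂`, per-residue contact probabilities, and binding
   modes from neighbor-count clustering with populations and
   `ΔF = −k_BT ln(p₂/p₁)`.

2. **Inter-protein coevolution by DCA over random paralog matchings.**
   A 21-state Potts model `P(x) ∝ exp(Σ J_ij(x_i,x_j) + Σ h_i(x_i))` is
   fitted to concatenated two-family alignments by asymmetric
   pseudo-likelihood (λ_h = λ_J = 0.01, 90% identity reweighting);
   couplings are scored by the Frobenius norm in the zero-sum gauge,
   corrected by a two-segment average-product correction, and
   renormalized to `S̃_ij = S_ij/|min S^Inter| · (1 + N/N_eff)`. Because
   interacting paralogs within an organism are unknown, paired
   alignments are built by matching sequences uniformly at random
   within each organism (single-copy organisms pair deterministically);
   contacts are ranked by their **selection frequency** — the fraction
   of matching realizations with `S̃ > 0.8` — and filtered by
   Shrake–Rupley solvent accessibility (buried = SASA < 1 Å²).

Trajectory stability metrics (inter-protein distance-matrix RMS and
principal-axis angular deviation) and fully seeded synthetic-data
generators with closed-form oracles (square-well binding toy, planted
Potts alignments, two-state trajectories) round out the package; every
analysis stage is testable offline at desk scale.

## Worked example

Dock an engineered toy complex whose ground-truth binding patch is known:

```r
library(chapdock)

tc  <- generate_toy_complex(seed = 3)          # bodies + truth record
ens <- remc_sample(energy_model(), tc$A, tc$B, box_edge = 70,
                   ladder = c(220, 260, 300), n_steps = 2e5,
                   record_stride = 40, seed = 5)
ens <- extract_bound(ens)
ens
#> complex_ensemble: 5000 poses x 3 replicas (220-300 K), box 70 A
#>   bound fraction (coldest->hottest): 0.375 0.216 0.117

cp <- contact_probability(ens)
head(cp$A[order(-cp$A$probability), ], 3)      # vs tc$truth$patch_A: 6 9 12
#>    residue_id probability
#> 6           6   0.6059238
#> 9           9   0.5320169
#> 12         12   0.4228491

cl <- cluster_bound(ens, cutoff = 12, temperature = 220)
cl                                             # coarse toy -> coarse cutoff
#> binding_mode_clusters: 1877 poses in 14 clusters; populations 0.490 0.213 ...
mode_free_energy_gap(cl, temperature = 220)
#> [1] 0.3643259
```

The three most contact-prone receptor residues are exactly the engineered
patch, and the two dominant binding modes are separated by ~0.36 kcal/mol.

Recover planted inter-protein couplings through the full
matching-ensemble DCA pipeline:

```r
gen   <- generate_paired_msa(seed = 11)        # 20+20 columns, 300 organisms
preds <- selection_frequencies(gen$family_A, gen$family_B,
                               n_realizations = 5, seed = 1)
head(as.data.frame(preds), 5)
#>   column_A column_B residue_A residue_B frequency
#> 1        3        5         3         5       1.0
#> 2       10       12        10        12       1.0
#> 3       17       19        17        19       1.0
#> 4       15       20        15        20       0.6
#> 5        2        3         2         3       0.4
gen$truth$planted_pairs                        # (3,5) (10,12) (17,19)
```

The three planted pairs are selected in every realization; matching-noise
pairs appear sporadically and fall away as `n_realizations` grows.
`sasa_filter()` then annotates predictions with per-residue SASA from a
full-atom structure and applies the burial rule, and
`write_contact_table()` emits the ranked TSV.

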