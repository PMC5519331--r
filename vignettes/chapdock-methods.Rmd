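---
title: "Methods: coarse-grained docking and paralog-matched coevolution for transient chaperone complexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coarse-grained docking and paralog-matched coevolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope

`chapdock` bundles two computational routes to characterizing a transient,
low-affinity protein-protein complex such as the Hsp70/Hsp40 (DnaK/DnaJ)
chaperone pair, where the encounter is too short-lived for conventional
structure determination:

1. **physics route** — residue-level rigid-body docking sampled by
   replica-exchange Monte Carlo (REMC), followed by thermodynamic
   (dissociation constant) and orientational (spherical/Euler angle,
   free-energy surface, binding-mode clustering) analysis of the bound
   ensemble;
2. **evolution route** — inter-protein direct coupling analysis (DCA) over
   an ensemble of stochastically paralog-matched paired alignments, with
   contacts ranked by how often they are selected across matchings and
   filtered by solvent exposure.

Both routes come with seeded synthetic-data generators and closed-form
oracles so that every stage is testable without external downloads.

## The coarse-grained energy model

Each protein is a rigid body with one bead per residue at the C$\alpha$
position. The interaction energy between beads $i$ and $j$ at distance $r$
is a statistical contact term plus screened Debye-Hückel electrostatics:

$$u_{ij}(r) = u^{c}_{ij}(r) + C\,\frac{q_i q_j\,e^{-r/\lambda_D}}{\epsilon_r\, r},
\qquad C = 332.0637\ \mathrm{kcal\,\mathring{A}/(mol\,e^2)}.$$

For attractive pairs ($\epsilon_{ij} < 0$) the contact term is a
Lennard-Jones-like well

$$u^{c}_{ij}(r) = |\epsilon_{ij}|\left[\left(\tfrac{\sigma_{ij}}{r}\right)^{12}
  - 2\left(\tfrac{\sigma_{ij}}{r}\right)^{6}\right],$$

with its minimum of exactly $-|\epsilon_{ij}|$ at $r = \sigma_{ij}$. For
repulsive pairs the same polynomial is used as a soft core up to
$\sigma_{ij}$ (shifted so the barrier height at $\sigma_{ij}$ is
$+\epsilon_{ij}$) and then mirrored into a positive decaying tail — the
standard construction for residue-level statistical potentials of this
family. Energies are plainly truncated (not shifted) at the cutoff.

Parameters that matter, with defaults:

* `epsilon_table` — pairwise well depths (kcal/mol). The shipped default
  derives from the Kyte-Doolittle hydropathy scale,
  $\epsilon_{ij} = -\lambda\,((h'_i + h'_j)/2 - e_0)$ with $h'$ rescaled to
  $[0,1]$, $\lambda = 1.2$ kcal/mol, $e_0 = 0.5$: hydrophobic pairs
  attract, polar pairs mildly repel. This is a self-contained,
  documented default suitable for method development and the synthetic
  systems in this package; a production docking study should load a
  calibrated statistical contact table through `param_file`.
* `sigma_table` — contact radii (Å) from mean residue volumes,
  $\sigma_i = 2(3V_i/4\pi)^{1/3}$, pair values averaged.
* charges — Lys/Arg $+1$, Asp/Glu $-1$, His $+0.5$, others 0. The
  histidine value reflects partial protonation near neutral pH and is a
  configurable choice.
* `dielectric` = 80, `debye_length` = 10 Å (roughly 100 mM monovalent
  salt), `cutoff` = 30 Å.

## REMC sampling

`remc_sample()` holds body A fixed and moves body B in a cubic periodic
box under the minimum-image convention. Defaults mirror a production
protocol for this kind of system: 20 replicas spanning 200–395 K
(geometric spacing — the ladder end points and count are the physically
motivated quantities, the spacing is our choice), $2\times10^6$ MC steps
per replica, samples recorded every 100 steps, neighbor-swap exchange
rounds every 100 steps with the standard criterion
$\min\{1, e^{(\beta_i-\beta_j)(E_i-E_j)}\}$.

The move set mixes, per step and replica: a box-wide reposition with a
fresh uniform orientation (probability 0.05) — a symmetric independence
proposal that lets the chain cross between bound and free states without
diffusing the whole box — and otherwise local translations (uniform in a
sphere) or small quaternion rotations in equal proportion. Local move
magnitudes adapt toward 30% acceptance during the first 10% of the run
only, so the recorded chain is (after that burn-in window) a
fixed-kernel Metropolis chain; the detailed-balance test in the suite
checks the resulting occupancies against exact Boltzmann weights on the
square-well toy at every ladder temperature.

**Bound state.** A pose is bound when at least one inter-body bead pair is
within 8 Å *and* the total interaction energy is at or below
$-2\,k_BT$ of its replica. Both thresholds are arguments of
`extract_bound()`. When analyzing a toy whose well is shallower than
$2\,k_BT$, the energy threshold must be placed between zero and the well
depth — the bound/unbound dichotomy of the toy is its well.

**Dissociation constant.** With one copy of each partner in volume $V$,

$$K_d = \frac{(1 - P_b)^2}{P_b\, N_A V},$$

reported as the mean over a series of increasing box volumes. The
uncertainty combines the standard error over boxes with the block-averaged
Monte Carlo error of each $P_b$ propagated through
$\partial K_d/\partial P_b$, in quadrature. Bound fractions are measured
at the ladder temperature closest to 300 K. A finite-size caveat follows
directly from the formula: per-box $K_d$ carries a relative bias of order
$V_b e^{\beta\epsilon}/V$, so volume-independence holds only in the
dilute regime; the test systems are sized accordingly (box edges of
7–11 well radii).

## Orientational analysis

`inertia_frame()` diagonalizes the (equal-mass) inertia tensor and orders
axes by decreasing moment, $I_1$ first. Eigenvectors have arbitrary sign,
so axes 1 and 2 are flipped to make their largest-magnitude component
positive and $I_3 = I_1 \times I_2$ completes a right-handed frame. This
makes frames — and therefore Euler angle values — reproducible; any other
sign convention would shift angle values, which is why the convention is
part of the documented interface. Near-degenerate tensors (two moments
equal within $10^{-6}$ relative) are rejected: the axes are not
identifiable.

The ligand position is summarized by the spherical coordinates of its
center of mass in the receptor frame — polar angle measured from $I_1$,
azimuth as atan2 of the $I_3$ over the $I_2$ component — and its
orientation by three Euler angles computed directly from inner products
of the two frames' axes:

$$\Theta = \mathrm{asin}(I_1^J\cdot I_2^K),\quad
\Omega = \mathrm{atan2}\!\left(\tfrac{I_2^J\cdot I_2^K}{\cos\Theta},
  -\tfrac{I_3^J\cdot I_2^K}{\cos\Theta}\right),\quad
\Psi = \mathrm{atan2}\!\left(\tfrac{I_1^J\cdot I_3^K}{\cos\Theta},
  \tfrac{I_1^J\cdot I_1^K}{\cos\Theta}\right).$$

At gimbal lock ($|I_1^J\cdot I_2^K| = 1$) only $\Omega + \Psi$ is
determined; the result is flagged and the joint angle reported rather
than silently splitting it.

Free-energy surfaces over angle pairs are $-\ln\hat p$ in $k_BT$ units
over 5° bins by default, min-shifted to zero; empty bins are reported as
missing data, never as $+\infty$.

**Binding modes.** Bound poses are clustered with the iterative
neighbor-count (leader) algorithm at a 5 Å cutoff: the pose with the most
neighbors becomes a center, its neighborhood is removed, repeat. The
metric is ligand-only C$\alpha$ RMSD in the shared receptor frame — the
receptor is rigid and identical in every pose, so superposition is a
no-op and ligand RMSD isolates binding-mode geometry. Cluster populations
are non-increasing by construction; the gap between the two largest
modes is $\Delta F = -k_BT\ln(p_2/p_1)$ in kcal/mol. Labeling the two
major modes (e.g. by where a functional loop points) is left to
inspection of the cluster centers; no automated classifier is attempted.

## Inter-protein coevolution

The sequence model is a 21-state Potts distribution over concatenated
pair alignments,

$$P(x) = \frac{1}{Z}\exp\Big(\sum_{ij} J_{ij}(x_i, x_j) + \sum_i h_i(x_i)\Big),$$

fitted by the asymmetric pseudo-likelihood method: each column's
conditional likelihood is maximized independently (L-BFGS, projected
gradient below $10^{-5}$) with $L_2$ penalties
$\lambda_h \|h\|^2 + \lambda_J \|J\|^2$, $\lambda_h = \lambda_J = 0.01$,
on the weight-normalized objective; couplings are then symmetrized,
$J_{ij} \leftarrow (J_{ij} + J_{ji}^{T})/2$. Sequences are down-weighted
at 90% identity (identity computed over all columns, gaps included — a
documented choice, configurable), giving the effective depth
$N_\mathrm{eff}$.

Scores follow the standard chain with two deliberate specifics:

* **Frobenius scores** are taken after shifting each $21\times21$ block
  to the zero-sum gauge, over the full block including the gap state.
* **Average product correction** is applied per segment pair: the A–B
  (inter-protein) block is corrected with its own row, column and grand
  means, and each intra-segment block likewise (self pairs excluded from
  intra means). This accounts for the two families' different mutation
  rates.
* **Renormalization**:
  $\tilde S_{ij} = S_{ij}/|\min S^{\mathrm{Inter}}| \times (1 + N/N_\mathrm{eff})$,
  with the minimum over interface scores only. The multiplicative form is
  implemented exactly as stated; because the depth factor could also be
  read as a divisor, `neff_mode = "divide"` provides that variant. The
  choice does not affect rankings, only the comparability of the 0.8
  selection threshold across alignments.

**Random paralog matching.** Interacting partners within an organism are
unknown when paralog counts vary, so paired alignments are built
stochastically: within each organism, sequences of the two families are
paired uniformly at random without replacement until the smaller family
is exhausted. Organisms with exactly one sequence per family are thereby
paired deterministically and identically in every realization; each
sequence appears at most once, which avoids diluting the signal with an
overwhelming majority of mismatched pairs. `selection_frequencies()`
repeats match → reweight → fit → score over many realizations (1000 by
default; a master seed spawns per-realization seeds) and reports, for
every inter-protein pair, the fraction of realizations in which
$\tilde S_{ij} > 0.8$. Pairs that persist across matchings reflect
couplings robust to matching noise.

**Exposure filter.** Predicted contacts are annotated with per-residue
solvent accessible surface area computed by a rolling-probe
(Shrake-Rupley) method on a full-atom structure (960 golden-spiral test
points per atom, 1.4 Å probe, element radii C 1.70/N 1.55/O 1.52/S
1.80/H 1.20 Å), normalized by per-residue reference maxima. Two burial
rules are supported, both walking the list in rank order with a 1 Å$^2$
threshold: *stop-at-first-buried* truncates the list at the first pair
containing a buried residue (the conservative main selection);
*discard-buried* drops only the offending pairs (the extended-list
variant). C$\alpha$-only structures are rejected — burial cannot be
judged from backbone traces.

A family-pair-level summary, the empirical inter-protein score, is the
mean of the four strongest inter-protein APC scores, averaged over
realizations.

## Trajectory metrics

For two-body trajectories (e.g. from external MD), `drms()` computes per
frame the RMS change over all inter-body C$\alpha$ pair distances
relative to the reference frame, and `angular_deviation()` the angle
between the mobile body's largest-moment inertia axis at time $t$ and at
the reference, after least-squares superposition of the reference body
each frame. Per-frame axes are sign-aligned with the previous frame
(positive dot product) to prevent spurious 180° jumps, which the raw
axis-angle formula cannot distinguish. Window averages default to the
trailing 10 ns when time metadata exist, else the last third of frames.

## Synthetic data: what it emulates, and what it does not

* `square_well_toy()` — two single-bead partners with a hard core and a
  flat well. Bound fraction and $K_d$ are closed-form
  ($P_b = V_b e^{\beta\epsilon}/(V_b e^{\beta\epsilon} + V_\mathrm{free})$),
  making it the exact reference for the sampler and the $K_d$ pipeline.
  Depth is specified in $k_BT$ at a reference temperature so oracle and
  sampler share one energy scale.
* `generate_toy_complex()` — small bead bodies with one engineered
  complementary patch (oppositely charged, mutually attractive residue
  types) so the docking pipeline produces a dominant, known binding
  mode with ground truth recorded.
* `generate_paired_msa()` — organisms with 1–3 paralog copies; each true
  pair Gibbs-sampled (1000 burn-in sweeps, thinning 10 — validated
  against exact enumeration of small models) from a Potts model with
  zero fields and ferromagnetic couplings $J_0\,\delta_{ab}$ planted on
  chosen inter-segment column pairs. Defaults: 20+20 columns, 300
  organisms, copy-count probabilities (0.5, 0.3, 0.2), $J_0 = 2$. At
  this scale the planted pairs score $\tilde S \approx 1.5$–2.3 against
  a matching-noise floor just under 1, i.e. $J_0 = 2$ sits comfortably
  above the detection threshold (around $J_0 \approx 1$ for this depth)
  while paralog mismatching still erases the signal in individual rows
  — exactly the regime the selection-frequency machinery is built for.
* `generate_two_state_trajectory()` — hops between two rigid poses with
  prescribed populations; the second pose is rotated about an axis
  perpendicular to $I_1$, so its exact angular deviation equals the
  rotation angle and its dRMS is computed directly from the constructed
  coordinates.

What the generators do *not* emulate: phylogenetic correlation between
sequences (rows are exchangeable given the organism), realistic
contact-map geometry (planted pairs are independent), alignment errors,
or flexible-backbone effects in docking. Green tests therefore certify
the statistical machinery and the samplers — not the adequacy of the
default contact parameterization for any particular real complex, for
which a calibrated table and full-atom follow-up remain necessary.

## Numerical choices and degenerate inputs

* L-BFGS per column, `pgtol = 1e-5`, iteration cap 1000; hitting the cap
  warns, other optimizer failures are errors.
* Clustering ties (equal neighbor counts) go to the earliest pose;
  deterministic given pose order.
* `estimate_kd()` refuses $P_b \in \{0, 1\}$ — affinity unresolvable at
  that box size — and warns when per-box values spread beyond 3 combined
  MC standard errors.
* Gimbal lock, degenerate inertia tensors, collinear point sets, gaps in
  requested residue ranges, unknown residue types, and buried-residue
  lookups for absent residues are all hard, named errors rather than
  silent repairs.
* Nonstandard alignment letters (B, Z, X, U, O, '.') map to gaps with a
  warning; alternate locations keep the highest-occupancy copy;
  insertion codes are rejected with a warning.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` run everything at desk scale,
chosen so the whole suite completes in minutes on one core while leaving
the oracles statistically decisive: square-well REMC at $6\times10^5$
steps per box over three boxes; 50 matching realizations on the default
synthetic families (~500 rows, 40 columns); 6000 matching seeds for the
fairness check; 1000 random orientations for the angle round-trip. The
full-scale protocol (20 replicas, $2\times10^6$ steps, five boxes, 1000
realizations on deposited alignments) is the same code with larger
arguments.

## Known limitations

* The rigid-body approximation ignores induced fit; binding modes whose
  stability depends on backbone rearrangement will be misranked.
* The shipped contact table is hydropathy-derived, not calibrated
  against binding affinities; absolute $K_d$ values from the defaults
  are order-of-magnitude tools only.
* Pseudo-likelihood fitting at full alignment width (hundreds of
  columns, tens of thousands of rows) is compute-heavy in a single
  process; the 1000-realization production ensemble is intended to be
  distributed across jobs (the per-realization seed interface exists for
  exactly that).
* The SASA filter needs a full-atom structure of each partner; which
  conformer to use (e.g. ADP- vs ATP-state) is a user decision that can
  change which contacts survive the burial rule.
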