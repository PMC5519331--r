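# Generators and analytic oracles: toy rigid-body systems with
# closed-form binding thermodynamics, planted-coupling paired MSAs, and
# constructed two-state trajectories.

#' Square-well binding toy
#'
#' Two single-bead partners interacting through a hard core and a flat
#' attractive well; its binding thermodynamics are known in closed form,
#' making it the exact reference for the REMC sampler and the Kd
#' pipeline.
#'
#' @param core_radius hard-core radius, A.
#' @param well_radius outer well radius, A.
#' @param well_depth_kt well depth in units of kB*T at
#'   `reference_temperature`.
#' @param box_edge cubic periodic box edge, A; must exceed twice the
#'   well radius.
#' @param reference_temperature K (default 300).
#' @return An object of class `square_well_toy`.
#' @export
square_well_toy <- function(core_radius, well_radius, well_depth_kt,
                            box_edge, reference_temperature = 300) {
  stopifnot(core_radius > 0, well_radius > core_radius,
            well_radius < box_edge / 2)
  structure(list(core_radius = core_radius, well_radius = well_radius,
                 well_depth_kt = well_depth_kt, box_edge = box_edge,
                 reference_temperature = reference_temperature),
            class = "square_well_toy")
}

#' Exact bound fraction and Kd of the square-well toy
#'
#' With bound volume \eqn{V_b = (4\pi/3)(r_{well}^3 - r_{core}^3)} and
#' free volume \eqn{V_{free} = L^3 - (4\pi/3) r_{well}^3},
#' \eqn{P_b = V_b e^{\beta\epsilon} / (V_b e^{\beta\epsilon} + V_{free})},
#' and Kd follows from the same one-pair-in-a-box conversion as
#' [estimate_kd()].
#'
#' @param toy a [square_well_toy()].
#' @param temperature K (default 300).
#' @return List with `p_bound` and `kd` (mol/L).
#' @export
analytic_kd <- function(toy, temperature = 300) {
  eps_kcal <- toy$well_depth_kt * .kB * toy$reference_temperature
  be <- eps_kcal / (.kB * temperature)
  vb <- 4 * pi / 3 * (toy$well_radius^3 - toy$core_radius^3)
  vfree <- toy$box_edge^3 - 4 * pi / 3 * toy$well_radius^3
  pb <- vb * exp(be) / (vb * exp(be) + vfree)
  kd <- (1 - pb)^2 / (pb * .NAvo * toy$box_edge^3 * 1e-27)
  list(p_bound = pb, kd = kd)
}

#' Energy model and bead bodies realizing a square-well toy
#'
#' @param toy a [square_well_toy()].
#' @return List with `model` (an [energy_model()]), and single-bead
#'   bodies `A`, `B`.
#' @export
toy_system <- function(toy) {
  model <- energy_model(type = "square_well", core_radius = toy$core_radius,
                        well_radius = toy$well_radius,
                        well_depth_kt = toy$well_depth_kt,
                        reference_temperature = toy$reference_temperature,
                        cutoff = toy$well_radius)
  A <- rigid_body_structure(1L, "G", matrix(rep(toy$box_edge / 2, 3), 1, 3),
                            0, "toy-A")
  B <- rigid_body_structure(1L, "G", matrix(0, 1, 3), 0, "toy-B")
  list(model = model, A = A, B = B)
}

#' Generate a toy two-body complex with an engineered binding patch
#'
#' Two compact bead bodies carrying complementary charged patches
#' (+1 per patch bead on A, -1 on B) so the docking pipeline produces a
#' dominant, known binding mode. The ground-truth patch residues are
#' returned.
#'
#' @param n_A,n_B bead counts (defaults 12 and 8; 5-50 supported).
#' @param patch_size beads per patch (default 3).
#' @param charged TRUE for the charged-patch system; FALSE gives the
#'   zero-interaction control (all charges 0, with a zero-type model the
#'   landscape is flat).
#' @param seed integer seed.
#' @return List with bodies `A`, `B` and `truth` (patch residue ids of
#'   each body).
#' @export
generate_toy_complex <- function(n_A = 12, n_B = 8, patch_size = 3,
                                 charged = TRUE, seed = 1) {
  set.seed(seed)
  make_body <- function(n, label) {
    # compact blob: points on a jittered cubic lattice
    g <- ceiling(n^(1 / 3))
    pts <- as.matrix(expand.grid(x = seq_len(g), y = seq_len(g),
                                 z = seq_len(g)))[seq_len(n), ] * 6
    pts <- pts + matrix(runif(3 * n, -0.8, 0.8), n, 3)
    types <- sample(c("G", "A", "S", "T", "N"), n, replace = TRUE)
    rigid_body_structure(seq_len(n), types, pts,
                         charges = rep(0, n), label = label)
  }
  A <- make_body(n_A, "toy-receptor")
  B <- make_body(n_B, "toy-ligand")
  # patch: the patch_size beads with the largest x (facing surfaces),
  # made sticky (aromatic type) and oppositely charged on the two bodies
  pA <- order(A$coords[, 1], decreasing = TRUE)[seq_len(patch_size)]
  pB <- order(B$coords[, 1])[seq_len(patch_size)]
  if (charged) {
    A$charges[pA] <- 1
    B$charges[pB] <- -1
    A$residue_types[pA] <- "F"
    B$residue_types[pB] <- "F"
  }
  list(A = A, B = B,
       truth = list(patch_A = A$residue_ids[pA], patch_B = B$residue_ids[pB],
                    charged = charged))
}

#' Generate paired family alignments from a planted Potts model
#'
#' Emulates the input of inter-protein coevolution analysis: organisms
#' carry 1..`max_paralogs` true interacting sequence pairs; each true
#' pair's concatenated sequence is Gibbs-sampled from a Potts model with
#' zero fields and ferromagnetic couplings \eqn{J_0 \delta_{ab}} planted
#' on the given inter-segment column pairs. The rows are split at the
#' boundary into two family alignments; the true pairing is recorded as
#' ground truth but not exposed through the family objects.
#'
#' @param n_A,n_B segment widths (default 20 each).
#' @param n_organisms number of organisms (default 300).
#' @param planted_pairs k x 2 matrix of (segment-A column, segment-B
#'   column) couplings.
#' @param J0 planted coupling strength (default 2).
#' @param paralog_probs probabilities of 1, 2, ... copies per organism
#'   (default `c(0.5, 0.3, 0.2)`, i.e. at most 3 paralogs).
#' @param alphabet_size states including the gap (default 21).
#' @param burnin,thin Gibbs sweeps to discard and between kept samples
#'   (defaults 1000 and 10).
#' @param seed integer seed.
#' @return List with `family_A`, `family_B` ([family_msa()] objects) and
#'   `truth` (`pairing` row map, `planted_pairs`, `J0`, `seed`).
#' @export
generate_paired_msa <- function(n_A = 20, n_B = 20, n_organisms = 300,
                                planted_pairs = cbind(c(3, 10, 17),
                                                      c(5, 12, 19)),
                                J0 = 2, paralog_probs = c(0.5, 0.3, 0.2),
                                alphabet_size = 21, burnin = 1000,
                                thin = 10, seed = 1) {
  set.seed(seed)
  planted_pairs <- matrix(as.integer(planted_pairs), ncol = 2)
  stopifnot(all(planted_pairs[, 1] >= 1), all(planted_pairs[, 1] <= n_A),
            all(planted_pairs[, 2] >= 1), all(planted_pairs[, 2] <= n_B),
            J0 >= 0)
  N <- n_A + n_B
  q <- alphabet_size
  copies <- sample(seq_along(paralog_probs), n_organisms, replace = TRUE,
                   prob = paralog_probs)
  M <- sum(copies)
  Jmat <- J0 * diag(q)
  X <- potts_gibbs_cpp(M, N, q, matrix(0, q, N),
                       pair_i = planted_pairs[, 1],
                       pair_j = planted_pairs[, 2] + n_A,
                       Jmats = rep(list(Jmat), nrow(planted_pairs)),
                       burnin = burnin, thin = thin)
  org <- rep(sprintf("org%04d", seq_len(n_organisms)), copies)
  labA <- sprintf("A%05d", seq_len(M))
  labB <- sprintf("B%05d", seq_len(M))
  famA <- family_msa(X[, seq_len(n_A), drop = FALSE], org, labA)
  famB <- family_msa(X[, n_A + seq_len(n_B), drop = FALSE], org, labB)
  list(family_A = famA, family_B = famB,
       truth = list(pairing = data.frame(row_A = seq_len(M),
                                         row_B = seq_len(M)),
                    planted_pairs = planted_pairs, J0 = J0, seed = seed))
}

#' Generate a two-state hopping trajectory
#'
#' A synthetic two-body trajectory in which the mobile body J hops
#' between two rigid poses with prescribed occupation probabilities: the
#' reference pose and a pose rotated by `rotation_deg` about an axis
#' perpendicular to J's largest-moment inertia axis (so the exact
#' principal-axis deviation of state 2 is `rotation_deg`) and translated
#' by `translation`. The reference body K stays fixed. Frame states are
#' drawn independently with the given populations; the first frame is
#' forced to state 1 so it can serve as the reference.
#'
#' @param n_frames number of frames (default 200).
#' @param populations probabilities of the two states (sums to 1).
#' @param rotation_deg state-2 rotation angle, degrees (default 60).
#' @param translation length-3 displacement of state 2, A.
#' @param noise isotropic Gaussian positional noise sd, A (default 0).
#' @param seed integer seed.
#' @return List with `traj` (a [two_body_trajectory()]) and `truth`
#'   (state sequence, exact state-2 dRMS and rotation angle).
#' @export
generate_two_state_trajectory <- function(n_frames = 200,
                                          populations = c(0.5, 0.5),
                                          rotation_deg = 60,
                                          translation = c(0, 0, 0),
                                          noise = 0, seed = 1) {
  stopifnot(abs(sum(populations) - 1) < 1e-9, length(populations) == 2)
  set.seed(seed)
  # asymmetric rigid bodies with well-separated inertia moments
  Jc <- matrix(c(0, 0, 0,  4, 0, 0,  8, 0, 0,  0, 2, 0,  4, 2, 0.5,
                 1, 0, 1.5), ncol = 3, byrow = TRUE)
  Kc <- matrix(c(20, 0, 0,  26, 0, 0,  32, 0, 0,  20, 3, 0,  26, 3, 1,
                 23, 1, 2.5), ncol = 3, byrow = TRUE)
  f0 <- inertia_frame(Jc)
  axis <- f0$axes[2, ]                     # perpendicular to I1
  ang <- rotation_deg * pi / 180
  K_ <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                 -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(ang) * K_ + (1 - cos(ang)) * (K_ %*% K_)
  J2 <- sweep(sweep(Jc, 2, f0$origin) %*% t(R), 2, f0$origin + translation, "+")
  states <- c(1L, sample(1:2, n_frames - 1, replace = TRUE,
                         prob = populations))
  cJ <- array(NA_real_, c(n_frames, nrow(Jc), 3))
  cK <- array(NA_real_, c(n_frames, nrow(Kc), 3))
  for (t in seq_len(n_frames)) {
    base <- if (states[t] == 1) Jc else J2
    cJ[t, , ] <- base + if (noise > 0)
      matrix(rnorm(length(base), 0, noise), nrow(base)) else 0
    cK[t, , ] <- Kc + if (noise > 0)
      matrix(rnorm(length(Kc), 0, noise), nrow(Kc)) else 0
  }
  traj <- two_body_trajectory(cJ, cK)
  D0 <- .cross_dist(Jc, Kc)
  D2 <- .cross_dist(J2, Kc)
  list(traj = traj,
       truth = list(states = states,
                    drms_state2 = sqrt(mean((D2 - D0)^2)),
                    theta_state2 = rotation_deg))
}
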