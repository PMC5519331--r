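# Orientational analysis of bound ensembles: inertia frames, angular
# coordinates, free-energy surfaces, contact probabilities, clustering.

#' Principal inertia frame of a point set
#'
#' Center of mass and the three orthonormal inertia axes, ordered by
#' decreasing moment of inertia (axis 1 has the largest moment). Masses
#' are equal by default (C-alpha bead model). Sign convention: axes 1 and
#' 2 are flipped so their largest-magnitude component is positive, axis 3
#' is their cross product, making the frame right-handed and reproducible
#' across runs. Euler-angle values downstream depend on this convention.
#'
#' @param coords n x 3 matrix, n >= 3 non-collinear points.
#' @param masses optional per-point masses.
#' @return An object of class `inertia_frame`: `origin` (COM) and `axes`
#'   (3 x 3, rows = axes I1, I2, I3).
#' @export
inertia_frame <- function(coords, masses = NULL) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 3) stop("need at least 3 points")
  if (is.null(masses)) masses <- rep(1, n)
  com <- colSums(coords * masses) / sum(masses)
  x <- sweep(coords, 2, com)
  r2 <- rowSums(x^2)
  I <- diag(sum(masses * r2), 3) - t(x * masses) %*% x
  e <- eigen(I, symmetric = TRUE)
  ord <- order(e$values, decreasing = TRUE)
  mom <- e$values[ord]
  scale <- max(abs(mom), .Machine$double.eps)
  if (any(abs(diff(mom)) / scale < 1e-6))
    stop(sprintf("degenerate inertia tensor: moments (%s) contain near-equal values",
                 paste(signif(mom, 6), collapse = ", ")))
  axes <- t(e$vectors[, ord])            # rows = axes
  for (k in 1:2) {
    j <- which.max(abs(axes[k, ]))
    if (axes[k, j] < 0) axes[k, ] <- -axes[k, ]
  }
  axes[3, ] <- c(axes[1, 2] * axes[2, 3] - axes[1, 3] * axes[2, 2],
                 axes[1, 3] * axes[2, 1] - axes[1, 1] * axes[2, 3],
                 axes[1, 1] * axes[2, 2] - axes[1, 2] * axes[2, 1])
  structure(list(origin = com, axes = axes, moments = mom),
            class = "inertia_frame")
}

#' Spherical coordinates of a point in an inertia frame
#'
#' Polar/azimuth pair of the displacement from the frame origin,
#' expressed in the frame's inertia basis. Convention: the polar angle
#' `phi_com` is measured from axis I1 (0 along I1, 90 degrees in the
#' I2-I3 plane); the azimuth `omega_com` is atan2 of the I3- over the
#' I2-component.
#'
#' @param com length-3 position (e.g. ligand center of mass).
#' @param frame an [inertia_frame()] (e.g. of the receptor).
#' @return Named numeric: `phi_com` in degrees within [0, 180],
#'   `omega_com` in degrees within (-180, 180].
#' @export
spherical_coords <- function(com, frame) {
  v <- as.numeric(com) - frame$origin
  if (sqrt(sum(v^2)) < 1e-12) stop("zero displacement from frame origin")
  u <- drop(frame$axes %*% v)
  u <- u / sqrt(sum(u^2))
  phi <- acos(max(-1, min(1, u[1]))) * 180 / pi
  omega <- atan2(u[3], u[2]) * 180 / pi
  c(phi_com = phi, omega_com = omega)
}

#' Euler angles between two inertia frames
#'
#' The relative orientation of a mobile frame (J) with respect to a
#' reference frame (K), computed directly from inner products of the
#' inertia axes:
#' \deqn{\Theta = \mathrm{asin}(I_1^J \cdot I_2^K)}
#' \deqn{\Omega = \mathrm{atan2}(I_2^J \cdot I_2^K / \cos\Theta,\;
#'       -I_3^J \cdot I_2^K / \cos\Theta)}
#' \deqn{\Psi = \mathrm{atan2}(I_1^J \cdot I_3^K / \cos\Theta,\;
#'       I_1^J \cdot I_1^K / \cos\Theta)}
#' At gimbal lock (|I1J . I2K| = 1) only the sum Omega + Psi is defined;
#' the result is flagged and the joint angle reported.
#'
#' @param jd_frame,nbd_frame [inertia_frame()] objects for the mobile and
#'   reference body.
#' @return Named numeric (`theta`, `omega`, `psi`) in degrees, theta in
#'   [-90, 90], omega and psi in (-180, 180]; attribute `gimbal` is TRUE
#'   with attribute `omega_plus_psi` set when locked.
#' @export
euler_angles <- function(jd_frame, nbd_frame) {
  J <- jd_frame$axes
  K <- nbd_frame$axes
  M <- J %*% t(K)                        # M[a, b] = I_a^J . I_b^K
  s <- max(-1, min(1, M[1, 2]))
  theta <- asin(s) * 180 / pi
  ct <- cos(asin(s))
  if (abs(s) > 1 - 1e-12) {
    # gimbal lock: only omega + psi is determined
    ops <- atan2(M[2, 3], M[2, 2]) * 180 / pi
    out <- c(theta = theta, omega = NA_real_, psi = NA_real_)
    attr(out, "gimbal") <- TRUE
    attr(out, "omega_plus_psi") <- ops
    return(out)
  }
  omega <- atan2(M[2, 2] / ct, -M[3, 2] / ct) * 180 / pi
  psi <- atan2(M[1, 3] / ct, M[1, 1] / ct) * 180 / pi
  out <- c(theta = theta, omega = omega, psi = psi)
  attr(out, "gimbal") <- FALSE
  out
}

#' Angular coordinates of every bound pose
#'
#' Convenience wrapper: for each bound pose, the ligand center-of-mass
#' spherical coordinates in the receptor inertia frame and the Euler
#' angles between the two inertia frames.
#'
#' @param ensemble a `complex_ensemble` with `bound_mask`.
#' @return data.frame with columns phi_com, omega_com, theta, omega, psi,
#'   replica, pose.
#' @export
bound_angles <- function(ensemble) {
  idx <- .bound_indices(ensemble)
  if (nrow(idx) == 0) stop("no bound poses in ensemble")
  kframe <- inertia_frame(ensemble$A$coords)
  lig <- .bound_ligand_coords(ensemble, idx)
  nB <- nrow(ensemble$B_local)
  out <- data.frame(phi_com = numeric(nrow(idx)), omega_com = NA_real_,
                    theta = NA_real_, omega = NA_real_, psi = NA_real_,
                    replica = idx[, 2], pose = idx[, 1])
  for (k in seq_len(nrow(idx))) {
    xyz <- matrix(lig[k, ], ncol = 3, byrow = TRUE)
    sph <- spherical_coords(colMeans(xyz), kframe)
    eul <- euler_angles(inertia_frame(xyz), kframe)
    out$phi_com[k] <- sph["phi_com"]; out$omega_com[k] <- sph["omega_com"]
    out$theta[k] <- eul["theta"]; out$omega[k] <- eul["omega"]
    out$psi[k] <- eul["psi"]
  }
  out
}

#' Two-dimensional free-energy surface over an angle pair
#'
#' \eqn{F = -\ln \hat p} in units of kB*T, with \eqn{\hat p} the
#' normalized 2-D histogram, shifted so the minimum is 0. Empty bins are
#' NA ("no data"), never +Inf.
#'
#' @param samples n x 2 matrix/data.frame of angle pairs (degrees).
#' @param breaks_x,breaks_y bin edges; by default 5-degree bins spanning
#'   the sample range.
#' @param temperature K, stored for converting to kcal/mol.
#' @return An object of class `free_energy_surface`: `values` (kB*T),
#'   `counts`, bin edges, `temperature`.
#' @export
free_energy_surface <- function(samples, breaks_x = NULL, breaks_y = NULL,
                                temperature = 300) {
  samples <- as.matrix(samples)
  if (nrow(samples) < 1) stop("need at least one sample")
  mk_breaks <- function(v) {
    lo <- floor(min(v) / 5) * 5
    hi <- ceiling(max(v) / 5) * 5
    if (hi <= lo) hi <- lo + 5
    seq(lo, hi, by = 5)
  }
  if (is.null(breaks_x)) breaks_x <- mk_breaks(samples[, 1])
  if (is.null(breaks_y)) breaks_y <- mk_breaks(samples[, 2])
  ix <- cut(samples[, 1], breaks_x, include.lowest = TRUE, labels = FALSE)
  iy <- cut(samples[, 2], breaks_y, include.lowest = TRUE, labels = FALSE)
  counts <- matrix(0L, length(breaks_x) - 1, length(breaks_y) - 1)
  ok <- !is.na(ix) & !is.na(iy)
  for (k in which(ok)) counts[ix[k], iy[k]] <- counts[ix[k], iy[k]] + 1L
  p <- counts / sum(counts)
  vals <- -log(p)
  vals[counts == 0] <- NA
  vals <- vals - min(vals, na.rm = TRUE)
  structure(list(values = vals, counts = counts, breaks_x = breaks_x,
                 breaks_y = breaks_y, temperature = temperature),
            class = "free_energy_surface")
}

# indices (pose, replica) of bound poses
.bound_indices <- function(ensemble) {
  if (is.null(ensemble$bound_mask)) stop("run extract_bound() first")
  which(ensemble$bound_mask, arr.ind = TRUE)
}

# ligand coordinates (rows = bound poses, 3*nB columns, xyz per bead
# consecutive) wrapped to the periodic image nearest the receptor COM
.bound_ligand_coords <- function(ensemble, idx = .bound_indices(ensemble)) {
  n_rec <- dim(ensemble$energy)[1]
  tr <- matrix(NA_real_, nrow(idx), 3)
  qu <- matrix(NA_real_, nrow(idx), 4)
  for (k in 1:3) tr[, k] <- ensemble$trans[cbind(idx[, 1], idx[, 2], k)]
  for (k in 1:4) qu[, k] <- ensemble$quat[cbind(idx[, 1], idx[, 2], k)]
  ref <- colMeans(ensemble$A$coords)
  pose_ligand_coords_cpp(ensemble$B_local, tr, qu, ensemble$box_edge, ref)
}

#' Per-residue contact probabilities in the bound ensemble
#'
#' For each residue of both partners, the fraction of bound poses in
#' which it has at least one partner C-alpha within `distance_cut`.
#'
#' @param ensemble a `complex_ensemble` with `bound_mask`.
#' @param distance_cut A (default 8).
#' @return List of two data.frames (`A`, `B`) with residue_id and
#'   probability.
#' @export
contact_probability <- function(ensemble, distance_cut = 8) {
  idx <- .bound_indices(ensemble)
  if (nrow(idx) == 0) stop("no bound poses in ensemble")
  tr <- matrix(NA_real_, nrow(idx), 3)
  qu <- matrix(NA_real_, nrow(idx), 4)
  for (k in 1:3) tr[, k] <- ensemble$trans[cbind(idx[, 1], idx[, 2], k)]
  for (k in 1:4) qu[, k] <- ensemble$quat[cbind(idx[, 1], idx[, 2], k)]
  cc <- contact_counts_cpp(ensemble$A$coords, ensemble$B_local, tr, qu,
                           ensemble$box_edge, distance_cut)
  list(A = data.frame(residue_id = ensemble$A$residue_ids,
                      probability = cc$count_A / nrow(idx)),
       B = data.frame(residue_id = ensemble$B$residue_ids,
                      probability = cc$count_B / nrow(idx)))
}

# greedy neighbor-count clustering on a precomputed distance matrix;
# ties broken by lowest pose index
neighbor_count_cluster <- function(D, cutoff) {
  n <- nrow(D)
  adj <- D <= cutoff
  assignments <- integer(n)
  centers <- integer(0)
  remaining <- seq_len(n)
  cl <- 0L
  while (length(remaining)) {
    counts <- rowSums(adj[remaining, remaining, drop = FALSE])
    center <- remaining[which.max(counts)]
    members <- remaining[adj[remaining, center]]
    cl <- cl + 1L
    assignments[members] <- cl
    centers[cl] <- center
    remaining <- setdiff(remaining, members)
  }
  list(assignments = assignments, centers = centers)
}

#' Cluster bound poses into binding modes
#'
#' Iterative neighbor-count (leader) clustering: the pose with the most
#' neighbors within `cutoff` becomes a cluster center, it and its
#' neighbors are removed, and the procedure repeats. The metric is
#' ligand-only C-alpha RMSD in the shared receptor frame (the receptor is
#' rigid and fixed, so no superposition is needed). Deterministic given
#' the pose ordering; ties go to the earliest pose.
#'
#' @param ensemble a `complex_ensemble` with `bound_mask`.
#' @param cutoff RMSD cutoff radius, A (default 5).
#' @param replica restrict to one ladder slot (default: the one closest
#'   to `temperature`).
#' @param temperature K used to pick the default replica (default 300).
#' @param max_poses optional cap; poses are subsampled evenly beyond it.
#' @return An object of class `binding_mode_clusters`: `assignments`,
#'   `centers` (indices into the clustered pose set), `populations`
#'   (descending), `pose_index` (rows into the recorded poses),
#'   `ligand_coords`.
#' @export
cluster_bound <- function(ensemble, cutoff = 5, replica = NULL,
                          temperature = 300, max_poses = 4000) {
  if (is.null(replica)) replica <- .replica_index(ensemble, temperature)
  idx <- .bound_indices(ensemble)
  idx <- idx[idx[, 2] == replica, , drop = FALSE]
  if (nrow(idx) == 0) stop("no bound poses in the selected replica")
  if (nrow(idx) > max_poses)
    idx <- idx[round(seq(1, nrow(idx), length.out = max_poses)), , drop = FALSE]
  lig <- .bound_ligand_coords(ensemble, idx)
  D <- rmsd_matrix_cpp(lig)
  cl <- neighbor_count_cluster(D, cutoff)
  sizes <- tabulate(cl$assignments)
  pop <- sizes / length(cl$assignments)
  structure(list(assignments = cl$assignments, centers = cl$centers,
                 populations = pop, pose_index = idx, cutoff = cutoff,
                 ligand_coords = lig),
            class = "binding_mode_clusters")
}

#' @export
print.binding_mode_clusters <- function(x, ...) {
  cat(sprintf("binding_mode_clusters: %d poses in %d clusters; populations %s\n",
              length(x$assignments), length(x$centers),
              paste(sprintf("%.3f", head(x$populations, 5)), collapse = " ")))
  invisible(x)
}

#' Free-energy gap between the two largest binding modes
#'
#' \eqn{\Delta F = -k_B T \ln(p_2 / p_1)} in kcal/mol, from the two
#' largest cluster populations.
#'
#' @param clusters a `binding_mode_clusters` object (or any list with a
#'   descending `populations` field).
#' @param temperature K (default 300).
#' @return Gap in kcal/mol (non-negative).
#' @export
mode_free_energy_gap <- function(clusters, temperature = 300) {
  p <- clusters$populations
  if (length(p) < 2) stop("need at least 2 clusters")
  -.kB * temperature * log(p[2] / p[1])
}
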