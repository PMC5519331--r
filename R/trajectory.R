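# Frame-wise stability metrics for two-body trajectories.

#' Construct a two-body trajectory
#'
#' Time-ordered C-alpha coordinate sets for a mobile body J and a
#' reference body K (e.g. a cochaperone domain against its chaperone).
#'
#' @param coords_J,coords_K arrays of dimension n_frames x n_residues x 3
#'   (or lists of n x 3 matrices).
#' @param time_values optional per-frame times, ns.
#' @param residue_ids_J,residue_ids_K residue numbering (defaults 1..n).
#' @param reference_frame index of the reference frame (default 1).
#' @return An object of class `two_body_trajectory`.
#' @export
two_body_trajectory <- function(coords_J, coords_K, time_values = NULL,
                                residue_ids_J = NULL, residue_ids_K = NULL,
                                reference_frame = 1) {
  to_array <- function(x) {
    if (is.list(x)) {
      n <- length(x)
      arr <- array(NA_real_, c(n, nrow(x[[1]]), 3))
      for (k in seq_len(n)) arr[k, , ] <- as.matrix(x[[k]])
      arr
    } else x
  }
  coords_J <- to_array(coords_J)
  coords_K <- to_array(coords_K)
  stopifnot(length(dim(coords_J)) == 3, length(dim(coords_K)) == 3,
            dim(coords_J)[1] == dim(coords_K)[1], dim(coords_J)[1] >= 1)
  if (is.null(residue_ids_J)) residue_ids_J <- seq_len(dim(coords_J)[2])
  if (is.null(residue_ids_K)) residue_ids_K <- seq_len(dim(coords_K)[2])
  structure(list(coords_J = coords_J, coords_K = coords_K,
                 time_values = time_values,
                 residue_ids_J = residue_ids_J,
                 residue_ids_K = residue_ids_K,
                 reference_frame = reference_frame),
            class = "two_body_trajectory")
}

#' Read a two-body trajectory from a multi-model PDB
#'
#' Each MODEL block becomes one frame; C-alpha atoms of the two chains
#' become the two bodies.
#'
#' @param path multi-model PDB file.
#' @param chain_J,chain_K chain identifiers of the mobile and reference
#'   body.
#' @param time_values optional per-frame times, ns.
#' @return A [two_body_trajectory()].
#' @export
read_trajectory_pdb <- function(path, chain_J, chain_K, time_values = NULL) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  ca <- pdb$atom$elety == "CA"
  selJ <- which(ca & pdb$atom$chain == chain_J)
  selK <- which(ca & pdb$atom$chain == chain_K)
  if (!length(selJ)) stop(sprintf("no C-alpha atoms in chain %s", chain_J))
  if (!length(selK)) stop(sprintf("no C-alpha atoms in chain %s", chain_K))
  xyz <- pdb$xyz                          # n_frames x (3*n_atoms)
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  grab <- function(sel) {
    n <- nrow(xyz)
    arr <- array(NA_real_, c(n, length(sel), 3))
    for (k in 1:3) arr[, , k] <- xyz[, 3 * (sel - 1) + k, drop = FALSE]
    arr
  }
  two_body_trajectory(grab(selJ), grab(selK), time_values,
                      pdb$atom$resno[selJ], pdb$atom$resno[selK])
}

.frame_xyz <- function(arr, t) matrix(arr[t, , ], ncol = 3)

.cross_dist <- function(J, K) {
  # all inter-body C-alpha distances: |J| x |K|
  sqrt(outer(rowSums(J^2), rowSums(K^2), "+") - 2 * J %*% t(K))
}

.trailing_window <- function(traj) {
  n <- dim(traj$coords_J)[1]
  if (!is.null(traj$time_values)) {
    which(traj$time_values >= max(traj$time_values) - 10)  # last 10 ns
  } else {
    seq(max(1, ceiling(2 * n / 3) + 1), n)                 # last third
  }
}

#' Inter-protein distance-matrix RMS
#'
#' Per frame, the root mean square over all inter-body residue pairs of
#' the change in C-alpha-C-alpha distance relative to the reference
#' frame:
#' \deqn{dRMS(t) = \sqrt{ \frac{1}{N_i N_j} \sum_{i,j}
#'   (d_{ij}(t) - d_{ij}(0))^2 }}
#' The window average is taken over the trailing 10 ns when time
#' metadata are present, else over the last third of frames.
#'
#' @param traj a [two_body_trajectory()].
#' @param window optional integer vector of frames for the window
#'   average.
#' @return List with `values` (per frame, A) and `window_average`.
#' @export
drms <- function(traj, window = NULL) {
  n <- dim(traj$coords_J)[1]
  ref <- traj$reference_frame
  D0 <- .cross_dist(.frame_xyz(traj$coords_J, ref), .frame_xyz(traj$coords_K, ref))
  vals <- vapply(seq_len(n), function(t) {
    Dt <- .cross_dist(.frame_xyz(traj$coords_J, t), .frame_xyz(traj$coords_K, t))
    sqrt(mean((Dt - D0)^2))
  }, numeric(1))
  if (is.null(window)) window <- .trailing_window(traj)
  list(values = vals, window_average = mean(vals[window]))
}

# Kabsch least-squares rotation + translation mapping x onto y
.kabsch <- function(x, y) {
  cx <- colMeans(x)
  cy <- colMeans(y)
  H <- t(sweep(x, 2, cx)) %*% sweep(y, 2, cy)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(R = R, t = cy - drop(R %*% cx))
}

#' Principal-axis angular deviation
#'
#' Per frame, body K is least-squares superposed onto its reference
#' coordinates and the same transform applied to body J; the angle
#' \deqn{\theta(t) = \frac{180}{\pi}
#'   \mathrm{acos}( I_1^J(t) \cdot I_1^J(0) )}
#' between body J's largest-moment inertia axis at t and at the
#' reference is reported in degrees. Axis signs are made continuous
#' frame-to-frame (positive dot product with the previous frame's axis)
#' to prevent spurious 180-degree jumps.
#'
#' @param traj a [two_body_trajectory()].
#' @param align superpose body K each frame (default TRUE).
#' @param window optional frames for the window average.
#' @return List with `values` (degrees, in [0, 180]), `window_average`,
#'   and `flagged` (frames with a degenerate inertia tensor, NA values).
#' @export
angular_deviation <- function(traj, align = TRUE, window = NULL) {
  n <- dim(traj$coords_J)[1]
  ref <- traj$reference_frame
  Kref <- .frame_xyz(traj$coords_K, ref)
  axis1 <- function(xyz) inertia_frame(xyz)$axes[1, ]
  flagged <- logical(n)
  a0 <- tryCatch(axis1(.frame_xyz(traj$coords_J, ref)), error = function(e) NULL)
  if (is.null(a0)) stop("degenerate inertia tensor in the reference frame")
  prev <- a0
  vals <- rep(NA_real_, n)
  for (t in seq_len(n)) {
    J <- .frame_xyz(traj$coords_J, t)
    if (align) {
      fit <- .kabsch(.frame_xyz(traj$coords_K, t), Kref)
      J <- sweep(J %*% t(fit$R), 2, fit$t, "+")
    }
    at <- tryCatch(axis1(J), error = function(e) NULL)
    if (is.null(at)) { flagged[t] <- TRUE; next }
    if (sum(at * prev) < 0) at <- -at     # sign continuity
    prev <- at
    vals[t] <- acos(max(-1, min(1, sum(at * a0)))) * 180 / pi
  }
  if (is.null(window)) window <- .trailing_window(traj)
  list(values = vals, window_average = mean(vals[window], na.rm = TRUE),
       flagged = which(flagged))
}

#' Distance traces for named inter-body residue pairs
#'
#' @param traj a [two_body_trajectory()].
#' @param pairs data.frame with columns `res_J`, `res_K` (residue ids).
#' @param breaks histogram breaks (default 30 bins over the pooled
#'   range).
#' @return List with `distances` (frames x pairs matrix, A), `pairs`,
#'   and `histograms` (one `hist` object per pair, pooled over frames).
#' @export
contact_distance_traces <- function(traj, pairs, breaks = 30) {
  iJ <- match(pairs$res_J, traj$residue_ids_J)
  iK <- match(pairs$res_K, traj$residue_ids_K)
  if (anyNA(iJ) || anyNA(iK))
    stop(sprintf("unknown residue(s): %s",
                 paste(c(pairs$res_J[is.na(iJ)], pairs$res_K[is.na(iK)]),
                       collapse = ", ")))
  n <- dim(traj$coords_J)[1]
  d <- matrix(NA_real_, n, nrow(pairs))
  colnames(d) <- paste(pairs$res_J, pairs$res_K, sep = "-")
  for (k in seq_len(nrow(pairs)))
    d[, k] <- sqrt(rowSums((traj$coords_J[, iJ[k], , drop = FALSE] -
                            traj$coords_K[, iK[k], , drop = FALSE])^2))
  hists <- lapply(seq_len(ncol(d)), function(k)
    graphics::hist(d[, k], breaks = breaks, plot = FALSE))
  names(hists) <- colnames(d)
  list(distances = d, pairs = pairs, histograms = hists)
}
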