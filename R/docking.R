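# Rigid-body two-body energy model and replica-exchange Monte Carlo.

#' Coarse-grained two-body energy model
#'
#' Residue-level interaction model combining a statistical contact
#' potential with screened Debye-Hueckel electrostatics
#' \eqn{u_{el} = C\, q_i q_j e^{-r/\lambda_D} / (\epsilon_r r)}. Attractive
#' residue pairs (\eqn{\epsilon_{ij} < 0}) interact through a
#' Lennard-Jones-like well of depth \eqn{|\epsilon_{ij}|} with its minimum
#' at \eqn{r = \sigma_{ij}}; repulsive pairs through a soft core with a
#' barrier of height \eqn{\epsilon_{ij}} at \eqn{\sigma_{ij}} and a
#' positive tail. Energies are plainly truncated (not shifted) at
#' `cutoff`. A `"square_well"` variant (hard core, flat well) backs the
#' analytic toy oracles, and `"zero"` gives a flat landscape.
#'
#' @param type "kim_hummer" (contact + electrostatics), "square_well", or
#'   "zero".
#' @param epsilon_table,sigma_table 20 x 20 named matrices of well depths
#'   (kcal/mol) and contact radii (A); defaults from
#'   [default_epsilon_table()] / [default_sigma_table()].
#' @param lambda,e0 scaling and offset for the default epsilon table.
#' @param dielectric relative permittivity (default 80).
#' @param debye_length Debye screening length, A (default 10, roughly
#'   100 mM ionic strength).
#' @param cutoff truncation radius, A (default 30).
#' @param param_file optional whitespace/TSV file with columns
#'   `res_i res_j epsilon sigma` overriding table entries symmetrically.
#' @param core_radius,well_radius,well_depth_kt square-well geometry (A)
#'   and depth in units of kB*T at `reference_temperature`.
#' @param reference_temperature K, fixes the energy scale of the
#'   square-well depth (default 300).
#' @return An object of class `energy_model`.
#' @export
energy_model <- function(type = c("kim_hummer", "square_well", "zero"),
                         epsilon_table = NULL, sigma_table = NULL,
                         lambda = 1.2, e0 = 0.5, dielectric = 80,
                         debye_length = 10, cutoff = 30, param_file = NULL,
                         core_radius = NULL, well_radius = NULL,
                         well_depth_kt = NULL, reference_temperature = 300) {
  type <- match.arg(type)
  m <- list(type = type, dielectric = dielectric, debye_length = debye_length,
            cutoff = cutoff, coulomb = 332.0637,
            reference_temperature = reference_temperature)
  if (type == "kim_hummer") {
    eps <- if (is.null(epsilon_table)) default_epsilon_table(lambda, e0) else epsilon_table
    sig <- if (is.null(sigma_table)) default_sigma_table() else sigma_table
    if (!is.null(param_file)) {
      tab <- read.table(param_file, header = TRUE,
                        colClasses = c("character", "character",
                                       "numeric", "numeric"))
      for (k in seq_len(nrow(tab))) {
        i <- tab[[1]][k]; j <- tab[[2]][k]
        eps[i, j] <- eps[j, i] <- tab[[3]][k]
        sig[i, j] <- sig[j, i] <- tab[[4]][k]
      }
    }
    if (any(sig <= 0) || any(abs(sig - t(sig)) > 1e-9))
      stop("sigma table must be symmetric and positive")
    m$epsilon_table <- eps
    m$sigma_table <- sig
  } else if (type == "square_well") {
    stopifnot(core_radius > 0, well_radius > core_radius)
    m$core_radius <- core_radius
    m$well_radius <- well_radius
    m$well_depth_kt <- well_depth_kt
    m$well_depth_kcal <- well_depth_kt * .kB * reference_temperature
  }
  class(m) <- "energy_model"
  m
}

# pack per-pair lookup tables for the C++ kernels
.pair_tables <- function(model, A, B) {
  if (model$type == "zero")
    return(list(type = 0L, cutoff = model$cutoff))
  if (model$type == "square_well")
    return(list(type = 2L, cutoff = model$cutoff, core = model$core_radius,
                well = model$well_radius, depth = model$well_depth_kcal))
  known <- rownames(model$epsilon_table)
  badA <- setdiff(A$residue_types, known)
  badB <- setdiff(B$residue_types, known)
  if (length(badA) || length(badB))
    stop(sprintf("unknown residue type(s): %s",
                 paste(unique(c(badA, badB)), collapse = ", ")))
  list(type = 1L,
       eps = model$epsilon_table[A$residue_types, B$residue_types, drop = FALSE],
       sig = model$sigma_table[A$residue_types, B$residue_types, drop = FALSE],
       qq = outer(A$charges, B$charges),
       dielectric = model$dielectric, debye = model$debye_length,
       cutoff = model$cutoff, coulomb = model$coulomb)
}

#' Pairwise bead-bead interaction energy
#'
#' Radial interaction energy between two beads: contact term plus screened
#' Coulomb term, truncated at the model cutoff. Vectorized over `r`.
#'
#' @param model an [energy_model()].
#' @param type_i,type_j one-letter residue codes.
#' @param q_i,q_j signed elementary charges.
#' @param r center-center distance(s), A; must be > 0.
#' @return Energy (kcal/mol), one value per element of `r`.
#' @export
pair_energy <- function(model, type_i, type_j, q_i, q_j, r) {
  stopifnot(all(r > 0))
  A <- rigid_body_structure(1L, type_i, matrix(0, 1, 3), q_i, "i")
  B <- rigid_body_structure(1L, type_j, matrix(0, 1, 3), q_j, "j")
  tabs <- .pair_tables(model, A, B)
  box <- 4 * max(model$cutoff, r) + 1
  vapply(r, function(ri)
    total_energy_cpp(A$coords, B$coords, c(ri, 0, 0), c(1, 0, 0, 0), box, tabs),
    numeric(1))
}

#' Total rigid-body interaction energy of a pose
#'
#' Sums [pair_energy()] over all inter-body bead pairs under the
#' minimum-image convention in a cubic periodic box. Body A is used as
#' placed; body B is rotated by the pose quaternion about its own center
#' of mass and translated so its center of mass sits at `translation`.
#'
#' @param model an [energy_model()].
#' @param A,B [rigid_body_structure()] objects.
#' @param translation length-3 vector, B center-of-mass position, A.
#' @param quaternion unit quaternion (w, x, y, z) for B's orientation.
#' @param box_edge cubic box edge, A; must exceed twice the cutoff.
#' @return Total interaction energy, kcal/mol.
#' @export
total_energy <- function(model, A, B, translation, quaternion = c(1, 0, 0, 0),
                         box_edge) {
  if (length(A$residue_ids) == 0 || length(B$residue_ids) == 0)
    stop("both structures must be nonempty")
  if (box_edge < 2 * model$cutoff)
    stop("box_edge must be at least twice the interaction cutoff")
  if (abs(sum(quaternion^2) - 1) > 1e-8)
    stop("quaternion must be normalized")
  Blocal <- sweep(B$coords, 2, colMeans(B$coords))
  total_energy_cpp(A$coords, Blocal, translation, quaternion, box_edge,
                   .pair_tables(model, A, B))
}

#' Geometric replica-temperature ladder
#'
#' @param n_replicas number of replicas (default 20).
#' @param t_min,t_max endpoint temperatures, K (defaults 200 and 395).
#' @return Strictly increasing numeric vector of temperatures.
#' @export
remc_ladder <- function(n_replicas = 20, t_min = 200, t_max = 395) {
  if (n_replicas == 1) return(t_min)
  t_min * (t_max / t_min)^((seq_len(n_replicas) - 1) / (n_replicas - 1))
}

#' Replica-exchange Monte Carlo sampling of a two-body complex
#'
#' Samples rigid translations and rotations of body B relative to fixed
#' body A in a cubic periodic box with Metropolis acceptance at each
#' ladder temperature and neighbor-swap replica exchange. Per step each
#' replica attempts one move: with probability `p_jump` a box-wide
#' reposition with fresh random orientation (a symmetric independence
#' proposal that accelerates mixing between bound and free states),
#' otherwise a local translation (uniform in a sphere) or quaternion
#' perturbation. Move magnitudes adapt toward `target_acceptance` during
#' the first `adapt_frac` of the run and are frozen afterwards.
#'
#' @param model an [energy_model()].
#' @param A,B [rigid_body_structure()] objects; A stays fixed.
#' @param box_edge cubic box edge, A.
#' @param ladder strictly increasing replica temperatures, K
#'   (default [remc_ladder()]).
#' @param n_steps MC steps per replica.
#' @param record_stride steps between recorded samples (default 100).
#' @param exchange_interval steps between exchange rounds (default 100);
#'   each round makes `n_replicas - 1` random neighbor-pair attempts.
#' @param move_params optional list overriding `trans_step`, `rot_step`,
#'   `p_jump`, `adapt_frac`, `target_acceptance`.
#' @param seed optional integer seed.
#' @return An object of class `complex_ensemble` with per-replica pose
#'   arrays (`trans`, `quat`), energies (kcal/mol), the ladder, box size,
#'   and acceptance statistics.
#' @export
remc_sample <- function(model, A, B, box_edge, ladder = remc_ladder(),
                        n_steps = 2e6, record_stride = 100,
                        exchange_interval = 100, move_params = list(),
                        seed = NULL) {
  if (any(diff(ladder) <= 0) && length(ladder) > 1)
    stop("temperature ladder must be strictly increasing")
  if (n_steps < record_stride)
    stop("n_steps must be at least record_stride")
  if (box_edge < 2 * model$cutoff)
    stop("box_edge must be at least twice the interaction cutoff")
  mp <- modifyList(list(trans_step = 5, rot_step = 0.5, p_jump = 0.05,
                        adapt_frac = 0.1, target_acceptance = 0.3),
                   move_params)
  if (!is.null(seed)) set.seed(seed)
  Blocal <- sweep(B$coords, 2, colMeans(B$coords))
  res <- remc_run_cpp(A$coords, Blocal, box_edge, .pair_tables(model, A, B),
                      as.numeric(ladder), as.integer(n_steps),
                      as.integer(record_stride), as.integer(exchange_interval),
                      mp$trans_step, mp$rot_step, mp$p_jump, mp$adapt_frac,
                      mp$target_acceptance)
  structure(list(trans = res$trans, quat = res$quat, energy = res$energy,
                 ladder = as.numeric(ladder), box_edge = box_edge,
                 record_stride = record_stride, n_steps = n_steps,
                 A = A, B = B, B_local = Blocal, model = model,
                 acceptance = res$acceptance,
                 swap_acceptance = res$swap_acceptance,
                 bound_mask = NULL),
            class = "complex_ensemble")
}

#' @export
print.complex_ensemble <- function(x, ...) {
  cat(sprintf("complex_ensemble: %d poses x %d replicas (%.0f-%.0f K), box %.0f A\n",
              dim(x$energy)[1], length(x$ladder), min(x$ladder),
              max(x$ladder), x$box_edge))
  if (!is.null(x$bound_mask))
    cat(sprintf("  bound fraction (coldest->hottest): %s\n",
                paste(sprintf("%.3f", colMeans(x$bound_mask)), collapse = " ")))
  invisible(x)
}

.replica_index <- function(ensemble, temperature)
  which.min(abs(ensemble$ladder - temperature))

#' Flag bound conformations
#'
#' A pose is bound iff the minimum inter-body bead distance is at most
#' `distance_cut` and the total interaction energy is at or below
#' `energy_cut_kt` times kB*T of its replica.
#'
#' @param ensemble a `complex_ensemble` from [remc_sample()].
#' @param distance_cut A (default 8).
#' @param energy_cut_kt energy threshold in kB*T units (default -2).
#' @return The ensemble with a logical `bound_mask` (poses x replicas).
#' @export
extract_bound <- function(ensemble, distance_cut = 8, energy_cut_kt = -2) {
  n_rec <- dim(ensemble$energy)[1]
  R <- length(ensemble$ladder)
  mask <- matrix(FALSE, n_rec, R)
  for (r in seq_len(R)) {
    md <- pose_min_dist_cpp(ensemble$A$coords, ensemble$B_local,
                            matrix(ensemble$trans[, r, ], ncol = 3),
                            matrix(ensemble$quat[, r, ], ncol = 4),
                            ensemble$box_edge)
    ecut <- energy_cut_kt * .kB * ensemble$ladder[r]
    mask[, r] <- md <= distance_cut & ensemble$energy[, r] <= ecut
  }
  ensemble$bound_mask <- mask
  ensemble$bound_params <- list(distance_cut = distance_cut,
                                energy_cut_kt = energy_cut_kt)
  ensemble
}

#' Bound fraction with block-averaged standard error
#'
#' Fraction of bound poses at the ladder temperature closest to
#' `temperature`, with a standard error from block averaging of the
#' time-ordered bound indicator (accounts for Monte Carlo
#' autocorrelation).
#'
#' @param ensemble a `complex_ensemble` with `bound_mask` (see
#'   [extract_bound()]).
#' @param temperature target temperature, K (default 300).
#' @param n_blocks number of blocks (default 20).
#' @return List with `p_bound`, `se`, `temperature` (the ladder value
#'   used) and `n`.
#' @export
bound_fraction <- function(ensemble, temperature = 300, n_blocks = 20) {
  if (is.null(ensemble$bound_mask))
    stop("run extract_bound() first")
  r <- .replica_index(ensemble, temperature)
  b <- ensemble$bound_mask[, r]
  n <- length(b)
  blocks <- split(b, cut(seq_len(n), n_blocks, labels = FALSE))
  bm <- vapply(blocks, mean, numeric(1))
  list(p_bound = mean(b), se = sd(bm) / sqrt(length(bm)),
       temperature = ensemble$ladder[r], n = n)
}

#' Dissociation constant from bound fractions over box volumes
#'
#' For one copy of each partner in periodic volume V, the bound fraction
#' \eqn{P_b} gives \eqn{K_d = (1 - P_b)^2 / (P_b N_A V)} with V in liters.
#' The estimate is the mean over boxes; the uncertainty is the standard
#' error over boxes (for a single box, the per-box MC error propagated
#' through the formula, when provided).
#'
#' @param per_box data.frame with columns `volume` (A^3) and `p_bound`,
#'   optionally `se` (MC standard error of `p_bound`).
#' @param temperature K, recorded for provenance (the conversion itself is
#'   temperature-free).
#' @return An object of class `kd_estimate`: `kd` (mol/L), `uncertainty`,
#'   `per_box` with per-box Kd values.
#' @export
estimate_kd <- function(per_box, temperature = 300) {
  per_box <- as.data.frame(per_box)
  stopifnot(all(c("volume", "p_bound") %in% names(per_box)))
  p <- per_box$p_bound
  if (any(p <= 0 | p >= 1))
    stop("p_bound must lie strictly in (0, 1): affinity unresolvable at this box size")
  V_l <- per_box$volume * 1e-27
  kd <- (1 - p)^2 / (p * .NAvo * V_l)
  per_box$kd <- kd
  n <- length(kd)
  # per-box MC error propagated through dKd/dp = -(1 - p^2)/p^2 / (N_A V)
  dkd <- if (!is.null(per_box$se))
    abs((1 - p^2) / (p^2 * .NAvo * V_l)) * per_box$se else NULL
  if (n > 1) {
    se_box <- sd(kd) / sqrt(n)
    unc <- if (is.null(dkd)) se_box
      else sqrt(se_box^2 + mean(dkd)^2 / n)   # combined in quadrature
    if (!is.null(dkd) && diff(range(kd)) > 3 * sqrt(2) * max(dkd))
      warning("per-box Kd values differ by more than 3 standard errors; check convergence/box sizes")
  } else {
    unc <- if (is.null(dkd)) NA_real_ else dkd
  }
  structure(list(kd = mean(kd), uncertainty = unc, per_box = per_box,
                 temperature = temperature),
            class = "kd_estimate")
}

#' @export
print.kd_estimate <- function(x, ...) {
  cat(sprintf("Kd = %.3g +/- %.2g M over %d box(es)\n", x$kd,
              x$uncertainty, nrow(x$per_box)))
  invisible(x)
}
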