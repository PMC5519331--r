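# Independent oracles used across the suite. These deliberately avoid the
# package's code paths: elementary-rotation composition for Euler angles,
# brute-force clustering, mean-field DCA, and quadrature-style SASA.

# ---- rotations --------------------------------------------------------------

rot_about_1 <- function(a) matrix(c(1, 0, 0,
                                    0, cos(a), -sin(a),
                                    0, sin(a), cos(a)), 3, 3, byrow = TRUE)
rot_about_2 <- function(a) matrix(c(cos(a), 0, sin(a),
                                    0, 1, 0,
                                    -sin(a), 0, cos(a)), 3, 3, byrow = TRUE)
rot_about_3 <- function(a) matrix(c(cos(a), -sin(a), 0,
                                    sin(a), cos(a), 0,
                                    0, 0, 1), 3, 3, byrow = TRUE)

# Compose the frame-overlap matrix M[a, b] = I_a^J . I_b^K realizing given
# angles (radians) under the asin/atan2 convention: a product of elementary
# rotations, derived independently of the decomposition formulas.
euler_compose <- function(theta, omega, psi)
  rot_about_1(omega - pi / 2) %*% rot_about_3(-theta) %*% rot_about_2(psi)

random_rotation_matrix <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

fake_frame <- function(axes, origin = c(0, 0, 0))
  structure(list(origin = origin, axes = axes), class = "inertia_frame")

quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# ---- clustering -------------------------------------------------------------

# Reference neighbor-count clustering, written as a plain loop with explicit
# bookkeeping (not shared with the package implementation).
brute_neighbor_cluster <- function(D, cutoff) {
  n <- nrow(D)
  assigned <- rep(NA_integer_, n)
  centers <- integer(0)
  cl <- 0L
  repeat {
    pool <- which(is.na(assigned))
    if (!length(pool)) break
    best <- -1L
    best_i <- NA_integer_
    for (i in pool) {
      cnt <- 0L
      for (j in pool) if (D[i, j] <= cutoff) cnt <- cnt + 1L
      if (cnt > best) { best <- cnt; best_i <- i }
    }
    cl <- cl + 1L
    centers <- c(centers, best_i)
    for (j in pool) if (D[best_i, j] <= cutoff) assigned[j] <- cl
  }
  list(assignments = assigned, centers = centers)
}

# ---- mean-field DCA oracle --------------------------------------------------

# Naive mean-field DCA on an integer MSA (states 1..q): pseudocount
# frequencies, inverse covariance over q-1 states, zero-padded coupling
# blocks, Frobenius norm after zero-sum gauge. Used only as a cross-check.
mf_dca_scores <- function(X, q, pseudocount = 0.5) {
  M <- nrow(X); N <- ncol(X)
  lam <- pseudocount
  f1 <- matrix(0, N, q)
  for (i in 1:N) f1[i, ] <- (tabulate(X[, i], q) / M) * (1 - lam) + lam / q
  p <- q - 1
  C <- matrix(0, N * p, N * p)
  for (i in 1:N) for (j in 1:N) {
    fij <- matrix(0, q, q)
    if (i == j) {
      # single-site "pair" counts live on the diagonal; pseudocount likewise
      diag(fij) <- (1 - lam) * tabulate(X[, i], q) / M + lam / q
    } else {
      for (m in 1:M) fij[X[m, i], X[m, j]] <- fij[X[m, i], X[m, j]] + 1 / M
      fij <- fij * (1 - lam) + lam / q^2
    }
    blk <- fij[1:p, 1:p] - outer(f1[i, 1:p], f1[j, 1:p])
    C[(i - 1) * p + 1:p, (j - 1) * p + 1:p] <- blk
  }
  J <- -solve(C)
  S <- matrix(0, N, N)
  for (i in 1:N) for (j in 1:N) {
    if (i == j) next
    blk <- matrix(0, q, q)
    blk[1:p, 1:p] <- J[(i - 1) * p + 1:p, (j - 1) * p + 1:p]
    blk <- blk - outer(rowMeans(blk), rep(1, q)) -
      outer(rep(1, q), colMeans(blk)) + mean(blk)
    S[i, j] <- sqrt(sum(blk^2))
  }
  (S + t(S)) / 2
}

# ---- SASA quadrature oracle -------------------------------------------------

# Latitude-band quadrature of the accessible surface: independent point
# placement and explicit area weights (vs the golden-spiral lattice).
lat_band_sasa <- function(coords, radii, probe, n_lat = 90) {
  n <- nrow(coords)
  out <- numeric(n)
  for (i in 1:n) {
    R <- radii[i] + probe
    area <- 0
    thetas <- seq(0, pi, length.out = n_lat + 1)
    for (k in 1:n_lat) {
      t0 <- thetas[k]; t1 <- thetas[k + 1]
      band <- 2 * pi * R^2 * (cos(t0) - cos(t1))
      tm <- (t0 + t1) / 2
      n_lon <- max(8, round(2 * n_lat * sin(tm)))
      phis <- (seq_len(n_lon) - 0.5) / n_lon * 2 * pi
      pts <- cbind(R * sin(tm) * cos(phis), R * sin(tm) * sin(phis),
                   R * cos(tm))
      pts <- sweep(pts, 2, coords[i, ], "+")
      exposed <- rep(TRUE, n_lon)
      for (j in seq_len(n)) {
        if (j == i) next
        rj <- radii[j] + probe
        d2 <- (pts[, 1] - coords[j, 1])^2 + (pts[, 2] - coords[j, 2])^2 +
          (pts[, 3] - coords[j, 3])^2
        exposed <- exposed & d2 >= rj^2
      }
      area <- area + band * mean(exposed)
    }
    out[i] <- area
  }
  out
}

# ---- Potts enumeration ------------------------------------------------------

# Exact single-column marginals of a small Potts model by full enumeration.
potts_exact_marginals <- function(N, q, h, pair_i, pair_j, Jlist) {
  states <- as.matrix(expand.grid(rep(list(1:q), N)))
  logw <- numeric(nrow(states))
  for (k in seq_len(N)) logw <- logw + h[cbind(states[, k], k)]
  for (t in seq_along(pair_i))
    logw <- logw + Jlist[[t]][cbind(states[, pair_i[t]], states[, pair_j[t]])]
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  marg <- matrix(0, q, N)
  for (k in seq_len(N))
    for (a in 1:q) marg[a, k] <- sum(w[states[, k] == a])
  marg
}

# weighted least-squares slope and its standard error (known variances)
wls_slope <- function(x, y, se) {
  w <- 1 / se^2
  xb <- sum(w * x) / sum(w)
  yb <- sum(w * y) / sum(w)
  sxx <- sum(w * (x - xb)^2)
  list(slope = sum(w * (x - xb) * (y - yb)) / sxx, se = sqrt(1 / sxx))
}
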