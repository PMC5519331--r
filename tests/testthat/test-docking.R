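test_that("pair energy has the advertised radial structure", {
  m <- energy_model()
  eps <- default_epsilon_table()
  sig <- default_sigma_table()
  # attractive pair: numerical minimum of the radial form sits at sigma
  # with depth |eps|
  r <- seq(3, 15, by = 0.001)
  u <- pair_energy(m, "I", "L", 0, 0, r)
  expect_lt(abs(r[which.min(u)] - sig["I", "L"]), 0.005)
  expect_equal(min(u), eps["I", "L"], ignore_attr = TRUE, tolerance = 1e-6)
  expect_equal(pair_energy(m, "I", "L", 0, 0, sig["I", "L"]),
               unname(eps["I", "L"]))
  # repulsive pair: barrier height +eps at sigma, nonnegative tail
  expect_gt(eps["D", "E"], 0)
  expect_equal(pair_energy(m, "D", "E", 0, 0, sig["D", "E"]),
               unname(eps["D", "E"]))
  expect_true(all(pair_energy(m, "D", "E", 0, 0, r) >= 0))
  # zero charge kills the electrostatic term: beyond the contact range the
  # uncharged energy is ~0 while the charged one is not
  far <- 20
  expect_equal(pair_energy(m, "K", "E", 0, -1, far),
               pair_energy(m, "K", "E", 0, 0, far))
  expect_lt(pair_energy(m, "K", "E", 1, -1, far),
            pair_energy(m, "K", "E", 0, 0, far))
  # plain truncation at the cutoff
  expect_identical(pair_energy(m, "K", "E", 1, -1, m$cutoff + 1), 0)
  expect_error(pair_energy(m, "B", "A", 0, 0, 5), "unknown residue")
})

test_that("screened Coulomb term matches its closed form", {
  m <- energy_model()
  r <- c(5, 8, 12)
  u_charged <- pair_energy(m, "K", "D", 1, -1, r)
  u_neutral <- pair_energy(m, "K", "D", 0, 0, r)
  expect_equal(u_charged - u_neutral,
               332.0637 * -1 * exp(-r / m$debye_length) / (m$dielectric * r),
               tolerance = 1e-12)
})

test_that("total energy is symmetric, periodic, and reduces to pair sums", {
  m <- energy_model(cutoff = 12)
  A <- random_body(5, 11, "A")
  B <- random_body(5, 22, "B")
  L <- 40
  tr <- c(12, 5, 7)
  qt <- c(cos(0.4), sin(0.4) * c(0.6, 0.64, 0.48))
  qt <- qt / sqrt(sum(qt^2))
  e <- total_energy(m, A, B, tr, qt, L)
  # brute-force O(n^2) reference with explicit minimum image
  R <- quat_to_matrix(qt)
  Bl <- sweep(B$coords, 2, colMeans(B$coords))
  Babs <- sweep(Bl %*% t(R), 2, tr, "+")
  ref <- 0
  for (i in 1:5) for (j in 1:5) {
    d <- A$coords[i, ] - Babs[j, ]
    d <- d - L * round(d / L)
    ref <- ref + pair_energy(m, A$residue_types[i], B$residue_types[j],
                             A$charges[i], B$charges[j], sqrt(sum(d * d)))
  }
  expect_equal(e, ref, tolerance = 1e-10)
  # symmetry in (A, B): give B's pose to A via the inverse transform
  Binv <- rigid_body_structure(B$residue_ids, B$residue_types, Babs,
                               B$charges, "Babs")
  comA <- colMeans(A$coords)
  e_swap <- total_energy(m, Binv, A, comA, c(1, 0, 0, 0), L)
  expect_equal(e_swap, e, tolerance = 1e-10)
  # translating both bodies together changes nothing
  v <- c(3.3, -8, 15)
  Ashift <- rigid_body_structure(A$residue_ids, A$residue_types,
                                 sweep(A$coords, 2, v, "+"), A$charges)
  expect_equal(total_energy(m, Ashift, B, tr + v, qt, L), e,
               tolerance = 1e-10)
  # box-lattice translation of B
  expect_equal(total_energy(m, A, B, tr + c(L, 0, -L), qt, L), e,
               tolerance = 1e-10)
  # beyond-cutoff separation gives exactly zero
  expect_identical(total_energy(m, A, B, c(L / 2, L / 2, L / 2), qt, L), 0)
  # single-bead reduction
  a1 <- rigid_body_structure(1, "K", matrix(0, 1, 3), 1)
  b1 <- rigid_body_structure(1, "E", matrix(0, 1, 3), -1)
  expect_equal(total_energy(m, a1, b1, c(7, 0, 0), c(1, 0, 0, 0), L),
               pair_energy(m, "K", "E", 1, -1, 7))
  expect_error(total_energy(m, A, B, tr, qt, 20), "twice")
})

test_that("flat landscape sampling is uniform with full acceptance", {
  m <- energy_model(type = "zero", cutoff = 10)
  A <- rigid_body_structure(1, "G", matrix(25, 1, 3), 0)
  B <- rigid_body_structure(1, "G", matrix(0, 1, 3), 0)
  ens <- remc_sample(m, A, B, 50, ladder = 300, n_steps = 5e4,
                     record_stride = 10, seed = 3)
  expect_equal(ens$acceptance, 1)
  x <- ens$trans[, 1, ]
  expect_equal(dim(x), c(5000L, 3L))
  # uniform over the box: mean L/2, sd L/sqrt(12), within generous noise
  expect_true(all(abs(colMeans(x) - 25) < 2))
  expect_true(all(abs(apply(x, 2, sd) - 50 / sqrt(12)) < 2))
})

test_that("sampler input contracts are enforced", {
  m <- energy_model(type = "zero", cutoff = 10)
  A <- rigid_body_structure(1, "G", matrix(0, 1, 3), 0)
  expect_error(remc_sample(m, A, A, 50, ladder = c(300, 250), n_steps = 1000),
               "increasing")
  expect_error(remc_sample(m, A, A, 50, ladder = 300, n_steps = 50,
                           record_stride = 100), "record_stride")
  # recorded pose count is n_steps / record_stride per replica
  ens <- remc_sample(m, A, A, 50, ladder = c(250, 300), n_steps = 5000,
                     record_stride = 100, seed = 1)
  expect_equal(dim(ens$energy), c(50L, 2L))
})

test_that("square-well REMC matches the two-state Boltzmann oracle on a ladder", {
  toy <- square_well_toy(3, 8, 2.5, 60)
  sys <- toy_system(toy)
  ens <- remc_sample(sys$model, sys$A, sys$B, toy$box_edge,
                     ladder = c(250, 300, 360), n_steps = 3e5,
                     record_stride = 30, seed = 17)
  ens <- extract_bound(ens)
  # occupancies match Boltzmann weights at every ladder temperature;
  # note the bound definition coincides with being inside the well here
  # (depth 2.5 kT at 300 K exceeds the 2 kT energy criterion up to ~375 K)
  for (k in 1:3) {
    bf <- bound_fraction(ens, temperature = ens$ladder[k])
    expect_equal(bf$temperature, ens$ladder[k])
    exact <- analytic_kd(toy, temperature = ens$ladder[k])$p_bound
    expect_lt(abs(bf$p_bound - exact), 3 * bf$se)
  }
})

test_that("exchange moves leave per-temperature marginals unchanged", {
  toy <- square_well_toy(3, 8, 2.5, 60)
  sys <- toy_system(toy)
  with_ex <- extract_bound(remc_sample(sys$model, sys$A, sys$B, toy$box_edge,
                                       ladder = c(250, 300), n_steps = 2e5,
                                       record_stride = 20,
                                       exchange_interval = 100, seed = 5))
  no_ex <- extract_bound(remc_sample(sys$model, sys$A, sys$B, toy$box_edge,
                                     ladder = c(250, 300), n_steps = 2e5,
                                     record_stride = 20,
                                     exchange_interval = 0, seed = 6))
  for (temp in c(250, 300)) {
    a <- bound_fraction(with_ex, temp)
    b <- bound_fraction(no_ex, temp)
    expect_lt(abs(a$p_bound - b$p_bound), 3 * sqrt(a$se^2 + b$se^2))
  }
})

test_that("bound extraction applies both criteria and matches brute force", {
  A <- random_body(4, 1, "A")
  B <- random_body(3, 2, "B")
  kT <- 0.0019872041 * 300
  # distance 9 A: unbound regardless of energy
  far <- fake_ensemble(A, B, matrix(c(colMeans(A$coords) + c(30, 0, 0)),
                                    1, 3), energy = -10 * kT)
  far <- extract_bound(far)
  md <- min(as.matrix(dist(rbind(A$coords,
    sweep(far$B_local, 2, far$trans[1, 1, ], "+"))))[1:4, 5:7])
  expect_gt(md, 8)
  expect_false(any(far$bound_mask))
  # close but weakly bound: -1 kT fails the energy criterion
  near <- fake_ensemble(A, B, matrix(colMeans(A$coords) + c(5, 0, 0), 1, 3),
                        energy = -1 * kT)
  expect_false(any(extract_bound(near)$bound_mask))
  expect_true(any(extract_bound(near, energy_cut_kt = -0.5)$bound_mask))
  # random ensemble: mask equals per-pose re-evaluation of both criteria
  set.seed(9)
  n <- 60
  tr <- matrix(runif(3 * n, 0, 60), n, 3)
  qt <- t(apply(matrix(rnorm(4 * n), n, 4), 1, function(q) q / sqrt(sum(q^2))))
  en <- runif(n, -3, 1) * kT
  ens <- fake_ensemble(A, B, tr, qt, en, box_edge = 60)
  ens <- extract_bound(ens)
  for (p in seq_len(n)) {
    R <- quat_to_matrix(qt[p, ])
    Babs <- sweep(ens$B_local %*% t(R), 2, tr[p, ], "+")
    dmin <- Inf
    for (i in 1:4) for (j in 1:3) {
      d <- A$coords[i, ] - Babs[j, ]
      d <- d - 60 * round(d / 60)
      dmin <- min(dmin, sqrt(sum(d^2)))
    }
    expect_identical(ens$bound_mask[p, 1], dmin <= 8 && en[p] <= -2 * kT)
  }
})

test_that("Kd plug-in, limits, and input guards", {
  # P_b = 0.5 in a 1e6 A^3 box: Kd = 0.5 / (N_A * 1e-21 L)
  est <- estimate_kd(data.frame(volume = 1e6, p_bound = 0.5))
  expect_equal(est$kd, 0.5 / (6.02214076e23 * 1e-21))
  expect_equal(est$kd, 8.3e-4, tolerance = 2e-3)   # ~0.83 mM
  # Kd -> 0 monotonically as P_b -> 1
  ps <- c(0.5, 0.9, 0.99, 0.999)
  kds <- vapply(ps, function(p)
    estimate_kd(data.frame(volume = 1e6, p_bound = p))$kd, numeric(1))
  expect_true(all(diff(kds) < 0))
  expect_lt(kds[4], 1e-6)
  expect_error(estimate_kd(data.frame(volume = 1e6, p_bound = 0)), "0, 1")
  expect_error(estimate_kd(data.frame(volume = 1e6, p_bound = 1)), "0, 1")
  # inconsistent per-box values trigger the consistency warning
  expect_warning(estimate_kd(data.frame(volume = c(1e6, 2e6),
                                        p_bound = c(0.5, 0.5),
                                        se = c(1e-4, 1e-4))), "3 standard")
})
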