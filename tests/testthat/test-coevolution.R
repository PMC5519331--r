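make_msa <- function(X, org = rep("o", nrow(X)))
  family_msa(X, org, sprintf("s%d", seq_len(nrow(X))))

test_that("sequence weights implement the 90% identity rule", {
  set.seed(1)
  # mutually distinct rows: all weights 1
  X <- matrix(sample(1:20, 20 * 10, TRUE), 20, 10)
  while (any(msa_dup <- duplicated(X))) X[msa_dup, 1] <- sample(1:20, sum(msa_dup), TRUE)
  w <- sequence_weights(make_msa(X))
  # verify the premise: no pair at >= 90% identity
  ok <- TRUE
  for (i in 1:19) for (j in (i + 1):20)
    if (mean(X[i, ] == X[j, ]) >= 0.9) ok <- FALSE
  if (ok) {
    expect_equal(w$weights, rep(1, 20))
    expect_equal(w$neff, 20)
  }
  # one row duplicated 4 times weighs 1/4 each
  Y <- rbind(X[1, ], X[1, ], X[1, ], X[1, ], X[2:6, ])
  wy <- sequence_weights(make_msa(Y))
  expect_equal(wy$weights[1:4], rep(0.25, 4))
  expect_equal(wy$weights[5:9], rep(1, 5))
  # 200 random rows against the O(M^2) direct-count oracle
  Z <- matrix(sample(1:4, 200 * 15, TRUE), 200, 15)
  wz <- sequence_weights(make_msa(Z), identity_threshold = 0.8)
  cnt <- integer(200)
  for (i in 1:200) cnt[i] <- sum(vapply(1:200, function(j)
    mean(Z[i, ] == Z[j, ]) >= 0.8, logical(1)))
  expect_equal(wz$weights, 1 / cnt)
  # duplicating every row leaves Neff unchanged
  w2 <- sequence_weights(make_msa(rbind(Z, Z)), identity_threshold = 0.8)
  expect_equal(w2$neff, wz$neff)
})

test_that("frobenius scores apply the zero-sum gauge over full blocks", {
  q <- 21; N <- 3
  J <- array(0, dim = c(N, N, q, q))
  mod <- structure(list(h = matrix(0, q, N), J = J, N = N, q = q,
                        boundary = 1L, neff = 10),
                   class = "potts_model")
  expect_equal(frobenius_scores(mod), matrix(0, 3, 3))
  # a single entry of 2 (no gauge) scores exactly 2
  J1 <- J; J1[1, 2, 3, 5] <- 2; J1[2, 1, 5, 3] <- 2
  mod1 <- mod; mod1$J <- J1
  expect_equal(frobenius_scores(mod1, gauge = "none")[1, 2], 2)
  # random block: equals the direct sqrt-sum-of-squares after gauging
  set.seed(5)
  B <- matrix(rnorm(q * q), q, q)
  J2 <- J; J2[1, 2, , ] <- B; J2[2, 1, , ] <- t(B)
  mod2 <- mod; mod2$J <- J2
  G <- B - outer(rowMeans(B), rep(1, q)) - outer(rep(1, q), colMeans(B)) +
    mean(B)
  expect_equal(frobenius_scores(mod2)[1, 2], sqrt(sum(G^2)), tolerance = 1e-12)
  # gauge shifts r_i(a) + c_j(b) leave the gauged score unchanged
  shift <- outer(rnorm(q), rep(1, q)) + outer(rep(1, q), rnorm(q))
  J3 <- J2; J3[1, 2, , ] <- B + shift; J3[2, 1, , ] <- t(B + shift)
  mod3 <- mod; mod3$J <- J3
  expect_equal(frobenius_scores(mod3)[1, 2], frobenius_scores(mod2)[1, 2],
               tolerance = 1e-12)
})

test_that("two-segment APC cancels uniform blocks and matches recomputation", {
  # uniform inter-block corrects to exactly 0
  S <- matrix(1, 5, 5)
  diag(S) <- 0
  expect_equal(apc_correct(S, 2)[1:2, 3:5], matrix(0, 2, 3))
  # 1x1 inter-block: S - S*S/S = 0
  S1 <- matrix(c(0, 0.7, 0.7, 0), 2, 2)
  expect_equal(apc_correct(S1, 1)[1, 2], 0)
  # random 6x8 inter-block against an explicit loop recomputation
  set.seed(6)
  N <- 14; bA <- 6
  Sr <- matrix(0, N, N)
  Sr[upper.tri(Sr)] <- runif(sum(upper.tri(Sr)), 0.1, 2)
  Sr <- Sr + t(Sr)
  S2 <- apc_correct(Sr, bA)
  inter <- Sr[1:bA, (bA + 1):N]
  ref <- matrix(NA_real_, bA, N - bA)
  for (i in 1:bA) for (j in 1:(N - bA))
    ref[i, j] <- inter[i, j] - mean(inter[i, ]) * mean(inter[, j]) / mean(inter)
  expect_equal(S2[1:bA, (bA + 1):N], ref, tolerance = 1e-12)
  expect_equal(S2, t(S2))
  expect_error(apc_correct(matrix(0, 4, 4), 2), "zero grand mean")
})

test_that("score renormalization behaves as stated and preserves ranking", {
  set.seed(7)
  N <- 10; bA <- 4; neff <- 50
  S <- matrix(rnorm(N * N), N, N); S <- (S + t(S)) / 2; diag(S) <- 0
  St <- normalize_scores(S, bA, N, neff)
  inter <- S[1:bA, (bA + 1):N]
  # the minimum inter pair maps to -(1 + N/Neff)
  expect_equal(min(St), -(1 + N / neff), tolerance = 1e-12)
  expect_equal(St[which.min(inter)], min(St))
  # ranking of inter pairs is unchanged
  expect_equal(order(inter), order(St))
  # N = Neff doubles the scale relative to plain min-normalization
  St2 <- normalize_scores(S, bA, N, neff = N)
  expect_equal(St2, inter / abs(min(inter)) * 2, tolerance = 1e-12)
  # divide variant
  Std <- normalize_scores(S, bA, N, neff, neff_mode = "divide")
  expect_equal(Std, inter / abs(min(inter)) / (1 + N / neff),
               tolerance = 1e-12)
})

test_that("random matching pairs within organisms without replacement", {
  X <- matrix(sample(1:20, 8 * 6, TRUE), 8, 6)
  famA <- family_msa(X[1:4, ], c("u", "v", "v", "w"), c("a1", "a2", "a3", "a4"))
  famB <- family_msa(X[5:8, ], c("u", "v", "w", "x"), c("b1", "b2", "b3", "b4"))
  for (s in 1:20) {
    pm <- random_match(famA, famB, seed = s)
    pairing <- attr(pm, "pairing")
    # u (1+1) and w (1+1) always deterministically paired
    expect_true(all(c(1, 4) %in% pairing$row_A))
    # v has 2 Hsp70-side and 1 Hsp40-side: exactly one pair
    expect_equal(sum(famA$organism_ids[pairing$row_A] == "v"), 1)
    # each sequence at most once
    expect_false(any(duplicated(pairing$row_A)))
    expect_false(any(duplicated(pairing$row_B)))
    # organism x exists only in family B: never matched
    expect_false("x" %in% famB$organism_ids[pairing$row_B])
  }
  famC <- family_msa(X[1:2, ], c("y", "z"), c("c1", "c2"))
  expect_error(random_match(famA, famC), "no organisms")
  # 3x3 organism: all 6 permutations occur under different seeds
  fam3A <- family_msa(X[1:3, ], rep("o", 3))
  fam3B <- family_msa(X[4:6, ], rep("o", 3))
  perms <- vapply(1:600, function(s) {
    p <- attr(random_match(fam3A, fam3B, seed = s), "pairing")
    paste(p$row_B[order(p$row_A)], collapse = "")
  }, character(1))
  expect_setequal(unique(perms),
                  c("123", "132", "213", "231", "312", "321"))
})

test_that("plm finds no inter-segment signal in independent columns", {
  set.seed(8)
  M <- 1500
  X <- matrix(sample(1:21, M * 4, TRUE), M, 4)
  pm <- paired_msa(X, 2, rep(sprintf("o%d", 1:M)))
  w <- list(weights = rep(1, M), neff = M)
  obs <- apc_correct(frobenius_scores(fit_plm(pm, weights = w)), 2)[1:2, 3:4]
  # permutation null: re-pair the B segment at random
  null_vals <- unlist(lapply(1:5, function(s) {
    set.seed(100 + s)
    Xp <- cbind(X[, 1:2], X[sample(M), 3:4])
    apc_correct(frobenius_scores(
      fit_plm(paired_msa(Xp, 2, rep("o", M)), weights = w)), 2)[1:2, 3:4]
  }))
  expect_lt(max(abs(obs)), mean(abs(null_vals)) + 3 * sd(abs(null_vals)) +
              max(abs(null_vals)))
  expect_lt(max(abs(obs)), 0.2)
})

test_that("identical rows give a no-signal score landscape", {
  M <- 40
  X <- matrix(rep(c(rep(3L, 4), rep(7L, 4)), each = M), M, 8)
  pm <- paired_msa(X, 4, rep("o", M))
  fit <- fit_plm(pm, weights = list(weights = rep(1, M), neff = M))
  S <- frobenius_scores(fit)
  # all pairs carry identical (pure-regularization) scores...
  expect_lt(diff(range(S[upper.tri(S)])), 1e-4)
  # ...so the two-segment APC wipes the inter block
  expect_lt(max(abs(apc_correct(S, 4)[1:4, 5:8])), 1e-4)
  # and Neff = 1 for identical rows is rejected upfront
  expect_error(fit_plm(pm), "exceed 1")
})

test_that("a planted coupling tops both plm and the mean-field oracle", {
  gen <- generate_paired_msa(n_A = 5, n_B = 5, n_organisms = 250,
                             planted_pairs = cbind(2, 4), J0 = 2,
                             alphabet_size = 8, paralog_probs = 1, seed = 31)
  pm <- random_match(gen$family_A, gen$family_B, seed = 1)
  fit <- fit_plm(pm)
  S <- apc_correct(frobenius_scores(fit), 5)
  inter <- S[1:5, 6:10]
  top <- which(inter == max(inter), arr.ind = TRUE)
  expect_equal(unname(top[1, ]), c(2, 4))
  # independent covariance-based mean-field DCA agrees on the top pair
  Smf <- mf_dca_scores(pm$rows, q = 21)
  imf <- Smf[1:5, 6:10]
  topmf <- which(imf == max(imf), arr.ind = TRUE)
  expect_equal(unname(topmf[1, ]), c(2, 4))
})

test_that("column permutations within a segment permute scores accordingly", {
  gen <- generate_paired_msa(n_A = 4, n_B = 4, n_organisms = 150,
                             planted_pairs = cbind(1, 3), J0 = 2,
                             alphabet_size = 6, paralog_probs = 1, seed = 32)
  pm <- random_match(gen$family_A, gen$family_B, seed = 2)
  w <- sequence_weights(pm)
  S <- apc_correct(frobenius_scores(fit_plm(pm, weights = w)), 4)
  perm <- c(3, 1, 4, 2)                    # permute segment-A columns
  pm2 <- paired_msa(cbind(pm$rows[, perm], pm$rows[, 5:8]), 4,
                    pm$organism_ids)
  S2 <- apc_correct(frobenius_scores(fit_plm(pm2, weights = w)), 4)
  expect_equal(S2[1:4, 5:8], S[perm, 5:8], tolerance = 1e-5)
})

test_that("selection frequencies rank a planted pair first", {
  gen <- generate_paired_msa(n_A = 5, n_B = 5, n_organisms = 200,
                             planted_pairs = cbind(3, 2), J0 = 2,
                             alphabet_size = 8,
                             paralog_probs = c(0.6, 0.4), seed = 33)
  # single realization: frequencies are 0 or 1
  one <- selection_frequencies(gen$family_A, gen$family_B,
                               n_realizations = 1, seed = 9)
  expect_true(all(one$frequency %in% c(0, 1)))
  preds <- selection_frequencies(gen$family_A, gen$family_B,
                                 n_realizations = 8, seed = 10)
  expect_equal(c(preds$column_A[1], preds$column_B[1]), c(3, 2))
  expect_equal(preds$frequency[1], 1)
  if (nrow(preds) > 1) expect_gt(preds$frequency[1], max(preds$frequency[-1]))
  expect_true(is.finite(attr(preds, "empirical_score")))
})

test_that("empirical inter-protein score averages the top four pairs", {
  S <- matrix(0, 4, 9)
  S[1, 5:9] <- c(4, 3, 2, 1, 0)
  full <- rbind(cbind(matrix(0, 4, 4), S[, 5:9]),
                cbind(t(S[, 5:9]), matrix(0, 5, 5)))
  expect_equal(empirical_interprotein_score(full, 4), 2.5)
  Su <- matrix(0.7, 9, 9)
  expect_equal(empirical_interprotein_score(Su, 4), 0.7)
  set.seed(11)
  Sr <- matrix(rnorm(81), 9, 9); Sr <- (Sr + t(Sr)) / 2
  inter <- as.numeric(Sr[1:4, 5:9])
  expect_equal(empirical_interprotein_score(Sr, 4),
               mean(sort(inter, decreasing = TRUE)[1:4]))
  expect_error(empirical_interprotein_score(matrix(0, 2, 2), 1), "at least 4")
})

test_that("the SASA filter applies both burial rules in rank order", {
  preds <- data.frame(residue_A = c(10, 20, 30, 40, 50, 60, 70, 80, 90),
                      residue_B = 1:9,
                      frequency = seq(0.9, 0.1, by = -0.1))
  class(preds) <- c("contact_predictions", "data.frame")
  sA <- setNames(rep(50, 9), preds$residue_A)
  sB <- setNames(rep(60, 9), preds$residue_B)
  all_exposed <- sasa_filter(preds, sA, sB)
  expect_true(all(all_exposed$retained))
  # rank-4 pair contains a residue with SASA 0.6: stop-at-buried keeps top 3
  sA2 <- sA; sA2["40"] <- 0.6
  stopped <- sasa_filter(preds, sA2, sB)
  expect_equal(stopped$retained, c(TRUE, TRUE, TRUE, rep(FALSE, 6)))
  # discard-buried on 9 pairs with 2 buried keeps the 7 others
  sA3 <- sA; sA3["40"] <- 0.6; sA3["80"] <- 0.3
  disc <- sasa_filter(preds, sA3, sB, mode = "discard_buried")
  expect_equal(sum(disc$retained), 7)
  expect_equal(disc$retained, !(preds$residue_A %in% c(40, 80)))
  expect_error(sasa_filter(preds, sA[-3], sB), "30")
})
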