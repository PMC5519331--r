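# Inter-protein direct coupling analysis over stochastically
# paralog-matched paired alignments.

#' Construct a paired (concatenated) two-family alignment
#'
#' @param rows integer matrix of concatenated sequence pairs (states
#'   1..21, 21 = gap).
#' @param boundary number of columns belonging to segment A; segment B is
#'   the rest.
#' @param organism_ids organism per row.
#' @param labels row identifiers.
#' @return An object of class `paired_msa`.
#' @export
paired_msa <- function(rows, boundary, organism_ids, labels = NULL) {
  if (boundary <= 0 || boundary >= ncol(rows))
    stop("boundary must split the alignment into two nonempty segments")
  if (length(organism_ids) != nrow(rows))
    stop("organism_ids must have one entry per row")
  if (is.null(labels)) labels <- as.character(seq_len(nrow(rows)))
  structure(list(rows = rows, boundary = as.integer(boundary),
                 organism_ids = as.character(organism_ids),
                 labels = as.character(labels)),
            class = "paired_msa")
}

#' @export
print.paired_msa <- function(x, ...) {
  cat(sprintf("paired_msa: %d pairs, %d + %d columns, %d organisms\n",
              nrow(x$rows), x$boundary, ncol(x$rows) - x$boundary,
              length(unique(x$organism_ids))))
  invisible(x)
}

.msa_matrix <- function(msa) {
  if (inherits(msa, "paired_msa")) msa$rows
  else if (inherits(msa, "family_msa")) msa$seqs
  else as.matrix(msa)
}

#' Sequence reweighting and effective depth
#'
#' Each sequence is down-weighted by the number of sequences (itself
#' included) with fractional identity at or above `identity_threshold`,
#' identity computed over all columns including gaps. `neff` is the sum
#' of weights.
#'
#' @param msa a `paired_msa`, `family_msa`, or integer matrix.
#' @param identity_threshold default 0.9 (maximum 90\% identity).
#' @return List with `weights` (in (0, 1]) and `neff`.
#' @export
sequence_weights <- function(msa, identity_threshold = 0.9) {
  X <- .msa_matrix(msa)
  if (nrow(X) == 0) stop("empty MSA")
  w <- msa_weights_cpp(X, identity_threshold)
  list(weights = w, neff = sum(w))
}

#' Fit a Potts model by asymmetric pseudo-likelihood
#'
#' Maximizes, independently for each column, the L2-regularized weighted
#' conditional log-likelihood of that column given all others (asymmetric
#' pseudo-likelihood maximization over the 21-state alphabet), then
#' symmetrizes the couplings
#' \eqn{J_{ij} \leftarrow (J_{ij} + J_{ji}^T)/2}. The negative
#' log-pseudolikelihood is normalized by the total sequence weight, and
#' the penalties are \eqn{\lambda_h \|h\|^2 + \lambda_J \|J\|^2}.
#' Optimization is quasi-Newton (L-BFGS-B) per column; convergence is
#' declared at projected-gradient norm below `pgtol`.
#'
#' @param msa a `paired_msa` (or integer matrix with `boundary` passed
#'   through attributes being absent; then scores lose segment structure).
#' @param lambda_J,lambda_h regularization strengths (default 0.01).
#' @param weights optional precomputed weights; default
#'   [sequence_weights()] at 90\% identity.
#' @param maxit,pgtol optimizer controls.
#' @return An object of class `potts_model`: fields `h` (q x N),
#'   symmetrized couplings `J` (N x N x q x q), `boundary`, `neff`,
#'   per-column convergence diagnostics.
#' @export
fit_plm <- function(msa, lambda_J = 0.01, lambda_h = 0.01, weights = NULL,
                    maxit = 1000, pgtol = 1e-5) {
  X <- .msa_matrix(msa)
  N <- ncol(X)
  q <- 21L
  if (N < 2) stop("alignment must have at least 2 columns")
  if (is.null(weights)) weights <- sequence_weights(msa)
  if (weights$neff <= 1) stop("effective number of sequences must exceed 1")
  w <- weights$weights
  h <- matrix(0, q, N)
  Jasym <- array(0, dim = c(N, N, q, q))
  conv <- integer(N)
  value <- numeric(N)
  for (r in seq_len(N)) {
    npar <- q + (N - 1) * q * q
    # optim calls fn and gr separately at the same point; cache the pair
    memo <- list(p = NULL)
    evalboth <- function(p) {
      if (is.null(memo$p) || !identical(p, memo$p))
        memo <<- c(list(p = p), plm_obj_grad(p, X, r, w, lambda_h, lambda_J, q))
      memo
    }
    fn <- function(p) evalboth(p)$value
    gr <- function(p) evalboth(p)$grad
    opt <- optim(numeric(npar), fn, gr, method = "L-BFGS-B",
                 control = list(maxit = maxit, pgtol = pgtol, factr = 0))
    if (opt$convergence != 0 && opt$convergence != 1)
      stop(sprintf("pseudo-likelihood optimizer failed for column %d: code %d (%s)",
                   r, opt$convergence, opt$message))
    if (opt$convergence == 1)
      warning(sprintf("column %d: iteration limit (%d) reached", r, maxit))
    conv[r] <- opt$convergence
    value[r] <- opt$value
    h[, r] <- opt$par[1:q]
    others <- setdiff(seq_len(N), r)
    for (k in seq_along(others)) {
      blk <- matrix(opt$par[q + ((k - 1) * q * q + 1):(k * q * q)], q, q)
      Jasym[r, others[k], , ] <- blk    # J_{r,j}(a_r, b_j)
    }
  }
  J <- array(0, dim = c(N, N, q, q))
  for (i in seq_len(N - 1)) for (j in (i + 1):N) {
    J[i, j, , ] <- (Jasym[i, j, , ] + t(Jasym[j, i, , ])) / 2
    J[j, i, , ] <- t(J[i, j, , ])
  }
  structure(list(h = h, J = J, lambda_J = lambda_J, lambda_h = lambda_h,
                 boundary = if (inherits(msa, "paired_msa")) msa$boundary else NA_integer_,
                 N = N, q = q, neff = weights$neff, weights = w,
                 convergence = conv, objective = value),
            class = "potts_model")
}

#' @export
print.potts_model <- function(x, ...) {
  cat(sprintf("potts_model: %d columns, q = %d, Neff = %.1f, lambda_J = %g\n",
              x$N, x$q, x$neff, x$lambda_J))
  invisible(x)
}

# shift a q x q coupling block to the zero-sum gauge
.zero_sum_gauge <- function(blk) {
  blk - outer(rowMeans(blk), rep(1, ncol(blk))) -
    outer(rep(1, nrow(blk)), colMeans(blk)) + mean(blk)
}

#' Frobenius coupling scores
#'
#' \eqn{S^{raw}_{ij} = \|J_{ij}\|_F}, the Frobenius norm of each local
#' q x q coupling block after shifting it to the zero-sum gauge (the
#' standard gauge for pseudo-likelihood couplings; the norm is taken over
#' the full block including the gap state).
#'
#' @param model a fitted [fit_plm()] model.
#' @param gauge "zero_sum" (default) or "none".
#' @return Symmetric N x N matrix with zero diagonal, entries >= 0.
#' @export
frobenius_scores <- function(model, gauge = c("zero_sum", "none")) {
  gauge <- match.arg(gauge)
  N <- model$N
  S <- matrix(0, N, N)
  for (i in seq_len(N - 1)) for (j in (i + 1):N) {
    blk <- model$J[i, j, , ]
    if (gauge == "zero_sum") blk <- .zero_sum_gauge(blk)
    S[i, j] <- S[j, i] <- sqrt(sum(blk^2))
  }
  S
}

#' Two-segment average product correction
#'
#' \eqn{S_{ij} = S^{raw}_{ij} - S^{raw}_{i.} S^{raw}_{.j} / S^{raw}_{..}}
#' with the averages taken over the two protein segments independently:
#' each of the three blocks (A-A, B-B, A-B) is corrected with its own row,
#' column, and grand means. For intra-segment blocks the self pair (the
#' zero diagonal) is excluded from the means.
#'
#' @param S_raw symmetric matrix of raw Frobenius scores.
#' @param boundary number of columns in segment A.
#' @return Corrected score matrix, same shape, symmetric.
#' @export
apc_correct <- function(S_raw, boundary) {
  N <- nrow(S_raw)
  stopifnot(ncol(S_raw) == N, boundary >= 1, boundary < N)
  if (max(abs(S_raw - t(S_raw))) > 1e-9) stop("S_raw must be symmetric")
  iA <- seq_len(boundary)
  iB <- (boundary + 1):N
  S <- matrix(0, N, N)

  apc_inter <- function(M) {
    g <- mean(M)
    if (g == 0) stop("zero grand mean in inter-segment block")
    M - outer(rowMeans(M), colMeans(M)) / g
  }
  apc_intra <- function(M) {
    n <- nrow(M)
    if (n == 1) return(M * 0)
    rm <- rowSums(M) / (n - 1)           # diagonal (self) excluded
    g <- sum(M) / (n * (n - 1))
    if (g == 0) stop("zero grand mean in intra-segment block")
    out <- M - outer(rm, rm) / g
    diag(out) <- 0
    out
  }

  S[iA, iB] <- apc_inter(S_raw[iA, iB, drop = FALSE])
  S[iB, iA] <- t(S[iA, iB])
  S[iA, iA] <- apc_intra(S_raw[iA, iA, drop = FALSE])
  S[iB, iB] <- apc_intra(S_raw[iB, iB, drop = FALSE])
  S
}

#' Renormalized inter-protein scores
#'
#' \eqn{\tilde S_{ij} = S_{ij} / |\min S^{Inter}| \times (1 + N/N_{eff})}
#' applied to inter-segment pairs only, with the minimum taken over the
#' inter-segment (interface) scores. The multiplicative form is applied
#' exactly as stated; `neff_mode = "divide"` offers the alternative
#' reading in which the depth factor divides instead.
#'
#' @param S APC-corrected score matrix.
#' @param boundary segment-A width.
#' @param N alignment width (defaults to `ncol(S)`).
#' @param neff effective sequence count.
#' @param neff_mode "multiply" (default, as stated) or "divide".
#' @return boundary x (N - boundary) matrix of normalized inter-protein
#'   scores; rows = segment-A columns, columns = segment-B columns.
#' @export
normalize_scores <- function(S, boundary, N = ncol(S), neff,
                             neff_mode = c("multiply", "divide")) {
  neff_mode <- match.arg(neff_mode)
  inter <- S[seq_len(boundary), (boundary + 1):ncol(S), drop = FALSE]
  if (length(inter) == 0) stop("empty inter-segment block")
  mn <- abs(min(inter))
  if (mn == 0) stop("minimum inter-segment score is 0; cannot renormalize")
  fac <- 1 + N / neff
  if (neff_mode == "multiply") inter / mn * fac else inter / mn / fac
}

#' Frobenius, APC, and renormalized scores in one shot
#'
#' @param model a fitted [fit_plm()] model with a segment boundary.
#' @param neff_mode passed to [normalize_scores()].
#' @return An object of class `score_matrix`: `S_raw`, `S` (APC),
#'   `S_tilde` (inter-segment only), `boundary`, `N`, `neff`.
#' @export
dca_scores <- function(model, neff_mode = c("multiply", "divide")) {
  if (is.na(model$boundary)) stop("model has no segment boundary")
  S_raw <- frobenius_scores(model)
  S <- apc_correct(S_raw, model$boundary)
  S_tilde <- normalize_scores(S, model$boundary, model$N, model$neff,
                              match.arg(neff_mode))
  structure(list(S_raw = S_raw, S = S, S_tilde = S_tilde,
                 boundary = model$boundary, N = model$N, neff = model$neff),
            class = "score_matrix")
}

#' Empirical inter-protein coevolution score
#'
#' Mean of the four strongest inter-segment APC-corrected scores; a
#' family-pair-level summary of inter-protein coevolution strength.
#'
#' @param S APC-corrected score matrix (full N x N).
#' @param boundary segment-A width.
#' @return Scalar.
#' @export
empirical_interprotein_score <- function(S, boundary) {
  inter <- S[seq_len(boundary), (boundary + 1):ncol(S), drop = FALSE]
  if (length(inter) < 4) stop("need at least 4 inter-segment pairs")
  mean(sort(as.numeric(inter), decreasing = TRUE)[1:4])
}

#' One stochastic paralog-matching realization
#'
#' Within each organism shared by the two families, sequences are paired
#' uniformly at random without replacement until the smaller family is
#' exhausted; leftovers stay unpaired. Organisms with exactly one
#' sequence in each family are therefore paired deterministically and
#' appear identically in every realization. Each sequence occurs at most
#' once in the result.
#'
#' @param family_A,family_B [family_msa()] objects.
#' @param seed optional integer seed.
#' @return A [paired_msa()] with attribute `pairing` (data.frame of row
#'   indices paired).
#' @export
random_match <- function(family_A, family_B, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  shared <- intersect(unique(family_A$organism_ids),
                      unique(family_B$organism_ids))
  if (length(shared) == 0) stop("families share no organisms")
  rowsA <- integer(0)
  rowsB <- integer(0)
  for (org in shared) {
    ia <- which(family_A$organism_ids == org)
    ib <- which(family_B$organism_ids == org)
    k <- min(length(ia), length(ib))
    ia <- if (length(ia) > 1) sample(ia) else ia
    ib <- if (length(ib) > 1) sample(ib) else ib
    rowsA <- c(rowsA, ia[seq_len(k)])
    rowsB <- c(rowsB, ib[seq_len(k)])
  }
  pm <- paired_msa(cbind(family_A$seqs[rowsA, , drop = FALSE],
                         family_B$seqs[rowsB, , drop = FALSE]),
                   boundary = ncol(family_A$seqs),
                   organism_ids = family_A$organism_ids[rowsA],
                   labels = paste(family_A$labels[rowsA],
                                  family_B$labels[rowsB], sep = "|"))
  attr(pm, "pairing") <- data.frame(row_A = rowsA, row_B = rowsB)
  pm
}

#' Selection frequencies over a random-matching ensemble
#'
#' Generates `n_realizations` stochastically matched paired alignments,
#' runs the full DCA pipeline on each (reweighting, asymmetric
#' pseudo-likelihood fit, Frobenius scores, two-segment APC,
#' renormalization), records every inter-protein pair whose normalized
#' score exceeds `score_threshold`, and reports for each pair the
#' fraction of realizations selecting it. A master seed spawns one
#' sub-seed per realization.
#'
#' @param family_A,family_B [family_msa()] objects.
#' @param n_realizations number of matching realizations (default 1000).
#' @param score_threshold normalized-score threshold (default 0.8).
#' @param seed master seed.
#' @param lambda_J,lambda_h,identity_threshold,neff_mode,maxit passed to
#'   the pipeline stages.
#' @param ref_map_A,ref_map_B optional integer vectors mapping alignment
#'   columns to reference residue numbering (default: column index).
#' @return data.frame of class `contact_predictions` with columns
#'   column_A, column_B, residue_A, residue_B, frequency, sorted by
#'   frequency descending (ties by residue pair); attribute
#'   `empirical_score` holds the realization-averaged mean of the top-4
#'   inter-protein APC scores, attribute `n_realizations` the ensemble
#'   size.
#' @export
selection_frequencies <- function(family_A, family_B, n_realizations = 1000,
                                  score_threshold = 0.8, seed = NULL,
                                  lambda_J = 0.01, lambda_h = 0.01,
                                  identity_threshold = 0.9,
                                  neff_mode = c("multiply", "divide"),
                                  maxit = 1000,
                                  ref_map_A = NULL, ref_map_B = NULL) {
  neff_mode <- match.arg(neff_mode)
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, n_realizations)
  nA <- ncol(family_A$seqs)
  nB <- ncol(family_B$seqs)
  counts <- matrix(0L, nA, nB)
  emp <- numeric(n_realizations)
  for (t in seq_len(n_realizations)) {
    pm <- random_match(family_A, family_B, seed = seeds[t])
    w <- sequence_weights(pm, identity_threshold)
    model <- fit_plm(pm, lambda_J = lambda_J, lambda_h = lambda_h,
                     weights = w, maxit = maxit)
    sc <- dca_scores(model, neff_mode = neff_mode)
    emp[t] <- empirical_interprotein_score(sc$S, sc$boundary)
    sel <- which(sc$S_tilde > score_threshold, arr.ind = TRUE)
    if (nrow(sel)) counts[sel] <- counts[sel] + 1L
  }
  hit <- which(counts > 0, arr.ind = TRUE)
  if (is.null(ref_map_A)) ref_map_A <- seq_len(nA)
  if (is.null(ref_map_B)) ref_map_B <- seq_len(nB)
  out <- data.frame(column_A = hit[, 1], column_B = hit[, 2],
                    residue_A = ref_map_A[hit[, 1]],
                    residue_B = ref_map_B[hit[, 2]],
                    frequency = counts[hit] / n_realizations)
  out <- out[order(-out$frequency, out$residue_A, out$residue_B), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "empirical_score") <- mean(emp)
  attr(out, "n_realizations") <- n_realizations
  class(out) <- c("contact_predictions", "data.frame")
  out
}

#' Solvent-exposure filter for predicted contacts
#'
#' Annotates predictions with per-residue SASA and applies one of two
#' burial rules while walking the list in descending selection
#' frequency: `"stop_at_buried"` retains contacts until the first pair
#' containing a buried residue (SASA below `burial_threshold`) and drops
#' that pair and everything ranked below it; `"discard_buried"` drops
#' only the pairs containing a buried residue and keeps the rest.
#'
#' @param predictions a `contact_predictions` data.frame.
#' @param sasa_A,sasa_B per-residue SASA for the two partners: either the
#'   data.frame returned by [compute_sasa()] or a named numeric vector
#'   keyed by residue id.
#' @param burial_threshold A^2 (default 1).
#' @param mode burial rule (see above).
#' @return `predictions` with added columns sasa_A, sasa_B, retained.
#' @export
sasa_filter <- function(predictions, sasa_A, sasa_B, burial_threshold = 1,
                        mode = c("stop_at_buried", "discard_buried")) {
  mode <- match.arg(mode)
  lookup <- function(sasa, ids, side) {
    if (is.data.frame(sasa)) sasa <- setNames(sasa$sasa, sasa$residue_id)
    v <- sasa[as.character(ids)]
    if (anyNA(v))
      stop(sprintf("no SASA for residue(s) %s of partner %s",
                   paste(unique(ids[is.na(v)]), collapse = ", "), side))
    unname(v)
  }
  ord <- order(-predictions$frequency, predictions$residue_A,
               predictions$residue_B)
  predictions <- predictions[ord, , drop = FALSE]
  predictions$sasa_A <- lookup(sasa_A, predictions$residue_A, "A")
  predictions$sasa_B <- lookup(sasa_B, predictions$residue_B, "B")
  buried <- predictions$sasa_A < burial_threshold |
    predictions$sasa_B < burial_threshold
  if (mode == "stop_at_buried") {
    first <- if (any(buried)) which(buried)[1] else nrow(predictions) + 1L
    predictions$retained <- seq_len(nrow(predictions)) < first
  } else {
    predictions$retained <- !buried
  }
  predictions
}

#' Per-residue solvent accessible surface area
#'
#' Rolling-probe (Shrake-Rupley) SASA on a full-atom structure, summed
#' per residue, with a normalized value relative to a per-residue
#' reference maximum. C-alpha-only models are rejected: burial cannot be
#' judged from backbone traces.
#'
#' @param pdb path/text of a full-atom PDB, or a bio3d `pdb` object.
#' @param chain optional chain filter.
#' @param probe probe radius, A (default 1.4).
#' @param n_points test points per atom (default 960).
#' @param reference_table named vector of reference maximal SASA per
#'   one-letter code (default [default_max_sasa_table()]).
#' @return data.frame with residue_id, residue_type, sasa (A^2),
#'   normalized.
#' @export
compute_sasa <- function(pdb, chain = NULL, probe = 1.4, n_points = 960,
                         reference_table = default_max_sasa_table()) {
  pdbobj <- .read_pdb_any(pdb)
  atoms <- pdbobj$atom[pdbobj$atom$type == "ATOM", , drop = FALSE]
  if (!is.null(chain)) atoms <- atoms[atoms$chain %in% chain, , drop = FALSE]
  if (nrow(atoms) == 0) stop("no atoms selected")
  per_res <- table(atoms$resno)
  if (max(per_res) == 1 && all(atoms$elety == "CA"))
    stop("structure is C-alpha-only; SASA needs full-atom coordinates")
  if (any(per_res < 4))
    warning(sprintf("%d residue(s) have fewer than 4 atoms; SASA may be incomplete",
                    sum(per_res < 4)))
  elem <- toupper(sub("^[0-9]*", "", substr(trimws(atoms$elety), 1, 1)))
  elem[trimws(atoms$elety) == "SE"] <- "SE"
  radii <- .ELEMENT_RADII[elem]
  radii[is.na(radii)] <- 1.70
  sasa_atom <- shrake_rupley_cpp(cbind(atoms$x, atoms$y, atoms$z),
                                 unname(radii), probe, as.integer(n_points))
  agg <- aggregate(sasa_atom, by = list(residue_id = atoms$resno), FUN = sum)
  types <- unname(.AA3TO1[atoms$resid[match(agg$residue_id, atoms$resno)]])
  ref <- reference_table[types]
  data.frame(residue_id = agg$residue_id, residue_type = types,
             sasa = agg$x, normalized = agg$x / unname(ref))
}
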