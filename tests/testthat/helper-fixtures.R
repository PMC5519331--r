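# Programmatic fixtures: synthetic PDB text, alignments, fabricated
# ensembles. Everything is generated in code at test time.

pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          occ = 1, b = 0, elem = substr(name, 1, 1),
                          altloc = " ", icode = " ") {
  sprintf("ATOM  %5d  %-3s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, altloc, resname, chain, resno, icode, x, y, z,
          occ, b, elem)
}

# C-alpha-only PDB text for given residues
make_ca_pdb <- function(resnos, resnames, coords, chain = "A") {
  lines <- character(0)
  for (k in seq_along(resnos))
    lines <- c(lines, pdb_atom_line(k, "CA", resnames[k], chain, resnos[k],
                                    coords[k, 1], coords[k, 2], coords[k, 3],
                                    elem = "C"))
  paste(c(lines, "END"), collapse = "\n")
}

# full-atom glycine (N, CA, C, O) centered near `center`
gly_atoms <- function(center = c(0, 0, 0), resno = 1, chain = "A",
                      serial0 = 0) {
  pos <- rbind(N = c(-0.57, 1.34, 0), CA = c(0, 0, 0),
               C = c(1.52, 0, 0), O = c(2.15, 1.06, 0))
  pos <- sweep(pos, 2, center, "+")
  vapply(seq_len(4), function(k)
    pdb_atom_line(serial0 + k, rownames(pos)[k], "GLY", chain, resno,
                  pos[k, 1], pos[k, 2], pos[k, 3],
                  elem = substr(rownames(pos)[k], 1, 1)),
    character(1))
}

write_fasta <- function(seqs, ids, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  for (k in seq_along(seqs)) {
    writeLines(paste0(">", ids[k]), con)
    writeLines(seqs[k], con)
  }
  path
}

write_taxonomy <- function(ids, organisms, path) {
  write.table(data.frame(ids, organisms), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  path
}

# Fabricate a complex_ensemble with prescribed poses for a single replica.
# Energies are in kcal/mol; temperature defaults to 300 K.
fake_ensemble <- function(A, B, trans, quat = NULL, energy = NULL,
                          box_edge = 200, temperature = 300) {
  n <- nrow(trans)
  if (is.null(quat)) quat <- matrix(rep(c(1, 0, 0, 0), each = n), n, 4)
  if (is.null(energy)) energy <- rep(0, n)
  tr <- array(NA_real_, c(n, 1, 3)); tr[, 1, ] <- trans
  qu <- array(NA_real_, c(n, 1, 4)); qu[, 1, ] <- quat
  structure(list(trans = tr, quat = qu,
                 energy = matrix(energy, n, 1), ladder = temperature,
                 box_edge = box_edge, record_stride = 1, n_steps = n,
                 A = A, B = B,
                 B_local = sweep(B$coords, 2, colMeans(B$coords)),
                 model = NULL, acceptance = 1, swap_acceptance = numeric(0),
                 bound_mask = NULL),
            class = "complex_ensemble")
}

# random small bead body
random_body <- function(n, seed, label = "body") {
  set.seed(seed)
  rigid_body_structure(seq_len(n), sample(c("G", "A", "S", "L"), n, TRUE),
                       matrix(runif(3 * n, 0, 10), n, 3), label = label)
}
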