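# Structure and alignment ingestion, and contact-table output.

#' Construct a rigid-body bead structure
#'
#' One interaction site (bead) per residue, centered on the C-alpha atom.
#'
#' @param residue_ids integer vector, author (PDB) residue numbering,
#'   strictly increasing.
#' @param residue_types one-letter amino-acid codes.
#' @param coords numeric matrix, n x 3, C-alpha positions in Angstrom.
#' @param charges signed elementary charges per residue; defaults to the
#'   package charge table applied to `residue_types`.
#' @param label free-text label.
#' @return An object of class `rigid_body_structure`.
#' @export
rigid_body_structure <- function(residue_ids, residue_types, coords,
                                 charges = NULL, label = "") {
  coords <- as.matrix(coords)
  n <- length(residue_ids)
  stopifnot(is.numeric(coords), ncol(coords) == 3)
  if (nrow(coords) != n || length(residue_types) != n)
    stop("residue_ids, residue_types and coords must describe the same number of residues")
  if (any(diff(residue_ids) <= 0))
    stop("residue_ids must be strictly increasing")
  if (is.null(charges)) {
    tab <- default_charge_table()
    charges <- unname(ifelse(residue_types %in% names(tab), tab[residue_types], 0))
  }
  if (length(charges) != n) stop("charges must have one value per residue")
  structure(list(residue_ids = as.integer(residue_ids),
                 residue_types = as.character(residue_types),
                 coords = unname(coords), charges = as.numeric(charges),
                 label = label),
            class = "rigid_body_structure")
}

#' @export
print.rigid_body_structure <- function(x, ...) {
  cat(sprintf("rigid_body_structure '%s': %d beads, residues %d-%d, net charge %+.1f\n",
              x$label, length(x$residue_ids), min(x$residue_ids),
              max(x$residue_ids), sum(x$charges)))
  invisible(x)
}

#' Read a rigid-body structure from a PDB file
#'
#' Extracts one bead per residue at the C-alpha position for the requested
#' chain and inclusive residue range, preserving author numbering
#' end-to-end so reported contacts stay in the deposited numbering. When
#' alternate locations are present the highest-occupancy one is kept;
#' residues with insertion codes are rejected with a warning. Charges are
#' assigned from `charge_table` (see [default_charge_table()]).
#'
#' @param pdb path to a PDB file, or the text of one.
#' @param chain chain identifier.
#' @param residue_range inclusive `c(first, last)` author numbering, or
#'   NULL for all residues of the chain.
#' @param charge_table named numeric vector, charge per one-letter code.
#' @param label free-text label; defaults to file/chain.
#' @return A [rigid_body_structure()].
#' @export
read_structure <- function(pdb, chain, residue_range = NULL,
                           charge_table = default_charge_table(),
                           label = NULL) {
  pdbobj <- .read_pdb_any(pdb)
  atoms <- pdbobj$atom
  atoms <- atoms[atoms$chain %in% chain & atoms$elety == "CA", , drop = FALSE]
  if (nrow(atoms) == 0)
    stop(sprintf("chain '%s' not found or has no C-alpha atoms", chain))
  if (any(!is.na(atoms$insert) & atoms$insert != "")) {
    bad <- unique(atoms$resno[!is.na(atoms$insert) & atoms$insert != ""])
    warning(sprintf("dropping residues with insertion codes: %s",
                    paste(bad, collapse = ", ")))
    atoms <- atoms[is.na(atoms$insert) | atoms$insert == "", , drop = FALSE]
  }
  # alternate locations: keep highest occupancy per residue
  if (anyDuplicated(atoms$resno)) {
    occ <- ifelse(is.na(atoms$o), 1, atoms$o)
    atoms <- atoms[order(atoms$resno, -occ), , drop = FALSE]
    atoms <- atoms[!duplicated(atoms$resno), , drop = FALSE]
  }
  atoms <- atoms[order(atoms$resno), , drop = FALSE]
  if (is.null(residue_range)) residue_range <- range(atoms$resno)
  wanted <- seq(residue_range[1], residue_range[2])
  missing <- setdiff(wanted, atoms$resno)
  if (length(missing))
    stop(sprintf("missing residues in range %d-%d: %s", residue_range[1],
                 residue_range[2], paste(missing, collapse = ", ")))
  atoms <- atoms[atoms$resno %in% wanted, , drop = FALSE]
  types <- unname(.AA3TO1[atoms$resid])
  if (anyNA(types)) {
    bad <- unique(atoms$resid[is.na(types)])
    stop(sprintf("nonstandard residue type(s): %s", paste(bad, collapse = ", ")))
  }
  if (is.null(label))
    label <- sprintf("%s:%s", if (is.character(pdb) && length(pdb) == 1 &&
                                  file.exists(pdb)) basename(pdb) else "pdb", chain)
  ch <- unname(ifelse(types %in% names(charge_table), charge_table[types], 0))
  rigid_body_structure(atoms$resno, types,
                       cbind(atoms$x, atoms$y, atoms$z), ch, label)
}

.read_pdb_any <- function(pdb) {
  if (inherits(pdb, "pdb")) return(pdb)
  if (is.character(pdb) && length(pdb) == 1 && !grepl("\n", pdb) &&
      file.exists(pdb)) {
    return(bio3d::read.pdb(pdb, rm.alt = FALSE, verbose = FALSE))
  }
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(if (length(pdb) > 1) pdb else strsplit(pdb, "\n")[[1]], tf)
  bio3d::read.pdb(tf, rm.alt = FALSE, verbose = FALSE)
}

# ---- alignments -------------------------------------------------------------

.aa_to_int <- function(chr_mat) {
  m <- match(chr_mat, .ALPHABET21)
  dim(m) <- dim(chr_mat)
  m
}

.int_to_aa <- function(int_mat) {
  m <- .ALPHABET21[int_mat]
  dim(m) <- dim(int_mat)
  m
}

#' Construct a single-family MSA object
#'
#' @param seqs character matrix (rows = aligned sequences over the
#'   20-letter alphabet plus '-') or integer matrix with states 1..21
#'   (21 = gap).
#' @param organism_ids taxonomy identifier per row.
#' @param labels row identifiers; defaults to rownames or seq numbers.
#' @return An object of class `family_msa` holding the integer-encoded
#'   alignment.
#' @export
family_msa <- function(seqs, organism_ids, labels = NULL) {
  if (is.character(seqs)) {
    seqs[seqs %in% c(".", "")] <- .GAP
    seqs <- toupper(seqs)
    bad <- !(seqs %in% .ALPHABET21)
    if (any(bad)) {
      warning(sprintf("mapping %d nonstandard letters (%s) to gap",
                      sum(bad), paste(unique(seqs[bad]), collapse = ",")))
      seqs[bad] <- .GAP
    }
    seqs <- .aa_to_int(seqs)
  }
  if (is.null(labels)) labels <- rownames(seqs)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(seqs)))
  if (length(organism_ids) != nrow(seqs))
    stop("organism_ids must have one entry per alignment row")
  if (anyNA(seqs) || any(seqs < 1 | seqs > 21))
    stop("alignment states must lie in 1..21")
  rownames(seqs) <- NULL
  structure(list(seqs = seqs, organism_ids = as.character(organism_ids),
                 labels = as.character(labels), alphabet = .ALPHABET21),
            class = "family_msa")
}

#' @export
print.family_msa <- function(x, ...) {
  cat(sprintf("family_msa: %d sequences x %d columns, %d organisms\n",
              nrow(x$seqs), ncol(x$seqs), length(unique(x$organism_ids))))
  invisible(x)
}

#' Read a family alignment with taxonomy
#'
#' Reads a FASTA or Stockholm alignment, maps nonstandard letters
#' (B, Z, X, U, O, '.') to gaps with a warning, removes rows with more
#' than `max_gap_frac` gapped positions (reporting the count), and
#' attaches an organism identifier to every surviving row from a
#' two-column id-to-organism table.
#'
#' @param msa path to the alignment (FASTA or Stockholm).
#' @param taxonomy two-column data.frame (id, organism) or path to a
#'   headerless two-column TSV.
#' @param format "auto" sniffs Stockholm's "# STOCKHOLM" header.
#' @param max_gap_frac rows with gap fraction strictly above this are
#'   removed (default 0.10).
#' @param on_missing_organism "error" (default) or "skip" rows whose id is
#'   absent from the taxonomy table (skipping warns).
#' @return A [family_msa()].
#' @export
read_family_msa <- function(msa, taxonomy,
                            format = c("auto", "fasta", "stockholm"),
                            max_gap_frac = 0.10,
                            on_missing_organism = c("error", "skip")) {
  format <- match.arg(format)
  on_missing_organism <- match.arg(on_missing_organism)
  if (format == "auto") {
    first <- readLines(msa, n = 1)
    format <- if (grepl("^# STOCKHOLM", first)) "stockholm" else "fasta"
  }
  if (format == "fasta") {
    ali <- bio3d::read.fasta(msa)$ali
  } else {
    if (!requireNamespace("Biostrings", quietly = TRUE))
      stop("reading Stockholm alignments requires the Biostrings package")
    aln <- Biostrings::readAAMultipleAlignment(msa, format = "stockholm")
    seqs <- as.character(Biostrings::unmasked(aln))
    ali <- do.call(rbind, strsplit(seqs, ""))
    rownames(ali) <- names(seqs)
  }
  ids <- rownames(ali)
  ali <- toupper(ali)
  ali[ali == "."] <- .GAP
  bad <- !(ali %in% .ALPHABET21)
  if (any(bad)) {
    warning(sprintf("mapping %d nonstandard letters (%s) to gap", sum(bad),
                    paste(sort(unique(ali[bad])), collapse = ",")))
    ali[bad] <- .GAP
  }
  gap_frac <- rowMeans(ali == .GAP)
  keep <- gap_frac <= max_gap_frac
  if (any(!keep))
    message(sprintf("removed %d/%d rows with more than %.0f%% gaps",
                    sum(!keep), length(keep), 100 * max_gap_frac))
  ali <- ali[keep, , drop = FALSE]
  ids <- ids[keep]

  if (is.character(taxonomy) && length(taxonomy) == 1)
    taxonomy <- read.table(taxonomy, sep = "\t", header = FALSE,
                           col.names = c("id", "organism"),
                           colClasses = "character", quote = "")
  org <- taxonomy$organism[match(ids, taxonomy$id)]
  if (anyNA(org)) {
    miss <- ids[is.na(org)]
    if (on_missing_organism == "error")
      stop(sprintf("no organism for row(s): %s",
                   paste(head(miss, 5), collapse = ", ")))
    warning(sprintf("skipping %d rows without organism", length(miss)))
    keep2 <- !is.na(org)
    ali <- ali[keep2, , drop = FALSE]
    ids <- ids[keep2]
    org <- org[keep2]
  }
  family_msa(ali, org, ids)
}

# ---- contact tables ---------------------------------------------------------

#' Write a contact-prediction table
#'
#' Tab-separated with columns residue_A, residue_B, selection_frequency,
#' SASA_A, SASA_B, retained_flag. Rows are ordered by frequency
#' descending, ties broken lexicographically by (residue_A, residue_B).
#'
#' @param predictions data.frame of contact predictions (see
#'   [selection_frequencies()]); missing SASA/retained columns are written
#'   as NA.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_contact_table <- function(predictions, path) {
  cols <- c("residue_A", "residue_B", "selection_frequency",
            "SASA_A", "SASA_B", "retained_flag")
  n <- length(predictions$residue_A)
  pick <- function(x) if (is.null(x)) rep(NA, n) else x
  df <- data.frame(residue_A = predictions$residue_A,
                   residue_B = predictions$residue_B,
                   selection_frequency = predictions$frequency,
                   SASA_A = as.numeric(pick(predictions$sasa_A)),
                   SASA_B = as.numeric(pick(predictions$sasa_B)),
                   retained_flag = as.logical(pick(predictions$retained)))
  df <- df[order(-df$selection_frequency, df$residue_A, df$residue_B), ,
           drop = FALSE]
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(cols, collapse = "\t"), con)
  if (nrow(df))
    write.table(format(df, trim = TRUE, digits = 15, scientific = FALSE),
                con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  invisible(path)
}

#' Read back a contact-prediction table
#'
#' Inverse of [write_contact_table()].
#'
#' @param path path to a table written by [write_contact_table()].
#' @return data.frame with columns residue_A, residue_B, frequency,
#'   sasa_A, sasa_B, retained.
#' @export
read_contact_table <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, na.strings = "NA")
  data.frame(residue_A = as.integer(df$residue_A),
             residue_B = as.integer(df$residue_B),
             frequency = as.numeric(df$selection_frequency),
             sasa_A = as.numeric(df$SASA_A), sasa_B = as.numeric(df$SASA_B),
             retained = as.logical(df$retained_flag))
}
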