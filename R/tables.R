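# Reference tables for the coarse-grained model and SASA normalization.

# canonical one-letter amino-acid alphabet (alphabetical) and the gap symbol
.AA1 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
.GAP <- "-"
.ALPHABET21 <- c(.AA1, .GAP)

#' Default per-residue charge table
#'
#' Signed elementary charges used by the coarse-grained electrostatics:
#' Lys/Arg +1, Asp/Glu -1, His +0.5 (a common compromise for its partial
#' protonation near neutral pH), all other residues 0. Histidine's value is
#' a modelling choice and can be overridden by passing a modified table to
#' [read_structure()].
#'
#' @return Named numeric vector over the 20 one-letter residue codes.
#' @export
default_charge_table <- function() {
  ch <- setNames(numeric(length(.AA1)), .AA1)
  ch[c("K", "R")] <- 1
  ch[c("D", "E")] <- -1
  ch["H"] <- 0.5
  ch
}

# Kyte-Doolittle hydropathy index
.KD_HYDROPATHY <- c(
  A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2,
  I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5,
  R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3)

# mean residue volumes (A^3), used to derive per-residue bead diameters
.RES_VOLUME <- c(
  A = 88.6, C = 108.5, D = 111.1, E = 138.4, F = 189.9, G = 60.1,
  H = 153.2, I = 166.7, K = 168.6, L = 166.7, M = 162.9, N = 114.1,
  P = 112.7, Q = 143.8, R = 173.4, S = 89.0, T = 116.1, V = 140.0,
  W = 227.8, Y = 193.6)

#' Reference maximum solvent accessibilities
#'
#' Theoretical maximum per-residue SASA values (A^2, tripeptide context)
#' used to normalize raw per-residue SASA into relative accessibility.
#' Override by passing your own named vector to [compute_sasa()].
#'
#' @return Named numeric vector over the 20 one-letter residue codes.
#' @export
default_max_sasa_table <- function() {
  c(A = 129, C = 167, D = 193, E = 223, F = 240, G = 104, H = 224,
    I = 197, K = 236, L = 201, M = 224, N = 195, P = 159, Q = 225,
    R = 274, S = 155, T = 172, V = 174, W = 285, Y = 263)
}

# van der Waals radii by element (A) for SASA
.ELEMENT_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20,
                    P = 1.80, SE = 1.90)

# three-letter -> one-letter residue codes
.AA3TO1 <- c(
  ALA = "A", CYS = "C", ASP = "D", GLU = "E", PHE = "F", GLY = "G",
  HIS = "H", ILE = "I", LYS = "K", LEU = "L", MET = "M", ASN = "N",
  PRO = "P", GLN = "Q", ARG = "R", SER = "S", THR = "T", VAL = "V",
  TRP = "W", TYR = "Y")

#' Default contact-potential well depths
#'
#' A documented default pairwise epsilon table (kcal/mol) derived from the
#' Kyte-Doolittle hydropathy scale: with \eqn{h'} the hydropathy rescaled to
#' \eqn{[0,1]}, \eqn{\epsilon_{ij} = -\lambda\,((h'_i + h'_j)/2 - e_0)}.
#' Hydrophobic pairs are attractive (negative), polar pairs mildly
#' repulsive. This is a generic stand-alone parameterization intended for
#' toy systems and method development; production docking should load a
#' calibrated statistical contact table via `param_file` in
#' [energy_model()].
#'
#' @param lambda overall energy scale, kcal/mol.
#' @param e0 neutral point of the rescaled hydropathy (dimensionless).
#' @return 20 x 20 named numeric matrix, symmetric.
#' @export
default_epsilon_table <- function(lambda = 1.2, e0 = 0.5) {
  h <- (.KD_HYDROPATHY[.AA1] + 4.5) / 9
  eps <- -lambda * (outer(h, h, "+") / 2 - e0)
  dimnames(eps) <- list(.AA1, .AA1)
  eps
}

#' Default contact radii
#'
#' Pairwise contact radii (A) from per-residue bead diameters
#' \eqn{\sigma_i = 2 (3 V_i / 4\pi)^{1/3}} with \eqn{V_i} the mean residue
#' volume; \eqn{\sigma_{ij} = (\sigma_i + \sigma_j)/2}.
#'
#' @return 20 x 20 named numeric matrix, symmetric.
#' @export
default_sigma_table <- function() {
  sig1 <- 2 * (3 * .RES_VOLUME[.AA1] / (4 * pi))^(1 / 3)
  sig <- outer(sig1, sig1, "+") / 2
  dimnames(sig) <- list(.AA1, .AA1)
  sig
}
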