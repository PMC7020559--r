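# Donor / acceptor chemistry tables for distance-only hydrogen-bond
# detection, and the charged-group atom sets used for salt bridges.
#
# The donor table lists heavy atoms carrying at least one polar hydrogen;
# the acceptor table lists N/O atoms with an accessible lone pair. Backbone
# amide N is a donor in every residue except proline; backbone carbonyl O
# (and a terminal OXT) is always an acceptor. His ND1/NE2, Ser OG, Thr OG1
# and Tyr OH are bifunctional. Sulfur (Cys SG donor, Met SD acceptor) is
# excluded by default: the criteria target conventional OH--O / OH--N
# bonds.

.SIDECHAIN_DONORS <- list(
  ARG = c("NE", "NH1", "NH2"),
  ASN = "ND2",
  GLN = "NE2",
  HIS = c("ND1", "NE2"),
  LYS = "NZ",
  SER = "OG",
  THR = "OG1",
  TRP = "NE1",
  TYR = "OH"
)

.SIDECHAIN_ACCEPTORS <- list(
  ASN = "OD1",
  ASP = c("OD1", "OD2"),
  GLN = "OE1",
  GLU = c("OE1", "OE2"),
  HIS = c("ND1", "NE2"),
  SER = "OG",
  THR = "OG1",
  TYR = "OH"
)

# salt-bridge partners: acidic carboxyl oxygens vs basic side-chain nitrogens
.ACIDIC_ATOMS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
.BASIC_ATOMS <- list(ARG = c("NH1", "NH2", "NE"), LYS = "NZ",
                     HIS = c("ND1", "NE2"))

# residues whose side chains commonly take part in conventional hydrogen
# bonds (hydroxyl, amide, aromatic N/O, charged groups)
.HBOND_PRONE <- c("S", "T", "N", "Q", "H", "Y", "W", "D", "E", "R", "K")
.POSITIVE <- c("R", "K", "H")
.NEGATIVE <- c("D", "E")

#' Hydrogen-bond donor heavy atoms of a residue
#'
#' @param residue_name Three-letter residue code (e.g. "ARG").
#' @param include_sulfur Include Cys SG as a (non-conventional) donor.
#' @return Character vector of PDB atom names that can act as hydrogen-bond
#'   donors. The backbone amide "N" is included for every canonical residue
#'   except proline, whose ring nitrogen carries no hydrogen. Unknown
#'   residue names yield an empty set with a warning.
#' @export
donor_atoms <- function(residue_name, include_sulfur = FALSE) {
  if (!(residue_name %in% .AA3)) {
    warning("unknown residue name: ", residue_name)
    return(character(0))
  }
  out <- if (residue_name == "PRO") character(0) else "N"
  out <- c(out, .SIDECHAIN_DONORS[[residue_name]])
  if (include_sulfur && residue_name == "CYS") out <- c(out, "SG")
  out
}

#' Hydrogen-bond acceptor heavy atoms of a residue
#'
#' @inheritParams donor_atoms
#' @param include_sulfur Include Met SD as a (non-conventional) acceptor.
#' @return Character vector of atom names acting as acceptors; the backbone
#'   carbonyl "O" and terminal "OXT" are always included.
#' @export
acceptor_atoms <- function(residue_name, include_sulfur = FALSE) {
  if (!(residue_name %in% .AA3)) {
    warning("unknown residue name: ", residue_name)
    return(character(0))
  }
  out <- c("O", "OXT", .SIDECHAIN_ACCEPTORS[[residue_name]])
  if (include_sulfur && residue_name == "MET") out <- c(out, "SD")
  out
}
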