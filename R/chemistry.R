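# donor/acceptor chemistry for hydrogen-free contact criteria (deposited
# cryo-EM models carry no hydrogens, so typing is by heavy atom)

RNA_RESIDUES <- c("A", "C", "G", "U", "RA", "RC", "RG", "RU")
DNA_RESIDUES <- c("DA", "DC", "DG", "DT", "T")
NUCLEIC_RESIDUES <- c(RNA_RESIDUES, DNA_RESIDUES)

is_nucleic <- function(resid) toupper(resid) %in% NUCLEIC_RESIDUES
is_purine <- function(resid) toupper(resid) %in% c("A", "G", "RA", "RG", "DA", "DG")

# base letter (A/C/G/U/T) from a residue name
base_letter <- function(resid) {
  r <- toupper(resid)
  r <- sub("^[RD]", "", r)
  ifelse(r %in% c("A", "C", "G", "U", "T"), r, NA_character_)
}

glycosidic_n <- function(resid) if (is_purine(resid)) "N9" else "N1"

# base-edge donor/acceptor atoms used for base pairing
BASE_DONORS <- list(A = "N6", G = c("N1", "N2"), C = "N4", U = "N3", T = "N3")
BASE_ACCEPTORS <- list(A = c("N1", "N3", "N7"), G = c("O6", "N7", "N3"),
                       C = c("N3", "O2"), U = c("O2", "O4"), T = c("O2", "O4"))

BASE_RING_ATOMS <- list(
  A = c("N9", "C8", "N7", "C5", "C4", "N1", "C2", "N3", "C6"),
  G = c("N9", "C8", "N7", "C5", "C4", "N1", "C2", "N3", "C6"),
  C = c("N1", "C2", "N3", "C4", "C5", "C6"),
  U = c("N1", "C2", "N3", "C4", "C5", "C6"),
  T = c("N1", "C2", "N3", "C4", "C5", "C6"))

PHOSPHATE_O <- c("OP1", "OP2", "O1P", "O2P", "OP3", "O3P")

PROTEIN_SIDE_DONORS <- list(
  ARG = c("NE", "NH1", "NH2"), LYS = "NZ", HIS = c("ND1", "NE2"),
  ASN = "ND2", GLN = "NE2", SER = "OG", THR = "OG1", TYR = "OH", TRP = "NE1")
PROTEIN_SIDE_ACCEPTORS <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH", HIS = c("ND1", "NE2"))

CATION_ATOMS <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ",
                     HIS = c("ND1", "NE2"))
ANION_PROTEIN <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

AROMATIC_RINGS <- list(
  PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2")),
  TRP = list(c("CG", "CD1", "CD2", "NE1", "CE2"),
             c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2")))

AMINO3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
            "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
            "TYR", "VAL")

is_protein <- function(resid) toupper(resid) %in% AMINO3

# TRUE for atoms able to donate a hydrogen bond (heavy-atom proxy)
is_donor_atom <- function(resid, name) {
  r <- toupper(resid); n <- toupper(name)
  out <- logical(length(r))
  prot <- is_protein(r)
  out[prot & n == "N" & r != "PRO"] <- TRUE
  nuc <- is_nucleic(r)
  out[nuc & n == "O2'"] <- TRUE
  for (i in which(prot & !out))
    out[i] <- n[i] %in% (PROTEIN_SIDE_DONORS[[r[i]]] %||% character(0))
  bl <- base_letter(r)
  for (i in which(nuc & !out))
    out[i] <- !is.na(bl[i]) && n[i] %in% (BASE_DONORS[[bl[i]]] %||% character(0))
  out
}

is_acceptor_atom <- function(resid, name) {
  r <- toupper(resid); n <- toupper(name)
  out <- logical(length(r))
  prot <- is_protein(r)
  out[prot & n %in% c("O", "OXT")] <- TRUE
  nuc <- is_nucleic(r)
  out[nuc & n %in% c(PHOSPHATE_O, "O5'", "O3'", "O4'", "O2'")] <- TRUE
  for (i in which(prot & !out))
    out[i] <- n[i] %in% (PROTEIN_SIDE_ACCEPTORS[[r[i]]] %||% character(0))
  bl <- base_letter(r)
  for (i in which(nuc & !out))
    out[i] <- !is.na(bl[i]) && n[i] %in% (BASE_ACCEPTORS[[bl[i]]] %||% character(0))
  out
}

is_cation_atom <- function(resid, name) {
  r <- toupper(resid); n <- toupper(name)
  mapply(function(ri, ni) ni %in% (CATION_ATOMS[[ri]] %||% character(0)), r, n,
         USE.NAMES = FALSE)
}

is_anion_atom <- function(resid, name) {
  r <- toupper(resid); n <- toupper(name)
  nuc_phos <- is_nucleic(r) & n %in% PHOSPHATE_O
  prot <- mapply(function(ri, ni) ni %in% (ANION_PROTEIN[[ri]] %||% character(0)),
                 r, n, USE.NAMES = FALSE)
  nuc_phos | prot
}
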