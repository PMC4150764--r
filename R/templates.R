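# Standard-geometry templates and chemical dictionaries.
#
# Base heavy atoms are given in the standard nucleic-acid base-pair reference
# frame: origin on the pseudo-dyad of an idealized Watson-Crick pair, x into
# the major groove, y along the long base-pair axis toward the strand I
# backbone, z along the helix advance.  A complementary base generated by the
# 180-degree rotation about x, (x, y, z) -> (x, -y, -z), forms an ideal pair
# with glycosidic N1-N3 separations of 2.96 A (A.T) and 3.00 A (G.C) and a
# C1'-C1' distance of 10.7 A.
#
# The sugar-phosphate backbone is schematic: atom names and connectivity-level
# placement are correct, and the phosphorus position is calibrated so that the
# windowed cross-strand P-P groove convention reports the canonical ideal-B
# widths (major 11.7 A, minor 5.7 A after the 5.8 A phosphate-radius
# correction) on the default fiber duplex (twist 36.0 deg, rise 3.38 A).
# The template is not intended for refinement-grade stereochemistry.

BASE_RING_ATOMS <- list(
  purine = c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4"),
  pyrimidine = c("N1", "C2", "N3", "C4", "C5", "C6")
)

.base_template_raw <- list(
  A = rbind(
    "C1'" = c(-2.479, 5.346, 0.000),
    N9 = c(-1.291, 4.498, 0.000),
    C8 = c(0.024, 4.897, 0.000),
    N7 = c(0.877, 3.902, 0.000),
    C5 = c(0.071, 2.771, 0.000),
    C6 = c(0.369, 1.398, 0.000),
    N6 = c(1.611, 0.909, 0.000),
    N1 = c(-0.668, 0.532, 0.000),
    C2 = c(-1.912, 1.023, 0.000),
    N3 = c(-2.320, 2.290, 0.000),
    C4 = c(-1.267, 3.124, 0.000)
  ),
  G = rbind(
    "C1'" = c(-2.477, 5.399, 0.000),
    N9 = c(-1.289, 4.551, 0.000),
    C8 = c(0.023, 4.962, 0.000),
    N7 = c(0.870, 3.969, 0.000),
    C5 = c(0.071, 2.833, 0.000),
    C6 = c(0.424, 1.460, 0.000),
    O6 = c(1.554, 0.955, 0.000),
    N1 = c(-0.700, 0.641, 0.000),
    C2 = c(-1.999, 1.087, 0.000),
    N2 = c(-2.949, 0.139, -0.001),
    N3 = c(-2.342, 2.364, 0.001),
    C4 = c(-1.265, 3.177, 0.000)
  ),
  C = rbind(
    "C1'" = c(-2.477, 5.402, 0.000),
    N1 = c(-1.285, 4.542, 0.000),
    C2 = c(-1.472, 3.158, 0.000),
    O2 = c(-2.628, 2.709, 0.001),
    N3 = c(-0.391, 2.344, 0.000),
    C4 = c(0.837, 2.868, 0.000),
    N4 = c(1.875, 2.027, 0.001),
    C5 = c(1.056, 4.275, 0.000),
    C6 = c(-0.023, 5.068, 0.000)
  ),
  T = rbind(
    "C1'" = c(-2.481, 5.354, 0.000),
    N1 = c(-1.284, 4.500, 0.000),
    C2 = c(-1.462, 3.135, 0.000),
    O2 = c(-2.562, 2.608, 0.000),
    N3 = c(-0.298, 2.407, 0.000),
    C4 = c(1.005, 2.897, 0.000),
    O4 = c(1.972, 2.140, 0.000),
    C5 = c(1.101, 4.338, 0.000),
    C7 = c(2.466, 4.961, 0.001),
    C6 = c(-0.024, 5.057, 0.000)
  )
)

# Phosphorus placement calibrated against the windowed groove convention
# (see groove_widths); remaining backbone atoms are interpolated between the
# phosphate and the glycosidic C1'.
.backbone_template <- local({
  P <- c(3.397078, 8.630535, -3.810780)
  C1p <- c(-2.479, 5.346, 0.000)
  O5p <- P + c(-1.02, -0.90, 0.70)
  lerp <- function(t, off) O5p + t * (C1p - O5p) + off
  rbind(
    P = P,
    OP1 = P + c(0.90, 0.90, 0.80),
    OP2 = P + c(0.90, -0.30, -1.15),
    "O5'" = O5p,
    "C5'" = lerp(0.20, c(0.45, 0.10, 0.45)),
    "C4'" = lerp(0.40, c(0.80, 0.00, 0.60)),
    "O4'" = lerp(0.60, c(0.35, -0.40, 0.85)),
    "C3'" = lerp(0.55, c(1.35, 0.45, -0.15)),
    "O3'" = lerp(0.70, c(1.90, 0.80, -0.65)),
    "C2'" = lerp(0.80, c(0.95, 0.55, 0.15))
  )
})

base_template <- function(base) {
  base <- normalize_base(base)
  .base_template_raw[[base]]
}

nucleotide_template <- function(base) {
  rbind(base_template(base), .backbone_template)
}

base_ring_atoms <- function(base) {
  if (normalize_base(base) %in% c("A", "G")) BASE_RING_ATOMS$purine else BASE_RING_ATOMS$pyrimidine
}

#' @keywords internal
normalize_base <- function(resid) {
  x <- toupper(sub("^D", "", trimws(resid)))
  if (!x %in% c("A", "C", "G", "T")) {
    stop("not a recognized deoxynucleotide residue name: ", resid, call. = FALSE)
  }
  x
}

is_nucleotide_resid <- function(resid) {
  toupper(trimws(resid)) %in% c("DA", "DC", "DG", "DT", "A", "C", "G", "T")
}

COMPLEMENT <- c(A = "T", T = "A", G = "C", C = "G")

# --- Polar-contact chemistry -------------------------------------------------
# Heavy-atom hydrogen-bond donors and acceptors for the 20 amino acids and the
# 4 deoxynucleotides.  His, Asn and Gln amide/imidazole nitrogens that are
# ambiguous at crystallographic resolution are listed on both sides.

PROTEIN_DONORS <- list(
  backbone = "N",
  ARG = c("NE", "NH1", "NH2"), LYS = "NZ", HIS = c("ND1", "NE2"),
  ASN = "ND2", GLN = "NE2", SER = "OG", THR = "OG1", TYR = "OH",
  TRP = "NE1", CYS = "SG"
)

PROTEIN_ACCEPTORS <- list(
  backbone = c("O", "OXT"),
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  HIS = c("ND1", "NE2"), SER = "OG", THR = "OG1", TYR = "OH", MET = "SD"
)

DNA_DONORS <- list(
  A = "N6", C = "N4", G = c("N1", "N2"), T = "N3"
)

DNA_ACCEPTORS <- list(
  backbone = c("OP1", "OP2", "O1P", "O2P", "O5'", "O3'", "O4'", "O2'"),
  A = c("N1", "N3", "N7"), G = c("N3", "N7", "O6"),
  C = c("N3", "O2"), T = c("O2", "O4")
)

DNA_BACKBONE_ATOMS <- c("P", "OP1", "OP2", "O1P", "O2P")

AMINO_ACIDS <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

#' Van der Waals radii used for surface-area calculations
#'
#' A fixed published heavy-atom radius set (C 1.70, N 1.55, O 1.52, S 1.80,
#' P 1.80, H 1.20 angstrom). Additional elements can be supplied by name.
#'
#' @param ... Named numeric overrides or additions, e.g. `FE = 1.9`.
#' @return Named numeric vector of radii in angstrom.
#' @export
#' @examples
#' vdw_radii()
#' vdw_radii(FE = 1.9)["FE"]
vdw_radii <- function(...) {
  r <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20)
  extra <- c(...)
  if (length(extra)) r[toupper(names(extra))] <- extra
  r
}
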