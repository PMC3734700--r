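# Idealized side-chain geometry templates (internal coordinates).
#
# Each entry lists the heavy atoms beyond CB in build order. An atom is
# placed by the NeRF construction from three previously known atoms (`refs`),
# a bond length (Angstrom), a valence angle (degrees) and a dihedral. The
# dihedral is either absolute (numeric) or chi1-relative (list(chi = offset)):
# the actual value is chi1 + offset, so the whole side chain rides on the
# inherited chi1 torsion N-CA-CB-gamma.

tpl_atom <- function(name, element, refs, bond, angle, dihedral) {
  list(name = name, element = element, refs = refs, bond = bond,
       angle = angle, dihedral = dihedral)
}
chi <- function(offset = 0) list(chi = offset)

.SIDECHAIN_TEMPLATES <- list(
  GLY = list(),
  ALA = list(),
  SER = list(tpl_atom("OG", "O", c("N", "CA", "CB"), 1.41, 110.8, chi())),
  CYS = list(tpl_atom("SG", "S", c("N", "CA", "CB"), 1.81, 114.4, chi())),
  THR = list(tpl_atom("OG1", "O", c("N", "CA", "CB"), 1.43, 109.6, chi()),
             tpl_atom("CG2", "C", c("N", "CA", "CB"), 1.52, 110.5, chi(-120))),
  VAL = list(tpl_atom("CG1", "C", c("N", "CA", "CB"), 1.52, 110.5, chi()),
             tpl_atom("CG2", "C", c("N", "CA", "CB"), 1.52, 110.5, chi(122))),
  LEU = list(tpl_atom("CG", "C", c("N", "CA", "CB"), 1.53, 116.3, chi()),
             tpl_atom("CD1", "C", c("CA", "CB", "CG"), 1.52, 110.7, 180),
             tpl_atom("CD2", "C", c("CA", "CB", "CG"), 1.52, 110.7, -60)),
  ILE = list(tpl_atom("CG1", "C", c("N", "CA", "CB"), 1.53, 110.4, chi()),
             tpl_atom("CG2", "C", c("N", "CA", "CB"), 1.53, 110.5, chi(-122)),
             tpl_atom("CD1", "C", c("CA", "CB", "CG1"), 1.51, 113.8, 180)),
  MET = list(tpl_atom("CG", "C", c("N", "CA", "CB"), 1.52, 114.1, chi()),
             tpl_atom("SD", "S", c("CA", "CB", "CG"), 1.80, 112.7, 180),
             tpl_atom("CE", "C", c("CB", "CG", "SD"), 1.79, 100.2, 180)),
  PHE = list(tpl_atom("CG", "C", c("N", "CA", "CB"), 1.50, 113.8, chi()),
             tpl_atom("CD1", "C", c("CA", "CB", "CG"), 1.39, 120.8, 90),
             tpl_atom("CD2", "C", c("CA", "CB", "CG"), 1.39, 120.8, -90),
             tpl_atom("CE1", "C", c("CB", "CG", "CD1"), 1.39, 121.0, 180),
             tpl_atom("CE2", "C", c("CB", "CG", "CD2"), 1.39, 121.0, 180),
             tpl_atom("CZ", "C", c("CG", "CD1", "CE1"), 1.39, 120.0, 0)),
  TYR = list(tpl_atom("CG", "C", c("N", "CA", "CB"), 1.50, 113.8, chi()),
             tpl_atom("CD1", "C", c("CA", "CB", "CG"), 1.39, 120.8, 90),
             tpl_atom("CD2", "C", c("CA", "CB", "CG"), 1.39, 120.8, -90),
             tpl_atom("CE1", "C", c("CB", "CG", "CD1"), 1.39, 121.0, 180),
             tpl_atom("CE2", "C", c("CB", "CG", "CD2"), 1.39, 121.0, 180),
             tpl_atom("CZ", "C", c("CG", "CD1", "CE1"), 1.39, 120.0, 0),
             tpl_atom("OH", "O", c("CD1", "CE1", "CZ"), 1.38, 120.0, 180)),
  ASP = list(tpl_atom("CG", "C", c("N", "CA", "CB"), 1.52, 112.6, chi()),
             tpl_atom("OD1", "O", c("CA", "CB", "CG"), 1.25, 118.4, 0),
             tpl_atom("OD2", "O", c("CA", "CB", "CG"), 1.25, 118.4, 180)),
  ASN = list(tpl_atom("CG", "C", c("N", "CA", "CB"), 1.52, 112.6, chi()),
             tpl_atom("OD1", "O", c("CA", "CB", "CG"), 1.23, 120.8, 0),
             tpl_atom("ND2", "N", c("CA", "CB", "CG"), 1.33, 116.4, 180)),
  GLU = list(tpl_atom("CG", "C", c("N", "CA", "CB"), 1.52, 114.1, chi()),
             tpl_atom("CD", "C", c("CA", "CB", "CG"), 1.52, 112.6, 180),
             tpl_atom("OE1", "O", c("CB", "CG", "CD"), 1.25, 118.4, 0),
             tpl_atom("OE2", "O", c("CB", "CG", "CD"), 1.25, 118.4, 180)),
  GLN = list(tpl_atom("CG", "C", c("N", "CA", "CB"), 1.52, 114.1, chi()),
             tpl_atom("CD", "C", c("CA", "CB", "CG"), 1.52, 112.6, 180),
             tpl_atom("OE1", "O", c("CB", "CG", "CD"), 1.23, 120.8, 0),
             tpl_atom("NE2", "N", c("CB", "CG", "CD"), 1.33, 116.4, 180)),
  LYS = list(tpl_atom("CG", "C", c("N", "CA", "CB"), 1.52, 114.1, chi()),
             tpl_atom("CD", "C", c("CA", "CB", "CG"), 1.52, 111.3, 180),
             tpl_atom("CE", "C", c("CB", "CG", "CD"), 1.52, 111.3, 180),
             tpl_atom("NZ", "N", c("CG", "CD", "CE"), 1.49, 111.9, 180)),
  ARG = list(tpl_atom("CG", "C", c("N", "CA", "CB"), 1.52, 114.1, chi()),
             tpl_atom("CD", "C", c("CA", "CB", "CG"), 1.52, 111.3, 180),
             tpl_atom("NE", "N", c("CB", "CG", "CD"), 1.46, 112.0, 180),
             tpl_atom("CZ", "C", c("CG", "CD", "NE"), 1.33, 124.2, 180),
             tpl_atom("NH1", "N", c("CD", "NE", "CZ"), 1.33, 120.0, 0),
             tpl_atom("NH2", "N", c("CD", "NE", "CZ"), 1.33, 120.0, 180)),
  HIS = list(tpl_atom("CG", "C", c("N", "CA", "CB"), 1.50, 113.8, chi()),
             tpl_atom("ND1", "N", c("CA", "CB", "CG"), 1.38, 122.7, 90),
             tpl_atom("CD2", "C", c("CA", "CB", "CG"), 1.36, 131.0, -90),
             tpl_atom("CE1", "C", c("CB", "CG", "ND1"), 1.32, 109.3, 180),
             tpl_atom("NE2", "N", c("CB", "CG", "CD2"), 1.37, 107.0, 180))
)

# Name of the gamma atom defining chi1 (torsion N-CA-CB-gamma).
.GAMMA_ATOM <- c(
  SER = "OG", CYS = "SG", THR = "OG1", VAL = "CG1", ILE = "CG1",
  LEU = "CG", MET = "CG", PHE = "CG", TYR = "CG", ASP = "CG", ASN = "CG",
  GLU = "CG", GLN = "CG", LYS = "CG", ARG = "CG", HIS = "CG"
)

# Residues whose protonation state must be declared before hydrogens are
# added ("added manually" policy: no silent pKa defaults).
.TITRATABLE <- c("ASP", "GLU", "HIS", "TYR", "CYS", "ARG", "LYS")

.WATER_NAMES <- c("HOH", "WAT", "H2O", "TIP", "SOL")

# Expected hydrogen counts per heavy atom, by residue. Backbone handled
# separately. Protonation-dependent atoms are resolved in h_count().
.SIDECHAIN_H <- list(
  GLY = c(),
  ALA = c(CB = 3),
  SER = c(CB = 2, OG = 1),
  CYS = c(CB = 2),                    # SG depends on state
  THR = c(CB = 1, OG1 = 1, CG2 = 3),
  VAL = c(CB = 1, CG1 = 3, CG2 = 3),
  LEU = c(CB = 2, CG = 1, CD1 = 3, CD2 = 3),
  ILE = c(CB = 1, CG1 = 2, CG2 = 3, CD1 = 3),
  MET = c(CB = 2, CG = 2, CE = 3),
  PHE = c(CB = 2, CD1 = 1, CD2 = 1, CE1 = 1, CE2 = 1, CZ = 1),
  TYR = c(CB = 2, CD1 = 1, CD2 = 1, CE1 = 1, CE2 = 1),  # OH per state
  ASP = c(CB = 2),                    # OD2 per state
  ASN = c(CB = 2, ND2 = 2),
  GLU = c(CB = 2, CG = 2),            # OE2 per state
  GLN = c(CB = 2, CG = 2, NE2 = 2),
  LYS = c(CB = 2, CG = 2, CD = 2, CE = 2),  # NZ per state
  ARG = c(CB = 2, CG = 2, CD = 2),    # NE/NH per state
  HIS = c(CB = 2, CD2 = 1, CE1 = 1),  # ND1/NE2 per state
  EPX = c(C1 = 1, C2 = 1, C3 = 2, C4 = 2, C5 = 2)
)

# Atoms treated as sp2 (trigonal H placement) rather than sp3.
.SP2_ATOMS <- list(
  PHE = c("CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CD1", "CD2", "CE1", "CE2"),
  HIS = c("ND1", "CD2", "CE1", "NE2"),
  ASN = c("ND2"), GLN = c("NE2"),
  ARG = c("NE", "NH1", "NH2")
)

# Expected H count for one heavy atom; NA means "no opinion" (0 added).
h_count <- function(resname, atomname, state = NULL) {
  resname <- toupper(resname)
  if (resname %in% .WATER_NAMES) return(if (atomname == "O") 2L else 0L)
  # backbone
  if (atomname == "N") return(if (resname == "PRO") 0L else 1L)
  if (atomname == "CA") return(if (resname == "GLY") 2L else 1L)
  if (atomname %in% c("C", "O", "OXT")) return(0L)
  base <- .SIDECHAIN_H[[resname]]
  if (!is.null(base) && atomname %in% names(base)) return(as.integer(base[[atomname]]))
  # protonation-dependent positions
  st <- state
  pick <- function(valid, counts) {
    if (is.null(st) || !(st %in% valid)) {
      stop(sprintf("unsupported protonation state '%s' for %s (expected one of: %s)",
                   if (is.null(st)) "<none>" else st, resname,
                   paste(valid, collapse = ", ")))
    }
    as.integer(counts[[st]])
  }
  switch(paste(resname, atomname),
    "ASP OD2" = pick(c("anionic", "neutral"), c(anionic = 0, neutral = 1)),
    "ASP OD1" = 0L,
    "GLU OE2" = pick(c("anionic", "neutral"), c(anionic = 0, neutral = 1)),
    "GLU OE1" = 0L,
    "CYS SG" = pick(c("thiol", "thiolate"), c(thiol = 1, thiolate = 0)),
    "TYR OH" = pick(c("neutral", "anionic"), c(neutral = 1, anionic = 0)),
    "TYR CZ" = 0L,
    "LYS NZ" = pick(c("protonated", "neutral"), c(protonated = 3, neutral = 2)),
    "ARG NE" = pick("protonated", c(protonated = 1)),
    "ARG NH1" = pick("protonated", c(protonated = 2)),
    "ARG NH2" = pick("protonated", c(protonated = 2)),
    "ARG CZ" = 0L,
    "HIS ND1" = pick(c("HID", "HIE", "HIP"), c(HID = 1, HIE = 0, HIP = 1)),
    "HIS NE2" = pick(c("HID", "HIE", "HIP"), c(HID = 0, HIE = 1, HIP = 1)),
    0L
  )
}

is_sp2_atom <- function(resname, atomname) {
  atomname %in% (.SP2_ATOMS[[toupper(resname)]] %||% character(0))
}

.H_BOND_LENGTH <- c(C = 1.09, N = 1.01, O = 0.96, S = 1.34)
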