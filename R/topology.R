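# Idealized covalent topology for the 19 non-proline amino acids.
#
# Each residue is described by a small internal-coordinate table for its
# sidechain heavy atoms (anchored on N/CA/C) plus a hydrogen count and
# hybridisation per heavy atom.  Hydrogens are placed generically from the
# heavy-atom skeleton, so a geminal methylene always has the idealized
# H-C-H geometry (1.09 A bonds, 109.47 deg) that underlies the 1.78 A NOE
# calibration reference.

# Reference covalent geometry (A / degrees).
.BOND <- list(
  N_CA = 1.458, CA_C = 1.525, C_N = 1.329, C_O = 1.231,
  C_C = 1.530, C_Car = 1.500, Car_Car = 1.390, C_Nsp3 = 1.489,
  C_Ngua = 1.329, C_Ocarb = 1.249, C_OH = 1.417, C_S = 1.808,
  S_C = 1.789, C_H = 1.090, N_H = 1.010, O_H = 0.960, S_H = 1.340
)
.ANG <- list(
  N_CA_C = 111.0, CA_C_N = 116.2, C_N_CA = 121.7, CA_C_O = 120.5,
  N_CA_CB = 110.5, CB_IMPROPER = 122.8, SP3 = 110.5, SP2 = 120.0,
  HCH = 109.471
)

# Sidechain heavy atoms beyond CB: name, parent, angle ref, torsion ref,
# bond length, bond angle, torsion.  Torsion refs "chi1".."chi4" are filled
# from default rotamers at build time; numeric strings are literal degrees
# offsets are expressed as chi +/- a constant via the `tor_off` column.
.sc_row <- function(name, parent, a2, a3, bond, angle, tor, tor_off = 0,
                    nh = 0L, geom = "sp3", elem = substr(name, 1L, 1L)) {
  data.frame(name = name, parent = parent, a2 = a2, a3 = a3, bond = bond,
             angle = angle, tor = tor, tor_off = tor_off, nh = nh,
             geom = geom, elem = elem, stringsAsFactors = FALSE)
}

# Default (helix-compatible) rotamers: chi1 gauche-minus, later chis trans
# unless a planar group dictates otherwise.
.DEFAULT_CHI <- c(chi1 = -60, chi2 = 180, chi3 = 180, chi4 = 180)

.SIDECHAINS <- local({
  B <- .BOND; A <- .ANG
  list(
    G = NULL,
    A = .sc_row("CB", "CA", "N", "C", B$C_C, A$N_CA_CB, "improper", 0, 3L),
    V = rbind(
      .sc_row("CB", "CA", "N", "C", B$C_C, A$N_CA_CB, "improper", 0, 1L),
      .sc_row("CG1", "CB", "CA", "N", B$C_C, A$SP3, "chi1", 0, 3L),
      .sc_row("CG2", "CB", "CA", "N", B$C_C, A$SP3, "chi1", 122.0, 3L)),
    L = rbind(
      .sc_row("CB", "CA", "N", "C", B$C_C, A$N_CA_CB, "improper", 0, 2L),
      .sc_row("CG", "CB", "CA", "N", B$C_C, A$SP3, "chi1", -120, 1L),
      .sc_row("CD1", "CG", "CB", "CA", B$C_C, A$SP3, "chi2", 0, 3L),
      .sc_row("CD2", "CG", "CB", "CA", B$C_C, A$SP3, "chi2", 122.0, 3L)),
    I = rbind(
      .sc_row("CB", "CA", "N", "C", B$C_C, A$N_CA_CB, "improper", 0, 1L),
      .sc_row("CG1", "CB", "CA", "N", B$C_C, A$SP3, "chi1", 0, 2L),
      .sc_row("CG2", "CB", "CA", "N", B$C_C, A$SP3, "chi1", -122.0, 3L),
      .sc_row("CD1", "CG1", "CB", "CA", B$C_C, A$SP3, "chi2", 0, 3L)),
    F = rbind(
      .sc_row("CB", "CA", "N", "C", B$C_C, A$N_CA_CB, "improper", 0, 2L),
      .sc_row("CG", "CB", "CA", "N", B$C_Car, A$SP3, "chi1", -120, 0L, "sp2"),
      .sc_row("CD1", "CG", "CB", "CA", B$Car_Car, A$SP2, "chi2", -90, 1L, "sp2"),
      .sc_row("CD2", "CG", "CB", "CA", B$Car_Car, A$SP2, "chi2", 90, 1L, "sp2"),
      .sc_row("CE1", "CD1", "CG", "CB", B$Car_Car, A$SP2, "180", 0, 1L, "sp2"),
      .sc_row("CE2", "CD2", "CG", "CB", B$Car_Car, A$SP2, "180", 0, 1L, "sp2"),
      .sc_row("CZ", "CE1", "CD1", "CG", B$Car_Car, A$SP2, "0", 0, 1L, "sp2")),
    Y = rbind(
      .sc_row("CB", "CA", "N", "C", B$C_C, A$N_CA_CB, "improper", 0, 2L),
      .sc_row("CG", "CB", "CA", "N", B$C_Car, A$SP3, "chi1", -120, 0L, "sp2"),
      .sc_row("CD1", "CG", "CB", "CA", B$Car_Car, A$SP2, "chi2", -90, 1L, "sp2"),
      .sc_row("CD2", "CG", "CB", "CA", B$Car_Car, A$SP2, "chi2", 90, 1L, "sp2"),
      .sc_row("CE1", "CD1", "CG", "CB", B$Car_Car, A$SP2, "180", 0, 1L, "sp2"),
      .sc_row("CE2", "CD2", "CG", "CB", B$Car_Car, A$SP2, "180", 0, 1L, "sp2"),
      .sc_row("CZ", "CE1", "CD1", "CG", B$Car_Car, A$SP2, "0", 0, 0L, "sp2"),
      .sc_row("OH", "CZ", "CE1", "CD1", 1.364, A$SP2, "180", 0, 0L, "sp3")),
    W = rbind(
      .sc_row("CB", "CA", "N", "C", B$C_C, A$N_CA_CB, "improper", 0, 2L),
      .sc_row("CG", "CB", "CA", "N", B$C_Car, A$SP3, "chi1", -120, 0L, "sp2"),
      .sc_row("CD1", "CG", "CB", "CA", 1.365, 126.9, "chi2", -90, 1L, "sp2"),
      .sc_row("CD2", "CG", "CB", "CA", 1.433, 126.8, "chi2", 90, 0L, "sp2"),
      .sc_row("NE1", "CD1", "CG", "CB", 1.374, 110.2, "180", 0, 0L, "sp2"),
      .sc_row("CE2", "CD2", "CG", "CD1", 1.409, 107.2, "0", 0, 0L, "sp2"),
      .sc_row("CE3", "CD2", "CG", "CD1", 1.398, 133.9, "180", 0, 1L, "sp2"),
      .sc_row("CZ2", "CE2", "CD2", "CG", 1.394, 122.4, "180", 0, 1L, "sp2"),
      .sc_row("CZ3", "CE3", "CD2", "CG", 1.382, 118.6, "180", 0, 1L, "sp2"),
      .sc_row("CH2", "CZ2", "CE2", "CD2", 1.368, 117.5, "0", 0, 1L, "sp2")),
    D = rbind(
      .sc_row("CB", "CA", "N", "C", B$C_C, A$N_CA_CB, "improper", 0, 2L),
      .sc_row("CG", "CB", "CA", "N", 1.516, A$SP3, "chi1", -120, 0L, "sp2"),
      .sc_row("OD1", "CG", "CB", "CA", B$C_Ocarb, 118.4, "chi2", 0, 0L, "sp2"),
      .sc_row("OD2", "CG", "CB", "CA", B$C_Ocarb, 118.4, "chi2", 180, 0L, "sp2")),
    N = rbind(
      .sc_row("CB", "CA", "N", "C", B$C_C, A$N_CA_CB, "improper", 0, 2L),
      .sc_row("CG", "CB", "CA", "N", 1.516, A$SP3, "chi1", -120, 0L, "sp2"),
      .sc_row("OD1", "CG", "CB", "CA", B$C_O, 120.8, "chi2", 0, 0L, "sp2"),
      .sc_row("ND2", "CG", "CB", "CA", 1.328, 116.4, "chi2", 180, 0L, "sp2")),
    E = rbind(
      .sc_row("CB", "CA", "N", "C", B$C_C, A$N_CA_CB, "improper", 0, 2L),
      .sc_row("CG", "CB", "CA", "N", B$C_C, A$SP3, "chi1", 0, 2L),
      .sc_row("CD", "CG", "CB", "CA", 1.516, A$SP3, "chi2", 0, 0L, "sp2"),
      .sc_row("OE1", "CD", "CG", "CB", B$C_Ocarb, 118.4, "chi3", 0, 0L, "sp2"),
      .sc_row("OE2", "CD", "CG", "CB", B$C_Ocarb, 118.4, "chi3", 180, 0L, "sp2")),
    Q = rbind(
      .sc_row("CB", "CA", "N", "C", B$C_C, A$N_CA_CB, "improper", 0, 2L),
      .sc_row("CG", "CB", "CA", "N", B$C_C, A$SP3, "chi1", 0, 2L),
      .sc_row("CD", "CG", "CB", "CA", 1.516, A$SP3, "chi2", 0, 0L, "sp2"),
      .sc_row("OE1", "CD", "CG", "CB", B$C_O, 120.8, "chi3", 0, 0L, "sp2"),
      .sc_row("NE2", "CD", "CG", "CB", 1.328, 116.4, "chi3", 180, 0L, "sp2")),
    K = rbind(
      .sc_row("CB", "CA", "N", "C", B$C_C, A$N_CA_CB, "improper", 0, 2L),
      .sc_row("CG", "CB", "CA", "N", B$C_C, A$SP3, "chi1", 0, 2L),
      .sc_row("CD", "CG", "CB", "CA", B$C_C, A$SP3, "chi2", 0, 2L),
      .sc_row("CE", "CD", "CG", "CB", B$C_C, A$SP3, "chi3", 0, 2L),
      .sc_row("NZ", "CE", "CD", "CG", B$C_Nsp3, A$SP3, "chi4", 0, 0L)),
    R = rbind(
      .sc_row("CB", "CA", "N", "C", B$C_C, A$N_CA_CB, "improper", 0, 2L),
      .sc_row("CG", "CB", "CA", "N", B$C_C, A$SP3, "chi1", 0, 2L),
      .sc_row("CD", "CG", "CB", "CA", B$C_C, A$SP3, "chi2", 0, 2L),
      .sc_row("NE", "CD", "CG", "CB", 1.461, A$SP3, "chi3", 0, 0L, "sp2"),
      .sc_row("CZ", "NE", "CD", "CG", B$C_Ngua, 124.2, "chi4", 0, 0L, "sp2"),
      .sc_row("NH1", "CZ", "NE", "CD", B$C_Ngua, A$SP2, "0", 0, 0L, "sp2"),
      .sc_row("NH2", "CZ", "NE", "CD", B$C_Ngua, A$SP2, "180", 0, 0L, "sp2")),
    H = rbind(
      .sc_row("CB", "CA", "N", "C", B$C_C, A$N_CA_CB, "improper", 0, 2L),
      .sc_row("CG", "CB", "CA", "N", 1.497, A$SP3, "chi1", -120, 0L, "sp2"),
      .sc_row("ND1", "CG", "CB", "CA", 1.371, 122.5, "chi2", -90, 0L, "sp2"),
      .sc_row("CD2", "CG", "CB", "CA", 1.356, 131.1, "chi2", 90, 1L, "sp2"),
      .sc_row("CE1", "ND1", "CG", "CB", 1.319, 109.0, "180", 0, 1L, "sp2"),
      .sc_row("NE2", "CD2", "CG", "ND1", 1.374, 107.2, "0", 0, 0L, "sp2")),
    S = rbind(
      .sc_row("CB", "CA", "N", "C", B$C_C, A$N_CA_CB, "improper", 0, 2L),
      .sc_row("OG", "CB", "CA", "N", B$C_OH, A$SP3, "chi1", 0, 0L)),
    T = rbind(
      .sc_row("CB", "CA", "N", "C", B$C_C, A$N_CA_CB, "improper", 0, 1L),
      .sc_row("OG1", "CB", "CA", "N", B$C_OH, A$SP3, "chi1", 0, 0L),
      .sc_row("CG2", "CB", "CA", "N", B$C_C, A$SP3, "chi1", -122.0, 3L)),
    C = rbind(
      .sc_row("CB", "CA", "N", "C", B$C_C, A$N_CA_CB, "improper", 0, 2L),
      .sc_row("SG", "CB", "CA", "N", B$C_S, A$SP3, "chi1", 0, 0L)),
    M = rbind(
      .sc_row("CB", "CA", "N", "C", B$C_C, A$N_CA_CB, "improper", 0, 2L),
      .sc_row("CG", "CB", "CA", "N", B$C_C, A$SP3, "chi1", 0, 2L),
      .sc_row("SD", "CG", "CB", "CA", B$C_S, A$SP3, "chi2", 0, 0L),
      .sc_row("CE", "SD", "CG", "CB", B$S_C, 100.2, "chi3", 0, 3L))
  )
})

# Ring-closure bonds absent from the internal-coordinate tree.
.RING_CLOSURES <- list(
  F = list(c("CZ", "CE2")),
  Y = list(c("CZ", "CE2")),
  H = list(c("CE1", "NE2")),
  W = list(c("NE1", "CE2"), c("CZ3", "CH2"))
)

# Atoms forming a rigid planar/ring group (pairwise distances holonomic).
.RIGID_GROUPS <- list(
  F = list(c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ",
             "HD1", "HD2", "HE1", "HE2", "HZ")),
  Y = list(c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH",
             "HD1", "HD2", "HE1", "HE2")),
  H = list(c("CB", "CG", "ND1", "CD2", "CE1", "NE2", "HD2", "HE1")),
  W = list(c("CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3",
             "CH2", "HD1", "HE3", "HZ2", "HZ3", "HH2")),
  R = list(c("CD", "NE", "CZ", "NH1", "NH2")),
  D = list(c("CB", "CG", "OD1", "OD2")),
  N = list(c("CB", "CG", "OD1", "ND2")),
  E = list(c("CG", "CD", "OE1", "OE2")),
  Q = list(c("CG", "CD", "OE1", "NE2"))
)

.AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
          E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
          M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
          Y = "TYR", V = "VAL")

supported_residues <- function() setdiff(names(.AA3), "P")

# Hydrogen naming follows PDB v3.3: strip the element letter from the heavy
# atom name; one H -> "H<rem>", two -> "H<rem>2/3", three -> "H<rem>1/2/3".
# Amide NH2 groups on a numbered nitrogen (Arg NH1/NH2) use suffixes 1/2.
.h_names <- function(heavy, nh, elem = substr(heavy, 1L, 1L)) {
  rem <- substring(heavy, 2L)
  if (nh == 1L) paste0("H", rem)
  else if (nh == 2L) {
    suf <- if (elem == "N" && grepl("[0-9]$", rem)) c("1", "2") else c("2", "3")
    paste0("H", rem, suf)
  } else paste0("H", rem, c("1", "2", "3"))
}

#' Covalent topology of a peptide
#'
#' Expands a [peptide_sequence()] into its idealized all-atom roster
#' (backbone, sidechain heavy atoms and amide/aliphatic/aromatic hydrogens)
#' with the covalent bond list.  This roster is shared by the helix builder,
#' the NOESY simulator and the distance-geometry engine, so simulated peaks,
#' restraints and conformers always refer to the same atoms.
#'
#' Proline is not supported (no amide proton, ring backbone); requesting it
#' is an error.
#'
#' @param sequence a [peptide_sequence()].
#' @return a list with `atoms` (data.frame: `resid`, `reskind`, `name`,
#'   `elem`), `bonds` (two-column matrix of atom indices) and `rigid`
#'   (list of integer vectors, atoms whose mutual distances are fixed).
#' @export
peptide_topology <- function(sequence) {
  sequence <- as_peptide_sequence(sequence)
  kinds <- sequence$residues
  resid <- seq(sequence$first_index, length.out = length(kinds))
  bad <- setdiff(kinds, supported_residues())
  if (length(bad))
    stop("unsupported residue kind(s): ", paste(unique(bad), collapse = ", "))

  atoms <- list(); bonds <- list(); rigid <- list()
  idx_of <- new.env(parent = emptyenv())
  n_at <- 0L
  add_atom <- function(resi, kind, name, elem) {
    n_at <<- n_at + 1L
    atoms[[n_at]] <<- data.frame(resid = resi, reskind = kind, name = name,
                                 elem = elem, stringsAsFactors = FALSE)
    assign(paste0(resi, ":", name), n_at, envir = idx_of)
    n_at
  }
  add_bond <- function(i, j) bonds[[length(bonds) + 1L]] <<- c(i, j)
  get_idx <- function(resi, name) get(paste0(resi, ":", name), envir = idx_of)

  for (k in seq_along(kinds)) {
    resi <- resid[k]; kind <- kinds[k]
    iN <- add_atom(resi, kind, "N", "N")
    iH <- add_atom(resi, kind, "H", "H")
    iCA <- add_atom(resi, kind, "CA", "C")
    add_bond(iN, iH); add_bond(iN, iCA)
    if (k > 1L) add_bond(get_idx(resid[k - 1L], "C"), iN)
    if (kind == "G") {
      add_bond(iCA, add_atom(resi, kind, "HA2", "H"))
      add_bond(iCA, add_atom(resi, kind, "HA3", "H"))
    } else {
      add_bond(iCA, add_atom(resi, kind, "HA", "H"))
    }
    sc <- .SIDECHAINS[[kind]]
    if (!is.null(sc)) {
      for (r in seq_len(nrow(sc))) {
        row <- sc[r, ]
        ii <- add_atom(resi, kind, row$name, row$elem)
        add_bond(get_idx(resi, row$parent), ii)
        if (row$nh > 0L) {
          for (hn in .h_names(row$name, row$nh, row$elem))
            add_bond(ii, add_atom(resi, kind, hn, "H"))
        }
      }
      for (cl in .RING_CLOSURES[[kind]] %||% list())
        add_bond(get_idx(resi, cl[1L]), get_idx(resi, cl[2L]))
    }
    iC <- add_atom(resi, kind, "C", "C")
    iO <- add_atom(resi, kind, "O", "O")
    add_bond(iCA, iC); add_bond(iC, iO)
    for (grp in .RIGID_GROUPS[[kind]] %||% list())
      rigid[[length(rigid) + 1L]] <-
        vapply(grp, function(nm) get_idx(resi, nm), integer(1L))
    # the trans peptide group is rigid
    if (k > 1L) {
      rp <- resid[k - 1L]
      rigid[[length(rigid) + 1L]] <-
        c(get_idx(rp, "CA"), get_idx(rp, "C"), get_idx(rp, "O"),
          iN, iH, iCA)
    }
  }
  atoms <- do.call(rbind, atoms)
  rownames(atoms) <- NULL
  list(atoms = atoms,
       bonds = do.call(rbind, bonds),
       rigid = rigid)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Atom identifiers "resid.name" for a topology roster
#' @noRd
atom_ids <- function(atoms) paste0(atoms$resid, ".", atoms$name)
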