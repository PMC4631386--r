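# All-atom construction of idealized peptide conformers.  The backbone is
# chained by NeRF placement from ideal covalent geometry; sidechain heavy
# atoms come from the per-residue internal-coordinate tables; hydrogens are
# completed generically from the heavy-atom skeleton so that every methylene
# carries the idealized H-C-H geometry.

#' Conformer: one all-atom coordinate set
#'
#' @param coords numeric matrix, one row per atom, 3 (or 4 during
#'   four-dimensional refinement) columns, Angstrom.
#' @param atoms atom roster data.frame as produced by [peptide_topology()].
#' @param energy restraint-penalty score (A^2), `NA` if not evaluated.
#' @param metadata named list (seed, pipeline stage, ...).
#' @return an object of class `conformer`.
#' @export
conformer <- function(coords, atoms, energy = NA_real_, metadata = list()) {
  coords <- as.matrix(coords)
  if (nrow(coords) != nrow(atoms))
    stop("coordinate rows (", nrow(coords), ") do not match atom roster (",
         nrow(atoms), ")")
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  rownames(coords) <- atom_ids(atoms)
  structure(list(coords = coords, atoms = atoms, energy = energy,
                 metadata = metadata),
            class = "conformer")
}

#' @export
print.conformer <- function(x, ...) {
  cat(sprintf("conformer: %d atoms, %d residues (%s), dim %d%s\n",
              nrow(x$coords), length(unique(x$atoms$resid)),
              paste(range(x$atoms$resid), collapse = "-"), ncol(x$coords),
              if (is.na(x$energy)) "" else sprintf(", energy %.4f A^2", x$energy)))
  invisible(x)
}

.place_missing_h <- function(coords, atoms, bonds, topo_meta) {
  # adjacency on heavy skeleton + which hydrogens hang off each heavy atom
  n <- nrow(atoms)
  adj <- vector("list", n)
  for (r in seq_len(nrow(bonds))) {
    i <- bonds[r, 1L]; j <- bonds[r, 2L]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  bond_h <- function(elem) switch(elem, N = .BOND$N_H, O = .BOND$O_H,
                                  S = .BOND$S_H, .BOND$C_H)
  for (i in seq_len(n)) {
    if (atoms$elem[i] == "H") next
    hs <- adj[[i]][atoms$elem[adj[[i]]] == "H"]
    if (!length(hs)) next
    heavies <- adj[[i]][atoms$elem[adj[[i]]] != "H"]
    b <- bond_h(atoms$elem[i])
    X <- coords[i, ]
    geom <- topo_meta$geom[i]
    nh <- length(hs)
    if (nh == 1L && length(heavies) >= 3L) {
      # sp3 CH: opposite the sum of neighbour directions
      s <- rowSums(vapply(heavies, function(j) unit_vec(coords[j, ] - X),
                          numeric(3L)))
      coords[hs, ] <- X - b * unit_vec(s)
    } else if (nh == 1L && length(heavies) == 2L) {
      # planar (aromatic CH, amide NH, Arg NE-H) or bent (S/O-H unused here)
      s <- unit_vec(coords[heavies[1L], ] - X) +
           unit_vec(coords[heavies[2L], ] - X)
      coords[hs, ] <- X - b * unit_vec(s)
    } else if (nh == 1L && length(heavies) == 1L) {
      # hydroxyl / thiol / N-terminal amide: torsion 180 off the grandparent
      p <- heavies[1L]
      gp <- setdiff(adj[[p]][atoms$elem[adj[[p]]] != "H"], i)[1L]
      ang <- switch(atoms$elem[i], O = 108.5, S = 96.0, N = 119.0, 109.5)
      coords[hs, ] <- place_atom(coords[gp, ], coords[p, ], X, b, ang, 180)
    } else if (nh == 2L && length(heavies) == 2L && geom != "sp2") {
      # methylene: idealized H-C-H (109.47 deg) astride the heavy plane
      u1 <- unit_vec(coords[heavies[1L], ] - X)
      u2 <- unit_vec(coords[heavies[2L], ] - X)
      bis <- -unit_vec(u1 + u2)
      w <- unit_vec(cross3(u1, u2))
      half <- (.ANG$HCH / 2) * pi / 180
      coords[hs[1L], ] <- X + b * (bis * cos(half) + w * sin(half))
      coords[hs[2L], ] <- X + b * (bis * cos(half) - w * sin(half))
    } else if (nh == 2L) {
      # planar NH2 (Arg NH1/NH2, Asn/Gln amide): in-plane, torsions 0/180
      p <- heavies[1L]
      gp <- setdiff(adj[[p]][atoms$elem[adj[[p]]] != "H"], i)[1L]
      coords[hs[1L], ] <- place_atom(coords[gp, ], coords[p, ], X, b, 120, 0)
      coords[hs[2L], ] <- place_atom(coords[gp, ], coords[p, ], X, b, 120, 180)
    } else if (nh == 3L) {
      # methyl / ammonium: staggered (60/180/-60) about the parent bond
      p <- heavies[1L]
      gp <- setdiff(adj[[p]][atoms$elem[adj[[p]]] != "H"], i)[1L]
      tors <- c(180, 60, -60)
      for (k in seq_len(3L))
        coords[hs[k], ] <- place_atom(coords[gp, ], coords[p, ], X, b,
                                      109.5, tors[k])
    } else stop("unhandled hydrogen pattern at atom ", atom_ids(atoms)[i])
  }
  coords
}

#' Build an idealized peptide conformer at fixed backbone dihedrals
#'
#' Constructs all-atom coordinates (heavy atoms plus amide, aliphatic and
#' aromatic hydrogens) for a peptide at uniform backbone dihedrals using
#' ideal covalent geometry and default sidechain rotamers (chi1 = -60, later
#' chis trans, planar groups planar).  The default (phi, psi) = (-57, -47)
#' produces the canonical right-handed alpha helix with a rise of about
#' 1.5 A per residue; it serves as the ground-truth bound-state conformation
#' for the synthetic transferred-NOESY generator and for structure-recovery
#' tests.  The construction is deterministic: identical inputs give
#' bit-identical coordinates.
#'
#' @param sequence a [peptide_sequence()] (proline unsupported).
#' @param phi,psi backbone dihedrals in degrees, applied to every residue.
#' @return a [conformer()].
#' @examples
#' helx <- make_ideal_helix(peptide_sequence("VRRFDLLKRILK", 62))
#' @export
make_ideal_helix <- function(sequence, phi = -57, psi = -47) {
  sequence <- as_peptide_sequence(sequence)
  topo <- peptide_topology(sequence)
  atoms <- topo$atoms
  resid <- residue_numbers(sequence)
  kinds <- sequence$residues
  n <- nrow(atoms)
  coords <- matrix(NA_real_, n, 3L)
  ids <- atom_ids(atoms)
  ix <- function(resi, name) match(paste0(resi, ".", name), ids)
  setp <- function(resi, name, p) coords[ix(resi, name), ] <<- p
  getp <- function(resi, name) coords[ix(resi, name), ]

  B <- .BOND; A <- .ANG
  for (k in seq_along(resid)) {
    ri <- resid[k]
    if (k == 1L) {
      setp(ri, "N", c(0, 0, 0))
      setp(ri, "CA", c(B$N_CA, 0, 0))
      th <- A$N_CA_C * pi / 180
      setp(ri, "C", c(B$N_CA - B$CA_C * cos(th), B$CA_C * sin(th), 0))
    } else {
      rp <- resid[k - 1L]
      setp(ri, "N", place_atom(getp(rp, "N"), getp(rp, "CA"), getp(rp, "C"),
                               B$C_N, A$CA_C_N, psi))
      setp(ri, "CA", place_atom(getp(rp, "CA"), getp(rp, "C"), getp(ri, "N"),
                                B$N_CA, A$C_N_CA, 180))
      setp(ri, "C", place_atom(getp(rp, "C"), getp(ri, "N"), getp(ri, "CA"),
                               B$CA_C, A$N_CA_C, phi))
    }
    setp(ri, "O", place_atom(getp(ri, "N"), getp(ri, "CA"), getp(ri, "C"),
                             B$C_O, A$CA_C_O, psi + 180))
    sc <- .SIDECHAINS[[kinds[k]]]
    if (!is.null(sc)) {
      for (r in seq_len(nrow(sc))) {
        row <- sc[r, ]
        tor <- if (row$tor == "improper") A$CB_IMPROPER
               else if (row$tor %in% names(.DEFAULT_CHI))
                 .DEFAULT_CHI[[row$tor]] + row$tor_off
               else as.numeric(row$tor) + row$tor_off
        setp(ri, row$name,
             place_atom(getp(ri, row$a3), getp(ri, row$a2),
                        getp(ri, row$parent), row$bond, row$angle, tor))
      }
    }
  }
  # geometry class per atom for the hydrogen pass
  geom <- rep("sp3", n)
  for (k in seq_along(resid)) {
    sc <- .SIDECHAINS[[kinds[k]]]
    if (!is.null(sc))
      geom[match(paste0(resid[k], ".", sc$name), ids)] <- sc$geom
    geom[ix(resid[k], "N")] <- "sp2"
  }
  coords <- .place_missing_h(coords, atoms, topo$bonds, list(geom = geom))
  if (anyNA(coords)) stop("internal error: unplaced atoms")
  conformer(coords, atoms,
            metadata = list(stage = "ideal", phi = phi, psi = psi))
}
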