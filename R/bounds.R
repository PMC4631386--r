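# Distance-bounds matrices: holonomic covalent bounds from idealized
# geometry, van der Waals defaults, experimental restraints, and
# triangle-inequality smoothing.

# Bondi-style van der Waals radii (A), scaled by 0.9 for the soft lower
# bounds used in distance geometry.
.VDW <- c(H = 1.1, C = 1.7, N = 1.55, O = 1.52, S = 1.8)
.VDW_SCALE <- 0.9
.UPPER_CEILING <- 999

#' Distance-bounds matrix
#'
#' @param atoms atom roster data.frame (as from [peptide_topology()]).
#' @param lower,upper symmetric matrices of distance bounds (A), zero
#'   diagonal, `lower <= upper` elementwise.
#' @param weight optional symmetric matrix of per-pair penalty weights
#'   (default 1 everywhere); experimental restraints are conventionally
#'   weighted above the generic geometric/soft-sphere bounds.
#' @return an object of class `bounds_matrix`.
#' @export
bounds_matrix <- function(atoms, lower, upper, weight = NULL) {
  n <- nrow(atoms)
  stopifnot(nrow(lower) == n, nrow(upper) == n)
  if (any(diag(lower) != 0) || any(diag(upper) != 0))
    stop("bounds diagonal must be zero")
  if (!isSymmetric(unname(lower)) || !isSymmetric(unname(upper)))
    stop("bounds matrices must be symmetric")
  bad <- which(lower > upper + 1e-9, arr.ind = TRUE)
  if (nrow(bad))
    stop("lower > upper for pair ", atom_ids(atoms)[bad[1L, 1L]], " / ",
         atom_ids(atoms)[bad[1L, 2L]])
  ids <- atom_ids(atoms)
  if (is.null(weight)) weight <- matrix(1, n, n)
  stopifnot(nrow(weight) == n, all(weight > 0))
  dimnames(lower) <- dimnames(upper) <- dimnames(weight) <- list(ids, ids)
  structure(list(atoms = atoms, lower = lower, upper = upper,
                 weight = weight),
            class = "bounds_matrix")
}

#' @export
print.bounds_matrix <- function(x, ...) {
  n <- nrow(x$atoms)
  fixed <- sum(x$lower == x$upper & upper.tri(x$lower))
  cat(sprintf("bounds_matrix: %d atoms, %d pairs (%d holonomic)\n",
              n, n * (n - 1L) / 2L, fixed))
  invisible(x)
}

# neighbour lists and 3-bond paths on the covalent graph
.bond_adjacency <- function(n, bonds) {
  adj <- vector("list", n)
  for (r in seq_len(nrow(bonds))) {
    i <- bonds[r, 1L]; j <- bonds[r, 2L]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

#' Build the distance-bounds matrix for a peptide
#'
#' Holonomic constraints from idealized covalent geometry fix all 1-2 and
#' 1-3 distances exactly, along with every pair inside a rigid group
#' (aromatic rings with substituents, guanidinium/amide/carboxylate
#' planes, the trans peptide unit).  Remaining 1-4 pairs are bounded by
#' their cis/trans rotation extremes; all other pairs default to the
#' scaled van der Waals contact distance below and a large ceiling above.
#' Experimental restraints then tighten the defaults where applicable; a
#' restraint whose upper bound falls below a holonomic lower bound is a
#' geometric contradiction and raises an error.
#'
#' @param sequence a [peptide_sequence()].
#' @param restraints optional [restraint_table()].
#' @param restraint_weight penalty weight of experimental restraint pairs
#'   relative to the geometric defaults.
#' @return a [bounds_matrix()].
#' @export
build_bounds <- function(sequence, restraints = NULL,
                         restraint_weight = 5) {
  sequence <- as_peptide_sequence(sequence)
  topo <- peptide_topology(sequence)
  ref <- make_ideal_helix(sequence)     # reference for holonomic distances
  co <- ref$coords
  atoms <- topo$atoms
  n <- nrow(atoms)
  ids <- atom_ids(atoms)
  vdw <- .VDW[atoms$elem]
  lower <- outer(vdw, vdw, `+`) * .VDW_SCALE
  upper <- matrix(.UPPER_CEILING, n, n)
  weight <- matrix(1, n, n)
  set_pair <- function(i, j, lo, up) {
    lower[i, j] <<- lower[j, i] <<- lo
    upper[i, j] <<- upper[j, i] <<- up
  }
  refdist <- function(i, j) sqrt(sum((co[i, ] - co[j, ])^2))
  adj <- .bond_adjacency(n, topo$bonds)
  # rigid groups: all mutual distances holonomic
  for (grp in topo$rigid) {
    for (a in seq_along(grp)) for (b in seq_along(grp)) {
      if (a < b) {
        d <- refdist(grp[a], grp[b])
        set_pair(grp[a], grp[b], d, d)
      }
    }
  }
  # 1-2 and 1-3: fixed by bond lengths and angles
  for (i in seq_len(n)) {
    for (j in adj[[i]]) {
      if (j > i) { d <- refdist(i, j); set_pair(i, j, d, d) }
      for (k in adj[[j]]) {
        if (k > i && k != i) { d <- refdist(i, k); set_pair(i, k, d, d) }
      }
    }
  }
  # 1-4: cis/trans extremes of the connecting dihedral (unless already
  # fixed through a rigid group)
  fixed14 <- lower == upper
  for (i in seq_len(n)) {
    for (j in adj[[i]]) for (k in setdiff(adj[[j]], i)) {
      for (l in setdiff(adj[[k]], c(i, j))) {
        if (l <= i || fixed14[i, l]) next
        rij <- refdist(i, j); rjk <- refdist(j, k); rkl <- refdist(k, l)
        aijk <- bond_angle(co[i, ], co[j, ], co[k, ])
        ajkl <- bond_angle(co[j, ], co[k, ], co[l, ])
        pcis <- place_atom(co[i, ], co[j, ], co[k, ], rkl, ajkl, 0)
        ptrans <- place_atom(co[i, ], co[j, ], co[k, ], rkl, ajkl, 180)
        dmin <- sqrt(sum((co[i, ] - pcis)^2))
        dmax <- sqrt(sum((co[i, ] - ptrans)^2))
        lo <- max(lower[i, l], min(dmin, dmax))
        up <- min(upper[i, l], max(dmin, dmax))
        if (lo > up) { lo <- min(dmin, dmax); up <- max(dmin, dmax) }
        set_pair(i, l, lo, up)
      }
    }
  }
  diag(lower) <- diag(upper) <- 0
  # experimental restraints intersect the defaults where tighter
  if (!is.null(restraints) && nrow(restraints)) {
    check_restraints_resolvable(restraints, sequence)
    for (k in seq_len(nrow(restraints))) {
      i <- match(restraints$atom_i[k], ids)
      j <- match(restraints$atom_j[k], ids)
      if (restraints$upper[k] < lower[i, j] - 1e-9 &&
          lower[i, j] == upper[i, j])
        stop("restraint ", restraints$atom_i[k], " / ",
             restraints$atom_j[k], " (upper ", restraints$upper[k],
             " A) contradicts the holonomic distance ",
             round(lower[i, j], 3), " A")
      lo <- max(lower[i, j], restraints$lower[k])
      up <- min(upper[i, j], restraints$upper[k])
      if (lo > up + 1e-9) {
        # bound conflict between restraint and geometry defaults
        stop("restraint ", restraints$atom_i[k], " / ",
             restraints$atom_j[k], " incompatible with geometric bounds [",
             round(lower[i, j], 3), ", ", round(upper[i, j], 3), "]")
      }
      set_pair(i, j, lo, up)
      weight[i, j] <- weight[j, i] <- restraint_weight
    }
  }
  bounds_matrix(atoms, lower, upper, weight)
}

#' Triangle-inequality smoothing of a bounds matrix
#'
#' Upper bounds are replaced by all-pairs shortest paths (Floyd-Warshall)
#' over the upper matrix; lower bounds are raised through the inverse
#' triangle inequality `l_ik >= max_j(l_ij - u_jk)`, iterated to a fixed
#' point.  The operation is idempotent.  If smoothing drives a lower bound
#' above its upper bound the input was geometrically inconsistent and an
#' error names the offending pair.
#'
#' @param bounds a [bounds_matrix()].
#' @return the smoothed [bounds_matrix()].
#' @export
smooth_bounds <- function(bounds) {
  stopifnot(inherits(bounds, "bounds_matrix"))
  res <- cpp_smooth_bounds(bounds$lower, bounds$upper)
  if (res$bad >= 0) {
    n <- nrow(bounds$atoms)
    i <- res$bad %/% n + 1L
    j <- res$bad %% n + 1L
    stop("inconsistent bounds after smoothing for pair ",
         atom_ids(bounds$atoms)[i], " / ", atom_ids(bounds$atoms)[j])
  }
  bounds_matrix(bounds$atoms, res$lower, res$upper, bounds$weight)
}
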