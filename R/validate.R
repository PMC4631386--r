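# Ensemble validation: restraint-violation statistics, ensemble precision
# (pairwise/medoid RMSD) and CSP-contact consistency of a docked pose.

# distance of a (possibly pseudoatom) restraint endpoint: pseudoatoms are
# evaluated at the mean position of their proton group
.restraint_positions <- function(conf, id) {
  ids <- rownames(conf$coords)
  i <- match(id, ids)
  if (!is.na(i)) return(conf$coords[i, ])
  # pseudoatom: average the matching proton group, e.g. "65.HB*" or a
  # methyl named by its protons
  pat <- paste0("^", gsub("\\*", ".*", gsub("\\.", "\\\\.", id)), "$")
  hits <- grep(pat, ids)
  if (!length(hits)) stop("atom ", id, " missing from conformer")
  colMeans(conf$coords[hits, , drop = FALSE])
}

#' Restraint-violation report for an ensemble
#'
#' Per restraint and conformer the violation is
#' `max(0, d - upper) + max(0, lower - d)`; the report aggregates the
#' maximum and mean violation per restraint and counts conformers
#' violating it, with AQUA-style summary counts above 0.1 and 0.5 A.
#'
#' @param ensemble a [conformer_ensemble()] (or single [conformer()]).
#' @param restraints a [restraint_table()].
#' @return object of class `violation_report`: data.frame
#'   (`atom_i`, `atom_j`, `max_violation`, `mean_violation`,
#'   `n_violated_conformers`) with attribute `summary` (list
#'   `n_over_0.1`, `n_over_0.5`, `largest`).
#' @export
violation_report <- function(ensemble, restraints) {
  if (inherits(ensemble, "conformer"))
    ensemble <- conformer_ensemble(list(ensemble))
  stopifnot(inherits(ensemble, "conformer_ensemble"),
            inherits(restraints, "restraint_table"))
  nr <- nrow(restraints)
  nc <- length(ensemble$conformers)
  V <- matrix(0, nr, nc)
  for (c in seq_len(nc)) {
    cf <- ensemble$conformers[[c]]
    for (k in seq_len(nr)) {
      pi_ <- .restraint_positions(cf, restraints$atom_i[k])
      pj <- .restraint_positions(cf, restraints$atom_j[k])
      d <- sqrt(sum((pi_ - pj)^2))
      V[k, c] <- max(0, d - restraints$upper[k]) +
                 max(0, restraints$lower[k] - d)
    }
  }
  df <- data.frame(atom_i = restraints$atom_i, atom_j = restraints$atom_j,
                   max_violation = if (nr) apply(V, 1L, max) else numeric(),
                   mean_violation = if (nr) rowMeans(V) else numeric(),
                   n_violated_conformers =
                     if (nr) rowSums(V > 1e-9) else integer(),
                   stringsAsFactors = FALSE)
  attr(df, "summary") <- list(
    n_over_0.1 = sum(df$max_violation > 0.1),
    n_over_0.5 = sum(df$max_violation > 0.5),
    largest = if (nr) max(df$max_violation) else 0)
  class(df) <- c("violation_report", "data.frame")
  df
}

#' @export
print.violation_report <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf(paste0("violation_report: %d restraints; largest violation",
                     " %.3f A; > 0.1 A: %d; > 0.5 A: %d\n"),
              nrow(x), s$largest, s$n_over_0.1, s$n_over_0.5))
  invisible(x)
}

# coordinate block of selected atoms for one conformer
.select_coords <- function(conf, atom_selection, region) {
  at <- conf$atoms
  keep <- rep(TRUE, nrow(at))
  if (!is.null(atom_selection)) keep <- keep & at$name %in% atom_selection
  if (!is.null(region)) keep <- keep & at$resid %in% region
  if (!any(keep)) stop("empty atom selection")
  conf$coords[keep, , drop = FALSE]
}

#' Ensemble precision: pairwise and medoid RMSD
#'
#' All conformer pairs are optimally superposed ([superpose()]) and the
#' report gives the mean pairwise RMSD and each conformer's RMSD to the
#' medoid (the conformer with the smallest total distance to the
#' others), which serves as the ensemble reference in place of an
#' unphysical mean structure.  By default each pair is superposed on the
#' same atoms it is evaluated on; passing a different `fit_region`
#' performs the standard ordered/disordered analysis — superpose on the
#' converged region, measure the spread elsewhere.
#'
#' @param ensemble a [conformer_ensemble()] with >= 2 conformers.
#' @param atom_selection atom names to superpose on (default backbone
#'   N/CA/C).
#' @param region residue numbers whose spread is measured (default all).
#' @param fit_region residue numbers used for the superposition
#'   (default: `region`).
#' @return list with `mean_pairwise`, `to_medoid` (vector), `medoid`
#'   (index), `pairwise` (matrix).
#' @export
ensemble_rmsd <- function(ensemble, atom_selection = c("N", "CA", "C"),
                          region = NULL, fit_region = region) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  nc <- length(ensemble$conformers)
  if (nc < 2L) stop("need at least 2 conformers")
  eval_blocks <- lapply(ensemble$conformers, .select_coords,
                        atom_selection, region)
  same_fit <- identical(fit_region, region)
  fit_blocks <- if (same_fit) eval_blocks
    else lapply(ensemble$conformers, .select_coords, atom_selection,
                fit_region)
  R <- matrix(0, nc, nc)
  for (i in seq_len(nc - 1L)) for (j in seq(i + 1L, nc)) {
    if (same_fit) {
      R[i, j] <- R[j, i] <- rmsd_fit(eval_blocks[[i]], eval_blocks[[j]])
    } else {
      tr <- .kabsch_transform(fit_blocks[[i]], fit_blocks[[j]])
      moved <- sweep(eval_blocks[[i]], 2L, tr$center_m) %*% t(tr$rotation)
      moved <- sweep(moved, 2L, tr$center_f, `+`)
      R[i, j] <- R[j, i] <-
        sqrt(mean(rowSums((moved - eval_blocks[[j]])^2)))
    }
  }
  medoid <- which.min(rowSums(R))
  list(mean_pairwise = mean(R[upper.tri(R)]),
       to_medoid = R[, medoid],
       medoid = medoid,
       pairwise = R)
}

#' CSP-contact consistency of a peptide pose on a partner protein
#'
#' For every residue of the partner's CSP profile the minimal heavy-atom
#' distance to any peptide atom is measured; the score is the rank
#' (Spearman) correlation between CSP magnitude and proximity (negated
#' distance), so a pose whose strongly perturbed residues hug the peptide
#' scores near +1.  Rigid motions of the whole pose leave the score
#' unchanged.
#'
#' @param partner_coords matrix of partner heavy-atom coordinates with a
#'   parallel vector `partner_resid` of residue numbers.
#' @param partner_resid residue number of each partner atom row.
#' @param peptide_coords matrix of peptide atom coordinates.
#' @param profile a [csp_profile()] for the partner residues.
#' @return object of class `pose_consistency`: list with
#'   `rank_correlation` and `per_residue` data.frame
#'   (`residue_index`, `d`, `min_distance`).
#' @export
csp_contact_consistency <- function(partner_coords, partner_resid,
                                    peptide_coords, profile) {
  stopifnot(inherits(profile, "csp_profile"),
            nrow(partner_coords) == length(partner_resid))
  prof <- profile[!is.na(profile$d), , drop = FALSE]
  res <- intersect(unique(partner_resid), prof$residue_index)
  if (length(res) < 3L)
    stop("need at least 3 profile residues present in the partner structure")
  mind <- vapply(res, function(r) {
    blk <- partner_coords[partner_resid == r, , drop = FALSE]
    min(vapply(seq_len(nrow(blk)), function(a)
      min(sqrt(colSums((t(peptide_coords) - blk[a, ])^2))), numeric(1L)))
  }, numeric(1L))
  d <- prof$d[match(res, prof$residue_index)]
  if (stats::sd(d) == 0)
    stop("uniform CSP profile: rank correlation undefined")
  if (stats::sd(mind) == 0)
    stop("degenerate geometry: all contact distances equal")
  rc <- stats::cor(d, -mind, method = "spearman")
  structure(list(rank_correlation = rc,
                 per_residue = data.frame(residue_index = res, d = d,
                                          min_distance = mind)),
            class = "pose_consistency")
}

#' @export
print.pose_consistency <- function(x, ...) {
  cat(sprintf("pose_consistency: rank correlation %.3f over %d residues\n",
              x$rank_correlation, nrow(x$per_residue)))
  invisible(x)
}
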