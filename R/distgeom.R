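# Distance-geometry engine: random metrization, metric-matrix embedding,
# four-dimensional refinement and fixed-schedule penalty minimization.

#' Sample a full distance matrix within smoothed bounds (random metrization)
#'
#' A seeded random subset of atom pairs is fixed one at a time: each is
#' drawn uniformly within its current bounds and the bounds of all
#' affected pairs are re-tightened through the triangle inequality before
#' the next draw (so later draws respect earlier ones).  Remaining pairs
#' are then sampled independently within the final smoothed bounds.
#' `fraction = 1` gives full metrization; the default 0.1 (partial
#' metrization) is the standard speed/quality compromise.  If an
#' inconsistency is met mid-way the metrization is retried with a fresh
#' pair order, up to `max_retry` times.
#'
#' @param bounds a smoothed [bounds_matrix()].
#' @param seed integer seed; the same seed gives the identical matrix.
#' @param fraction fraction of pairs to fix with propagation.
#' @param max_retry bounded number of re-orderings before failing.
#' @return symmetric distance matrix satisfying all pair bounds.
#' @export
metrize_sample <- function(bounds, seed = 1L, fraction = 0.1,
                           max_retry = 5L) {
  stopifnot(inherits(bounds, "bounds_matrix"))
  n <- nrow(bounds$atoms)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  m <- max(1L, round(fraction * nrow(pairs)))
  for (attempt in seq_len(max_retry)) {
    res <- with_seed(seed + (attempt - 1L) * 104729L, {
      sel <- pairs[sample.int(nrow(pairs), m), , drop = FALSE]
      cpp_metrize(bounds$lower, bounds$upper, sel - 1L)
    })
    if (isTRUE(res$ok)) {
      D <- res$dist
      dimnames(D) <- dimnames(bounds$lower)
      return(D)
    }
  }
  i <- res$bad %/% n + 1L
  j <- res$bad %% n + 1L
  stop("metrization failed after ", max_retry, " attempts at pair ",
       atom_ids(bounds$atoms)[i], " / ", atom_ids(bounds$atoms)[j])
}

#' Metric-matrix embedding of a distance matrix
#'
#' Classical multidimensional scaling: the squared-distance matrix is
#' double-centred into a Gram matrix whose leading eigenpairs give the
#' coordinates.  Exact Euclidean input is reproduced up to rigid motion
#' and reflection.  If fewer than `dimensions` eigenvalues are positive
#' the geometry is degenerate: a lower-rank embedding is returned with a
#' warning and the missing columns set to zero.
#'
#' @param distances symmetric matrix with zero diagonal.
#' @param dimensions 3, or 4 for the four-dimensional refinement path.
#' @return coordinate matrix (n x dimensions) with attribute
#'   `"eigenvalues"`.
#' @export
embed_distances <- function(distances, dimensions = 3L) {
  D <- as.matrix(distances)
  n <- nrow(D)
  if (n != ncol(D) || any(abs(diag(D)) > 1e-9))
    stop("need a square distance matrix with zero diagonal")
  if (max(abs(D - t(D))) > 1e-9) stop("distance matrix must be symmetric")
  D2 <- D^2
  rm_ <- rowMeans(D2); gm <- mean(D2)
  B <- -0.5 * (sweep(sweep(D2, 1L, rm_), 2L, rm_) + gm)
  e <- eigen(B, symmetric = TRUE)
  pos <- sum(e$values > 1e-9 * max(abs(e$values)))
  k <- min(dimensions, pos)
  X <- matrix(0, n, dimensions)
  if (k > 0L)
    X[, seq_len(k)] <- e$vectors[, seq_len(k), drop = FALSE] %*%
      diag(sqrt(e$values[seq_len(k)]), k)
  if (pos < dimensions)
    warning("degenerate geometry: only ", pos,
            " positive eigenvalue(s); returning rank-", k, " embedding")
  rownames(X) <- rownames(D)
  attr(X, "eigenvalues") <- e$values
  X
}

# chirality quadruples (CA, C, N, CB) per non-Gly residue, 1-based indices
.chirality_quads <- function(atoms) {
  ids <- atom_ids(atoms)
  res <- unique(atoms$resid[atoms$reskind != "G"])
  quads <- matrix(0L, 0L, 4L)
  for (r in res) {
    q <- match(paste0(r, ".", c("CA", "C", "N", "CB")), ids)
    if (!anyNA(q)) quads <- rbind(quads, q)
  }
  quads
}

# 0-based copy for the C++ kernels
.quads0 <- function(quads) if (nrow(quads)) quads - 1L else quads

# weight matrix of a bounds object (all-ones for objects built without one)
.bounds_weight <- function(bounds) {
  bounds$weight %||% matrix(1, nrow(bounds$lower), ncol(bounds$lower))
}

# signed chiral volumes of a 3D coordinate set for the given quads
.chiral_volumes <- function(X, quads) {
  if (!nrow(quads)) return(numeric())
  vapply(seq_len(nrow(quads)), function(k)
    chiral_volume(X[quads[k, 3L], 1:3], X[quads[k, 1L], 1:3],
                  X[quads[k, 2L], 1:3], X[quads[k, 4L], 1:3]),
    numeric(1L))
}

#' Count of inverted (D-configuration) alpha-carbon centres
#' @param conf a 3D [conformer()].
#' @return number of chiral centres with non-positive signed volume.
#' @export
count_chirality_inversions <- function(conf) {
  stopifnot(inherits(conf, "conformer"), ncol(conf$coords) == 3L)
  quads <- .chirality_quads(conf$atoms)
  sum(.chiral_volumes(conf$coords, quads) <= 0)
}

#' Four-dimensional refinement of an embedded conformer
#'
#' Minimizes the squared bound-violation penalty plus an L-configuration
#' chirality penalty, with the fourth coordinate suppressed by a quadratic
#' penalty whose weight is annealed upward until the fourth dimension
#' collapses (max |x4| below `collapse`); the conformer is then projected
#' to 3D and polished.  The extra dimension lets wrong-handed centres
#' invert smoothly instead of getting trapped, which is the point of
#' refining in four dimensions.  Because an embedding is only defined up
#' to reflection, the conformer is mirror-imaged first whenever the
#' majority of alpha-carbon centres are inverted.  Each stage runs a
#' bounded-memory quasi-Newton descent (L-BFGS) on the analytic gradient.
#'
#' @param conf a 4-column [conformer()] from [embed_distances()] (a 3D
#'   conformer is polished directly).
#' @param bounds the [bounds_matrix()] being satisfied.
#' @param w4_init,w4_factor annealing schedule of the fourth-dimension
#'   penalty weight.
#' @param collapse threshold on |x4| (A) for projection to 3D.
#' @param iters descent iterations per annealing stage.
#' @param wchir,vmin chirality penalty weight and minimum target volume
#'   (A^3).
#' @return a 3D [conformer()] with the restraint-penalty energy.
#' @export
refine_conformer <- function(conf, bounds, w4_init = 0.02, w4_factor = 2,
                             collapse = 1e-3, iters = 250L,
                             wchir = 20, vmin = 0.25) {
  stopifnot(inherits(conf, "conformer"), inherits(bounds, "bounds_matrix"))
  X <- conf$coords
  quads <- .chirality_quads(bounds$atoms)
  q0 <- .quads0(quads)
  L <- bounds$lower; U <- bounds$upper; W <- .bounds_weight(bounds)
  n <- nrow(X)
  fn <- function(p, w4, d) cpp_energy(matrix(p, n, d), L, U, W, w4, q0,
                                      wchir, vmin)$energy
  gr <- function(p, w4, d) as.numeric(cpp_energy(matrix(p, n, d), L, U, W,
                                                 w4, q0, wchir, vmin)$grad)
  reflect_if_majority_inverted <- function(X) {
    if (nrow(quads)) {
      vols <- .chiral_volumes(X, quads)
      if (sum(vols < 0) > length(vols) / 2) X[, 1L] <- -X[, 1L]
    }
    X
  }
  X <- reflect_if_majority_inverted(X)
  if (ncol(X) == 4L) {
    w4 <- w4_init
    for (stage in 1:24) {
      o <- stats::optim(as.numeric(X), fn, gr, w4 = w4, d = 4L,
                        method = "L-BFGS-B", control = list(maxit = iters))
      X <- matrix(o$par, n, 4L)
      if (max(abs(X[, 4L])) < collapse) break
      w4 <- w4 * w4_factor
    }
    X <- X[, 1:3, drop = FALSE]
  } else if (ncol(X) != 3L) stop("conformer must be 3D or 4D")
  X <- reflect_if_majority_inverted(X)
  o <- stats::optim(as.numeric(X), fn, gr, w4 = 0, d = 3L,
                    method = "L-BFGS-B",
                    control = list(maxit = 12L * iters, factr = 1e3))
  X <- matrix(o$par, n, 3L)
  if (!all(is.finite(X)) || !is.finite(o$value))
    stop("non-finite energy during refinement")
  conformer(X, bounds$atoms, energy = o$value,
            metadata = c(conf$metadata, list(stage = "refined")))
}

#' Fixed-schedule penalty minimization of a conformer
#'
#' Exactly `sd_steps` steepest-descent steps followed by `cg_steps`
#' conjugate-gradient steps on the restraint-penalty energy (which
#' includes the scaled van der Waals soft-sphere lower bounds of the
#' bounds matrix), each step displacing no atom by more than `step` (A).
#' The energy is non-increasing across the run.
#'
#' @param conf a 3D [conformer()].
#' @param bounds a [bounds_matrix()].
#' @param sd_steps,cg_steps,step schedule parameters (defaults: 200
#'   steepest-descent and 10 conjugate-gradient steps of 0.02 A).
#' @param wchir,vmin chirality penalty parameters.
#' @return the minimized [conformer()].
#' @export
minimize_conformer <- function(conf, bounds, sd_steps = 200L,
                               cg_steps = 10L, step = 0.02,
                               wchir = 10, vmin = 0.25) {
  stopifnot(inherits(conf, "conformer"), ncol(conf$coords) == 3L)
  quads <- .chirality_quads(bounds$atoms)
  r <- cpp_minimize(conf$coords, bounds$lower, bounds$upper,
                    .bounds_weight(bounds), .quads0(quads), wchir, vmin,
                    sd_steps, cg_steps, step)
  conformer(r$X, bounds$atoms, energy = r$energy,
            metadata = c(conf$metadata, list(stage = "minimized")))
}

#' Restraint-penalty energy of a conformer against a bounds matrix
#' @param conf a 3D [conformer()].
#' @param bounds a [bounds_matrix()].
#' @return penalty energy (A^2).
#' @export
conformer_energy <- function(conf, bounds) {
  quads <- .chirality_quads(bounds$atoms)
  cpp_energy(conf$coords, bounds$lower, bounds$upper,
             .bounds_weight(bounds), 0, .quads0(quads), 10, 0.25)$energy
}
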