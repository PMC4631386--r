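# Conformer ensembles: seeded generation (metrize -> embed -> refine ->
# minimize) and lowest-energy selection.

#' Conformer ensemble
#'
#' @param conformers list of [conformer()]s sharing one atom roster.
#' @param selection_rule optional list `list(n_generated, n_kept)`.
#' @param failures optional list of per-run failure records.
#' @return an object of class `conformer_ensemble`.
#' @export
conformer_ensemble <- function(conformers, selection_rule = NULL,
                               failures = list()) {
  if (!length(conformers)) stop("empty ensemble")
  ref <- atom_ids(conformers[[1L]]$atoms)
  for (c in conformers)
    if (!identical(atom_ids(c$atoms), ref))
      stop("conformers do not share a common atom roster")
  structure(list(conformers = conformers, selection_rule = selection_rule,
                 failures = failures),
            class = "conformer_ensemble")
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  en <- vapply(x$conformers, function(c) c$energy, numeric(1L))
  cat(sprintf("conformer_ensemble: %d conformer(s), %d atoms",
              length(x$conformers), nrow(x$conformers[[1L]]$coords)))
  if (!all(is.na(en)))
    cat(sprintf(", energies %.3f-%.3f A^2", min(en, na.rm = TRUE),
                max(en, na.rm = TRUE)))
  if (!is.null(x$selection_rule))
    cat(sprintf(" [kept %d of %d]", x$selection_rule$n_kept,
                x$selection_rule$n_generated))
  if (length(x$failures)) cat(sprintf(", %d failed run(s)", length(x$failures)))
  cat("\n")
  invisible(x)
}

#' @export
length.conformer_ensemble <- function(x) length(x$conformers)

#' Energies of an ensemble's conformers
#' @param ensemble a [conformer_ensemble()].
#' @return numeric vector.
#' @export
ensemble_energies <- function(ensemble) {
  vapply(ensemble$conformers, function(c) c$energy, numeric(1L))
}

#' Generate a conformer ensemble by repeated distance-geometry runs
#'
#' Runs `n` independent metrize -> embed(4D) -> refine -> minimize chains,
#' run `i` seeded `seed + i - 1`, so the whole ensemble is reproducible
#' from one base seed.  Runs that fail (metrization inconsistency,
#' degenerate embedding) are recorded in the result's `failures` field
#' rather than silently dropped; only if every run fails is an error
#' raised, carrying the per-run diagnostics.
#'
#' A run whose refined penalty energy stays above `reanneal_energy` is
#' lifted back into four dimensions (fresh seeded fourth coordinate) and
#' re-annealed up to `reanneal` times: the extra dimension lets a
#' misfolded structure escape its local minimum, and the rescue is part of
#' the seeded, reproducible protocol.
#'
#' @param bounds a [bounds_matrix()] (smoothed internally).
#' @param n number of structures to calculate.
#' @param seed base seed.
#' @param fraction metrization fraction (see [metrize_sample()]).
#' @param minimize run the fixed-schedule minimization after refinement.
#' @param reanneal maximum number of 4D re-annealing rescues per run.
#' @param reanneal_energy penalty-energy threshold (A^2) triggering a
#'   rescue.
#' @param verbose report per-run progress to stderr.
#' @return a [conformer_ensemble()].
#' @export
generate_ensemble <- function(bounds, n = 97L, seed = 1L, fraction = 0.05,
                              minimize = TRUE, reanneal = 1L,
                              reanneal_energy = 8, verbose = FALSE) {
  stopifnot(inherits(bounds, "bounds_matrix"), n >= 1L)
  sm <- smooth_bounds(bounds)
  confs <- list(); fails <- list()
  for (i in seq_len(n)) {
    si <- seed + i - 1L
    res <- tryCatch({
      D <- metrize_sample(sm, seed = si, fraction = fraction)
      X4 <- suppressWarnings(embed_distances(D, dimensions = 4L))
      c0 <- conformer(X4, sm$atoms, metadata = list(seed = si))
      cf <- refine_conformer(c0, sm)
      tries <- 0L
      while (cf$energy > reanneal_energy && tries < reanneal) {
        tries <- tries + 1L
        x4 <- with_seed(si + 7919L * tries,
                        stats::runif(nrow(cf$coords), -1.5, 1.5))
        cf <- refine_conformer(conformer(cbind(cf$coords, x4), sm$atoms,
                                         metadata = cf$metadata), sm)
      }
      if (minimize) cf <- minimize_conformer(cf, sm)
      cf
    }, error = function(e) e)
    if (inherits(res, "error")) {
      fails[[length(fails) + 1L]] <- list(run = i, seed = si,
                                          message = conditionMessage(res))
      if (verbose) message(sprintf("run %d (seed %d): FAILED: %s", i, si,
                                   conditionMessage(res)))
    } else {
      confs[[length(confs) + 1L]] <- res
      if (verbose) message(sprintf("run %d (seed %d): energy %.4f", i, si,
                                   res$energy))
    }
  }
  if (!length(confs)) {
    msgs <- vapply(fails, function(f)
      sprintf("run %d (seed %d): %s", f$run, f$seed, f$message),
      character(1L))
    stop("all ", n, " distance-geometry runs failed:\n",
         paste(msgs, collapse = "\n"))
  }
  conformer_ensemble(confs,
                     selection_rule = list(n_generated = n,
                                           n_kept = length(confs)),
                     failures = fails)
}

#' Keep the lowest-energy conformers of an ensemble
#'
#' Sorts by ascending penalty energy (ties broken by generation order,
#' i.e. seed order) and keeps the `k` smallest.
#'
#' @param ensemble a [conformer_ensemble()].
#' @param k number of conformers to keep.
#' @return a [conformer_ensemble()] of `k` conformers sorted by energy.
#' @export
select_lowest <- function(ensemble, k = 21L) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  en <- ensemble_energies(ensemble)
  if (k < 1L || k > length(en))
    stop("k must be between 1 and the ensemble size (", length(en), ")")
  ord <- order(en)  # stable: ties keep generation order
  keep <- ord[seq_len(k)]
  conformer_ensemble(
    ensemble$conformers[keep],
    selection_rule = list(
      n_generated = ensemble$selection_rule$n_generated %||% length(en),
      n_kept = k),
    failures = ensemble$failures)
}
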