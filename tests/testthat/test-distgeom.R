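# Distance-geometry engine: bounds construction, triangle smoothing,
# metrization, embedding, refinement, minimization.

test_that("build_bounds fixes covalent geometry and merges restraints", {
  gg <- peptide_sequence("GG")
  b <- build_bounds(gg)
  ids <- rownames(b$lower)
  # N-CA fixed at the ideal bond length, both bounds
  expect_equal(b$lower["1.N", "1.CA"], b$upper["1.N", "1.CA"])
  expect_equal(b$lower["1.N", "1.CA"], 1.458, tolerance = 1e-6)
  # a default long-range pair carries the scaled vdW sum below and the
  # ceiling above
  expect_equal(b$lower["1.H", "2.O"], 0.9 * (1.1 + 1.52), tolerance = 1e-9)
  expect_gt(b$upper["1.H", "2.HA2"], 100)

  # an experimental restraint intersects the defaults: default lower wins
  # when tighter
  r <- restraint_table("1.HA2", "2.HA2", 1.8, 3.5)
  b2 <- build_bounds(gg, r)
  expect_equal(b2$lower["1.HA2", "2.HA2"], max(1.8, 0.9 * 2.2))
  expect_equal(b2$upper["1.HA2", "2.HA2"], 3.5)
  expect_equal(b2$weight["1.HA2", "2.HA2"], 5)

  # a restraint contradicting covalent geometry is an error
  bad <- restraint_table("1.N", "1.CA", 0.5, 1.0)
  expect_error(build_bounds(gg, bad), "contradicts the holonomic")
})

test_that("smooth_bounds equals the shortest-path oracle and is idempotent", {
  # hand-checked 3-atom case: u(A,C) collapses to u(A,B)+u(B,C)
  atoms <- data.frame(resid = 1L, reskind = "G",
                      name = c("A", "B", "C"), elem = "C")
  L <- matrix(0.5, 3, 3); diag(L) <- 0
  U <- matrix(c(0, 2, 10, 2, 0, 2, 10, 2, 0), 3, 3)
  sm <- smooth_bounds(bounds_matrix(atoms, L, U))
  expect_equal(sm$upper[1L, 3L], 4)

  # inverse triangle inequality raises the lower bound:
  # l(A,C) >= l(A,B) - u(B,C)
  L2 <- matrix(0, 3, 3); L2[1L, 2L] <- L2[2L, 1L] <- 5
  U2 <- matrix(c(0, 9, 9, 9, 0, 1, 9, 1, 0), 3, 3)
  sm2 <- smooth_bounds(bounds_matrix(atoms, L2, U2))
  expect_gte(sm2$lower[1L, 3L], 4)

  # random instances match a plain-R Floyd-Warshall oracle, and
  # smoothing is idempotent
  for (s in 1:25) {
    rb <- random_bounds(10L, seed = s)
    at10 <- data.frame(resid = 1L, reskind = "G",
                       name = paste0("X", 1:10), elem = "C")
    bm <- bounds_matrix(at10, rb$lower, rb$upper)
    sm <- smooth_bounds(bm)
    expect_equal(unname(sm$upper), unname(fw_oracle(rb$upper)),
                 tolerance = 1e-12)
    sm_again <- smooth_bounds(sm)
    expect_equal(sm_again$upper, sm$upper, tolerance = 1e-12)
    expect_equal(sm_again$lower, sm$lower, tolerance = 1e-12)
  }

  # inconsistent bounds are named
  L3 <- matrix(0, 3, 3); L3[1L, 3L] <- L3[3L, 1L] <- 8
  expect_error(smooth_bounds(bounds_matrix(atoms, L3, U)),
               "1\\.A / 1\\.[BC]")
})

test_that("metrization samples within bounds and is seed-deterministic", {
  sm <- fx_smooth_bounds()
  D1 <- metrize_sample(sm, seed = 3)
  D2 <- metrize_sample(sm, seed = 3)
  expect_identical(D1, D2)
  D3 <- metrize_sample(sm, seed = 4)
  expect_false(identical(D1, D3))
  # all sampled distances respect the smoothed bounds
  expect_true(all(D1 >= sm$lower - 1e-9))
  expect_true(all(D1 <= sm$upper + 1e-9))

  # fully tight bounds reproduce themselves for any seed
  atoms <- data.frame(resid = 1L, reskind = "G",
                      name = c("A", "B", "C"), elem = "C")
  Dfix <- as.matrix(stats::dist(matrix(c(0, 0, 0, 3, 0, 0, 0, 4, 0),
                                       3, 3, byrow = TRUE)))
  bt <- bounds_matrix(atoms, Dfix, Dfix)
  for (s in c(1, 7, 99))
    expect_equal(unname(metrize_sample(bt, seed = s)), unname(Dfix),
                 tolerance = 1e-12)
})

test_that("metric-matrix embedding reproduces Euclidean geometry", {
  # equilateral triangle, side 1 (planar, so a 3D request warns)
  D <- matrix(1, 3, 3); diag(D) <- 0
  X <- suppressWarnings(embed_distances(D, dimensions = 3L))
  expect_equal(as.matrix(stats::dist(X)), D, tolerance = 1e-8,
               ignore_attr = TRUE)

  # distances measured from a known conformer embed back to it
  helix <- fx_helix()
  Dh <- as.matrix(stats::dist(helix$coords))
  Xh <- embed_distances(Dh, dimensions = 3L)
  # embedding is defined up to reflection: superpose the better mirror
  rmsd <- min(rmsd_fit(Xh, helix$coords),
              rmsd_fit(Xh %*% diag(c(-1, 1, 1)), helix$coords))
  expect_lt(rmsd, 1e-6)

  # colinear points are rank-deficient and flagged
  P <- cbind(0:3, 0, 0)
  expect_warning(X1 <- embed_distances(as.matrix(stats::dist(P)), 3L),
                 "degenerate")
  expect_lt(max(abs(X1[, 2:3])), 1e-8)
})

test_that("refinement reaches 3D bound-satisfying, L-configured structures", {
  sm <- fx_smooth_bounds()
  helix <- fx_helix()
  # an already-satisfying 3D conformer is a fixed point up to the residual
  # soft-sphere strain of the generator's rigid rotamers
  c0 <- conformer(helix$coords, helix$atoms)
  e0 <- conformer_energy(c0, sm)
  r0 <- refine_conformer(c0, sm)
  expect_lte(r0$energy, e0 + 1e-9)
  # the backbone barely moves; sidechains may relax packing strain
  bb <- helix$atoms$name %in% c("N", "CA", "C")
  expect_lt(max(abs(r0$coords[bb, ] - helix$coords[bb, ])), 1.0)

  # a mirror-imaged helix is detected and re-inverted
  mir <- conformer(helix$coords %*% diag(c(-1, 1, 1)), helix$atoms)
  expect_equal(count_chirality_inversions(mir),
               length(unique(helix$atoms$resid[helix$atoms$reskind != "G"])))
  rmir <- refine_conformer(mir, sm)
  expect_equal(count_chirality_inversions(rmir), 0L)

  # a full metrize -> embed -> refine chain recovers the fold for a
  # well-behaved seed
  D <- metrize_sample(sm, seed = 12)
  X4 <- suppressWarnings(embed_distances(D, dimensions = 4L))
  rf <- refine_conformer(conformer(X4, sm$atoms), sm)
  expect_equal(ncol(rf$coords), 3L)
  expect_equal(count_chirality_inversions(rf), 0L)
})

test_that("the fixed-schedule minimizer never raises the energy", {
  sm <- fx_smooth_bounds()
  helix <- fx_helix()
  set.seed(8)
  pert <- conformer(helix$coords + matrix(stats::rnorm(length(helix$coords),
                                                       0, 0.3),
                                          nrow(helix$coords)), helix$atoms)
  e_before <- conformer_energy(pert, sm)
  m <- minimize_conformer(pert, sm)
  expect_lt(m$energy, e_before)

  # per-restraint violations do not grow in aggregate
  rest <- fx_restraints()
  v_before <- sum(violation_report(pert, rest)$max_violation)
  v_after <- sum(violation_report(m, rest)$max_violation)
  expect_lte(v_after, v_before)

  # an energy-zero input stays put
  zero_atoms <- data.frame(resid = 1L, reskind = "G",
                           name = c("A", "B"), elem = "C")
  Dz <- matrix(c(0, 3, 3, 0), 2, 2)
  bz <- bounds_matrix(zero_atoms, Dz - c(0, 1, 1, 0), Dz + c(0, 1, 1, 0))
  cz <- conformer(matrix(c(0, 0, 0, 3, 0, 0), 2, 3, byrow = TRUE),
                  zero_atoms)
  mz <- minimize_conformer(cz, bz)
  expect_equal(mz$coords, cz$coords, tolerance = 1e-12)
  expect_equal(mz$energy, 0)
})

test_that("ensemble generation is seeded and selection keeps lowest energies", {
  sm <- fx_bounds()
  ens <- generate_ensemble(sm, n = 4L, seed = 11L)
  expect_lte(length(ens$failures), 3L)
  expect_equal(ens$selection_rule$n_generated, 4L)

  # n = k = 1 works
  one <- select_lowest(generate_ensemble(sm, n = 1L, seed = 12L), 1L)
  expect_equal(length(one), 1L)

  # selection semantics: energies {5, 1, 3}, keep 2 -> {1, 3}
  helix <- fx_helix()
  mk <- function(e) conformer(helix$coords, helix$atoms, energy = e)
  toy <- conformer_ensemble(list(mk(5), mk(1), mk(3)))
  kept <- select_lowest(toy, 2L)
  expect_equal(ensemble_energies(kept), c(1, 3))
  expect_error(select_lowest(toy, 4L), "between 1 and")

  # bit-reproducibility of a full generation for a fixed seed
  e1 <- generate_ensemble(sm, n = 2L, seed = 31L)
  e2 <- generate_ensemble(sm, n = 2L, seed = 31L)
  expect_identical(lapply(e1$conformers, `[[`, "coords"),
                   lapply(e2$conformers, `[[`, "coords"))
})
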