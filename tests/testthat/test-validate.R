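# Validation metrics: violation statistics, ensemble precision, CSP-contact
# consistency.

# a minimal two-atom conformer at a chosen separation
two_atom <- function(d) {
  atoms <- data.frame(resid = c(1L, 2L), reskind = "G",
                      name = c("HA2", "HA3"), elem = "H")
  conformer(matrix(c(0, 0, 0, d, 0, 0), 2L, 3L, byrow = TRUE), atoms)
}

test_that("violation_report measures one-sided bound violations", {
  r_up <- restraint_table("1.HA2", "2.HA3", 1.8, 4.0)
  # 4.5 A against upper 4.0 -> 0.5 A violation
  v1 <- violation_report(two_atom(4.5), r_up)
  expect_equal(v1$max_violation, 0.5, tolerance = 1e-12)
  expect_equal(v1$n_violated_conformers, 1L)
  # inside the bounds -> zero
  v2 <- violation_report(two_atom(2.0), restraint_table("1.HA2", "2.HA3",
                                                        1.8, 3.5))
  expect_equal(v2$max_violation, 0)
  # below the lower bound counts too
  v3 <- violation_report(two_atom(1.0), r_up)
  expect_equal(v3$max_violation, 0.8, tolerance = 1e-12)

  # aggregation across an ensemble, with the summary consistent
  ens <- conformer_ensemble(list(two_atom(4.5), two_atom(3.0)))
  v4 <- violation_report(ens, r_up)
  expect_equal(v4$max_violation, 0.5)
  expect_equal(v4$mean_violation, 0.25)
  expect_equal(v4$n_violated_conformers, 1L)
  s <- attr(v4, "summary")
  expect_equal(s$n_over_0.1, 1L)
  expect_equal(s$n_over_0.5, 0L)
  expect_equal(s$largest, 0.5)

  # missing atoms are named
  expect_error(violation_report(two_atom(3), restraint_table("1.HA2",
                                                             "7.HZ", 1.8, 4)),
               "7.HZ")
})

test_that("ensemble RMSD satisfies metric axioms and uses a medoid", {
  helix <- fx_helix()
  dup <- conformer(helix$coords, helix$atoms)
  shifted <- conformer(helix$coords + 5, helix$atoms)
  r <- ensemble_rmsd(conformer_ensemble(list(helix, dup, shifted)))
  # identical and rigidly shifted copies superpose to zero
  expect_equal(r$mean_pairwise, 0, tolerance = 1e-9)
  expect_true(all(r$to_medoid < 1e-9))
  # symmetry of the pairwise matrix
  expect_equal(r$pairwise, t(r$pairwise), tolerance = 1e-12)

  expect_error(ensemble_rmsd(conformer_ensemble(list(helix))), "at least 2")
  expect_error(ensemble_rmsd(conformer_ensemble(list(helix, dup)),
                             region = 999), "empty")
})

test_that("restrained regions are more precise than unrestrained ones", {
  # restraints covering only residues 65-72: the covered backbone
  # converges, the uncovered N-terminal tail stays disordered
  seq <- fx_r4_sequence()
  peaks <- fx_noe_peaks()
  core <- peaks[{
    ri <- as.integer(sub("\\..*", "", peaks$atom_i))
    rj <- as.integer(sub("\\..*", "", peaks$atom_j))
    (ri >= 65 & ri <= 72 & rj >= 65 & rj <= 72) | peaks$is_reference
  }, ]
  class(core) <- class(peaks)
  rest_core <- build_restraints(core, NULL, seq)
  ens <- select_lowest(generate_ensemble(build_bounds(seq, rest_core),
                                         n = 10L, seed = 21L), 3L)
  # superpose every pair on the restrained core, then compare the spread
  # of the core itself with the spread of the unrestrained tail
  r_core <- ensemble_rmsd(ens, region = 65:72)
  r_tail <- ensemble_rmsd(ens, region = 62:64, fit_region = 65:72)
  expect_lt(r_core$mean_pairwise, r_tail$mean_pairwise)
})

test_that("CSP-contact consistency scores poses by rank correlation", {
  # constructed geometry: partner residues on a line, peptide at origin;
  # the highest-CSP residues are the closest
  set.seed(30)
  nres <- 12L
  dist_along <- seq(2, 30, length.out = nres)
  partner <- cbind(dist_along, 0, 0)
  partner_resid <- seq_len(nres)
  peptide <- matrix(c(0, 0, 0, 0.5, 0, 0), 2L, 3L, byrow = TRUE)
  d_csp <- rev(seq_len(nres)) / 100  # CSP decreasing with distance
  prof <- csp_profile(partner_resid, d_csp)
  sc <- csp_contact_consistency(partner, partner_resid, peptide, prof)
  expect_gt(sc$rank_correlation, 0.8)

  # rigid motion of the whole pose leaves the score unchanged
  R <- diag(3)[c(2, 3, 1), ]
  sc2 <- csp_contact_consistency(partner %*% R + 7, partner_resid,
                                 peptide %*% R + 7, prof)
  expect_equal(sc2$rank_correlation, sc$rank_correlation, tolerance = 1e-12)

  # uniform profile: undefined correlation is an error
  expect_error(csp_contact_consistency(partner, partner_resid, peptide,
                                       csp_profile(partner_resid,
                                                   rep(0.05, nres))),
               "uniform")

  # a far-translated peptide against a random profile scores near zero
  set.seed(31)
  d_rand <- stats::runif(nres, 0, 0.1)
  far <- peptide + 100
  sc3 <- csp_contact_consistency(partner, partner_resid, far,
                                 csp_profile(partner_resid, d_rand))
  expect_lt(abs(sc3$rank_correlation), 0.75)

  expect_error(csp_contact_consistency(partner[1:2, ], partner_resid[1:2],
                                       peptide,
                                       csp_profile(1:2, c(0.1, 0.2))),
               "at least 3")
})
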