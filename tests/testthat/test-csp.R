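# CSP computation, peak tracking and sigma-tier epitope classification.

test_that("compute_csp matches the hand-evaluated weighted distance", {
  expect_equal(compute_csp(0, 0, "A"), 0)
  # frozen hand evaluations: sqrt((dH^2 + (alpha dN)^2)/2)
  expect_equal(compute_csp(0.05, 0.20, "L"),
               sqrt((0.05^2 + (0.14 * 0.20)^2) / 2), tolerance = 1e-12)
  expect_equal(compute_csp(0.05, 0.20, "L"), 0.04052160, tolerance = 1e-5)
  expect_equal(compute_csp(0, 0.10, "G"), 0.020 / sqrt(2), tolerance = 1e-12)
  expect_equal(compute_csp(0, 0.10, "G"), 0.01414214, tolerance = 1e-5)

  # property: agrees with a brute-force two-term evaluation on random
  # inputs for both alpha values
  set.seed(99)
  dh <- stats::rnorm(500, 0, 0.1)
  dn <- stats::rnorm(500, 0, 0.5)
  kinds <- sample(c("G", "A", "K", "F"), 500, replace = TRUE)
  brute <- vapply(seq_len(500), function(i) {
    a <- if (kinds[i] == "G") 0.20 else 0.14
    sqrt(0.5 * (dh[i]^2 + (a * dn[i])^2))
  }, numeric(1L))
  expect_equal(compute_csp(dh, dn, kinds), brute, tolerance = 1e-12)
})

test_that("track_peaks follows drifting peaks and flags ambiguity", {
  # single residue drifting linearly over 3 points
  mk <- function(h, n, r) peak_table(1L, "A", h, n, ratio_label = r)
  tr <- track_peaks(list(mk(8.0, 120, 0), mk(8.1, 120.5, 1),
                         mk(8.2, 121, 2)))
  expect_equal(tr$h[1L, ], c(8.0, 8.1, 8.2))
  expect_false(tr$ambiguous[1L])

  # two residues whose peaks land at comparable distances from both
  # previous positions are both ambiguous
  t0 <- peak_table(1:2, c("A", "A"), c(8.00, 8.16), c(120, 120),
                   ratio_label = 0)
  t1 <- peak_table(1:2, c("A", "A"), c(8.06, 8.10), c(120, 120),
                   ratio_label = 1)
  tr2 <- track_peaks(list(t0, t1))
  expect_true(all(tr2$ambiguous))

  # noiseless simulated titration: every trajectory recovers the
  # generator's peak positions exactly
  prof <- fx_shift_profile()
  cfg <- simulation_config(shift_noise = 0)
  tabs <- simulate_titration(cfg, prof)
  tr3 <- track_peaks(tabs)
  fs <- fraction_bound(cfg$protein_conc, cfg$ratios * cfg$protein_conc,
                       cfg$true_kd)
  keep <- !tr3$ambiguous
  expect_gt(mean(keep), 0.95)
  truth_h <- outer(prof$free_h, rep(1, length(fs))) + outer(prof$dh, fs)
  expect_equal(tr3$h[keep, ], truth_h[keep, ], tolerance = 1e-10,
               ignore_attr = TRUE)

  expect_error(track_peaks(list()), "empty")
})

test_that("classify_epitope applies strict sigma tiers", {
  # all-zero CSPs: sigma 0, nothing exceeds any tier
  p0 <- csp_profile(1:5, rep(0, 5))
  cls0 <- classify_epitope(p0)
  expect_equal(cls0$sigma, 0)
  expect_length(cls0$over_2sigma, 0L)
  expect_length(cls0$over_1sigma, 0L)

  # one large value among small ones: exactly one residue above sigma
  d <- c(0.1, 0.01, 0.01, 0.01, 0.01)
  sig <- sqrt(mean((d - mean(d))^2))
  cls1 <- classify_epitope(csp_profile(1:5, d))
  expect_equal(cls1$sigma, sig)
  expect_equal(sort(c(cls1$over_2sigma, cls1$over_1sigma)), 1L)
  expect_equal(sum(d > sig), 1L)

  # degenerate inputs
  expect_error(csp_profile(1:3, rep(NA_real_, 3)), "at least 2")
  expect_error(classify_epitope(csp_profile(1:3, c(0.1, NA, NA),
                                            sigma = 0.05)),
               "at least 2")

  # tier counts are invariant under global scaling of d
  set.seed(11)
  d2 <- stats::rexp(50, 20)
  c_a <- classify_epitope(csp_profile(1:50, d2))
  c_b <- classify_epitope(csp_profile(1:50, 10 * d2))
  expect_equal(c_a$over_2sigma, c_b$over_2sigma)
  expect_equal(c_a$over_1sigma, c_b$over_1sigma)
})

test_that("a planted epitope is recovered exactly at zero noise", {
  prof <- fx_shift_profile()
  tabs <- simulate_titration(simulation_config(shift_noise = 0), prof)
  csp <- csp_between(tabs[[1L]], tabs[[length(tabs)]])
  cls <- classify_epitope(csp)
  expect_setequal(cls$over_2sigma, 5:12)
  # unassigned residues never contribute to sigma
  csp_na <- csp
  csp_na$d[20:30] <- NA
  s2 <- attr(csp_profile(csp_na$residue_index, csp_na$d), "sigma")
  s_manual <- {
    dv <- csp_na$d[!is.na(csp_na$d)]
    sqrt(mean((dv - mean(dv))^2))
  }
  expect_equal(s2, s_manual)
})
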