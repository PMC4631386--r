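# Synthetic-data generators: ideal helix construction, NOESY intensities,
# fast-exchange titrations, plate reads.

test_that("the ideal helix has canonical geometry and is deterministic", {
  helix <- fx_helix()
  # rise per residue from a principal-axis fit of the CA trace
  ca <- helix$coords[helix$atoms$name == "CA", ]
  proj <- stats::prcomp(ca)$x[, 1L]
  expect_equal(mean(abs(diff(proj))), 1.5, tolerance = 0.05)

  # uniform L-configuration at every CA
  expect_equal(count_chirality_inversions(helix), 0L)

  # deterministic: bit-identical on repeat
  expect_identical(helix$coords, make_ideal_helix(fx_r4_sequence())$coords)

  # single glycine: backbone only, no sidechain beyond the two HA protons
  g <- make_ideal_helix(peptide_sequence("G"))
  expect_setequal(g$atoms$name, c("N", "H", "CA", "HA2", "HA3", "C", "O"))

  # proline is not supported
  expect_error(make_ideal_helix(peptide_sequence("GPG")), "unsupported")
})

test_that("geminal methylenes reproduce the analytic reference distance", {
  helix <- fx_helix()
  d <- sqrt(sum((helix$coords["65.HB2", ] - helix$coords["65.HB3", ])^2))
  expect_equal(d, geminal_reference_distance(), tolerance = 1e-9)
  expect_equal(round(d, 2), 1.78)
})

test_that("simulated NOESY intensities follow the r^-6 law", {
  helix <- fx_helix()
  peaks <- fx_noe_peaks()
  expect_equal(sum(peaks$is_reference), 1L)
  # the geminal reference pair sits at the calibration distance, so its
  # intensity is exactly 1
  expect_equal(peaks$intensity[peaks$is_reference], 1, tolerance = 1e-12)

  # every intensity equals (r_ref / r)^6 for the generated coordinates
  r <- vapply(seq_len(nrow(peaks)), function(k)
    sqrt(sum((helix$coords[peaks$atom_i[k], ] -
                helix$coords[peaks$atom_j[k], ])^2)), numeric(1L))
  expect_equal(peaks$intensity, (geminal_reference_distance() / r)^6,
               tolerance = 1e-10)
  # a pair at twice the reference distance would read 1/64
  expect_equal(intensity_to_distance(1 / 64), 2 * geminal_reference_distance(),
               tolerance = 1e-12)

  # every sequential amide-amide pair is inside the 5 A cutoff
  key <- paste(peaks$atom_i, peaks$atom_j)
  for (i in 62:72) {
    pair <- c(paste0(i, ".H ", i + 1L, ".H"), paste0(i + 1L, ".H ", i, ".H"))
    expect_true(any(pair %in% key), info = paste("HN-HN", i))
  }

  # intensities decrease with distance at zero noise (ties between
  # symmetry-equivalent pairs allowed to float precision)
  ord <- order(r)
  expect_true(all(diff(peaks$intensity[ord]) <= 1e-9))

  # noise is seeded: same config reproduces, different seed differs
  cfgA <- simulation_config(noe_noise = 0.02, seed = 5)
  cfgB <- simulation_config(noe_noise = 0.02, seed = 6)
  expect_identical(simulate_noesy(helix, cfgA)$intensity,
                   simulate_noesy(helix, cfgA)$intensity)
  expect_false(identical(simulate_noesy(helix, cfgA)$intensity,
                         simulate_noesy(helix, cfgB)$intensity))
})

test_that("titrations follow the ligand-depletion fast-exchange model", {
  prof <- fx_shift_profile()
  cfg <- simulation_config(shift_noise = 0)
  tabs <- simulate_titration(cfg, prof)
  expect_length(tabs, length(cfg$ratios))

  # zero ratio reproduces the free state exactly
  expect_equal(tabs[[1L]]$h_shift, prof$free_h, tolerance = 1e-12)
  expect_equal(tabs[[1L]]$n_shift, prof$free_n, tolerance = 1e-12)

  # at 1:1 and the default concentrations every residue is displaced by
  # f_bound ~ 0.3671 of its bound-state shift (closed-form mass balance)
  i11 <- which(cfg$ratios == 1)
  f <- fraction_bound(cfg$protein_conc, cfg$protein_conc, cfg$true_kd)
  expect_equal(f, 0.36714, tolerance = 1e-4)
  expect_equal(tabs[[i11]]$h_shift, prof$free_h + f * prof$dh,
               tolerance = 1e-10)
  expect_equal(tabs[[i11]]$n_shift, prof$free_n + f * prof$dn,
               tolerance = 1e-10)

  # saturation limit: a huge ligand excess at tiny K_D lands on
  # free + bound shift
  cfg_sat <- simulation_config(true_kd = 1e-12, ratios = c(0, 1e6),
                               shift_noise = 0)
  sat <- simulate_titration(cfg_sat, prof)[[2L]]
  expect_equal(sat$h_shift, prof$free_h + prof$dh, tolerance = 1e-6)

  # f_bound is within [0,1] and monotone along the default ratios
  fs <- fraction_bound(cfg$protein_conc, cfg$ratios * cfg$protein_conc,
                       cfg$true_kd)
  expect_true(all(fs >= 0 & fs <= 1))
  expect_true(all(diff(fs) >= 0))

  # the zero ratio is mandatory
  expect_error(simulation_config(ratios = c(0.5, 1, 2)), "start at 0")
})

test_that("plate simulation matches the dose-response closed form", {
  cfg <- simulation_config(plate_noise = 0)
  p <- cfg$plate_params
  plate <- simulate_plate(cfg)
  # midpoint identity at x = m3
  expect_equal(fourpl(p[["m3"]], p[["m1"]], p[["m2"]], p[["m3"]], p[["m4"]]),
               (p[["m1"]] + p[["m2"]]) / 2, tolerance = 1e-12)
  # zero-concentration limit is m2
  expect_equal(fourpl(0, p[["m1"]], p[["m2"]], p[["m3"]], p[["m4"]]),
               p[["m2"]], tolerance = 1e-12)
  # wells agree with the closed form at zero noise
  expect_equal(plate$signal,
               fourpl(plate$concentration, p[["m1"]], p[["m2"]], p[["m3"]],
                      p[["m4"]]), tolerance = 1e-10)

  # seeding: different seeds change only the noise
  n1 <- simulate_plate(simulation_config(seed = 1))
  n2 <- simulate_plate(simulation_config(seed = 2))
  expect_false(identical(n1$signal, n2$signal))
  expect_identical(n1$concentration, n2$concentration)
  base <- simulate_plate(simulation_config(plate_noise = 0))
  expect_equal(stats::sd(n1$signal - base$signal), 10, tolerance = 0.35)

  # the competition mode descends from the full signal
  comp <- simulate_plate(simulation_config(plate_noise = 0),
                         descending = TRUE)
  s <- tapply(comp$signal, comp$concentration, mean)
  expect_true(all(diff(s[order(as.numeric(names(s)))]) < 0))
})
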