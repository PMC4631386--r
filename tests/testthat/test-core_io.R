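# Readers and writers: TSV peak tables, assign-dialect restraints,
# multi-MODEL PDB, FASTA.

test_that("peak tables parse, reject malformed input, and round-trip", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#ratio 1.5", "# residue kind H N", "65\tF\t8.10\t118.2"), f)
  tab <- read_peak_table(f)
  expect_equal(attr(tab, "ratio"), 1.5)
  expect_equal(tab$residue_index, 65L)
  expect_equal(tab$residue_kind, "F")
  expect_equal(tab$h_shift, 8.10)
  expect_equal(tab$n_shift, 118.2)

  # empty file
  writeLines("#ratio 0", f)
  expect_error(read_peak_table(f), "no peaks")

  # malformed line carries the line number
  writeLines(c("#ratio 0", "65 F 8.10"), f)
  expect_error(read_peak_table(f), "line 2")
  writeLines(c("#ratio 0", "65 F eight 118.2"), f)
  expect_error(read_peak_table(f), "line 2")

  # duplicate residue
  expect_error(peak_table(c(5L, 5L), c("A", "A"), c(8, 8.1), c(120, 121)),
               "duplicate")

  # round trip of a 10-entry table (shifts at the writer's 5-decimal
  # resolution, so equality is exact)
  orig <- peak_table(1:10, rep(c("A", "G"), 5),
                     round(8 + (1:10) / 7, 5), round(110 + (1:10) / 3, 5),
                     ratio_label = 2)
  write_peak_table(orig, f)
  back <- read_peak_table(f)
  expect_equal(as.data.frame(back), as.data.frame(orig))
  expect_equal(attr(back, "ratio"), 2)

  # a CLI-style ratio override beats the header directive
  expect_equal(attr(read_peak_table(f, ratio = 9), "ratio"), 9)
})

test_that("restraint tables serialize to the assign dialect and back", {
  tab <- restraint_table(c("65.HB2", "65.HB2"), c("68.HN", "70.HA"),
                         c(1.8, 1.8), c(3.5, 5.0))
  f <- withr::local_tempfile(fileext = ".tbl")
  write_restraint_table(tab, f)
  lines <- readLines(f)
  expect_equal(lines[1L],
               "assign (resid 65 and name HB2)(resid 68 and name HN) 1.80 3.50")
  expect_equal(as.data.frame(read_restraint_table(f)), as.data.frame(tab))

  # empty table round-trips to an empty table
  write_restraint_table(restraint_table(), f)
  expect_equal(nrow(read_restraint_table(f)), 0L)

  # 80-row synthetic table keeps its count through the round trip
  n <- 80L
  big <- restraint_table(paste0(1:n, ".HA"), paste0(1:n + 1L, ".H"),
                         rep(1.8, n), rep(5, n))
  write_restraint_table(big, f)
  expect_equal(nrow(read_restraint_table(f)), 80L)

  # inverted bounds are rejected on read
  writeLines("assign (resid 1 and name HA)(resid 2 and name H) 5.0 1.8", f)
  expect_error(read_restraint_table(f), "lower > upper")

  # and at construction
  expect_error(restraint_table("1.HA", "2.H", 5, 1.8), "lower > upper")
})

test_that("multi-MODEL PDB writing and reading preserve the ensemble", {
  helix <- fx_helix()
  shifted <- conformer(helix$coords + 0.25, helix$atoms)
  ens <- conformer_ensemble(list(helix, shifted))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble(ens, f)
  lines <- readLines(f)
  expect_equal(sum(startsWith(lines, "MODEL")), 2L)
  expect_equal(sum(startsWith(lines, "ENDMDL")), 2L)

  back <- read_ensemble(f)
  expect_equal(length(back), 2L)
  expect_equal(back$conformers[[1L]]$atoms$name, helix$atoms$name)
  expect_lt(max(abs(back$conformers[[1L]]$coords - helix$coords)), 1e-3)
  expect_lt(max(abs(back$conformers[[2L]]$coords - shifted$coords)), 1e-3)

  # a single conformer writes one MODEL and is read by an independent
  # PDB parser
  write_ensemble(helix, f)
  expect_equal(sum(startsWith(readLines(f), "MODEL")), 1L)
  skip_if_not_installed("bio3d")
  pdb <- bio3d::read.pdb(f)
  expect_equal(nrow(pdb$atom), nrow(helix$coords))
  expect_equal(unname(pdb$atom$resno[1L]), 62)

  # inconsistent rosters are rejected
  gly <- make_ideal_helix(peptide_sequence("G"))
  expect_error(conformer_ensemble(list(helix, gly)), "roster")
})

test_that("FASTA sequences parse with numbering offsets and normalization", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">R4 start=62", "VRRFDLLKRILK"), f)
  s <- read_sequence(f)
  expect_equal(length(s), 12L)
  expect_equal(residue_numbers(s), 62:73)
  expect_equal(as.character(s), "VRRFDLLKRILK")

  writeLines(c(">x", "G"), f)
  s1 <- read_sequence(f)
  expect_equal(length(s1), 1L)
  expect_equal(s1$first_index, 1L)

  # lowercase input is upcased
  writeLines(c(">R4 start=62", "vrrfdllkrilk"), f)
  expect_equal(as.character(read_sequence(f)), "VRRFDLLKRILK")

  # multi-record files and illegal codes are rejected
  writeLines(c(">a", "GA", ">b", "GG"), f)
  expect_error(read_sequence(f), "single-record")
  expect_error(peptide_sequence("GAX"), "illegal")

  # writer round trip
  write_sequence(fx_r4_sequence(), f, name = "R4")
  expect_equal(residue_numbers(read_sequence(f)), 62:73)
})
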