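# Structure reading/writing and configuration objects.

test_that("a hand-written PDB is read back field-for-field, deterministically", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_tiny_pdb(path, c(
    pdb_line(1, "N", "GLY", "A", 1, 1.234, 2.345, 3.456, element = "N"),
    pdb_line(2, "CA", "GLY", "A", 1, 4.000, 5.250, -6.125),
    pdb_line(3, "C", "GLY", "A", 1, 7.100, 8.200, 9.300)))
  m <- read_structure(path)
  expect_s3_class(m, "AtomModel")
  expect_equal(nrow(m$atoms), 3)
  expect_equal(m$atoms$atom, c("N", "CA", "C"))
  expect_equal(m$atoms$x, c(1.234, 4.000, 7.100))
  expect_equal(m$atoms$y, c(2.345, 5.250, 8.200))
  expect_equal(m$atoms$z, c(3.456, -6.125, 9.300))
  m2 <- read_structure(path)
  expect_identical(m$atoms, m2$atoms)
})

test_that("alternate locations resolve to the highest-occupancy conformer", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_tiny_pdb(path, c(
    pdb_line(1, "CA", "ALA", "A", 1, 1, 1, 1, occ = 0.6, alt = "A"),
    pdb_line(2, "CA", "ALA", "A", 1, 2, 2, 2, occ = 0.4, alt = "B")))
  m <- read_structure(path)
  expect_equal(nrow(m$atoms), 1)
  expect_equal(m$atoms$x, 1)
  expect_equal(m$atoms$altloc, "A")
  # occupancy tie broken by altloc letter order
  write_tiny_pdb(path, c(
    pdb_line(1, "CA", "ALA", "A", 1, 9, 9, 9, occ = 0.5, alt = "B"),
    pdb_line(2, "CA", "ALA", "A", 1, 8, 8, 8, occ = 0.5, alt = "A")))
  expect_equal(read_structure(path)$atoms$altloc, "A")
})

test_that("missing files and unparseable content give clear errors", {
  expect_error(read_structure("no/such/file.pdb"), class = "elevator_io")
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines("this is not a structure", path)
  expect_error(read_structure(path), class = "elevator_format")
  write_tiny_pdb(path, pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0))
  expect_error(read_structure(path, chains = "Z"),
               class = "elevator_empty_selection")
  expect_error(read_structure(path, model = 3), class = "elevator_io")
})

test_that("extract_calpha keeps one CA per residue and logs dropped residues", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_tiny_pdb(path, peptide_pdb_lines(5))
  ca <- extract_calpha(read_structure(path))
  expect_equal(nrow(ca$xyz), 5)

  write_tiny_pdb(path, peptide_pdb_lines(5, skip_ca = 3))
  expect_warning(ca4 <- extract_calpha(read_structure(path)),
                 "A:3", class = "elevator_missing_ca")
  expect_equal(nrow(ca4$xyz), 4)
  expect_false(3 %in% ca4$residues$resno)

  # glycine-only: no CB requirement
  write_tiny_pdb(path, c(pdb_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
                         pdb_line(2, "CA", "GLY", "A", 2, 3.8, 0, 0)))
  expect_equal(nrow(extract_calpha(read_structure(path))$xyz), 2)

  write_tiny_pdb(path, pdb_line(1, "N", "ALA", "A", 1, 0, 0, 0, element = "N"))
  expect_error(extract_calpha(read_structure(path)),
               class = "elevator_empty_selection")
})

test_that("write_models round-trips coordinates and multi-model structure", {
  m <- random_calpha(8, seed = 3)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_models(path, m)
  back <- extract_calpha(read_structure(path))
  expect_lt(max(abs(back$xyz - m$xyz)), 0.001)
  expect_identical(back$residues$resno, m$residues$resno)

  frames <- lapply(1:10, function(i)
    calpha_model(m$residues, m$xyz + i * 0.1))
  write_models(path, frames)
  expect_equal(sum(grepl("^MODEL", readLines(path))), 10)
  f7 <- extract_calpha(read_structure(path, model = 7))
  expect_lt(max(abs(f7$xyz - frames[[7]]$xyz)), 0.001)

  bad <- calpha_model(data.frame(chain = "B", resno = 1:8, resname = "ALA"),
                      m$xyz)
  expect_error(write_models(path, list(m, bad)),
               class = "elevator_consistency")
})

test_that("residue numbers beyond 9999 survive a write/read round-trip", {
  res <- data.frame(chain = "A", resno = c(9999L, 10000L, 10001L),
                    resname = "ALA")
  m <- calpha_model(res, matrix(c(0, 0, 0, 3.8, 0, 0, 7.6, 0, 0),
                                ncol = 3, byrow = TRUE))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_models(path, m)
  # hybrid-36: width-4 field, 10000 -> A000 (verified by hand against the
  # fixed-column convention: A000 = 10*36^3 + 0 - offset)
  lines <- grep("^ATOM", readLines(path), value = TRUE)
  expect_equal(trimws(substr(lines, 23, 26)), c("9999", "A000", "A001"))
  back <- extract_calpha(read_structure(path))
  expect_identical(back$residues$resno, res$resno)
  expect_lt(max(abs(back$xyz - m$xyz)), 0.001)
})

test_that("read -> write -> read is the identity on coordinates and identity", {
  set.seed(11)
  res <- data.frame(chain = rep(c("A", "B"), c(4, 3)),
                    resno = c(1:4, 11:13),
                    resname = sample(c("ALA", "VAL", "GLY"), 7, replace = TRUE))
  m <- calpha_model(res, matrix(round(runif(21, -20, 20), 3), ncol = 3))
  p1 <- withr::local_tempfile(fileext = ".pdb")
  p2 <- withr::local_tempfile(fileext = ".pdb")
  write_models(p1, m)
  r1 <- extract_calpha(read_structure(p1))
  write_models(p2, r1)
  r2 <- extract_calpha(read_structure(p2))
  expect_identical(r1$residues[c("chain", "resno", "resname")],
                   r2$residues[c("chain", "resno", "resname")])
  expect_equal(r1$xyz, r2$xyz, tolerance = 1e-12)
  expect_lt(max(abs(r1$xyz - m$xyz)), 0.001)
})

test_that("domain definitions load, validate and reject overlap", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "domains:",
    "  dimer_domain: {A: [[1, 50]]}",
    "  core_domain: {A: [[51, 120]]}",
    "binding_site: {A: [90]}",
    "membrane_normal: [0, 0, 1]"), path)
  dom <- load_domain_definition(path)
  expect_equal(nrow(dom$domains$dimer_domain), 50)
  expect_equal(range(dom$domains$core_domain$resno), c(51, 120))
  expect_equal(dom$binding_site$resno, 90)
  expect_equal(dom$membrane_normal, c(0, 0, 1))

  writeLines(c(
    "domains:",
    "  dimer_domain: {A: [[1, 50]]}",
    "  core_domain: {A: [[30, 120]]}"), path)
  expect_error(load_domain_definition(path), "A:30",
               class = "elevator_validation")

  writeLines(c("domains:", "  dimer_domain: {A: [[1, 5]]}",
               "unknown_key: 1"), path)
  expect_error(load_domain_definition(path), "unknown_key",
               class = "elevator_validation")
})

test_that("domain definitions round-trip through YAML", {
  toy <- make_toy_elevator()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_domain_definition(toy$domains, path)
  back <- load_domain_definition(path)
  for (nm in names(toy$domains$domains))
    expect_setequal(paste(back$domains[[nm]]$chain, back$domains[[nm]]$resno),
                    paste(toy$domains$domains[[nm]]$chain,
                          toy$domains$domains[[nm]]$resno))
  expect_equal(back$membrane_normal, toy$domains$membrane_normal)
})

test_that("correspondence tables validate cells and uniqueness", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("s1\ts2", "A:1\tB:11", "A:2\tB:12"), path)
  corr <- load_correspondence(path)
  expect_equal(corr$ids, c("s1", "s2"))
  expect_equal(corr$entries$s2$resno, c(11L, 12L))

  writeLines(c("s1\ts2", "A:1\tB:11", "A:2\t"), path)
  expect_error(load_correspondence(path), "s2",
               class = "elevator_validation")

  writeLines(c("s1\ts2", "A:1\tB:11", "A:1\tB:12"), path)
  expect_error(load_correspondence(path), "s1",
               class = "elevator_validation")
})
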