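# Model reading/writing, atom selection, and resolution truncation.

test_that("a minimal one-atom P1 PDB round-trips through read and write", {
  p <- write_tiny_pdb()
  s <- read_model(p)
  expect_s3_class(s, "xtal_structure")
  expect_equal(nrow(s$atoms), 1L)
  expect_equal(s$atoms$occ, 1.0)
  expect_equal(s$unit_cell, c(10, 10, 10, 90, 90, 90))

  p2 <- tempfile(fileext = ".pdb")
  write_model(s, p2)
  s2 <- read_model(p2)
  expect_equal(as.matrix(s2$atoms[, c("x", "y", "z")]),
               as.matrix(s$atoms[, c("x", "y", "z")]),
               tolerance = 1e-3)               # PDB coordinate precision
  expect_identical(s2$atoms$occ, s$atoms$occ)
  expect_identical(s2$atoms$b, s$atoms$b)
})

test_that("invalid atom records are rejected", {
  p <- write_tiny_pdb(occ = 1.2)
  expect_error(read_model(p), "occupancy")
  expect_error(
    xtal_structure(c(10, 10, 10, 90, 90, 90),
                   atoms = data.frame(element = "C", x = 0, y = 0, z = 0,
                                      occ = 1, b = -1, chain = "A",
                                      resid = "LIG", resno = 1, elety = "C1")),
    "B factor")
})

test_that("a model without a unit cell is refused", {
  p <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  C1  LIG A   1       5.000   5.000   5.000  1.00 10.00           C",
    "END"), p)
  expect_error(read_model(p), "unit cell")
})

test_that("alternate conformers collapse to the highest-occupancy copy", {
  p <- tempfile(fileext = ".pdb")
  writeLines(c(
    "CRYST1   10.000   10.000   10.000  90.00  90.00  90.00 P 1           1",
    "ATOM      1  C1 ALIG A   1       5.000   5.000   5.000  0.40 10.00           C",
    "ATOM      2  C1 BLIG A   1       5.500   5.000   5.000  0.60 10.00           C",
    "END"), p)
  expect_message(s <- read_model(p), "alternate")
  expect_equal(nrow(s$atoms), 1L)
  expect_equal(s$atoms$x, 5.5)      # the 0.60-occupancy copy
  expect_equal(s$atoms$occ, 0.6)
})

test_that("selection filters by identity and excludes hydrogens on request", {
  atoms <- data.frame(
    element = c("C", "H", "N", "O"),
    x = 1:4, y = 1:4, z = 1:4, occ = 1, b = 10,
    chain = "A", resid = c("AZM", "AZM", "AZM", "HOH"),
    resno = c(1L, 1L, 1L, 2L), elety = c("C1", "H1", "N1", "O"))
  s <- xtal_structure(c(10, 10, 10, 90, 90, 90), atoms = atoms)

  azm <- select_atoms(s, atom_selection(resid = "AZM",
                                        exclude_hydrogens = FALSE))
  expect_identical(azm$elety, c("C1", "H1", "N1"))   # file order

  heavy <- select_atoms(s, atom_selection(resid = "AZM"))
  expect_identical(heavy$elety, c("C1", "N1"))

  expect_error(select_atoms(s, atom_selection(resid = "XYZ")), "no atoms")
})

test_that("resolution truncation keeps exactly the low-resolution records", {
  # known d-spacings on a 10 A cube: (h00) families give d = 10/|h|
  cell <- c(10, 10, 10, 90, 90, 90)
  rec <- data.frame(h = c(10, 5, 4, 3), k = 0, l = 0,
                    f_obs = 1, sig_f_obs = 0.1, f_calc = 1, phase = 0,
                    fom = 1, d_factor = 1)   # d = 1.0, 2.0, 2.5, 3.333
  refl <- reflection_set(cell, "P 1", rec)
  tr <- truncate_resolution(refl, 2.0)
  expect_equal(nrow(tr$records), 3L)
  expect_true(tr$d_min >= 2.0)
  expect_equal(nrow(refl$records), 4L)       # input untouched

  # no-op below d_min, error beyond d_max
  expect_equal(nrow(truncate_resolution(refl, 0.5)$records), 4L)
  expect_error(truncate_resolution(refl, 11), "no reflections")
})

test_that("truncation matches a brute-force d-spacing recount and is idempotent", {
  refl <- tiny_reflections(cell = c(9, 11, 13, 90, 100, 90), d_min = 1.8)
  d_cut <- 2.4
  tr <- truncate_resolution(refl, d_cut)

  # independent d-spacing from the real-space metric tensor
  cell <- refl$unit_cell
  ca <- cos(cell[4] * pi / 180); cb <- cos(cell[5] * pi / 180)
  cg <- cos(cell[6] * pi / 180)
  G <- matrix(c(cell[1]^2, cell[1] * cell[2] * cg, cell[1] * cell[3] * cb,
                cell[1] * cell[2] * cg, cell[2]^2, cell[2] * cell[3] * ca,
                cell[1] * cell[3] * cb, cell[2] * cell[3] * ca, cell[3]^2),
              3, 3)
  Gs <- solve(G)
  hkl <- as.matrix(refl$records[, c("h", "k", "l")])
  d_brute <- 1 / sqrt(rowSums((hkl %*% Gs) * hkl))
  expect_equal(nrow(tr$records), sum(d_brute >= d_cut))

  tr2 <- truncate_resolution(tr, d_cut)
  expect_equal(tr2$records, tr$records)
})

test_that("reflection text tables round-trip and validate", {
  refl <- tiny_reflections()
  p <- tempfile(fileext = ".hkl")
  write_reflections(refl, p)
  r2 <- read_reflections(p)
  expect_equal(r2$records$f_obs, refl$records$f_obs, tolerance = 1e-9)
  expect_equal(r2$records$phase, refl$records$phase, tolerance = 1e-9)
  expect_equal(r2$d_min, refl$d_min, tolerance = 1e-9)

  # without m/D columns the documented fallback is m = D = 1, with a warning
  lines <- readLines(p)
  hdr <- grep("^#", lines, value = TRUE)
  tab <- read.table(text = lines[!grepl("^#", lines)], header = TRUE)
  tab$FOM <- NULL; tab$D <- NULL
  p2 <- tempfile(fileext = ".hkl")
  writeLines(c(hdr, paste(colnames(tab), collapse = " ")), p2)
  write.table(tab, p2, append = TRUE, col.names = FALSE, row.names = FALSE,
              quote = FALSE)
  expect_warning(expect_warning(r3 <- read_reflections(p2), "figure-of-merit"),
                 "D column")
  expect_true(all(r3$records$fom == 1) && all(r3$records$d_factor == 1))

  # negative amplitude violates the invariant
  tab2 <- tab; tab2$FP[1] <- -1
  p3 <- tempfile(fileext = ".hkl")
  writeLines(c(hdr, paste(colnames(tab2), collapse = " ")), p3)
  write.table(tab2, p3, append = TRUE, col.names = FALSE, row.names = FALSE,
              quote = FALSE)
  expect_error(suppressWarnings(read_reflections(p3)), "negative")

  # missing mandatory column names the available ones
  tab3 <- tab; names(tab3)[names(tab3) == "FC"] <- "FCALC"
  p4 <- tempfile(fileext = ".hkl")
  writeLines(c(hdr, paste(colnames(tab3), collapse = " ")), p4)
  write.table(tab3, p4, append = TRUE, col.names = FALSE, row.names = FALSE,
              quote = FALSE)
  expect_error(read_reflections(p4), "FCALC|available")
})

test_that("centricity follows space-group symmetry", {
  hkl <- rbind(c(1, 2, 3), c(1, 2, 0), c(0, 0, 2))
  expect_equal(centric_flags(hkl, "P 1"), c(FALSE, FALSE, FALSE))
  expect_equal(centric_flags(hkl, "P -1"), c(TRUE, TRUE, TRUE))
  expect_equal(centric_flags(hkl, "P 2"), c(FALSE, TRUE, FALSE))
})
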