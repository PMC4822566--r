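# Strain energy: reference force field, optimizer contract, external
# backend protocol.

test_that("a stretched diatomic has the closed-form harmonic strain", {
  k <- 250; r0 <- 1.5; dr <- 0.2
  bonds <- data.frame(i = 1, j = 2, k_bond = k, r0 = r0)
  be <- reference_backend(bonds)
  mol <- molecule(c("C", "C"), rbind(c(0, 0, 0), c(r0 + dr, 0, 0)))
  res <- strain_energy(mol, be)
  expect_equal(res$strain, 0.5 * k * dr^2, tolerance = 1e-6)
  expect_equal(res$e_optimized, 0, tolerance = 1e-6)
  expect_s3_class(res, "strain_result")
})

test_that("strain is invariant under rigid rotation and translation", {
  bonds <- toy_ff()
  atoms <- default_toy_atoms()
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  xyz[3, ] <- xyz[3, ] + c(0.25, -0.1, 0.15)   # distort one atom
  be <- reference_backend(bonds)
  s1 <- strain_energy(molecule(atoms$element, xyz), be)$strain
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xyz2 <- t(rot %*% t(xyz)) + matrix(c(5, -2, 11), nrow(xyz), 3, byrow = TRUE)
  s2 <- strain_energy(molecule(atoms$element, xyz2), be)$strain
  expect_gt(s1, 0.1)
  expect_equal(s1, s2, tolerance = 1e-6)
})

test_that("a conformation at the force-field minimum has zero strain", {
  bonds <- toy_ff()
  atoms <- default_toy_atoms()
  be <- reference_backend(bonds, e0 = 3.7)
  mol <- molecule(atoms$element, as.matrix(atoms[, c("x", "y", "z")]))
  res <- strain_energy(mol, be)
  expect_equal(res$e_single_point, 3.7, tolerance = 1e-9)  # offset only
  expect_equal(res$strain, 0, tolerance = 1e-8)
  expect_gte(res$strain, 0)
})

test_that("analytic gradients match finite differences", {
  atoms <- default_toy_atoms()
  set.seed(31)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  xyz <- xyz + matrix(runif(12, -0.2, 0.2), 4, 3)   # generic point
  params <- list(
    bonds = toy_ff(),
    angles = data.frame(i = 1, j = 2, k = c(3, 4),
                        k_theta = 40, theta0 = c(1.9, 2.1)),
    repulsion_a = 100, e0 = 0)
  an <- modescore:::reference_energy(xyz, params, gradient = TRUE)$gradient
  h <- 1e-6
  for (a in 1:4) for (d in 1:3) {
    xp <- xyz; xp[a, d] <- xp[a, d] + h
    xm <- xyz; xm[a, d] <- xm[a, d] - h
    fd <- (modescore:::reference_energy(xp, params) -
             modescore:::reference_energy(xm, params)) / (2 * h)
    expect_lt(abs(an[a, d] - fd), 1e-5 * max(1, abs(fd)))
  }
})

test_that("optimization recovers the minimum from a perturbed start", {
  k <- 300; r0 <- 1.4
  bonds <- data.frame(i = c(1, 2), j = c(2, 3), k_bond = k, r0 = r0)
  angles <- data.frame(i = 1, j = 2, k = 3, k_theta = 60, theta0 = 2.0)
  be <- reference_backend(bonds, angles)
  xyz0 <- rbind(c(0, 0, 0), c(r0, 0, 0),
                c(r0 - r0 * cos(2.0), r0 * sin(2.0), 0))
  set.seed(8)
  start <- xyz0 + matrix(rnorm(9, sd = 0.15), 3, 3)
  mol <- molecule(c("O", "C", "O"), start)
  opt <- be$optimize(mol)
  expect_lt(opt$energy, 1e-8)
  d12 <- sqrt(sum((opt$xyz[1, ] - opt$xyz[2, ])^2))
  d23 <- sqrt(sum((opt$xyz[2, ] - opt$xyz[3, ])^2))
  expect_equal(d12, r0, tolerance = 1e-4)
  expect_equal(d23, r0, tolerance = 1e-4)
  u <- opt$xyz[1, ] - opt$xyz[2, ]; v <- opt$xyz[3, ] - opt$xyz[2, ]
  expect_equal(acos(sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))), 2.0,
               tolerance = 1e-4)
})

test_that("parameter tables are validated against the molecule", {
  mol <- molecule(c("C", "C"), rbind(c(0, 0, 0), c(1.5, 0, 0)))
  be_bad <- reference_backend(data.frame(i = 1, j = 5, k_bond = 100, r0 = 1.5))
  expect_error(strain_energy(mol, be_bad), "outside the molecule")
  be_none <- reference_backend(data.frame(i = integer(), j = integer(),
                                          k_bond = numeric(), r0 = numeric()))
  expect_error(strain_energy(mol, be_none), "missing parameter")
  expect_error(reference_backend(data.frame(a = 1)), "columns")
})

test_that("an external program is driven through the file protocol", {
  wd <- tempfile("ext")
  dir.create(wd)
  # a mock 'energy program': a shell script that checks the XYZ input and
  # writes fixed energies
  script <- file.path(wd, "mock.sh")
  writeLines(c(
    "#!/bin/sh",
    "natoms=$(head -n 1 \"$1\")",
    "echo \"single_point 12.5\" > \"$2\"",
    "echo \"optimized 4.25\" >> \"$2\"",
    "echo \"natoms $natoms\" >> \"$2\""), script)
  Sys.chmod(script, "0755")
  be <- external_backend(paste(shQuote(script), "{input} {output}"),
                         workdir = wd)
  mol <- molecule(c("N", "H"), rbind(c(0, 0, 0), c(1, 0, 0)), charge = 1)
  res <- strain_energy(mol, be)
  expect_equal(res$e_single_point, 12.5)
  expect_equal(res$e_optimized, 4.25)
  expect_equal(res$strain, 8.25)
  # the XYZ file really carried the molecule
  xyzs <- list.files(wd, pattern = "\\.xyz$", full.names = TRUE)
  lines <- readLines(xyzs[1])
  expect_equal(lines[1], "2")
  expect_match(lines[2], "charge 1")
})

test_that("external backends violating the energy contract are rejected", {
  wd <- tempfile("extbad")
  dir.create(wd)
  bad <- file.path(wd, "bad.sh")
  writeLines(c("#!/bin/sh",
               "echo 'single_point 3.0' > \"$2\"",
               "echo 'optimized 9.0' >> \"$2\""), bad)
  Sys.chmod(bad, "0755")
  be <- external_backend(paste(shQuote(bad), "{input} {output}"), workdir = wd)
  mol <- molecule("C", matrix(c(0, 0, 0), 1, 3))
  expect_error(strain_energy(mol, be), "contract")

  junk <- file.path(wd, "junk.sh")
  writeLines(c("#!/bin/sh", "echo 'no energies here' > \"$2\""), junk)
  Sys.chmod(junk, "0755")
  be2 <- external_backend(paste(shQuote(junk), "{input} {output}"),
                          workdir = wd)
  expect_error(strain_energy(mol, be2), "unparseable")

  fail <- file.path(wd, "fail.sh")
  writeLines(c("#!/bin/sh", "exit 3"), fail)
  Sys.chmod(fail, "0755")
  be3 <- external_backend(paste(shQuote(fail), "{input} {output}"),
                          workdir = wd)
  expect_error(suppressWarnings(strain_energy(mol, be3)), "status")

  expect_error(external_backend("prog {input}"), "placeholders")
})
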