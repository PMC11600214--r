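test_that("PDB parsing converts units, respects chains and residue order", {
  st <- read_ca_structure(tiny_pdb(), "A")
  expect_equal(st$sequence, "AGL")
  expect_equal(st$coords,
               rbind(c(0, 0, 0), c(0.38, 0, 0), c(0.76, 0, 0)),
               ignore_attr = TRUE)
  expect_error(read_ca_structure(tiny_pdb(), "Z"), "chain 'Z' not found")

  # shuffled ATOM record order comes back in residue-number order
  st10 <- random_test_structure(10, 4)
  f <- tempfile(fileext = ".pdb")
  write_ca_pdb(st10, f)
  lines <- readLines(f)
  atoms <- lines[startsWith(lines, "ATOM")]
  set.seed(1)
  writeLines(c(sample(atoms), "TER"), f)
  back <- read_ca_structure(f, "A")
  expect_equal(back$coords, st10$coords, tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_equal(back$sequence, st10$sequence)
})

test_that("altloc resolution keeps the highest-occupancy CA", {
  pdb <- paste(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.30  0.00           C",
    "ATOM      2  CA BALA A   1       9.000   0.000   0.000  0.70  0.00           C",
    "ATOM      3  CA  GLY A   2       3.800   0.000   0.000  1.00  0.00           C",
    "ATOM      4  CA  GLY A   3       7.600   0.000   0.000  1.00  0.00           C",
    sep = "\n")
  st <- read_ca_structure(pdb, "A")
  expect_equal(st$coords[1, 1], 0.9)
})

test_that("residues lacking a CA atom are reported", {
  pdb <- paste(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  N   GLY A   2       3.800   0.000   0.000  1.00  0.00           N",
    sep = "\n")
  expect_error(read_ca_structure(pdb, "A"), "without a CA atom")
})

test_that("superposition RMSD is exact, rigid-invariant and matches oracles", {
  x <- random_test_chain(12, 7)
  expect_equal(superpose_rmsd(x, x)$rmsd, 0)

  th <- 0.9
  rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  y <- sweep(x %*% rot, 2, c(1, -2, 0.5), "+")
  expect_lt(superpose_rmsd(x, y)$rmsd, 1e-10)

  # 4-point toy set with one displaced point: brute-force rotation
  # search agrees with the Kabsch answer
  a <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  b <- a; b[4, ] <- b[4, ] + c(0.1, 0, 0)
  sp <- superpose_rmsd(a, b)
  expect_equal(sp$rmsd, brute_rmsd(a, b), tolerance = 1e-6)

  # symmetry and linear scaling
  expect_equal(superpose_rmsd(a, b)$rmsd, superpose_rmsd(b, a)$rmsd,
               tolerance = 1e-12)
  expect_equal(superpose_rmsd(3 * a, 3 * b)$rmsd, 3 * sp$rmsd,
               tolerance = 1e-10)

  # agreement with bio3d's least-squares fit on a random pair
  x2 <- random_test_chain(15, 21)
  y2 <- x2 + matrix(rnorm(45, 0, 0.05), 15)
  fit <- suppressWarnings(bio3d::fit.xyz(as.vector(t(x2)), as.vector(t(y2))))
  ref_rmsd <- sqrt(mean(rowSums((x2 - matrix(fit, ncol = 3,
                                             byrow = TRUE))^2)))
  expect_equal(superpose_rmsd(x2, y2)$rmsd, ref_rmsd, tolerance = 1e-6)

  expect_error(superpose_rmsd(a[1:2, ], b[1:2, ]), "at least 3")
  line <- cbind(0:4, 0, 0)
  expect_true(superpose_rmsd(line, line)$degenerate)
})

test_that("radius of gyration matches closed forms and direct formula", {
  expect_equal(radius_of_gyration(matrix(c(1, 2, 3), 1)), 0)
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(1, 0, 0))), 0.5)
  x <- random_test_chain(5, 3)
  direct <- sqrt(mean(rowSums(sweep(x, 2, colMeans(x))^2)))
  expect_equal(radius_of_gyration(x), direct)
})

test_that("pairwise distances are symmetric and exact", {
  expect_equal(pairwise_ca_distances(rbind(c(0, 0, 0), c(1, 0, 0))),
               rbind(c(0, 1), c(1, 0)), ignore_attr = TRUE)
  x <- random_test_chain(9, 5)
  d <- pairwise_ca_distances(x)
  expect_identical(d, t(d))
  x4 <- random_test_chain(4, 6)
  d4 <- pairwise_ca_distances(x4)
  for (i in 1:4) for (j in 1:4)
    expect_equal(d4[i, j], sqrt(sum((x4[i, ] - x4[j, ])^2)))
})

test_that("approximate SASA behaves like sphere areas and converges", {
  one <- ca_structure("one", "A", matrix(0, 1, 3))
  r <- residue_radii()[["A"]] + 0.14
  sa <- approx_sasa(one)
  expect_equal(sa$total, 4 * pi * r^2, tolerance = 1e-6)
  expect_equal(sa$total, sa$polar + sa$hydrophobic)

  two <- ca_structure("two", "AA", rbind(c(0, 0, 0), c(0.01, 0, 0)))
  expect_lt(approx_sasa(two)$total, 2 * 4 * pi * r^2)

  ext <- ca_structure("e", strrep("K", 10),
                      cbind(0.38 * (0:9), 0, 0))
  set.seed(8)
  col <- ca_structure("c", strrep("K", 10),
                      matrix(rnorm(30, 0, 0.18), 10))
  expect_gte(approx_sasa(ext)$total, approx_sasa(col)$total)

  s960 <- approx_sasa(col, n_points = 960)$total
  s1920 <- approx_sasa(col, n_points = 1920)$total
  expect_lt(abs(s960 - s1920) / s1920, 0.01)
})

test_that("structure containers validate and round-trip through files", {
  expect_error(ca_structure("x", "AAA", matrix(0, 2, 3)), "2 rows")
  expect_error(ca_structure("x", "AA", matrix(c(0, NA), 2, 3)),
               "non-finite")
  expect_error(ca_structure("x", "AA", matrix(0, 2, 3), ss = "HX"),
               "H, E, C")

  st <- random_test_structure(8, 11)
  st$ss <- strrep("H", 8)
  f <- tempfile(fileext = ".tsv")
  write_ca_table(st, f)
  back <- read_ca_table(f)
  expect_equal(back$coords, st$coords, ignore_attr = TRUE)
  expect_equal(back$sequence, st$sequence)
  expect_equal(back$ss, st$ss)

  fp <- tempfile(fileext = ".pdb")
  write_ca_pdb(st, fp)
  pback <- read_ca_structure(fp, "A")
  expect_equal(pback$coords, st$coords, tolerance = 1e-3,
               ignore_attr = TRUE)
})

test_that("state pairs enforce the mapping invariants", {
  a <- random_test_structure(10, 1)
  b <- random_test_structure(10, 2)
  p <- state_pair("p", a, b)
  expect_equal(nrow(p$residue_map), 10)
  expect_error(state_pair("p", a, b, cbind(c(1, 3, 2, 4), c(1, 2, 3, 4))),
               "strictly increasing")
  expect_error(state_pair("p", a, b, cbind(1:3, 1:3)), "at least 4")
  expect_error(state_pair("p", a, b, cbind(c(1, 2, 3, 11), 1:4)),
               "out of bounds")
  # substitutions recorded, not rejected
  expect_true(is.null(p$substitutions) || is.data.frame(p$substitutions))
})
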