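test_that("PDB and mmCIF writers/parsers round-trip a two-chain model", {
  fx <- gen_complex_fixture(c("salt_bridge", "beta_antiparallel"), seed = 4)
  p <- tmp_file(".pdb"); c_ <- tmp_file(".cif")
  write_pdb(fx$model, p); write_mmcif(fx$model, c_)
  mp <- parse_structure(p)
  mc <- parse_structure(c_)
  expect_equal(model_chains(mp), c("A", "B"))
  # dialect equivalence, field by field (coordinates at format precision)
  for (col in c("chain", "res_seq", "res_name", "atom_name", "element"))
    expect_equal(mp$atoms[[col]], mc$atoms[[col]])
  expect_lt(max(abs(mp$atoms$x - mc$atoms$x)), 1e-9)
  expect_lt(max(abs(mp$atoms$bfactor - mc$atoms$bfactor)), 1e-9)
  # and both match the in-memory source
  expect_equal(mp$atoms$res_seq, fx$model$atoms$res_seq)
  expect_lt(max(abs(mp$atoms$x - fx$model$atoms$x)), 1e-3)
  expect_equal(mp$atoms$bfactor, fx$model$atoms$bfactor)
})

test_that("parser keeps author numbering, confidence, and flags zero coordinates", {
  p <- tmp_file(".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A 261      11.000   2.000   3.000  1.00 91.50           N",
    "ATOM      2  CA  ALA A 261      12.000   2.500   3.200  1.00 91.50           C",
    "ATOM      3  CA  GLY B2989       0.000   0.000   0.000  1.00 45.00           C",
    "HETATM    4  O   HOH A 401       5.000   5.000   5.000  1.00  0.00           O",
    "END"), p)
  m <- parse_structure(p)
  expect_equal(sort(unique(m$atoms$res_seq)), c(261L, 401L, 2989L))
  expect_equal(m$zero_coord_atoms, which(m$atoms$res_seq == 2989L))
  res <- chain_residues(m, "B")
  expect_equal(res$confidence, 45)
  # waters/hetero excluded from residue tables by default
  expect_equal(chain_residues(m, "A")$res_seq, 261L)
  expect_equal(chain_sequence(m, "A"), "A")
})

test_that("parser errors carry file context; altlocs keep highest occupancy", {
  bad <- tmp_file(".pdb")
  writeLines(c("ATOM      1  N   ALA A   1      xx.xxx   2.000   3.000  1.00  0.00           N"), bad)
  expect_error(parse_structure(bad), "line 1")
  alt <- tmp_file(".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       1.000   0.000   0.000  0.30 10.00           C",
    "ATOM      2  CA BALA A   1       9.000   0.000   0.000  0.70 10.00           C",
    "END"), alt)
  m <- parse_structure(alt)
  expect_equal(nrow(m$atoms), 1L)
  expect_equal(m$atoms$x, 9)
})

test_that("structure model validates and orders atoms", {
  expect_error(structure_model(data.frame(chain = "A")), "missing column")
  a <- data.frame(chain = "A", res_seq = c(2, 1), res_name = "GLY",
                  atom_name = "CA", element = "C", x = c(1, 2), y = 0, z = 0,
                  occupancy = 1, bfactor = 50)
  m <- structure_model(a)
  expect_equal(m$atoms$res_seq, c(1L, 2L))
  a$x[1] <- NaN
  expect_error(structure_model(a), "finite")
})

test_that("SASA matches the closed form for isolated spheres and is additive at distance", {
  one <- data.frame(element = "C", x = 0, y = 0, z = 0)
  expect_equal(attr(sasa(one), "total"), 4 * pi * (1.7 + 1.4)^2,
               tolerance = 1e-10)
  # probe radius enters the closed form
  expect_equal(attr(sasa(one, probe = 2.0), "total"), 4 * pi * 3.7^2,
               tolerance = 1e-10)
  two <- data.frame(element = c("C", "N"), x = c(0, 40), y = 0, z = 0)
  expect_equal(attr(sasa(two), "total"),
               4 * pi * ((1.7 + 1.4)^2 + (1.55 + 1.4)^2), tolerance = 1e-10)
})

test_that("overlapping-pair SASA agrees with the analytic two-sphere area and a dense oracle", {
  d <- 2.2
  atoms <- data.frame(element = c("C", "O"), x = c(0, d), y = 0, z = 0)
  R1 <- 1.7 + 1.4; R2 <- 1.52 + 1.4
  cap <- function(R, Ro) 2 * pi * R * (R - (d^2 + R^2 - Ro^2) / (2 * d))
  analytic <- 4 * pi * (R1^2 + R2^2) - cap(R1, R2) - cap(R2, R1)
  num <- attr(sasa(atoms), "total")
  expect_lt(abs(num - analytic) / analytic, 0.02)
  # independent double-loop oracle at 10x the sphere points
  oracle <- oracle_sasa_total(atoms, n_points = 9600L)
  expect_lt(abs(num - oracle) / oracle, 0.02)
})

test_that("SASA converges and respects burial non-negativity on fixtures", {
  fx <- gen_complex_fixture(c("insertion"), seed = 9)
  t1 <- sasa_total(fx$model, n_points = 960L)
  t2 <- sasa_total(fx$model, n_points = 1920L)
  expect_lt(abs(t2 - t1) / t1, 0.01)
  # per-residue burial non-negativity on every client residue
  for (rs in chain_residues(fx$model, "B")$res_seq) {
    b <- delta_sasa_insertion(fx$model, "B", "A", rs)
    expect_lte(b$sasa_complex, b$sasa_isolated + 1e-6)
  }
  expect_warning(sasa(data.frame(element = "ZZ", x = 0, y = 0, z = 0)),
                 "unknown element")
})

test_that("hydrophobicity map reproduces the published scale values", {
  a <- do.call(rbind, lapply(seq_along(c("ILE", "ARG", "GLY")), function(i)
    data.frame(chain = "A", res_seq = i, res_name = c("ILE", "ARG", "GLY")[i],
               atom_name = "CA", element = "C", x = i * 5, y = 0, z = 0,
               occupancy = 1, bfactor = 90)))
  m <- structure_model(a)
  h <- hydrophobicity_map(m, "A")
  expect_equal(h$hydrophobicity, c(4.5, -4.5, -0.4))
  a2 <- rbind(a, within(a[1, ], { res_seq <- 4; res_name <- "XYZ" }))
  expect_warning(h2 <- hydrophobicity_map(structure_model(a2), "A"),
                 "non-standard")
  expect_equal(h2$hydrophobicity[4], 0)
})
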