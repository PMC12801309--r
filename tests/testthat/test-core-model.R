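# Containers, PDB/XYZ I/O, selection and superposition.

test_that("PDB round trip preserves coordinates and metadata", {
  st <- place_cd_pose(fx_duplex12(), fx_cd_plus(), "unbound")
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(st, f)
  r <- read_pdb(f)
  expect_equal(nrow(r$atoms), nrow(st$atoms))
  expect_lt(max(abs(coords(r) - coords(st))), 1e-4 + 1e-12)
  expect_identical(r$atoms$name, st$atoms$name)
  expect_identical(r$atoms$resname, st$atoms$resname)
  expect_identical(r$atoms$chain, st$atoms$chain)
  expect_equal(r$atoms$resno, st$atoms$resno, ignore_attr = TRUE)
  expect_equal(r$atoms$charge, st$atoms$charge, ignore_attr = TRUE)
})

test_that("multi-model files become trajectories and round-trip", {
  st <- build_duplex("ACGT")
  xyz <- coords(st)
  tr <- trajectory(st, list(xyz, xyz + 0.1, xyz + 0.2))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(tr, f)
  # file holds one MODEL block per frame
  expect_equal(sum(grepl("^MODEL", readLines(f))), 3)
  r <- read_pdb(f)
  expect_s3_class(r, "trajectory")
  expect_equal(n_frames(r), 3)
  expect_lt(max(abs(r$frames[[3]] - xyz - 0.2)), 1e-4 + 1e-12)
})

test_that("PDB reader converts Angstrom to nm and validates records", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  C1  LIG A   1       3.400   0.000   0.000  1.00  0.00           C",
    "END"), f)
  st <- read_pdb(f)
  expect_equal(st$atoms$x[1], 0.340, tolerance = 1e-9)

  writeLines(c(
    "ATOM      1  C1  LIG A   1       3.400   0.000   0.000  1.00  0.00           C",
    "ATOM      2  C2  LIG A   1       bad     0.000   0.000  1.00  0.00           C",
    "END"), f)
  expect_error(read_pdb(f), "line 2")

  writeLines(c("MODEL        1",
               "ATOM      1  C1  LIG A   1       1.000   0.000   0.000  1.00  0.00           C",
               "ENDMDL", "MODEL        2",
               "ATOM      1  C1  LIG A   1       1.000   0.000   0.000  1.00  0.00           C",
               "ATOM      2  C2  LIG A   1       2.000   0.000   0.000  1.00  0.00           C",
               "ENDMDL", "END"), f)
  expect_error(read_pdb(f), "inconsistent atom count")
})

test_that("writer rejects degenerate inputs", {
  st <- build_duplex("ACGT")
  st$atoms <- st$atoms[0, ]
  expect_error(write_pdb(st, tempfile()), "empty|no atoms")
  big <- fx_cd0()$structure
  big$atoms <- big$atoms[rep(seq_len(nrow(big$atoms)), 400), ]
  big$atoms$serial <- seq_len(nrow(big$atoms))
  big$atoms$resno <- 1L
  big$bonds <- NULL
  expect_error(write_pdb(big, tempfile()), "99999")
})

test_that("XYZ round trip works for structures and trajectories", {
  st <- fx_cd0()$structure
  f <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(st, f)
  r <- read_xyz(f)
  expect_lt(max(abs(coords(r) - coords(st))), 1e-6)
  tr <- trajectory(st, list(coords(st), coords(st) + 0.05))
  write_xyz(tr, f)
  r2 <- read_xyz(f, template = st)
  expect_s3_class(r2, "trajectory")
  expect_equal(n_frames(r2), 2)
})

test_that("superposition is exact for rigid transforms and symmetric", {
  set.seed(11)
  for (k in 1:5) {
    A <- matrix(rnorm(24), ncol = 3)
    R <- random_rotation(); tv <- rnorm(3)
    B <- sweep(A %*% t(R), 2, -tv)
    expect_lt(superpose_rmsd(A, B)$rmsd, 1e-9)
    s <- superpose_rmsd(A, B)
    expect_equal(det(s$rotation), 1, tolerance = 1e-9)
  }
  A <- matrix(rnorm(30), ncol = 3); B <- matrix(rnorm(30), ncol = 3)
  expect_equal(superpose_rmsd(A, B)$rmsd, superpose_rmsd(B, A)$rmsd,
               tolerance = 1e-9)
  expect_error(superpose_rmsd(A, B[1:5, ]), "equal")
})

test_that("superposition matches the brute-force rotation-grid oracle", {
  set.seed(7)
  for (k in 1:3) {
    A <- matrix(rnorm(12), ncol = 3)
    B <- matrix(rnorm(12), ncol = 3)
    kab <- superpose_rmsd(A, B)$rmsd
    ora <- oracle_rmsd(A, B)
    expect_lt(abs(kab - ora), 1e-4)
    expect_lte(kab, ora + 1e-10)  # Kabsch is the optimum
  }
})

test_that("collinear point sets fall back to a flagged translation fit", {
  A <- cbind(1:5, 0, 0); B <- cbind(1:5, 1, 1)
  expect_warning(s <- superpose_rmsd(A, B), "degenerate")
  expect_true(s$degenerate)
})

test_that("selection supports conjunctions and rejects unknown keys", {
  d <- fx_duplex12()
  expect_equal(nrow(select_atoms(d, element = "P")), 22)
  expect_equal(nrow(select_atoms(d)), nrow(d$atoms))
  expect_equal(nrow(select_atoms(d, chain = "A", element = "P")), 11)
  expect_error(select_atoms(d, altloc = "A"), "unknown selection key")
  cdp <- fx_cd_plus()
  n_sites <- sum(cdp$structure$atoms$name == "NZ")
  expect_equal(n_sites, 9)
  expect_equal(sum(select_atoms(cdp$structure,
                                tag = "func:NH3+")$element == "N"), 9)
})

test_that("structure validation enforces the container invariants", {
  at <- data.frame(serial = c(1, 1), name = "C", element = "C",
                   resno = 1, resname = "X", chain = "A",
                   x = 0, y = 0, z = 0)
  expect_error(mol_structure(at), "unique")
  at2 <- at; at2$serial <- 1:2; at2$x <- c(0, NA)
  expect_error(mol_structure(at2), "finite")
  at3 <- at; at3$serial <- 1:2; at3$element <- "Xx"
  expect_error(mol_structure(at3), "element")
  st <- build_duplex("ACGT")
  expect_error(trajectory(st, list(coords(st)[1:5, ])), "n_atoms")
  expect_error(trajectory(st, list(coords(st), coords(st)),
                          times = c(1, 1)), "increasing")
})
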