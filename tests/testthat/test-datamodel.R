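test_that("a toy PDB parses into the right roles and captures B factors", {
  pdb <- c(
    "ATOM      1  N   ALA A   1       1.000   2.000   3.000  1.00 25.00           N",
    "ATOM      2  CA  ALA A   1       2.500   2.000   3.000  1.00 30.50           C",
    "HETATM    3  C1  LIG L   2       5.000   5.000   5.000  1.00 12.25           C",
    "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb, f)
  cx <- read_complex_pdb(f, entry_id = "TOY1")
  expect_equal(length(cx$protein_indices), 2L)
  expect_equal(length(cx$ligand_indices), 1L)
  expect_equal(cx$atoms$b_factor[1], 25.0)
  expect_equal(cx$atoms$x, c(1, 2.5, 5))
  ## every atom carries exactly one role
  expect_true(all(cx$atoms$role %in% c("protein", "ligand", "ion", "water")))
})

test_that("malformed ATOM records fail with the offending line number", {
  pdb <- c(
    "ATOM      1  N   ALA A   1       1.000   2.000   3.000  1.00 25.00           N",
    "ATOM      2  CA  ALA A   1       BADX    2.000   3.000  1.00 30.50           C")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb, f)
  expect_error(read_complex_pdb(f), "line 2", class = "ligdyn_format_error")
})

test_that("a complex without ligand or protein atoms is rejected", {
  pdb <- "ATOM      1  N   ALA A   1       1.000   2.000   3.000  1.00 25.00           N"
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(pdb, "END"), f)
  expect_error(read_complex_pdb(f), "ligand", class = "ligdyn_validation_error")
})

test_that("PDB write/read round trip preserves coordinates and order", {
  cx <- generate_complex(17, n_residues = 12, n_ligand_atoms = 6)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_complex_pdb(cx, f)
  back <- read_complex_pdb(f)
  expect_lt(max(abs(coords(cx) - coords(back))), 1e-3)
  expect_identical(back$atoms$element, cx$atoms$element)
  expect_identical(back$atoms$role, cx$atoms$role)
})

test_that("HDF5 round trip is bit-exact and lookups fail informatively", {
  cx <- generate_complex(3, 6, 5)
  tr <- generate_trajectory(cx, mobility_profile(rep(0.3, nrow(cx$atoms))),
                            n_frames = 10, seed = 2)
  tr$frame_properties$ligand_rmsd <- ligand_rmsd(tr, cx)
  tr$trajectory_properties$mean_com <- mean(com_distance(tr, cx))
  qm <- qm_record("QREC", molecular = list(electron_affinity = 1.25),
                  atomic = list(partial_charge = rnorm(5)))
  f <- withr::local_tempfile(fileext = ".h5")
  write_h5(list(tr, qm), f)
  back <- read_h5(f, cx$entry_id, "trajectory_coordinates")
  expect_identical(as.numeric(back), as.numeric(tr$coordinates))
  expect_identical(as.numeric(read_h5(f, "QREC", "atomic_partial_charge")),
                   tr <- as.numeric(qm$atomic$partial_charge))
  ## stored dataset names are exactly the written set, prefix-tagged
  expect_setequal(h5_keys(f, cx$entry_id),
                  c("trajectory_coordinates", "frames_time",
                    "frames_ligand_rmsd", "trajectory_mean_com"))
  expect_setequal(h5_keys(f), c(cx$entry_id, "QREC"))
  expect_error(read_h5(f, "XXXX", "frames_time"), "available",
               class = "ligdyn_validation_error")
  expect_error(read_h5(f, cx$entry_id, "nope"), "available",
               class = "ligdyn_validation_error")
})

test_that("the H5 key map translates foreign dataset names", {
  qm <- qm_record("QKEY", molecular = list(electron_affinity = 2.5))
  f <- withr::local_tempfile(fileext = ".h5")
  write_h5(qm, f)
  v <- read_h5(f, "QKEY", "ea_canonical",
               key_map = c(ea_canonical = "molecular_electron_affinity"))
  expect_equal(as.numeric(v), 2.5)
})

test_that("affinity tables validate, normalize types and round trip", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("entry_id,affinity_value,affinity_type,protein_group",
               "1ABC,120.5,ki,P00001",
               "2DEF,3.2,KD,P00002",
               "3GHI,4500,IC50,P00001"), f)
  tab <- read_affinity_table(f)
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$affinity_type, c("Ki", "Kd", "IC50"))

  writeLines(c("entry_id,affinity_value,affinity_type,protein_group",
               "1ABC,-5,Ki,P00001"), f)
  expect_error(read_affinity_table(f), "positive",
               class = "ligdyn_validation_error")
  writeLines(c("entry_id,affinity_value,affinity_type,protein_group",
               "1ABC,5,EC50,P00001"), f)
  expect_error(read_affinity_table(f), "EC50",
               class = "ligdyn_validation_error")

  set.seed(8)
  tab2 <- affinity_table(sprintf("E%03d", 1:20), 10^runif(20, 0, 5),
                         sample(c("Ki", "Kd", "IC50"), 20, TRUE),
                         sample(c("P1", "P2"), 20, TRUE),
                         sample(c("pubA", "pubB"), 20, TRUE),
                         sample(c(TRUE, FALSE), 20, TRUE))
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_affinity_table(tab2, f2)
  expect_equal(read_affinity_table(f2), tab2, tolerance = 1e-12)
})

test_that("atom and record invariants are enforced", {
  expect_error(atom_table("C", x = NA, y = 0, z = 0), "finite",
               class = "ligdyn_validation_error")
  expect_error(atom_table("Xx", 0, 0, 0), "unsupported",
               class = "ligdyn_validation_error")
  expect_error(trajectory_record("T", array(0, c(2, 3, 3)),
                                 frame_times = c(1, 1)),
               "increasing", class = "ligdyn_validation_error")
  expect_error(qm_record("Q", atomic = list(a = 1:3, b = 1:4)),
               "length", class = "ligdyn_validation_error")
  ## protein and ligand index sets partition correctly
  cx <- generate_complex(5, 5, 4)
  expect_length(intersect(cx$protein_indices, cx$ligand_indices), 0)
  expect_setequal(c(cx$protein_indices, cx$ligand_indices),
                  seq_len(nrow(cx$atoms)))
})
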