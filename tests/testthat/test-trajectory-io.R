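test_that("multi-model PDB files round-trip through write and read", {
  set.seed(1)
  fix <- h3_dimer_fixture("extended", n_frames = 100, seed = 5)
  traj <- fix$trajectory
  path <- withr::local_tempfile(fileext = ".pdb")
  write_multimodel_pdb(traj, path)
  back <- read_multimodel_pdb(path)

  expect_equal(n_frames(back), n_frames(traj))
  expect_identical(back$atoms$atom_name, traj$atoms$atom_name)
  expect_identical(back$atoms$chain_id, traj$atoms$chain_id)
  expect_identical(back$atoms$residue_index, traj$atoms$residue_index)
  expect_identical(back$atoms$residue_name, traj$atoms$residue_name)
  expect_identical(back$atoms$element, traj$atoms$element)
  # %8.3f fixed-width coordinates are exact to half a milli-Angstrom
  expect_lt(max(abs(back$xyz - traj$xyz)), 1e-3)
  # one MODEL block per frame
  expect_equal(sum(grepl("^MODEL", readLines(path))), n_frames(traj))
})

test_that("the reader enforces model count, chain count and roster", {
  lineA <- "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C"
  lineB <- "ATOM      2  CA  GLY B   1       3.000   0.000   0.000  1.00  0.00           C"
  lineB2 <- "ATOM      3  CB  GLY B   1       4.000   0.000   0.000  1.00  0.00           C"
  tmp <- withr::local_tempfile(fileext = ".pdb")

  writeLines(c("HEADER", "END"), tmp)
  expect_error(read_multimodel_pdb(tmp), "no models")

  writeLines(c("MODEL     1", lineA, lineB, lineB2, "ENDMDL",
               "MODEL     2", lineA, lineB, "ENDMDL"), tmp)
  expect_error(read_multimodel_pdb(tmp), "roster mismatch.*MODEL 2.*CB")

  writeLines(c("MODEL     1", lineA, "ENDMDL"), tmp)
  expect_error(read_multimodel_pdb(tmp), "exactly two chains, found 1")

  writeLines(c("MODEL     1", lineA, lineB,
               sub(" B ", " C ", lineB2), "ENDMDL"), tmp)
  expect_error(read_multimodel_pdb(tmp), "exactly two chains, found 3")
})

test_that("solvent and ion records are dropped with a message", {
  lines <- c(
    "MODEL     1",
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  GLY B   1       3.000   0.000   0.000  1.00  0.00           C",
    "HETATM    3  O   HOH A 101      9.000    9.000   9.000  1.00  0.00           O",
    "HETATM    4 NA    NA A 102      8.000    8.000   8.000  1.00  0.00          NA",
    "ENDMDL")
  tmp <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, tmp)
  expect_message(traj <- read_multimodel_pdb(tmp), "dropped 2 solvent/ion")
  expect_equal(nrow(traj$atoms), 2)
})

test_that("element symbols fall back to the atom name when absent", {
  lines <- c(
    "MODEL     1",
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00",
    "ATOM      2  N   GLY A   1       1.400   0.000   0.000  1.00  0.00",
    "ATOM      3 1HB  GLY A   1       2.000   0.000   0.000  1.00  0.00",
    "ATOM      4  CA  GLY B   1       9.000   0.000   0.000  1.00  0.00",
    "ENDMDL")
  tmp <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, tmp)
  traj <- read_multimodel_pdb(tmp)
  expect_identical(traj$atoms$element, c("C", "N", "H", "C"))
})

test_that("heavy_atom_view removes hydrogens, is idempotent and commutes with chain_view", {
  xyz <- matrix(seq_len(24), ncol = 3)
  fr <- make_frame(xyz, element = c("C", "H", "N", "H", "O", "C", "H", "S"),
                   chain_id = c(rep("A", 4), rep("B", 4)))
  hv <- heavy_atom_view(fr)
  expect_equal(nrow(hv$atoms), 5)
  expect_identical(heavy_atom_view(hv)$atoms, hv$atoms)
  # commutes with chain_view
  a1 <- chain_view(heavy_atom_view(fr), "A")
  a2 <- heavy_atom_view(chain_view(fr, "A"))
  expect_identical(a1$atoms, a2$atoms)
  expect_identical(a1$xyz, a2$xyz)
})

test_that("chain_view partitions a frame and rejects unknown chains", {
  fr <- random_two_chain_frame(10, 10)
  va <- chain_view(fr, "A"); vb <- chain_view(fr, "B")
  expect_equal(nrow(va$atoms) + nrow(vb$atoms), nrow(fr$atoms))
  expect_true(all(va$atoms$chain_id == "A"))
  expect_error(chain_view(fr, "Q"), "unknown chain id 'Q'")
  # single-chain frame with its own id is the identity
  expect_identical(chain_view(va, "A")$xyz, va$xyz)
})

test_that("written PDB files are readable by an independent parser", {
  skip_if_not_installed("bio3d")
  fix <- h3_dimer_fixture("extended", n_frames = 100, seed = 5)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_multimodel_pdb(fix$trajectory, path)
  ref <- bio3d::read.pdb(path, multi = TRUE)
  expect_equal(nrow(ref$atom), nrow(fix$trajectory$atoms))
  expect_equal(dim(ref$xyz)[1], n_frames(fix$trajectory))
  # coordinates of the first frame agree to PDB precision
  ours <- fix$trajectory$xyz[, , 1]
  theirs <- matrix(ref$xyz[1, ], ncol = 3, byrow = TRUE)
  expect_lt(max(abs(ours - theirs)), 1e-3)
  expect_identical(unique(ref$atom$chain), c("A", "B"))
})

test_that("topology sidecars round-trip", {
  ps <- builtin_peptides()
  topo <- list(A = ps$P1M2, B = ps$P0M0_ala)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_topology(topo, path, label = "P1M2/P0M0_ala", conformation = "helical")
  back <- read_topology(path)
  expect_identical(back$label, "P1M2/P0M0_ala")
  expect_identical(back$conformation, "helical")
  expect_identical(format_annotation(back$chains$A), format_annotation(ps$P1M2))
  expect_identical(compute_formal_charge(back$chains$B), 5L)
})
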