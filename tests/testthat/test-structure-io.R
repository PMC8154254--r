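test_that("a minimal ATOM record parses with inferred element", {
  path <- write_pdb_text(pdb_line("ATOM", 1, "CA", "ALA", "A", 1, 1, 2, 3))
  s <- read_pdb(path)
  expect_equal(nrow(s$atoms), 1)
  expect_equal(s$atoms$element, "C")
  expect_false(s$atoms$het)
  expect_equal(model_xyz(s, 1)[1, ], c(1, 2, 3))
})

test_that("heme iron HETATM gets element Fe and het flag", {
  path <- write_pdb_text(pdb_line("HETATM", 1, "FE", "HEM", "A", 501,
                                  0, 0, 0))
  s <- read_pdb(path)
  expect_equal(s$atoms$element, "Fe")
  expect_true(s$atoms$het)
})

test_that("MODEL blocks become models with shared atom table", {
  lines <- unlist(lapply(1:5, function(m) {
    c(sprintf("MODEL     %4d", m),
      vapply(1:10, function(k)
        pdb_line("ATOM", k, "CA", "GLY", "A", k, k * 1.5, m, 0, "C"),
        character(1)),
      "ENDMDL")
  }))
  s <- read_pdb(write_pdb_text(lines))
  expect_equal(n_models(s), 5)
  expect_equal(nrow(s$atoms), 10)
  expect_equal(model_xyz(s, 4)[, 2], rep(4, 10))
})

test_that("a single-model file equals the same file wrapped in MODEL 1", {
  rec <- c(pdb_line("ATOM", 1, "N", "GLY", "A", 1, 0, 0, 0, "N"),
           pdb_line("ATOM", 2, "CA", "GLY", "A", 1, 1.5, 0, 0, "C"))
  plain <- read_pdb(write_pdb_text(rec))
  wrapped <- read_pdb(write_pdb_text(c("MODEL        1", rec, "ENDMDL")))
  expect_identical(plain$atoms, wrapped$atoms)
  expect_equal(plain$xyz, wrapped$xyz)
})

test_that("degenerate PDB inputs error", {
  expect_error(read_pdb(tempfile()), "cannot read")
  empty <- write_pdb_text("REMARK nothing here")
  expect_error(read_pdb(empty))
})

test_that("altloc conformers collapse to the highest-occupancy one", {
  l1 <- pdb_line("ATOM", 1, "CA", "ALA", "A", 1, 0, 0, 0, "C")
  l2 <- pdb_line("ATOM", 2, "CA", "ALA", "A", 1, 9, 9, 9, "C")
  substr(l1, 17, 17) <- "A"; substr(l1, 57, 60) <- "0.40"
  substr(l2, 17, 17) <- "B"; substr(l2, 57, 60) <- "0.60"
  s <- read_pdb(write_pdb_text(c(l1, l2)))
  expect_equal(nrow(s$atoms), 1)
  expect_equal(model_xyz(s, 1)[1, 1], 9)  # occupancy 0.60 wins
})

test_that("multi-model PDB reads as a trajectory", {
  s <- make_covalent_chain(3)
  path <- tempfile(fileext = ".pdb")
  xyz <- model_xyz(s, 1)
  multi <- et_structure(s$atoms, array(c(xyz, xyz + 0.5, xyz + 1),
                                       dim = c(4, 3, 3)))
  write_pdb(multi, path)
  traj <- read_trajectory(path)
  expect_equal(n_frames(traj), 3)
  expect_equal(frame_xyz(traj, 3), xyz + 1, tolerance = 1e-3)
})

test_that("XYZ frame stacks need and respect a topology", {
  path <- tempfile(fileext = ".xyz")
  writeLines(c("2", "frame 1", "C 0 0 0", "C 1.5 0 0",
               "2", "frame 2", "C 0 0 1", "C 1.5 0 1"), path)
  topo <- make_covalent_chain(1)
  traj <- read_trajectory(path, topo)
  expect_equal(n_frames(traj), 2)
  expect_equal(frame_xyz(traj, 2)[1, 3], 1)
  expect_error(read_trajectory(path), "topology")
  bad <- tempfile(fileext = ".xyz")
  writeLines(c("3", "f", "C 0 0 0", "C 1 0 0", "C 2 0 0"), bad)
  expect_error(read_trajectory(bad, topo), "topology has 2")
})

test_that("ranking serialization round-trips and rejects empty input", {
  ranking <- rank_residues(mini_peroxidase())
  tsv <- tempfile(fileext = ".tsv")
  jsn <- tempfile(fileext = ".json")
  write_ranking(ranking, tsv, "tsv")
  write_ranking(ranking, jsn, "json")
  back_tsv <- read_ranking(tsv, "tsv")
  expect_equal(nrow(back_tsv), nrow(ranking))
  back <- read_ranking(jsn, "json")
  expect_identical(back$ln_k, ranking$ln_k)   # bit-exact through JSON
  expect_identical(back$atom_count, ranking$atom_count)
  expect_error(write_ranking(ranking[0, ], tempfile(), "tsv"), "empty")
})
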