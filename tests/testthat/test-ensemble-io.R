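# Multi-model PDB round trips, parsing conventions and atom selection.

test_that("write -> read round trip preserves topology and coordinates", {
  top <- make_topology(c("N", "C", "C", "O", "C", "S"),
                       chains = c("A", "A", "A", "B", "B", "B"),
                       residues = c(1, 1, 2, 5, 5, 6),
                       names = c("N", "CA", "CA", "C", "CA", "SD"))
  set.seed(11)
  frames <- replicate(3, matrix(round(rnorm(18, sd = 5), 3), ncol = 3),
                      simplify = FALSE)
  ens <- make_ensemble(top, frames, frame_ids = c(1L, 2L, 7L))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_multimodel_pdb(ens, path)
  back <- read_multimodel_pdb(path)
  expect_equal(back$topology, ens$topology)
  expect_equal(back$frame_ids, c(1L, 2L, 7L))
  expect_equal(back$coords, ens$coords, tolerance = 1e-12)  # inputs already at 3 dp
  # coordinates not on the 3-decimal grid survive to 3 decimals
  ens2 <- make_ensemble(top, list(frames[[1]] + pi * 1e-4))
  path2 <- withr::local_tempfile(fileext = ".pdb")
  write_multimodel_pdb(ens2, path2)
  expect_equal(read_multimodel_pdb(path2)$coords[, , 1],
               round(ens2$coords[, , 1], 3), ignore_attr = TRUE)
})

test_that("MODEL bookkeeping: counts, implicit single model, subsets", {
  top <- make_topology(rep("C", 12), residues = rep(1:3, each = 4))
  frames <- replicate(3, matrix(runif(36, -9, 9), ncol = 3), simplify = FALSE)
  ens <- make_ensemble(top, frames)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_multimodel_pdb(ens, path)
  lines <- readLines(path)
  expect_equal(sum(startsWith(lines, "MODEL")), 3L)
  back <- read_multimodel_pdb(path)
  expect_equal(n_frames(back), 3L)
  expect_equal(n_atoms(back), 12L)

  # subset [1, 3] -> exactly 2 MODEL records
  path2 <- withr::local_tempfile(fileext = ".pdb")
  write_multimodel_pdb(ens, path2, frame_subset = c(1L, 3L))
  expect_equal(sum(startsWith(readLines(path2), "MODEL")), 2L)
  expect_error(write_multimodel_pdb(ens, path2, frame_subset = integer(0)),
               "empty")

  # file without MODEL/ENDMDL is one implicit model with frame_id 1
  atom_lines <- grep("^ATOM", readLines(path2), value = TRUE)
  n_per_model <- length(atom_lines) / 2
  path3 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(atom_lines[seq_len(n_per_model)], "END"), path3)
  single <- read_multimodel_pdb(path3)
  expect_equal(n_frames(single), 1L)
  expect_equal(single$frame_ids, 1L)
})

test_that("malformed input is rejected with informative errors", {
  expect_error(read_multimodel_pdb(file.path(tempdir(), "nope.pdb")), "not found")
  top <- make_topology(c("C", "O"))
  ens <- make_ensemble(top, list(matrix(0, 2, 3), matrix(1, 2, 3)))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_multimodel_pdb(ens, path)
  lines <- readLines(path)
  # drop one atom from model 2 -> atom-count mismatch names the model
  drop <- max(grep("^ATOM", lines))
  writeLines(lines[-drop], path)
  expect_error(read_multimodel_pdb(path), "model 2")
  # insertion codes rejected
  write_multimodel_pdb(ens, path)
  lines <- readLines(path)
  i <- grep("^ATOM", lines)[1]
  substr(lines[i], 27, 27) <- "A"
  writeLines(lines, path)
  expect_error(read_multimodel_pdb(path), "insertion")
})

test_that("altLoc policy keeps ' ' and 'A' only", {
  top <- make_topology(c("C", "O", "N"))
  ens <- make_ensemble(top, list(matrix(seq_len(9), 3, 3)))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_multimodel_pdb(ens, path)
  lines <- readLines(path)
  atoms <- grep("^ATOM", lines)
  substr(lines[atoms[1]], 17, 17) <- "A"  # kept
  substr(lines[atoms[2]], 17, 17) <- "B"  # dropped
  writeLines(lines, path)
  back <- read_multimodel_pdb(path)
  expect_equal(n_atoms(back), 2L)
  expect_equal(back$topology$element, c("C", "N"))
})

test_that("parsing agrees with the bio3d reference reader", {
  skip_if_not_installed("bio3d")
  top <- make_topology(c("N", "C", "C", "O", "S", "C"),
                       chains = c("A", "A", "A", "B", "B", "B"),
                       residues = c(10, 10, 11, 3, 3, 4))
  set.seed(4)
  frames <- replicate(4, matrix(round(rnorm(18, sd = 8), 3), ncol = 3),
                      simplify = FALSE)
  ens <- make_ensemble(top, frames)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_multimodel_pdb(ens, path)
  ref <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  expect_equal(nrow(ref$atom), 6L)
  expect_equal(ref$atom$chain, top$chain_id)
  expect_equal(ref$atom$resno, top$residue_number)
  expect_equal(nrow(ref$xyz), 4L)
  for (f in 1:4)
    expect_equal(matrix(ref$xyz[f, ], ncol = 3, byrow = TRUE),
                 ens$coords[, , f], ignore_attr = TRUE)
})

test_that("select_atoms resolves residue groups and enforces errors", {
  top <- make_topology(c("N", "C", "H", "H", "C", "O"),
                       chains = c("E", "E", "E", "E", "E", "I"),
                       residues = c(185, 185, 185, 186, 186, 1))
  s <- select_atoms(top, "E", c(185, 186))
  expect_equal(s$atom_indices, c(1L, 2L, 5L))  # heavy atoms only
  # all-atom selection is larger by exactly the 2 hydrogens
  s_all <- select_atoms(top, "E", c(185, 186), heavy_only = FALSE)
  expect_equal(length(s_all$atom_indices) - length(s$atom_indices), 2L)
  # order-independence and idempotence over residue_numbers
  expect_equal(select_atoms(top, "E", c(186, 185, 185))$atom_indices,
               s$atom_indices)
  expect_error(select_atoms(top, "E", 999), "selection error")
  expect_error(select_atoms(top, "E", integer(0)), "non-empty")
})

test_that("union of per-chain selections over all residues covers every atom", {
  b <- generate_binding_ensemble(synthetic_spec(n_frames = 2, seed = 3))
  top <- b$ensemble$topology
  got <- sort(unlist(lapply(unique(top$chain_id), function(ch) {
    select_atoms(top, ch,
                 unique(top$residue_number[top$chain_id == ch]),
                 heavy_only = FALSE)$atom_indices
  })))
  expect_equal(got, top$atom_index)
})

test_that("selection config files parse groups, ranges and flags", {
  path <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c(
    "# residue groups",
    "group.loop = chain:A residues:185-200 heavy_only:true",
    "group.active = chain:A residues:108,278,298",
    "group.all = chain:B residues:1-3,7 heavy_only:false"
  ), path)
  cfg <- read_selection_config(path)
  expect_named(cfg, c("loop", "active", "all"))
  expect_equal(cfg$loop$residue_numbers, 185:200)
  expect_equal(cfg$active$residue_numbers, c(108L, 278L, 298L))
  expect_equal(cfg$all$residue_numbers, c(1:3, 7L))
  expect_false(cfg$all$heavy_only)
  expect_true(cfg$active$heavy_only)
})
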