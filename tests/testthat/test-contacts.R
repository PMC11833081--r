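# Contact detection (strict < 3.3 A over heavy atoms), ensemble filtering
# and frame-normalised residue statistics.

two_chain_top <- function() {
  make_topology(c("C", "C", "N", "O", "C", "H"),
                chains = c("A", "A", "A", "B", "B", "B"),
                residues = c(10, 10, 10, 5, 6, 6))
}

test_that("cutoff is strict and hydrogens are ignored", {
  top <- two_chain_top()
  xyz <- rbind(c(0, 0, 0), c(0, 5, 0), c(0, 10, 0),
               c(3.2, 0, 0),   # 3.2 A from atom 1 -> contact
               c(3.3, 5, 0),   # exactly 3.3 A -> NOT a contact
               c(0.5, 10, 0))  # hydrogen, close to atom 3 -> ignored
  ens <- make_ensemble(top, list(xyz))
  cs <- detect_contacts(ens, sel(1:3, "A"), sel(4:6, "B"))
  expect_equal(nrow(cs$atom_pairs[[1]]), 1L)
  expect_equal(unname(cs$atom_pairs[[1]][1, ]), c(1L, 4L))
  expect_equal(cs$residue_pairs[[1]]$residue_a, 10L)
  expect_equal(cs$residue_pairs[[1]]$residue_b, 5L)
})

test_that("atom pairs project onto deduplicated residue pairs", {
  # 3 atoms of residue 10 (A) each within 3 A of 2 atoms of residue 5 (B)
  top <- make_topology(c("C", "C", "C", "O", "N"),
                       chains = c("A", "A", "A", "B", "B"),
                       residues = c(10, 10, 10, 5, 5))
  xyz <- rbind(c(0, 0, 0), c(0.5, 0, 0), c(1, 0, 0),
               c(0.5, 1, 0), c(0.5, -1, 0))
  ens <- make_ensemble(top, list(xyz))
  cs <- detect_contacts(ens, sel(1:3), sel(4:5))
  expect_equal(nrow(cs$atom_pairs[[1]]), 6L)
  expect_equal(nrow(cs$residue_pairs[[1]]), 1L)
})

test_that("cell-list kernel returns the identical pair set as brute force", {
  set.seed(77)
  n <- 120
  top <- make_topology(rep(c("C", "N", "O"), length.out = n),
                       chains = rep(c("A", "B"), each = n / 2),
                       residues = rep(1:(n / 4), each = 2))
  for (rep_i in 1:6) {
    xyz <- matrix(runif(3 * n, 0, 18), ncol = 3)
    ens <- make_ensemble(top, list(xyz))
    a <- sel(1:(n / 2), "A"); b <- sel((n / 2 + 1):n, "B")
    brute <- detect_contacts(ens, a, b, kernel = "brute")$atom_pairs[[1]]
    cell <- detect_contacts(ens, a, b, kernel = "cell")$atom_pairs[[1]]
    expect_identical(cell, brute)
    expect_gt(nrow(brute), 0)  # box is dense enough that the check is real
  }
})

test_that("contact detection is symmetric in the selections", {
  set.seed(5)
  top <- two_chain_top()
  ens <- make_ensemble(top, list(matrix(runif(18, 0, 6), ncol = 3)))
  ab <- detect_contacts(ens, sel(1:3, "A"), sel(4:6, "B"))$atom_pairs[[1]]
  ba <- detect_contacts(ens, sel(4:6, "B"), sel(1:3, "A"))$atom_pairs[[1]]
  transposed <- ba[, c(2, 1), drop = FALSE]
  colnames(transposed) <- c("atom_a", "atom_b")
  expect_identical(ab[order(ab[, 1], ab[, 2]), , drop = FALSE],
                   transposed[order(transposed[, 1], transposed[, 2]), , drop = FALSE])
})

test_that("contact filters match planted ground truth and are idempotent", {
  b <- generate_binding_ensemble(synthetic_spec(n_frames = 120, seed = 13))
  top <- b$ensemble$topology
  se <- select_atoms(top, "E", unique(top$residue_number[top$chain_id == "E"]))
  sl <- select_atoms(top, "I", unique(top$residue_number[top$chain_id == "I"]))
  cs <- detect_contacts(b$ensemble, se, sl)
  any_f <- filter_frames_any_contact(cs)
  expect_identical(any_f$keep, b$ground_truth$bound)
  expect_equal(any_f$n_kept, sum(b$ground_truth$bound))

  site_f <- filter_frames_site_contact(cs, b$groups$pocket, chain = "E")
  expect_identical(site_f$keep, b$ground_truth$bound)
  expect_error(filter_frames_site_contact(cs, 9999, chain = "E"), "absent")

  # filtering an already-filtered series keeps every frame
  kept <- apply_filter(cs, any_f)
  refilt <- filter_frames_any_contact(kept)
  expect_equal(refilt$n_kept, length(kept$frame_ids))

  # AND composition
  both <- combine_filters(any_f, site_f)
  expect_identical(both$keep, any_f$keep & site_f$keep)
})

test_that("residue statistics are normalised per frame and may exceed 1", {
  # frame 1: residue 10(A) contacts residues 5(B) and 6(B); frame 2: nothing
  top <- make_topology(c("C", "O", "N"), chains = c("A", "B", "B"),
                       residues = c(10, 5, 6))
  f1 <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0))
  f2 <- rbind(c(0, 0, 0), c(20, 0, 0), c(0, 20, 0))
  ens <- make_ensemble(top, list(f1, f2))
  cs <- detect_contacts(ens, sel(1, "A"), sel(2:3, "B"))
  st <- residue_contact_statistics(cs)
  expect_equal(st$n_frames, 2L)
  r10 <- st$residues$mean_contacts[st$residues$chain == "A" &
                                     st$residues$residue_number == 10]
  expect_equal(r10, 1.0)
  expect_equal(sort(st$pairs$contact_fraction), c(0.5, 0.5))

  # contact in every frame with 2 partners -> value 2 (> 1 permitted)
  ens2 <- make_ensemble(top, list(f1, f1))
  st2 <- residue_contact_statistics(detect_contacts(ens2, sel(1, "A"), sel(2:3, "B")))
  expect_equal(st2$residues$mean_contacts[st2$residues$chain == "A"], 2.0)

  # empty series -> all zero
  ens3 <- make_ensemble(top, list(f2))
  st3 <- residue_contact_statistics(detect_contacts(ens3, sel(1, "A"), sel(2:3, "B")))
  expect_equal(nrow(st3$pairs), 0L)
})

test_that("pooled per-residue values sum to twice the pair total per frame", {
  b <- generate_binding_ensemble(synthetic_spec(n_frames = 60, seed = 29))
  top <- b$ensemble$topology
  se <- select_atoms(top, "E", unique(top$residue_number[top$chain_id == "E"]))
  sl <- select_atoms(top, "I", unique(top$residue_number[top$chain_id == "I"]))
  cs <- detect_contacts(b$ensemble, se, sl)
  st <- residue_contact_statistics(cs)
  total_pairs <- sum(vapply(cs$residue_pairs, nrow, integer(1)))
  expect_equal(sum(st$residues$mean_contacts), 2 * total_pairs / st$n_frames)
})

test_that("contact network export round-trips and orders edges", {
  b <- generate_binding_ensemble(synthetic_spec(n_frames = 40, seed = 8))
  top <- b$ensemble$topology
  se <- select_atoms(top, "E", unique(top$residue_number[top$chain_id == "E"]))
  sl <- select_atoms(top, "I", unique(top$residue_number[top$chain_id == "I"]))
  st <- residue_contact_statistics(detect_contacts(b$ensemble, se, sl))
  path <- withr::local_tempfile(fileext = ".tsv")
  paths <- export_contact_network(st, path)
  edges <- read.delim(paths[["edges"]])
  nodes <- read.delim(paths[["nodes"]])
  expect_equal(nrow(edges), nrow(st$pairs))
  expect_equal(edges$contact_fraction, st$pairs$contact_fraction)
  expect_false(is.unsorted(rev(edges$contact_fraction)))
  expect_equal(nodes$mean_contacts, st$residues$mean_contacts)
})
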