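# In-code fixtures: tiny hand-built topologies and ensembles.

# Topology with one atom per row; defaults give a single chain of glycine
# pseudo-residues.
make_topology <- function(elements, chains = "A", residues = seq_along(elements),
                          names = elements) {
  n <- length(elements)
  chains <- rep_len(chains, n)
  residues <- rep_len(residues, n)
  data.frame(
    atom_index = seq_len(n), atom_name = names, element = elements,
    chain_id = chains, residue_number = as.integer(residues),
    residue_name = "GLY", mass = loopscape::element_mass(elements),
    is_heavy = !toupper(elements) %in% c("H", "D"),
    stringsAsFactors = FALSE
  )
}

# Ensemble from a list of n_atoms x 3 coordinate matrices.
make_ensemble <- function(topology, frames, frame_ids = seq_along(frames)) {
  coords <- array(NA_real_, dim = c(nrow(topology), 3L, length(frames)))
  for (i in seq_along(frames)) coords[, , i] <- frames[[i]]
  structure_ensemble(topology, coords, frame_ids)
}

sel <- function(idx, label = "sel") {
  structure(list(atom_indices = as.integer(idx), label = label),
            class = "AtomSelection")
}

# random rigid rotation matrix (uniform via QR of Gaussians)
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

skip_if_no_python <- function() {
  testthat::skip_if(Sys.which("python") == "", "python not on PATH")
}
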