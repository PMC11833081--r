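# Seeded synthetic two-chain ensembles with ground truth.
#
# The generators emulate the statistical structure the analysis pipeline
# assumes -- a bimodal loop/active-site COM distance with a controllable open
# fraction, a ligand chain occupying K discrete binding poses, and planted
# inter-chain contact patterns -- using deliberately schematic geometry
# (pseudo-residues on a helical template). The pipeline consumes only
# coordinates, masses and labels, so statistical rather than stereochemical
# realism is the requirement.
#
# Loop placement solves the COM constraint exactly: the loop group is a rigid
# template translated along a fixed axis from the active-site centroid, and
# Gaussian noise is applied to the translation scalar, so the COM distance
# (not each atom position) carries exactly the specified sigma.

#' Specification for a synthetic ensemble
#'
#' Collects every knob of the synthetic generators with defaults sized so the
#' full pipeline runs in seconds: a 40-residue enzyme and 15-residue ligand
#' with 4 heavy atoms per pseudo-residue, 2000 frames, a two-state loop at
#' 12 A (closed) / 20 A (open) with 0.8 A COM noise, and K = 2 ligand poses
#' at 70/30 occupancy 10 A apart, the first in contact with the pocket.
#'
#' @param n_frames Number of frames.
#' @param f_open Open-state probability per frame.
#' @param d_closed,d_open Loop/active-site COM distance (Angstrom) of the two
#'   states.
#' @param loop_noise_sigma Gaussian noise on the COM distance (Angstrom).
#' @param n_enzyme_residues,n_ligand_residues Pseudo-residue counts of the
#'   two chains.
#' @param atoms_per_residue Heavy atoms per pseudo-residue.
#' @param n_poses Number of discrete ligand poses K.
#' @param pose_occupancies Occupancy per pose, summing to 1.
#' @param pose_spacing Distance (Angstrom) between consecutive pose offsets.
#' @param bound_poses Indices of poses placed in contact with the pocket.
#' @param pose_jitter_sigma Isotropic Gaussian jitter of the rigid ligand per
#'   frame (Angstrom), truncated at 4 sigma so planted contact/no-contact
#'   geometry is exact.
#' @param f_open_bound Open probability for frames in a bound pose when
#'   `couple_loop` is `TRUE`.
#' @param couple_loop Couple loop state to pose occupancy (allosteric
#'   opening).
#' @param seed Integer seed; the generators are fully deterministic given the
#'   spec.
#' @return A `SyntheticSpec` list.
#' @export
synthetic_spec <- function(n_frames = 2000L, f_open = 0.25,
                           d_closed = 12, d_open = 20, loop_noise_sigma = 0.8,
                           n_enzyme_residues = 40L, n_ligand_residues = 15L,
                           atoms_per_residue = 4L,
                           n_poses = 2L, pose_occupancies = c(0.7, 0.3),
                           pose_spacing = 10, bound_poses = 1L,
                           pose_jitter_sigma = 0.25,
                           f_open_bound = 0.63, couple_loop = FALSE,
                           seed = 1L) {
  spec <- list(n_frames = as.integer(n_frames), f_open = f_open,
               d_closed = d_closed, d_open = d_open,
               loop_noise_sigma = loop_noise_sigma,
               n_enzyme_residues = as.integer(n_enzyme_residues),
               n_ligand_residues = as.integer(n_ligand_residues),
               atoms_per_residue = as.integer(atoms_per_residue),
               n_poses = as.integer(n_poses),
               pose_occupancies = pose_occupancies,
               pose_spacing = pose_spacing,
               bound_poses = as.integer(bound_poses),
               pose_jitter_sigma = pose_jitter_sigma,
               f_open_bound = f_open_bound, couple_loop = couple_loop,
               seed = as.integer(seed))
  if (spec$f_open < 0 || spec$f_open > 1) stop("f_open must lie in [0, 1]")
  if (spec$d_open <= spec$d_closed || spec$d_closed <= 0)
    stop("need d_open > d_closed > 0")
  if (length(spec$pose_occupancies) != spec$n_poses)
    stop("pose_occupancies length must equal n_poses")
  if (abs(sum(spec$pose_occupancies) - 1) > 1e-12)
    stop("pose_occupancies must sum to 1")
  if (spec$n_poses < 1L) stop("need at least one pose")
  if (spec$d_open - spec$d_closed < 6 * spec$loop_noise_sigma)
    warning("open and closed distances are within 6 sigma; states may not be separable")
  class(spec) <- "SyntheticSpec"
  spec
}

# Heavy-atom template of one pseudo-residue (N, CA, C, O backbone motif),
# centred near the origin.
.residue_template <- function() {
  list(
    names = c("N", "CA", "C", "O"),
    elements = c("N", "C", "C", "O"),
    offsets = rbind(c(-0.7, -0.4, 0), c(0, 0.5, 0.4),
                    c(0.7, -0.1, -0.3), c(0.9, -0.9, 0.2))
  )
}

# Place n_res pseudo-residues on a coarse helix starting at `origin` and
# advancing along `axis`; returns coordinates and bookkeeping columns.
.chain_coords <- function(n_res, atoms_per_residue, origin, axis = c(-1, 0, 0),
                          radius = 6, pitch = 1.6, turn_deg = 100) {
  tmpl <- .residue_template()
  apr <- atoms_per_residue
  stopifnot(apr <= length(tmpl$names))
  axis <- axis / sqrt(sum(axis^2))
  # orthonormal frame around the helix axis
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * axis) * axis; u <- u / sqrt(sum(u^2))
  v <- c(axis[2] * u[3] - axis[3] * u[2],
         axis[3] * u[1] - axis[1] * u[3],
         axis[1] * u[2] - axis[2] * u[1])
  theta <- (seq_len(n_res) - 1) * turn_deg * pi / 180
  centers <- t(vapply(seq_len(n_res), function(i) {
    origin + (i - 1) * pitch * axis +
      radius * (cos(theta[i]) * u + sin(theta[i]) * v)
  }, numeric(3)))
  coords <- centers[rep(seq_len(n_res), each = apr), , drop = FALSE] +
    tmpl$offsets[rep(seq_len(apr), n_res), , drop = FALSE]
  list(coords = coords,
       atom_name = rep(tmpl$names[seq_len(apr)], n_res),
       element = rep(tmpl$elements[seq_len(apr)], n_res),
       residue_number = rep(seq_len(n_res), each = apr))
}

# Assemble the static enzyme scaffold shared by both generators. Chain "E":
# residues 1..3 form the active site (compact cluster at the origin), the
# last 6 residues form the mobile loop (rigid template, COM at origin before
# placement), the remainder is a static helical body placed along -x. The
# pocket is a designated stretch of body residues.
.enzyme_scaffold <- function(spec) {
  apr <- spec$atoms_per_residue
  n_res <- spec$n_enzyme_residues
  n_loop <- 6L
  n_active <- 3L
  if (n_res < n_active + n_loop + 6L)
    stop("enzyme needs at least ", n_active + n_loop + 6L, " residues")
  active <- .chain_coords(n_active, apr, origin = c(0, 0, 0),
                          axis = c(0, 0, 1), radius = 1.2, pitch = 1.2)
  body_n <- n_res - n_active - n_loop
  body <- .chain_coords(body_n, apr, origin = c(-12, 0, 0), axis = c(-1, 0, 0))
  loop <- .chain_coords(n_loop, apr, origin = c(0, 0, 0),
                        axis = c(1, 0, 0), radius = 2.5, pitch = 1.4)
  loop_w <- element_mass(loop$element)
  loop$coords <- sweep(loop$coords, 2,
                       colSums(loop$coords * loop_w) / sum(loop_w))  # mass-weighted COM at origin
  masses <- element_mass(c(active$element, body$element, loop$element))
  active_com <- colSums(active$coords * element_mass(active$element)) /
    sum(element_mass(active$element))
  topology <- data.frame(
    atom_index = seq_len((n_active + body_n + n_loop) * apr),
    atom_name = c(active$atom_name, body$atom_name, loop$atom_name),
    element = c(active$element, body$element, loop$element),
    chain_id = "E",
    residue_number = c(active$residue_number,
                       body$residue_number + n_active,
                       loop$residue_number + n_active + body_n),
    residue_name = "GLY",
    stringsAsFactors = FALSE
  )
  topology$mass <- masses
  topology$is_heavy <- !.is_hydrogen(topology$element)
  pocket_res <- (n_active + 1L):(n_active + 3L)  # first three body residues
  list(topology = topology,
       static_coords = rbind(active$coords, body$coords),
       loop_template = loop$coords,
       active_com = active_com,
       loop_atoms = which(topology$residue_number > n_active + body_n),
       loop_residues = (n_active + body_n + 1L):n_res,
       active_residues = 1:3,
       pocket_residues = pocket_res,
       pocket_atoms = which(topology$residue_number %in% pocket_res))
}

.place_loop <- function(scaffold, d) {
  # rigid loop translated along +x from the active-site COM; its COM distance
  # to the active-site COM is exactly d (template COM sits at the origin)
  sweep(scaffold$loop_template, 2, scaffold$active_com + c(d, 0, 0), "+")
}

#' Generate a two-state occluding-loop ensemble
#'
#' One enzyme chain whose loop segment hops between a closed and an open
#' placement; per frame the state is Bernoulli(`f_open`) and the planted
#' loop/active-site COM distance is `d_state + N(0, loop_noise_sigma)`.
#' Deterministic for a fixed spec.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `ensemble` (a `StructureEnsemble`), `ground_truth`
#'   (data frame: `frame_id`, `state`, `distance`), and `groups` (residue
#'   numbers of `loop`, `active_site`, `pocket` on chain "E").
#' @export
generate_two_state_enzyme <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  sc <- .enzyme_scaffold(spec)
  nat <- nrow(sc$topology)
  with_seed(spec$seed, {
    open <- stats::rbinom(spec$n_frames, 1L, spec$f_open) == 1L
    d <- ifelse(open, spec$d_open, spec$d_closed) +
      stats::rnorm(spec$n_frames, 0, spec$loop_noise_sigma)
    d <- pmax(d, 0.1)
    coords <- array(NA_real_, dim = c(nat, 3L, spec$n_frames))
    for (f in seq_len(spec$n_frames)) {
      coords[, , f] <- rbind(sc$static_coords, .place_loop(sc, d[f]))
    }
    list(
      ensemble = structure_ensemble(sc$topology, coords, seq_len(spec$n_frames)),
      ground_truth = data.frame(
        frame_id = seq_len(spec$n_frames),
        state = ifelse(open, "open", "closed"),
        distance = d
      ),
      groups = list(loop = sc$loop_residues, active_site = sc$active_residues,
                    pocket = sc$pocket_residues, chain = "E")
    )
  })
}

# Deterministic-by-seed isotropic Gaussian, truncated at 4 sigma (resampled),
# so the jitter never breaks the planted contact geometry.
.truncated_jitter <- function(n, sigma) {
  if (sigma == 0) return(matrix(0, n, 3))
  j <- matrix(stats::rnorm(3L * n, 0, sigma), n, 3)
  norms <- sqrt(rowSums(j^2))
  bad <- norms > 4 * sigma
  while (any(bad)) {
    j[bad, ] <- matrix(stats::rnorm(3L * sum(bad), 0, sigma), sum(bad), 3)
    norms[bad] <- sqrt(rowSums(j[bad, , drop = FALSE]^2))
    bad <- norms > 4 * sigma
  }
  j
}

#' Generate a two-chain binding ensemble with K discrete poses
#'
#' Adds a rigid ligand chain "I" to the two-state enzyme. Per frame a pose is
#' drawn from `pose_occupancies`; the ligand is rigidly placed at that pose's
#' offset plus truncated Gaussian jitter. Poses listed in `bound_poses` are
#' anchored so that one ligand heavy atom always sits closer than 3.3 A to a
#' pocket-residue atom (and jitter cannot break this); the remaining poses
#' are displaced along the pocket normal far enough that no inter-chain atom
#' pair can come within the cutoff. With `couple_loop = TRUE`, frames in a
#' bound pose draw their loop state with probability `f_open_bound` instead
#' of `f_open`, emulating allosteric opening.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `ensemble`, `ground_truth` (data frame: `frame_id`,
#'   `state`, `distance`, `pose`, `bound`), and `groups` (as in
#'   [generate_two_state_enzyme()], plus `ligand_chain`).
#' @export
generate_binding_ensemble <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  sc <- .enzyme_scaffold(spec)
  apr <- spec$atoms_per_residue
  lig <- .chain_coords(spec$n_ligand_residues, apr,
                       origin = c(0, 0, 0), axis = c(0, 1, 0),
                       radius = 4, pitch = 1.6)
  lig$coords <- sweep(lig$coords, 2, colMeans(lig$coords))
  # anchor: the ligand heavy atom that will face the pocket (largest -z)
  anchor <- which.min(lig$coords[, 3])
  pocket_xyz <- sc$static_coords[sc$pocket_atoms, , drop = FALSE]
  pocket_ref <- pocket_xyz[which.max(pocket_xyz[, 3]), ]
  # pose 1..K offsets: bound poses put the anchor 1.8 A above the reference
  # pocket atom along +z; unbound poses stack further out in pose_spacing steps
  normal <- c(0, 0, 1)
  pose_offsets <- matrix(NA_real_, spec$n_poses, 3)
  out_rank <- 0L
  for (k in seq_len(spec$n_poses)) {
    if (k %in% spec$bound_poses) {
      base <- pocket_ref + 1.8 * normal
    } else {
      out_rank <- out_rank + 1L
      base <- pocket_ref + (1.8 + out_rank * spec$pose_spacing) * normal
    }
    pose_offsets[k, ] <- base - lig$coords[anchor, ]
  }
  if (spec$pose_spacing < 3 * spec$pose_jitter_sigma)
    warning("pose spacing under 3x jitter; poses may not be separable")

  lig_top <- data.frame(
    atom_index = nrow(sc$topology) + seq_len(spec$n_ligand_residues * apr),
    atom_name = lig$atom_name,
    element = lig$element,
    chain_id = "I",
    residue_number = lig$residue_number,
    residue_name = "GLY",
    stringsAsFactors = FALSE
  )
  lig_top$mass <- element_mass(lig_top$element)
  lig_top$is_heavy <- !.is_hydrogen(lig_top$element)
  topology <- rbind(sc$topology, lig_top)
  nat <- nrow(topology)

  with_seed(spec$seed, {
    pose <- sample.int(spec$n_poses, spec$n_frames, replace = TRUE,
                       prob = spec$pose_occupancies)
    bound <- pose %in% spec$bound_poses
    p_open <- if (spec$couple_loop)
      ifelse(bound, spec$f_open_bound, spec$f_open) else spec$f_open
    open <- stats::rbinom(spec$n_frames, 1L, p_open) == 1L
    d <- ifelse(open, spec$d_open, spec$d_closed) +
      stats::rnorm(spec$n_frames, 0, spec$loop_noise_sigma)
    d <- pmax(d, 0.1)
    jit <- .truncated_jitter(spec$n_frames, spec$pose_jitter_sigma)
    coords <- array(NA_real_, dim = c(nat, 3L, spec$n_frames))
    for (f in seq_len(spec$n_frames)) {
      lig_xyz <- sweep(lig$coords, 2, pose_offsets[pose[f], ] + jit[f, ], "+")
      coords[, , f] <- rbind(sc$static_coords, .place_loop(sc, d[f]), lig_xyz)
    }
    list(
      ensemble = structure_ensemble(topology, coords, seq_len(spec$n_frames)),
      ground_truth = data.frame(
        frame_id = seq_len(spec$n_frames),
        state = ifelse(open, "open", "closed"),
        distance = d,
        pose = pose,
        bound = bound
      ),
      groups = list(loop = sc$loop_residues, active_site = sc$active_residues,
                    pocket = sc$pocket_residues, chain = "E",
                    ligand_chain = "I")
    )
  })
}
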