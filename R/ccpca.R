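# Contact-contact PCA (ccPCA): an equal-size inter-chain heavy-atom mesh,
# per-frame pairwise-distance features, PCA onto two components, Boltzmann
# inversion of the score density into a Gibbs free-energy landscape, and
# per-cluster conformational-state summaries.

#' Gas constant in kJ/(mol K)
#' @export
GAS_CONSTANT_KJ <- 0.008314462618

#' Build an equal-size inter-chain contact mesh
#'
#' Let m be the heavy-atom count of the smaller chain. The smaller chain
#' contributes all m heavy atoms (in residue-number, then atom-name order);
#' the larger chain contributes every k-th heavy atom in the same ordering,
#' with stride `k = floor(n_large / m)`, taking the first m strided atoms.
#' The feature pair list is the full m x m cross product, optionally capped
#' by a seeded uniform subsample (the cap is an engineering escape hatch for
#' very large chains, off by default).
#'
#' @param topology Topology data frame.
#' @param chain_a,chain_b Chain ids of the two proteins.
#' @param cap Optional maximum pair count; `NULL` for the full cross product.
#' @param seed Integer seed used only when `cap` is set.
#' @return A `ContactMesh`: `mesh_a`, `mesh_b` (1-based topology atom
#'   indices, length m each), `pair_list` (matrix, columns `a`, `b`, indices
#'   into `mesh_a`/`mesh_b`), `cap`, `seed`.
#' @export
build_contact_mesh <- function(topology, chain_a, chain_b, cap = NULL, seed = 1L) {
  heavy_of <- function(ch) {
    sub <- topology[topology$chain_id == ch & topology$is_heavy, ]
    if (nrow(sub) == 0L) stop("chain '", ch, "' has no heavy atoms")
    sub$atom_index[order(sub$residue_number, sub$atom_name)]
  }
  a <- heavy_of(chain_a); b <- heavy_of(chain_b)
  swap <- length(b) < length(a)
  small <- if (swap) b else a
  large <- if (swap) a else b
  m <- length(small)
  k <- max(1L, length(large) %/% m)
  large_sel <- large[seq(1L, by = k, length.out = m)]
  mesh_a <- if (swap) large_sel else small
  mesh_b <- if (swap) small else large_sel
  pair_list <- as.matrix(expand.grid(a = seq_len(m), b = seq_len(m),
                                     KEEP.OUT.ATTRS = FALSE))
  if (!is.null(cap) && cap < nrow(pair_list)) {
    pick <- with_seed(seed, sort(sample.int(nrow(pair_list), cap)))
    pair_list <- pair_list[pick, , drop = FALSE]
  }
  structure(
    list(mesh_a = mesh_a, mesh_b = mesh_b, pair_list = pair_list,
         cap = cap, seed = seed, chain_a = chain_a, chain_b = chain_b),
    class = "ContactMesh"
  )
}

#' @export
print.ContactMesh <- function(x, ...) {
  cat(sprintf("ContactMesh %s|%s: m=%d atoms per chain, %d distance pairs%s\n",
              x$chain_a, x$chain_b, length(x$mesh_a), nrow(x$pair_list),
              if (is.null(x$cap)) "" else sprintf(" (cap %d, seed %d)", x$cap, x$seed)))
  invisible(x)
}

#' Per-frame mesh distance features
#'
#' Collects the Euclidean distance (Angstrom) of every mesh pair in every
#' kept frame: one row per frame, one column per pair.
#'
#' @param ensemble A `StructureEnsemble`.
#' @param mesh A `ContactMesh` built on the same topology.
#' @param frame_filter Optional `FrameFilter`; only kept frames become rows.
#' @return A `FeatureMatrix`: list with `values` (frames x pairs matrix),
#'   `frame_ids`, and the `mesh`.
#' @export
compute_features <- function(ensemble, mesh, frame_filter = NULL) {
  stopifnot(inherits(ensemble, "StructureEnsemble"), inherits(mesh, "ContactMesh"))
  keep <- if (is.null(frame_filter)) rep(TRUE, n_frames(ensemble)) else {
    if (length(frame_filter$keep) != n_frames(ensemble))
      stop("filter length does not match frame count")
    frame_filter$keep
  }
  if (!any(keep)) stop("frame filter keeps zero frames")
  ai <- mesh$mesh_a[mesh$pair_list[, "a"]]
  bi <- mesh$mesh_b[mesh$pair_list[, "b"]]
  frames <- which(keep)
  vals <- matrix(NA_real_, nrow = length(frames), ncol = length(ai))
  for (r in seq_along(frames)) {
    xyz <- matrix(ensemble$coords[, , frames[r]], ncol = 3L)
    d <- xyz[ai, , drop = FALSE] - xyz[bi, , drop = FALSE]
    vals[r, ] <- sqrt(rowSums(d * d))
  }
  structure(
    list(values = vals, frame_ids = ensemble$frame_ids[frames], mesh = mesh),
    class = "FeatureMatrix"
  )
}

#' Principal component analysis of mesh distance features
#'
#' Centres features by their column means (no scaling: all features share
#' Angstrom units), drops zero-variance columns, and fits PCA by singular
#' value decomposition via [stats::prcomp()]. Component signs are fixed so
#' that each component's largest-magnitude loading is positive, making
#' scores reproducible across linear-algebra backends.
#'
#' @param features A `FeatureMatrix` or plain numeric matrix (rows = frames).
#' @param n_components Number of components to retain (default 2).
#' @return A `PCAModel`: `mean`, `components` (features x k, orthonormal),
#'   `explained_variance` (all ranks), `scores` (frames x k),
#'   `dropped_columns`, `total_variance`, `frame_ids`.
#' @export
fit_pca <- function(features, n_components = 2L) {
  x <- if (inherits(features, "FeatureMatrix")) features$values else as.matrix(features)
  frame_ids <- if (inherits(features, "FeatureMatrix")) features$frame_ids
               else seq_len(nrow(x))
  if (nrow(x) < 2L) stop("PCA needs at least 2 frames")
  v <- apply(x, 2, stats::var)
  dropped <- which(v == 0)
  if (length(dropped)) x <- x[, -dropped, drop = FALSE]
  if (ncol(x) == 0L) stop("all features have zero variance")
  if (n_components > min(nrow(x) - 1L, ncol(x)))
    stop("n_components exceeds the rank supported by the data")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  comps <- pc$rotation[, seq_len(n_components), drop = FALSE]
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  # sign convention: largest |loading| positive per component
  for (j in seq_len(ncol(comps))) {
    i_max <- which.max(abs(comps[, j]))
    if (comps[i_max, j] < 0) {
      comps[, j] <- -comps[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(
    list(mean = pc$center, components = comps,
         explained_variance = pc$sdev^2, scores = scores,
         dropped_columns = dropped, total_variance = sum(v[v > 0]),
         frame_ids = frame_ids),
    class = "PCAModel"
  )
}

#' @export
print.PCAModel <- function(x, ...) {
  ev <- x$explained_variance / sum(x$explained_variance)
  k <- ncol(x$components)
  cat(sprintf("PCAModel: %d frames, %d components (%s of variance)\n",
              nrow(x$scores), k,
              paste(sprintf("%.1f%%", 100 * ev[seq_len(k)]), collapse = " + ")))
  invisible(x)
}

#' Gibbs free-energy landscape from PC scores
#'
#' Bins the PC1/PC2 scores onto a 2D histogram (axis ranges padded by 1% of
#' the span on each side), converts bin counts to probabilities P and applies
#' Boltzmann inversion, `delta_g = -R T ln(P / max(P))`, so the modal bin has
#' exactly zero free energy. Empty bins are masked (`NA` energy), never
#' assigned an infinite value.
#'
#' @param scores Numeric matrix (frames x 2) of PC scores.
#' @param bins Number of bins per axis (default 100).
#' @param temperature Temperature in Kelvin (default 300, the bottom of a
#'   typical replica ladder).
#' @param gas_constant R in kJ/(mol K); default [GAS_CONSTANT_KJ].
#' @return A `FreeEnergyLandscape`: `edges_pc1`, `edges_pc2`, `probability`
#'   (bins x bins), `delta_g` (kJ/mol, `NA` on empty bins), `empty_mask`,
#'   `gas_constant`, `temperature`.
#' @export
free_energy_landscape <- function(scores, bins = 100L, temperature = 300,
                                  gas_constant = GAS_CONSTANT_KJ) {
  scores <- as.matrix(scores)
  if (ncol(scores) != 2L) stop("scores must have exactly two columns")
  if (!all(is.finite(scores))) stop("scores must be finite")
  if (nrow(scores) < 1L) stop("need at least one score row")
  if (bins < 2L) stop("bins must be >= 2")
  if (temperature <= 0) stop("temperature must be positive")
  pad_edges <- function(v) {
    lo <- min(v); hi <- max(v); span <- hi - lo
    if (span == 0) { lo <- lo - 0.5; hi <- hi + 0.5 }
    else { lo <- lo - 0.01 * span; hi <- hi + 0.01 * span }
    seq(lo, hi, length.out = bins + 1L)
  }
  e1 <- pad_edges(scores[, 1]); e2 <- pad_edges(scores[, 2])
  b1 <- findInterval(scores[, 1], e1, rightmost.closed = TRUE, all.inside = TRUE)
  b2 <- findInterval(scores[, 2], e2, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- matrix(0, bins, bins)
  tab <- table(factor(b1, levels = seq_len(bins)),
               factor(b2, levels = seq_len(bins)))
  counts[] <- as.numeric(tab)
  p <- counts / sum(counts)
  empty <- p == 0
  dg <- matrix(NA_real_, bins, bins)
  dg[!empty] <- -gas_constant * temperature * log(p[!empty] / max(p))
  structure(
    list(edges_pc1 = e1, edges_pc2 = e2, probability = p, delta_g = dg,
         empty_mask = empty, gas_constant = gas_constant,
         temperature = temperature),
    class = "FreeEnergyLandscape"
  )
}

#' @export
print.FreeEnergyLandscape <- function(x, ...) {
  cat(sprintf("FreeEnergyLandscape: %dx%d bins, %d occupied, max dG %.2f kJ/mol (T=%g K)\n",
              nrow(x$probability), ncol(x$probability), sum(!x$empty_mask),
              max(x$delta_g, na.rm = TRUE), x$temperature))
  invisible(x)
}

#' Landscape grid as a long-format table
#'
#' @param landscape A `FreeEnergyLandscape`.
#' @return Data frame with bin centres, probability, free energy and an
#'   `empty` flag, one row per bin.
#' @export
landscape_table <- function(landscape) {
  c1 <- (head(landscape$edges_pc1, -1) + tail(landscape$edges_pc1, -1)) / 2
  c2 <- (head(landscape$edges_pc2, -1) + tail(landscape$edges_pc2, -1)) / 2
  grid <- expand.grid(pc1_bin_center = c1, pc2_bin_center = c2,
                      KEEP.OUT.ATTRS = FALSE)
  data.frame(grid,
             probability = as.vector(landscape$probability),
             delta_g_kj_mol = as.vector(landscape$delta_g),
             empty = as.vector(landscape$empty_mask))
}

#' Per-cluster conformational state summary
#'
#' For each cluster, the mean and standard deviation of the loop/active-site
#' COM distance over member frames and the open-state fraction at the given
#' threshold — the per-cluster numbers behind "average COM distance (+/- SD)
#' for major cluster states".
#'
#' @param clusters A `ClusterResult` from [cluster_scores()].
#' @param trace A `DistanceTrace` aligned with the clustered frames (same
#'   length and order).
#' @param threshold Open/closed threshold in Angstrom (default 16.5).
#' @return Data frame (`ClusterStateSummary`) with `cluster_id`, `n`,
#'   `mean_distance`, `sd_distance`, `open_fraction`.
#' @export
cluster_state_summary <- function(clusters, trace, threshold = 16.5) {
  stopifnot(inherits(clusters, "ClusterResult"), inherits(trace, "DistanceTrace"))
  if (length(trace$values) != length(clusters$labels))
    stop("trace and cluster labels cover different frame counts")
  out <- lapply(seq_len(nrow(clusters$clusters)), function(k) {
    d <- trace$values[clusters$members[[k]]]
    data.frame(cluster_id = k, n = length(d),
               mean_distance = mean(d),
               sd_distance = stats::sd(d),
               open_fraction = mean(d > threshold))
  })
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(cluster_id = integer(0), n = integer(0),
               mean_distance = numeric(0), sd_distance = numeric(0),
               open_fraction = numeric(0))
  structure(res, class = c("ClusterStateSummary", "data.frame"))
}
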