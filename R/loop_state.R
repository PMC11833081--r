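# Occluding-loop state analysis: centre-of-mass distance traces, open/closed
# classification, threshold scans, and the open-state fold-change statistic.
#
# The reaction coordinate is the Euclidean distance between the mass-weighted
# centroids of two atom groups (by default the occluding loop and the
# active-site residues). COM is computed over heavy atoms with standard
# atomic weights, which keeps results independent of any hydrogen-mass
# repartitioning the sampling engine may have applied; set
# `heavy_only = FALSE` to include hydrogens as a sensitivity check.

.group_com <- function(coords, idx, masses) {
  # coords: n_atoms x 3 x n_frames; returns n_frames x 3 matrix of COMs
  w <- masses[idx] / sum(masses[idx])
  sub <- coords[idx, , , drop = FALSE]
  t(apply(sub, 3, function(xyz) colSums(matrix(xyz, ncol = 3L) * w)))
}

#' Centre-of-mass distance trace between two atom groups
#'
#' Per frame, the Euclidean distance (Angstrom) between the mass-weighted
#' centroids of two disjoint selections.
#'
#' @param ensemble A `StructureEnsemble`.
#' @param group_a,group_b `AtomSelection` objects (see [select_atoms()]).
#' @param heavy_only Restrict both groups to heavy atoms before weighting
#'   (default `TRUE`).
#' @return A `DistanceTrace`: list with `values` (Angstrom), `frame_ids`,
#'   `group_a_label`, `group_b_label`.
#' @export
com_distance_trace <- function(ensemble, group_a, group_b, heavy_only = TRUE) {
  stopifnot(inherits(ensemble, "StructureEnsemble"))
  ia <- group_a$atom_indices; ib <- group_b$atom_indices
  if (any(ia > n_atoms(ensemble)) || any(ib > n_atoms(ensemble)))
    stop("selection indices out of range for this topology")
  if (length(intersect(ia, ib)))
    stop("groups share atoms; COM distance requires disjoint selections")
  if (heavy_only) {
    heavy <- ensemble$topology$is_heavy
    ia <- ia[heavy[ia]]; ib <- ib[heavy[ib]]
    if (!length(ia) || !length(ib))
      stop("selection has no heavy atoms; set heavy_only = FALSE to use all atoms")
  }
  m <- ensemble$topology$mass
  ca <- .group_com(ensemble$coords, ia, m)
  cb <- .group_com(ensemble$coords, ib, m)
  structure(
    list(values = sqrt(rowSums((ca - cb)^2)),
         frame_ids = ensemble$frame_ids,
         group_a_label = group_a$label, group_b_label = group_b$label),
    class = "DistanceTrace"
  )
}

#' @export
print.DistanceTrace <- function(x, ...) {
  cat(sprintf("DistanceTrace %s <-> %s: %d frames, range %.2f-%.2f A\n",
              x$group_a_label, x$group_b_label, length(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Classify open/closed states against a distance threshold
#'
#' A frame is labelled `closed` when its COM distance is less than or equal
#' to the threshold (the boundary belongs to the closed state), `open`
#' otherwise. The default 16.5 A is the closed-state threshold of the
#' murine cathepsin B preset.
#'
#' @param trace A `DistanceTrace`.
#' @param threshold Distance threshold in Angstrom (> 0).
#' @return A `StateSeries`: list with `labels` (factor closed/open),
#'   `threshold`, `fraction_open`, `fraction_closed`, `frame_ids`.
#' @export
classify_states <- function(trace, threshold = 16.5) {
  stopifnot(inherits(trace, "DistanceTrace"))
  if (length(trace$values) == 0L) stop("empty distance trace")
  if (!is.numeric(threshold) || threshold <= 0) stop("threshold must be > 0")
  closed <- trace$values <= threshold
  structure(
    list(labels = factor(ifelse(closed, "closed", "open"),
                         levels = c("closed", "open")),
         threshold = threshold,
         fraction_closed = mean(closed),
         fraction_open = mean(!closed),
         frame_ids = trace$frame_ids),
    class = "StateSeries"
  )
}

#' @export
print.StateSeries <- function(x, ...) {
  cat(sprintf("StateSeries at %.2f A: %.1f%% closed / %.1f%% open (%d frames)\n",
              x$threshold, 100 * x$fraction_closed, 100 * x$fraction_open,
              length(x$labels)))
  invisible(x)
}

#' Closed-state fraction over a grid of thresholds
#'
#' Evaluates the empirical cumulative distribution of the distance trace on a
#' strictly ascending threshold grid; `closed_fraction` at threshold t is the
#' proportion of frames with distance <= t.
#'
#' @param trace A `DistanceTrace`.
#' @param grid Strictly ascending numeric vector of thresholds (Angstrom);
#'   default 12-24 A in 0.1 A steps.
#' @return Data frame (`ThresholdScan`) with columns `threshold`,
#'   `closed_fraction`, `open_fraction`.
#' @export
threshold_scan <- function(trace, grid = seq(12, 24, by = 0.1)) {
  stopifnot(inherits(trace, "DistanceTrace"))
  if (length(grid) == 0L || is.unsorted(grid, strictly = TRUE))
    stop("grid must be non-empty and strictly ascending")
  ecdf_fun <- stats::ecdf(trace$values)
  cf <- ecdf_fun(grid)
  structure(
    data.frame(threshold = grid, closed_fraction = cf, open_fraction = 1 - cf),
    class = c("ThresholdScan", "data.frame")
  )
}

#' Fold change in open-state fraction between two conditions
#'
#' Ratio of the mean open fraction of the case condition to the mean open
#' fraction of the reference condition — the statistic behind the reported
#' increase in active (open) states under allosteric binding. Computed as a
#' ratio of group means, not a mean of pairwise ratios.
#'
#' @param case_fractions Numeric vector of open fractions in `[0, 1]`.
#' @param reference_fractions Numeric vector of open fractions in `[0, 1]`.
#' @return Scalar fold change.
#' @export
open_fraction_fold_change <- function(case_fractions, reference_fractions) {
  if (!length(case_fractions) || !length(reference_fractions))
    stop("both fraction vectors must be non-empty")
  if (any(case_fractions < 0 | case_fractions > 1) ||
      any(reference_fractions < 0 | reference_fractions > 1))
    stop("open fractions must lie in [0, 1]")
  ref <- mean(reference_fractions)
  if (ref == 0) stop("reference mean open fraction is zero; ratio undefined")
  mean(case_fractions) / ref
}
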