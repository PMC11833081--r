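# OPTICS density-based clustering (Ankerst et al. reachability ordering with
# xi-based cluster extraction, including predecessor correction). Operates on
# small 2D score sets, so neighbour queries use a full distance matrix; the
# extraction logic mirrors the scikit-learn reference implementation, which a
# test cross-checks against.

#' OPTICS reachability analysis
#'
#' Computes the OPTICS processing order, reachability distances, core
#' distances and predecessors for a point set, using an unbounded
#' neighbourhood radius.
#'
#' @param x Numeric matrix, points in rows.
#' @param min_samples Neighbourhood size defining core distance (the point
#'   itself counts as its own first neighbour).
#' @return List with `order` (processing order, point indices),
#'   `reachability`, `core_distance`, `predecessor` (per point; `NA` where
#'   undefined).
#' @export
optics_reachability <- function(x, min_samples) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (min_samples < 2L) stop("min_samples must be >= 2")
  if (n < min_samples) stop("need at least min_samples points")
  D <- as.matrix(stats::dist(x))
  core <- apply(D, 1L, function(d) sort(d, partial = min_samples)[min_samples])
  reach <- rep(Inf, n)
  pred <- rep(NA_integer_, n)
  processed <- rep(FALSE, n)
  ord <- integer(n)
  for (i in seq_len(n)) {
    unproc <- which(!processed)
    p <- unproc[which.min(reach[unproc])]
    processed[p] <- TRUE
    ord[i] <- p
    cand <- !processed
    newreach <- pmax(core[p], D[p, ])
    upd <- cand & newreach < reach
    reach[upd] <- newreach[upd]
    pred[upd] <- p
  }
  list(order = ord, reachability = reach, core_distance = core,
       predecessor = pred)
}

# --- xi cluster extraction ------------------------------------------------
# All positions below are 1-based indices into the ordered reachability plot
# rp (which carries a trailing Inf so trailing clusters close properly).

.extend_region <- function(steep, xward, start, min_samples) {
  n <- length(steep)
  non_xward <- 0L; index <- start; end <- start
  while (index <= n) {
    if (steep[index]) {
      non_xward <- 0L; end <- index
    } else if (!xward[index]) {
      non_xward <- non_xward + 1L
      if (non_xward > min_samples) break
    } else return(end)
    index <- index + 1L
  }
  end
}

.update_filter_sdas <- function(sdas, mib, xi_complement, rp) {
  if (is.infinite(mib)) return(list())
  keep <- vapply(sdas, function(s) mib <= rp[s$start] * xi_complement, logical(1))
  lapply(sdas[keep], function(s) { s$mib <- max(s$mib, mib); s })
}

.correct_predecessor <- function(rp, pred_plot, ordering, s, e) {
  while (s < e) {
    if (rp[s] > rp[e]) return(c(s, e))
    p_e <- pred_plot[e]
    if (!is.na(p_e) && p_e %in% ordering[s:(e - 1L)]) return(c(s, e))
    e <- e - 1L
  }
  NULL
}

.xi_cluster <- function(reach_ordered, pred_ordered, ordering, xi,
                        min_samples, min_cluster_size) {
  rp <- c(reach_ordered, Inf)
  n_trans <- length(rp) - 1L
  xic <- 1 - xi
  ratio <- rp[seq_len(n_trans)] / rp[seq_len(n_trans) + 1L]
  nan <- is.nan(ratio)
  steep_up <- !nan & ratio <= xic
  steep_down <- !nan & ratio >= 1 / xic
  downward <- !nan & ratio > 1
  upward <- !nan & ratio < 1
  sdas <- list()
  clusters <- list()
  index <- 1L
  mib <- 0
  for (steep_index in which(steep_up | steep_down)) {
    if (steep_index < index) next
    mib <- max(mib, max(rp[index:steep_index]))
    if (steep_down[steep_index]) {
      sdas <- .update_filter_sdas(sdas, mib, xic, rp)
      d_start <- steep_index
      d_end <- .extend_region(steep_down, upward, d_start, min_samples)
      sdas[[length(sdas) + 1L]] <- list(start = d_start, end = d_end, mib = 0)
      index <- d_end + 1L
      mib <- rp[index]
    } else {
      sdas <- .update_filter_sdas(sdas, mib, xic, rp)
      u_start <- steep_index
      u_end <- .extend_region(steep_up, downward, u_start, min_samples)
      index <- u_end + 1L
      mib <- rp[index]
      u_clusters <- list()
      for (d in sdas) {
        c_start <- d$start; c_end <- u_end
        # reachability after the cluster must rise clearly above the SDA's mib
        if (rp[c_end + 1L] * xic < d$mib) next
        d_max <- rp[d$start]
        if (d_max * xic >= rp[c_end + 1L]) {
          while (c_start < d$end && rp[c_start + 1L] > rp[c_end + 1L])
            c_start <- c_start + 1L
        } else if (rp[c_end + 1L] * xic >= d_max) {
          while (c_end > u_start && rp[c_end - 1L] > d_max)
            c_end <- c_end - 1L
        }
        se <- .correct_predecessor(rp, pred_ordered, ordering, c_start, c_end)
        if (is.null(se)) next
        c_start <- se[1]; c_end <- se[2]
        if (c_end - c_start + 1L < min_cluster_size) next
        if (c_start > d$end) next
        if (c_end < u_start) next
        u_clusters[[length(u_clusters) + 1L]] <- c(c_start, c_end)
      }
      clusters <- c(clusters, rev(u_clusters))
    }
  }
  clusters
}

.extract_xi_labels <- function(ordering, clusters) {
  n <- length(ordering)
  lab_ord <- rep(-1L, n)
  lab <- 0L
  for (cl in clusters) {
    if (all(lab_ord[cl[1]:cl[2]] == -1L)) {
      lab_ord[cl[1]:cl[2]] <- lab
      lab <- lab + 1L
    }
  }
  labels <- integer(n)
  labels[ordering] <- lab_ord
  labels
}

#' OPTICS clustering of PC scores
#'
#' Runs OPTICS reachability analysis on the first two principal-component
#' scores and extracts clusters with the xi method. Noise points get label
#' `-1`; clusters are renumbered 1, 2, ... in descending size order. Each
#' cluster's representative is the member whose score is nearest (Euclidean)
#' to the cluster centroid, ties broken by lowest frame position.
#'
#' @param scores Numeric matrix (frames x 2) of PC scores.
#' @param min_samples Minimum neighbourhood size; default
#'   `max(10, ceiling(0.01 * n))`.
#' @param xi Steepness threshold in (0, 1) for cluster boundaries
#'   (default 0.05).
#' @param min_cluster_size Minimum cluster size; default
#'   `max(min_samples, ceiling(0.05 * n))`, so reported clusters are major
#'   states holding at least 5% of frames rather than density micro-leaves.
#' @return A `ClusterResult`: list with `labels` (per frame; -1 = noise),
#'   `clusters` data frame (`cluster_id`, `size`, `representative` frame
#'   position), `members` list, `reachability`, `order`, and the parameters.
#' @export
cluster_scores <- function(scores, min_samples = NULL, xi = 0.05,
                           min_cluster_size = NULL) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (is.null(min_samples)) min_samples <- max(10L, as.integer(ceiling(0.01 * n)))
  if (min_samples < 2L) stop("min_samples must be >= 2")
  if (n < min_samples) stop("fewer points than min_samples")
  if (xi <= 0 || xi >= 1) stop("xi must be in (0, 1)")
  if (is.null(min_cluster_size))
    min_cluster_size <- max(min_samples, as.integer(ceiling(0.05 * n)))
  opt <- optics_reachability(scores, min_samples)
  reach_ordered <- opt$reachability[opt$order]
  pred_ordered <- opt$predecessor[opt$order]
  cl <- .xi_cluster(reach_ordered, pred_ordered, opt$order, xi,
                    min_samples, min_cluster_size)
  raw_labels <- .extract_xi_labels(opt$order, cl)
  # renumber clusters by descending size (ties: lower original id first)
  ids <- sort(unique(raw_labels[raw_labels >= 0L]))
  labels <- rep(-1L, n)
  clusters <- data.frame(cluster_id = integer(0), size = integer(0),
                         representative = integer(0))
  if (length(ids)) {
    sizes <- vapply(ids, function(i) sum(raw_labels == i), integer(1))
    ord <- order(-sizes, ids)
    members <- vector("list", length(ids))
    for (k in seq_along(ord)) {
      mem <- which(raw_labels == ids[ord[k]])
      labels[mem] <- k
      members[[k]] <- mem
    }
    rep_pos <- vapply(members, function(mem) {
      centroid <- colMeans(scores[mem, , drop = FALSE])
      d2 <- rowSums(sweep(scores[mem, , drop = FALSE], 2, centroid)^2)
      mem[which.min(d2)]  # which.min takes the first (lowest position) on ties
    }, integer(1))
    clusters <- data.frame(cluster_id = seq_along(ord),
                           size = sizes[ord],
                           representative = rep_pos)
  } else members <- list()
  structure(
    list(labels = labels, clusters = clusters, members = members,
         reachability = opt$reachability, order = opt$order,
         optics_min_samples = min_samples, optics_xi = xi,
         min_cluster_size = min_cluster_size),
    class = "ClusterResult"
  )
}

#' @export
print.ClusterResult <- function(x, ...) {
  cat(sprintf("ClusterResult: %d clusters, %d noise of %d points (min_samples=%d, xi=%.3f)\n",
              nrow(x$clusters), sum(x$labels == -1L), length(x$labels),
              x$optics_min_samples, x$optics_xi))
  invisible(x)
}
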