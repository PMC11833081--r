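# Inter-chain contact detection, ensemble filtering and residue contact
# statistics.
#
# A contact is two heavy atoms of different selections strictly closer than
# the cutoff (default 3.3 A, i.e. 0.33 nm); a pair at exactly the cutoff is
# NOT a contact. Two kernels produce identical pair sets: a brute-force
# all-pairs kernel (reference, and default for small selections) and a
# cell-list kernel with cell edge equal to the cutoff (default for larger
# selections). Both compare squared distances computed with the same
# expression, so their results are bitwise identical.

.pair_dist2 <- function(A, B) {
  # squared distances, |A| x |B|; A, B are n x 3 coordinate matrices
  outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
}

.contacts_brute <- function(A, B, cutoff) {
  hits <- which(.pair_dist2(A, B) < cutoff^2, arr.ind = TRUE)
  hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
}

.contacts_cell <- function(A, B, cutoff) {
  ca <- floor(A / cutoff); cb <- floor(B / cutoff)
  keyb <- paste(cb[, 1], cb[, 2], cb[, 3])
  bmap <- split(seq_len(nrow(B)), keyb)
  keya <- paste(ca[, 1], ca[, 2], ca[, 3])
  amap <- split(seq_len(nrow(A)), keya)
  acells <- do.call(rbind, strsplit(names(amap), " "))
  storage.mode(acells) <- "integer"
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  out <- vector("list", length(amap))
  for (k in seq_along(amap)) {
    nb <- sweep(offs, 2, acells[k, ], "+")
    cand <- unlist(bmap[paste(nb[, 1], nb[, 2], nb[, 3])], use.names = FALSE)
    if (is.null(cand) || !length(cand)) next
    ai <- amap[[k]]
    hits <- which(.pair_dist2(A[ai, , drop = FALSE], B[cand, , drop = FALSE])
                  < cutoff^2, arr.ind = TRUE)
    if (nrow(hits))
      out[[k]] <- cbind(ai[hits[, 1]], cand[hits[, 2]])
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- matrix(integer(0), ncol = 2L)
  colnames(res) <- c("row", "col")
  res[order(res[, 1], res[, 2]), , drop = FALSE]
}

#' Detect inter-selection heavy-atom contacts per frame
#'
#' For every frame, finds all heavy-atom pairs (one atom from each selection)
#' strictly closer than `cutoff` Angstrom, and the deduplicated projection of
#' those atom pairs onto residue pairs.
#'
#' @param ensemble A `StructureEnsemble`.
#' @param selection_a,selection_b Disjoint `AtomSelection`s (e.g. the two
#'   chains of a complex). Hydrogens in either selection are ignored.
#' @param cutoff Contact cutoff in Angstrom (default 3.3, i.e. 0.33 nm).
#' @param kernel `"auto"` (cell list for > 500 atoms in play, else brute
#'   force), `"brute"`, or `"cell"`.
#' @return A `ContactSeries`: per-frame atom-pair matrices (columns `atom_a`,
#'   `atom_b`, 1-based topology indices) and residue-pair data frames
#'   (`chain_a`, `residue_a`, `chain_b`, `residue_b`), plus `cutoff`,
#'   `frame_ids` and the residue universe of the topology.
#' @export
detect_contacts <- function(ensemble, selection_a, selection_b, cutoff = 3.3,
                            kernel = c("auto", "brute", "cell")) {
  kernel <- match.arg(kernel)
  stopifnot(inherits(ensemble, "StructureEnsemble"))
  if (cutoff <= 0) stop("cutoff must be > 0")
  top <- ensemble$topology
  ia <- selection_a$atom_indices; ib <- selection_b$atom_indices
  if (!length(ia) || !length(ib)) stop("empty selection")
  if (length(intersect(ia, ib))) stop("selections must be disjoint")
  ia <- ia[top$is_heavy[ia]]; ib <- ib[top$is_heavy[ib]]
  if (!length(ia) || !length(ib)) stop("selection contains no heavy atoms")
  use_cell <- switch(kernel, brute = FALSE, cell = TRUE,
                     auto = length(ia) + length(ib) > 500L)
  nf <- n_frames(ensemble)
  atom_pairs <- vector("list", nf)
  residue_pairs <- vector("list", nf)
  for (f in seq_len(nf)) {
    A <- matrix(ensemble$coords[ia, , f], ncol = 3L)
    B <- matrix(ensemble$coords[ib, , f], ncol = 3L)
    hits <- if (use_cell) .contacts_cell(A, B, cutoff) else .contacts_brute(A, B, cutoff)
    ap <- cbind(atom_a = ia[hits[, 1]], atom_b = ib[hits[, 2]])
    atom_pairs[[f]] <- ap
    rp <- unique(data.frame(
      chain_a = top$chain_id[ap[, 1]], residue_a = top$residue_number[ap[, 1]],
      chain_b = top$chain_id[ap[, 2]], residue_b = top$residue_number[ap[, 2]],
      stringsAsFactors = FALSE
    ))
    residue_pairs[[f]] <- rp[order(rp$residue_a, rp$residue_b), , drop = FALSE]
  }
  structure(
    list(atom_pairs = atom_pairs, residue_pairs = residue_pairs,
         cutoff = cutoff, frame_ids = ensemble$frame_ids,
         label_a = selection_a$label, label_b = selection_b$label,
         residue_universe = unique(top[, c("chain_id", "residue_number")])),
    class = "ContactSeries"
  )
}

#' @export
print.ContactSeries <- function(x, ...) {
  n_contact <- vapply(x$atom_pairs, nrow, integer(1))
  cat(sprintf("ContactSeries %s | %s (< %.2f A): %d frames, %d with contacts\n",
              x$label_a, x$label_b, x$cutoff, length(n_contact),
              sum(n_contact > 0)))
  invisible(x)
}

.frame_filter <- function(keep, rule) {
  structure(list(keep = keep, rule = rule, n_kept = sum(keep)),
            class = "FrameFilter")
}

#' @export
print.FrameFilter <- function(x, ...) {
  cat(sprintf("FrameFilter [%s]: %d of %d frames kept\n",
              x$rule, x$n_kept, length(x$keep)))
  invisible(x)
}

#' Keep frames with at least one inter-chain contact
#'
#' The ensemble-filtering rule that discards structures without any contact
#' within the cutoff, applied before clustering.
#'
#' @param series A `ContactSeries`.
#' @return A `FrameFilter` (logical `keep` per frame, `rule`, `n_kept`).
#' @export
filter_frames_any_contact <- function(series) {
  stopifnot(inherits(series, "ContactSeries"))
  keep <- vapply(series$atom_pairs, nrow, integer(1)) > 0L
  .frame_filter(keep, sprintf("any contact < %.2f A", series$cutoff))
}

#' Keep frames contacting a specific residue site
#'
#' Restricts to frames with at least one residue-pair contact touching the
#' given site residues (e.g. the allosteric-pocket residues used for
#' mutagenesis, 169/215/221/222/224/333 on the enzyme chain). Either end of a
#' residue pair may match.
#'
#' @param series A `ContactSeries`.
#' @param site_residues Data frame with columns `chain_id` and
#'   `residue_number`, or an integer vector of residue numbers combined with
#'   `chain`.
#' @param chain Chain id used when `site_residues` is a plain vector.
#' @return A `FrameFilter`.
#' @export
filter_frames_site_contact <- function(series, site_residues, chain = NULL) {
  stopifnot(inherits(series, "ContactSeries"))
  if (!is.data.frame(site_residues)) {
    if (is.null(chain)) stop("give site_residues as data frame or supply chain")
    site_residues <- data.frame(chain_id = chain,
                                residue_number = as.integer(site_residues))
  }
  if (nrow(site_residues) == 0L) stop("site_residues must be non-empty")
  site_key <- paste(site_residues$chain_id, site_residues$residue_number)
  known <- paste(series$residue_universe$chain_id,
                 series$residue_universe$residue_number)
  if (!all(site_key %in% known))
    stop("site residues absent from topology: ",
         paste(setdiff(site_key, known), collapse = ", "))
  keep <- vapply(series$residue_pairs, function(rp) {
    if (nrow(rp) == 0L) return(FALSE)
    any(paste(rp$chain_a, rp$residue_a) %in% site_key |
          paste(rp$chain_b, rp$residue_b) %in% site_key)
  }, logical(1))
  .frame_filter(keep, sprintf("contact with site {%s}",
                              paste(site_key, collapse = ",")))
}

#' Combine frame filters by logical AND
#'
#' @param ... `FrameFilter` objects over the same frame set.
#' @return A `FrameFilter` keeping frames kept by every input filter.
#' @export
combine_filters <- function(...) {
  fl <- list(...)
  stopifnot(length(fl) >= 1L)
  keep <- Reduce(`&`, lapply(fl, `[[`, "keep"))
  .frame_filter(keep, paste(vapply(fl, `[[`, character(1), "rule"),
                            collapse = " AND "))
}

#' Apply a frame filter to an ensemble or contact series
#'
#' @param x A `StructureEnsemble` or `ContactSeries`.
#' @param filter A `FrameFilter` whose length matches the frame count.
#' @return Object of the same class restricted to kept frames.
#' @export
apply_filter <- function(x, filter) {
  stopifnot(inherits(filter, "FrameFilter"))
  if (filter$n_kept == 0L) stop("filter keeps zero frames")
  if (inherits(x, "StructureEnsemble")) {
    if (length(filter$keep) != n_frames(x)) stop("filter length mismatch")
    structure_ensemble(x$topology,
                       x$coords[, , filter$keep, drop = FALSE],
                       x$frame_ids[filter$keep])
  } else if (inherits(x, "ContactSeries")) {
    if (length(filter$keep) != length(x$frame_ids)) stop("filter length mismatch")
    x$atom_pairs <- x$atom_pairs[filter$keep]
    x$residue_pairs <- x$residue_pairs[filter$keep]
    x$frame_ids <- x$frame_ids[filter$keep]
    x
  } else stop("unsupported object for apply_filter")
}

#' Frame-normalised residue contact statistics
#'
#' Per residue: the number of residue-pair contacts involving that residue,
#' summed over frames and divided by the number of frames (the average
#' contact count per frame; values above 1 mean the residue binds several
#' partner residues at a time). Per residue pair: the fraction of frames in
#' which the pair is in contact.
#'
#' @param series A `ContactSeries`.
#' @return A `ContactStatistics`: list with `residues` (chain,
#'   residue_number, mean_contacts), `pairs` (chain_a, residue_a, chain_b,
#'   residue_b, contact_fraction) and `n_frames`.
#' @export
residue_contact_statistics <- function(series) {
  stopifnot(inherits(series, "ContactSeries"))
  nf <- length(series$frame_ids)
  if (nf < 1L) stop("contact series covers no frames")
  all_pairs <- do.call(rbind, series$residue_pairs)
  if (is.null(all_pairs) || nrow(all_pairs) == 0L) {
    pairs <- data.frame(chain_a = character(0), residue_a = integer(0),
                        chain_b = character(0), residue_b = integer(0),
                        contact_fraction = numeric(0))
    residues <- data.frame(chain = character(0), residue_number = integer(0),
                           mean_contacts = numeric(0))
  } else {
    key <- paste(all_pairs$chain_a, all_pairs$residue_a,
                 all_pairs$chain_b, all_pairs$residue_b, sep = "|")
    tab <- table(key)
    split_key <- do.call(rbind, strsplit(names(tab), "|", fixed = TRUE))
    pairs <- data.frame(
      chain_a = split_key[, 1], residue_a = as.integer(split_key[, 2]),
      chain_b = split_key[, 3], residue_b = as.integer(split_key[, 4]),
      contact_fraction = as.numeric(tab) / nf,
      stringsAsFactors = FALSE
    )
    pairs <- pairs[order(-pairs$contact_fraction, pairs$residue_a, pairs$residue_b), ]
    rownames(pairs) <- NULL
    ends <- rbind(
      data.frame(chain = all_pairs$chain_a, residue_number = all_pairs$residue_a),
      data.frame(chain = all_pairs$chain_b, residue_number = all_pairs$residue_b)
    )
    rkey <- paste(ends$chain, ends$residue_number, sep = "|")
    rtab <- table(rkey)
    rsplit <- do.call(rbind, strsplit(names(rtab), "|", fixed = TRUE))
    residues <- data.frame(
      chain = rsplit[, 1], residue_number = as.integer(rsplit[, 2]),
      mean_contacts = as.numeric(rtab) / nf,
      stringsAsFactors = FALSE
    )
    residues <- residues[order(residues$chain, residues$residue_number), ]
    rownames(residues) <- NULL
  }
  structure(list(residues = residues, pairs = pairs, n_frames = nf),
            class = "ContactStatistics")
}

#' @export
print.ContactStatistics <- function(x, ...) {
  cat(sprintf("ContactStatistics over %d frames: %d residues, %d residue pairs\n",
              x$n_frames, nrow(x$residues), nrow(x$pairs)))
  invisible(x)
}

#' Export contact statistics as network tables
#'
#' Writes an edge list (chain_a, residue_a, chain_b, residue_b,
#' contact_fraction; sorted by descending fraction, ties by residue numbers
#' ascending) to `path` and a node table (chain, residue_number,
#' mean_contacts) alongside it (suffix `_nodes`). Both are tab-delimited with
#' headers, directly loadable into network tools.
#'
#' @param stats A `ContactStatistics`.
#' @param path Output path for the edge table.
#' @return Invisible character vector: edge path and node path.
#' @export
export_contact_network <- function(stats, path) {
  stopifnot(inherits(stats, "ContactStatistics"))
  node_path <- sub("(\\.[A-Za-z0-9]+)?$", "_nodes\\1", path)
  if (identical(node_path, path)) node_path <- paste0(path, "_nodes")
  utils::write.table(stats$pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(stats$residues, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(edges = path, nodes = node_path))
}
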