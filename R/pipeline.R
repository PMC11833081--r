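# End-to-end pipeline: ingest/simulate -> states -> contact filters ->
# ccPCA -> landscape -> OPTICS clusters -> cross-condition comparison,
# driven by a single YAML config. Every output table carries a comment
# header naming the producing stage, its parameters and the seed; outputs
# contain no timestamps, so identical config + seed reruns are byte-identical.

.default_config <- function() {
  list(
    threshold = 16.5,     # closed-state COM threshold, Angstrom
    cutoff = 3.3,         # heavy-atom contact cutoff, Angstrom (0.33 nm)
    temperature = 300,    # K, for Boltzmann inversion
    bins = 100L,
    mesh = list(cap = NULL, seed = 1L),
    optics = list(min_samples = NULL, xi = 0.05),
    seed = 1L,
    conditions = list(
      reference = list(type = "two_state", role = "reference",
                       n_frames = 1500L, f_open = 0.2),
      allosteric = list(type = "binding", role = "case",
                       n_frames = 1500L, f_open = 0.2, couple_loop = TRUE,
                       f_open_bound = 0.63)
    )
  )
}

.merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]) && nm != "conditions")
      base[[nm]] <- .merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Load a pipeline run configuration
#'
#' Reads a YAML config (or takes a list) and fills every unset key with the
#' package defaults: state threshold 16.5 A, contact cutoff 3.3 A, T = 300 K,
#' 100x100 landscape bins, OPTICS xi = 0.05 with min_samples =
#' max(10, 1% of frames). `conditions` is a named list; each condition has a
#' `type` (`two_state`, `binding`, or `pdb` with `path` and group
#' definitions), a `role` (`case` or `reference`), and any
#' [synthetic_spec()] fields to override.
#'
#' @param config Path to a YAML file, or a list.
#' @return Resolved config list.
#' @export
load_run_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  cfg <- .merge_config(.default_config(), config)
  if (length(config$conditions)) cfg$conditions <- config$conditions
  for (nm in names(cfg$conditions)) {
    cond <- cfg$conditions[[nm]]
    if (is.null(cond$type)) stop("condition '", nm, "' lacks a type")
    if (is.null(cond$role))
      cfg$conditions[[nm]]$role <- if (cond$type == "two_state") "reference" else "case"
  }
  cfg
}

.write_table <- function(df, path, stage, params, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# stage: %s", stage),
               sprintf("# parameters: %s", params),
               sprintf("# seed: %d", seed)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

.run_condition <- function(name, cond, cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cond$seed %||% cfg$seed)
  if (cond$type %in% c("two_state", "binding")) {
    spec_args <- cond[setdiff(names(cond), c("type", "role", "groups", "path"))]
    spec_args$seed <- seed
    spec <- do.call(synthetic_spec, spec_args)
    gen <- if (cond$type == "binding") generate_binding_ensemble(spec)
           else generate_two_state_enzyme(spec)
    ens <- gen$ensemble; groups <- gen$groups
    utils::write.table(gen$ground_truth, file.path(out_dir, "ground_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (cond$type == "pdb") {
    if (is.null(cond$path)) stop("ingest: condition '", name, "' needs a path")
    ens <- read_multimodel_pdb(cond$path)
    groups <- cond$groups
    if (is.null(groups))
      stop("ingest: condition '", name, "' needs group definitions")
    groups$loop <- parse_residue_spec(groups$loop)
    groups$active_site <- parse_residue_spec(groups$active_site)
    if (!is.null(groups$pocket)) groups$pocket <- parse_residue_spec(groups$pocket)
  } else stop("ingest: unknown condition type '", cond$type, "'")

  loop_sel <- select_atoms(ens$topology, groups$chain, groups$loop,
                           label = "loop")
  site_sel <- select_atoms(ens$topology, groups$chain, groups$active_site,
                           label = "active_site")
  trace <- com_distance_trace(ens, loop_sel, site_sel)
  states <- classify_states(trace, cfg$threshold)
  .write_table(
    data.frame(frame_id = trace$frame_ids,
               distance_angstrom = round(trace$values, 4),
               state = as.character(states$labels)),
    file.path(out_dir, "states.tsv"), "states",
    sprintf("threshold=%g A", cfg$threshold), seed)
  scan <- threshold_scan(trace)
  .write_table(
    data.frame(threshold_angstrom = scan$threshold,
               closed_fraction = scan$closed_fraction,
               open_fraction = scan$open_fraction),
    file.path(out_dir, "scan.tsv"), "scan", "grid=12-24 A by 0.1", seed)

  res <- list(name = name, role = cond$role, n_input = n_frames(ens),
              trace = trace, states = states,
              open_fraction = states$fraction_open,
              n_kept = n_frames(ens), n_clustered = NA_integer_,
              n_clusters = NA_integer_)

  has_ligand <- !is.null(groups$ligand_chain) &&
    groups$ligand_chain %in% ens$topology$chain_id
  if (has_ligand) {
    sel_e <- select_atoms(ens$topology, groups$chain,
                          unique(ens$topology$residue_number[
                            ens$topology$chain_id == groups$chain]),
                          label = "enzyme")
    sel_l <- select_atoms(ens$topology, groups$ligand_chain,
                          unique(ens$topology$residue_number[
                            ens$topology$chain_id == groups$ligand_chain]),
                          label = "ligand")
    contacts <- detect_contacts(ens, sel_e, sel_l, cutoff = cfg$cutoff)
    filt <- filter_frames_any_contact(contacts)
    if (!is.null(groups$pocket)) {
      site_filt <- filter_frames_site_contact(contacts, groups$pocket,
                                              chain = groups$chain)
      filt <- combine_filters(filt, site_filt)
    }
    if (filt$n_kept == 0L) stop("filter: no frames retain inter-chain contacts")
    kept <- apply_filter(contacts, filt)
    stats <- residue_contact_statistics(kept)
    export_contact_network(stats, file.path(out_dir, "contact_network.tsv"))

    mesh <- build_contact_mesh(ens$topology, groups$chain, groups$ligand_chain,
                               cap = cfg$mesh$cap, seed = as.integer(cfg$mesh$seed))
    feats <- compute_features(ens, mesh, filt)
    pca <- fit_pca(feats, n_components = 2L)
    landscape <- free_energy_landscape(pca$scores, bins = cfg$bins,
                                       temperature = cfg$temperature)
    .write_table(landscape_table(landscape),
                 file.path(out_dir, "landscape.tsv"), "landscape",
                 sprintf("bins=%d T=%g K R=%.12g", cfg$bins, cfg$temperature,
                         GAS_CONSTANT_KJ), seed)
    clus <- cluster_scores(pca$scores,
                           min_samples = cfg$optics$min_samples,
                           xi = cfg$optics$xi)
    kept_pos <- which(filt$keep)
    .write_table(
      data.frame(frame_id = feats$frame_ids,
                 pc1 = round(pca$scores[, 1], 6),
                 pc2 = round(pca$scores[, 2], 6),
                 cluster = clus$labels),
      file.path(out_dir, "ccpca_scores.tsv"), "ccpca",
      sprintf("m=%d pairs=%d min_samples=%d xi=%g", length(mesh$mesh_a),
              nrow(mesh$pair_list), clus$optics_min_samples, clus$optics_xi),
      seed)
    kept_trace <- trace
    kept_trace$values <- trace$values[kept_pos]
    kept_trace$frame_ids <- trace$frame_ids[kept_pos]
    summary <- cluster_state_summary(clus, kept_trace, cfg$threshold)
    .write_table(as.data.frame(summary), file.path(out_dir, "clusters.tsv"),
                 "clusters", sprintf("threshold=%g A", cfg$threshold), seed)
    if (nrow(clus$clusters) > 0L) {
      rep_frames <- kept_pos[clus$clusters$representative]
      write_multimodel_pdb(ens, file.path(out_dir, "representatives.pdb"),
                           frame_subset = rep_frames)
    }
    res$n_kept <- filt$n_kept
    res$n_clustered <- sum(clus$labels != -1L)
    res$n_clusters <- nrow(clus$clusters)
    res$cluster_summary <- summary
    # open fraction over filtered frames (the condition's reported number)
    res$open_fraction <- mean(kept_trace$values > cfg$threshold)
  }
  res
}

#' Run the full analysis pipeline
#'
#' Executes every stage over all configured conditions and writes per-stage
#' tables, a cross-condition comparison, a plain-text run report and the
#' resolved config into `out_dir`. On a stage error, partial outputs are
#' kept, a `FAILED` marker file naming the stage is written, and the error
#' is re-thrown.
#'
#' @param config Config list or YAML path (see [load_run_config()]).
#' @param out_dir Output directory (created if needed).
#' @param seed Optional integer overriding the config seed.
#' @return Run report list: per-condition frame counts and open fractions,
#'   fold change, comparison result, output paths. Invisibly.
#' @export
run_pipeline <- function(config = list(), out_dir, seed = NULL) {
  cfg <- load_run_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "config"
  results <- tryCatch({
    yaml::write_yaml(cfg, file.path(out_dir, "resolved_config.yaml"))
    out <- list()
    for (nm in names(cfg$conditions)) {
      stage <- paste0(if (cfg$conditions[[nm]]$type == "pdb") "ingest" else "simulate",
                      ":", nm)
      message("[loopscape] running condition '", nm, "'")
      out[[nm]] <- .run_condition(nm, cfg$conditions[[nm]], cfg,
                                  file.path(out_dir, nm))
    }
    out
  }, error = function(e) {
    writeLines(paste0("stage ", stage, " failed: ", conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })

  roles <- vapply(results, `[[`, character(1), "role")
  fold <- NA_real_
  comparison <- NULL
  if (any(roles == "case") && any(roles == "reference")) {
    fold <- open_fraction_fold_change(
      vapply(results[roles == "case"], `[[`, numeric(1), "open_fraction"),
      vapply(results[roles == "reference"], `[[`, numeric(1), "open_fraction"))
  }
  if (length(results) >= 2L) {
    comparison <- compare_groups(lapply(results, function(r) r$trace$values))
    .write_table(comparison$pairwise, file.path(out_dir, "compare.tsv"),
                 "compare",
                 sprintf("anova F=%.6g p=%.6g", comparison$f_statistic,
                         comparison$p_value),
                 as.integer(cfg$seed))
  }

  report <- c(
    "loopscape run report",
    sprintf("seed: %d", as.integer(cfg$seed)),
    sprintf("threshold: %g A | cutoff: %g A | T: %g K | bins: %d",
            cfg$threshold, cfg$cutoff, cfg$temperature, cfg$bins),
    "",
    sprintf("%-14s %-10s %8s %8s %10s %9s %12s",
            "condition", "role", "frames", "kept", "clustered", "clusters",
            "open_frac"),
    vapply(results, function(r) {
      sprintf("%-14s %-10s %8d %8d %10s %9s %12.4f",
              r$name, r$role, r$n_input, r$n_kept,
              ifelse(is.na(r$n_clustered), "-", as.character(r$n_clustered)),
              ifelse(is.na(r$n_clusters), "-", as.character(r$n_clusters)),
              r$open_fraction)
    }, character(1)),
    "",
    if (!is.na(fold)) sprintf("open-state fold change (case / reference): %.4f", fold)
    else "open-state fold change: n/a (need case and reference conditions)",
    if (!is.null(comparison))
      sprintf("one-way ANOVA across conditions: F(%d, %d) = %.6g, p = %.6g",
              comparison$df_between, comparison$df_within,
              comparison$f_statistic, comparison$p_value)
    else NULL
  )
  writeLines(report, file.path(out_dir, "report.txt"))
  invisible(list(conditions = results, fold_change = fold,
                 comparison = comparison, out_dir = out_dir,
                 report = report))
}
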