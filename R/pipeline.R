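#' Pipeline configuration
#'
#' One document holding every protocol constant: agreement and redundancy
#' thresholds (2 Angstrom), the seed search geometry (18 Angstrom sphere,
#' 32 Angstrom cube), the flexible-residue budget (10), the per-compound
#' carry-forward (top 5), the cluster cutoff, metric orientations, the
#' anchor residue and the mutated-residue list. Values can be loaded from
#' a YAML/JSON file and individually overridden.
#'
#' @param ... overrides of the defaults (see Details in the docs).
#' @param file optional YAML or JSON config file; `...` overrides it.
#' @return a named list of class `condock_config`.
#' @export
run_config <- function(..., file = NULL) {
  defaults <- list(
    match_threshold = 2.0,
    redundancy_rmsd = 2.0,
    max_pairs = 20,
    sphere_radius = 18,
    box_edge = 32,
    n_flexible = 10,
    top_k = 5,
    cluster_cutoff = 2.0,
    cluster_linkage = "complete",
    min_mode_population = 2,
    anchor = NULL,
    anchor_atom = "CG2",
    mutated = integer(),
    region_pad = 0,
    seed = 7,
    metrics = list(vina = "lower_better", goldscore = "higher_better",
                   chemplp = "higher_better")
  )
  cfg <- defaults
  if (!is.null(file)) {
    loaded <- if (grepl("\\.json$", file, ignore.case = TRUE)) {
      jsonlite::read_json(file, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(file)
    }
    cfg[names(loaded)] <- loaded
  }
  overrides <- list(...)
  cfg[names(overrides)] <- overrides
  stopifnot(cfg$match_threshold > 0, cfg$redundancy_rmsd > 0,
            cfg$cluster_cutoff > 0, cfg$top_k >= 1)
  structure(cfg, class = "condock_config")
}

config_metrics <- function(cfg) {
  do.call(metric_specs, as.list(cfg$metrics))
}

#' Run the consensus docking analysis end-to-end
#'
#' Wires the whole protocol for one or more ligands, each supplied as a
#' pair of pose sets from two engines plus a score table:
#'
#' 1. *match* — cross-engine agreement filter at the RMSD threshold;
#' 2. *rank* — Borda aggregation of the three scoring metrics over the
#'    matched pairs (engine-native metrics read from each pair's own
#'    engine poses);
#' 3. *dedup* — greedy redundancy removal in Borda order, capped;
#' 4. *top-k* — per-ligand carry-forward;
#' 5. *cluster* — hierarchical RMSD clustering of the carried-forward
#'    engine-A poses across all ligands, and consensus-mode calling.
#'
#' Every stage's output is returned (and optionally serialized) so any
#' stage can be audited or re-run in isolation; per-stage pose counts are
#' logged.
#'
#' @param ligands named list; each element is
#'   `list(set_a =, set_b =, scores =)` with pose-set tibbles and a score
#'   table as from [read_score_table()].
#' @param config a [run_config()].
#' @param out_dir optional directory: stage outputs are written as
#'   TSV/JSON/PDB with a manifest.
#' @param quiet suppress stage logging.
#' @return list with `pairs`, `ranked`, `deduplicated`, `top`,
#'   (per-ligand lists), `clusters`, `modes`, `region`, `counts`,
#'   `status`.
#' @export
run_pipeline <- function(ligands, config = run_config(), out_dir = NULL,
                         quiet = FALSE) {
  log_stage <- function(...) if (!quiet) inform(paste0("[condock] ", ...))
  metrics <- config_metrics(config)
  stages <- list()

  per_ligand <- map(names(ligands), function(lid) {
    inp <- ligands[[lid]]
    pairs <- match_poses(inp$set_a, inp$set_b,
                         threshold = config$match_threshold)
    log_stage("match ", lid, ": ",
              nrow(inp$set_a) * nrow(inp$set_b), " cross pairs -> ",
              nrow(pairs), " within ", config$match_threshold, " A")
    if (nrow(pairs) == 0) {
      return(list(pairs = pairs, ranked = NULL, dedup = pairs, top = pairs))
    }
    scored <- attach_pair_scores(pairs, inp$scores, inp$set_a$engine[1],
                                 inp$set_b$engine[1], metrics)
    ranked <- borda_rank(scored, metrics)
    dedup <- deduplicate_pairs(
      ranked, order = order(ranked$final_rank, na.last = NA),
      max_pairs = config$max_pairs,
      redundancy_rmsd = config$redundancy_rmsd)
    log_stage("dedup ", lid, ": ", nrow(ranked), " -> ", nrow(dedup),
              " pairs (cap ", config$max_pairs, ")")
    top <- top_k(dedup, config$top_k)
    list(pairs = pairs, ranked = ranked, dedup = dedup, top = top)
  })
  names(per_ligand) <- names(ligands)

  all_pairs <- bind_rows(map(per_ligand, function(x) {
    if (nrow(x$pairs)) x$pairs[c("ligand_id", "idx_a", "idx_b", "rmsd")]
    else NULL
  }))
  region <- if (nrow(all_pairs)) {
    pr <- bind_rows(map(per_ligand, function(x) {
      as_tibble(x$pairs)[c("atoms_a", "atoms_b")]
    }))
    pr$ligand_id <- "all"
    derive_region(pr, pad = config$region_pad)
  } else NULL

  top_all <- bind_rows(map(per_ligand, function(x) {
    if (!is.null(x$top) && nrow(x$top)) as_tibble(x$top) else NULL
  }))
  if (nrow(top_all) >= 2) {
    # cluster on the engine-A member of each carried-forward pair
    cluster_input <- tibble(
      ligand_id = top_all$ligand_id,
      engine = "engine_A",
      pose_index = top_all$idx_a,
      atoms = top_all$atoms_a,
      final_rank = top_all$final_rank
    )
    clusters <- cluster_poses(cluster_input,
                              linkage = config$cluster_linkage,
                              cutoff = config$cluster_cutoff)
    modes <- consensus_modes(clusters,
                             min_population = config$min_mode_population)
    status <- if (nrow(modes)) "consensus" else "no consensus"
  } else {
    clusters <- NULL
    modes <- consensus_modes_empty()
    status <- "no consensus"
  }
  log_stage("cluster: ", nrow(top_all), " poses -> ",
            if (is.null(clusters)) 0 else length(clusters$populations),
            " cluster(s), ", nrow(modes), " mode(s); status: ", status)

  counts <- tibble(
    ligand_id = names(per_ligand),
    n_pairs = unname(map_int(per_ligand, function(x) nrow(x$pairs))),
    n_dedup = unname(map_int(per_ligand, function(x) nrow(x$dedup))),
    n_top = unname(map_int(per_ligand, function(x) {
      if (is.null(x$top)) 0L else nrow(x$top)
    }))
  )

  result <- list(per_ligand = per_ligand, region = region,
                 clusters = clusters, modes = modes, counts = counts,
                 status = status)
  if (!is.null(out_dir)) write_run_artifacts(result, out_dir, config)
  result
}

consensus_modes_empty <- function() {
  tibble(mode = integer(), cluster = integer(), population = integer(),
         mean_rank = numeric(), ligands = list(),
         representative = integer(), center = list())
}

#' Attach per-pose scores to matched pairs
#'
#' Joins a score table onto a matched-pair tibble so the pairs can be
#' Borda-ranked: each metric is read from its *native* engine's pose of
#' the pair (fitness scores from the engine-A pose via `idx_a`,
#' energy-like scores from the engine-B pose via `idx_b`). A metric is
#' considered native to engine A when the table carries non-missing
#' values for it on engine-A rows.
#'
#' @param pairs matched-pair tibble from [match_poses()].
#' @param scores score table as from [read_score_table()].
#' @param engine_a,engine_b engine labels used in `scores$engine`.
#' @param metrics a [metric_specs()] tibble.
#' @return `pairs` with one added column per metric.
#' @export
attach_pair_scores <- function(pairs, scores, engine_a, engine_b,
                               metrics = metric_specs()) {
  a_scores <- scores[scores$engine == engine_a, , drop = FALSE]
  b_scores <- scores[scores$engine == engine_b, , drop = FALSE]
  out <- pairs
  for (m in metrics$name) {
    from_a <- m %in% names(a_scores) && any(!is.na(a_scores[[m]]))
    src <- if (from_a) a_scores else b_scores
    idx <- if (from_a) pairs$idx_a else pairs$idx_b
    out[[m]] <- src[[m]][match(idx, src$pose_index)]
  }
  out
}

write_run_artifacts <- function(result, out_dir, config) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = unclass(config), files = list())
  add <- function(name, path) {
    manifest$files[[name]] <<- basename(path)
  }
  for (lid in names(result$per_ligand)) {
    x <- result$per_ligand[[lid]]
    p <- file.path(out_dir, paste0("pairs_", lid, ".tsv"))
    readr::write_tsv(as_tibble(x$pairs)[
      c("ligand_id", "idx_a", "idx_b", "rmsd")], p)
    add(paste0("pairs_", lid), p)
    if (!is.null(x$ranked)) {
      p <- file.path(out_dir, paste0("borda_", lid, ".tsv"))
      readr::write_tsv(tidy(x$ranked), p)
      add(paste0("borda_", lid), p)
    }
  }
  if (!is.null(result$region)) {
    p <- file.path(out_dir, "region.json")
    jsonlite::write_json(result$region[c("center", "sphere_radius",
                                         "box_edges")],
                         p, auto_unbox = FALSE, digits = NA)
    add("region", p)
  }
  if (!is.null(result$clusters)) {
    p <- file.path(out_dir, "clusters.tsv")
    readr::write_tsv(tidy(result$clusters), p)
    add("clusters", p)
    reps <- result$clusters$poses$atoms[result$clusters$representatives]
    p <- file.path(out_dir, "representatives.pdb")
    write_poses_pdb(reps, p)
    add("representatives", p)
  }
  p <- file.path(out_dir, "modes.json")
  modes <- result$modes
  modes$center <- map(modes$center, as.numeric)
  jsonlite::write_json(
    list(status = result$status,
         modes = modes[c("mode", "cluster", "population", "mean_rank",
                         "ligands", "representative", "center")]),
    p, auto_unbox = TRUE, digits = NA, na = "null")
  add("modes", p)
  p <- file.path(out_dir, "counts.tsv")
  readr::write_tsv(result$counts, p)
  add("counts", p)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
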