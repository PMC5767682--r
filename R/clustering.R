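#' Hierarchical RMSD clustering of docked poses
#'
#' Agglomerative clustering of poses — typically the top-ranked engine-A
#' poses of every compound in a chemical series — on the pairwise
#' Hungarian RMSD matrix, cut at a distance cutoff. Clusters of poses
#' from multiple compounds mark binding modes predicted consistently
#' across the series; the most populated ones are read as the most
#' probable binding site.
#'
#' When the poses are different molecules, distances use the relaxed
#' (element-free, rectangular) assignment mode automatically.
#'
#' @param poses pose-set tibble (rows may mix ligands); an optional
#'   `final_rank` column (e.g. carried over from [borda_rank()]) selects
#'   cluster representatives.
#' @param linkage `"complete"` (default), `"average"` or `"single"`.
#' @param cutoff tree cut height, Angstrom (default 2, the protocol's
#'   single distance scale).
#' @param mode distance mode passed to [pairwise_rmsd_matrix()];
#'   `"auto"` picks `"relaxed"` iff heavy-atom element multisets differ.
#' @return a `condock_clusters` object: list with `labels` (per-pose
#'   cluster id), `populations`, `representatives` (pose-set row indices),
#'   `hclust` (the merge tree), `poses`, `dist`; supports
#'   [tidy()]/[glance()]/[autoplot()].
#' @export
cluster_poses <- function(poses, linkage = c("complete", "average", "single"),
                          cutoff = 2.0,
                          mode = c("auto", "same_element", "relaxed")) {
  linkage <- match.arg(linkage)
  mode <- match.arg(mode)
  poses <- as_tibble(poses)
  n <- nrow(poses)
  if (n < 2) {
    warn("fewer than 2 poses: returning a single trivial cluster")
    return(new_clusters(labels = rep(1L, n), poses = poses, hc = NULL,
                        d = matrix(0, n, n)))
  }
  if (mode == "auto") {
    multisets <- map_chr(poses$atoms, function(a) {
      paste(sort(heavy_atoms(a)$element), collapse = "")
    })
    mode <- if (length(unique(multisets)) > 1) "relaxed" else "same_element"
  }
  d <- pairwise_rmsd_matrix(poses, mode = mode)
  hc <- hclust(as.dist(d), method = linkage)
  raw <- cutree(hc, h = cutoff)
  # relabel so cluster ids are ordered by population (desc), then by the
  # first member's position — deterministic under fixed input order
  sizes <- table(raw)
  ord <- order(-as.integer(sizes), map_int(names(sizes), function(l) {
    which(raw == as.integer(l))[1]
  }))
  relabel <- setNames(seq_along(ord), names(sizes)[ord])
  labels <- as.integer(relabel[as.character(raw)])
  new_clusters(labels, poses, hc, d)
}

new_clusters <- function(labels, poses, hc, d) {
  populations <- as.integer(table(factor(labels, levels = seq_len(max(labels, 1)))))
  reps <- map_int(seq_along(populations), function(cl) {
    members <- which(labels == cl)
    if (length(members) == 1) return(members)
    if ("final_rank" %in% names(poses) &&
        !all(is.na(poses$final_rank[members]))) {
      best <- min(poses$final_rank[members], na.rm = TRUE)
      cand <- members[which(poses$final_rank[members] == best)]
    } else {
      cand <- members
    }
    if (length(cand) > 1) {
      # tie: lowest mean RMSD to the other cluster members (medoid-like)
      mean_d <- map_dbl(cand, function(i) mean(d[i, setdiff(members, i)]))
      cand <- cand[which.min(mean_d)]
    }
    cand[1]
  })
  structure(list(labels = labels, populations = populations,
                 representatives = reps, hclust = hc, poses = poses,
                 dist = d),
            class = "condock_clusters")
}

#' @export
print.condock_clusters <- function(x, ...) {
  cat("<pose clusters> ", length(x$labels), " poses in ",
      length(x$populations), " cluster(s); populations: ",
      paste(x$populations, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.condock_clusters <- function(x, ...) {
  out <- tibble(
    pose = seq_along(x$labels),
    cluster = x$labels,
    is_representative = seq_along(x$labels) %in% x$representatives
  )
  for (col in intersect(c("ligand_id", "engine", "pose_index", "final_rank"),
                        names(x$poses))) {
    out[[col]] <- x$poses[[col]]
  }
  out
}

#' @export
glance.condock_clusters <- function(x, ...) {
  tibble(n_poses = length(x$labels),
         n_clusters = length(x$populations),
         max_population = max(x$populations),
         n_singletons = sum(x$populations == 1L))
}

#' @export
autoplot.condock_clusters <- function(object, ...) {
  df <- tibble(cluster = factor(seq_along(object$populations)),
               population = object$populations)
  ggplot(df, aes(x = .data$cluster, y = .data$population)) +
    geom_col(fill = "steelblue") +
    labs(x = "cluster (ordered by population)", y = "poses",
         title = "Binding-mode cluster populations") +
    theme_minimal()
}

#' Consensus binding modes from a cluster set
#'
#' Clusters with population at least `min_population` are reported as
#' consensus binding modes, ordered by population (descending) and then
#' by mean final rank of their members. Each mode lists the contributing
#' ligands and its representative pose.
#'
#' @param clusters a `condock_clusters` from [cluster_poses()].
#' @param min_population minimum cluster population to call a mode
#'   (default 2: a mode must be supported by more than one pose).
#' @return tibble `mode`, `cluster`, `population`, `mean_rank`,
#'   `ligands` (list-column), `representative` (pose row index),
#'   `center` (list-column, heavy-atom centroid of the cluster).
#' @export
consensus_modes <- function(clusters, min_population = 2) {
  keep <- which(clusters$populations >= min_population)
  if (!length(keep)) {
    return(tibble(mode = integer(), cluster = integer(),
                  population = integer(), mean_rank = numeric(),
                  ligands = list(), representative = integer(),
                  center = list()))
  }
  poses <- clusters$poses
  info <- map(keep, function(cl) {
    members <- which(clusters$labels == cl)
    mean_rank <- if ("final_rank" %in% names(poses)) {
      mean(poses$final_rank[members], na.rm = TRUE)
    } else NA_real_
    xyz <- do.call(rbind, map(poses$atoms[members],
                              function(a) coords(heavy_atoms(a))))
    list(cluster = cl, population = clusters$populations[cl],
         mean_rank = mean_rank,
         ligands = unique(poses$ligand_id[members]),
         representative = clusters$representatives[cl],
         center = colMeans(xyz))
  })
  out <- tibble(
    cluster = map_int(info, "cluster"),
    population = map_int(info, "population"),
    mean_rank = map_dbl(info, "mean_rank"),
    ligands = map(info, "ligands"),
    representative = map_int(info, "representative"),
    center = map(info, "center")
  )
  out <- out[order(-out$population, out$mean_rank), , drop = FALSE]
  out$mode <- seq_len(nrow(out))
  out[c("mode", "cluster", "population", "mean_rank", "ligands",
        "representative", "center")]
}
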