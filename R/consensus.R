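#' Seed the docking search region at an anchor residue
#'
#' Stage 1 of the consensus protocol searches a generous volume around a
#' pore-facing anchor residue, expressed in both dialects the two engines
#' understand: a sphere (radius 18 Angstrom by default) and a cube
#' (32 Angstrom edge by default), both centered on a named anchor atom —
#' by default the gamma-carbon of a threonine (`CG2`).
#'
#' @param receptor atom tibble (see [read_receptor()]).
#' @param anchor list or residue spec `list(chain =, resno =)`;
#'   alternatively a string `"A:277"`.
#' @param anchor_atom atom name holding the center (default `"CG2"`).
#' @param sphere_radius sphere radius, Angstrom.
#' @param box_edge cube edge length, Angstrom.
#' @return a `condock_region`: list with `center`, `sphere_radius`,
#'   `box_edges` (3-vector).
#' @export
seed_region <- function(receptor, anchor, anchor_atom = "CG2",
                        sphere_radius = 18, box_edge = 32) {
  receptor <- as_atoms(receptor)
  anchor <- parse_residue_spec(anchor)
  sel <- receptor$resno == anchor$resno &
    (is.null(anchor$chain) | receptor$chain == (anchor$chain %||% receptor$chain)) &
    receptor$name == anchor_atom
  if (!any(sel)) {
    abort(paste0("anchor atom ", anchor_atom, " not found in residue ",
                 anchor$chain %||% "", ":", anchor$resno))
  }
  center <- as.numeric(coords(receptor)[which(sel)[1], ])
  new_region(center, sphere_radius, rep(box_edge, 3))
}

new_region <- function(center, sphere_radius, box_edges) {
  stopifnot(sphere_radius > 0, all(box_edges > 0))
  structure(list(center = as.numeric(center),
                 sphere_radius = sphere_radius,
                 box_edges = as.numeric(box_edges)),
            class = "condock_region")
}

#' @export
print.condock_region <- function(x, ...) {
  cat(sprintf(
    "<search region> center (%.2f, %.2f, %.2f) A; sphere r = %.2f A; box %s A\n",
    x$center[1], x$center[2], x$center[3], x$sphere_radius,
    paste(sprintf("%.2f", x$box_edges), collapse = " x ")))
  invisible(x)
}

parse_residue_spec <- function(spec) {
  if (is.list(spec)) return(spec)
  if (is.numeric(spec)) return(list(chain = NULL, resno = as.integer(spec)))
  parts <- strsplit(as.character(spec), ":", fixed = TRUE)[[1]]
  if (length(parts) == 2) {
    list(chain = parts[1], resno = as.integer(parts[2]))
  } else {
    list(chain = NULL, resno = as.integer(parts[1]))
  }
}

#' Match poses across two docking engines
#'
#' The consensus filter: every cross-engine pose pair whose
#' symmetry-corrected ([hungarian_rmsd()]) RMSD is at or below `threshold`
#' (2 Angstrom by default) counts as an agreement between the engines.
#' Pairs are returned sorted by ascending RMSD.
#'
#' @param set_a,set_b pose-set tibbles from two different engines for the
#'   same ligand.
#' @param threshold agreement threshold, Angstrom.
#' @return tibble of matched pairs: `ligand_id`, `idx_a`, `idx_b`, `rmsd`,
#'   plus list-columns `atoms_a`, `atoms_b`.
#' @export
match_poses <- function(set_a, set_b, threshold = 2.0) {
  if (set_a$ligand_id[1] != set_b$ligand_id[1]) {
    abort("pose sets are for different ligands")
  }
  if (set_a$engine[1] == set_b$engine[1]) {
    abort("pose sets must come from different engines")
  }
  pairs <- tidyr::expand_grid(i = seq_len(nrow(set_a)),
                              j = seq_len(nrow(set_b)))
  pairs$rmsd <- map_dbl(seq_len(nrow(pairs)), function(k) {
    hungarian_rmsd(set_a$atoms[[pairs$i[k]]], set_b$atoms[[pairs$j[k]]])
  })
  pairs <- pairs[pairs$rmsd <= threshold, , drop = FALSE]
  pairs <- pairs[order(pairs$rmsd, pairs$i, pairs$j), , drop = FALSE]
  tibble(
    ligand_id = set_a$ligand_id[1],
    idx_a = pairs$i, idx_b = pairs$j, rmsd = pairs$rmsd,
    atoms_a = set_a$atoms[pairs$i], atoms_b = set_b$atoms[pairs$j]
  )
}

#' Centroid of the consensus subset
#'
#' Unweighted mean of all heavy-atom coordinates over every pose (both
#' engines) appearing in the matched pairs. This is the point from which
#' the refined second-stage search region is grown.
#'
#' @param pairs matched-pair tibble from [match_poses()].
#' @return 3-vector, Angstrom.
#' @export
consensus_centroid <- function(pairs) {
  xyz <- pair_atom_coords(pairs)
  colMeans(xyz)
}

pair_atom_coords <- function(pairs) {
  if (nrow(pairs) == 0) abort("no matched pairs")
  all_atoms <- c(pairs$atoms_a, pairs$atoms_b)
  do.call(rbind, map(all_atoms, function(a) coords(heavy_atoms(a))))
}

#' Derive the refined search region from the consensus subset
#'
#' The second-stage region is grown from the consensus centroid so that
#' every heavy atom of every matched pose lies inside both dialects: the
#' sphere radius is the maximum atom distance from the centroid (plus
#' `pad`), and each box edge is twice the maximum per-axis deviation
#' (plus `2 * pad`). Degenerate zero extents (a single atom) are floored
#' at 1 Angstrom per dimension with a warning, since docking engines
#' reject zero volumes.
#'
#' @param pairs matched-pair tibble from [match_poses()].
#' @param pad extra margin, Angstrom (>= 0).
#' @return a `condock_region`.
#' @export
derive_region <- function(pairs, pad = 0) {
  stopifnot(pad >= 0)
  xyz <- pair_atom_coords(pairs)
  center <- colMeans(xyz)
  dev <- sweep(xyz, 2, center)
  radius <- max(sqrt(rowSums(dev^2))) + pad
  edges <- 2 * apply(abs(dev), 2, max) + 2 * pad
  if (radius < 1 || any(edges < 1)) {
    warn("degenerate region extent floored at 1 Angstrom")
    radius <- max(radius, 1)
    edges <- pmax(edges, 1)
  }
  new_region(center, radius, edges)
}

#' Is a point inside a search region?
#'
#' @param region a `condock_region`.
#' @param xyz n x 3 matrix of points.
#' @param dialect `"sphere"` or `"box"`.
#' @return logical vector.
#' @export
region_contains <- function(region, xyz, dialect = c("sphere", "box")) {
  dialect <- match.arg(dialect)
  xyz <- matrix(xyz, ncol = 3)
  dev <- sweep(xyz, 2, region$center)
  if (dialect == "sphere") {
    sqrt(rowSums(dev^2)) <= region$sphere_radius + 1e-9
  } else {
    apply(abs(dev) <= matrix(region$box_edges / 2 + 1e-9,
                             nrow(xyz), 3, byrow = TRUE), 1, all)
  }
}

#' Select side chains to make flexible in the second docking stage
#'
#' Chooses `n` residues whose side chains reach into the refined search
#' region, in three priority tiers: (1) residues mutated in the
#' accompanying mutagenesis work, (2) polar residues, (3) everything else.
#' Within tiers 2 and 3, residues are picked by greedy farthest-point
#' sampling on side-chain centroids (each pick maximizes the minimum
#' distance to all already-selected residues), which spreads flexibility
#' evenly over the pocket instead of biasing one wall. Ties break by
#' `(chain, resno)` so the selection is deterministic.
#'
#' @param receptor atom tibble.
#' @param region a `condock_region`; a side chain is "in region" when any
#'   of its heavy atoms falls inside the sphere dialect.
#' @param n number of residues to select.
#' @param mutated integer vector of mutated residue numbers (or
#'   `"chain:resno"` strings).
#' @param polar_set residue names counted as polar.
#' @return tibble `chain`, `resno`, `resname`, `tag`
#'   (mutated/polar/spread), in selection order.
#' @export
select_flexible_residues <- function(receptor, region, n = 10,
                                     mutated = integer(),
                                     polar_set = c("SER", "THR", "TYR", "CYS",
                                                   "ASN", "GLN", "HIS", "LYS",
                                                   "ARG", "ASP", "GLU")) {
  stopifnot(n >= 1)
  receptor <- as_atoms(receptor)
  side <- receptor[!receptor$is_hetero &
                     !receptor$name %in% c("N", "CA", "C", "O") &
                     receptor$element != "H", , drop = FALSE]
  if (nrow(side) == 0) abort("receptor has no side-chain atoms")
  side$in_region <- region_contains(region, coords(side), "sphere")

  cand <- side |>
    group_by(.data$chain, .data$resno, .data$resname) |>
    summarise(in_region = any(.data$in_region),
              cx = mean(.data$x), cy = mean(.data$y), cz = mean(.data$z),
              .groups = "drop") |>
    filter(.data$in_region) |>
    arrange(.data$chain, .data$resno)
  if (nrow(cand) == 0) abort("no side chains intersect the region")

  mutated_specs <- map(as.list(mutated), parse_residue_spec)
  is_mut <- map_lgl_safe(seq_len(nrow(cand)), function(i) {
    any(map_lgl_safe(mutated_specs, function(m) {
      cand$resno[i] == m$resno &&
        (is.null(m$chain) || cand$chain[i] == m$chain)
    }))
  })
  cand$tier <- ifelse(is_mut, 1L, ifelse(cand$resname %in% polar_set, 2L, 3L))

  if (nrow(cand) < n) {
    warn(paste0("only ", nrow(cand), " candidate residues in region; ",
                "returning all"))
  }

  selected <- cand[cand$tier == 1L, , drop = FALSE]
  selected <- head(selected, n)
  selected$tag <- rep("mutated", nrow(selected))
  for (tier in 2:3) {
    pool <- cand[cand$tier == tier, , drop = FALSE]
    while (nrow(selected) < n && nrow(pool) > 0) {
      pick <- farthest_point_pick(pool, selected)
      row <- pool[pick, , drop = FALSE]
      row$tag <- if (tier == 2L) "polar" else "spread"
      selected <- bind_rows(selected, row)
      pool <- pool[-pick, , drop = FALSE]
    }
  }
  selected[c("chain", "resno", "resname", "tag")]
}

map_lgl_safe <- function(x, f) {
  if (length(x) == 0) return(logical(0))
  vapply(x, f, logical(1))
}

farthest_point_pick <- function(pool, selected) {
  # index in pool maximizing min distance to selected centroids;
  # with nothing selected yet, the point farthest from the pool's own
  # centroid (a deterministic, spread-seeking start)
  pxyz <- cbind(pool$cx, pool$cy, pool$cz)
  if (nrow(selected) == 0) {
    ref <- matrix(colMeans(pxyz), 1)
    score <- sqrt(rowSums((pxyz - ref[rep(1, nrow(pxyz)), , drop = FALSE])^2))
  } else {
    sxyz <- cbind(selected$cx, selected$cy, selected$cz)
    score <- apply(sqrt(cross_dist2(pxyz, sxyz)), 1, min)
  }
  # ties: lowest (chain, resno) — pool is pre-sorted, which.max keeps first
  which.max(score)
}

#' Remove redundant matched pairs
#'
#' Greedy redundancy removal in rank order: walking the pairs from best to
#' worst consensus rank, a pair is kept only if its engine-A pose lies
#' more than `redundancy_rmsd` (Hungarian RMSD) from the engine-A pose of
#' every already-kept pair. Selection stops at `max_pairs` (20 by
#' default). The same 2 Angstrom scale as the agreement filter is used so
#' the whole protocol works on a single distance scale.
#'
#' @param pairs matched-pair tibble from [match_poses()].
#' @param order integer vector: row indices of `pairs` from best to worst
#'   (e.g. the Borda final order). Default: ascending RMSD order as given.
#' @param max_pairs maximum pairs retained.
#' @param redundancy_rmsd minimum engine-A RMSD between kept pairs,
#'   Angstrom.
#' @return the retained rows of `pairs`, in rank order.
#' @export
deduplicate_pairs <- function(pairs, order = seq_len(nrow(pairs)),
                              max_pairs = 20, redundancy_rmsd = 2.0) {
  if (nrow(pairs) == 0) return(pairs)
  kept <- integer(0)
  for (k in order) {
    if (length(kept) >= max_pairs) break
    a_new <- pairs$atoms_a[[k]]
    redundant <- any(map_lgl_safe(kept, function(j) {
      hungarian_rmsd(a_new, pairs$atoms_a[[j]]) <= redundancy_rmsd
    }))
    if (!redundant) kept <- c(kept, k)
  }
  pairs[kept, , drop = FALSE]
}
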