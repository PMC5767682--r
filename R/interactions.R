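#' Ligand-residue contact geometry
#'
#' Distance, hydrogen-bond and pocket reports on a docked protein-ligand
#' complex, the quantities used to describe predicted binding modes
#' ("the ring sits ~5 Angstrom from L247", "hydrogen bonds with S284").
#'
#' The "distance to residue X" convention is the minimum heavy-atom
#' distance between the chosen ligand selection and the side chain of the
#' residue; a `"centroid"` mode (distance between the two selections'
#' heavy-atom centroids) is also available since published "~X Angstrom"
#' figures do not always state the convention.
#'
#' @param complex atom tibble of the receptor-ligand complex.
#' @param ligand atom tibble, or a HETATM residue name (e.g. `"TQS"`)
#'   selecting ligand atoms from `complex`.
#' @param residue residue spec (`"A:253"`, `list(chain=, resno=)`, or a
#'   bare residue number).
#' @param side_chain_only restrict the residue side to side-chain atoms.
#' @param mode `"min"` (closest heavy-atom pair, default) or
#'   `"centroid"`.
#' @return distance in Angstrom.
#' @export
min_distance <- function(complex, ligand, residue, side_chain_only = TRUE,
                         mode = c("min", "centroid")) {
  mode <- match.arg(mode)
  complex <- as_atoms(complex)
  lig <- resolve_ligand(complex, ligand)
  res <- select_residue(complex, residue, side_chain_only)
  if (nrow(lig) == 0) abort("empty ligand selection")
  if (nrow(res) == 0) abort("empty residue selection")
  xa <- coords(heavy_atoms(lig)); xb <- coords(heavy_atoms(res))
  if (mode == "min") {
    sqrt(min(cross_dist2(xa, xb)))
  } else {
    sqrt(sum((colMeans(xa) - colMeans(xb))^2))
  }
}

resolve_ligand <- function(complex, ligand) {
  if (is.data.frame(ligand)) return(as_atoms(ligand))
  sel <- complex[complex$resname == ligand & complex$is_hetero, , drop = FALSE]
  if (nrow(sel) == 0) {
    abort(paste0("no HETATM atoms with residue name '", ligand, "'"))
  }
  sel
}

select_residue <- function(complex, residue, side_chain_only = TRUE) {
  spec <- parse_residue_spec(residue)
  sel <- complex$resno == spec$resno & !complex$is_hetero
  if (!is.null(spec$chain)) sel <- sel & complex$chain == spec$chain
  res <- complex[sel, , drop = FALSE]
  if (side_chain_only) {
    res <- res[!res$name %in% c("N", "CA", "C", "O", "OXT"), , drop = FALSE]
  }
  res
}

#' Detect ligand-receptor hydrogen bonds
#'
#' Geometric hydrogen-bond detection between ligand and receptor: a
#' nitrogen or oxygen on one side within `d_max` of a nitrogen/oxygen on
#' the other counts as a candidate donor-acceptor pair; when explicit
#' hydrogens are present on the donor, the D-H...A angle must also reach
#' `angle_min`. Without hydrogens (the common case for docked heavy-atom
#' poses) detection runs in distance-only mode and the report says so.
#' The 3.5 Angstrom / 120 degree defaults are the standard geometric
#' criteria.
#'
#' @inheritParams min_distance
#' @param d_max maximum donor-acceptor heavy-atom distance, Angstrom.
#' @param angle_min minimum D-H...A angle, degrees (applied only when a
#'   hydrogen within 1.25 Angstrom of the donor exists).
#' @return tibble `ligand_atom`, `receptor_atom`, `chain`, `resno`,
#'   `resname`, `distance`, `angle` (NA in distance-only mode),
#'   `criterion` (`"distance+angle"` or `"distance_only"`).
#' @export
detect_hbonds <- function(complex, ligand, d_max = 3.5, angle_min = 120) {
  complex <- as_atoms(complex)
  lig <- resolve_ligand(complex, ligand)
  rec <- complex[!complex$is_hetero, , drop = FALSE]
  lig_po <- lig[lig$element %in% c("N", "O"), , drop = FALSE]
  rec_po <- rec[rec$element %in% c("N", "O"), , drop = FALSE]
  if (nrow(lig_po) == 0 || nrow(rec_po) == 0) return(empty_hbonds())

  d <- sqrt(cross_dist2(coords(lig_po), coords(rec_po)))
  hits <- which(d <= d_max, arr.ind = TRUE)
  if (!nrow(hits)) return(empty_hbonds())

  out <- map(seq_len(nrow(hits)), function(k) {
    i <- hits[k, 1]; j <- hits[k, 2]
    don <- lig_po[i, ]; acc <- rec_po[j, ]
    ang <- best_dha_angle(complex, lig, don, acc)
    tibble(ligand_atom = don$name, receptor_atom = acc$name,
           chain = acc$chain, resno = acc$resno, resname = acc$resname,
           distance = d[i, j], angle = ang,
           criterion = if (is.na(ang)) "distance_only" else "distance+angle")
  })
  out <- bind_rows(out)
  out <- out[is.na(out$angle) | out$angle >= angle_min, , drop = FALSE]
  out[order(out$distance), , drop = FALSE]
}

empty_hbonds <- function() {
  tibble(ligand_atom = character(), receptor_atom = character(),
         chain = character(), resno = integer(), resname = character(),
         distance = numeric(), angle = numeric(), criterion = character())
}

best_dha_angle <- function(complex, lig, don, acc) {
  # hydrogens covalently bound to either polar partner (<= 1.25 A);
  # returns the best D-H...A angle over both donor directions, or NA
  # when no hydrogen exists (distance-only mode)
  h_of <- function(mol, heavy) {
    hs <- heavy_neighbors(mol, heavy, element = "H", r = 1.25)
    hs
  }
  angles <- c()
  for (pair in list(list(d = don, a = acc, mol = lig),
                    list(d = acc, a = don, mol = complex))) {
    hs <- h_of(pair$mol, pair$d)
    if (nrow(hs)) {
      dxyz <- as.numeric(coords(pair$d))
      axyz <- as.numeric(coords(pair$a))
      angles <- c(angles, map_dbl(seq_len(nrow(hs)), function(m) {
        hxyz <- as.numeric(coords(hs[m, ]))
        v1 <- dxyz - hxyz; v2 <- axyz - hxyz
        acos(pmin(1, pmax(-1, sum(v1 * v2) /
                            (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))))) * 180 / pi
      }))
    }
  }
  if (length(angles)) max(angles) else NA_real_
}

heavy_neighbors <- function(mol, atom, element, r) {
  cand <- mol[mol$element == element, , drop = FALSE]
  if (!nrow(cand)) return(cand)
  d <- sqrt(cross_dist2(coords(cand), coords(atom)))
  cand[d[, 1] <= r, , drop = FALSE]
}

#' Residues lining the ligand pocket
#'
#' All receptor residues with at least one side-chain heavy atom within
#' `pocket_cutoff` of any ligand heavy atom, annotated with the minimal
#' distance and an interface-side label: the chain burying the larger
#' share of the ligand (by contact count) is called the principal `(+)`
#' side, the other contact chains the complementary `(-)` side.
#'
#' @inheritParams min_distance
#' @param pocket_cutoff contact cutoff, Angstrom (default 4.5).
#' @return tibble `chain`, `resno`, `resname`, `min_dist`, `n_contacts`,
#'   `side` (`"+"`/`"-"`).
#' @export
pocket_residues <- function(complex, ligand, pocket_cutoff = 4.5) {
  complex <- as_atoms(complex)
  lig <- heavy_atoms(resolve_ligand(complex, ligand))
  side_atoms <- complex[!complex$is_hetero &
                          !complex$name %in% c("N", "CA", "C", "O", "OXT") &
                          complex$element != "H", , drop = FALSE]
  if (nrow(side_atoms) == 0 || nrow(lig) == 0) {
    return(tibble(chain = character(), resno = integer(),
                  resname = character(), min_dist = numeric(),
                  n_contacts = integer(), side = character()))
  }
  d <- sqrt(cross_dist2(coords(side_atoms), coords(lig)))
  side_atoms$min_dist <- apply(d, 1, min)
  pocket <- side_atoms |>
    group_by(.data$chain, .data$resno, .data$resname) |>
    summarise(min_dist = min(.data$min_dist),
              n_contacts = sum(.data$min_dist <= pocket_cutoff),
              .groups = "drop") |>
    filter(.data$min_dist <= pocket_cutoff) |>
    arrange(.data$min_dist)
  if (nrow(pocket) == 0) {
    pocket$side <- character(0)
    return(pocket)
  }
  by_chain <- pocket |>
    group_by(.data$chain) |>
    summarise(contacts = sum(.data$n_contacts), .groups = "drop")
  principal <- by_chain$chain[which.max(by_chain$contacts)]
  pocket$side <- ifelse(pocket$chain == principal, "+", "-")
  pocket
}

#' Full contact report for a docked complex
#'
#' Convenience wrapper combining [min_distance()] (both conventions) for
#' a set of named residues, [detect_hbonds()], and [pocket_residues()].
#'
#' @inheritParams min_distance
#' @param residues character vector of residue specs to measure.
#' @param pocket_cutoff,d_max,angle_min see the component functions.
#' @return list with tibbles `distances`, `hbonds`, `pocket`.
#' @export
contact_report <- function(complex, ligand, residues = character(),
                           pocket_cutoff = 4.5, d_max = 3.5,
                           angle_min = 120) {
  complex <- as_atoms(complex)
  distances <- bind_rows(map(residues, function(r) {
    spec <- parse_residue_spec(r)
    tibble(residue = as.character(r),
           min_dist = min_distance(complex, ligand, r, mode = "min"),
           centroid_dist = min_distance(complex, ligand, r,
                                        mode = "centroid"))
  }))
  list(distances = distances,
       hbonds = detect_hbonds(complex, ligand, d_max, angle_min),
       pocket = pocket_residues(complex, ligand, pocket_cutoff))
}
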