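#' Ligand-pose RMSD without superposition
#'
#' Two RMSD flavours between docked poses of the same (or chemically
#' related) ligand, computed in the fixed receptor frame — no rotation or
#' translation is ever fitted, because the quantity of interest is whether
#' two engines placed the ligand in the same *binding position*, not
#' whether conformers overlap after superposition.
#'
#' `naive_rmsd()` pairs atoms by their input order and is only defined when
#' both poses list the same elements in the same order. It serves as a
#' baseline and as an upper bound for the assignment-corrected value.
#'
#' `hungarian_rmsd()` corrects for topological symmetry (e.g. a phenyl ring
#' flip relabels equivalent carbons) by minimizing the total squared
#' distance over atom correspondences with an optimal linear assignment,
#' solved independently within each element class. With
#' `same_element = FALSE` (the "relaxed" mode used when clustering
#' chemically similar but non-identical compounds) every heavy atom of the
#' smaller pose is matched to a distinct heavy atom of the larger pose
#' regardless of element, and the RMSD is normalized by the number of
#' matched atoms.
#'
#' Hydrogens are excluded by default: docking engines differ in whether
#' and where they write hydrogens, while heavy-atom positions are what the
#' agreement filter compares.
#'
#' @param a,b atom tables (see [as_atoms()]).
#' @param heavy_only drop hydrogens before comparing (default `TRUE`).
#' @param same_element restrict the assignment to same-element pairs
#'   (default `TRUE`); requires equal heavy-atom element multisets.
#' @return RMSD in Angstrom (single number).
#' @seealso [pairwise_rmsd_matrix()], [solve_assignment()]
#' @examples
#' hex <- make_symmetric_ligand(6, 1.4)
#' rot <- dplyr::mutate(hex,
#'   x0 = x, x = x0 * cos(pi / 3) - y * sin(pi / 3),
#'   y = x0 * sin(pi / 3) + y * cos(pi / 3), x0 = NULL)
#' naive_rmsd(hex, rot)     # 1.4: chord length of a 60 degree turn
#' hungarian_rmsd(hex, rot) # 0:   the rotation is a symmetry permutation
#' @export
naive_rmsd <- function(a, b, heavy_only = TRUE) {
  a <- as_atoms(a); b <- as_atoms(b)
  if (heavy_only) { a <- heavy_atoms(a); b <- heavy_atoms(b) }
  if (nrow(a) == 0 || nrow(b) == 0) abort("empty pose")
  if (nrow(a) != nrow(b)) abort("atom count mismatch between poses")
  if (!identical(a$element, b$element)) {
    abort("ordered element lists differ; naive RMSD undefined (use hungarian_rmsd)")
  }
  d2 <- rowSums((coords(a) - coords(b))^2)
  sqrt(mean(d2))
}

#' @rdname naive_rmsd
#' @export
hungarian_rmsd <- function(a, b, same_element = TRUE, heavy_only = TRUE) {
  a <- as_atoms(a); b <- as_atoms(b)
  if (heavy_only) { a <- heavy_atoms(a); b <- heavy_atoms(b) }
  if (nrow(a) == 0 || nrow(b) == 0) abort("empty pose")
  xa <- coords(a); xb <- coords(b)

  if (same_element) {
    ta <- sort(a$element); tb <- sort(b$element)
    if (length(ta) != length(tb) || !all(ta == tb)) {
      abort("heavy-atom element multisets differ; use same_element = FALSE")
    }
    # block-diagonal solve per element class: exactly equivalent to one big
    # assignment with infinite cross-element costs, at much lower cost
    total <- 0
    for (el in unique(a$element)) {
      ia <- which(a$element == el)
      ib <- which(b$element == el)
      total <- total + solve_assignment(cross_dist2(xa[ia, , drop = FALSE],
                                                    xb[ib, , drop = FALSE]))$cost
    }
    sqrt(total / nrow(a))
  } else {
    if (nrow(a) > nrow(b)) { tmp <- xa; xa <- xb; xb <- tmp }
    sol <- solve_assignment(cross_dist2(xa, xb))
    sqrt(sol$cost / nrow(xa))
  }
}

cross_dist2 <- function(xa, xb) {
  # squared Euclidean distances, rows of xa vs rows of xb; clamp the tiny
  # negative values that cancellation produces for coincident points
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * tcrossprod(xa, xb)
  pmax(d2, 0)
}

#' Pairwise Hungarian RMSD matrix
#'
#' Symmetric matrix of [hungarian_rmsd()] values between every pair of
#' poses, used as the distance input for hierarchical binding-mode
#' clustering. When the poses are different molecules, use
#' `mode = "relaxed"`.
#'
#' @param poses a pose-set tibble (see [pose_set()]) or a list of atom
#'   tables.
#' @param mode `"same_element"` (default) or `"relaxed"`.
#' @return symmetric numeric matrix (Angstrom) with a zero diagonal.
#' @export
pairwise_rmsd_matrix <- function(poses, mode = c("same_element", "relaxed")) {
  mode <- match.arg(mode)
  atoms_list <- if (is.data.frame(poses) && "atoms" %in% names(poses)) {
    poses$atoms
  } else {
    poses
  }
  n <- length(atoms_list)
  if (n < 2) abort("need at least 2 poses")
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- hungarian_rmsd(atoms_list[[i]], atoms_list[[j]],
                                           same_element = mode == "same_element")
    }
  }
  d
}
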