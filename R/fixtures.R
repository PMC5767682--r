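#' Synthetic ligands, pose ensembles and receptors for end-to-end testing
#'
#' Every stage of the consensus-docking pipeline can be exercised without
#' any external structure download through a family of deterministic
#' generators. They emulate the statistical shape of a two-engine docking
#' campaign — a handful of true binding modes sampled with small coordinate
#' noise by both engines, atom relabelling within element classes
#' (topological symmetry), a fraction of scattered decoy placements, and
#' score tables with a planted consensus order — while making the ground
#' truth available for recovery checks. They do not emulate real docking
#' energetics, receptor flexibility, or solvent.
#'
#' @name fixtures
NULL

#' Regular-polygon test ligand
#'
#' A planar regular n-gon of carbons of the given circumradius, centered
#' at the origin in the xy-plane, optionally with one axial nitrogen
#' marker atom above the plane. Rotating the polygon by `360/fold` degrees
#' about its axis maps it onto itself atom-for-atom, which makes it the
#' canonical probe for symmetry-corrected RMSD: the naive index-paired
#' RMSD sees the full chord displacement while the assignment-corrected
#' RMSD is zero. The on-axis marker preserves the rotational symmetry.
#'
#' @param fold rotational symmetry order (>= 2).
#' @param radius circumradius in Angstrom.
#' @param marker add an axial N atom at `(0, 0, 1.5)`.
#' @return an atom tibble.
#' @export
make_symmetric_ligand <- function(fold, radius = 1.4, marker = FALSE) {
  if (fold < 2) abort("fold must be >= 2")
  theta <- 2 * pi * (seq_len(fold) - 1) / fold
  a <- tibble(element = "C",
              x = radius * cos(theta), y = radius * sin(theta), z = 0)
  if (marker) a <- bind_rows(a, tibble(element = "N", x = 0, y = 0, z = 1.5))
  as_atoms(a)
}

#' Two-engine pose ensemble with planted binding modes
#'
#' Generates matched pose sets for two engines around `n_modes` planted
#' mode centers. Non-decoy poses are the template translated to a mode
#' center with i.i.d. Gaussian coordinate noise of standard deviation
#' `noise_sd` per coordinate, so two poses of one mode sit at an expected
#' Hungarian RMSD of about `noise_sd * sqrt(6)` — comfortably inside a
#' 2 Angstrom agreement threshold at the default 0.3 Angstrom. Decoy poses
#' are randomly rotated copies placed by rejection sampling at least
#' `decoy_clearance` from every mode center, so they can never form
#' cross-engine agreements with mode members. Mode centers themselves are
#' kept at least `decoy_clearance` apart.
#'
#' Pose counts default to 50 and 20, matching a campaign that keeps fifty
#' diverse solutions from the first engine and twenty runs of the second.
#'
#' @param template atom tibble of the ligand (e.g.
#'   [make_symmetric_ligand()]).
#' @param n_modes number of planted binding modes.
#' @param poses_per_engine integer vector of length 2: poses for engine A
#'   and engine B.
#' @param noise_sd per-coordinate Gaussian noise, Angstrom.
#' @param decoy_fraction fraction of each engine's poses scattered outside
#'   all modes.
#' @param permute_atoms shuffle atoms within element classes (tests that
#'   downstream analysis is assignment-corrected).
#' @param decoy_clearance minimum decoy-to-mode-center distance, Angstrom.
#' @param box_half half-width of the placement box, Angstrom.
#' @param ligand_id,engines labels for the generated pose sets.
#' @param seed integer seed; the generator is bit-deterministic given it.
#' @return list with `set_a`, `set_b` (pose-set tibbles), `truth` (tibble
#'   `engine`, `pose_index`, `mode` with `mode = 0` for decoys) and
#'   `mode_centers` (matrix, one row per mode).
#' @export
make_pose_ensemble <- function(template, n_modes = 2,
                               poses_per_engine = c(50, 20),
                               noise_sd = 0.3, decoy_fraction = 0.3,
                               permute_atoms = TRUE, decoy_clearance = 8,
                               box_half = 20, ligand_id = "LIG1",
                               engines = c("engine_A", "engine_B"),
                               seed = 7) {
  stopifnot(n_modes >= 1, length(poses_per_engine) == 2,
            noise_sd >= 0, decoy_fraction >= 0, decoy_fraction <= 1)
  template <- as_atoms(template)
  set.seed(seed)

  centers <- matrix(NA_real_, 0, 3)
  while (nrow(centers) < n_modes) {
    cand <- runif(3, -box_half, box_half)
    if (nrow(centers) == 0 ||
        min(sqrt(rowSums((centers - matrix(cand, nrow(centers), 3,
                                           byrow = TRUE))^2))) >= decoy_clearance) {
      centers <- rbind(centers, cand)
    }
  }

  place <- function(center, noise, rotate) {
    xyz <- coords(template)
    if (rotate) xyz <- xyz %*% random_rotation()
    xyz <- sweep(xyz, 2, center, "+") +
      matrix(rnorm(length(xyz), 0, noise), ncol = 3)
    out <- template
    out$x <- xyz[, 1]; out$y <- xyz[, 2]; out$z <- xyz[, 3]
    if (permute_atoms) {
      ord <- seq_len(nrow(out))
      for (el in unique(out$element)) {
        idx <- which(out$element == el)
        if (length(idx) > 1) ord[idx] <- sample(idx)
      }
      out <- out[ord, ]
      out$serial <- seq_len(nrow(out))
    }
    out
  }

  # decoys keep their clearance from every mode center and 6 A from each
  # other (across both engines), so no decoy can sit within the 2 A
  # agreement threshold of any other pose — threshold tests stay unambiguous
  decoy_centers <- matrix(NA_real_, 0, 3)
  sample_decoy_center <- function() {
    repeat {
      cand <- runif(3, -box_half, box_half)
      d_mode <- sqrt(rowSums((centers - matrix(cand, nrow(centers), 3,
                                               byrow = TRUE))^2))
      d_decoy <- if (nrow(decoy_centers)) {
        sqrt(rowSums((decoy_centers - matrix(cand, nrow(decoy_centers), 3,
                                             byrow = TRUE))^2))
      } else Inf
      if (min(d_mode) >= decoy_clearance && min(d_decoy) >= 6) {
        decoy_centers <<- rbind(decoy_centers, cand)
        return(cand)
      }
    }
  }

  gen_engine <- function(n_poses, engine) {
    n_decoy <- round(decoy_fraction * n_poses)
    modes <- c(rep(seq_len(n_modes), length.out = n_poses - n_decoy),
               rep(0L, n_decoy))
    atoms_list <- map(modes, function(m) {
      if (m == 0L) place(sample_decoy_center(), noise_sd, rotate = TRUE)
      else place(centers[m, ], noise_sd, rotate = FALSE)
    })
    list(set = pose_set(atoms_list, ligand_id, engine),
         truth = tibble(engine = engine, pose_index = seq_len(n_poses),
                        mode = as.integer(modes)))
  }

  a <- gen_engine(poses_per_engine[1], engines[1])
  b <- gen_engine(poses_per_engine[2], engines[2])
  list(set_a = a$set, set_b = b$set,
       truth = bind_rows(a$truth, b$truth),
       mode_centers = unname(centers))
}

random_rotation <- function() {
  # uniform random rotation via QR of a Gaussian matrix, sign-fixed
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Score table with a planted consensus order
#'
#' Builds a three-metric score table (`vina`: lower better; `goldscore`
#' and `chemplp`: higher better) for the poses of an ensemble such that,
#' at `noise = 0`, Borda aggregation over the three metrics reproduces the
#' planted pose order exactly within each engine. Engine-native metrics
#' are attached to their engine's poses: `goldscore`/`chemplp` to engine A
#' and `vina` to engine B (each metric is `NA` for the other engine).
#'
#' @param ensemble result of [make_pose_ensemble()].
#' @param planted_order_a,planted_order_b permutations of the pose indices
#'   of engines A and B, best first. Default: mode members (in mode order)
#'   before decoys.
#' @param noise standard deviation of Gaussian noise added to each score.
#' @param seed integer seed.
#' @return score tibble as from [read_score_table()].
#' @export
make_score_table <- function(ensemble, planted_order_a = NULL,
                             planted_order_b = NULL, noise = 0, seed = 7) {
  set.seed(seed + 1L)
  default_order <- function(truth_engine) {
    tr <- ensemble$truth[ensemble$truth$engine == truth_engine, ]
    order(ifelse(tr$mode == 0L, Inf, tr$mode), tr$pose_index)
  }
  ea <- ensemble$set_a$engine[1]; eb <- ensemble$set_b$engine[1]
  planted_order_a <- planted_order_a %||% default_order(ea)
  planted_order_b <- planted_order_b %||% default_order(eb)
  na <- nrow(ensemble$set_a); nb <- nrow(ensemble$set_b)
  pos_a <- order(planted_order_a) # pos_a[i] = planted position of pose i
  pos_b <- order(planted_order_b)

  tab_a <- tibble(
    ligand_id = ensemble$set_a$ligand_id[1], engine = ea,
    pose_index = seq_len(na),
    vina = NA_real_,
    goldscore = (na - pos_a) * 2 + rnorm(na, 0, noise),
    chemplp = (na - pos_a) * 5 + 10 + rnorm(na, 0, noise)
  )
  tab_b <- tibble(
    ligand_id = ensemble$set_b$ligand_id[1], engine = eb,
    pose_index = seq_len(nb),
    vina = -10 + pos_b * 0.5 + rnorm(nb, 0, noise),
    goldscore = NA_real_, chemplp = NA_real_
  )
  bind_rows(tab_a, tab_b)
}

#' Toy receptor scaffold
#'
#' A single-chain toy protein whose residues sit on a sphere around a
#' pocket center with one side-chain atom pointing inward — enough
#' geometry for search-region seeding, flexible-residue selection and
#' contact reporting. Residue 1 is a threonine whose gamma-carbon (CG2)
#' lies exactly at `pocket_center`, serving as the anchor residue. A
#' configurable subset of residues is named after positions mutated in
#' mutagenesis work (tagged via the `mutated` attribute on the return
#' value); polar and apolar residue names alternate elsewhere.
#'
#' @param n_residues total residue count (>= 1).
#' @param pocket_center 3-vector, Angstrom.
#' @param mutated_resno integer vector of residue numbers to flag as
#'   mutated (default `c(5, 12, 19)` when they exist).
#' @param shell_radius radius of the residue shell around the pocket.
#' @param seed integer seed (jitters side-chain atoms deterministically).
#' @return an atom tibble with attribute `mutated` (integer resno vector).
#' @export
make_toy_receptor <- function(n_residues = 30, pocket_center = c(0, 0, 0),
                              mutated_resno = NULL, shell_radius = 8,
                              seed = 7) {
  stopifnot(n_residues >= 1)
  set.seed(seed + 2L)
  mutated_resno <- mutated_resno %||% intersect(c(5L, 12L, 19L),
                                                seq_len(n_residues))
  polar <- c("SER", "THR", "TYR", "ASN", "GLN", "HIS", "LYS", "ARG",
             "ASP", "GLU")
  apolar <- c("ALA", "LEU", "VAL", "ILE", "PHE", "MET")

  rows <- list()
  serial <- 0L
  for (i in seq_len(n_residues)) {
    if (i == 1) {
      resname <- "THR"
    } else if (i %in% mutated_resno) {
      resname <- "LEU"
    } else {
      resname <- if (i %% 2 == 0) polar[1 + (i %/% 2) %% length(polar)]
                 else apolar[1 + (i %/% 2) %% length(apolar)]
    }
    # golden-spiral placement on the shell, side chain pointing inward
    k <- (i - 0.5) / n_residues
    phi <- acos(1 - 2 * k); th <- pi * (1 + sqrt(5)) * i
    u <- c(sin(phi) * cos(th), sin(phi) * sin(th), cos(phi))
    ca <- pocket_center + shell_radius * u
    cb <- pocket_center + (shell_radius - 1.5) * u + rnorm(3, 0, 0.1)
    sc <- pocket_center + (shell_radius - 3) * u + rnorm(3, 0, 0.1)
    has_sc_tip <- resname != "ALA"
    atom_names <- c("N", "CA", "C", "O", "CB",
                    if (has_sc_tip) (if (resname == "THR") "CG2" else "CG"))
    res <- tibble(
      name = atom_names,
      element = c("N", "C", "C", "O", "C", if (has_sc_tip) "C"),
      x = 0, y = 0, z = 0, resname = resname, resno = i, chain = "A",
      is_hetero = FALSE
    )
    bb <- unname(rbind(ca + c(-1.2, 0.5, 0), ca, ca + c(1.2, 0.5, 0),
                       ca + c(1.8, 1.5, 0), cb, sc))
    res$x <- bb[seq_len(nrow(res)), 1]
    res$y <- bb[seq_len(nrow(res)), 2]
    res$z <- bb[seq_len(nrow(res)), 3]
    if (i == 1) { # anchor: gamma-carbon exactly at the pocket center
      gi <- which(res$name == "CG2")
      res$x[gi] <- pocket_center[1]; res$y[gi] <- pocket_center[2]
      res$z[gi] <- pocket_center[3]
    }
    res$serial <- serial + seq_len(nrow(res))
    serial <- serial + nrow(res)
    rows[[i]] <- res
  }
  out <- as_atoms(bind_rows(rows))
  attr(out, "mutated") <- as.integer(mutated_resno)
  out
}

#' Planted density grid for loop-ranking tests
#'
#' Simulates a density map from a model, optionally displacing one
#' segment's atoms before simulation so that the density of that region no
#' longer matches the model — the planted ground truth for
#' [rank_loops()]: a candidate that traces the displaced density must
#' outrank candidates built from the original coordinates.
#'
#' @param model atom tibble.
#' @param displaced_segment optional [segment()]; its atoms are shifted by
#'   `displacement` before the map is simulated.
#' @param displacement 3-vector, Angstrom.
#' @param resolution,voxel map parameters passed to [simulate_map()].
#' @return a [density_grid()].
#' @export
make_planted_density <- function(model, displaced_segment = NULL,
                                 displacement = c(10, 0, 0),
                                 resolution = 6.2, voxel = 1.5) {
  model <- as_atoms(model)
  if (!is.null(displaced_segment)) {
    idx <- segment_atom_indices(model, displaced_segment)
    model$x[idx] <- model$x[idx] + displacement[1]
    model$y[idx] <- model$y[idx] + displacement[2]
    model$z[idx] <- model$z[idx] + displacement[3]
  }
  simulate_map(model, resolution = resolution, voxel = voxel)
}
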