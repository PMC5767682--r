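toy_pocket <- function() make_toy_receptor(30, pocket_center = c(0, 0, 0))

test_that("seed region centers on the anchor gamma-carbon with protocol defaults", {
  rec <- toy_pocket()
  reg <- seed_region(rec, "A:1")
  expect_equal(reg$center, c(0, 0, 0))
  expect_equal(reg$sphere_radius, 18)
  expect_equal(reg$box_edges, rep(32, 3))
  custom <- seed_region(rec, "A:1", sphere_radius = 10)
  expect_equal(custom$sphere_radius, 10)
  expect_error(seed_region(rec, "A:999"), "not found")
  expect_error(seed_region(rec, "A:3", anchor_atom = "CG2"), "CG2")
})

test_that("match_poses keeps exactly the cross pairs within threshold", {
  hex <- make_symmetric_ligand(6, 1.4)
  # engine A: three sites; engine B: one near site 1 (1 A), one near site 2
  # (1.5 A), one far from everything -> exactly 2 of 9 pairs within 2 A
  a <- pose_set(list(hex, translate(hex, c(20, 0, 0)),
                     translate(hex, c(0, 20, 0))), "L", "engine_A")
  b <- pose_set(list(translate(hex, c(1, 0, 0)),
                     translate(hex, c(20, 1.5, 0)),
                     translate(hex, c(50, 50, 0))), "L", "engine_B")
  pairs <- match_poses(a, b)
  expect_equal(nrow(pairs), 2)
  expect_equal(pairs$rmsd, c(1, 1.5), tolerance = 1e-9) # ascending
  expect_equal(pairs$idx_a, c(1L, 2L))

  far_b <- pose_set(list(translate(hex, c(100, 0, 0))), "L", "engine_B")
  expect_equal(nrow(match_poses(a, far_b)), 0)

  # a copied, relabeled set matches itself on the diagonal at 0
  b2 <- a
  b2$engine <- "engine_B"
  self <- match_poses(a, b2)
  expect_true(all(self$rmsd[self$idx_a == self$idx_b] < 1e-5))
  expect_equal(sum(self$idx_a == self$idx_b), 3)

  expect_error(match_poses(a, pose_set(list(hex), "OTHER", "engine_B")),
               "different ligands")
  expect_error(match_poses(a, a), "different engines")
})

test_that("consensus centroid is the flat mean of heavy atoms and is equivariant", {
  p1 <- as_atoms(data.frame(element = "C", x = 0, y = 0, z = 0))
  p2 <- as_atoms(data.frame(element = "C", x = 2, y = 0, z = 0))
  pairs <- tibble::tibble(ligand_id = "L", idx_a = 1L, idx_b = 1L,
                          rmsd = 2, atoms_a = list(p1), atoms_b = list(p2))
  expect_equal(consensus_centroid(pairs), c(x = 1, y = 0, z = 0))

  set.seed(81)
  hex <- make_symmetric_ligand(6, 1.4)
  a <- pose_set(lapply(1:4, function(i) translate(hex, rnorm(3))), "L", "eA")
  b <- pose_set(lapply(1:3, function(i) translate(hex, rnorm(3))), "L", "eB")
  pr <- match_poses(a, b, threshold = 50)
  cen <- consensus_centroid(pr)
  # independent flat loop over every heavy atom of every pose in the pairs
  acc <- c(0, 0, 0); count <- 0
  for (k in seq_len(nrow(pr))) {
    for (at in list(pr$atoms_a[[k]], pr$atoms_b[[k]])) {
      at <- at[at$element != "H", ]
      acc <- acc + c(sum(at$x), sum(at$y), sum(at$z))
      count <- count + nrow(at)
    }
  }
  expect_equal(unname(cen), acc / count, tolerance = 1e-12)
  v <- c(3, -2, 7)
  pr2 <- pr
  pr2$atoms_a <- lapply(pr$atoms_a, translate, v = v)
  pr2$atoms_b <- lapply(pr$atoms_b, translate, v = v)
  expect_equal(unname(consensus_centroid(pr2)), unname(cen) + v,
               tolerance = 1e-9)
  expect_error(consensus_centroid(pr[0, ]), "no matched pairs")
})

test_that("derived region contains every consensus atom in both dialects", {
  p1 <- as_atoms(data.frame(element = "C", x = -1, y = 0, z = 0))
  p2 <- as_atoms(data.frame(element = "C", x = 1, y = 0, z = 0))
  pairs <- tibble::tibble(ligand_id = "L", idx_a = 1L, idx_b = 1L,
                          rmsd = 2, atoms_a = list(p1), atoms_b = list(p2))
  expect_warning(reg <- derive_region(pairs), "floored")
  expect_equal(reg$center, c(0, 0, 0))
  expect_equal(reg$sphere_radius, 1)             # max distance from center
  expect_equal(unname(reg$box_edges), c(2, 1, 1)) # y/z extents floored

  single <- pairs
  single$atoms_b <- list(p1)
  expect_warning(degenerate <- derive_region(single), "floored")
  expect_equal(degenerate$sphere_radius, 1)

  set.seed(91)
  hex <- make_symmetric_ligand(6, 1.4)
  a <- pose_set(lapply(1:5, function(i) translate(hex, rnorm(3, 0, 3))), "L", "eA")
  b <- pose_set(lapply(1:4, function(i) translate(hex, rnorm(3, 0, 3))), "L", "eB")
  pr <- match_poses(a, b, threshold = 50)
  reg <- derive_region(pr, pad = 2)
  xyz <- do.call(rbind, lapply(c(pr$atoms_a, pr$atoms_b),
                               function(x) cbind(x$x, x$y, x$z)))
  expect_true(all(region_contains(reg, xyz, "sphere")))
  expect_true(all(region_contains(reg, xyz, "box")))
})

test_that("flexible residues honor mutated > polar > spread priority tiers", {
  rec <- toy_pocket()
  mutated <- attr(rec, "mutated")
  reg <- seed_region(rec, "A:1", sphere_radius = 18)
  sel <- select_flexible_residues(rec, reg, n = 10, mutated = mutated)
  expect_equal(nrow(sel), 10)
  expect_setequal(sel$resno[sel$tag == "mutated"], mutated)
  # all mutated first, then polar before any spread pick
  expect_equal(sel$tag[seq_along(mutated)], rep("mutated", length(mutated)))
  first_spread <- match("spread", sel$tag)
  if (!is.na(first_spread)) {
    expect_false(any(sel$tag[seq_len(first_spread)] == "polar" &
                       seq_len(first_spread) > first_spread))
  }
  # n = 1 with a mutated residue present -> exactly that tier fires
  sel1 <- select_flexible_residues(rec, reg, n = 1, mutated = mutated)
  expect_equal(sel1$tag, "mutated")

  # greedy farthest-point spread equals an independent reimplementation
  sel_polar <- select_flexible_residues(rec, reg, n = 10, mutated = integer())
  cand <- unique(rec[!rec$is_hetero &
                       !rec$name %in% c("N", "CA", "C", "O"), ]$resno)
  # independent greedy: side-chain centroids, start farthest from pool mean
  side <- rec[!rec$name %in% c("N", "CA", "C", "O"), ]
  cents <- do.call(rbind, lapply(split(side, side$resno), function(r) {
    c(resno = r$resno[1], colMeans(cbind(r$x, r$y, r$z)))
  }))
  cents <- cents[order(cents[, 1]), ]
  polar_names <- c("SER", "THR", "TYR", "CYS", "ASN", "GLN", "HIS", "LYS",
                   "ARG", "ASP", "GLU")
  resnames <- vapply(split(side, side$resno),
                     function(r) r$resname[1], character(1))
  resnames <- resnames[order(as.integer(names(resnames)))]
  in_reg <- sqrt(rowSums(sweep(cents[, 2:4], 2, reg$center)^2)) <
    reg$sphere_radius + 5 # every toy side chain is inside r = 18 anyway
  pool <- which(resnames %in% polar_names)
  chosen <- integer()
  while (length(chosen) < min(10, length(pool))) {
    remaining <- setdiff(pool, chosen)
    score <- vapply(remaining, function(i) {
      if (!length(chosen)) {
        ref <- colMeans(cents[remaining, 2:4, drop = FALSE])
        sqrt(sum((cents[i, 2:4] - ref)^2))
      } else {
        min(sqrt(rowSums(sweep(cents[chosen, 2:4, drop = FALSE], 2,
                               cents[i, 2:4])^2)))
      }
    }, numeric(1))
    chosen <- c(chosen, remaining[which.max(score)])
  }
  expect_equal(sel_polar$resno[sel_polar$tag == "polar"],
               as.integer(unname(cents[chosen, 1]))[
                 seq_len(sum(sel_polar$tag == "polar"))])

  expect_warning(
    few <- select_flexible_residues(rec, seed_region(rec, "A:1",
                                                     sphere_radius = 4),
                                    n = 10),
    "returning all")
  expect_lte(nrow(few), 10)
})

test_that("redundancy removal keeps the best-ranked member of each mode", {
  hex <- make_symmetric_ligand(6, 1.4)
  # 3 planted modes, 7 near-duplicates each (within 0.6 A), modes 15 A apart
  set.seed(101)
  centers <- list(c(0, 0, 0), c(15, 0, 0), c(0, 15, 0))
  atoms_a <- list()
  mode_of <- integer()
  for (m in 1:3) {
    for (r in 1:7) {
      atoms_a <- c(atoms_a, list(translate(hex, centers[[m]] + rnorm(3, 0, 0.2))))
      mode_of <- c(mode_of, m)
    }
  }
  pairs <- tibble::tibble(
    ligand_id = "L", idx_a = seq_along(atoms_a), idx_b = seq_along(atoms_a),
    rmsd = 0.5, atoms_a = atoms_a, atoms_b = atoms_a)
  rank_order <- sample(nrow(pairs)) # Borda order, best first
  kept <- deduplicate_pairs(pairs, order = rank_order)
  expect_equal(nrow(kept), 3)
  expect_setequal(mode_of[kept$idx_a], 1:3)
  # each kept pair is the best-ranked of its mode
  for (k in kept$idx_a) {
    same_mode <- which(mode_of == mode_of[k])
    expect_equal(k, same_mode[which.min(match(same_mode, rank_order))])
  }
  # kept pairs are pairwise beyond the redundancy radius
  d <- pairwise_rmsd_matrix(kept$atoms_a)
  expect_true(all(d[upper.tri(d)] > 2))

  # 5 identical pairs -> 1; cap respected for mutually distant pairs
  ident <- pairs[rep(1, 5), ]
  expect_equal(nrow(deduplicate_pairs(ident)), 1)
  distant <- tibble::tibble(
    ligand_id = "L", idx_a = 1:25, idx_b = 1:25,
    rmsd = 0.5,
    atoms_a = lapply(1:25, function(i) translate(hex, c(10 * i, 0, 0))))
  distant$atoms_b <- distant$atoms_a
  expect_equal(nrow(deduplicate_pairs(distant)), 20)
  expect_equal(nrow(deduplicate_pairs(pairs[0, ])), 0)
})
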