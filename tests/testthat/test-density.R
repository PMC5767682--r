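one_atom <- function(x = 0, y = 0, z = 0, element = "C") {
  as_atoms(data.frame(element = element, x = x, y = y, z = z))
}

test_that("simulated maps peak at atoms and integrate to the Gaussian integral", {
  g <- simulate_map(one_atom(0.2, -0.3, 0.1), resolution = 5, voxel = 1)
  peak <- which(g$values == max(g$values), arr.ind = TRUE)[1, ]
  ax <- list(x = g$origin[1] + (seq_len(dim(g$values)[1]) - 1) * g$voxel[1],
             y = g$origin[2] + (seq_len(dim(g$values)[2]) - 1) * g$voxel[2],
             z = g$origin[3] + (seq_len(dim(g$values)[3]) - 1) * g$voxel[3])
  expect_lte(abs(ax$x[peak[1]] - 0.2), g$voxel[1] / 2 + 1e-9)
  expect_lte(abs(ax$y[peak[2]] + 0.3), g$voxel[2] / 2 + 1e-9)
  expect_lte(abs(ax$z[peak[3]] - 0.1), g$voxel[3] / 2 + 1e-9)

  # voxel sum x voxel volume ~ amplitude * (2 pi sigma^2)^(3/2)
  fine <- simulate_map(one_atom(), resolution = 5, voxel = 0.5, pad = 12)
  sigma <- 5 / (2 * sqrt(2 * log(2)))
  analytic <- 6 * (2 * pi * sigma^2)^(3 / 2)
  expect_equal(sum(fine$values) * prod(fine$voxel), analytic,
               tolerance = 0.01)

  # two well-separated atoms give two local maxima with a valley between
  two <- simulate_map(as_atoms(data.frame(element = "C", x = c(0, 15),
                                          y = 0, z = 0)),
                      resolution = 5, voxel = 1)
  at <- function(p) {
    idx <- round((p - two$origin) / two$voxel) + 1
    two$values[idx[1], idx[2], idx[3]]
  }
  expect_gt(at(c(0, 0, 0)), 10 * at(c(7.5, 0, 0)))
  expect_gt(at(c(15, 0, 0)), 10 * at(c(7.5, 0, 0)))
  expect_error(simulate_map(one_atom()[0, ], resolution = 5), "empty")
  expect_error(simulate_map(one_atom(), resolution = 1, voxel = 1),
               "twice the voxel")
})

test_that("cross-correlation: self, negation, and direct recomputation", {
  set.seed(201)
  g <- simulate_map(random_pose(c("C", "N", "O"), span = 3),
                    resolution = 6, voxel = 1.5)
  expect_equal(ccc(g, g), 1.0)
  neg <- density_grid(-g$values, g$voxel, g$origin)
  expect_equal(ccc(g, neg), -1.0)
  shuffled <- density_grid(
    array(sample(as.numeric(g$values)), dim(g$values)), g$voxel, g$origin)
  # independent two-pass Pearson
  a <- as.numeric(g$values); b <- as.numeric(shuffled$values)
  r <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(ccc(g, shuffled), r, tolerance = 1e-12)
  flat <- density_grid(array(1, dim(g$values)), g$voxel, g$origin)
  expect_error(ccc(g, flat), "zero-variance")
  other <- density_grid(g$values, g$voxel * 2, g$origin)
  expect_error(ccc(g, other), "congruent")
})

test_that("scores are symmetric and scale invariant", {
  set.seed(211)
  g1 <- simulate_map(random_pose(c("C", "N"), span = 2), 6, 1.5)
  g2 <- density_grid(array(runif(length(g1$values)), dim(g1$values)),
                     g1$voxel, g1$origin)
  expect_equal(ccc(g1, g2), ccc(g2, g1))
  expect_equal(manders_overlap(g1, g2), manders_overlap(g2, g1))
  g1s <- density_grid(g1$values * 7.3, g1$voxel, g1$origin)
  expect_equal(ccc(g1s, g2), ccc(g1, g2), tolerance = 1e-12)
  expect_equal(manders_overlap(g1s, g2), manders_overlap(g1, g2),
               tolerance = 1e-12)
})

test_that("Manders overlap: identical 1, disjoint 0, formula on random grids", {
  set.seed(221)
  dims <- c(6, 5, 4)
  a <- array(runif(prod(dims)), dims)
  ga <- density_grid(a, 1)
  expect_equal(manders_overlap(ga, ga), 1.0)
  b <- array(0, dims); b[1:3, , ] <- runif(3 * 5 * 4)
  c_ <- array(0, dims); c_[4:6, , ] <- runif(3 * 5 * 4)
  expect_equal(manders_overlap(density_grid(b, 1), density_grid(c_, 1)), 0)
  d <- array(runif(prod(dims)), dims)
  got <- manders_overlap(ga, density_grid(d, 1))
  expect_equal(got, sum(a * d) / sqrt(sum(a^2) * sum(d^2)),
               tolerance = 1e-12)
  zero <- density_grid(array(0, dims), 1)
  expect_error(manders_overlap(ga, zero), "zero-norm")
})

test_that("segment CCC is ~1 against the model's own map and low when displaced", {
  # sparse shell so the displaced segment leaves a clear density hole
  rec <- make_toy_receptor(20, pocket_center = c(0, 0, 0), shell_radius = 12)
  seg <- segment("A", 5, 8)
  own <- simulate_map(rec, resolution = 6.2, voxel = 1.5)
  expect_gte(segment_ccc(rec, seg, own, resolution = 6.2), 0.99)
  planted <- make_planted_density(rec, displaced_segment = seg,
                                  displacement = c(10, 0, 0))
  expect_lt(segment_ccc(rec, seg, planted, resolution = 6.2), 0.2)
  expect_error(segment_atom_indices(rec, segment("A", 900, 910)),
               "no atoms")
})

test_that("loop ranking puts the density-tracing candidate first", {
  rec <- make_toy_receptor(20, pocket_center = c(0, 0, 0), shell_radius = 12)
  seg <- segment("A", 5, 8)
  exp_map <- make_planted_density(rec, displaced_segment = seg,
                                  displacement = c(8, 0, 0))
  # candidate 3 traces the displaced density; 1, 2, 4 keep or worsen it
  shift_seg <- function(model, v) {
    idx <- condock:::segment_atom_indices(model, seg)
    model$x[idx] <- model$x[idx] + v[1]
    model$y[idx] <- model$y[idx] + v[2]
    model
  }
  candidates <- list(rec, shift_seg(rec, c(-4, 0, 0)),
                     shift_seg(rec, c(8, 0, 0)), shift_seg(rec, c(0, 6, 0)))
  ranked <- rank_loops(candidates, seg, exp_map, resolution = 6.2)
  expect_equal(ranked$candidate[1], 3)
  expect_true(ranked$is_best[1])
  expect_gte(ranked$sccc[1], 0.99)
  # identical candidates tie-break by input order
  same <- rank_loops(list(rec, rec), seg, exp_map, resolution = 6.2)
  expect_equal(same$candidate, c(1, 2))
  single <- rank_loops(list(rec), seg, exp_map, resolution = 6.2)
  expect_equal(nrow(single), 1)
})

test_that("MRC round trip preserves geometry and values at float precision", {
  set.seed(231)
  g <- simulate_map(random_pose(c("C", "N", "O", "S"), span = 4),
                    resolution = 6, voxel = 1.25)
  path <- tempfile(fileext = ".mrc")
  write_mrc(g, path)
  back <- read_mrc(path)
  expect_equal(dim(back$values), dim(g$values))
  expect_equal(back$voxel, g$voxel, tolerance = 1e-6)
  expect_equal(back$origin, g$origin, tolerance = 1e-5)
  expect_equal(as.numeric(back$values), as.numeric(g$values),
               tolerance = 1e-6)
  expect_equal(ccc(g, back), 1.0, tolerance = 1e-9)
})

test_that("regrid reproduces values on a congruent or shifted grid", {
  set.seed(241)
  g <- simulate_map(random_pose(c("C", "N", "O"), span = 3),
                    resolution = 6, voxel = 1)
  same <- regrid(g, g)
  expect_equal(same$values, g$values, tolerance = 1e-12)
  # half-voxel shift: trilinear interpolation = midpoint averages along x
  tmpl <- density_grid(g$values, g$voxel, g$origin + c(0.5, 0, 0))
  shifted <- regrid(g, tmpl)
  nx <- dim(g$values)[1]
  expect_equal(shifted$values[1:(nx - 1), , ],
               (g$values[1:(nx - 1), , ] + g$values[2:nx, , ]) / 2,
               tolerance = 1e-12)
})
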