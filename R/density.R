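#' Density grids
#'
#' A `density_grid` is a 3D scalar field on a regular orthogonal grid:
#' `values` (array, x fastest), `voxel` (Angstrom per axis, length 3) and
#' `origin` (Cartesian position of the center of voxel `[1,1,1]`,
#' Angstrom). It backs the model-to-map fit scores (cross-correlation and
#' Manders' overlap).
#'
#' @param values numeric 3D array.
#' @param voxel voxel size per axis, Angstrom (scalar or length 3).
#' @param origin 3-vector, Angstrom.
#' @return a `density_grid`.
#' @export
density_grid <- function(values, voxel, origin = c(0, 0, 0)) {
  voxel <- rep_len(as.numeric(voxel), 3)
  if (any(voxel <= 0)) abort("voxel sizes must be positive")
  if (!all(is.finite(values))) abort("non-finite density values")
  if (length(dim(values)) != 3) abort("values must be a 3D array")
  structure(list(values = values, voxel = voxel,
                 origin = as.numeric(origin)),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("<density grid> %s voxels; voxel %.2f x %.2f x %.2f A; origin (%.1f, %.1f, %.1f)\n",
              paste(dim(x$values), collapse = " x "),
              x$voxel[1], x$voxel[2], x$voxel[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

congruent_grids <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$voxel - b$voxel) < 1e-6) &&
    all(abs(a$origin - b$origin) < 1e-4)
}

grid_axes <- function(g) {
  dims <- dim(g$values)
  list(x = g$origin[1] + (seq_len(dims[1]) - 1) * g$voxel[1],
       y = g$origin[2] + (seq_len(dims[2]) - 1) * g$voxel[2],
       z = g$origin[3] + (seq_len(dims[3]) - 1) * g$voxel[3])
}

#' Simulate a density map from atomic coordinates
#'
#' Each atom contributes a spherical Gaussian centered on its position
#' with amplitude proportional to its atomic number. The Gaussian width
#' follows the FWHM convention by default — `sigma = resolution /
#' (2 * sqrt(2 * log(2)))`, i.e. the map resolution is read as the full
#' width at half maximum of the point-spread function; the historical
#' `resolution / pi` width used by some fitting tools is selectable,
#' since segment scores reported by different tools depend on this
#' convention.
#'
#' @param model atom tibble.
#' @param resolution nominal map resolution, Angstrom; must exceed twice
#'   the voxel size (Nyquist).
#' @param voxel voxel size, Angstrom.
#' @param sigma_convention `"fwhm"` (default) or `"res_over_pi"`.
#' @param pad padding around the model extent, Angstrom.
#' @param grid optional template `density_grid`: simulate onto its exact
#'   geometry (ignores `voxel`/`pad`), guaranteeing congruence with an
#'   experimental map.
#' @return a `density_grid`.
#' @export
simulate_map <- function(model, resolution, voxel = 1.0,
                         sigma_convention = c("fwhm", "res_over_pi"),
                         pad = NULL, grid = NULL) {
  sigma_convention <- match.arg(sigma_convention)
  model <- heavy_atoms(as_atoms(model))
  if (nrow(model) == 0) abort("empty model")
  sigma <- switch(sigma_convention,
                  fwhm = resolution / (2 * sqrt(2 * log(2))),
                  res_over_pi = resolution / pi)
  if (is.null(grid)) {
    if (resolution <= 2 * voxel) {
      abort("resolution must exceed twice the voxel size")
    }
    pad <- pad %||% (3 * sigma)
    lo <- c(min(model$x), min(model$y), min(model$z)) - pad
    hi <- c(max(model$x), max(model$y), max(model$z)) + pad
    dims <- pmax(2L, as.integer(ceiling((hi - lo) / voxel)) + 1L)
    g <- density_grid(array(0, dims), voxel, lo)
  } else {
    g <- density_grid(array(0, dim(grid$values)), grid$voxel, grid$origin)
  }
  ax <- grid_axes(g)
  vals <- g$values
  amp <- atomic_number(model$element)
  cut <- 4 * sigma
  for (i in seq_len(nrow(model))) {
    p <- c(model$x[i], model$y[i], model$z[i])
    ix <- which(abs(ax$x - p[1]) <= cut)
    iy <- which(abs(ax$y - p[2]) <= cut)
    iz <- which(abs(ax$z - p[3]) <= cut)
    if (!length(ix) || !length(iy) || !length(iz)) next
    gx <- exp(-(ax$x[ix] - p[1])^2 / (2 * sigma^2))
    gy <- exp(-(ax$y[iy] - p[2])^2 / (2 * sigma^2))
    gz <- exp(-(ax$z[iz] - p[3])^2 / (2 * sigma^2))
    vals[ix, iy, iz] <- vals[ix, iy, iz] +
      amp[i] * (gx %o% gy %o% gz)
  }
  g$values <- vals
  g
}

#' Cross-correlation between two density grids
#'
#' Pearson correlation of voxel values, optionally restricted to a voxel
#' mask. Grids must be congruent (same shape, voxel size and origin);
#' use [regrid()] first when they are not.
#'
#' @param a,b `density_grid`s.
#' @param mask optional logical array of the same shape.
#' @return correlation in `[-1, 1]`.
#' @export
ccc <- function(a, b, mask = NULL) {
  if (!congruent_grids(a, b)) abort("grids are not congruent; use regrid()")
  va <- as.numeric(a$values); vb <- as.numeric(b$values)
  if (!is.null(mask)) {
    m <- as.logical(mask)
    if (length(m) != length(va)) abort("mask shape mismatch")
    if (!any(m)) abort("empty mask")
    va <- va[m]; vb <- vb[m]
  }
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    abort("zero-variance input to cross-correlation")
  }
  cor(va, vb)
}

#' Manders' overlap coefficient
#'
#' Normalized inner product of two nonnegative density grids over a mask:
#' `sum(a * b) / sqrt(sum(a^2) * sum(b^2))`. Values below zero are
#' clamped to zero before the product, as the coefficient is defined for
#' nonnegative signals. Ranges from 0 (disjoint support) to 1 (identical
#' up to positive scale).
#'
#' @inheritParams ccc
#' @return overlap coefficient in `[0, 1]`.
#' @export
manders_overlap <- function(a, b, mask = NULL) {
  if (!congruent_grids(a, b)) abort("grids are not congruent; use regrid()")
  va <- pmax(as.numeric(a$values), 0)
  vb <- pmax(as.numeric(b$values), 0)
  if (!is.null(mask)) {
    m <- as.logical(mask)
    if (!any(m)) abort("empty mask")
    va <- va[m]; vb <- vb[m]
  }
  denom <- sqrt(sum(va^2) * sum(vb^2))
  if (denom == 0) abort("zero-norm input to Manders' overlap")
  sum(va * vb) / denom
}

#' Structure segments
#'
#' A segment names one or more residue ranges on named chains, defining a
#' local model region (e.g. the TM1-TM2 loop) for segment-based fit
#' scores.
#'
#' @param chain chain id (recycled against ranges).
#' @param from,to inclusive residue-number range(s).
#' @return a `condock_segment`.
#' @export
segment <- function(chain, from, to) {
  stopifnot(length(from) == length(to), all(to >= from))
  structure(list(chain = rep_len(chain, length(from)),
                 from = as.integer(from), to = as.integer(to)),
            class = "condock_segment")
}

segment_atom_indices <- function(model, seg) {
  idx <- logical(nrow(model))
  for (k in seq_along(seg$from)) {
    idx <- idx | (model$chain == seg$chain[k] &
                    model$resno >= seg$from[k] & model$resno <= seg$to[k])
  }
  out <- which(idx)
  if (!length(out)) abort("segment matches no atoms in the model")
  out
}

#' Segment-based cross-correlation coefficient (SCCC)
#'
#' Local fit score of a model region against an experimental map: the
#' Pearson correlation between the experimental map and the model's
#' simulated map, restricted to voxels within `mask_radius` of the
#' segment's atoms. High values mean the segment traces its density;
#' a displaced or misfolded segment scores near zero.
#'
#' @param model atom tibble.
#' @param seg a [segment()].
#' @param exp_map experimental `density_grid`.
#' @param resolution simulation resolution, Angstrom.
#' @param mask_radius mask radius around segment atoms, Angstrom.
#' @param sigma_convention passed to [simulate_map()].
#' @return correlation in `[-1, 1]`.
#' @export
segment_ccc <- function(model, seg, exp_map, resolution,
                        mask_radius = 3,
                        sigma_convention = c("fwhm", "res_over_pi")) {
  model <- as_atoms(model)
  sim <- simulate_map(model, resolution, grid = exp_map,
                      sigma_convention = match.arg(sigma_convention))
  mask <- segment_mask(model, seg, exp_map, mask_radius)
  ccc(exp_map, sim, mask)
}

segment_mask <- function(model, seg, grid, mask_radius) {
  idx <- segment_atom_indices(model, seg)
  seg_atoms <- heavy_atoms(model[idx, , drop = FALSE])
  ax <- grid_axes(grid)
  dims <- dim(grid$values)
  mask <- array(FALSE, dims)
  xyz <- coords(seg_atoms)
  for (i in seq_len(nrow(xyz))) {
    ix <- which(abs(ax$x - xyz[i, 1]) <= mask_radius)
    iy <- which(abs(ax$y - xyz[i, 2]) <= mask_radius)
    iz <- which(abs(ax$z - xyz[i, 3]) <= mask_radius)
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx2 <- (ax$x[ix] - xyz[i, 1])^2
    dy2 <- (ax$y[iy] - xyz[i, 2])^2
    dz2 <- (ax$z[iz] - xyz[i, 3])^2
    ball <- outer(outer(dx2, dy2, "+"), dz2, "+") <= mask_radius^2
    mask[ix, iy, iz] <- mask[ix, iy, iz] | ball
  }
  if (!any(mask)) abort("segment mask is empty on this grid")
  mask
}

#' Rank candidate loop models by segment fit
#'
#' Orders candidate models (e.g. alternative loop conformations from a
#' loop-modelling run) by their [segment_ccc()] against the experimental
#' map, best first. Ties keep input order.
#'
#' @param candidates list of atom tibbles.
#' @param seg a [segment()].
#' @param exp_map experimental `density_grid`.
#' @param resolution simulation resolution, Angstrom.
#' @param ... passed to [segment_ccc()].
#' @return tibble `candidate`, `sccc`, `rank`, `is_best`, sorted by rank.
#' @export
rank_loops <- function(candidates, seg, exp_map, resolution, ...) {
  if (!length(candidates)) abort("no candidates")
  sccc <- map_dbl(candidates, function(m) {
    segment_ccc(m, seg, exp_map, resolution, ...)
  })
  ord <- order(-sccc, seq_along(sccc))
  tibble(candidate = ord, sccc = sccc[ord],
         rank = seq_along(ord), is_best = seq_along(ord) == 1)
}

#' Resample a density grid onto a template geometry
#'
#' Trilinear interpolation of `g` at the voxel centers of `template`.
#' Points outside `g` get `fill`. Congruence with `template` is exact by
#' construction, so downstream scores are bit-stable.
#'
#' @param g `density_grid` to resample.
#' @param template `density_grid` whose geometry to adopt.
#' @param fill value for out-of-bounds points.
#' @return a `density_grid` congruent with `template`.
#' @export
regrid <- function(g, template, fill = 0) {
  ax_t <- grid_axes(template)
  dims_t <- dim(template$values)
  dims_g <- dim(g$values)
  # fractional indices of template voxel centers in g's index space
  fx <- (ax_t$x - g$origin[1]) / g$voxel[1] + 1
  fy <- (ax_t$y - g$origin[2]) / g$voxel[2] + 1
  fz <- (ax_t$z - g$origin[3]) / g$voxel[3] + 1
  out <- array(fill, dims_t)
  interp1 <- function(f, n) {
    i0 <- floor(f); w <- f - i0
    ok <- i0 >= 1 & i0 <= n - 1
    # clamp exact upper boundary
    at_end <- abs(f - n) < 1e-9
    i0[at_end] <- n - 1; w[at_end] <- 1; ok[at_end] <- n > 1
    list(i0 = i0, w = w, ok = ok)
  }
  X <- interp1(fx, dims_g[1]); Y <- interp1(fy, dims_g[2])
  Z <- interp1(fz, dims_g[3])
  for (k in which(Z$ok)) {
    for (j in which(Y$ok)) {
      i <- which(X$ok)
      if (!length(i)) next
      c00 <- g$values[cbind(X$i0[i], Y$i0[j], Z$i0[k])] * (1 - X$w[i]) +
        g$values[cbind(X$i0[i] + 1, Y$i0[j], Z$i0[k])] * X$w[i]
      c10 <- g$values[cbind(X$i0[i], Y$i0[j] + 1, Z$i0[k])] * (1 - X$w[i]) +
        g$values[cbind(X$i0[i] + 1, Y$i0[j] + 1, Z$i0[k])] * X$w[i]
      c01 <- g$values[cbind(X$i0[i], Y$i0[j], Z$i0[k] + 1)] * (1 - X$w[i]) +
        g$values[cbind(X$i0[i] + 1, Y$i0[j], Z$i0[k] + 1)] * X$w[i]
      c11 <- g$values[cbind(X$i0[i], Y$i0[j] + 1, Z$i0[k] + 1)] * (1 - X$w[i]) +
        g$values[cbind(X$i0[i] + 1, Y$i0[j] + 1, Z$i0[k] + 1)] * X$w[i]
      c0 <- c00 * (1 - Y$w[j]) + c10 * Y$w[j]
      c1 <- c01 * (1 - Y$w[j]) + c11 * Y$w[j]
      out[i, j, k] <- c0 * (1 - Z$w[k]) + c1 * Z$w[k]
    }
  }
  density_grid(out, template$voxel, template$origin)
}

#' Read and write MRC/CCP4 density maps
#'
#' Minimal reader/writer for the MRC2014 single-volume format (mode 2,
#' 32-bit float), the interchange format of cryo-EM maps. Axis order is
#' normalized to x-fastest on read; the origin is taken from the ORIGIN
#' header words when set, else from the start offsets and cell. No R
#' package on hand parses MRC, so the 1024-byte fixed header is handled
#' directly here.
#'
#' @param path file path.
#' @return `read_mrc()` returns a `density_grid`.
#' @export
read_mrc <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_int <- readBin(con, integer(), n = 256, size = 4, endian = "little")
  seek(con, 0)
  hdr_flt <- readBin(con, numeric(), n = 256, size = 4, endian = "little")
  nxyz <- hdr_int[1:3]
  mode <- hdr_int[4]
  if (mode != 2) abort(paste0("unsupported MRC mode ", mode, " (only mode 2)"))
  nstart <- hdr_int[5:7]
  mxyz <- hdr_int[8:10]
  cella <- hdr_flt[11:13]
  mapcrs <- hdr_int[17:19]
  origin_hdr <- hdr_flt[50:52]
  voxel <- cella / mxyz
  seek(con, 1024 + 4 * hdr_int[24]) # skip extended header (NSYMBT bytes)
  vals <- readBin(con, numeric(), n = prod(nxyz), size = 4,
                  endian = "little")
  arr <- array(vals, nxyz)
  # normalize axis order: mapc/mapr/maps give the crystallographic axis of
  # each file dimension; permute so dimension 1 is x, 2 is y, 3 is z
  perm <- order(mapcrs)
  if (!all(perm == 1:3)) {
    arr <- aperm(arr, perm)
    nstart <- nstart[perm]
  }
  # cella/mxyz is already per crystallographic axis (x, y, z)
  origin <- if (any(origin_hdr != 0)) origin_hdr else nstart * voxel
  density_grid(arr, voxel, origin)
}

#' @rdname read_mrc
#' @param g a `density_grid` to write.
#' @return `write_mrc()` returns `path` invisibly.
#' @export
write_mrc <- function(g, path) {
  dims <- dim(g$values)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(dims)                     # NX NY NZ
  wi(2)                        # MODE 2: float32
  wi(c(0, 0, 0))               # NXSTART..
  wi(dims)                     # MX MY MZ
  wf(dims * g$voxel)           # CELLA
  wf(c(90, 90, 90))            # CELLB
  wi(c(1, 2, 3))               # MAPC MAPR MAPS
  v <- as.numeric(g$values)
  wf(c(min(v), max(v), mean(v)))  # DMIN DMAX DMEAN
  wi(c(1, 0))                  # ISPG NSYMBT
  wi(rep(0, 25))               # EXTRA (words 25-49)
  wf(g$origin)                 # ORIGIN
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con) # MACHST little-endian
  wf(stats::sd(v))             # RMS
  wi(0)                        # NLABL
  writeBin(raw(800), con)      # labels
  wf(v)
  invisible(path)
}
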