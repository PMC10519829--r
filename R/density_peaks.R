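# Electron-density map analysis: sigma-level computation, peak detection,
# fixed-radius sphere integration and per-site totals, plus CCP4/MRC
# (mode-2 float) map input/output written directly with readBin/writeBin
# since no installed R package handles the format.

#' Construct a density grid
#'
#' A regular orthorhombic 3D scalar map.  Voxel `[i, j, k]` has its centre
#' at `origin + (c(i, j, k) - 1) * spacing`.
#'
#' @param values 3D numeric array (x, y, z order), finite.
#' @param spacing Voxel spacing per axis, Angstrom (> 0); scalar recycled.
#' @param origin Position of the first voxel centre, Angstrom.
#' @return Object of class `density_grid`.
#' @export
density_grid <- function(values, spacing = 1, origin = c(0, 0, 0)) {
  if (length(dim(values)) != 3) stop("values must be a 3D array")
  if (!all(is.finite(values))) stop("map contains non-finite values")
  spacing <- rep(as.numeric(spacing), length.out = 3)
  if (any(spacing <= 0)) stop("voxel spacing must be positive")
  structure(list(values = values, spacing = spacing,
                 origin = as.numeric(origin)), class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  d <- dim(x$values)
  cat("<density_grid> ", d[1], "x", d[2], "x", d[3], " voxels, spacing ",
      paste(signif(x$spacing, 4), collapse = "/"), " A\n", sep = "")
  invisible(x)
}

#' Sigma level of a density map
#'
#' Population standard deviation of all voxel values about the map mean
#' (mFo-DFc difference maps are near zero-mean, so this closely matches the
#' about-zero convention; set `about_zero = TRUE` to use the latter).
#'
#' @param grid A [density_grid()].
#' @param about_zero Compute the RMS about zero instead of about the mean.
#' @return Sigma in map value units.  A constant map yields 0 with a
#'   warning.
#' @export
map_sigma <- function(grid, about_zero = FALSE) {
  v <- as.numeric(grid$values)
  if (length(v) < 2) stop("sigma needs at least 2 voxels")
  s <- if (about_zero) sqrt(mean(v^2)) else sqrt(mean((v - mean(v))^2))
  if (s == 0) warning("constant map: sigma is 0")
  s
}

#' Find density peaks above a sigma level
#'
#' A peak is a voxel strictly greater than all 26 neighbours whose
#' mean-subtracted value reaches `level * sigma` (so detection is invariant
#' under adding a constant to the map).  Boundary voxels are compared
#' against their existing neighbours only.
#'
#' @param grid A [density_grid()].
#' @param level Threshold in multiples of sigma (default 3.0).
#' @param sigma Optional precomputed sigma; default [map_sigma()].
#' @return Object of class `peak_list`: data.frame with voxel indices,
#'   positions (Angstrom, voxel centres) and raw values, ordered by
#'   decreasing value; plus `level` and `sigma`.
#' @export
find_peaks <- function(grid, level = 3.0, sigma = NULL) {
  v <- grid$values
  if (is.null(sigma)) sigma <- suppressWarnings(map_sigma(grid))
  if (sigma <= 0) {
    return(structure(list(peaks = data.frame(
      i = integer(0), j = integer(0), k = integer(0), x = numeric(0),
      y = numeric(0), z = numeric(0), value = numeric(0)),
      level = level, sigma = sigma), class = "peak_list"))
  }
  d <- dim(v)
  vc <- v - mean(v)
  is_max <- vc >= level * sigma
  shifts <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  shifts <- shifts[!(shifts$dx == 0 & shifts$dy == 0 & shifts$dz == 0), ]
  pad <- array(-Inf, d + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- v
  for (s in seq_len(nrow(shifts))) {
    nb <- pad[(2:(d[1] + 1)) + shifts$dx[s],
              (2:(d[2] + 1)) + shifts$dy[s],
              (2:(d[3] + 1)) + shifts$dz[s]]
    is_max <- is_max & (v > nb)
    if (!any(is_max)) break
  }
  idx <- which(is_max, arr.ind = TRUE)
  pos <- sweep(sweep(idx - 1, 2, grid$spacing, "*"), 2, grid$origin, "+")
  pk <- data.frame(i = idx[, 1], j = idx[, 2], k = idx[, 3],
                   x = pos[, 1], y = pos[, 2], z = pos[, 3],
                   value = v[idx])
  pk <- pk[order(-pk$value), , drop = FALSE]
  rownames(pk) <- NULL
  structure(list(peaks = pk, level = level, sigma = sigma),
            class = "peak_list")
}

#' @export
print.peak_list <- function(x, ...) {
  cat("<peak_list>", nrow(x$peaks), "peaks at", x$level, "sigma (sigma =",
      signif(x$sigma, 4), ")\n")
  invisible(x)
}

#' Integrate density in a sphere
#'
#' Sum of `value * voxel_volume` over voxels whose centres lie within
#' `radius` of `center` (voxel-centre-in-sphere rule; no partial-voxel
#' weighting, so the voxelization error is bounded by the surface-shell
#' volume).  Spheres reaching outside the grid are clipped with a warning.
#'
#' @param grid A [density_grid()].
#' @param center Length-3 position, Angstrom.
#' @param radius Sphere radius, Angstrom (default 3.5).
#' @return Integrated density, value units x Angstrom^3.
#' @export
integrate_sphere <- function(grid, center, radius = 3.5) {
  if (radius <= 0) stop("radius must be positive")
  d <- dim(grid$values); sp <- grid$spacing; o <- grid$origin
  hi <- o + (d - 1) * sp
  if (any(center - radius < o - sp / 2) || any(center + radius > hi + sp / 2))
    warning("integration sphere extends beyond the grid; clipped")
  rng <- lapply(1:3, function(ax) {
    lo <- max(1L, ceiling((center[ax] - radius - o[ax]) / sp[ax]) + 1L)
    up <- min(d[ax], floor((center[ax] + radius - o[ax]) / sp[ax]) + 1L)
    if (lo > up) integer(0) else lo:up
  })
  if (any(lengths(rng) == 0)) return(0)
  xs <- o[1] + (rng[[1]] - 1) * sp[1]
  ys <- o[2] + (rng[[2]] - 1) * sp[2]
  zs <- o[3] + (rng[[3]] - 1) * sp[3]
  dx2 <- (xs - center[1])^2
  dy2 <- (ys - center[2])^2
  dz2 <- (zs - center[3])^2
  r2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
  sub <- grid$values[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
  sum(sub[r2 <= radius^2]) * prod(sp)
}

#' Total integrated peak density in a site
#'
#' Implements the per-site total of the difference-density procedure: peaks
#' at `level` sigma are filtered to the site region (a sphere), a sphere of
#' `radius` is integrated around each, and the integrals are summed.
#' Overlapping peak spheres double-count by design ("the integrals are
#' added"); `dedupe = TRUE` switches to a union-of-spheres integral.
#'
#' @param grid A [density_grid()].
#' @param site_center Length-3 region centre, Angstrom.
#' @param site_radius Region radius, Angstrom (default 8).
#' @param level Peak threshold in sigma units (default 3.0).
#' @param radius Integration sphere radius (default 3.5 Angstrom).
#' @param dedupe Integrate the union of spheres instead of summing.
#' @param peaks Optional precomputed [find_peaks()] result.
#' @return Object of class `site_integral`: `total`, `n_peaks`, `peaks`
#'   (with per-peak integrals), `radius`, `level`.
#' @export
site_total <- function(grid, site_center, site_radius = 8, level = 3.0,
                       radius = 3.5, dedupe = FALSE, peaks = NULL) {
  if (is.null(peaks)) peaks <- find_peaks(grid, level)
  pk <- peaks$peaks
  if (nrow(pk)) {
    d2 <- (pk$x - site_center[1])^2 + (pk$y - site_center[2])^2 +
      (pk$z - site_center[3])^2
    pk <- pk[d2 <= site_radius^2, , drop = FALSE]
  }
  if (!nrow(pk)) {
    return(structure(list(total = 0, n_peaks = 0L, peaks = pk,
                          radius = radius, level = level),
                     class = "site_integral"))
  }
  if (!dedupe) {
    ints <- vapply(seq_len(nrow(pk)), function(i)
      integrate_sphere(grid, c(pk$x[i], pk$y[i], pk$z[i]), radius),
      numeric(1))
    pk$integral <- ints
    total <- sum(ints)
  } else {
    d <- dim(grid$values); sp <- grid$spacing; o <- grid$origin
    ax <- lapply(1:3, function(a) o[a] + (seq_len(d[a]) - 1) * sp[a])
    inside <- array(FALSE, d)
    for (i in seq_len(nrow(pk))) {
      r2 <- outer(outer((ax[[1]] - pk$x[i])^2, (ax[[2]] - pk$y[i])^2, "+"),
                  (ax[[3]] - pk$z[i])^2, "+")
      inside <- inside | (r2 <= radius^2)
    }
    total <- sum(grid$values[inside]) * prod(sp)
    pk$integral <- NA_real_
  }
  structure(list(total = total, n_peaks = nrow(pk), peaks = pk,
                 radius = radius, level = level), class = "site_integral")
}

#' @export
print.site_integral <- function(x, ...) {
  cat("<site_integral>", x$n_peaks, "peaks; total", signif(x$total, 6),
      "value*A^3\n")
  invisible(x)
}

# ---- CCP4/MRC map I/O ---------------------------------------------------

#' Read a CCP4/MRC density map
#'
#' Mode-2 (32-bit float) maps; the MAPC/MAPR/MAPS axis-order header words
#' are honoured, so the returned array is always in x, y, z order.  The
#' origin is taken from the MRC2000 ORIGIN words when set, otherwise from
#' the start indices times the voxel spacing.
#'
#' @param path Path to the map file.
#' @return A [density_grid()].
#' @export
read_ccp4 <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  hdr_raw <- readBin(con, "raw", 1024)
  ints <- readBin(hdr_raw, "integer", 256, size = 4, endian = "little")
  flts <- readBin(hdr_raw, "double", 256, size = 4, endian = "little")
  nc <- ints[1]; nr <- ints[2]; ns <- ints[3]; mode <- ints[4]
  if (mode != 2) stop("only mode-2 (float32) CCP4/MRC maps are supported; ",
                      "got mode ", mode)
  start <- ints[5:7]
  mxyz <- ints[8:10]
  cell <- flts[11:13]
  angles <- flts[14:16]
  if (any(abs(angles - 90) > 1e-3))
    stop("triclinic map cells are not supported (angles ",
         paste(signif(angles, 5), collapse = ", "), ")")
  mapcrs <- ints[17:19]
  if (!setequal(mapcrs, 1:3)) stop("invalid MAPC/MAPR/MAPS axis order")
  nsymbt <- ints[24]
  if (nsymbt > 0) readBin(con, "raw", nsymbt)
  vals <- readBin(con, "double", nc * nr * ns, size = 4, endian = "little")
  if (length(vals) != nc * nr * ns)
    stop("truncated map data: expected ", nc * nr * ns, " voxels, got ",
         length(vals))
  arr_crs <- array(vals, dim = c(nc, nr, ns))
  # permute column/row/section axes into x/y/z order
  perm <- match(1:3, mapcrs)
  arr <- aperm(arr_crs, perm)
  spacing <- cell / mxyz
  origin_words <- flts[50:52]
  origin <- if (any(origin_words != 0)) origin_words else
    start[perm] * spacing
  density_grid(arr, spacing = spacing, origin = origin)
}

#' Write a CCP4/MRC density map
#'
#' Mode-2 float map in x, y, z axis order (MAPC/MAPR/MAPS = 1/2/3), with
#' the grid origin stored in the MRC2000 ORIGIN words.
#'
#' @param grid A [density_grid()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ccp4 <- function(grid, path) {
  d <- dim(grid$values)
  v <- as.numeric(grid$values)
  ints <- integer(256)
  flts <- numeric(256)
  use_int <- rep(FALSE, 256)
  set_i <- function(w, x) { ints[w] <<- as.integer(x); use_int[w] <<- TRUE }
  set_i(1, d[1]); set_i(2, d[2]); set_i(3, d[3])
  set_i(4, 2)
  set_i(5, 0); set_i(6, 0); set_i(7, 0)
  set_i(8, d[1]); set_i(9, d[2]); set_i(10, d[3])
  flts[11:13] <- d * grid$spacing
  flts[14:16] <- 90
  set_i(17, 1); set_i(18, 2); set_i(19, 3)
  flts[20] <- min(v); flts[21] <- max(v); flts[22] <- mean(v)
  set_i(23, 1)   # ISPG P1
  set_i(24, 0)   # NSYMBT
  flts[50:52] <- grid$origin
  set_i(53, readBin(charToRaw("MAP "), "integer", size = 4))
  set_i(54, readBin(as.raw(c(0x44, 0x41, 0x00, 0x00)), "integer", size = 4))
  flts[55] <- sqrt(mean((v - mean(v))^2))
  set_i(56, 0)
  con <- file(path, "wb"); on.exit(close(con))
  for (w in 1:256) {
    if (use_int[w]) writeBin(ints[w], con, size = 4, endian = "little")
    else writeBin(flts[w], con, size = 4, endian = "little")
  }
  writeBin(v, con, size = 4, endian = "little")
  invisible(path)
}
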