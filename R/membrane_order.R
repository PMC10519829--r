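# Lipid-order statistics: nematic P2 order of chain directors, hexatic
# bond-orientational order |Psi6|, Voronoi area-per-lipid under periodic
# boundaries, and mass-density profiles across the bilayer.

# Resolve director chains to atom-index matrices once per topology.
# Returns data.frame(mol_id, species, chain) with a list-column of indices.
.resolve_chains <- function(topology, directors) {
  mol <- topology$molecules
  out <- list()
  for (i in seq_len(nrow(mol))) {
    sp <- mol$species[i]
    if (!sp %in% names(directors)) next
    idx <- mol$first[i]:mol$last[i]
    nm <- topology$atoms$atom_name[idx]
    for (cn in names(directors[[sp]])) {
      want <- directors[[sp]][[cn]]
      pos <- idx[match(want, nm)]
      if (anyNA(pos)) next  # chain definition absent from this molecule
      out[[length(out) + 1L]] <- list(mol_id = mol$mol_id[i], species = sp,
                                      chain = cn, atoms = pos)
    }
  }
  out
}

#' Director vector of one acyl chain
#'
#' The director is the principal axis (largest-eigenvalue eigenvector of the
#' coordinate second-moment matrix) of the listed chain carbons, sign-fixed
#' to point from the first listed atom (head) towards the last (tail).  With
#' two atoms this reduces exactly to the normalized difference vector.
#'
#' @param frame A [new_frame()].
#' @param chain_atoms Integer atom indices, ordered head to tail.
#' @param method `"principal"` (default) or `"endpoints"` (first-to-last
#'   difference vector).
#' @return Unit length-3 vector.
#' @export
lipid_director <- function(frame, chain_atoms, method = c("principal", "endpoints")) {
  method <- match.arg(method)
  x <- frame$positions[chain_atoms, , drop = FALSE]
  if (nrow(x) < 2) stop("a director needs at least two atoms")
  ht <- x[nrow(x), ] - x[1, ]
  if (method == "endpoints") {
    n <- sqrt(sum(ht^2))
    if (n < 1e-12) stop("degenerate chain: endpoints coincide")
    return(ht / n)
  }
  xc <- sweep(x, 2, colMeans(x))
  m <- crossprod(xc)
  if (sum(diag(m)) < 1e-18) stop("degenerate chain: all atoms coincident")
  v <- eigen(m, symmetric = TRUE)$vectors[, 1]
  if (sum(v * ht) < 0) v <- -v
  v / sqrt(sum(v^2))
}

#' Nematic (P2) order parameter of lipid chains
#'
#' For each frame and species, the squared cosine of the angle between each
#' chain director and the bilayer normal is pooled over that species'
#' chains, and P2 = 0.5 (3 <cos^2 theta> - 1).  The per-species summary is
#' the mean and standard deviation of the per-frame P2 values (the frame
#' spread); the per-molecule spread within frames is also returned.
#'
#' Bounds: 1 for directors parallel to the normal, -0.5 for in-plane
#' directors, 0 for an isotropic distribution.
#'
#' @param trajectory A [new_trajectory()].
#' @param directors Director spec, see [default_directors()].
#' @param normal Membrane normal (default z).
#' @param method Passed to [lipid_director()].
#' @param return_angles If `TRUE`, keep per-chain angle samples (degrees).
#' @return Object of class `p2_result`: `per_frame` (frame, species, p2),
#'   `summary` (species, mean, sd, sd_molecule), optional `angles`.
#' @export
compute_p2 <- function(trajectory, directors = default_directors(),
                       normal = c(0, 0, 1), method = "principal",
                       return_angles = FALSE) {
  chains <- .resolve_chains(trajectory$topology, directors)
  if (!length(chains)) stop("no director chains resolvable in topology")
  sp <- vapply(chains, `[[`, character(1), "species")
  requested <- names(directors)
  missing_sp <- setdiff(requested, unique(sp))
  if (length(missing_sp))
    warning("species with zero chains excluded: ",
            paste(missing_sp, collapse = ", "))
  normal <- normal / sqrt(sum(normal^2))
  nf <- length(trajectory$frames)
  per_frame <- list(); angles <- list(); per_mol_c2 <- list()
  for (f in seq_len(nf)) {
    fr <- trajectory$frames[[f]]
    c2 <- vapply(chains, function(ch) {
      d <- lipid_director(fr, ch$atoms, method = method)
      sum(d * normal)^2
    }, numeric(1))
    agg <- tapply(c2, sp, mean)
    per_frame[[f]] <- data.frame(frame = f, species = names(agg),
                                 p2 = 0.5 * (3 * as.numeric(agg) - 1),
                                 stringsAsFactors = FALSE)
    per_mol_c2[[f]] <- c2
    if (return_angles)
      angles[[f]] <- data.frame(frame = f, species = sp,
                                theta_deg = acos(pmin(1, sqrt(c2))) * 180 / pi)
  }
  pf <- do.call(rbind, per_frame)
  mean_by <- tapply(pf$p2, pf$species, mean)
  sd_by <- tapply(pf$p2, pf$species, function(v) if (length(v) > 1) sd(v) else 0)
  # molecule-spread alternative: sd over chains of per-chain P2, pooled frames
  allc2 <- unlist(per_mol_c2)
  allsp <- rep(sp, nf)
  sd_mol <- tapply(0.5 * (3 * allc2 - 1), allsp, sd)
  res <- list(per_frame = pf,
              summary = data.frame(species = names(mean_by),
                                   mean = as.numeric(mean_by),
                                   sd = as.numeric(sd_by),
                                   sd_molecule = as.numeric(sd_mol[names(mean_by)]),
                                   stringsAsFactors = FALSE),
              n_frames = nf)
  if (return_angles) res$angles <- do.call(rbind, angles)
  structure(res, class = "p2_result")
}

#' @export
print.p2_result <- function(x, ...) {
  cat("<p2_result> over", x$n_frames, "frames\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Per-chain 2D positions for lateral-order statistics
#'
#' Extracts one xy point per acyl chain (the configured terminal atom) for
#' the lipids of one leaflet.  Hexatic order and Voronoi areas are
#' leaflet-local 2D statistics; cross-leaflet neighbours are excluded by
#' construction.
#'
#' @param frame A [new_frame()].
#' @param topology A [new_topology()].
#' @param leaflets A [assign_leaflets()] result.
#' @param leaflet `"upper"` or `"lower"`.
#' @param terminal_atoms Per-species terminal atom names,
#'   see [default_terminal_atoms()].
#' @return data.frame with columns `mol_id`, `species`, `atom`, `x`, `y`.
#' @export
chain_points <- function(frame, topology, leaflets, leaflet = "upper",
                         terminal_atoms = default_terminal_atoms()) {
  keep <- leaflets$assignment$mol_id[leaflets$assignment$leaflet == leaflet]
  mol <- topology$molecules[topology$molecules$mol_id %in% keep, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(mol))) {
    sp <- mol$species[i]
    if (!sp %in% names(terminal_atoms)) next
    idx <- mol$first[i]:mol$last[i]
    nm <- topology$atoms$atom_name[idx]
    hit <- idx[match(terminal_atoms[[sp]], nm)]
    hit <- hit[!is.na(hit)]
    for (h in hit)
      rows[[length(rows) + 1L]] <- data.frame(
        mol_id = mol$mol_id[i], species = sp,
        atom = topology$atoms$atom_name[h],
        x = frame$positions[h, 1], y = frame$positions[h, 2],
        stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no chain terminal atoms found in leaflet '",
                          leaflet, "'")
  do.call(rbind, rows)
}

#' Hexatic bond-orientational order parameter
#'
#' For each site k, Psi6k = (1/6) sum over the six nearest neighbours l of
#' exp(6 i theta_kl), with theta_kl the angle between the fixed laboratory
#' x-axis and the minimum-image vector from k to l.  The modulus |Psi6k|
#' lies in `[0, 1]` (1 on a perfect hexagonal lattice) and is independent of
#' the reference-vector choice and of global rotations/translations.
#' Nearest-neighbour ties are broken by smallest site index.
#'
#' @param points N x 2 matrix (or data.frame with `x`,`y`) of one position
#'   per lipid chain, Angstrom.
#' @param box Length-2 (or 3; z ignored) periodic box edges, Angstrom.
#' @param species Optional per-point species labels for the summary.
#' @return Object of class `psi6_result`: complex `psi6`, `modulus`,
#'   `neighbors` (N x 6 index matrix), optional per-species `summary`.
#' @export
compute_psi6 <- function(points, box, species = NULL) {
  if (is.data.frame(points)) {
    if (is.null(species) && "species" %in% names(points)) species <- points$species
    points <- cbind(points$x, points$y)
  }
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 7) stop("hexatic order needs at least 7 sites (", n, " given)")
  bx <- box[1]; by <- box[2]
  dx <- outer(points[, 1], points[, 1], "-")
  dy <- outer(points[, 2], points[, 2], "-")
  dx <- dx - bx * floor(dx / bx + 0.5)
  dy <- dy - by * floor(dy / by + 0.5)
  d2 <- dx^2 + dy^2
  diag(d2) <- Inf
  psi <- complex(n); nbrs <- matrix(NA_integer_, n, 6)
  for (k in seq_len(n)) {
    # order() is stable: equal distances resolve to the smallest index
    nn <- order(d2[k, ])[1:6]
    nbrs[k, ] <- nn
    th <- atan2(-dy[k, nn], -dx[k, nn])   # vector k -> l is -d[k,l] as built
    psi[k] <- mean(exp(1i * 6 * th))
  }
  res <- list(psi6 = psi, modulus = Mod(psi), neighbors = nbrs, n = n)
  if (!is.null(species)) {
    res$summary <- data.frame(
      species = names(tapply(Mod(psi), species, mean)),
      mean = as.numeric(tapply(Mod(psi), species, mean)),
      sd = as.numeric(tapply(Mod(psi), species, function(v)
        if (length(v) > 1) sd(v) else 0)),
      stringsAsFactors = FALSE)
  }
  structure(res, class = "psi6_result")
}

#' @export
print.psi6_result <- function(x, ...) {
  cat("<psi6_result>", x$n, "sites; mean |Psi6| =",
      signif(mean(x$modulus), 4), "\n")
  if (!is.null(x$summary)) print(x$summary, row.names = FALSE)
  invisible(x)
}

# polygon area by the shoelace formula
.poly_area <- function(x, y) abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2

#' Periodic planar Voronoi cell areas
#'
#' Realizes the periodic tessellation by replicating all points into the
#' eight neighbouring images, tessellating the 3x3 tiling (deldir), and
#' keeping the central-image cells.  Cell areas are recomputed from tile
#' vertices by the shoelace formula; they partition the box, so their sum
#' equals `box[1] * box[2]` to floating-point accuracy.
#'
#' @param points N x 2 matrix of positions (Angstrom); must be distinct
#'   under the periodic metric.
#' @param box Length-2 (or 3) box edges.
#' @return Numeric vector of N cell areas (Angstrom^2).
#' @export
periodic_voronoi <- function(points, box) {
  points <- as.matrix(points)
  n <- nrow(points)
  bx <- box[1]; by <- box[2]
  # wrap into the primary box first
  pts <- cbind(points[, 1] - bx * floor(points[, 1] / bx),
               points[, 2] - by * floor(points[, 2] / by))
  dx <- outer(pts[, 1], pts[, 1], "-"); dx <- dx - bx * floor(dx / bx + 0.5)
  dy <- outer(pts[, 2], pts[, 2], "-"); dy <- dy - by * floor(dy / by + 0.5)
  d2 <- dx^2 + dy^2; diag(d2) <- Inf
  if (any(d2 < 1e-16))
    stop("duplicate chain positions under the periodic metric; ",
         "deduplicate before tessellating")
  sh <- expand.grid(ix = -1:1, iy = -1:1)
  allx <- rep(pts[, 1], nrow(sh)) + rep(sh$ix * bx, each = n)
  ally <- rep(pts[, 2], nrow(sh)) + rep(sh$iy * by, each = n)
  dd <- deldir::deldir(allx, ally,
                       rw = c(-bx, 2 * bx, -by, 2 * by), suppressMsge = TRUE)
  tl <- deldir::tile.list(dd)
  central <- which(sh$ix == 0 & sh$iy == 0) # block index of the unshifted copy
  offset <- (central - 1L) * n
  vapply(seq_len(n), function(i) {
    t <- tl[[offset + i]]
    .poly_area(t$x, t$y)
  }, numeric(1))
}

#' Voronoi area-per-lipid in one leaflet
#'
#' One tessellation point per acyl chain (terminal carbons); a molecule's
#' area is the sum of its chains' cell areas.
#'
#' @inheritParams chain_points
#' @return Object of class `voronoi_result`: `per_chain` (mol_id, species,
#'   atom, area), `per_molecule`, per-species `summary`, and `box_area`.
#' @export
voronoi_areas <- function(frame, topology, leaflets, leaflet = "upper",
                          terminal_atoms = default_terminal_atoms()) {
  cp <- chain_points(frame, topology, leaflets, leaflet, terminal_atoms)
  areas <- periodic_voronoi(cbind(cp$x, cp$y), frame$box)
  per_chain <- cbind(cp[, c("mol_id", "species", "atom")], area = areas)
  pm <- aggregate(area ~ mol_id + species, data = per_chain, FUN = sum)
  summ <- aggregate(area ~ species, data = pm, FUN = mean)
  names(summ)[2] <- "mean_area"
  structure(list(per_chain = per_chain, per_molecule = pm, summary = summ,
                 box_area = frame$box[1] * frame$box[2]),
            class = "voronoi_result")
}

#' @export
print.voronoi_result <- function(x, ...) {
  cat("<voronoi_result> box area", signif(x$box_area, 6), "A^2; total",
      signif(sum(x$per_chain$area), 6), "A^2\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Standard atomic masses (Da) by element symbol
#'
#' @param elements Character vector of element symbols.
#' @return Numeric masses; unknown elements default to 12.
#' @export
atomic_masses <- function(elements) {
  tab <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974,
           S = 32.06, K = 39.098, CL = 35.45, NA_ = 22.99, MG = 24.305,
           SE = 78.971, FE = 55.845)
  key <- toupper(elements)
  key[key == "NA"] <- "NA_"
  m <- tab[key]
  m[is.na(m)] <- 12
  unname(m)
}

#' Mass-density profile across the bilayer
#'
#' Per frame, the z origin is moved to the phosphate midplane, coordinates
#' are wrapped into one box period about it, group masses are histogrammed
#' along z, divided by the bin volume (`Lx * Ly * dz`), and averaged over
#' frames.  The integral of each profile times the box area recovers the
#' group mass (binning conservation).
#'
#' @param trajectory A [new_trajectory()].
#' @param groups Named list of atom index vectors.
#' @param n_bins Number of z bins (>= 10).
#' @param masses Per-atom masses (Da); default from the topology elements.
#' @param phosphate_atom_name Reference-atom name for the midplane.
#' @param normalize `"mass"` (absolute density) or `"max"` (per-group
#'   max-normalized curves).
#' @return Object of class `density_profile`: `z` bin centres (midplane at
#'   0), `density` matrix (bins x groups), `bin_width`, `box_area`.
#' @export
density_profile <- function(trajectory, groups, n_bins = 50, masses = NULL,
                            phosphate_atom_name = "P",
                            normalize = c("mass", "max")) {
  normalize <- match.arg(normalize)
  if (n_bins < 10) stop("n_bins must be at least 10")
  keep <- vapply(groups, length, integer(1)) > 0
  if (any(!keep))
    warning("empty groups excluded: ", paste(names(groups)[!keep], collapse = ", "))
  groups <- groups[keep]
  if (!length(groups)) stop("no non-empty groups")
  top <- trajectory$topology
  if (is.null(masses)) masses <- atomic_masses(top$atoms$element)
  nf <- length(trajectory$frames)
  acc <- NULL
  for (f in seq_len(nf)) {
    fr <- trajectory$frames[[f]]
    lz <- fr$box[3]
    mid <- assign_leaflets(fr, top, phosphate_atom_name)$midplane_z
    z <- fr$positions[, 3] - mid
    z <- z - lz * floor(z / lz + 0.5)           # wrap to [-lz/2, lz/2)
    edges <- seq(-lz / 2, lz / 2, length.out = n_bins + 1)
    dz <- edges[2] - edges[1]
    vol <- fr$box[1] * fr$box[2] * dz
    dens <- vapply(groups, function(g) {
      b <- pmin(pmax(floor((z[g] + lz / 2) / dz) + 1, 1), n_bins)
      as.numeric(tapply(masses[g], factor(b, levels = seq_len(n_bins)), sum,
                        default = 0)) / vol
    }, numeric(n_bins))
    acc <- if (is.null(acc)) dens else acc + dens
  }
  dens <- acc / nf
  lz <- trajectory$frames[[1]]$box[3]
  centers <- seq(-lz / 2, lz / 2, length.out = n_bins + 1)
  centers <- (centers[-1] + centers[-(n_bins + 1)]) / 2
  if (normalize == "max")
    dens <- sweep(dens, 2, apply(dens, 2, max), "/")
  structure(list(z = centers, density = dens, bin_width = lz / n_bins,
                 box_area = trajectory$frames[[1]]$box[1] *
                   trajectory$frames[[1]]$box[2],
                 normalize = normalize, n_frames = nf),
            class = "density_profile")
}

#' @export
print.density_profile <- function(x, ...) {
  cat("<density_profile>", length(x$z), "bins x", ncol(x$density),
      "groups over", x$n_frames, "frames\n")
  invisible(x)
}
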