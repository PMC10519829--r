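# Ligand and protein conformational metrics: radius of gyration, Kabsch
# superposition, RMSD/RMSF with pseudo-B conversion, membrane insertion
# depth, reentrant-helix hinge angle, and loop-openness CA distances.

#' Mass-weighted radius of gyration
#'
#' Rg^2 = sum m_i |r_i - r_cm|^2 / sum m_i.  Coordinates are Angstrom
#' internally; the result is reported in nm (the ligand-conformation
#' convention), converted only at this reporting layer.
#'
#' @param coords M x 3 matrix, Angstrom.
#' @param masses Per-atom masses (> 0); default unit masses.
#' @return Rg in nm.
#' @export
radius_of_gyration <- function(coords, masses = NULL) {
  coords <- as.matrix(coords)
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 3)
  m <- if (is.null(masses)) rep(1, nrow(coords)) else as.numeric(masses)
  if (any(m < 0) || sum(m) <= 0) stop("masses must be positive with nonzero total")
  cm <- colSums(coords * m) / sum(m)
  rg2 <- sum(m * rowSums(sweep(coords, 2, cm)^2)) / sum(m)
  sqrt(rg2) / 10
}

#' Per-frame radius of gyration of a selection
#'
#' @param trajectory A [new_trajectory()].
#' @param selection Atom indices (or selection string resolved against the
#'   trajectory topology).
#' @param masses Optional per-atom masses for the whole topology.
#' @return Object of class `rg_series`: `per_frame` (frame, rg_nm), `mean`,
#'   `sd`.
#' @export
rg_series <- function(trajectory, selection, masses = NULL) {
  if (is.character(selection))
    selection <- select_atoms(trajectory$topology, selection)
  if (is.null(masses))
    masses <- atomic_masses(trajectory$topology$atoms$element)
  rg <- vapply(trajectory$frames, function(fr)
    radius_of_gyration(fr$positions[selection, , drop = FALSE],
                       masses[selection]), numeric(1))
  structure(list(per_frame = data.frame(frame = seq_along(rg), rg_nm = rg),
                 mean = mean(rg), sd = if (length(rg) > 1) sd(rg) else 0),
            class = "rg_series")
}

#' @export
print.rg_series <- function(x, ...) {
  cat("<rg_series>", nrow(x$per_frame), "frames; Rg =", signif(x$mean, 4),
      "+/-", signif(x$sd, 3), "nm\n")
  invisible(x)
}

#' Kabsch superposition
#'
#' Least-squares rigid-body fit of `mobile` onto `reference` (optionally
#' weighted), via SVD of the weighted covariance with a determinant
#' correction enforcing a proper rotation (det = +1).
#'
#' @param mobile,reference Matched M x 3 matrices (M >= 3, non-collinear).
#' @param weights Optional non-negative per-atom weights.
#' @return List with `rotation` (3 x 3), `translation` (so that
#'   `mobile %*% rotation + translation` is the fit), `rmsd` (Angstrom,
#'   weighted), and `fitted` coordinates.
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)))
    stop("mobile and reference must have matching dimensions")
  m <- nrow(mobile)
  if (m < 3) stop("superposition needs at least 3 atoms")
  w <- if (is.null(weights)) rep(1, m) else as.numeric(weights)
  if (any(w < 0) || sum(w) <= 0) stop("weights must be non-negative, nonzero total")
  w <- w / sum(w)
  cm_m <- colSums(mobile * w); cm_r <- colSums(reference * w)
  a <- sweep(mobile, 2, cm_m); b <- sweep(reference, 2, cm_r)
  h <- crossprod(a * w, b)                      # 3x3 covariance
  sv <- svd(h)
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1))
    stop("degenerate (collinear) coordinates: rotation under-determined")
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  fitted <- a %*% rot
  rmsd <- sqrt(sum(w * rowSums((fitted - b)^2)))
  list(rotation = rot, translation = cm_r - cm_m %*% rot, rmsd = rmsd,
       fitted = sweep(fitted, 2, cm_r, "+"))
}

#' RMSD time series against a reference structure
#'
#' Each frame is superposed onto the reference over the selection before
#' the RMSD is evaluated.  The empirical cumulative distribution of the
#' series is also returned.
#'
#' @param trajectory A [new_trajectory()].
#' @param reference A [new_frame()] (e.g. the crystal structure).
#' @param selection Atom indices into the trajectory topology.
#' @param ref_selection Matching indices into the reference (default: same).
#' @return Object of class `rmsd_series`: `per_frame` (frame, rmsd),
#'   `mean`, `cdf` (sorted rmsd, cumulative fraction).
#' @export
rmsd_series <- function(trajectory, reference, selection,
                        ref_selection = selection) {
  if (is.character(selection))
    selection <- select_atoms(trajectory$topology, selection)
  if (length(selection) != length(ref_selection))
    stop("selection and ref_selection must match atom-for-atom (",
         length(selection), " vs ", length(ref_selection), ")")
  ref <- reference$positions[ref_selection, , drop = FALSE]
  r <- vapply(trajectory$frames, function(fr)
    kabsch_superpose(fr$positions[selection, , drop = FALSE], ref)$rmsd,
    numeric(1))
  s <- sort(r)
  structure(list(per_frame = data.frame(frame = seq_along(r), rmsd = r),
                 mean = mean(r),
                 cdf = data.frame(rmsd = s,
                                  fraction = seq_along(s) / length(s))),
            class = "rmsd_series")
}

#' @export
print.rmsd_series <- function(x, ...) {
  cat("<rmsd_series>", nrow(x$per_frame), "frames; mean RMSD =",
      signif(x$mean, 4), "A\n")
  invisible(x)
}

# Iteratively superpose a K x 3M coordinate stack (rows = conformations,
# columns atom-major x,y,z triples) onto its evolving mean, fitting on the
# atom rows in fit_rows.
.iterative_align <- function(xmat, fit_rows = seq_len(ncol(xmat) %/% 3L),
                             tol = 1e-6, max_iter = 100) {
  k <- nrow(xmat)
  shift <- Inf
  mean_prev <- colMeans(xmat)
  for (it in seq_len(max_iter)) {
    ref <- matrix(mean_prev, ncol = 3, byrow = TRUE)
    ref_fit <- ref[fit_rows, , drop = FALSE]
    for (i in seq_len(k)) {
      xi <- matrix(xmat[i, ], ncol = 3, byrow = TRUE)
      f <- kabsch_superpose(xi[fit_rows, , drop = FALSE], ref_fit)
      xmat[i, ] <- as.vector(t(sweep(xi %*% f$rotation, 2,
                                     as.numeric(f$translation), "+")))
    }
    mean_new <- colMeans(xmat)
    shift <- sqrt(max(rowSums(matrix(mean_new - mean_prev, ncol = 3,
                                     byrow = TRUE)^2)))
    mean_prev <- mean_new
    if (shift < tol) return(list(xmat = xmat, mean = mean_new, iter = it))
  }
  stop("iterative superposition did not converge in ", max_iter,
       " iterations (last mean shift ", signif(shift, 3), " A)")
}

#' Root-mean-square fluctuation per atom
#'
#' Frames are iteratively superposed onto the evolving mean structure
#' (converged to < 1e-6 A mean shift); RMSF_i = sqrt(<|r_i - <r_i>|^2>).
#' The crystallographic pseudo-B `B = 8 pi^2 <u^2> / 3` is reported
#' alongside so RMSF can be compared with experimental B-factors.
#'
#' @param trajectory A [new_trajectory()].
#' @param selection Atom indices whose RMSF is computed.
#' @param fit_selection Atoms used for superposition (default: the same;
#'   typically the rigid scaffold so a mobile loop does not dominate the
#'   fit).  Must be a subset of `selection`.
#' @return Object of class `rmsf_profile`: `per_atom` (atom, residue_id,
#'   rmsf, pseudo_b), `mean_structure` (M x 3), `iterations`.
#' @export
rmsf_profile <- function(trajectory, selection, fit_selection = selection) {
  if (is.character(selection))
    selection <- select_atoms(trajectory$topology, selection)
  if (is.character(fit_selection))
    fit_selection <- select_atoms(trajectory$topology, fit_selection)
  if (length(trajectory$frames) < 2) stop("RMSF needs at least 2 frames")
  fpos <- match(fit_selection, selection)
  if (anyNA(fpos)) stop("fit_selection must be a subset of selection")
  xmat <- t(vapply(trajectory$frames, function(fr)
    as.vector(t(fr$positions[selection, , drop = FALSE])),
    numeric(3 * length(selection))))
  al <- .iterative_align(xmat, fpos)
  dev <- sweep(al$xmat, 2, al$mean)
  msf <- colMeans(dev^2)
  msf_atom <- matrix(msf, ncol = 3, byrow = TRUE)
  rmsf <- sqrt(rowSums(msf_atom))
  structure(list(
    per_atom = data.frame(atom = selection,
                          residue_id = trajectory$topology$atoms$residue_id[selection],
                          rmsf = rmsf,
                          pseudo_b = 8 * pi^2 * rmsf^2 / 3),
    mean_structure = matrix(al$mean, ncol = 3, byrow = TRUE),
    iterations = al$iter), class = "rmsf_profile")
}

#' @export
print.rmsf_profile <- function(x, ...) {
  cat("<rmsf_profile>", nrow(x$per_atom), "atoms; mean RMSF =",
      signif(mean(x$per_atom$rmsf), 4), "A (", x$iterations,
      "alignment iterations )\n")
  invisible(x)
}

#' Membrane insertion depth of a protein
#'
#' The reference plane is the per-frame mean phosphate z of the leaflet the
#' protein sits in; an atom's depth is its distance below (for the upper
#' leaflet) or above (lower leaflet) that plane, clamped at zero so atoms
#' outside the membrane contribute nothing.  "Into the membrane" is
#' positive by construction.  Invariant under global z-translation: the
#' plane moves with the phosphates.
#'
#' @param trajectory A [new_trajectory()].
#' @param protein_selection Atom indices of the protein.
#' @param leaflet `"upper"` or `"lower"`: the leaflet containing the
#'   protein's membrane-inserted residues.
#' @param phosphate_atom_name Passed to [assign_leaflets()].
#' @return Object of class `depth_result`: `per_frame` (frame, max_depth),
#'   `per_atom` depth matrix (atoms x frames), `max`.
#' @export
insertion_depth <- function(trajectory, protein_selection, leaflet = "upper",
                            phosphate_atom_name = "P") {
  if (is.character(protein_selection))
    protein_selection <- select_atoms(trajectory$topology, protein_selection)
  s <- if (leaflet == "upper") 1 else -1
  top <- trajectory$topology
  depth <- vapply(trajectory$frames, function(fr) {
    la <- assign_leaflets(fr, top, phosphate_atom_name)
    pz <- la$assignment$phosphate_z[la$assignment$leaflet == leaflet]
    if (!length(pz)) stop("leaflet '", leaflet, "' contains no lipids")
    plane <- mean(pz)
    pmax(0, s * (plane - fr$positions[protein_selection, 3]))
  }, numeric(length(protein_selection)))
  depth <- matrix(depth, nrow = length(protein_selection))
  per_frame <- apply(depth, 2, max)
  structure(list(per_frame = data.frame(frame = seq_along(per_frame),
                                        max_depth = per_frame),
                 per_atom = depth, max = max(per_frame),
                 leaflet = leaflet), class = "depth_result")
}

#' @export
print.depth_result <- function(x, ...) {
  cat("<depth_result> max insertion depth", signif(x$max, 4), "A (",
      x$leaflet, "leaflet )\n")
  invisible(x)
}

# principal axis of a CA window, sign-fixed N-terminal -> C-terminal
.window_axis <- function(ca) {
  xc <- sweep(ca, 2, colMeans(ca))
  v <- eigen(crossprod(xc), symmetric = TRUE)$vectors[, 1]
  if (sum(v * (ca[nrow(ca), ] - ca[1, ])) < 0) v <- -v
  v / sqrt(sum(v^2))
}

#' Hinge angle between two helices
#'
#' Each window's axis is the principal axis of its CA coordinates,
#' sign-fixed N to C.  The hinge angle is the interior angle at the kink,
#' `acos(-u . v)`: a straight (collinear, same-direction) helix pair reads
#' 180 degrees, and a reentrant helix kinked like the Ser-Pro motif of a
#' reentrant membrane helix reads its interior kink angle (about 118
#' degrees for the system this package models).  `convention = "axis"`
#' instead returns the raw inter-axis angle `acos(u . v)` (the supplement).
#'
#' @param frame A [new_frame()].
#' @param topology A [new_topology()].
#' @param window1,window2 Length-2 residue-id ranges (file numbering), each
#'   covering at least 4 CA atoms.
#' @param chain Chain id (default first protein chain).
#' @param convention `"interior"` (default) or `"axis"`.
#' @return Hinge angle in degrees, in (0, 180].
#' @export
hinge_angle <- function(frame, topology, window1 = c(7, 22),
                        window2 = c(25, 36), chain = NULL,
                        convention = c("interior", "axis")) {
  convention <- match.arg(convention)
  a <- topology$atoms
  if (is.null(chain)) {
    pm <- topology$molecules[topology$molecules$species == "PROTEIN", ]
    chain <- if (nrow(pm)) pm$chain_id[1] else a$chain_id[1]
  }
  get_ca <- function(w) {
    sel <- which(a$atom_name == "CA" & a$chain_id == chain &
                 a$residue_id >= w[1] & a$residue_id <= w[2])
    if (length(sel) < 4)
      stop("window ", w[1], "-", w[2], " has ", length(sel),
           " CA atoms; need at least 4")
    frame$positions[sel[order(a$residue_id[sel])], , drop = FALSE]
  }
  u <- .window_axis(get_ca(window1))
  v <- .window_axis(get_ca(window2))
  dp <- max(-1, min(1, sum(u * v)))
  ang <- if (convention == "interior") acos(-dp) else acos(dp)
  ang * 180 / pi
}

#' CA-CA distance between two residues
#'
#' Plain Euclidean distance (no periodic wrapping: intended for crystal
#' coordinates, e.g. the loop-openness distance from the mobile-loop apex
#' to a reference residue).
#'
#' @param frame A [new_frame()].
#' @param topology A [new_topology()].
#' @param res_a,res_b Residue ids (file numbering).
#' @param chain Chain id (default: any).
#' @return Distance in Angstrom.
#' @export
ca_distance <- function(frame, topology, res_a, res_b, chain = NULL) {
  a <- topology$atoms
  find_ca <- function(r) {
    sel <- which(a$atom_name == "CA" & a$residue_id == r &
                 (if (is.null(chain)) TRUE else a$chain_id == chain))
    if (!length(sel)) stop("residue ", r, if (!is.null(chain))
      paste0(" chain ", chain), " has no CA atom")
    sel[1]
  }
  sqrt(sum((frame$positions[find_ca(res_a), ] -
            frame$positions[find_ca(res_b), ])^2))
}
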