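# Seeded synthetic-data generators with planted ground truth.  Geometries
# are simplified bead/united-atom constructions carrying the correct
# topology labels (species, chain-carbon atom names); the analyses consume
# geometry plus names only, so chemical realism is not attempted.  Each
# generator derives per-molecule RNG sub-seeds from the call seed, so
# adding molecules or frames does not reshuffle existing ones, and returns
# a manifest of the planted quantities.

# deterministic 32-bit sub-seed from (seed, stream ids)
.subseed <- function(seed, ...) {
  ids <- c(seed, ...)
  h <- 0
  for (v in ids) h <- (h * 7919 + (v %% 2147483647) + 104729) %% 2147483647
  as.integer(h)
}

#' Write a generator manifest
#'
#' @param manifest Named list of planted ground-truth values.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# atom-name sets per lipid species (head phosphates, then acyl chains)
.lipid_atoms <- function(species) {
  switch(species,
    POPE = ,
    POPG = list(phos = "P",
                chains = list(paste0("C3", 1:16), paste0("C2", 1:14))),
    CL = list(phos = c("P1", "P3"),
              chains = list(paste0("CA", 1:12), paste0("CB", 1:12),
                            paste0("CC", 1:12), paste0("CD", 1:12))),
    UNDP = list(phos = "P", chains = list(paste0("C", 1:11))),
    stop("unknown lipid species ", species))
}

.lipid_resname <- c(POPE = "POPE", POPG = "POPG", CL = "CL", UNDP = "UNP")

# even-ny hexagonal lattice factorization with the squarest aspect ratio
.hex_factor <- function(n_sites) {
  div <- which(n_sites %% seq_len(n_sites) == 0)
  ny <- div[div %% 2 == 0]
  if (!length(ny)) stop("chain count ", n_sites,
                        " admits no even-row hexagonal lattice")
  nx <- n_sites / ny
  aspect <- abs(log((nx) / (ny * sqrt(3) / 2)))
  ny <- ny[which.min(aspect)]
  c(nx = n_sites / ny, ny = ny)
}

#' Generate a synthetic three-component bilayer with planted order
#'
#' Two leaflets of acyl chains on jittered hexagonal lattices.  Every chain
#' is a straight run of carbons tilted at exactly `tilt_theta` from the
#' leaflet normal (random azimuth per chain per frame), so the planted
#' nematic order is P2 = 0.5 (3 cos^2 theta - 1) exactly.  Phosphate atoms
#' sit at the planted interfacial |z| = `z_head`; undecaprenol-phosphate
#' molecules are placed in the upper leaflet with their phosphate anchored
#' at the interface.  Defaults emulate the study conditions: a 67:23:10
#' POPE:POPG:CL bilayer of 200 lipids (100 per leaflet) with 1 mol% UndP
#' (two molecules) and a liquid-disordered tilt.
#'
#' @param seed Integer RNG seed.
#' @param n_frames Number of frames (default 5).
#' @param n_lipids Total phospholipid count, split evenly across leaflets
#'   (default 200).
#' @param fractions Mole fractions for POPE/POPG/CL summing to 1.
#' @param undp_molpct UndP concentration, mol% of `n_lipids` (default 1.0;
#'   the physiologically motivated range is 0.5-1.0).
#' @param tilt_theta Planted tilt angle from the leaflet normal, degrees
#'   (default 28, giving P2 close to the liquid-disordered value 0.67).
#' @param jitter_xy Lateral Gaussian jitter, as a fraction of the lattice
#'   spacing (default 0.2, chosen so the emulated bilayer's mean hexatic
#'   order |Psi6| sits at the liquid-disordered scale of about 0.4).
#' @param spacing Hexagonal lattice spacing, Angstrom (default 5.8, i.e.
#'   about 29 Angstrom^2 per chain).
#' @param z_head Interfacial phosphate |z|, Angstrom (default 18).
#' @param z_jitter Gaussian jitter on phosphate z (default 0.3).
#' @param box_z Box height, Angstrom (default 80).
#' @return List with `topology`, `trajectory`, `manifest` (planted P2,
#'   per-leaflet composition, box, seeds).
#' @export
gen_membrane <- function(seed, n_frames = 5, n_lipids = 200,
                         fractions = c(POPE = 0.67, POPG = 0.23, CL = 0.10),
                         undp_molpct = 1.0, tilt_theta = 28,
                         jitter_xy = 0.2, spacing = 5.8, z_head = 18,
                         z_jitter = 0.3, box_z = 80) {
  if (abs(sum(fractions) - 1) > 1e-9) stop("mole fractions must sum to 1")
  if (n_lipids %% 2 != 0) stop("n_lipids must be even (two equal leaflets)")
  n_leaf <- n_lipids / 2
  counts <- round(fractions * n_leaf)
  counts[1] <- counts[1] + (n_leaf - sum(counts))  # absorb rounding
  if (any(counts < 0)) stop("composition incompatible with leaflet size")
  chains_per <- c(POPE = 2L, POPG = 2L, CL = 4L)
  n_chain_sites <- sum(counts * chains_per[names(counts)])
  lat <- .hex_factor(n_chain_sites)
  bx <- lat["nx"] * spacing
  by <- lat["ny"] * spacing * sqrt(3) / 2
  box <- c(unname(bx), unname(by), box_z)
  n_undp <- round(undp_molpct / 100 * n_lipids)
  theta <- tilt_theta * pi / 180

  # lattice site coordinates (row-major, odd rows offset half a spacing)
  site_xy <- function(s) {
    row <- (s - 1) %/% lat["nx"]
    col <- (s - 1) %% lat["nx"]
    c(col * spacing + (row %% 2) * spacing / 2, row * spacing * sqrt(3) / 2)
  }

  species_seq <- rep(names(counts), counts)
  atoms <- list(); mols <- list(); placement <- list()
  atom_n <- 0L; mol_n <- 0L; resno <- 0L
  add_mol <- function(species, leaflet, sites) {
    la <- .lipid_atoms(species)
    nm <- c(la$phos, unlist(la$chains))
    mol_n <<- mol_n + 1L; resno <<- resno + 1L
    atoms[[mol_n]] <<- data.frame(
      atom_name = nm, element = substr(nm, 1, 1), # P.. -> P, C.. -> C
      residue_name = unname(.lipid_resname[species]), residue_id = resno,
      chain_id = if (leaflet > 0) "U" else "L",
      occupancy = 1, b_factor = 0, stringsAsFactors = FALSE)
    mols[[mol_n]] <<- data.frame(
      mol_id = mol_n, species = species, first = atom_n + 1L,
      last = atom_n + length(nm), residue_name = unname(.lipid_resname[species]),
      chain_id = if (leaflet > 0) "U" else "L", stringsAsFactors = FALSE)
    atom_n <<- atom_n + length(nm)
    placement[[mol_n]] <<- list(species = species, leaflet = leaflet,
                                sites = sites)
  }
  for (leaflet in c(1, -1)) {
    s <- 0L
    for (sp in species_seq) {
      nc <- chains_per[sp]
      add_mol(sp, leaflet, s + seq_len(nc))
      s <- s + nc
    }
  }
  for (u in seq_len(n_undp)) add_mol("UNDP", 1, NA)

  atoms <- do.call(rbind, atoms)
  mols <- do.call(rbind, mols)
  topology <- new_topology(atoms, mols)

  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    pos <- matrix(0, atom_n, 3)
    for (m in seq_len(mol_n)) {
      pl <- placement[[m]]
      set.seed(.subseed(seed, m, f))
      srow <- mols[m, ]
      la <- .lipid_atoms(pl$species)
      s <- pl$leaflet
      i0 <- srow$first
      if (pl$species == "UNDP") {
        head_xy <- c(runif(1, 0, box[1]), runif(1, 0, box[2]))
        pos[i0, ] <- c(head_xy, s * z_head + rnorm(1, 0, z_jitter))
        dir <- c(rnorm(2, 0, 0.08), -s)
        dir <- dir / sqrt(sum(dir^2))
        for (b in seq_len(11))
          pos[i0 + b, ] <- c(head_xy, s * (z_head - 2)) + (b - 1) * 1.6 * dir
        next
      }
      ch_heads <- list()
      ai <- i0 + length(la$phos)
      for (ci in seq_along(la$chains)) {
        xy0 <- site_xy(pl$sites[ci])
        jit <- rnorm(2, 0, jitter_xy * spacing)
        phi <- runif(1, 0, 2 * pi)
        dir <- c(sin(theta) * cos(phi), sin(theta) * sin(phi), -s * cos(theta))
        n_at <- length(la$chains[[ci]])
        # tail (last carbon) anchored at the lattice site; chain rises
        # head-ward along the director
        tail_pos <- c(xy0 + jit, s * 1.5)
        for (k in seq_len(n_at))
          pos[ai + k - 1L, ] <- tail_pos - (n_at - k) * 1.2 * dir
        ch_heads[[ci]] <- pos[ai, 1:2]
        ai <- ai + n_at
      }
      # phosphates above the chain heads at the interface
      if (length(la$phos) == 1) {
        hxy <- colMeans(do.call(rbind, ch_heads))
        pos[i0, ] <- c(hxy, s * z_head + rnorm(1, 0, z_jitter))
      } else {
        pos[i0, ] <- c(colMeans(do.call(rbind, ch_heads[1:2])),
                       s * z_head + rnorm(1, 0, z_jitter))
        pos[i0 + 1L, ] <- c(colMeans(do.call(rbind, ch_heads[3:4])),
                            s * z_head + rnorm(1, 0, z_jitter))
      }
    }
    frames[[f]] <- new_frame(pos, box)
  }
  manifest <- list(
    generator = "gen_membrane", seed = seed, n_frames = n_frames,
    n_lipids = n_lipids, n_per_leaflet = n_leaf,
    composition = as.list(counts), n_undp = n_undp, undp_leaflet = "upper",
    tilt_theta_deg = tilt_theta,
    planted_p2 = 0.5 * (3 * cos(theta)^2 - 1),
    jitter_xy = jitter_xy, spacing = spacing, z_head = z_head,
    box = box, lattice = as.list(lat))
  list(topology = topology,
       trajectory = new_trajectory(topology, frames),
       manifest = manifest)
}

# chain atoms C1..C11 shared by the conformer generator
.undp_topology <- function(n_beads = 11) {
  nm <- paste0("C", seq_len(n_beads))
  atoms <- data.frame(atom_name = nm, element = "C", residue_name = "UNP",
                      residue_id = 1L, chain_id = " ", occupancy = 1,
                      b_factor = 0, stringsAsFactors = FALSE)
  new_topology(atoms, data.frame(mol_id = 1L, species = "UNDP", first = 1L,
                                 last = n_beads, residue_name = "UNP",
                                 chain_id = " ", stringsAsFactors = FALSE))
}

#' Generate undecaprenol-phosphate-like conformer trajectories
#'
#' An 11-bead isoprene-unit chain in `extended` (straight rod; planted
#' Rg = bond * sqrt((n^2 - 1) / 12)), `coiled` (closed ring of radius
#' R = bond / (2 sin(pi / n)); planted Rg = R), or `mixture` (each frame
#' drawn 50/50 between the two, giving a bimodal Rg histogram) mode.
#'
#' @param seed Integer RNG seed.
#' @param n_frames Number of frames (default 50).
#' @param mode `"extended"`, `"coiled"` or `"mixture"`.
#' @param bond Bead spacing, Angstrom (default 4.4 per isoprene unit).
#' @param jitter Per-coordinate Gaussian jitter, Angstrom (default 0).
#' @return List with `topology`, `trajectory`, `manifest` (planted Rg in
#'   nm per mode, per-frame mode labels).
#' @export
gen_undp_conformers <- function(seed, n_frames = 50,
                                mode = c("extended", "coiled", "mixture"),
                                bond = 4.4, jitter = 0) {
  mode <- match.arg(mode)
  n <- 11L
  top <- .undp_topology(n)
  r_ring <- bond / (2 * sin(pi / n))
  frames <- vector("list", n_frames)
  labels <- character(n_frames)
  for (f in seq_len(n_frames)) {
    set.seed(.subseed(seed, f))
    lab <- switch(mode, extended = "extended", coiled = "coiled",
                  mixture = if (runif(1) < 0.5) "extended" else "coiled")
    labels[f] <- lab
    pos <- if (lab == "extended") {
      cbind(0, 0, (seq_len(n) - 1) * bond)
    } else {
      th <- 2 * pi * (seq_len(n) - 1) / n
      cbind(r_ring * cos(th), r_ring * sin(th), 0)
    }
    if (jitter > 0) pos <- pos + matrix(rnorm(3 * n, 0, jitter), n, 3)
    pos <- sweep(pos, 2, c(100, 100, 100), "+")
    frames[[f]] <- new_frame(pos, c(200, 200, 200))
  }
  manifest <- list(
    generator = "gen_undp_conformers", seed = seed, mode = mode,
    n_frames = n_frames, bond = bond, n_beads = n,
    rg_extended_nm = bond * sqrt((n^2 - 1) / 12) / 10,
    rg_coiled_nm = r_ring / 10,
    frame_modes = labels)
  list(topology = top, trajectory = new_trajectory(top, frames),
       manifest = manifest)
}

# deterministic compact CA scaffold: biased random walk, fixed sub-seed
.scaffold_ca <- function(seed, n_res) {
  set.seed(.subseed(seed, 424243))
  pos <- matrix(0, n_res, 3)
  for (i in 2:n_res) {
    repeat {
      step <- rnorm(3)
      step <- step / sqrt(sum(step^2)) * 3.8
      cand <- pos[i - 1, ] + step
      # soft confinement keeps the fold compact
      if (sqrt(sum(cand^2)) < 18 || runif(1) < 0.15) break
    }
    pos[i, ] <- cand
  }
  pos
}

#' Generate a two-state mobile-loop protein ensemble
#'
#' A rigid scaffold with the loop residues displaced along one fixed
#' 3M-direction (a rigid loop translation towards a reference residue) with
#' two-state amplitudes -a (open) / +a (closed) plus isotropic Gaussian
#' noise.  Emits both a "simulation" trajectory (`n_frames` frames, states
#' drawn 50/50) and a "crystal octamer" (8 chains A-H: two closed, four
#' open, two intermediate) sharing the same planted mode, so cross-ensemble
#' PCA overlap can be tested as a recovery experiment.
#'
#' @param seed Integer RNG seed.
#' @param n_res Number of residues (default 140).
#' @param loop Loop residue range (default 61-81, the mobile loop).
#' @param ref_residue Residue the closed loop approaches (default 121).
#' @param n_frames Simulation frames (default 200).
#' @param n_chains Crystal chains (default 8).
#' @param amplitude Planted per-atom loop displacement a, Angstrom
#'   (default 1.5): every loop atom moves by `state * a` along the mode
#'   direction.
#' @param noise Isotropic per-coordinate noise standard deviation, Angstrom
#'   (default `amplitude / 10`, the 10:1 signal-to-noise amplitude ratio).
#' @return List with `trajectory`, `crystal` (`list(topology, frame)` with
#'   chains A-H), and `manifest` (planted mode vector on the backbone
#'   correspondence, states, amplitude, noise).
#' @export
gen_protein_two_state <- function(seed, n_res = 140, loop = c(61, 81),
                                  ref_residue = 121, n_frames = 200,
                                  n_chains = 8, amplitude = 1.5,
                                  noise = amplitude / 10) {
  bb <- c("N", "CA", "C", "O")
  off <- rbind(N = c(-1.2, 0.4, 0), CA = c(0, 0, 0), C = c(1.2, 0.4, 0),
               O = c(1.6, 1.5, 0.3))
  ca <- .scaffold_ca(seed, n_res)
  m <- n_res * 4L
  scaffold <- matrix(0, m, 3)
  for (r in seq_len(n_res))
    scaffold[(r - 1) * 4 + 1:4, ] <- sweep(off, 2, ca[r, ], "+")
  loop_res <- as.integer(loop[1]):as.integer(loop[2])
  loop_rows <- as.vector(vapply(loop_res, function(r) (r - 1L) * 4L + 1:4,
                                integer(4)))
  u <- ca[ref_residue, ] - colMeans(ca[loop_res, , drop = FALSE])
  u <- u / sqrt(sum(u^2))
  # raw mode: a rigid loop translation towards the reference residue.  Its
  # net-translation/rotation content would be absorbed by ensemble
  # superposition, so the rigid-body component (6 generators about the
  # scaffold centroid) is projected out; the internal-motion remainder is
  # rescaled to |amplitude| Angstrom RMS per loop atom.
  disp_vec <- matrix(0, m, 3)
  disp_vec[loop_rows, ] <- matrix(u, length(loop_rows), 3, byrow = TRUE)
  rc <- sweep(scaffold, 2, colMeans(scaffold))
  gens <- cbind(
    as.vector(t(matrix(c(1, 0, 0), m, 3, byrow = TRUE))),
    as.vector(t(matrix(c(0, 1, 0), m, 3, byrow = TRUE))),
    as.vector(t(matrix(c(0, 0, 1), m, 3, byrow = TRUE))),
    as.vector(t(cbind(0, -rc[, 3], rc[, 2]))),
    as.vector(t(cbind(rc[, 3], 0, -rc[, 1]))),
    as.vector(t(cbind(-rc[, 2], rc[, 1], 0))))
  gq <- qr.Q(qr(gens))
  disp_flat <- as.vector(t(disp_vec))
  disp_flat <- disp_flat - gq %*% crossprod(gq, disp_flat)
  disp_flat <- as.numeric(disp_flat) / sqrt(sum(disp_flat^2)) *
    sqrt(length(loop_rows))
  mode_flat <- disp_flat / sqrt(sum(disp_flat^2))

  make_atoms <- function(chain) data.frame(
    atom_name = rep(bb, n_res), element = substr(rep(bb, n_res), 1, 1),
    residue_name = "ALA", residue_id = rep(seq_len(n_res), each = 4),
    chain_id = chain, occupancy = 1, b_factor = 0, stringsAsFactors = FALSE)

  conf <- function(state, sub) {
    set.seed(sub)
    x <- as.vector(t(scaffold)) + state * amplitude * disp_flat +
      rnorm(3 * m, 0, noise)
    matrix(x, m, 3, byrow = TRUE)
  }

  states_traj <- {
    set.seed(.subseed(seed, 99991))
    sample(c(-1, 1), n_frames, replace = TRUE)
  }
  top1 <- new_topology(make_atoms("A"), data.frame(
    mol_id = 1L, species = "PROTEIN", first = 1L, last = m,
    residue_name = "ALA", chain_id = "A", stringsAsFactors = FALSE))
  frames <- lapply(seq_len(n_frames), function(f)
    new_frame(conf(states_traj[f], .subseed(seed, 1, f)), c(500, 500, 500)))
  trajectory <- new_trajectory(top1, frames)

  states_chains <- c(0, 0, -1, -1, -1, -1, 1, 1)[seq_len(n_chains)]
  chain_ids <- LETTERS[seq_len(n_chains)]
  atoms8 <- do.call(rbind, lapply(chain_ids, make_atoms))
  mols8 <- data.frame(mol_id = seq_len(n_chains), species = "PROTEIN",
                      first = (seq_len(n_chains) - 1) * m + 1L,
                      last = seq_len(n_chains) * m, residue_name = "ALA",
                      chain_id = chain_ids, stringsAsFactors = FALSE)
  pos8 <- do.call(rbind, lapply(seq_len(n_chains), function(i)
    conf(states_chains[i], .subseed(seed, 2, i))))
  crystal <- list(topology = new_topology(atoms8, mols8),
                  frame = new_frame(pos8, c(500, 500, 500)))

  manifest <- list(
    generator = "gen_protein_two_state", seed = seed, n_res = n_res,
    loop = loop, ref_residue = ref_residue, amplitude = amplitude,
    noise = noise, n_frames = n_frames, n_chains = n_chains,
    states_trajectory = states_traj, states_chains = states_chains,
    n_loop_atoms = length(loop_rows),
    displacement_norm2 = amplitude^2 * length(loop_rows),
    mode = mode_flat)
  list(trajectory = trajectory, crystal = crystal, manifest = manifest)
}

#' Generate a density map of Gaussian blobs with known integrals
#'
#' The map is a sum of isotropic Gaussians `A exp(-r^2 / (2 w^2))` plus
#' optional Gaussian noise; each blob's analytic integral
#' `A (2 pi)^{3/2} w^3` is recorded in the manifest.
#'
#' @param seed Integer RNG seed (used only when `noise_sd > 0`).
#' @param dims Grid dimensions (default 64^3).
#' @param spacing Voxel spacing, Angstrom (default 0.5).
#' @param blobs data.frame with columns `x`, `y`, `z`, `amplitude`,
#'   `width` (Angstrom).  `NULL` for an empty map.
#' @param noise_sd Gaussian noise standard deviation (default 0).
#' @return List with `grid` ([density_grid()]) and `manifest` (per-blob
#'   analytic integrals).
#' @export
gen_density_map <- function(seed, dims = c(64, 64, 64), spacing = 0.5,
                            blobs = NULL, noise_sd = 0) {
  spacing <- rep(spacing, length.out = 3)
  ax <- lapply(1:3, function(a) (seq_len(dims[a]) - 1) * spacing[a])
  v <- array(0, dims)
  integrals <- numeric(0)
  if (!is.null(blobs) && nrow(blobs)) {
    for (i in seq_len(nrow(blobs))) {
      r2 <- outer(outer((ax[[1]] - blobs$x[i])^2, (ax[[2]] - blobs$y[i])^2,
                        "+"), (ax[[3]] - blobs$z[i])^2, "+")
      v <- v + blobs$amplitude[i] * exp(-r2 / (2 * blobs$width[i]^2))
    }
    integrals <- blobs$amplitude * (2 * pi)^1.5 * blobs$width^3
  }
  if (noise_sd > 0) {
    set.seed(.subseed(seed, 5))
    v <- v + array(rnorm(prod(dims), 0, noise_sd), dims)
  }
  manifest <- list(generator = "gen_density_map", seed = seed,
                   dims = dims, spacing = spacing, noise_sd = noise_sd,
                   blob_integrals = integrals,
                   blobs = if (is.null(blobs)) list() else blobs)
  list(grid = density_grid(v, spacing = spacing), manifest = manifest)
}

#' Generate a binding trajectory with a scheduled contact pattern
#'
#' Protein residues are single beads spaced 20 Angstrom apart on a line;
#' the ligand is one residue with one atom per scheduled protein residue,
#' placed 4 Angstrom from it while the contact is "on" and 12 Angstrom
#' while "off" (for the conventional 5 Angstrom cutoff).  The contact for
#' residue r is on in the first `round(fraction_r * n_frames)` frames, so
#' realized probabilities are exact by construction and recorded in the
#' manifest.
#'
#' @param seed Integer RNG seed (kept for interface symmetry; the schedule
#'   is deterministic).
#' @param n_frames Number of frames (default 100).
#' @param n_residues Protein residue count (default 200).
#' @param schedule Named numeric vector: residue id -> contact fraction in
#'   `[0, 1]`.
#' @param on_dist,off_dist Ligand-residue distances in the on/off states.
#' @return List with `topology`, `trajectory`, `manifest` (realized
#'   fractions).
#' @export
gen_binding_trajectory <- function(seed, n_frames = 100, n_residues = 200,
                                   schedule = c(`88` = 1.0, `145` = 1.0,
                                                `179` = 0.95, `30` = 0.5,
                                                `60` = 0.2),
                                   on_dist = 4, off_dist = 12) {
  res_ids <- as.integer(names(schedule))
  if (any(is.na(res_ids)) || any(res_ids < 1 | res_ids > n_residues))
    stop("schedule names must be residue ids within 1..n_residues")
  if (any(schedule < 0 | schedule > 1))
    stop("contact fractions must lie in [0, 1]")
  prot_atoms <- data.frame(
    atom_name = "CA", element = "C", residue_name = "ALA",
    residue_id = seq_len(n_residues), chain_id = "A", occupancy = 1,
    b_factor = 0, stringsAsFactors = FALSE)
  lig_atoms <- data.frame(
    atom_name = paste0("L", seq_along(res_ids)), element = "C",
    residue_name = "UNP", residue_id = 9999L, chain_id = "X", occupancy = 1,
    b_factor = 0, stringsAsFactors = FALSE)
  atoms <- rbind(prot_atoms, lig_atoms)
  mols <- rbind(
    data.frame(mol_id = 1L, species = "PROTEIN", first = 1L,
               last = n_residues, residue_name = "ALA", chain_id = "A",
               stringsAsFactors = FALSE),
    data.frame(mol_id = 2L, species = "UNDP", first = n_residues + 1L,
               last = n_residues + length(res_ids), residue_name = "UNP",
               chain_id = "X", stringsAsFactors = FALSE))
  top <- new_topology(atoms, mols)
  box <- c(20 * (n_residues + 1), 100, 100)
  n_on <- round(schedule * n_frames)
  frames <- lapply(seq_len(n_frames), function(f) {
    pos <- matrix(0, nrow(atoms), 3)
    pos[seq_len(n_residues), 1] <- 20 * seq_len(n_residues)
    pos[seq_len(n_residues), 2:3] <- 50
    for (j in seq_along(res_ids)) {
      dy <- if (f <= n_on[j]) on_dist else off_dist
      pos[n_residues + j, ] <- c(20 * res_ids[j], 50 + dy, 50)
    }
    new_frame(pos, box)
  })
  manifest <- list(generator = "gen_binding_trajectory", seed = seed,
                   n_frames = n_frames, schedule = as.list(schedule),
                   realized_fractions = as.list(setNames(n_on / n_frames,
                                                         names(schedule))),
                   on_dist = on_dist, off_dist = off_dist)
  list(topology = top, trajectory = new_trajectory(top, frames),
       manifest = manifest)
}

#' Generate an ideal reentrant-helix pair with a planted hinge angle
#'
#' Two ideal alpha-helices (2.3 Angstrom radius, 1.5 Angstrom rise, 100
#' degrees per residue) meeting at a Ser-Pro-style kink between residues
#' 23 and 24, with axes arranged so the interior hinge angle is exactly
#' `hinge_deg`.  A synthetic stand-in for the deposited reentrant-helix
#' coordinates, usable wherever a real structure is unavailable.
#'
#' @param hinge_deg Planted interior hinge angle, degrees (default 118).
#' @param n_res Total residues (default 36, the reentrant helix).
#' @param kink_after Last residue of the first helix (default 23).
#' @return List with `topology`, `frame` (CA-only chain A), `manifest`.
#' @export
gen_ideal_hinge <- function(hinge_deg = 118, n_res = 36, kink_after = 23) {
  h <- hinge_deg * pi / 180
  d1 <- c(sin(h / 2), 0, -cos(h / 2))
  d2 <- c(sin(h / 2), 0, cos(h / 2))
  helix <- function(axis, origin, n, phase = 0) {
    e1 <- c(0, 1, 0)
    e1 <- e1 - sum(e1 * axis) * axis
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
            axis[3] * e1[1] - axis[1] * e1[3],
            axis[1] * e1[2] - axis[2] * e1[1])
    t(vapply(seq_len(n) - 1, function(t)
      origin + axis * 1.5 * t +
        2.3 * (cos(phase + t * 100 * pi / 180) * e1 +
               sin(phase + t * 100 * pi / 180) * e2), numeric(3)))
  }
  ca1 <- helix(d1, c(0, 0, 0), kink_after)
  junction <- ca1[kink_after, ] + d1 * 1.5
  ca2 <- helix(d2, junction, n_res - kink_after)
  ca <- rbind(ca1, ca2)
  atoms <- data.frame(atom_name = "CA", element = "C", residue_name = "ALA",
                      residue_id = seq_len(n_res), chain_id = "A",
                      occupancy = 1, b_factor = 0, stringsAsFactors = FALSE)
  top <- new_topology(atoms, data.frame(
    mol_id = 1L, species = "PROTEIN", first = 1L, last = n_res,
    residue_name = "ALA", chain_id = "A", stringsAsFactors = FALSE))
  list(topology = top, frame = new_frame(ca, c(200, 200, 200)),
       manifest = list(generator = "gen_ideal_hinge",
                       planted_hinge_deg = hinge_deg, n_res = n_res,
                       kink_after = kink_after))
}
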