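test_that("radius of gyration matches point, pair and ring closed forms", {
  expect_equal(radius_of_gyration(matrix(c(1, 2, 3), 1)), 0)
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(2, 0, 0))), 0.1)
  th <- 2 * pi * seq_len(100) / 100
  ring <- cbind(5 * cos(th), 5 * sin(th), 0)
  expect_equal(radius_of_gyration(ring), 0.5)
  # rigid-motion invariance
  set.seed(71)
  x <- matrix(rnorm(60), ncol = 3)
  ang <- 0.7
  rot <- matrix(c(cos(ang), -sin(ang), 0, sin(ang), cos(ang), 0, 0, 0, 1), 3,
                byrow = TRUE)
  expect_equal(radius_of_gyration(x %*% rot + 5), radius_of_gyration(x))
  expect_error(radius_of_gyration(x, masses = rep(0, 20)), "mass")
})

test_that("rod and ring conformer generators give their closed-form Rg", {
  ge <- gen_undp_conformers(seed = 72, n_frames = 5, mode = "extended")
  re <- rg_series(ge$trajectory, 1:11, masses = rep(1, 11))
  expect_equal(re$mean, ge$manifest$rg_extended_nm, tolerance = 1e-12)
  gc <- gen_undp_conformers(seed = 72, n_frames = 5, mode = "coiled")
  rc <- rg_series(gc$trajectory, 1:11, masses = rep(1, 11))
  expect_equal(rc$mean, gc$manifest$rg_coiled_nm, tolerance = 1e-12)
  expect_gt(re$mean, rc$mean)
  # mixture: clearly bimodal about the two planted values
  gm <- gen_undp_conformers(seed = 73, n_frames = 40, mode = "mixture")
  rm_ <- rg_series(gm$trajectory, 1:11, masses = rep(1, 11))
  lab <- gm$manifest$frame_modes
  expect_equal(unique(rm_$per_frame$rg_nm[lab == "extended"]),
               gm$manifest$rg_extended_nm, tolerance = 1e-12)
  expect_equal(unique(rm_$per_frame$rg_nm[lab == "coiled"]),
               gm$manifest$rg_coiled_nm, tolerance = 1e-12)
})

test_that("Kabsch superposition recovers exact fits and matches a numerical minimizer", {
  set.seed(81)
  a <- matrix(rnorm(300), ncol = 3)
  f0 <- kabsch_superpose(a, a)
  expect_equal(f0$rmsd, 0, tolerance = 1e-12)
  expect_equal(f0$rotation, diag(3), tolerance = 1e-10)
  ang <- pi / 2
  rot <- matrix(c(cos(ang), -sin(ang), 0, sin(ang), cos(ang), 0, 0, 0, 1), 3,
                byrow = TRUE)
  f1 <- kabsch_superpose(a, a %*% rot + matrix(c(3, -2, 7), 100, 3, byrow = TRUE))
  expect_equal(f1$rmsd, 0, tolerance = 1e-10)
  expect_equal(det(f1$rotation), 1, tolerance = 1e-10)
  # one displaced atom among 100: compare with a brute-force numerical
  # minimizer over rotation angles + translation
  b <- a; b[7, ] <- b[7, ] + c(1, 0, 0)
  fk <- kabsch_superpose(a, b)
  obj <- function(p) {
    cz <- cos(p[1]); sz <- sin(p[1]); cy <- cos(p[2]); sy <- sin(p[2])
    cx <- cos(p[3]); sx <- sin(p[3])
    rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
    ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
    rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    fit <- a %*% (rz %*% ry %*% rx) +
      matrix(p[4:6], nrow(a), 3, byrow = TRUE)
    sqrt(mean(rowSums((fit - b)^2)))
  }
  opt <- optim(rep(0, 6), obj, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 500))
  expect_equal(fk$rmsd, opt$value, tolerance = 1e-6)
  expect_lt(fk$rmsd, sqrt(1 / 100))   # superposition spreads the 1 A shift
  expect_error(kabsch_superpose(cbind(1:5, 0, 0), cbind(2 * (1:5), 0, 0)),
               "collinear")
})

test_that("RMSD series is zero for a frozen trajectory and symmetric between frames", {
  g <- gen_protein_two_state(seed = 82, n_frames = 6, noise = 0.1)
  fr1 <- g$trajectory$frames[[1]]
  frozen <- new_trajectory(g$trajectory$topology,
                           rep(list(fr1), 4))
  sel <- which(g$trajectory$topology$atoms$atom_name == "CA")
  r0 <- rmsd_series(frozen, fr1, sel)
  expect_equal(r0$per_frame$rmsd, rep(0, 4), tolerance = 1e-10)
  # symmetry under swapping mobile and reference
  fr2 <- g$trajectory$frames[[2]]
  ab <- kabsch_superpose(fr1$positions[sel, ], fr2$positions[sel, ])$rmsd
  ba <- kabsch_superpose(fr2$positions[sel, ], fr1$positions[sel, ])$rmsd
  expect_equal(ab, ba, tolerance = 1e-10)
  r <- rmsd_series(g$trajectory, fr1, sel)
  expect_true(all(r$per_frame$rmsd >= 0))
  expect_equal(r$cdf$fraction, seq_len(6) / 6)
})

test_that("RMSF matches a direct variance oracle on a scaffold-pinned trajectory", {
  # big rigid scaffold + one atom oscillating +/- d along x; fitting on the
  # scaffold pins the superposition to the identity
  set.seed(83)
  n_sc <- 60
  scaffold <- matrix(rnorm(3 * n_sc, sd = 8), ncol = 3)
  d <- 0.9
  frames <- lapply(1:10, function(f) {
    pos <- rbind(scaffold, c(20, 0, 0) + c(ifelse(f %% 2, d, -d), 0, 0))
    new_frame(pos, c(200, 200, 200))
  })
  atoms <- data.frame(atom_name = "CA", element = "C", residue_name = "ALA",
                      residue_id = seq_len(n_sc + 1), chain_id = "A",
                      occupancy = 1, b_factor = 0, stringsAsFactors = FALSE)
  top <- new_topology(atoms, data.frame(
    mol_id = 1L, species = "PROTEIN", first = 1L, last = n_sc + 1L,
    residue_name = "ALA", chain_id = "A", stringsAsFactors = FALSE))
  tr <- new_trajectory(top, frames)
  rp <- rmsf_profile(tr, seq_len(n_sc + 1), fit_selection = seq_len(n_sc))
  expect_equal(rp$per_atom$rmsf[seq_len(n_sc)], rep(0, n_sc), tolerance = 1e-9)
  expect_equal(rp$per_atom$rmsf[n_sc + 1], d, tolerance = 1e-9)
  expect_equal(rp$per_atom$pseudo_b[n_sc + 1], 8 * pi^2 * d^2 / 3,
               tolerance = 1e-9)
  # frozen trajectory: identically zero
  tr0 <- new_trajectory(top, rep(frames[1], 3))
  rp0 <- rmsf_profile(tr0, seq_len(n_sc + 1))
  expect_equal(max(rp0$per_atom$rmsf), 0, tolerance = 1e-9)
})

test_that("two-state loop ensembles show elevated loop RMSF", {
  g <- gen_protein_two_state(seed = 84, n_frames = 60)
  ca <- which(g$trajectory$topology$atoms$atom_name == "CA")
  rp <- rmsf_profile(g$trajectory, ca)
  loop <- rp$per_atom$residue_id %in% 61:81
  expect_gt(min(rp$per_atom$rmsf[loop]), max(rp$per_atom$rmsf[!loop]))
})

test_that("insertion depth measures protrusion below the phosphate plane", {
  # 4 point lipids at z = 20 (upper) and -20 (lower) plus probe atoms
  probe <- data.frame(atom_name = c("X1", "X2"), element = "C",
                      residue_name = "PRB", residue_id = 999L, chain_id = "Z",
                      occupancy = 1, b_factor = 0, stringsAsFactors = FALSE)
  top <- point_lipid_topology(4, probe)
  mkframe <- function(zs) new_frame(
    rbind(c(0, 0, 20), c(5, 5, 20), c(0, 0, -20), c(5, 5, -20),
          c(2, 2, zs[1]), c(3, 3, zs[2])), c(50, 50, 100))
  # probes above the upper plane: depth 0
  tr_above <- new_trajectory(top, list(mkframe(c(25, 30))))
  expect_equal(insertion_depth(tr_above, 5:6, "upper")$max, 0)
  # probe planted 14 A below the plane
  tr14 <- new_trajectory(top, list(mkframe(c(6, 25))))
  expect_equal(insertion_depth(tr14, 5:6, "upper")$max, 14)
  # z-translation invariance: shift everything by +9
  fr_shift <- mkframe(c(6, 25))
  fr_shift$positions[, 3] <- fr_shift$positions[, 3] + 9
  expect_equal(insertion_depth(new_trajectory(top, list(fr_shift)), 5:6,
                               "upper")$max, 14)
})

test_that("planted insertion depth is recovered from a jittered membrane", {
  set.seed(85)
  g <- gen_membrane(seed = 85, n_frames = 6)
  depth_true <- 11
  # plant a probe at fixed depth below the upper phosphate plane per frame
  top <- g$topology
  probe <- data.frame(atom_name = "X1", element = "C", residue_name = "PRB",
                      residue_id = 9999L, chain_id = "Z", occupancy = 1,
                      b_factor = 0, stringsAsFactors = FALSE)
  atoms2 <- rbind(top$atoms, probe)
  mols2 <- rbind(top$molecules,
                 data.frame(mol_id = max(top$molecules$mol_id) + 1L,
                            species = "other", first = top$n_atoms + 1L,
                            last = top$n_atoms + 1L, residue_name = "PRB",
                            chain_id = "Z", stringsAsFactors = FALSE))
  top2 <- new_topology(atoms2, mols2)
  frames2 <- lapply(g$trajectory$frames, function(fr) {
    la <- assign_leaflets(fr, top)
    plane <- mean(la$assignment$phosphate_z[la$assignment$leaflet == "upper"])
    new_frame(rbind(fr$positions, c(10, 10, plane - depth_true)), fr$box)
  })
  tr2 <- new_trajectory(top2, frames2)
  d <- insertion_depth(tr2, top$n_atoms + 1L, "upper")
  expect_equal(mean(d$per_frame$max_depth), depth_true, tolerance = 1e-9)
})

test_that("hinge angle reads 180 for a straight chain and recovers planted kinks", {
  # straight CA run: both window axes identical
  n <- 36
  ca <- cbind(seq_len(n) * 1.5, 0, 0)
  atoms <- data.frame(atom_name = "CA", element = "C", residue_name = "ALA",
                      residue_id = seq_len(n), chain_id = "A", occupancy = 1,
                      b_factor = 0, stringsAsFactors = FALSE)
  top <- new_topology(atoms, data.frame(
    mol_id = 1L, species = "PROTEIN", first = 1L, last = n,
    residue_name = "ALA", chain_id = "A", stringsAsFactors = FALSE))
  fr <- new_frame(ca, c(100, 100, 100))
  expect_equal(hinge_angle(fr, top, c(7, 22), c(25, 36)), 180, tolerance = 1e-8)
  # planted ideal-helix kinks recovered within the helix-phase wobble
  for (h in c(100, 118, 120, 150)) {
    gh <- gen_ideal_hinge(hinge_deg = h)
    got <- hinge_angle(gh$frame, gh$topology, c(7, 22), c(25, 36))
    expect_lt(abs(got - h), 2.5)
  }
  # rigid-body invariance
  gh <- gen_ideal_hinge(118)
  ang <- 1.1
  rot <- matrix(c(cos(ang), -sin(ang), 0, sin(ang), cos(ang), 0, 0, 0, 1), 3,
                byrow = TRUE)
  fr2 <- new_frame(gh$frame$positions %*% rot + 30, gh$frame$box)
  expect_equal(hinge_angle(fr2, gh$topology, c(7, 22), c(25, 36)),
               hinge_angle(gh$frame, gh$topology, c(7, 22), c(25, 36)),
               tolerance = 1e-8)
  # axis convention is the supplement
  expect_equal(hinge_angle(fr, top, c(7, 22), c(25, 36), convention = "axis"),
               0, tolerance = 1e-8)
  expect_error(hinge_angle(fr, top, c(7, 9), c(25, 36)), "at least 4")
})

test_that("CA distances are exact and separate open from closed loop states", {
  atoms <- data.frame(atom_name = "CA", element = "C", residue_name = "ALA",
                      residue_id = 1:2, chain_id = "A", occupancy = 1,
                      b_factor = 0, stringsAsFactors = FALSE)
  top <- new_topology(atoms, data.frame(
    mol_id = 1L, species = "PROTEIN", first = 1L, last = 2L,
    residue_name = "ALA", chain_id = "A", stringsAsFactors = FALSE))
  fr <- new_frame(rbind(c(0, 0, 0), c(3, 4, 0)), c(100, 100, 100))
  expect_equal(ca_distance(fr, top, 1, 2), 5)
  expect_equal(ca_distance(fr, top, 1, 1), 0)
  expect_error(ca_distance(fr, top, 1, 7), "no CA")

  g <- gen_protein_two_state(seed = 86, n_frames = 30)
  d <- vapply(g$trajectory$frames, function(f)
    ca_distance(f, g$trajectory$topology, 70, 121), numeric(1))
  st <- g$manifest$states_trajectory
  expect_gt(mean(d[st == -1]), mean(d[st == 1]))  # open wider than closed
})
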