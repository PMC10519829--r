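test_that("lipid_director recovers chain axes and reduces to a segment for 2 atoms", {
  fr <- new_frame(cbind(0, 0, seq(0, -15, length.out = 16)), c(50, 50, 50))
  expect_equal(lipid_director(fr, 1:16), c(0, 0, -1))
  # transverse jitter around the -z axis: principal axis stays near -z
  set.seed(21)
  pos <- cbind(rnorm(16, 0, 0.3), rnorm(16, 0, 0.3), seq(0, -15, length.out = 16))
  frj <- new_frame(pos, c(50, 50, 50))
  d <- lipid_director(frj, 1:16)
  expect_lt(d[3], -0.99)
  # principal-axis oracle: direct SVD of centred coordinates
  xc <- sweep(pos, 2, colMeans(pos))
  v <- svd(xc)$v[, 1]
  if (v[3] > 0) v <- -v
  expect_equal(d, v, tolerance = 1e-10)
  # 2-atom chain: exactly the normalized difference
  fr2 <- new_frame(rbind(c(0, 0, 0), c(3, 4, 0)), c(50, 50, 50))
  expect_equal(lipid_director(fr2, 1:2), c(0.6, 0.8, 0))
  frd <- new_frame(rbind(c(1, 1, 1), c(1, 1, 1), c(1, 1, 1)), c(50, 50, 50))
  expect_error(lipid_director(frd, 1:3), "degenerate")
})

test_that("P2 hits the closed-form values for planted tilt angles", {
  for (case in list(list(theta = 0, p2 = 1.0), list(theta = 90, p2 = -0.5),
                    list(theta = 45, p2 = 0.25))) {
    g <- gen_membrane(seed = 31, n_frames = 2, tilt_theta = case$theta,
                      z_jitter = 0)
    r <- compute_p2(g$trajectory)
    expect_equal(r$summary$mean, rep(case$p2, nrow(r$summary)),
                 tolerance = 1e-12)
    expect_equal(r$per_frame$p2, rep(case$p2, nrow(r$per_frame)),
                 tolerance = 1e-12)
  }
})

test_that("P2 of isotropically random directors vanishes at the Monte Carlo rate", {
  set.seed(33)
  n <- 4000
  u <- matrix(rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  p2 <- mean(0.5 * (3 * u[, 3]^2 - 1))
  expect_lt(abs(p2), 3 / sqrt(n))
})

test_that("P2 values stay within the theoretical bounds on noisy membranes", {
  g <- gen_membrane(seed = 34, n_frames = 3, tilt_theta = 28, jitter_xy = 0.2)
  r <- compute_p2(g$trajectory)
  expect_true(all(r$per_frame$p2 >= -0.5 & r$per_frame$p2 <= 1.0))
  expect_equal(r$summary$mean, rep(g$manifest$planted_p2, nrow(r$summary)),
               tolerance = 1e-9)
})

test_that("hexatic order is 1 on a perfect lattice and rotation/translation invariant", {
  pts <- hex_lattice(10, 10, a = 2)
  box <- hex_box(10, 10, a = 2)
  r <- compute_psi6(pts, box)
  expect_true(all(abs(r$modulus - 1) < 1e-10))
  expect_true(all(r$modulus >= 0 & r$modulus <= 1))
  # rotation invariance checked on an unwrapped cluster in a huge box
  bigbox <- c(1e5, 1e5, 1)
  ctr <- colMeans(pts)
  base <- compute_psi6(sweep(pts, 2, ctr), bigbox)$modulus
  for (ang in c(0.3, 1.2, 2.9)) {
    rot <- matrix(c(cos(ang), -sin(ang), sin(ang), cos(ang)), 2)
    rpts <- sweep(pts, 2, ctr) %*% rot + 17.5
    expect_equal(compute_psi6(rpts, bigbox)$modulus, base, tolerance = 1e-10)
  }
  expect_error(compute_psi6(pts[1:6, ], box), "at least 7")
})

test_that("hexatic order matches an independent direct-sum oracle on a jittered lattice", {
  set.seed(41)
  a <- 2
  pts <- hex_lattice(8, 8, a)
  pts <- pts + matrix(rnorm(length(pts), 0, 0.3 * a), ncol = 2)
  box <- hex_box(8, 8, a)
  r <- compute_psi6(pts, box)
  expect_equal(r$modulus, psi6_oracle(pts, box), tolerance = 1e-12)
  # jittered lattice sits between random-gas and perfect order
  expect_gt(mean(r$modulus), 0.1)
  expect_lt(mean(r$modulus), 0.95)
})

test_that("Voronoi cells on a square lattice are equal and partition the box", {
  n <- 5
  g <- expand.grid(x = (0:(n - 1)) + 0.5, y = (0:(n - 1)) + 0.5)
  areas <- periodic_voronoi(as.matrix(g), c(n, n, 1))
  expect_equal(areas, rep(1, n * n), tolerance = 1e-9)
  set.seed(51)
  for (i in 1:3) {
    pts <- cbind(runif(120, 0, 30), runif(120, 0, 20))
    areas <- periodic_voronoi(pts, c(30, 20, 1))
    expect_true(all(areas > 0))
    expect_equal(sum(areas), 600, tolerance = 1e-6)
  }
  expect_error(periodic_voronoi(rbind(c(1, 1), c(1, 1), c(2, 2)), c(10, 10)),
               "duplicate")
})

test_that("per-molecule Voronoi areas scale with chain count on the ordered bilayer", {
  g <- gen_membrane(seed = 52, n_frames = 1, tilt_theta = 0, jitter_xy = 0,
                    z_jitter = 0)
  fr <- g$trajectory$frames[[1]]
  la <- assign_leaflets(fr, g$topology)
  va <- voronoi_areas(fr, g$topology, la, "upper")
  expect_equal(sum(va$per_chain$area), va$box_area, tolerance = 1e-6)
  s <- va$summary
  # all chains occupy identical hexagonal cells: a 4-chain CL covers twice
  # the area of a 2-chain POPE/POPG
  expect_equal(s$mean_area[s$species == "CL"],
               2 * s$mean_area[s$species == "POPE"], tolerance = 1e-6)
  expect_equal(s$mean_area[s$species == "POPE"],
               s$mean_area[s$species == "POPG"], tolerance = 1e-6)
})

test_that("density profiles conserve group mass and centre on the midplane", {
  # uniform gas: flat within binomial sampling bounds
  n <- 6000
  set.seed(61)
  extra <- data.frame(atom_name = "AR", element = "AR", residue_name = "GAS",
                      residue_id = 1000L, chain_id = "G", occupancy = 1,
                      b_factor = 0, stringsAsFactors = FALSE)[rep(1, n), ]
  top <- point_lipid_topology(2, extra)
  box <- c(20, 20, 50)
  pos <- rbind(c(0, 0, 10), c(0, 0, -10),
               cbind(runif(n, 0, 20), runif(n, 0, 20), runif(n, -25, 25)))
  tr <- new_trajectory(top, list(new_frame(pos, box)))
  nb <- 25
  dp <- density_profile(tr, list(gas = 2 + seq_len(n)), n_bins = nb,
                        masses = rep(1, n + 2))
  counts <- dp$density[, 1] * dp$bin_width * dp$box_area
  p <- 1 / nb
  expect_true(all(abs(counts - n * p) <= 4 * sqrt(n * p * (1 - p))))
  # point slab: single-bin spike conserving mass
  pos2 <- pos; pos2[2 + seq_len(n), 3] <- 15.2
  tr2 <- new_trajectory(top, list(new_frame(pos2, box)))
  dp2 <- density_profile(tr2, list(gas = 2 + seq_len(n)), n_bins = nb,
                         masses = rep(1, n + 2))
  expect_equal(sum(dp2$density[, 1] > 0), 1L)
  expect_equal(sum(dp2$density[, 1]) * dp2$bin_width * dp2$box_area, n)
  # integer-box z-wrap leaves the profile unchanged
  pos3 <- pos; pos3[, 3] <- pos3[, 3] + box[3]
  dp3 <- density_profile(new_trajectory(top, list(new_frame(pos3, box))),
                         list(gas = 2 + seq_len(n)), n_bins = nb,
                         masses = rep(1, n + 2))
  expect_equal(dp3$density, dp$density)
  expect_warning(
    density_profile(tr, list(gas = 2 + seq_len(n), none = integer(0)),
                    n_bins = nb, masses = rep(1, n + 2)), "empty group")
})

test_that("bilayer phosphate density is bimodal with UndP anchored at one interface", {
  g <- gen_membrane(seed = 62, n_frames = 3)
  top <- g$topology
  ph <- select_atoms(top, "name P or name P1 or name P3")
  ph <- ph[top$atoms$residue_name[ph] != "UNP"]
  up <- which(top$atoms$atom_name == "P" & top$atoms$residue_name == "UNP")
  dp <- density_profile(g$trajectory, list(phos = ph, undp = up), n_bins = 40)
  prof <- dp$density[, "phos"]
  upper_peak <- dp$z[dp$z > 0][which.max(prof[dp$z > 0])]
  lower_peak <- dp$z[dp$z < 0][which.max(prof[dp$z < 0])]
  expect_gt(upper_peak, 10)
  expect_lt(lower_peak, -10)
  undp_peak <- dp$z[which.max(dp$density[, "undp"])]
  expect_lt(abs(undp_peak - upper_peak), 2 * dp$bin_width)
})
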