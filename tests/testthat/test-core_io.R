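test_that("read_structure parses hand-written PDB records with metadata intact", {
  p <- write_tiny_pdb(c(
    pdb_atom_line(1, "N", "ALA", "A", 1, 0, 0, 0, occ = 0.5, b = 11.5, element = "N"),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 1.5, 0, 0, b = 12.5),
    pdb_atom_line(3, "C", "ALA", "A", 1, 2.2, 1.1, 0, b = 13.5),
    "END"))
  s <- read_structure(p)
  expect_equal(s$topology$n_atoms, 3L)
  expect_equal(nrow(s$topology$molecules), 1L)
  expect_equal(s$topology$molecules$species, "PROTEIN")
  expect_equal(s$frame$positions[2, ], c(1.5, 0, 0))
  expect_equal(s$topology$atoms$b_factor, c(11.5, 12.5, 13.5))
  expect_equal(s$topology$atoms$occupancy[1], 0.5)
})

test_that("two protein chains become two molecules with correct residue ranges", {
  p <- write_tiny_pdb(c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "GLY", "A", 2, 3.8, 0, 0),
    pdb_atom_line(3, "CA", "ALA", "B", 5, 0, 5, 0),
    pdb_atom_line(4, "CA", "GLY", "B", 6, 3.8, 5, 0),
    "END"))
  s <- read_structure(p)
  mol <- s$topology$molecules
  expect_equal(nrow(mol), 2L)
  expect_equal(mol$chain_id, c("A", "B"))
  expect_equal(s$topology$atoms$residue_id[mol$first[2]:mol$last[2]], c(5L, 6L))
})

test_that("malformed and degenerate structure files raise parse errors", {
  bad <- write_tiny_pdb(c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    sub("   0.000", "  xx.yyy", pdb_atom_line(2, "CA", "GLY", "A", 2, 0, 1, 0))))
  expect_error(read_structure(bad), "line")
  empty <- write_tiny_pdb("END")
  expect_error(read_structure(empty), "no ATOM")
  expect_error(read_structure(tempfile()), "not found")
})

test_that("triclinic unit cells are rejected", {
  p <- write_tiny_pdb(c(
    "CRYST1   50.000   50.000   50.000  90.00  90.00 120.00 P 1           1",
    pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    "END"))
  expect_error(read_structure(p), "triclinic")
})

test_that("multi-model PDB trajectories read in file order and round-trip", {
  p <- write_tiny_pdb(c(
    "MODEL        1",
    pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "GLY", "A", 2, 3.8, 0, 0),
    "ENDMDL",
    "MODEL        2",
    pdb_atom_line(1, "CA", "ALA", "A", 1, 0.25, 0, 0),
    pdb_atom_line(2, "CA", "GLY", "A", 2, 4.05, 0, 0),
    "ENDMDL"))
  tr <- read_trajectory(p)
  expect_equal(length(tr), 2L)
  expect_equal(tr$frames[[2]]$positions[1, 1], 0.25)

  g <- gen_membrane(seed = 91, n_frames = 2, n_lipids = 20)
  out <- tempfile(fileext = ".pdb")
  write_trajectory(g$trajectory, out)
  rt <- read_trajectory(out)
  expect_equal(length(rt), 2L)
  # PDB precision contract: 3 decimals
  expect_lt(max(abs(rt$frames[[1]]$positions - g$trajectory$frames[[1]]$positions)),
            5.1e-4)
  expect_identical(rt$topology$atoms$atom_name, g$topology$atoms$atom_name)
  expect_equal(table(rt$topology$molecules$species),
               table(g$topology$molecules$species))
})

test_that("a model with a missing atom is reported by model index", {
  p <- write_tiny_pdb(c(
    "MODEL        1",
    pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "GLY", "A", 2, 3.8, 0, 0),
    "ENDMDL",
    "MODEL        2",
    pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    "ENDMDL"))
  expect_error(read_trajectory(p), "model 2")
})

test_that("XYZ-with-box trajectories round-trip with per-frame boxes", {
  g <- gen_membrane(seed = 92, n_frames = 3, n_lipids = 20)
  out <- tempfile(fileext = ".xyz")
  write_trajectory(g$trajectory, out)
  rt <- read_trajectory(out)
  expect_equal(length(rt), 3L)
  expect_lt(max(abs(rt$frames[[3]]$positions - g$trajectory$frames[[3]]$positions)),
            1e-5)
  expect_equal(rt$frames[[1]]$box, g$trajectory$frames[[1]]$box, tolerance = 1e-5)
  # malformed comment line
  ln <- readLines(out)
  ln[2] <- "not a box line"
  writeLines(ln, out)
  expect_error(read_trajectory(out), "box Lx Ly Lz")
})

test_that("minimum_image wraps into [-box/2, box/2) and is idempotent", {
  box <- c(10, 10, 10)
  expect_equal(minimum_image(c(9, 0, 0), box), c(-1, 0, 0))
  expect_equal(minimum_image(c(0, 0, 0), box), c(0, 0, 0))
  # boundary convention: +box/2 maps to -box/2
  expect_equal(minimum_image(c(5, 5, 5), box), c(-5, -5, -5))
  set.seed(11)
  d <- matrix(runif(300, -50, 50), ncol = 3)
  w <- minimum_image(d, box)
  expect_true(all(w >= -5 & w < 5))
  expect_equal(minimum_image(w, box), w)
})

test_that("leaflet assignment is translation-invariant and splits the bilayer evenly", {
  # two point lipids straddling zero
  top <- point_lipid_topology(2)
  fr <- new_frame(rbind(c(0, 0, 20), c(0, 0, -20)), c(50, 50, 100))
  la <- assign_leaflets(fr, top)
  expect_equal(la$assignment$leaflet, c("upper", "lower"))
  expect_equal(la$midplane_z, 0)
  fr2 <- new_frame(fr$positions + matrix(c(0, 0, 7), 2, 3, byrow = TRUE), fr$box)
  la2 <- assign_leaflets(fr2, top)
  expect_equal(la2$assignment$leaflet, la$assignment$leaflet)
  expect_equal(la2$midplane_z, la$midplane_z + 7)

  g <- gen_membrane(seed = 5, n_frames = 1)
  la3 <- assign_leaflets(g$trajectory$frames[[1]], g$topology)
  phl <- la3$assignment[la3$assignment$species != "UNDP", ]
  expect_equal(sum(phl$leaflet == "upper"), g$manifest$n_per_leaflet)
  expect_equal(sum(phl$leaflet == "lower"), g$manifest$n_per_leaflet)
  # UndP planted in the upper leaflet
  expect_true(all(la3$assignment$leaflet[la3$assignment$species == "UNDP"] ==
                  "upper"))
})

test_that("a lipid without the named phosphate is reported by molecule", {
  top <- point_lipid_topology(2)
  top$atoms$atom_name[2] <- "C1"
  fr <- new_frame(rbind(c(0, 0, 20), c(0, 0, -20)), c(50, 50, 100))
  expect_error(assign_leaflets(fr, top), "molecule 2")
})

test_that("selection grammar resolves species/name/resid/chain with and/or", {
  g <- gen_membrane(seed = 6, n_frames = 1, n_lipids = 20)
  top <- g$topology
  pe_p <- select_atoms(top, "species POPE and name P")
  expect_true(all(top$atoms$atom_name[pe_p] == "P"))
  expect_equal(length(pe_p), 2 * unname(unlist(g$manifest$composition["POPE"])))
  both <- select_atoms(top, "name P1 or name P3")
  expect_true(all(top$atoms$residue_name[both] == "CL"))
  rr <- select_atoms(top, "resid 3-5 and chain U")
  expect_true(all(top$atoms$residue_id[rr] %in% 3:5))
  expect_warning(empty <- select_atoms(top, "name ZZZ"), "matched no atoms")
  expect_length(empty, 0L)
  expect_error(select_atoms(top, "bogus POPE"), "unknown token")
  expect_error(select_atoms(top, "resid abc"), "bad resid")
})

test_that("config files parse species, director, terminal and selection sections", {
  cfg <- tempfile(fileext = ".cfg")
  writeLines(c(
    "# comment",
    "[species]",
    "CDL2 = CL",
    "[directors]",
    "POPE.sn1 = C31 C32 C33",
    "[terminal]",
    "POPE = C316 C214",
    "[selections]",
    "loop = resid 61-81"), cfg)
  cc <- read_config(cfg)
  expect_equal(unname(cc$species["CDL2"]), "CL")
  expect_equal(cc$directors$POPE$sn1, c("C31", "C32", "C33"))
  expect_equal(cc$terminal$POPE, c("C316", "C214"))
  expect_equal(cc$selections$loop, "resid 61-81")
  writeLines(c("no section = 1"), cfg)
  expect_error(read_config(cfg), "malformed")
})
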