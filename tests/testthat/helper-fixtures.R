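# fixtures built in code: tiny PDB texts and hand-made topologies

write_tiny_pdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(lines, path)
  path
}

pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          occ = 1, b = 0, element = substr(name, 1, 1),
                          record = "ATOM  ") {
  nm <- if (nchar(name) < 4) paste0(" ", name) else name
  sprintf("%s%5d %-4s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, nm, resname, chain, resno, x, y, z, occ, b, element)
}

# topology of n single-atom "lipids" (one P each) plus optional extra atoms
point_lipid_topology <- function(n, extra_atoms = NULL) {
  atoms <- data.frame(atom_name = rep("P", n), element = "P",
                      residue_name = "POPE", residue_id = seq_len(n),
                      chain_id = "A", occupancy = 1, b_factor = 0,
                      stringsAsFactors = FALSE)
  mols <- data.frame(mol_id = seq_len(n), species = "POPE",
                     first = seq_len(n), last = seq_len(n),
                     residue_name = "POPE", chain_id = "A",
                     stringsAsFactors = FALSE)
  if (!is.null(extra_atoms)) {
    k <- nrow(extra_atoms)
    atoms <- rbind(atoms, extra_atoms)
    mols <- rbind(mols, data.frame(
      mol_id = n + 1L, species = "other", first = n + 1L, last = n + k,
      residue_name = extra_atoms$residue_name[1],
      chain_id = extra_atoms$chain_id[1], stringsAsFactors = FALSE))
  }
  new_topology(atoms, mols)
}

# perfect hexagonal lattice with periodic wrap, nx columns x ny rows (even)
hex_lattice <- function(nx, ny, a = 1) {
  stopifnot(ny %% 2 == 0)
  row <- rep(seq_len(ny) - 1, each = nx)
  col <- rep(seq_len(nx) - 1, times = ny)
  cbind(x = col * a + (row %% 2) * a / 2, y = row * a * sqrt(3) / 2)
}

hex_box <- function(nx, ny, a = 1) c(nx * a, ny * a * sqrt(3) / 2, 1)

# independent direct-sum hexatic oracle: explicit 9-image minimum distance
psi6_oracle <- function(pts, box) {
  n <- nrow(pts)
  shifts <- as.matrix(expand.grid(ix = -1:1, iy = -1:1))
  mods <- numeric(n)
  for (k in seq_len(n)) {
    best <- matrix(NA_real_, n, 3) # d2, dx, dy per partner
    for (l in seq_len(n)) {
      if (l == k) { best[l, 1] <- Inf; next }
      cand <- cbind(pts[l, 1] + shifts[, 1] * box[1] - pts[k, 1],
                    pts[l, 2] + shifts[, 2] * box[2] - pts[k, 2])
      d2 <- cand[, 1]^2 + cand[, 2]^2
      j <- which.min(d2)
      best[l, ] <- c(d2[j], cand[j, 1], cand[j, 2])
    }
    nn <- order(best[, 1])[1:6]
    th <- atan2(best[nn, 3], best[nn, 2])
    mods[k] <- Mod(mean(exp(1i * 6 * th)))
  }
  mods
}
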