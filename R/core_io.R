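#' @importFrom stats sd setNames aggregate
#' @importFrom utils head tail read.table write.csv
NULL

# Residue names treated as amino acids when classifying molecules.
.aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "HSD",
          "HSE", "HSP", "ILE", "LEU", "LYS", "MET", "MSE", "PHE", "PRO", "SER",
          "THR", "TRP", "TYR", "VAL")

#' Default residue-name to species mapping
#'
#' PDB residue naming for lipids is dialect-ridden; species identification
#' therefore goes through an explicit, overridable mapping from residue name
#' to one of the species labels `POPE`, `POPG`, `CL`, `UNDP`, `PROTEIN`
#' (amino-acid residue names map to `PROTEIN` automatically) or `other`.
#'
#' @return Named character vector: names are residue names as written in the
#'   file, values are species labels.
#' @export
default_species_map <- function() {
  c(POPE = "POPE", POPG = "POPG",
    CL = "CL", CDL = "CL", CDL2 = "CL", TOCL = "CL",
    UNP = "UNDP", UNDP = "UNDP", UDP55 = "UNDP")
}

#' Construct a simulation frame
#'
#' @param positions Numeric N x 3 matrix of coordinates in Angstrom.
#' @param box Length-3 numeric vector of orthorhombic box edges (Angstrom).
#' @return Object of class `frame`.
#' @export
new_frame <- function(positions, box) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  if (ncol(positions) != 3L)
    stop("positions must be an N x 3 matrix")
  if (!all(is.finite(positions)))
    stop("positions contain non-finite values")
  box <- as.numeric(box)
  if (length(box) != 3L || !all(is.finite(box)) || any(box <= 0))
    stop("box must be three positive orthorhombic edge lengths (Angstrom)")
  structure(list(positions = positions, box = box), class = "frame")
}

#' Construct a topology
#'
#' A topology holds the per-atom record table and the molecule table that
#' partitions atoms into molecules with species labels.
#'
#' @param atoms data.frame with columns `atom_name`, `element`,
#'   `residue_name`, `residue_id`, `chain_id`, `occupancy`, `b_factor`.
#' @param molecules data.frame with columns `mol_id`, `species`, `first`,
#'   `last` (1-based inclusive atom index ranges).
#' @return Object of class `topology`.
#' @export
new_topology <- function(atoms, molecules) {
  stopifnot(is.data.frame(atoms), is.data.frame(molecules))
  n <- nrow(atoms)
  o <- order(molecules$first)
  molecules <- molecules[o, , drop = FALSE]
  if (nrow(molecules)) {
    if (molecules$first[1] != 1L || molecules$last[nrow(molecules)] != n ||
        any(molecules$first[-1] != molecules$last[-nrow(molecules)] + 1L))
      stop("molecule atom ranges must be disjoint and cover all atoms")
  }
  oc <- atoms$occupancy
  if (any(!is.na(oc) & (oc < 0 | oc > 1)))
    stop("occupancy values must lie in [0, 1]")
  rownames(molecules) <- NULL
  structure(list(atoms = atoms, molecules = molecules, n_atoms = n),
            class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat("<topology> ", x$n_atoms, " atoms, ", nrow(x$molecules),
      " molecules\n", sep = "")
  print(table(x$molecules$species))
  invisible(x)
}

#' Construct a trajectory
#'
#' @param topology A [new_topology()] object.
#' @param frames List of [new_frame()] objects with identical atom counts.
#' @param times Optional numeric frame times (ns), strictly increasing.
#' @return Object of class `trajectory`.
#' @export
new_trajectory <- function(topology, frames, times = NULL) {
  stopifnot(inherits(topology, "topology"), is.list(frames), length(frames) >= 1)
  n <- vapply(frames, function(f) nrow(f$positions), integer(1))
  if (any(n != topology$n_atoms))
    stop("frame ", which(n != topology$n_atoms)[1],
         " has ", n[which(n != topology$n_atoms)[1]],
         " atoms but topology declares ", topology$n_atoms)
  if (!is.null(times)) {
    if (length(times) != length(frames) || any(diff(times) <= 0))
      stop("frame times must match frame count and increase strictly")
  }
  structure(list(topology = topology, frames = frames, times = times),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", length(x$frames), " frames x ",
      x$topology$n_atoms, " atoms\n", sep = "")
  invisible(x)
}

#' @export
length.trajectory <- function(x) length(x$frames)

# Classify bio3d atom table rows into molecules: each non-protein residue is
# one molecule; protein = one molecule per chain (contiguous amino residues).
.molecules_from_atoms <- function(atoms, species_map) {
  is_aa <- atoms$residue_name %in% .aa3
  key <- ifelse(is_aa,
                paste0("PROT|", atoms$chain_id),
                paste("RES", atoms$chain_id, atoms$residue_id,
                      atoms$residue_name, sep = "|"))
  # preserve file order of first appearance
  grp <- match(key, unique(key))
  first <- tapply(seq_along(grp), grp, min)
  last <- tapply(seq_along(grp), grp, max)
  rn <- atoms$residue_name[first]
  species <- ifelse(rn %in% .aa3, "PROTEIN",
                    ifelse(rn %in% names(species_map),
                           unname(species_map[rn]), "other"))
  data.frame(mol_id = seq_along(first), species = species,
             first = as.integer(first), last = as.integer(last),
             residue_name = rn, chain_id = atoms$chain_id[first],
             stringsAsFactors = FALSE)
}

.atoms_from_bio3d <- function(pdb) {
  data.frame(
    atom_name = trimws(pdb$atom$elety),
    element = ifelse(is.na(pdb$atom$elesy) | pdb$atom$elesy == "",
                     substr(trimws(pdb$atom$elety), 1, 1),
                     trimws(pdb$atom$elesy)),
    residue_name = trimws(pdb$atom$resid),
    residue_id = pdb$atom$resno,
    chain_id = ifelse(is.na(pdb$atom$chain), " ", pdb$atom$chain),
    occupancy = pdb$atom$o,
    b_factor = pdb$atom$b,
    stringsAsFactors = FALSE)
}

# Validate MODEL blocks of a PDB file: equal atom counts, report model index.
.scan_pdb_models <- function(path) {
  ln <- readLines(path, warn = FALSE)
  rec <- substr(ln, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) stop("no ATOM/HETATM records in '", path, "'")
  xs <- substr(ln[is_atom], 31, 54)
  bad <- which(is.na(suppressWarnings(as.numeric(substr(xs, 1, 8)))) |
               is.na(suppressWarnings(as.numeric(substr(xs, 9, 16)))) |
               is.na(suppressWarnings(as.numeric(substr(xs, 17, 24)))))
  if (length(bad)) {
    line_no <- which(is_atom)[bad[1]]
    stop("malformed coordinate field at line ", line_no, " of '", path, "'")
  }
  model_starts <- which(startsWith(ln, "MODEL"))
  if (length(model_starts) <= 1L) return(invisible(sum(is_atom)))
  model_of <- findInterval(which(is_atom), model_starts)
  counts <- tabulate(model_of, nbins = length(model_starts))
  if (length(unique(counts[counts > 0])) > 1L) {
    ref <- counts[counts > 0][1]
    bad_model <- which(counts > 0 & counts != ref)[1]
    stop("model ", bad_model, " has ", counts[bad_model],
         " atoms; expected ", ref)
  }
  invisible(counts[1])
}

.box_from_cryst1 <- function(path) {
  ln <- readLines(path, warn = FALSE)
  cr <- ln[startsWith(ln, "CRYST1")]
  if (!length(cr)) return(NULL)
  v <- suppressWarnings(as.numeric(c(substr(cr[1], 7, 15), substr(cr[1], 16, 24),
                                     substr(cr[1], 25, 33))))
  ang <- suppressWarnings(as.numeric(c(substr(cr[1], 34, 40), substr(cr[1], 41, 47),
                                       substr(cr[1], 48, 54))))
  if (any(is.na(v))) return(NULL)
  if (!all(is.na(ang)) && any(abs(ang - 90) > 1e-3))
    stop("triclinic unit cells are not supported (angles ",
         paste(ang, collapse = ", "), "); orthorhombic boxes only")
  v
}

#' Read a structure from a PDB file
#'
#' Parses ATOM/HETATM records (via bio3d), classifies atoms into molecules
#' (one per non-protein residue; one per protein chain) and returns the
#' topology together with the single coordinate frame.  B-factors and
#' occupancies are preserved on the atom table.
#'
#' @param path Path to a PDB file.
#' @param species_map Residue-name to species mapping, see
#'   [default_species_map()].
#' @param box Optional box override (Angstrom); default from CRYST1 when
#'   present, else a bounding box with 10 A padding.
#' @return List with elements `topology` and `frame`.
#' @export
read_structure <- function(path, species_map = default_species_map(),
                           box = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  .scan_pdb_models(path)
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  atoms <- .atoms_from_bio3d(pdb)
  if (nrow(atoms) == 0L) stop("no atoms parsed from '", path, "'")
  pos <- cbind(pdb$atom$x, pdb$atom$y, pdb$atom$z)
  if (is.null(box)) box <- .box_from_cryst1(path)
  if (is.null(box)) box <- apply(pos, 2, function(v) diff(range(v))) + 20
  box[box <= 0] <- 1
  mol <- .molecules_from_atoms(atoms, species_map)
  list(topology = new_topology(atoms, mol),
       frame = new_frame(pos, box))
}

#' Read a multi-frame trajectory
#'
#' Accepts multi-model PDB (MODEL/ENDMDL blocks; all models must share atom
#' count and order) or the XYZ-with-box dialect, where each frame's comment
#' line reads `box Lx Ly Lz` in Angstrom.  Format is chosen by file
#' extension (`.pdb` vs `.xyz`).
#'
#' @inheritParams read_structure
#' @param topology Optional pre-built topology (required for `.xyz`, whose
#'   records carry only element symbols).
#' @return A [new_trajectory()] object, frames in file order.
#' @export
read_trajectory <- function(path, species_map = default_species_map(),
                            topology = NULL, box = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "xyz") return(.read_xyz_box(path, topology))
  .scan_pdb_models(path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atoms <- .atoms_from_bio3d(pdb)
  if (is.null(box)) box <- .box_from_cryst1(path)
  n <- nrow(atoms)
  xyz <- pdb$xyz                       # n_models x 3N
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  frames <- lapply(seq_len(nrow(xyz)), function(i) {
    pos <- matrix(xyz[i, ], ncol = 3, byrow = TRUE)
    b <- box
    if (is.null(b)) b <- apply(pos, 2, function(v) diff(range(v))) + 20
    b[b <= 0] <- 1
    new_frame(pos, b)
  })
  if (is.null(topology))
    topology <- new_topology(atoms, .molecules_from_atoms(atoms, species_map))
  new_trajectory(topology, frames)
}

.read_xyz_box <- function(path, topology) {
  ln <- readLines(path, warn = FALSE)
  i <- 1L; frames <- list(); k <- 0L
  while (i <= length(ln)) {
    if (!nzchar(trimws(ln[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(ln[i])))
    if (is.na(n)) stop("expected atom count at line ", i, " of '", path, "'")
    cm <- strsplit(trimws(ln[i + 1L]), "\\s+")[[1]]
    if (length(cm) < 4L || tolower(cm[1]) != "box")
      stop("frame ", k + 1L, ": comment line must read 'box Lx Ly Lz'")
    box <- as.numeric(cm[2:4])
    rows <- ln[(i + 2L):(i + 1L + n)]
    fields <- strsplit(trimws(rows), "\\s+")
    pos <- t(vapply(fields, function(f) as.numeric(f[2:4]), numeric(3)))
    if (any(!is.finite(pos)))
      stop("frame ", k + 1L, ": non-numeric coordinate")
    k <- k + 1L
    frames[[k]] <- new_frame(pos, box)
    i <- i + 2L + n
  }
  if (!length(frames)) stop("no frames in '", path, "'")
  nn <- vapply(frames, function(f) nrow(f$positions), integer(1))
  if (length(unique(nn)) != 1L)
    stop("model ", which(nn != nn[1])[1], " has inconsistent atom count")
  if (is.null(topology)) {
    fields <- strsplit(trimws(ln[3:(2 + nn[1])]), "\\s+")
    el <- vapply(fields, `[`, character(1), 1)
    atoms <- data.frame(atom_name = el, element = el, residue_name = "UNK",
                        residue_id = seq_along(el), chain_id = " ",
                        occupancy = NA_real_, b_factor = NA_real_,
                        stringsAsFactors = FALSE)
    topology <- new_topology(atoms, data.frame(
      mol_id = 1L, species = "other", first = 1L, last = nn[1],
      residue_name = "UNK", chain_id = " ", stringsAsFactors = FALSE))
  }
  new_trajectory(topology, frames)
}

#' Write a trajectory
#'
#' Multi-model PDB (`.pdb`, coordinates at the format's 3-decimal precision,
#' box on CRYST1) or XYZ-with-box (`.xyz`).
#'
#' @param trajectory A [new_trajectory()] object.
#' @param path Output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  ext <- tolower(tools::file_ext(path))
  top <- trajectory$topology
  if (ext == "xyz") {
    con <- file(path, "w"); on.exit(close(con))
    for (fr in trajectory$frames) {
      writeLines(c(as.character(top$n_atoms),
                   sprintf("box %.6f %.6f %.6f", fr$box[1], fr$box[2], fr$box[3]),
                   sprintf("%-4s %12.6f %12.6f %12.6f", top$atoms$element,
                           fr$positions[, 1], fr$positions[, 2], fr$positions[, 3])),
                 con)
    }
    return(invisible(path))
  }
  a <- top$atoms
  spec <- rep("PROTEIN", nrow(a))
  for (i in seq_len(nrow(top$molecules)))
    spec[top$molecules$first[i]:top$molecules$last[i]] <- top$molecules$species[i]
  lines <- character(0)
  b <- trajectory$frames[[1]]$box
  lines <- c(lines, sprintf(
    "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1", b[1], b[2], b[3],
    90, 90, 90))
  multi <- length(trajectory$frames) > 1
  for (m in seq_along(trajectory$frames)) {
    p <- trajectory$frames[[m]]$positions
    if (multi) lines <- c(lines, sprintf("MODEL     %4d", m))
    nm <- ifelse(nchar(a$atom_name) < 4, paste0(" ", a$atom_name), a$atom_name)
    rec <- ifelse(spec == "PROTEIN", "ATOM  ", "HETATM")
    # columns: serial 7-11, name 13-16, altLoc 17, resName 18-21,
    # chain 22, resSeq 23-26, coords 31-54, occ 55-60, B 61-66, elem 77-78
    lines <- c(lines, sprintf(
      "%s%5d %-4s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      rec, (seq_len(nrow(a)) - 1L) %% 99999L + 1L, substr(nm, 1, 4),
      substr(a$residue_name, 1, 4), substr(a$chain_id, 1, 1),
      a$residue_id %% 10000L, p[, 1], p[, 2], p[, 3],
      ifelse(is.na(a$occupancy), 1, a$occupancy),
      ifelse(is.na(a$b_factor), 0, a$b_factor), a$element))
    if (multi) lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Minimum-image convention for displacement vectors
#'
#' Wraps each displacement component into `[-box/2, box/2)` for an
#' orthorhombic box.  Vectorized over rows when `d` is a matrix.
#'
#' @param d Displacement vector (length 3) or N x 3 matrix, Angstrom.
#' @param box Length-3 box edges, Angstrom.
#' @return Wrapped displacement(s), same shape as `d`.
#' @export
minimum_image <- function(d, box) {
  box <- as.numeric(box)
  if (any(box <= 0)) stop("box edges must be positive")
  if (is.matrix(d)) {
    b <- matrix(box, nrow(d), 3, byrow = TRUE)
    return(d - b * floor(d / b + 0.5))
  }
  d - box * floor(d / box + 0.5)
}

# z of the leaflet-reference phosphate of one molecule: atoms matching the
# phosphate name exactly or with one trailing digit (CL carries two, e.g.
# P1/P3; their mean is used).
.phosphate_z <- function(frame, topology, mol_row, phosphate_atom_name) {
  idx <- mol_row$first:mol_row$last
  nm <- topology$atoms$atom_name[idx]
  hit <- idx[nm == phosphate_atom_name |
             grepl(paste0("^", phosphate_atom_name, "[0-9]$"), nm)]
  if (!length(hit)) return(NA_real_)
  mean(frame$positions[hit, 3])
}

#' Assign lipids to bilayer leaflets
#'
#' The bilayer midplane is the mean z of all phosphate reference atoms
#' (robust to asymmetric solvation, unlike the box centre); a lipid is
#' `upper` iff its phosphate z exceeds the midplane.  Labels are invariant
#' under rigid z-translation of the frame.
#'
#' @param frame A [new_frame()].
#' @param topology A [new_topology()]; all molecules with a lipid species
#'   label (not `PROTEIN`/`other`) are assigned.
#' @param phosphate_atom_name Atom name of the phosphate reference
#'   (default "P"; also matches "P1", "P3", ... for cardiolipin).
#' @return Object of class `leaflet_assignment`: data.frame `assignment`
#'   (mol_id, species, phosphate_z, leaflet) plus `midplane_z`.
#' @export
assign_leaflets <- function(frame, topology, phosphate_atom_name = "P") {
  lip <- topology$molecules[!(topology$molecules$species %in%
                              c("PROTEIN", "other")), , drop = FALSE]
  if (!nrow(lip)) stop("topology contains no lipid molecules")
  pz <- vapply(seq_len(nrow(lip)), function(i)
    .phosphate_z(frame, topology, lip[i, ], phosphate_atom_name), numeric(1))
  if (anyNA(pz))
    stop("molecule ", lip$mol_id[which(is.na(pz))[1]], " (",
         lip$residue_name[which(is.na(pz))[1]],
         ") has no atom matching phosphate name '", phosphate_atom_name, "'")
  mid <- mean(pz)
  structure(list(
    assignment = data.frame(mol_id = lip$mol_id, species = lip$species,
                            phosphate_z = pz,
                            leaflet = ifelse(pz > mid, "upper", "lower"),
                            stringsAsFactors = FALSE),
    midplane_z = mid), class = "leaflet_assignment")
}

#' @export
print.leaflet_assignment <- function(x, ...) {
  cat("<leaflet_assignment> midplane z =", signif(x$midplane_z, 6), "A\n")
  print(table(x$assignment$leaflet))
  invisible(x)
}

# ---- selection mini-language -------------------------------------------

#' Select atoms by a small expression grammar
#'
#' Grammar: `species <label>`, `resid <a>` or `resid <a>-<b>`,
#' `name <atom_name>`, `chain <id>`, combined with `and` / `or`
#' (`and` binds tighter).  Residue ids are file numbering.
#'
#' @param topology A [new_topology()].
#' @param expression Selection string.
#' @return Sorted integer vector of atom indices (1-based).  An empty
#'   selection is legal and raises a warning.
#' @export
select_atoms <- function(topology, expression) {
  toks <- strsplit(trimws(expression), "\\s+")[[1]]
  if (!length(toks) || !nzchar(toks[1])) stop("empty selection expression")
  a <- topology$atoms
  spec <- rep(NA_character_, nrow(a))
  for (i in seq_len(nrow(topology$molecules)))
    spec[topology$molecules$first[i]:topology$molecules$last[i]] <-
      topology$molecules$species[i]
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
  parse_atom <- function() {
    kw <- tolower(take())
    arg <- take()
    if (is.na(arg)) stop("selection syntax error: keyword '", kw,
                         "' at token ", pos - 1L, " needs an argument")
    switch(kw,
      species = spec == arg,
      name = a$atom_name == arg,
      chain = a$chain_id == arg,
      resid = {
        if (grepl("^-?[0-9]+--?[0-9]+$", arg) || grepl("^[0-9]+-[0-9]+$", arg)) {
          ab <- as.integer(strsplit(arg, "(?<=[0-9])-", perl = TRUE)[[1]])
          a$residue_id >= ab[1] & a$residue_id <= ab[2]
        } else if (grepl("^-?[0-9]+$", arg)) {
          a$residue_id == as.integer(arg)
        } else stop("selection syntax error: bad resid '", arg,
                    "' at token ", pos - 1L)
      },
      stop("selection syntax error: unknown token '", kw, "' at token ",
           pos - 1L))
  }
  parse_and <- function() {
    m <- parse_atom()
    while (!is.na(peek()) && tolower(peek()) == "and") { take(); m <- m & parse_atom() }
    m
  }
  m <- parse_and()
  while (!is.na(peek()) && tolower(peek()) == "or") { take(); m <- m | parse_and() }
  if (!is.na(peek())) stop("selection syntax error: unexpected token '",
                           peek(), "' at token ", pos)
  idx <- which(m)
  if (!length(idx)) warning("selection '", expression, "' matched no atoms")
  idx
}

# ---- config files -------------------------------------------------------

#' Read a structured analysis config
#'
#' INI-style sections.  `[species]` maps residue names to species labels
#' (`RESNAME = LABEL`); `[directors]` lists director chains as
#' `SPECIES.chainN = name1 name2 ...` (head to tail); `[terminal]` lists
#' per-species terminal (chain-position) atom names; `[selections]` holds
#' named selection strings.
#'
#' @param path Path to the config file.
#' @return Nested list with elements `species`, `directors`, `terminal`,
#'   `selections`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ln <- readLines(path, warn = FALSE)
  ln <- sub("[#;].*$", "", ln)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln)]
  out <- list(species = character(0), directors = list(),
              terminal = list(), selections = list())
  section <- NULL
  for (l in ln) {
    if (grepl("^\\[.+\\]$", l)) { section <- tolower(gsub("[][]", "", l)); next }
    kv <- strsplit(l, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2 || is.null(section))
      stop("malformed config line: '", l, "'")
    key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
    if (section == "species") {
      out$species[key] <- val
    } else if (section == "directors") {
      sp <- strsplit(key, ".", fixed = TRUE)[[1]]
      if (length(sp) != 2) stop("director key must be SPECIES.chain: '", key, "'")
      out$directors[[sp[1]]][[sp[2]]] <- strsplit(val, "\\s+")[[1]]
    } else if (section == "terminal") {
      out$terminal[[key]] <- strsplit(val, "\\s+")[[1]]
    } else if (section == "selections") {
      out$selections[[key]] <- val
    } else stop("unknown config section [", section, "]")
  }
  out
}

#' Default director-atom specification
#'
#' Chain-carbon subsets defining lipid directors: the sn-1 palmitoyl chain
#' C1-C16 and the sn-1' subset C1-C14 of the oleoyl chain for POPE/POPG,
#' and C1-C12 for each of cardiolipin's four chains.  Atom names follow the
#' generator's convention (chain prefix + position); override via the
#' `[directors]` config section for other naming dialects.
#'
#' @return Named list: species -> list of chains -> atom-name vectors.
#' @export
default_directors <- function() {
  pe <- list(sn1 = paste0("C3", 1:16), sn2 = paste0("C2", 1:14))
  list(POPE = pe, POPG = pe,
       CL = list(ch1 = paste0("CA", 1:12), ch2 = paste0("CB", 1:12),
                 ch3 = paste0("CC", 1:12), ch4 = paste0("CD", 1:12)))
}

#' Default terminal-atom specification for chain positions
#'
#' One atom per acyl chain: the C16 and C14 terminal carbons for POPE/POPG
#' and the four C12 carbons for cardiolipin, used as the per-chain 2D
#' positions for hexatic order and Voronoi tessellation.
#'
#' @return Named list: species -> character vector of terminal atom names.
#' @export
default_terminal_atoms <- function() {
  list(POPE = c("C316", "C214"), POPG = c("C316", "C214"),
       CL = c("CA12", "CB12", "CC12", "CD12"))
}
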