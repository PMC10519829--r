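# Protein-ligand contact analysis: boolean residue-residue contacts at a
# distance cutoff (minimum image) and contact probabilities over a
# trajectory.

# split atom indices into residues, ordered by file residue numbering
.residue_groups <- function(topology, atoms, heavy_only = TRUE) {
  a <- topology$atoms
  if (heavy_only) atoms <- atoms[!(toupper(a$element[atoms]) %in% "H")]
  if (!length(atoms)) stop("group contains no atoms after hydrogen filtering")
  key <- paste(a$chain_id[atoms], a$residue_id[atoms], sep = "|")
  sp <- split(atoms, key)
  resno <- as.integer(sub("^.*\\|", "", names(sp)))
  sp[order(resno)]
}

#' Residue-residue contacts in one frame
#'
#' A residue pair is in contact iff any atom pair across the two residues
#' has minimum-image distance strictly below the cutoff.  Hydrogens are
#' excluded by default (heavy-atom convention for a 5 Angstrom cutoff);
#' set `include_h = TRUE` to count all atoms.
#'
#' @param frame A [new_frame()].
#' @param topology A [new_topology()].
#' @param group_a,group_b Atom index vectors (or selection strings).
#' @param cutoff Contact cutoff, Angstrom (> 0).
#' @param include_h Include hydrogens?
#' @return Logical matrix, rows = residues of `group_a`, cols = residues of
#'   `group_b`, dimnames = residue ids (file numbering).
#' @export
contacts_frame <- function(frame, topology, group_a, group_b, cutoff = 5,
                           include_h = FALSE) {
  if (cutoff <= 0) stop("cutoff must be positive")
  if (is.character(group_a)) group_a <- select_atoms(topology, group_a)
  if (is.character(group_b)) group_b <- select_atoms(topology, group_b)
  if (!length(group_a) || !length(group_b)) stop("empty contact group")
  ra <- .residue_groups(topology, group_a, !include_h)
  rb <- .residue_groups(topology, group_b, !include_h)
  pos <- frame$positions; box <- frame$box
  out <- matrix(FALSE, length(ra), length(rb),
                dimnames = list(sub("^.*\\|", "", names(ra)),
                                sub("^.*\\|", "", names(rb))))
  for (i in seq_along(ra)) {
    pa <- pos[ra[[i]], , drop = FALSE]
    for (j in seq_along(rb)) {
      pb <- pos[rb[[j]], , drop = FALSE]
      d <- cbind(rep(pa[, 1], each = nrow(pb)) - pb[, 1],
                 rep(pa[, 2], each = nrow(pb)) - pb[, 2],
                 rep(pa[, 3], each = nrow(pb)) - pb[, 3])
      d <- minimum_image(d, box)
      out[i, j] <- min(rowSums(d^2)) < cutoff^2
    }
  }
  out
}

#' Contact probability map over a trajectory
#'
#' Per residue pair, the fraction of frames in contact: 1 means the contact
#' is maintained throughout the trajectory, 0 that it never forms.
#'
#' @inheritParams contacts_frame
#' @param trajectory A [new_trajectory()].
#' @return Object of class `contact_map`: `probability` matrix in `[0, 1]`,
#'   `n_frames`, `cutoff`, and a long-format `table` (res_a, res_b,
#'   probability).
#' @export
contact_probability <- function(trajectory, group_a, group_b, cutoff = 5,
                                include_h = FALSE) {
  top <- trajectory$topology
  if (is.character(group_a)) group_a <- select_atoms(top, group_a)
  if (is.character(group_b)) group_b <- select_atoms(top, group_b)
  nf <- length(trajectory$frames)
  acc <- NULL
  for (fr in trajectory$frames) {
    m <- contacts_frame(fr, top, group_a, group_b, cutoff, include_h)
    acc <- if (is.null(acc)) m + 0 else acc + m
  }
  p <- acc / nf
  tab <- data.frame(res_a = rep(rownames(p), ncol(p)),
                    res_b = rep(colnames(p), each = nrow(p)),
                    probability = as.vector(p), stringsAsFactors = FALSE)
  structure(list(probability = p, n_frames = nf, cutoff = cutoff,
                 table = tab), class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat("<contact_map>", nrow(x$probability), "x", ncol(x$probability),
      "residues over", x$n_frames, "frames; cutoff", x$cutoff, "A\n")
  invisible(x)
}
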