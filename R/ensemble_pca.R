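# Principal component analysis of backbone-coordinate ensembles (simulation
# frames or crystal asymmetric-unit chains) and cross-ensemble mode
# comparison through eigenvector inner products.

.backbone_names <- c("N", "CA", "C", "O")

#' Build an aligned structure ensemble
#'
#' Conformations (matched M x 3 coordinate matrices) are iteratively
#' superposed onto the evolving ensemble mean until the mean shifts by less
#' than 1e-6 Angstrom (at most 100 iterations), then mean-centred.
#'
#' @param coords List of K >= 2 matched M x 3 matrices (Angstrom).
#' @param atom_table Optional data.frame describing the M atoms (carried
#'   through to reporting).
#' @param align Superpose conformations before centring (default `TRUE`;
#'   disable for conformations that are already in a common frame, e.g.
#'   closed-form constructions).
#' @return Object of class `structure_ensemble`: `xmat` (K x 3M aligned
#'   coordinates, atom-major), `mean` (M x 3), `n_atoms`, `atom_table`.
#' @export
build_ensemble <- function(coords, atom_table = NULL, align = TRUE) {
  if (length(coords) < 2) stop("an ensemble needs at least 2 conformations")
  m <- nrow(coords[[1]])
  ok <- vapply(coords, function(x) nrow(x) == m && ncol(x) == 3, logical(1))
  if (!all(ok)) stop("conformation ", which(!ok)[1],
                     " does not match the first (", m, " x 3)")
  xmat <- t(vapply(coords, function(x) as.vector(t(x)), numeric(3 * m)))
  al <- if (align) .iterative_align(xmat) else
    list(xmat = xmat, mean = colMeans(xmat), iter = 0L)
  structure(list(xmat = al$xmat, mean = matrix(al$mean, ncol = 3, byrow = TRUE),
                 n_atoms = m, n_conf = length(coords),
                 atom_table = atom_table, iterations = al$iter),
            class = "structure_ensemble")
}

#' @export
print.structure_ensemble <- function(x, ...) {
  cat("<structure_ensemble>", x$n_conf, "conformations x", x$n_atoms,
      "atoms\n")
  invisible(x)
}

#' Extract matched backbone conformations from a trajectory
#'
#' @param trajectory A [new_trajectory()].
#' @param atom_names Backbone atom names (default N, CA, C, O; use `"CA"`
#'   alone for CA-only ensembles from low-resolution crystal data).
#' @param chain Restrict to one chain id.
#' @param residues Optional residue-id vector to keep.
#' @return List of M x 3 matrices plus an `atom_table` attribute.
#' @export
ensemble_from_trajectory <- function(trajectory, atom_names = .backbone_names,
                                     chain = NULL, residues = NULL) {
  a <- trajectory$topology$atoms
  sel <- which(a$atom_name %in% atom_names &
               (if (is.null(chain)) TRUE else a$chain_id == chain) &
               (if (is.null(residues)) TRUE else a$residue_id %in% residues))
  if (!length(sel)) stop("no backbone atoms matched")
  out <- lapply(trajectory$frames, function(fr)
    fr$positions[sel, , drop = FALSE])
  attr(out, "atom_table") <- a[sel, c("atom_name", "residue_id", "chain_id")]
  out
}

#' Extract matched backbone conformations from a multi-chain structure
#'
#' One conformation per chain (e.g. the eight protomers of a crystal
#' asymmetric unit).  Residues are matched by residue id across chains;
#' residues missing the full backbone atom set in any chain are dropped
#' pairwise so the correspondence is gap-free.
#'
#' @param structure A `list(topology, frame)` as returned by
#'   [read_structure()].
#' @param chains Character vector of chain ids (default: all protein
#'   chains).
#' @param atom_names Backbone atom names, as in
#'   [ensemble_from_trajectory()].
#' @return List of matched M x 3 matrices with an `atom_table` attribute.
#' @export
ensemble_from_chains <- function(structure, chains = NULL,
                                 atom_names = .backbone_names) {
  top <- structure$topology; fr <- structure$frame
  a <- top$atoms
  if (is.null(chains)) {
    pm <- top$molecules[top$molecules$species == "PROTEIN", ]
    chains <- unique(pm$chain_id)
  }
  if (length(chains) < 2) stop("need at least 2 chains for an ensemble")
  per_chain <- lapply(chains, function(ch) {
    sel <- which(a$chain_id == ch & a$atom_name %in% atom_names)
    spl <- split(sel, a$residue_id[sel])
    complete <- vapply(spl, function(s)
      all(atom_names %in% a$atom_name[s]), logical(1))
    spl[complete]
  })
  common <- Reduce(intersect, lapply(per_chain, names))
  if (!length(common))
    stop("no residues with complete backbone shared by chains ",
         paste(chains, collapse = ", "))
  common <- common[order(as.integer(common))]
  out <- lapply(per_chain, function(spl) {
    idx <- unlist(lapply(spl[common], function(s)
      s[match(atom_names, a$atom_name[s])]), use.names = FALSE)
    fr$positions[idx, , drop = FALSE]
  })
  attr(out, "atom_table") <- data.frame(
    atom_name = rep(atom_names, length(common)),
    residue_id = rep(as.integer(common), each = length(atom_names)))
  out
}

#' Principal component analysis of a structure ensemble
#'
#' Diagonalizes the 3M x 3M coordinate covariance of the aligned ensemble
#' (via the equivalent K-rank SVD of the centred coordinate stack).
#' Covariance uses 1/K (population) normalization - visible for a K = 8
#' crystal ensemble and switchable via `bessel`.  Eigenvector signs are
#' fixed deterministically: the largest-magnitude component is positive.
#'
#' @param ensemble A [build_ensemble()] object.
#' @param bessel If `TRUE`, use 1/(K-1) normalization instead of 1/K.
#' @param tol Relative variance below which modes are dropped as null.
#' @return Object of class `pc_model`: `mean` (M x 3), `vectors` (3M x n,
#'   orthonormal columns), `values` (Angstrom^2, descending),
#'   `total_variance`.
#' @export
pca_ensemble <- function(ensemble, bessel = FALSE, tol = 1e-12) {
  x <- sweep(ensemble$xmat, 2, colMeans(ensemble$xmat))
  k <- nrow(x)
  denom <- if (bessel) k - 1 else k
  total <- sum(x^2) / denom
  if (total < 1e-300)
    return(structure(list(mean = ensemble$mean,
                          vectors = matrix(0, ncol(x), 0), values = numeric(0),
                          total_variance = 0), class = "pc_model"))
  sv <- svd(x)
  lam <- sv$d^2 / denom
  keep <- lam > tol * lam[1]
  vec <- sv$v[, keep, drop = FALSE]
  for (j in seq_len(ncol(vec))) {
    i <- which.max(abs(vec[, j]))
    if (vec[i, j] < 0) vec[, j] <- -vec[, j]
  }
  structure(list(mean = ensemble$mean, vectors = vec,
                 values = lam[keep], total_variance = total),
            class = "pc_model")
}

#' @export
print.pc_model <- function(x, ...) {
  cat("<pc_model>", length(x$values), "modes; top eigenvalues:",
      paste(signif(head(x$values, 5), 4), collapse = ", "), "A^2\n")
  invisible(x)
}

#' Inner-product overlap of two sets of principal components
#'
#' O_ij = |v_i . w_j| for the first n eigenvectors of each model; 1 means
#' identical mode directions, 0 orthogonality.  Both models must share the
#' same atom correspondence.
#'
#' @param model_a,model_b [pca_ensemble()] models.
#' @param n Number of leading modes to compare (default 5).
#' @return n x n matrix with entries in `[0, 1]`.
#' @export
pc_overlap <- function(model_a, model_b, n = 5) {
  if (nrow(model_a$vectors) != nrow(model_b$vectors))
    stop("models have mismatched atom sets (",
         nrow(model_a$vectors) / 3, " vs ", nrow(model_b$vectors) / 3,
         " atoms)")
  n <- min(n, ncol(model_a$vectors), ncol(model_b$vectors))
  if (n < 1) stop("no modes available for overlap")
  abs(crossprod(model_a$vectors[, seq_len(n), drop = FALSE],
                model_b$vectors[, seq_len(n), drop = FALSE]))
}
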