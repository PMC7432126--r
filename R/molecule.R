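#' Construct a molecule with per-atom probe properties
#'
#' A light-weight container for an aligned small molecule: coordinates plus
#' the per-atom properties the similarity-field probes read.  Charges are
#' expected in elementary-charge units (e.g. Gasteiger-Huckel), radii in
#' Angstrom, the hydrophobicity parameter is dimensionless, and donor /
#' acceptor are 0/1 flags.  Properties are supplied, not perceived: the
#' package has no charge or pharmacophore model of its own.
#'
#' @param id molecule label.
#' @param atoms data.frame with columns `element`, `x`, `y`, `z`, and
#'   optionally `charge`, `vdw`, `hydrophob`, `donor`, `acceptor` (missing
#'   property columns are filled with neutral defaults: charge 0, vdw 1.7,
#'   hydrophob 0, flags 0).
#' @return An object of class `molecule`.
#' @export
molecule <- function(id, atoms) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  need <- c("element", "x", "y", "z")
  if (!all(need %in% names(atoms)))
    stop("atoms needs columns ", paste(need, collapse = ", "), call. = FALSE)
  if (nrow(atoms) < 1L) stop("molecule needs at least one atom", call. = FALSE)
  defaults <- list(charge = 0, vdw = 1.7, hydrophob = 0, donor = 0, acceptor = 0)
  for (nm in names(defaults))
    if (is.null(atoms[[nm]])) atoms[[nm]] <- defaults[[nm]]
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (any(!is.finite(xyz))) stop("non-finite coordinates", call. = FALSE)
  if (any(atoms$vdw <= 0)) stop("vdW radii must be positive", call. = FALSE)
  structure(list(id = id, atoms = atoms), class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat("<molecule> ", x$id, ": ", nrow(x$atoms), " atoms\n", sep = "")
  invisible(x)
}

mol_xyz <- function(mol) as.matrix(mol$atoms[, c("x", "y", "z")])

#' Rigid-body least-squares superposition onto a template
#'
#' Kabsch algorithm: finds the proper rotation (determinant +1) and
#' translation minimizing the RMSD between mapped atom pairs, and applies it
#' to the whole mobile molecule.  This is how a series of analogues sharing
#' a common skeleton is brought into a single frame before field
#' computation: the mapping lists which mobile atoms correspond to which
#' template (skeleton) atoms.
#'
#' @param mobile,template [molecule()] objects.
#' @param mapping two-column matrix or data.frame of atom index pairs
#'   (template index, mobile index); at least 3 non-collinear pairs.
#'   Defaults to the identity mapping over the shorter molecule.
#' @return List with the transformed `molecule`, the `rmsd` (Angstrom) over
#'   the mapped pairs, the rotation matrix `R` and translation `t` such that
#'   transformed = mobile %*% t(R) + t.
#' @export
superpose <- function(mobile, template, mapping = NULL) {
  stopifnot(inherits(mobile, "molecule"), inherits(template, "molecule"))
  if (is.null(mapping)) {
    n <- min(nrow(mobile$atoms), nrow(template$atoms))
    mapping <- cbind(seq_len(n), seq_len(n))
  }
  mapping <- as.matrix(mapping)
  if (ncol(mapping) != 2L || nrow(mapping) < 3L)
    stop("mapping needs >= 3 (template, mobile) index pairs", call. = FALSE)
  if (anyDuplicated(mapping[, 1L]) || anyDuplicated(mapping[, 2L]))
    stop("mapping indices must be unique within each molecule", call. = FALSE)
  A <- mol_xyz(template)[mapping[, 1L], , drop = FALSE]
  B <- mol_xyz(mobile)[mapping[, 2L], , drop = FALSE]
  if (anyNA(A) || anyNA(B))
    stop("mapping index out of range", call. = FALSE)
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  # collinearity check: centered template points must span >= 2 dimensions
  if (sum(svd(Bc)$d > 1e-8 * max(1, max(abs(Bc)))) < 2L)
    stop("degenerate mapping: mapped atoms are collinear", call. = FALSE)
  s <- svd(crossprod(Bc, Ac))            # 3x3 covariance B^T A
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- ca - drop(R %*% cb)
  xyz_new <- sweep(mol_xyz(mobile) %*% t(R), 2, tr, "+")
  out <- mobile
  out$atoms[, c("x", "y", "z")] <- xyz_new
  fitted <- xyz_new[mapping[, 2L], , drop = FALSE]
  rmsd <- sqrt(mean(rowSums((fitted - A)^2)))
  list(molecule = out, rmsd = rmsd, R = R, t = tr)
}

#' Rectangular field grid enclosing a set of aligned molecules
#'
#' Axis-aligned bounding box over every atom of every molecule, padded by
#' `margin` on all sides and discretized at `spacing`; conventional CoMSIA
#' settings are a 2 Angstrom lattice with a 4 Angstrom margin.
#'
#' @param molecules list of [molecule()] objects (or a single molecule).
#' @param spacing grid spacing in Angstrom (> 0).
#' @param margin padding beyond the bounding box in Angstrom (> 0).
#' @return An object of class `field_grid` with `origin`, `spacing`,
#'   `counts` (nx, ny, nz) and the `points` matrix (n_points x 3, x fastest).
#' @export
build_grid <- function(molecules, spacing = 2, margin = 4) {
  if (inherits(molecules, "molecule")) molecules <- list(molecules)
  if (!length(molecules)) stop("empty molecule set", call. = FALSE)
  if (spacing <= 0 || margin <= 0)
    stop("spacing and margin must be positive", call. = FALSE)
  xyz <- do.call(rbind, lapply(molecules, mol_xyz))
  lo <- apply(xyz, 2, min) - margin
  hi <- apply(xyz, 2, max) + margin
  counts <- pmax(1L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  axes <- lapply(1:3, function(k) lo[k] + spacing * (seq_len(counts[k]) - 1L))
  points <- as.matrix(expand.grid(x = axes[[1]], y = axes[[2]], z = axes[[3]],
                                  KEEP.OUT.ATTRS = FALSE))
  structure(list(origin = lo, spacing = spacing, counts = counts,
                 points = points),
            class = "field_grid")
}

#' @export
print.field_grid <- function(x, ...) {
  cat("<field_grid> ", paste(x$counts, collapse = " x "), " points, spacing ",
      x$spacing, " A, origin (", paste(round(x$origin, 2), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

probe_kinds <- c("steric", "electrostatic", "hydrophobic", "donor", "acceptor")

# per-probe atomic weight: vdW volume proxy, charge, hydrophobicity, flags
atom_probe_weight <- function(atoms, probe) {
  switch(probe,
         steric = atoms$vdw^3,
         electrostatic = atoms$charge,
         hydrophobic = atoms$hydrophob,
         donor = atoms$donor,
         acceptor = atoms$acceptor,
         stop("unknown probe: ", probe, call. = FALSE))
}

#' Gaussian similarity field of one molecule on a grid
#'
#' CoMSIA-style similarity index at grid point q:
#' \deqn{A_q = -\sum_{atoms} w_{probe} w_{atom} e^{-\alpha r_{atom,q}^2}}
#' with Gaussian distance attenuation (no singularities at atom positions,
#' unlike Lennard-Jones/Coulomb fields).  The per-atom weight is the cubed
#' vdW radius for the steric probe, the partial charge for the electrostatic
#' probe, the hydrophobicity parameter for the hydrophobic probe, and the
#' donor/acceptor flag for the hydrogen-bond probes.
#'
#' @param mol a [molecule()].
#' @param grid a [build_grid()] result.
#' @param probe one of `"steric"`, `"electrostatic"`, `"hydrophobic"`,
#'   `"donor"`, `"acceptor"`.
#' @param alpha attenuation factor in Angstrom^-2 (conventional 0.3).
#' @param probe_weight probe atom property (charge +1 e, hydrophobicity +1,
#'   flags +1 by default).
#' @return Numeric vector over grid points.
#' @export
similarity_field <- function(mol, grid, probe, alpha = 0.3, probe_weight = 1) {
  stopifnot(inherits(mol, "molecule"), inherits(grid, "field_grid"))
  probe <- match.arg(probe, probe_kinds)
  w <- atom_probe_weight(mol$atoms, probe) * probe_weight
  xyz <- mol_xyz(mol)
  pts <- grid$points
  # squared distances grid-points x atoms without forming 3D arrays
  d2 <- outer(rowSums(pts^2), rowSums(xyz^2), "+") - 2 * tcrossprod(pts, xyz)
  d2[d2 < 0] <- 0
  -drop(exp(-alpha * d2) %*% w)
}

#' Compute all probe field blocks for a molecule set
#'
#' @inheritParams similarity_field
#' @param molecules list of aligned [molecule()] objects.
#' @param probes probes to evaluate (default all five).
#' @return List of probe-named matrices (molecules x grid points), plus the
#'   grid, wrapped in class `field_set`.
#' @export
compute_fields <- function(molecules, grid = NULL, probes = probe_kinds,
                           alpha = 0.3, spacing = 2, margin = 4) {
  if (inherits(molecules, "molecule")) molecules <- list(molecules)
  probes <- match.arg(probes, probe_kinds, several.ok = TRUE)
  if (is.null(grid)) grid <- build_grid(molecules, spacing, margin)
  blocks <- lapply(probes, function(p) {
    m <- t(vapply(molecules, similarity_field, numeric(nrow(grid$points)),
                  grid = grid, probe = p, alpha = alpha))
    rownames(m) <- vapply(molecules, `[[`, "", "id")
    m
  })
  names(blocks) <- probes
  structure(list(blocks = blocks, grid = grid, alpha = alpha),
            class = "field_set")
}

#' Assemble the PLS descriptor matrix from field blocks
#'
#' Concatenates the probe blocks column-wise with CoMSIA block scaling
#' (every block is divided by the standard deviation of all its entries, so
#' no probe dominates by sheer numeric magnitude), then drops columns whose
#' standard deviation across molecules falls below `drop_sigma` — the
#' analogue of a minimum-sigma column filter, removing grid points far from
#' every molecule that carry no signal.
#'
#' @param fields a `field_set` from [compute_fields()].
#' @param drop_sigma column standard-deviation threshold applied after block
#'   scaling (default 0.01).
#' @return List with the descriptor matrix `X` (molecules x retained
#'   columns) and `colmap`, a data.frame mapping each retained column to its
#'   `probe` and grid `point` index.
#' @export
assemble_descriptor_matrix <- function(fields, drop_sigma = 0.01) {
  stopifnot(inherits(fields, "field_set"))
  if (nrow(fields$blocks[[1L]]) < 2L)
    stop("need at least 2 molecules", call. = FALSE)
  scaled <- lapply(fields$blocks, function(b) {
    s <- stats::sd(as.vector(b))
    if (s > 0) b / s else b
  })
  X <- do.call(cbind, scaled)
  colmap <- data.frame(
    probe = rep(names(scaled), vapply(scaled, ncol, 1L)),
    point = unlist(lapply(scaled, function(b) seq_len(ncol(b)))),
    stringsAsFactors = FALSE)
  keep <- apply(X, 2, stats::sd) >= drop_sigma
  if (!any(keep))
    stop("all descriptor columns dropped: no variance above drop_sigma",
         call. = FALSE)
  X <- X[, keep, drop = FALSE]
  colmap <- colmap[keep, , drop = FALSE]
  colnames(X) <- paste0(colmap$probe, ".", colmap$point)
  rownames(colmap) <- colnames(X)
  list(X = X, colmap = colmap)
}
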