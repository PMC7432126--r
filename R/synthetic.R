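#' Generate a synthetic docking-score matrix with controlled dispersion
#'
#' Emulates the structure of the 17-compound, 3-enzyme docking-score table:
#' each endpoint column is a normal bulk of scores plus two range-anchor
#' compounds (the analogue of the far-out template molecule and the worst
#' binder) placed asymmetrically at `+2.8 d` and `-1.2 d` bulk standard
#' deviations, while the bulk tightens as `1/sqrt(d)`.  With `d = 1` the
#' column looks like an ordinary skewed docking-score column; larger `d`
#' stretches the range so that after range normalization the bulk sits
#' tightly in the high-information region of the \[0.1, 1\] scale, and the
#' entropy-weight method rewards the endpoint with a larger weight.  (A
#' per-column affine change of scale alone cannot move the weights, since
#' range normalization absorbs it.)
#'
#' @param n_compounds number of compounds (rows, >= 2).
#' @param dispersion numeric vector of per-endpoint dispersion multipliers;
#'   its length sets the endpoint count.
#' @param mu,s location and scale of the raw scores (cosmetic only).
#' @param seed integer seed; the same seed reproduces the matrix exactly.
#' @return A [score_matrix()] (all endpoints benefit-oriented).
#' @export
gen_score_matrix <- function(n_compounds = 17, dispersion = c(1, 1, 1),
                             mu = 7, s = 1.5, seed = 20200723) {
  if (n_compounds < 2L) stop("need at least 2 compounds", call. = FALSE)
  set.seed(seed)
  X <- vapply(dispersion, function(d) {
    z <- stats::rnorm(n_compounds) / sqrt(d)
    anchors <- sample(n_compounds, 2L)
    z[anchors] <- c(2.8, -1.2) * d
    mu + s * z
  }, numeric(n_compounds))
  score_matrix(X,
               compound_ids = sprintf("cmp%02d", seq_len(n_compounds)),
               endpoint_ids = sprintf("enz%d", seq_along(dispersion)),
               orientation = "benefit")
}

#' Generate an aligned toy molecule set with a planted linear field SAR
#'
#' Emulates a congeneric series such as the phthalate esters: every
#' molecule shares an identical rigid scaffold (so the set is aligned by
#' construction) and differs only in a few substituent pseudo-atoms whose
#' positions and probe properties vary randomly around a template.  Field
#' descriptors are computed on a shared grid and the response is
#' constructed as a known linear function of those true descriptors plus
#' Gaussian noise: \eqn{y = X_d \beta + \varepsilon}.
#'
#' @param n_molecules number of molecules.
#' @param n_scaffold scaffold atoms (>= 3).
#' @param n_sub substituent pseudo-atoms per molecule.
#' @param perturb positional jitter of substituent atoms, Angstrom.
#' @param sigma noise standard deviation, in units of `sd(Xd beta)`
#'   (0 = noiseless).
#' @param beta planted coefficient vector; recycled/truncated to the number
#'   of retained descriptor columns.  Default: standard-normal draws.
#' @param spacing,margin,alpha,drop_sigma,probes field-grid settings passed
#'   to [compute_fields()] / [assemble_descriptor_matrix()].
#' @param beta_in_span plant `beta` inside the row space of the centered
#'   descriptor matrix.  With many more field columns than molecules only
#'   that component of a coefficient vector is identifiable, so recovery
#'   experiments should plant what is recoverable in principle.
#' @param seed integer seed; fully determines molecules, descriptors and
#'   noise.
#' @return List with `molecules`, `grid`, `Xd`, `colmap`, `y`, `beta`,
#'   `sigma`.
#' @export
gen_molecule_set <- function(n_molecules = 20, n_scaffold = 6, n_sub = 3,
                             perturb = 1.0, sigma = 0.1, beta = NULL,
                             spacing = 2, margin = 4, alpha = 0.3,
                             drop_sigma = 0.01, probes = probe_kinds,
                             beta_in_span = FALSE, seed = 20200723) {
  if (n_scaffold < 3L) stop("scaffold needs at least 3 atoms", call. = FALSE)
  set.seed(seed)
  scaffold <- data.frame(
    element = "C",
    x = stats::runif(n_scaffold, -2, 2),
    y = stats::runif(n_scaffold, -2, 2),
    z = stats::runif(n_scaffold, -2, 2),
    charge = round(stats::rnorm(n_scaffold, 0, 0.2), 3),
    vdw = 1.7, hydrophob = round(stats::rnorm(n_scaffold, 0, 0.5), 3),
    donor = 0, acceptor = 0, stringsAsFactors = FALSE)
  sub_base <- matrix(stats::runif(3 * n_sub, 2, 4), ncol = 3)
  mols <- lapply(seq_len(n_molecules), function(i) {
    sub <- data.frame(
      element = sample(c("C", "N", "O"), n_sub, replace = TRUE),
      x = sub_base[, 1] + stats::rnorm(n_sub, 0, perturb),
      y = sub_base[, 2] + stats::rnorm(n_sub, 0, perturb),
      z = sub_base[, 3] + stats::rnorm(n_sub, 0, perturb),
      charge = round(stats::rnorm(n_sub, 0, 0.3), 3),
      vdw = round(stats::runif(n_sub, 1.2, 2.2), 3),
      hydrophob = round(stats::rnorm(n_sub, 0, 1), 3),
      donor = stats::rbinom(n_sub, 1, 0.3),
      acceptor = stats::rbinom(n_sub, 1, 0.3),
      stringsAsFactors = FALSE)
    molecule(sprintf("syn%02d", i), rbind(scaffold, sub))
  })
  fields <- compute_fields(mols, probes = probes, alpha = alpha,
                           spacing = spacing, margin = margin)
  desc <- assemble_descriptor_matrix(fields, drop_sigma = drop_sigma)
  p <- ncol(desc$X)
  if (is.null(beta)) beta <- stats::rnorm(p)
  beta <- rep_len(beta, p)
  if (beta_in_span) {
    Xc <- sweep(desc$X, 2, colMeans(desc$X))
    v <- svd(Xc, nu = 0)
    keep <- v$d > 1e-8 * v$d[1L]
    V <- v$v[, keep, drop = FALSE]
    beta <- drop(V %*% crossprod(V, beta))
  }
  signal <- drop(desc$X %*% beta)
  noise_sd <- sigma * max(stats::sd(signal), .Machine$double.eps)
  y <- signal + stats::rnorm(n_molecules, 0, noise_sd)
  list(molecules = mols, grid = fields$grid, Xd = desc$X,
       colmap = desc$colmap, y = y, beta = beta, sigma = sigma)
}
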