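test_that("grid geometry follows the bounding box + margin arithmetic", {
  m <- molecule("one", data.frame(element = "C", x = 0, y = 0, z = 0))
  g <- build_grid(m, spacing = 2, margin = 4)
  expect_equal(unname(g$counts), c(5L, 5L, 5L))
  expect_equal(sort(unique(g$points[, 1])), c(-4, -2, 0, 2, 4))
  expect_error(build_grid(m, spacing = 0), "positive")
  expect_error(build_grid(list()), "empty")
})

test_that("the grid encloses every atom of every molecule", {
  set.seed(10)
  mols <- lapply(1:17, function(i) random_test_molecule(paste0("m", i)))
  g <- build_grid(mols, spacing = 2, margin = 4)
  lo <- g$origin
  hi <- g$origin + g$spacing * (g$counts - 1L)
  for (m in mols) {
    xyz <- as.matrix(m$atoms[, c("x", "y", "z")])
    expect_true(all(sweep(xyz, 2, lo, ">") & sweep(xyz, 2, hi, "<")))
  }
})

test_that("a unit-weight atom contributes -1 at zero distance", {
  m <- molecule("pt", data.frame(element = "C", x = 0, y = 0, z = 0,
                                 vdw = 1, charge = 1, hydrophob = 1,
                                 donor = 1, acceptor = 1))
  g <- build_grid(m, spacing = 2, margin = 4)
  at_origin <- which(rowSums(abs(g$points)) == 0)
  for (probe in c("steric", "electrostatic", "hydrophobic", "donor",
                  "acceptor")) {
    f <- similarity_field(m, g, probe, alpha = 0.3)
    expect_equal(f[at_origin], -1)
  }
  expect_error(similarity_field(m, g, "magnetic"), "arg")
})

test_that("field magnitude decays monotonically away from an isolated atom", {
  m <- molecule("pt", data.frame(element = "C", x = 0, y = 0, z = 0, vdw = 1.5))
  g <- build_grid(m, spacing = 1, margin = 6)
  f <- similarity_field(m, g, "steric")
  d <- sqrt(rowSums(g$points^2))
  ord <- order(d)
  expect_true(all(diff(abs(f[ord])) <= 1e-12))
})

test_that("a mirror-symmetric molecule yields a mirror-symmetric field", {
  m <- molecule("mir", data.frame(element = "C", x = c(-1.5, 1.5), y = 0,
                                  z = 0, vdw = 1.7))
  g <- build_grid(m, spacing = 1, margin = 4)
  f <- similarity_field(m, g, "steric")
  # map each grid point to its mirror image (x -> -x)
  key <- function(p) paste(round(p[, 1], 6), round(p[, 2], 6),
                           round(p[, 3], 6))
  mirrored <- g$points
  mirrored[, 1] <- -mirrored[, 1]
  idx <- match(key(mirrored), key(g$points))
  expect_false(anyNA(idx))
  expect_equal(f, f[idx], tolerance = 1e-10)
})

test_that("vectorized fields equal a naive double-loop summation", {
  set.seed(11)
  for (rep in 1:3) {
    m <- random_test_molecule(n = 10)
    g <- build_grid(m, spacing = 3, margin = 4)
    pts <- g$points[sample(nrow(g$points), 50), , drop = FALSE]
    g2 <- g
    g2$points <- pts
    for (probe in c("steric", "electrostatic", "hydrophobic")) {
      f <- similarity_field(m, g2, probe, alpha = 0.3)
      w <- switch(probe, steric = m$atoms$vdw^3,
                  electrostatic = m$atoms$charge,
                  hydrophobic = m$atoms$hydrophob)
      oracle <- numeric(nrow(pts))
      for (q in seq_len(nrow(pts)))
        for (a in seq_len(nrow(m$atoms)))
          oracle[q] <- oracle[q] - w[a] *
            exp(-0.3 * sum((pts[q, ] - unlist(m$atoms[a, c("x", "y", "z")]))^2))
      expect_equal(f, oracle, tolerance = 1e-12)
    }
  }
})

test_that("descriptor assembly block-scales to unit variance and filters", {
  set.seed(12)
  mols <- lapply(1:6, function(i) random_test_molecule(paste0("m", i)))
  fields <- compute_fields(mols, spacing = 2.5, margin = 3)
  desc <- assemble_descriptor_matrix(fields, drop_sigma = 0)
  # with drop_sigma = 0 nothing is dropped and each block has unit variance
  expect_equal(ncol(desc$X), 5 * nrow(fields$grid$points))
  for (probe in names(fields$blocks)) {
    block <- desc$X[, desc$colmap$probe == probe, drop = FALSE]
    expect_equal(stats::sd(as.vector(block)), 1, tolerance = 1e-10)
  }
  # identical molecules carry no variance at all
  same <- compute_fields(list(mols[[1]], mols[[1]]), spacing = 2.5)
  expect_error(assemble_descriptor_matrix(same, drop_sigma = 0.01),
               "dropped")
  expect_error(
    assemble_descriptor_matrix(
      compute_fields(mols[1], spacing = 2.5), 0.01),
    "2 molecules")
})

test_that("descriptors are invariant under a global rigid motion", {
  set.seed(13)
  mols <- lapply(1:5, function(i) random_test_molecule(paste0("m", i)))
  fields <- compute_fields(mols, spacing = 2, margin = 4)
  desc <- assemble_descriptor_matrix(fields, drop_sigma = 0.01)
  R <- random_rotation(); shift <- rnorm(3, 0, 4)
  mols2 <- lapply(mols, transform_molecule, R = R, shift = shift)
  g2 <- fields$grid
  g2$points <- sweep(fields$grid$points %*% t(R), 2, shift, "+")
  fields2 <- compute_fields(mols2, grid = g2)
  desc2 <- assemble_descriptor_matrix(fields2, drop_sigma = 0.01)
  expect_equal(desc2$X, desc$X, tolerance = 1e-8, ignore_attr = TRUE)
})
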