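test_that("range normalization maps extremes to the floor and ceiling", {
  sm <- score_matrix(matrix(c(0, 0.4, 1, 5, 3, 4), ncol = 2,
                            dimnames = list(c("a", "b", "c"), c("e1", "e2"))))
  nm <- range_normalize(sm, 0.9)
  expect_equal(unname(nm$Y["a", "e1"]), 0.1)
  expect_equal(unname(nm$Y["c", "e1"]), 1.0)
  expect_true(all(nm$Y >= 0.1 - 1e-12 & nm$Y <= 1 + 1e-12))
  expect_equal(unname(apply(nm$Y, 2, min)), c(0.1, 0.1))
  expect_equal(unname(apply(nm$Y, 2, max)), c(1, 1))

  # cost orientation mirrors the column
  smc <- score_matrix(sm$X, orientation = "cost")
  expect_equal(unname(range_normalize(smc)$Y[, "e1"]), c(1.0, 0.64, 0.1))
})

test_that("the BBP 2PIA example normalizes to its published value", {
  sm <- pae_docking_scores()
  Y <- range_normalize(sm, 0.9)$Y
  expect_equal(round(unname(Y["BBP", "2PIA"]), 3), 0.509)
})

test_that("range normalization rejects bad inputs", {
  expect_error(score_matrix(matrix(c(1, 1, 2, 3), ncol = 2)), "constant")
  sm <- score_matrix(matrix(c(0, 1, 2, 5, 3, 4), ncol = 2))
  expect_error(range_normalize(sm, 0), "floor_a")
  expect_error(range_normalize(sm, 1), "floor_a")
  expect_error(score_matrix(matrix(1:2, ncol = 1),
                            compound_ids = c("x", "x")), "duplicate")
})

test_that("column entropy matches a term-by-term hand evaluation", {
  # m = 3 column (0.1, 0.55, 1.0), term by term:
  # -(0.1 ln 0.1 + 0.55 ln 0.55 + 1 ln 1) / ln 3 = 0.559069 / 1.098612
  Y <- matrix(c(0.1, 0.55, 1.0), ncol = 1)
  expect_equal(entropy_per_endpoint(Y), 0.5088866, tolerance = 1e-6)
  # all-ones column: ln 1 = 0 everywhere
  expect_equal(entropy_per_endpoint(matrix(1, 3, 1)), 0)
  expect_error(entropy_per_endpoint(matrix(c(-0.1, 0.5, 1), ncol = 1)),
               "positive")
})

test_that("proportion-variant entropy is bounded by 1", {
  sm <- pae_docking_scores()
  nm <- range_normalize(sm)
  E <- entropy_per_endpoint(nm, proportions = TRUE)
  expect_true(all(E <= 1 + 1e-12))
  res <- comprehensive_table(sm, proportions = TRUE)
  expect_equal(sum(res$W), 1)
})

test_that("difference coefficients and weights follow |1 - E| / sum", {
  hw <- entropy_weights(c(0.5, 0.75))
  expect_equal(hw$H, c(0.5, 0.25))
  expect_equal(hw$W, c(2 / 3, 1 / 3))
  # entropies above 1 (direct-Y convention) give H = E - 1
  hw2 <- entropy_weights(c(1.799, 1.792, 1.497))
  expect_equal(hw2$H, c(0.799, 0.792, 0.497))
  expect_equal(round(100 * hw2$W, 2), c(38.27, 37.93, 23.80))
  # equal entropies give equal weights
  expect_equal(entropy_weights(c(1.3, 1.3, 1.3, 1.3))$W, rep(0.25, 4))
  expect_error(entropy_weights(c(1, 1)), "zero information")
})

test_that("composite scores are the weighted normalized values", {
  # published DEP row with the published weights
  z <- sum(c(0.347, 0.303, 0.100) * c(0.3828, 0.3793, 0.2379))
  expect_equal(round(z, 3), 0.272)
  nm <- range_normalize(score_matrix(matrix(c(0, 1, 2, 5, 3, 4), ncol = 2)))
  expect_equal(unname(composite_scores(nm, c(1, 0))), unname(nm$Y[, 1]))
  expect_error(composite_scores(nm, c(0.5, 0.2)), "sum to 1")
  expect_error(composite_scores(nm, c(1, 0, 0)), "length")
})

test_that("the single-endpoint comprehensive table degenerates correctly", {
  sm <- score_matrix(matrix(c(0, 1), ncol = 1,
                            dimnames = list(c("lo", "hi"), "only")))
  res <- comprehensive_table(sm)
  expect_equal(unname(res$W), 1)
  expect_equal(unname(res$Z), c(0.1, 1.0))
})

test_that("weights and composites are invariant to per-column affine rescaling", {
  set.seed(101)
  for (rep in 1:5) {
    X <- matrix(rnorm(20 * 4, 6, 2), 20, 4)
    sm <- score_matrix(X)
    res <- comprehensive_table(sm)
    alpha <- runif(4, 0.2, 5)
    beta <- rnorm(4, 0, 10)
    X2 <- sweep(sweep(X, 2, alpha, "*"), 2, beta, "+")
    res2 <- comprehensive_table(score_matrix(X2))
    expect_equal(res2$W, res$W, tolerance = 1e-10)
    expect_equal(res2$Z, res$Z, tolerance = 1e-10)
  }
})

test_that("raising a benefit score never lowers that compound's composite", {
  set.seed(202)
  X <- matrix(rnorm(12 * 3, 5, 1.5), 12, 3)
  res <- comprehensive_table(score_matrix(X))
  for (rep in 1:10) {
    i <- sample(12, 1); j <- sample(3, 1)
    X2 <- X
    X2[i, j] <- X2[i, j] + runif(1, 0.1, 2)
    Y2 <- range_normalize(score_matrix(X2))
    z2 <- composite_scores(Y2, res$W)   # weights held at original values
    expect_gte(z2[i] + 1e-12, res$Z[i])
  }
})

test_that("composite values stay inside the normalization bounds", {
  set.seed(303)
  X <- matrix(rexp(30 * 3, 0.5), 30, 3)
  res <- comprehensive_table(score_matrix(X), floor_a = 0.7)
  expect_true(all(res$Z >= 0.3 - 1e-12 & res$Z <= 1 + 1e-12))
  expect_equal(sum(res$W), 1, tolerance = 1e-12)
})

test_that("the report table carries raw, converted and summary rows", {
  res <- comprehensive_table(pae_docking_scores())
  rep_ <- composite_report(res)
  expect_equal(nrow(rep_), 17 + 3)
  expect_equal(rep_$Compound[18:20], c("Ej", "Hj", "Wj"))
  expect_match(rep_$Converted.2PIA[20], "%$")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_composite_report(res, path, header = "demo")
  expect_true(file.exists(path))
  reread <- readLines(path)
  expect_match(reread[1], "^# demo")
})
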