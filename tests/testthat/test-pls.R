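make_xy <- function(n = 20, p = 5, beta = NULL, sigma = 0, seed = 7) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("v", seq_len(p))
  if (is.null(beta)) beta <- rnorm(p)
  y <- drop(X %*% beta) + rnorm(n, 0, sigma)
  list(X = X, y = y, beta = beta)
}

test_that("a single component recovers an exact one-column relationship", {
  # mean-zero orthogonal columns: the first weight vector then points
  # exactly along column 7
  set.seed(7)
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(150), 15, 10))))
  d <- list(X = Q[, -1])
  colnames(d$X) <- paste0("v", 1:10)
  y <- 2 * d$X[, 7] + 1
  fit <- pls_fit(d$X, y, 1)
  expect_equal(predict(fit, d$X), y, tolerance = 1e-10)
  st <- fit_statistics(fit, d$X, y)
  expect_equal(st$R2, 1, tolerance = 1e-10)
})

test_that("a covariance-free response yields zero coefficients", {
  set.seed(8)
  X <- matrix(rnorm(40), 20, 2)
  # project noise orthogonal to both centered columns and the constant
  Xc <- sweep(X, 2, colMeans(X))
  e <- rnorm(20)
  e <- e - Xc %*% solve(crossprod(Xc), crossprod(Xc, e))
  y <- drop(e - mean(e)) + 5
  fit <- pls_fit(X, y, 1)
  expect_equal(unname(fit$coef), c(0, 0), tolerance = 1e-10)
  expect_equal(predict(fit, X), rep(mean(y), 20), tolerance = 1e-8)
})

test_that("full-component PLS matches the ordinary least-squares oracle", {
  d <- make_xy(n = 20, p = 5, sigma = 0.3)
  fit <- pls_fit(d$X, d$y, 5)
  ols <- stats::lm(d$y ~ d$X)
  expect_equal(unname(fit$coef), unname(stats::coef(ols)[-1]),
               tolerance = 1e-8)
  expect_equal(fit$intercept, unname(stats::coef(ols)[1]), tolerance = 1e-8)
})

test_that("predictions agree with an independent PLS implementation", {
  d <- make_xy(n = 25, p = 8, sigma = 0.5, seed = 21)
  fit <- pls_fit(d$X, d$y, 3)
  mo <- mixOmics::pls(d$X, d$y, ncomp = 3, mode = "regression",
                      scale = FALSE)
  pred_mo <- predict(mo, d$X)$predict[, 1, 3]
  expect_equal(predict(fit, d$X), unname(pred_mo), tolerance = 1e-10)
})

test_that("degenerate fits are refused", {
  d <- make_xy()
  expect_error(pls_fit(d$X, rep(1, 20), 2), "zero-variance")
  expect_error(pls_fit(d$X, d$y, 0), "n_components")
  expect_error(pls_fit(d$X, d$y, 20), "n_components")
  expect_error(pls_fit(d$X[1:2, ], d$y[1:2], 1), "at least 3")
})

test_that("LOO PRESS equals a manual per-fold computation", {
  # univariate case: each PLS fold is the simple regression lm would fit
  set.seed(9)
  x <- matrix(rnorm(5), 5, 1)
  y <- drop(2 * x) + rnorm(5, 0, 0.5)
  cv <- loo_q2(x, y, 1)
  manual <- vapply(1:5, function(i) {
    df <- data.frame(xx = x[-i, 1], yy = y[-i])
    f <- stats::lm(yy ~ xx, data = df)
    unname((y[i] - stats::predict(f, data.frame(xx = x[i, 1])))^2)
  }, numeric(1))
  expect_equal(cv$press[1], sum(manual), tolerance = 1e-8)
  expect_equal(cv$q2[1], 1 - sum(manual) / sum((y - mean(y))^2),
               tolerance = 1e-8)
})

test_that("LOO q2 separates noiseless linear structure from pure noise", {
  d <- make_xy(n = 30, p = 10, sigma = 0, seed = 30)
  cv <- loo_q2(d$X, d$y, 10)
  expect_gt(cv$q2_opt, 0.999)
  set.seed(31)
  cvn <- loo_q2(d$X, rnorm(30), 10)
  expect_lt(cvn$q2_opt, 0.2)
})

test_that("q2 never exceeds the training R2 and degrades with noise", {
  q2s <- R2s <- numeric(3)
  for (k in seq_along(c(0, 0.5, 1))) {
    sigma <- c(0, 0.5, 1)[k]
    d <- make_xy(n = 25, p = 6, sigma = sigma, seed = 40 + k)
    cv <- loo_q2(d$X, d$y, 6)
    fit <- pls_fit(d$X, d$y, cv$n_opt)
    st <- fit_statistics(fit, d$X, d$y)
    expect_lte(cv$q2_opt, st$R2 + 1e-10)
    q2s[k] <- cv$q2_opt; R2s[k] <- st$R2
  }
  expect_true(all(diff(q2s) < 0))
})

test_that("fit statistics follow the stated R2/SEE/F definitions", {
  d <- make_xy(n = 13, p = 9, sigma = 0.4, seed = 50)
  fit <- pls_fit(d$X, d$y, 8)
  st <- fit_statistics(fit, d$X, d$y)
  res <- d$y - predict(fit, d$X)
  ss_res <- sum(res^2); ss_tot <- sum((d$y - mean(d$y))^2)
  expect_equal(st$R2, 1 - ss_res / ss_tot, tolerance = 1e-12)
  # the published 13-compound, 8-component geometry: denominator n-c-1 = 4
  expect_equal(st$SEE, sqrt(ss_res / 4), tolerance = 1e-12)
  expect_equal(st$F, (st$R2 / 8) / ((1 - st$R2) / 4), tolerance = 1e-10)
  # perfect fit reports an infinite F
  y_exact <- drop(d$X %*% rnorm(9))
  fit2 <- pls_fit(d$X, y_exact, 9)
  st2 <- fit_statistics(fit2, d$X, y_exact)
  expect_equal(st2$R2, 1, tolerance = 1e-10)
  expect_lt(st2$SEE, 1e-6)
  expect_identical(st2$F, Inf)
  expect_error(fit_statistics(fit, d$X[1:9, ], d$y[1:9]), "undefined")
})

test_that("external r2_pred follows the (SD - PRESS)/SD definition", {
  d <- make_xy(n = 12, p = 3, sigma = 0, seed = 60)
  fit <- pls_fit(d$X[1:9, ], d$y[1:9], 3)
  # noiseless linear: test predictions are exact, r2_pred = 1
  expect_equal(external_r2pred(fit, d$X[10:12, ], d$y[10:12]), 1,
               tolerance = 1e-8)
  # hand-computed three-compound oracle
  yhat <- predict(fit, d$X[10:12, ])
  ytest <- d$y[10:12] + c(0.5, -0.2, 0.1)
  sd_ <- sum((ytest - fit$y_mean)^2)
  press <- sum((ytest - yhat)^2)
  expect_equal(external_r2pred(fit, d$X[10:12, ], ytest),
               (sd_ - press) / sd_, tolerance = 1e-12)
  # predicting the training mean gives r2_pred = 0 by construction
  expect_equal(external_r2pred(fit, matrix(fit$x_mean, 2, 3, byrow = TRUE),
                               c(fit$y_mean + 1, fit$y_mean - 1)), 0,
               tolerance = 1e-8)
  expect_error(external_r2pred(fit, d$X[10:11, ],
                               rep(fit$y_mean, 2)), "undefined")
})

test_that("y-scrambling is seeded, anchored, and collapses q2", {
  d <- make_xy(n = 20, p = 5, sigma = 0.2, seed = 70)
  sc1 <- y_scramble(d$X, d$y, n_perm = 5, levels = c(0.5, 1), seed = 99,
                    max_components = 4)
  sc2 <- y_scramble(d$X, d$y, n_perm = 5, levels = c(0.5, 1), seed = 99,
                    max_components = 4)
  expect_identical(sc1[c("Q2", "cSDEP", "dq2_dr2yy")],
                   sc2[c("Q2", "cSDEP", "dq2_dr2yy")])
  # the identity anchor reproduces the unscrambled q2
  expect_equal(sc1$runs$q2[1], sc1$q2_unscrambled)
  expect_equal(sc1$runs$r2yy[1], 1)
  # informative data: scrambling destroys most of the cross-validated signal
  expect_gt(sc1$q2_unscrambled - sc1$mean_scrambled_q2, 0.3)
})

test_that("field contributions aggregate coefficient mass per block", {
  set.seed(80)
  X <- matrix(rnorm(60), 12, 5)
  colmap <- data.frame(probe = c("steric", "steric", "steric",
                                 "hydrophobic", "hydrophobic"),
                       point = c(1, 2, 3, 1, 2))
  # response built only from steric columns
  y <- drop(X[, 1:3] %*% c(1, -1, 2))
  fit <- pls_fit(X, y, 5)
  fc <- field_contributions(fit, colmap, X)
  expect_equal(unname(fc["steric"]), 1, tolerance = 1e-6)
  expect_equal(sum(fc), 1, tolerance = 1e-10)
  # two blocks with identical coefficient mass split 50/50
  X2 <- cbind(X[, 1], X[, 1])
  colnames(X2) <- c("a", "b")
  fit2 <- pls_fit(X2, drop(X[, 1]) + 3, 1)
  fc2 <- field_contributions(fit2, data.frame(probe = c("steric",
                                                        "hydrophobic"),
                                              point = c(1, 1)), X2)
  expect_equal(unname(fc2), c(0.5, 0.5), tolerance = 1e-10)
  # independent per-column accumulation oracle
  mass <- abs(fit$coef * apply(X, 2, stats::sd))
  expect_equal(unname(fc["hydrophobic"]),
               sum(mass[4:5]) / sum(mass), tolerance = 1e-12)
  expect_error(field_contributions(fit, colmap[1:3, ], X), "colmap")
})

test_that("duplicating a descriptor column leaves predictions stable", {
  # at full rank the PLS fit equals the projection onto the column space,
  # which a duplicated column does not change
  d <- make_xy(n = 18, p = 6, sigma = 0.3, seed = 90)
  fit <- pls_fit(d$X, d$y, 6)
  Xdup <- cbind(d$X, d$X[, 3])
  fit2 <- pls_fit(Xdup, d$y, 7)
  expect_equal(predict(fit2, Xdup), predict(fit, d$X), tolerance = 1e-6)
})
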