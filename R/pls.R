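#' Fit a mean-centered NIPALS partial least squares model
#'
#' Standard NIPALS PLS1: latent components are extracted from the
#' mean-centered descriptor matrix to maximize covariance with the
#' (mean-centered) response, and the regression coefficient vector is
#' recovered as \eqn{b = W (P^T W)^{-1} q}.  No column autoscaling is done
#' here: CoMSIA-style block scaling is the assembly step's job
#' ([assemble_descriptor_matrix()]).
#'
#' @param Xd numeric descriptor matrix (n compounds x p columns).
#' @param y numeric response vector of length n.
#' @param n_components number of latent components (1 to n - 1).
#' @return An object of class `pls_qsar` with the centering vectors, weight
#'   (`W`), loading (`P`), score (`T`) and y-loading (`q`) structure, the
#'   coefficient vector `coef` and intercept.
#' @export
pls_fit <- function(Xd, y, n_components) {
  Xd <- as.matrix(Xd)
  y <- as.numeric(y)
  n <- nrow(Xd); p <- ncol(Xd)
  if (length(y) != n) stop("length(y) != nrow(Xd)", call. = FALSE)
  if (n < 3L) stop("need at least 3 training compounds", call. = FALSE)
  if (stats::sd(y) == 0)
    stop("zero-variance response: nothing to fit", call. = FALSE)
  n_components <- as.integer(n_components)
  if (n_components < 1L || n_components > n - 1L)
    stop("n_components must lie in [1, n - 1]", call. = FALSE)
  x_mean <- colMeans(Xd); y_mean <- mean(y)
  E <- sweep(Xd, 2, x_mean); f <- y - y_mean
  W <- P <- matrix(0, p, n_components)
  TT <- matrix(0, n, n_components)
  q <- numeric(n_components)
  a_used <- 0L
  for (a in seq_len(n_components)) {
    w <- drop(crossprod(E, f))
    wn <- sqrt(sum(w^2))
    if (wn < 1e-12) break                       # residual X carries no covariance
    w <- w / wn
    t_ <- drop(E %*% w)
    tt <- sum(t_^2)
    if (tt < 1e-12) break
    p_ <- drop(crossprod(E, t_)) / tt
    q_ <- sum(t_ * f) / tt
    E <- E - tcrossprod(t_, p_)
    f <- f - t_ * q_
    W[, a] <- w; P[, a] <- p_; TT[, a] <- t_; q[a] <- q_
    a_used <- a
  }
  if (a_used == 0L) {
    # response carries no covariance with any column: the fit is the mean,
    # all coefficients zero
    a_used <- 1L
    W[1L, 1L] <- 1
    P[1L, 1L] <- 1
  }
  W <- W[, seq_len(a_used), drop = FALSE]
  P <- P[, seq_len(a_used), drop = FALSE]
  TT <- TT[, seq_len(a_used), drop = FALSE]
  q <- q[seq_len(a_used)]
  coef <- drop(W %*% solve(crossprod(P, W), q))
  structure(list(n_components = a_used, x_mean = x_mean, y_mean = y_mean,
                 W = W, P = P, T = TT, q = q, coef = coef,
                 intercept = y_mean - sum(x_mean * coef),
                 train_ids = rownames(Xd)),
            class = "pls_qsar")
}

#' @export
print.pls_qsar <- function(x, ...) {
  cat("<pls_qsar> ", x$n_components, " components, ", length(x$coef),
      " descriptor columns\n", sep = "")
  invisible(x)
}

#' @param object a `pls_qsar` model.
#' @param newdata descriptor matrix with the training columns.
#' @param ... unused.
#' @rdname pls_fit
#' @export
predict.pls_qsar <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  drop(newdata %*% object$coef) + object$intercept
}

#' Leave-one-out cross-validation of a PLS model
#'
#' For each candidate component count, every compound is held out in turn,
#' the model refitted on the remainder, and the held-out compound predicted;
#' \eqn{q^2 = 1 - PRESS / SS_{tot}} with the total sum of squares about the
#' full-sample mean.  The optimal component count maximizes q2.
#'
#' @inheritParams pls_fit
#' @param max_components largest component count to scan; silently clipped
#'   to n - 2 (each LOO fold must itself satisfy components <= n_fold - 1).
#' @return List with `q2` (per component count), `press`, `n_opt`, the best
#'   q2 (`q2_opt`), and the LOO predictions at `n_opt`.
#' @export
loo_q2 <- function(Xd, y, max_components = 10) {
  Xd <- as.matrix(Xd); y <- as.numeric(y)
  n <- nrow(Xd)
  if (n < 3L) stop("need at least 3 compounds for LOO", call. = FALSE)
  max_c <- min(as.integer(max_components), n - 2L)
  if (max_c < as.integer(max_components))
    warning("max_components clipped to ", max_c, " (n = ", n, ")")
  preds <- matrix(NA_real_, n, max_c)
  for (i in seq_len(n)) {
    fit <- pls_fit(Xd[-i, , drop = FALSE], y[-i], max_c)
    for (a in seq_len(max_c)) {
      used <- min(a, fit$n_components)
      coef_a <- drop(fit$W[, 1:used, drop = FALSE] %*%
                       solve(crossprod(fit$P[, 1:used, drop = FALSE],
                                       fit$W[, 1:used, drop = FALSE]),
                             fit$q[1:used]))
      preds[i, a] <- sum(Xd[i, ] * coef_a) + fit$y_mean - sum(fit$x_mean * coef_a)
    }
  }
  ss_tot <- sum((y - mean(y))^2)
  press <- colSums((preds - y)^2)
  q2 <- 1 - press / ss_tot
  n_opt <- which.max(q2)
  list(q2 = q2, press = press, n_opt = n_opt, q2_opt = q2[n_opt],
       predictions = preds[, n_opt])
}

#' Non-validated fit statistics of a PLS model
#'
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}}; the standard error of estimate uses
#' the component count as the model degrees of freedom,
#' \eqn{SEE = \sqrt{SS_{res}/(n - c - 1)}}, and
#' \eqn{F = (R^2/c) / ((1 - R^2)/(n - c - 1))}.  A perfect fit reports
#' `F = Inf`.
#'
#' @param model a `pls_qsar` model.
#' @inheritParams pls_fit
#' @return List with `R2`, `SEE`, `F`.
#' @export
fit_statistics <- function(model, Xd, y) {
  stopifnot(inherits(model, "pls_qsar"))
  n <- length(y); cc <- model$n_components
  if (n - cc - 1L <= 0L)
    stop("undefined statistics: n - components - 1 <= 0", call. = FALSE)
  res <- y - predict(model, Xd)
  ss_res <- sum(res^2)
  ss_tot <- sum((y - mean(y))^2)
  R2 <- 1 - ss_res / ss_tot
  SEE <- sqrt(ss_res / (n - cc - 1L))
  Fv <- if (ss_res == 0) Inf else (R2 / cc) / ((1 - R2) / (n - cc - 1L))
  list(R2 = R2, SEE = SEE, F = Fv)
}

#' External predictive coefficient on a held-out test set
#'
#' \eqn{r^2_{pred} = (SD - PRESS)/SD} where `SD` is the sum of squared
#' deviations of the test responses about the *training-set* mean and
#' `PRESS` the squared prediction errors on the test set.
#'
#' @param model a `pls_qsar` model.
#' @param Xd_test,y_test test-set descriptors and responses.
#' @param y_train_mean training-set response mean; defaults to the model's.
#' @return `r2_pred` (scalar).
#' @export
external_r2pred <- function(model, Xd_test, y_test, y_train_mean = model$y_mean) {
  if (!length(y_test)) stop("empty test set", call. = FALSE)
  sd_ <- sum((y_test - y_train_mean)^2)
  if (sd_ == 0)
    stop("undefined r2_pred: test responses all equal the training mean",
         call. = FALSE)
  press <- sum((y_test - predict(model, Xd_test))^2)
  (sd_ - press) / sd_
}

#' Response-scrambling (y-randomization) stability analysis
#'
#' Guards against chance correlation: the response is perturbed by random
#' pairwise swaps at graded fractions of the sample, the model is re-fitted
#' and LOO-validated for each perturbed response, and the scrambled q2
#' values are regressed on the squared correlation \eqn{r^2_{yy'}} between
#' perturbed and original response.  Reported are `Q2`, the regression's
#' extrapolation to full perturbation (\eqn{r^2_{yy'} = 0}); `cSDEP`, the
#' cross-validated standard error of prediction
#' \eqn{\sqrt{PRESS/n}} averaged over the scrambled runs; and
#' `dq2_dr2yy`, the regression slope (a steep slope means the apparent q2
#' collapses as soon as the response is disturbed — the mark of a model
#' driven by real structure rather than chance).  The unperturbed model
#' (identity permutation, level 0) is included as an anchor.
#'
#' @inheritParams loo_q2
#' @param n_perm permutations per perturbation level (>= 10 recommended).
#' @param levels pairwise-swap fractions in (0, 1].
#' @param seed integer seed; the same seed always yields the same triple.
#' @return List with `Q2`, `cSDEP`, `dq2_dr2yy`, the unscrambled `q2`, and
#'   the per-run detail table.
#' @export
y_scramble <- function(Xd, y, n_perm = 20, levels = c(0.2, 0.4, 0.6, 0.8, 1),
                       seed = 1729, max_components = 10) {
  Xd <- as.matrix(Xd); y <- as.numeric(y)
  n <- length(y)
  if (n_perm < 2L) stop("n_perm must be at least 2", call. = FALSE)
  base <- loo_q2(Xd, y, max_components)
  runs <- data.frame(level = 0, r2yy = 1, q2 = base$q2_opt,
                     csdep = sqrt(base$press[base$n_opt] / n))
  set.seed(seed)
  for (lev in levels) {
    n_swap <- max(1L, round(lev * n / 2))
    for (r in seq_len(n_perm)) {
      yp <- y
      for (s in seq_len(n_swap)) {
        ij <- sample.int(n, 2L)
        yp[ij] <- yp[rev(ij)]
      }
      cv <- loo_q2(Xd, yp, max_components)
      runs <- rbind(runs, data.frame(
        level = lev, r2yy = stats::cor(yp, y)^2, q2 = cv$q2_opt,
        csdep = sqrt(cv$press[cv$n_opt] / n)))
    }
  }
  fit <- stats::lm(q2 ~ r2yy, data = runs)
  list(Q2 = unname(stats::coef(fit)[1L]),
       dq2_dr2yy = unname(stats::coef(fit)[2L]),
       cSDEP = mean(runs$csdep[runs$level > 0]),
       q2_unscrambled = base$q2_opt,
       mean_scrambled_q2 = mean(runs$q2[runs$level > 0]),
       runs = runs)
}

#' Per-probe field contribution fractions
#'
#' The contribution of a probe block is the summed absolute product of each
#' of its columns' regression coefficient and standard deviation,
#' \eqn{\sum_{k \in B} |b_k s_k|}, normalized over all blocks — i.e. the
#' share of predicted-response variation each field type accounts for.
#'
#' @param model a `pls_qsar` model.
#' @param colmap column map from [assemble_descriptor_matrix()].
#' @param Xd the training descriptor matrix (for column standard deviations).
#' @return Named numeric vector of fractions summing to 1.
#' @export
field_contributions <- function(model, colmap, Xd) {
  stopifnot(inherits(model, "pls_qsar"))
  if (nrow(colmap) != length(model$coef))
    stop("colmap rows must match coefficient length", call. = FALSE)
  mass <- abs(model$coef * apply(as.matrix(Xd), 2, stats::sd))
  shares <- tapply(mass, colmap$probe, sum)
  shares <- shares / sum(shares)
  ord <- intersect(probe_kinds, names(shares))
  stats::setNames(as.numeric(shares[ord]), ord)
}
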