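#' Range-normalize a score matrix to the interval [1 - a, 1]
#'
#' Min-max rescaling with a floor, so that the worst compound on an endpoint
#' maps to `1 - floor_a` and the best to 1.  Benefit endpoints use
#' \deqn{Y = (1 - a) + a (X - X_{min}) / (X_{max} - X_{min}),}
#' cost endpoints the mirrored form with \eqn{X_{max} - X} in the numerator.
#' The floor keeps every normalized value strictly positive, which the
#' entropy step requires (\eqn{Y \log Y} must be defined).
#'
#' @param scores a [score_matrix()].
#' @param floor_a floor parameter `a`, strictly inside (0, 1); conventionally
#'   0.9, giving normalized values in \[0.1, 1\].
#' @return An object of class `normalized_matrix` with fields `Y` (the
#'   normalized matrix), `floor_a` and `orientation`.
#' @examples
#' sm <- score_matrix(matrix(c(3.293, 7.070, 11.595), ncol = 1,
#'                           dimnames = list(c("DMP", "BBP", "DUP"), "2PIA")))
#' range_normalize(sm)$Y  # BBP -> 0.5094
#' @export
range_normalize <- function(scores, floor_a = 0.9) {
  stopifnot(inherits(scores, "score_matrix"))
  if (!is.numeric(floor_a) || length(floor_a) != 1L ||
      floor_a <= 0 || floor_a >= 1)
    stop("floor_a must lie strictly in (0, 1)", call. = FALSE)
  X <- scores$X
  Y <- X
  for (j in seq_len(ncol(X))) {
    xj <- X[, j]
    span <- max(xj) - min(xj)
    if (span <= 0)
      stop("degenerate normalization: endpoint ", scores$endpoint_ids[j],
           " is constant", call. = FALSE)
    Y[, j] <- if (scores$orientation[j] == "benefit")
      (1 - floor_a) + floor_a * (xj - min(xj)) / span
    else
      (1 - floor_a) + floor_a * (max(xj) - xj) / span
  }
  structure(list(Y = Y, floor_a = floor_a, orientation = scores$orientation),
            class = "normalized_matrix")
}

#' Shannon information entropy of each normalized endpoint column
#'
#' Computes \eqn{E_j = -k \sum_i Y_{ij} \ln Y_{ij}} with \eqn{k = 1/\ln m},
#' `m` the number of compounds.  By default the normalized values are used
#' directly (so `E_j` may exceed 1, since the column does not sum to 1);
#' `proportions = TRUE` switches to the textbook entropy-weight variant that
#' first rescales each column to proportions \eqn{p_{ij} = Y_{ij}/\sum_i
#' Y_{ij}}, for which \eqn{E_j \le 1}.
#'
#' @param normed a `normalized_matrix` from [range_normalize()], or any
#'   strictly positive numeric matrix.
#' @param proportions use the column-proportion variant (default `FALSE`).
#' @return Numeric vector of entropies, one per endpoint.
#' @export
entropy_per_endpoint <- function(normed, proportions = FALSE) {
  Y <- if (inherits(normed, "normalized_matrix")) normed$Y else as.matrix(normed)
  if (any(Y <= 0))
    stop("entropy requires strictly positive normalized values", call. = FALSE)
  m <- nrow(Y)
  k <- 1 / log(m)
  if (proportions)
    Y <- sweep(Y, 2, colSums(Y), "/")
  -k * colSums(Y * log(Y))
}

#' Difference coefficients and entropy weights from endpoint entropies
#'
#' The difference coefficient is \eqn{H_j = |1 - E_j|}: endpoints whose
#' normalized values are more dispersed (entropy farther from 1) carry more
#' information and receive larger weights \eqn{W_j = H_j / \sum_j H_j}.
#' The absolute value accommodates entropies above 1, which arise when the
#' entropy is evaluated on the raw normalized values rather than on column
#' proportions.
#'
#' @param E numeric vector of endpoint entropies.
#' @return List with components `H` (difference coefficients) and `W`
#'   (weights, summing to 1).
#' @export
entropy_weights <- function(E) {
  if (!length(E)) stop("empty entropy vector", call. = FALSE)
  H <- abs(1 - E)
  if (all(H == 0))
    stop("all endpoints carry zero information (E = 1 everywhere); ",
         "weights are undefined", call. = FALSE)
  list(H = H, W = H / sum(H))
}

#' Weighted composite score per compound
#'
#' \eqn{Z_i = \sum_j W_j Y_{ij}}: the entropy-weighted mean of each
#' compound's normalized endpoint scores, bounded in \[1 - a, 1\].
#'
#' @param normed a `normalized_matrix` from [range_normalize()].
#' @param W weight vector summing to 1, one entry per endpoint.
#' @return Named numeric vector of composite scores.
#' @export
composite_scores <- function(normed, W) {
  Y <- if (inherits(normed, "normalized_matrix")) normed$Y else as.matrix(normed)
  if (length(W) != ncol(Y))
    stop("weight vector length (", length(W),
         ") does not match endpoint count (", ncol(Y), ")", call. = FALSE)
  if (abs(sum(W) - 1) > 1e-8)
    stop("weights must sum to 1", call. = FALSE)
  drop(Y %*% W)
}

#' Full composite-biodegradability table
#'
#' Chains [range_normalize()], [entropy_per_endpoint()], [entropy_weights()]
#' and [composite_scores()] into the complete entropy-weight composite-index
#' procedure, returning every intermediate alongside the final composite.
#'
#' @inheritParams range_normalize
#' @inheritParams entropy_per_endpoint
#' @return An object of class `entropy_weight_result`: a list with the raw
#'   matrix `X`, normalized matrix `Y`, entropies `E`, difference
#'   coefficients `H`, weights `W`, composites `Z`, the entropy constant `k`,
#'   compound count `m`, endpoint count `n_endpoints` and `floor_a`.
#' @examples
#' res <- comprehensive_table(pae_docking_scores())
#' round(res$Z[c("DEP", "DUP", "DTDP")], 3)
#' @export
comprehensive_table <- function(scores, floor_a = 0.9, proportions = FALSE) {
  stopifnot(inherits(scores, "score_matrix"))
  normed <- range_normalize(scores, floor_a)
  E <- entropy_per_endpoint(normed, proportions = proportions)
  hw <- entropy_weights(E)
  Z <- composite_scores(normed, hw$W)
  structure(list(X = scores$X, Y = normed$Y, E = E, H = hw$H, W = hw$W,
                 Z = Z, k = 1 / log(nrow(scores$X)), m = nrow(scores$X),
                 n_endpoints = ncol(scores$X), floor_a = floor_a,
                 orientation = scores$orientation,
                 compound_ids = scores$compound_ids,
                 endpoint_ids = scores$endpoint_ids),
            class = "entropy_weight_result")
}

#' @export
print.entropy_weight_result <- function(x, digits = 3, ...) {
  cat("Entropy-weight composite biodegradability (", x$m, " compounds, ",
      x$n_endpoints, " endpoints, a = ", x$floor_a, ")\n\n", sep = "")
  print(composite_report(x, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Assemble the composite-index report table
#'
#' Lays out raw scores, converted values, and the composite column in the
#' conventional report order (raw and converted value side by side per
#' endpoint), followed by the E/H/W summary rows.
#'
#' @param result an `entropy_weight_result` from [comprehensive_table()].
#' @param digits decimal places for values (weights are always given in
#'   percent to 2 places).
#' @return A `data.frame` in display form (all columns character).
#' @export
composite_report <- function(result, digits = 3) {
  stopifnot(inherits(result, "entropy_weight_result"))
  fmt <- function(v) formatC(round(v, digits), format = "f", digits = digits)
  out <- data.frame(Compound = result$compound_ids, stringsAsFactors = FALSE)
  for (j in seq_len(result$n_endpoints)) {
    out[[paste0("Score.", result$endpoint_ids[j])]] <- fmt(result$X[, j])
    out[[paste0("Converted.", result$endpoint_ids[j])]] <- fmt(result$Y[, j])
  }
  out$Composite <- fmt(result$Z)
  summary_rows <- data.frame(
    Compound = c("Ej", "Hj", "Wj"), stringsAsFactors = FALSE)
  for (j in seq_len(result$n_endpoints)) {
    summary_rows[[paste0("Score.", result$endpoint_ids[j])]] <- ""
    summary_rows[[paste0("Converted.", result$endpoint_ids[j])]] <-
      c(fmt(result$E[j]), fmt(result$H[j]),
        paste0(formatC(round(100 * result$W[j], 2), format = "f", digits = 2), "%"))
  }
  summary_rows$Composite <- "-"
  rbind(out, summary_rows)
}

#' Write a composite-index report to a TSV file
#'
#' @inheritParams composite_report
#' @param path output file path.
#' @param header optional comment lines written before the table (each
#'   prefixed with `#`).
#' @return `path`, invisibly.
#' @export
write_composite_report <- function(result, path, digits = 3, header = NULL) {
  tab <- composite_report(result, digits = digits)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
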