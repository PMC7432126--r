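#' Substituent sets used for DEP derivative design
#'
#' The contour-map-derived substitution rules for diethyl phthalate: at the
#' ring hydrogen H1, groups more electropositive than -H; at C1, groups
#' smaller than -CH2CH3; at C2, hydrophilic groups introduced singly or as
#' a pair; and combined H1 x C2 double substitutions restricted to the two
#' amide/ketone hydrophiles.
#'
#' @return An object of class `substitution_scheme`: a list of blocks, each
#'   with a `site` label, `groups`, and a `mode` (`"single"`, `"double"` for
#'   bis-substitution of one group, or `"combo"` for site-pair products).
#' @export
dep_substitution_scheme <- function() {
  h1 <- c("-CH3", "-CH2CH3", "-CH(CH3)2", "-C(CH3)3")
  c1 <- c("-CH3", "-OH", "-H", "-CN", "-NH2", "-CHO")
  c2 <- c("-OH", "-CHO", "-COOH", "-NH2", "-COCH3", "-CONH2")
  structure(list(
    list(site = "H1", groups = h1, mode = "single"),
    list(site = "C1", groups = c1, mode = "single"),
    list(site = "C2", groups = c2, mode = "single"),
    list(site = "C2", groups = c2, mode = "double"),
    list(site = c("H1", "C2"), groups = list(h1, c("-COCH3", "-CONH2")),
         mode = "combo")),
    class = "substitution_scheme")
}

known_substituents <- c("-CH3", "-CH2CH3", "-CH(CH3)2", "-C(CH3)3", "-OH",
                        "-H", "-CN", "-NH2", "-CHO", "-COOH", "-COCH3",
                        "-CONH2")

#' Enumerate the derivative catalogue of a substitution scheme
#'
#' Expands every block of the scheme into derivative records with
#' sequential ids (`<parent>-1`, `<parent>-2`, ...).  `"single"` blocks
#' yield one record per group, `"double"` blocks one bis-substitution
#' record per group (`site-(G)2`), and `"combo"` blocks the cartesian
#' product over the listed sites.  The default DEP scheme yields exactly 30
#' derivatives in the published order.
#'
#' @param scheme a `substitution_scheme`.
#' @param parent parent compound label used in the ids.
#' @return data.frame with columns `id` and `substituent`.
#' @export
enumerate_derivatives <- function(scheme = dep_substitution_scheme(),
                                  parent = "DEP") {
  if (!length(scheme)) return(data.frame(id = character(),
                                         substituent = character(),
                                         stringsAsFactors = FALSE))
  labels <- unlist(lapply(scheme, function(block) {
    gs <- unlist(block$groups)
    unknown <- setdiff(gs, known_substituents)
    if (length(unknown))
      stop("unknown substituent label(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    switch(block$mode,
      single = paste0(block$site, block$groups),
      double = paste0(block$site, "-(", sub("^-", "", block$groups), ")2"),
      combo = {
        # second-site groups in the outer loop, first-site groups inner
        combos <- expand.grid(a = block$groups[[1L]], b = block$groups[[2L]],
                              stringsAsFactors = FALSE)
        paste0(block$site[1L], combos$a, "-", block$site[2L], combos$b)
      },
      stop("unknown mode: ", block$mode, call. = FALSE))
  }))
  data.frame(id = paste0(parent, "-", seq_along(labels)),
             substituent = labels, stringsAsFactors = FALSE)
}

#' Percent change of a predicted value against its parent
#'
#' `100 * (new - parent) / parent`.  Used throughout the derivative
#' bookkeeping (composite values and per-enzyme docking scores alike).
#'
#' @param new_value,parent_value numeric (vectorized).
#' @return Percent change.
#' @export
change_rate <- function(new_value, parent_value) {
  if (any(parent_value == 0))
    stop("change rate undefined for zero parent value", call. = FALSE)
  100 * (new_value - parent_value) / parent_value
}

#' Share decomposition of per-endpoint change rates
#'
#' Expresses each endpoint's change rate as a percentage share of the
#' summed change rates, `100 * rate_j / sum(rates)` — the "which enzyme
#' drove the improvement" triple attached to each double-substituted
#' derivative.
#'
#' @param endpoint_change_rates numeric vector of positive change rates.
#' @return Percentage shares summing to 100.
#' @export
ratio_decomposition <- function(endpoint_change_rates) {
  if (any(endpoint_change_rates <= 0))
    stop("ratio decomposition needs strictly positive change rates",
         call. = FALSE)
  100 * endpoint_change_rates / sum(endpoint_change_rates)
}

#' L1 distance between an endpoint-share triple and the entropy weights
#'
#' Ranks derivatives by how closely the decomposition of their per-enzyme
#' improvements matches the entropy-weight profile of the composite index
#' (a derivative whose gains mirror the weights improves "across the
#' board" rather than on one enzyme).
#'
#' @param ratio percentage shares (summing to ~100).
#' @param W weights as fractions (summing to ~1) or percentages.
#' @return Scalar L1 distance in percentage points.
#' @export
compare_to_weights <- function(ratio, W) {
  if (sum(W) <= 1.5) W <- 100 * W
  if (length(ratio) != length(W))
    stop("ratio and weight vectors must have equal length", call. = FALSE)
  sum(abs(ratio - W))
}

#' Full derivative change-rate and share bookkeeping table
#'
#' Computes, for every derivative row, the composite and per-endpoint
#' change rates against the parent row, and — where all endpoint rates are
#' positive — the endpoint share triple, reproducing the published
#' derivative-prediction table layout.
#'
#' @param predictions data.frame as [dep_derivative_predictions()]: columns
#'   `id`, `substituent`, `composite`, then one score column per endpoint.
#' @param parent_id id of the parent/reference row (default `"DEP"`).
#' @param digits rounding applied to the reported rates (2 = printed
#'   convention); computation is at full precision, rounding only on output.
#' @return data.frame with change-rate columns (`*_chg`), the share triple
#'   as `ratio` text, and the L1 `weight_distance` when `weights` is given.
#' @param weights optional entropy-weight vector for [compare_to_weights()].
#' @export
derivative_change_table <- function(predictions, parent_id = "DEP",
                                    weights = NULL, digits = 2) {
  stopifnot(is.data.frame(predictions))
  if (!parent_id %in% predictions$id)
    stop("parent row ", parent_id, " not found", call. = FALSE)
  score_cols <- setdiff(names(predictions), c("id", "substituent", "composite"))
  parent <- predictions[predictions$id == parent_id, , drop = FALSE]
  rows <- predictions[predictions$id != parent_id, , drop = FALSE]
  out <- rows[, c("id", "substituent", "composite"), drop = FALSE]
  out$composite_chg <- round(change_rate(rows$composite, parent$composite),
                             digits)
  rates <- sapply(score_cols, function(cn)
    change_rate(rows[[cn]], parent[[cn]]))
  rates <- matrix(rates, nrow = nrow(rows),
                  dimnames = list(rows$id, score_cols))
  for (cn in score_cols) {
    out[[cn]] <- rows[[cn]]
    out[[paste0(cn, "_chg")]] <- round(rates[, cn], digits)
  }
  out$ratio <- apply(rates, 1, function(r) {
    if (any(r <= 0)) return(NA_character_)
    paste(formatC(round(ratio_decomposition(r), digits),
                  format = "f", digits = digits), collapse = ":")
  })
  if (!is.null(weights)) {
    out$weight_distance <- apply(rates, 1, function(r) {
      if (any(r <= 0)) return(NA_real_)
      compare_to_weights(ratio_decomposition(r), weights)
    })
  }
  rownames(out) <- NULL
  out
}
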