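#' Validate and structure a degradation pathway table
#'
#' Checks that each compound/path group forms a connected chain (each
#' step's product is the next step's reactant) with strictly positive
#' barriers, and returns the table with a `pathway_table` class attached.
#'
#' @param steps long-format data.frame with columns `compound`, `path`,
#'   `step`, `reactant`, `product`, `barrier` (kJ/mol), as produced by
#'   [dep_pathway_steps()] or read from a TSV.
#' @return The validated data.frame, class `pathway_table`.
#' @export
pathway_table <- function(steps) {
  need <- c("compound", "path", "step", "reactant", "product", "barrier")
  if (!all(need %in% names(steps)))
    stop("pathway table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(steps$barrier)) || any(steps$barrier <= 0))
    stop("step barriers must be positive and finite", call. = FALSE)
  for (key in split(steps, paste(steps$compound, steps$path))) {
    key <- key[order(key$step), ]
    if (nrow(key) > 1L &&
        any(key$product[-nrow(key)] != key$reactant[-1L]))
      stop("broken chain in ", key$compound[1L], " ", key$path[1L],
           ": step products do not feed the next reactant", call. = FALSE)
  }
  class(steps) <- c("pathway_table", class(steps))
  steps
}

#' Total energy barrier of one path
#'
#' Sum of the step barriers along a (validated) path.
#'
#' @param path data.frame of steps for a single compound/path.
#' @return Total barrier, kJ/mol.
#' @export
path_total <- function(path) {
  if (!nrow(path)) stop("empty path", call. = FALSE)
  path <- path[order(path$step), ]
  if (nrow(path) > 1L &&
      any(path$product[-nrow(path)] != path$reactant[-1L]))
    stop("broken chain: step products do not feed the next reactant",
         call. = FALSE)
  sum(path$barrier)
}

#' Percent change of a path total against the reference compound
#'
#' @param derivative_total,reference_total totals in kJ/mol.
#' @return Percent change; negative means the derivative's degradation is
#'   easier than the reference's.
#' @export
path_change_rate <- function(derivative_total, reference_total) {
  if (any(reference_total <= 0))
    stop("reference total must be positive", call. = FALSE)
  100 * (derivative_total - reference_total) / reference_total
}

#' Aggregate per-path change rates into one number per derivative
#'
#' The published aggregate is the plain SUM of the per-path percent
#' changes — a bookkeeping convention, not a physically meaningful
#' percentage (summing percentages of different baselines).  A mean
#' aggregate is available as an alternative.
#'
#' @param path_change_rates numeric vector of per-path percent changes.
#' @param method `"sum"` (published convention) or `"mean"`.
#' @return Scalar aggregate, percent.
#' @export
total_change_rate <- function(path_change_rates, method = c("sum", "mean")) {
  method <- match.arg(method)
  if (!length(path_change_rates)) return(0)
  switch(method, sum = sum(path_change_rates),
         mean = mean(path_change_rates))
}

#' Summarize a pathway table against a reference compound
#'
#' Computes each path's total barrier, its change rate against the same
#' path of the reference compound, and each derivative's aggregate change
#' rate.
#'
#' @param steps a [pathway_table()] (coerced if plain data.frame).
#' @param reference reference compound id (default `"DEP"`).
#' @inheritParams total_change_rate
#' @return List with `totals` (compound x path totals and change rates) and
#'   `aggregate` (per-derivative total change rate).
#' @export
pathway_summary <- function(steps, reference = "DEP",
                            method = c("sum", "mean")) {
  method <- match.arg(method)
  if (!inherits(steps, "pathway_table")) steps <- pathway_table(steps)
  if (!reference %in% steps$compound)
    stop("reference compound ", reference, " not in table", call. = FALSE)
  groups <- split(steps, list(steps$compound, steps$path), drop = TRUE)
  totals <- do.call(rbind, lapply(groups, function(g)
    data.frame(compound = g$compound[1L], path = g$path[1L],
               n_steps = nrow(g), total = path_total(g),
               stringsAsFactors = FALSE)))
  totals <- totals[order(totals$compound, totals$path), ]
  ref <- totals[totals$compound == reference, ]
  ref_lookup <- stats::setNames(ref$total, ref$path)
  totals$change_rate <- ifelse(
    totals$compound == reference, NA_real_,
    path_change_rate(totals$total, ref_lookup[totals$path]))
  derivs <- setdiff(unique(totals$compound), reference)
  aggregate <- vapply(derivs, function(d)
    total_change_rate(totals$change_rate[totals$compound == d], method),
    numeric(1))
  rownames(totals) <- NULL
  list(totals = totals,
       aggregate = data.frame(compound = derivs,
                              total_change_rate = unname(aggregate),
                              stringsAsFactors = FALSE))
}

#' Pair barrier change rates with biodegradability change rates
#'
#' Joins each derivative's aggregate barrier change with its predicted
#' composite-biodegradability change and reports whether the signs oppose
#' (barrier down while biodegradability up — the consistency the barrier
#' calculation is meant to confirm).  The report is independent of input
#' row order.
#'
#' @param barrier_change data.frame with `compound` and `total_change_rate`
#'   (as from `pathway_summary()$aggregate`).
#' @param biodeg_change data.frame with columns `id` (or `compound`) and a
#'   change-rate column, e.g. from [derivative_change_table()].
#' @return data.frame with both rates and a logical `sign_opposed`.
#' @export
consistency_report <- function(barrier_change, biodeg_change) {
  if (!nrow(barrier_change) || !nrow(biodeg_change))
    return(data.frame(compound = character(), barrier_change = numeric(),
                      biodeg_change = numeric(), sign_opposed = logical(),
                      stringsAsFactors = FALSE))
  idcol <- if (!is.null(biodeg_change$id)) "id" else "compound"
  ratecol <- if (!is.null(biodeg_change$composite_chg)) "composite_chg"
             else setdiff(names(biodeg_change), idcol)[1L]
  ids <- sort(barrier_change$compound)
  missing <- setdiff(ids, biodeg_change[[idcol]])
  if (length(missing))
    stop("no biodegradability change for: ",
         paste(missing, collapse = ", "), call. = FALSE)
  b <- barrier_change$total_change_rate[match(ids, barrier_change$compound)]
  z <- biodeg_change[[ratecol]][match(ids, biodeg_change[[idcol]])]
  data.frame(compound = ids, barrier_change = b, biodeg_change = z,
             sign_opposed = sign(b) * sign(z) < 0,
             stringsAsFactors = FALSE)
}
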