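#' Bioconcentration factor from its common logarithm
#'
#' `BCF = 10^logBCF`.  Screening operates on the linear-scale BCF: a
#' compound with BCF below 100 does not appreciably accumulate in
#' organisms.
#'
#' @param logBCF numeric, log10 units.
#' @return BCF, dimensionless.
#' @export
bcf_from_log <- function(logBCF) {
  10^logBCF
}

# Per-column reporting conventions of the published property table:
# the sign each printed change-rate column carries relative to the plain
# relative change (new - parent) / |parent|.
property_rate_spec <- function() {
  data.frame(
    column = c("energy_au", "logLC50", "logt12", "logKOA"),
    rate_column = c("energy_chg", "logLC50_chg", "logt12_chg", "logKOA_chg"),
    sign = c(1, -1, -1, 1),
    stringsAsFactors = FALSE)
}

#' Change rates of derivative properties against the parent compound
#'
#' Adds percent change-rate columns for total energy, bio-toxicity
#' (logLC50), persistence (logt1/2) and migration (logKOA).  The base rate
#' is `100 * (new - parent) / |parent|` (absolute-value denominator so that
#' a more negative total energy reports as a negative, i.e. stabilizing,
#' change); the toxicity and persistence columns are reported with flipped
#' sign, following the published convention of printing the growth of the
#' hazard (toxicity up when logLC50 falls) rather than of the logarithm.
#' A `BCF` column is derived from `logBCF`.
#'
#' @param records data.frame as [dep_property_table()], parent row included.
#' @param parent_id id of the parent row (default `"DEP"`).
#' @param digits output rounding for the rate columns (2 = printed
#'   convention).
#' @return The records with rate and `BCF` columns added (parent rates NA).
#' @export
property_change_rates <- function(records, parent_id = "DEP", digits = 2) {
  stopifnot(is.data.frame(records))
  if (!parent_id %in% records$id)
    stop("parent row ", parent_id, " not found", call. = FALSE)
  parent <- records[records$id == parent_id, , drop = FALSE]
  spec <- property_rate_spec()
  for (k in seq_len(nrow(spec))) {
    cn <- spec$column[k]
    if (is.null(records[[cn]])) next
    pv <- parent[[cn]]
    if (pv == 0)
      stop("change rate undefined: parent ", cn, " is zero", call. = FALSE)
    rate <- spec$sign[k] * 100 * (records[[cn]] - pv) / abs(pv)
    rate[records$id == parent_id] <- NA_real_
    records[[spec$rate_column[k]]] <- round(rate, digits)
  }
  if (!is.null(records$logBCF))
    records$BCF <- round(bcf_from_log(records$logBCF), digits)
  records
}

#' Default functionality / environmental-friendliness screening rules
#'
#' @param min_frequency lowest acceptable vibrational frequency (cm^-1);
#'   a positive lowest frequency marks a true energy minimum, i.e. a
#'   molecule that can exist in the environment.
#' @param max_bcf bioaccumulation ceiling on the linear BCF scale.
#' @param max_toxicity_change largest tolerated percent change in
#'   bio-toxicity (absolute value).
#' @param min_biodeg_gain required percent improvement of the composite
#'   biodegradability over the parent.
#' @return A named list of thresholds.
#' @export
screening_rules <- function(min_frequency = 0, max_bcf = 100,
                            max_toxicity_change = 10, min_biodeg_gain = 15) {
  list(min_frequency = min_frequency, max_bcf = max_bcf,
       max_toxicity_change = max_toxicity_change,
       min_biodeg_gain = min_biodeg_gain)
}

#' Screen derivatives for functionality and environmental friendliness
#'
#' Applies four pass/fail rules to each derivative record: (i) lowest
#' vibrational frequency above `min_frequency`; (ii) BCF below `max_bcf`;
#' (iii) bio-toxicity change within `max_toxicity_change` percent in
#' magnitude; (iv) composite biodegradability improved by more than
#' `min_biodeg_gain` percent.  Persistence and migration changes are
#' reported but carry no pass/fail weight.  Records missing a needed field
#' fail with a record-level reason; the remaining records are still
#' screened.  The verdicts are deterministic and independent of row order.
#'
#' @param records property table (see [dep_property_table()]); change-rate
#'   and `BCF` columns are added via [property_change_rates()] if absent.
#' @param biodeg_change named numeric vector (or two-column data.frame) of
#'   composite-biodegradability change rates per derivative id, e.g. the
#'   `composite_chg` column of [derivative_change_table()].
#' @param rules a [screening_rules()] list.
#' @param parent_id parent row id; the parent itself is screened too (and
#'   fails the improvement rule by construction: its change is zero).
#' @return data.frame with `id`, `verdict` (`"pass"`/`"fail"`) and a
#'   semicolon-separated `reasons` column naming each failed rule.
#' @export
screen_derivatives <- function(records, biodeg_change,
                               rules = screening_rules(),
                               parent_id = "DEP") {
  if (is.data.frame(biodeg_change))
    biodeg_change <- stats::setNames(biodeg_change[[2L]], biodeg_change[[1L]])
  if (!all(c("logLC50_chg", "BCF") %in% names(records)))
    records <- property_change_rates(records, parent_id = parent_id)
  res <- data.frame(id = records$id, verdict = "pass", reasons = "",
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    fails <- character()
    if (is.na(r$frequency)) fails <- c(fails, "missing frequency")
    else if (r$frequency <= rules$min_frequency)
      fails <- c(fails, sprintf("lowest frequency %.2f <= %g cm^-1",
                                r$frequency, rules$min_frequency))
    if (is.na(r$BCF)) fails <- c(fails, "missing BCF")
    else if (r$BCF >= rules$max_bcf)
      fails <- c(fails, sprintf("BCF %.2f >= %g", r$BCF, rules$max_bcf))
    tox <- r$logLC50_chg
    if (r$id == parent_id) tox <- 0
    if (is.na(tox)) fails <- c(fails, "missing toxicity change")
    else if (abs(tox) >= rules$max_toxicity_change)
      fails <- c(fails, sprintf("|toxicity change| %.2f%% >= %g%%",
                                abs(tox), rules$max_toxicity_change))
    gain <- if (r$id == parent_id) 0 else unname(biodeg_change[r$id])
    if (is.null(gain) || is.na(gain))
      fails <- c(fails, "missing biodegradability change")
    else if (gain <= rules$min_biodeg_gain)
      fails <- c(fails, sprintf("biodegradability gain %.2f%% <= %g%%",
                                gain, rules$min_biodeg_gain))
    if (length(fails)) {
      res$verdict[i] <- "fail"
      res$reasons[i] <- paste(fails, collapse = "; ")
    }
  }
  res
}
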