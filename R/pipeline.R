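#' Run the full composite-scoring / design / screening / pathway pipeline
#'
#' Chains the package's stages over one consistent set of inputs — by
#' default the bundled reference tables — and writes each stage's report as
#' a TSV under `out_dir`.  Every output file starts with comment lines
#' recording the package version and the stage configuration, so a rerun
#' with the same inputs is reproducible and self-describing.  A stage
#' failure aborts with the stage name in the error.
#'
#' @param out_dir output directory (created if needed).
#' @param scores a [score_matrix()] for the composite stage.
#' @param predictions derivative prediction table (see
#'   [dep_derivative_predictions()]).
#' @param properties derivative property table (see [dep_property_table()]).
#' @param pathway_steps pathway step table (see [dep_pathway_steps()]).
#' @param floor_a range-normalization floor.
#' @param rules screening thresholds from [screening_rules()].
#' @param parent_id parent compound for derivative/screening/pathway stages.
#' @param qsar optional list with elements `Xd`, `y` (and optionally
#'   `max_components`, `colmap`) to fit and validate a PLS model on field
#'   descriptors as part of the run.
#' @return Invisibly, a list with each stage's in-memory result and the
#'   paths written.
#' @export
run_pipeline <- function(out_dir,
                         scores = pae_docking_scores(),
                         predictions = dep_derivative_predictions(),
                         properties = dep_property_table(),
                         pathway_steps = dep_pathway_steps(),
                         floor_a = 0.9,
                         rules = screening_rules(),
                         parent_id = "DEP",
                         qsar = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  hdr <- function(name, extra = character())
    c(paste0("paedeg ", as.character(utils::packageVersion("paedeg")),
             " | stage: ", name),
      paste0("floor_a = ", floor_a, "; parent = ", parent_id), extra)
  wt <- function(df, name, stage_name, extra = character()) {
    path <- file.path(out_dir, name)
    con <- file(path, "w", encoding = "UTF-8")
    writeLines(paste0("# ", hdr(stage_name, extra)), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    path
  }

  composite <- stage("composite", comprehensive_table(scores, floor_a))
  paths <- c(composite = wt(composite_report(composite),
                            "composite_report.tsv", "composite"))

  qsar_result <- NULL
  if (!is.null(qsar)) {
    qsar_result <- stage("qsar", {
      max_c <- if (is.null(qsar$max_components))
        min(nrow(qsar$Xd) - 2L, 10L) else qsar$max_components
      cv <- loo_q2(qsar$Xd, qsar$y, max_c)
      model <- pls_fit(qsar$Xd, qsar$y, cv$n_opt)
      stats_ <- fit_statistics(model, qsar$Xd, qsar$y)
      contrib <- if (!is.null(qsar$colmap))
        field_contributions(model, qsar$colmap, qsar$Xd) else NULL
      list(model = model, cv = cv, stats = stats_, contributions = contrib)
    })
    qdf <- data.frame(q2 = qsar_result$cv$q2_opt,
                      n_opt = qsar_result$cv$n_opt,
                      R2 = qsar_result$stats$R2,
                      SEE = qsar_result$stats$SEE,
                      F = qsar_result$stats$F)
    paths <- c(paths, qsar = wt(qdf, "qsar_summary.tsv", "qsar"))
  }

  design <- stage("design", derivative_change_table(
    predictions, parent_id = parent_id, weights = composite$W))
  paths <- c(paths, design = wt(design, "derivative_table.tsv", "design"))

  screened <- stage("screen", {
    props <- property_change_rates(properties, parent_id = parent_id)
    verdicts <- screen_derivatives(
      props, stats::setNames(design$composite_chg, design$id),
      rules = rules, parent_id = parent_id)
    merge(props, verdicts, by = "id", sort = FALSE)
  })
  paths <- c(paths, screen = wt(
    screened, "screening_report.tsv", "screen",
    sprintf("rules: freq > %g; BCF < %g; |tox chg| < %g%%; biodeg gain > %g%%",
            rules$min_frequency, rules$max_bcf, rules$max_toxicity_change,
            rules$min_biodeg_gain)))

  pathways <- stage("pathways", {
    summ <- pathway_summary(pathway_steps, reference = parent_id)
    summ$consistency <- consistency_report(
      summ$aggregate, design[, c("id", "composite_chg")])
    summ
  })
  paths <- c(paths,
             pathways = wt(pathways$totals, "pathway_totals.tsv", "pathways"),
             consistency = wt(pathways$consistency,
                              "pathway_consistency.tsv", "pathways"))

  invisible(list(composite = composite, qsar = qsar_result, design = design,
                 screening = screened, pathways = pathways, paths = paths))
}
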