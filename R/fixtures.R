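#' Docking scores of 17 phthalic acid esters against three degrading enzymes
#'
#' Published docking scores of 17 PAE plasticizers against phthalate
#' dioxygenase reductase (*Burkholderia cepacia*, PDB 2PIA), esterase
#' (*Archaeoglobus fulgidus*, PDB 2ZYI) and carboxylesterase (*Pseudomonas
#' aeruginosa*, PDB 3CN7).  Higher scores indicate stronger predicted
#' binding, so all three endpoints are benefit-oriented.  This table is the
#' canonical input of the composite-index stage.
#'
#' @return A [score_matrix()] of 17 compounds by 3 endpoints.
#' @export
pae_docking_scores <- function() {
  X <- matrix(c(
    7.070,  1.908, 5.116,
    5.918,  5.461, 5.275,
    5.754,  5.551, 6.047,
    5.574,  4.711, 3.548,
    7.455,  7.221, 6.964,
    4.824,  5.081, 5.006,
    8.634, 10.570, 7.870,
    7.462, 10.548, 6.660,
    6.313,  5.916, 6.061,
    5.339,  4.609, 5.885,
    7.085,  4.088, 6.876,
    3.293,  4.624, 3.940,
    10.420, 4.797, 8.333,
    5.484,  4.970, 6.313,
    6.273,  6.681, 4.746,
    9.112, 13.722, 8.584,
    11.595, 14.334, 8.561), ncol = 3, byrow = TRUE)
  ids <- c("BBP", "DAP", "DBP", "DEP", "DHP", "DIBP", "DIHP", "DIHXP",
           "DIPP", "DIPRP", "DMEP", "DMP", "DNOP", "DPP", "DPRP",
           "DTDP", "DUP")
  score_matrix(X, compound_ids = ids,
               endpoint_ids = c("2PIA", "2ZYI", "3CN7"),
               orientation = "benefit")
}

#' Published role of each PAE in the QSAR model (training/test/template)
#'
#' @return A data.frame with columns `compound` and `role` (`train`, `test`
#'   or `template`); the template molecule DUP was used in both sets.
#' @export
pae_model_roles <- function() {
  roles <- c(BBP = "train", DAP = "train", DBP = "test", DEP = "train",
             DHP = "train", DIBP = "train", DIHP = "train", DIHXP = "none",
             DIPP = "train", DIPRP = "train", DMEP = "test", DMP = "train",
             DNOP = "train", DPP = "train", DPRP = "test", DTDP = "train",
             DUP = "template")
  data.frame(compound = names(roles), role = unname(roles),
             stringsAsFactors = FALSE)
}

#' Predicted scores of the 30 designed DEP derivatives
#'
#' Model-predicted comprehensive biodegradation values and per-enzyme
#' docking scores for the 30 substituted diethyl-phthalate derivatives,
#' together with the parent DEP baseline row used for all change-rate
#' bookkeeping (note the baselines are the published low-precision values
#' 0.27 / 5.57 / 4.71 / 3.55, not the higher-precision entries of the
#' docking-score table: the published change rates are computed from these).
#'
#' @return A data.frame with columns `id`, `substituent`, `composite`,
#'   `s2PIA`, `s2ZYI`, `s3CN7`.  The first row is the DEP parent.
#' @export
dep_derivative_predictions <- function() {
  txt <- c(
    "DEP|—|0.27|5.57|4.71|3.55",
    "DEP-1|H1-CH3|0.293|5.637|5.232|4.319",
    "DEP-2|H1-CH2CH3|0.311|5.762|5.353|4.329",
    "DEP-3|H1-CH(CH3)2|0.328|5.876|5.397|4.399",
    "DEP-4|H1-C(CH3)3|0.349|5.976|5.673|4.36",
    "DEP-5|C1-CH3|0.269|5.500|4.827|4.262",
    "DEP-6|C1-OH|0.228|4.828|4.838|4.224",
    "DEP-7|C1-H|0.272|5.059|4.784|4.372",
    "DEP-8|C1-CN|0.255|5.266|4.874|4.172",
    "DEP-9|C1-NH2|0.225|4.967|4.677|4.327",
    "DEP-10|C1-CHO|0.255|4.938|5.077|4.113",
    "DEP-11|C2-OH|0.249|5.658|4.594|4.29",
    "DEP-12|C2-CHO|0.262|5.737|4.871|4.282",
    "DEP-13|C2-COOH|0.269|5.892|4.921|4.312",
    "DEP-14|C2-NH2|0.256|5.504|4.911|4.199",
    "DEP-15|C2-COCH3|0.289|6.109|4.969|4.378",
    "DEP-16|C2-CONH2|0.235|5.755|4.776|4.436",
    "DEP-17|C2-(OH)2|0.267|5.484|5.495|4.170",
    "DEP-18|C2-(CHO)2|0.267|5.409|5.73|4.131",
    "DEP-19|C2-(COOH)2|0.284|5.621|5.826|4.119",
    "DEP-20|C2-(NH2)2|0.259|5.444|5.434|4.295",
    "DEP-21|C2-(COCH3)2|0.310|5.799|6.015|4.188",
    "DEP-22|C2-(CONH2)2|0.261|5.362|5.946|4.175",
    "DEP-23|H1-CH3-C2-COCH3|0.357|6.317|5.547|4.198",
    "DEP-24|H1-CH2CH3-C2-COCH3|0.377|6.453|5.725|4.169",
    "DEP-25|H1-CH(CH3)2-C2-COCH3|0.389|6.565|5.708|4.200",
    "DEP-26|H1-C(CH3)3-C2-COCH3|0.406|6.725|5.787|4.282",
    "DEP-27|H1-CH3-C2-CONH2|0.333|6.077|5.778|4.129",
    "DEP-28|H1-CH2CH3-C2-CONH2|0.343|6.151|5.898|4.130",
    "DEP-29|H1-CH(CH3)2-C2-CONH2|0.356|6.263|5.879|4.144",
    "DEP-30|H1-C(CH3)3-C2-CONH2|0.370|6.382|5.953|4.230")
  parts <- strsplit(txt, "|", fixed = TRUE)
  data.frame(
    id = vapply(parts, `[[`, "", 1L),
    substituent = vapply(parts, `[[`, "", 2L),
    composite = as.numeric(vapply(parts, `[[`, "", 3L)),
    s2PIA = as.numeric(vapply(parts, `[[`, "", 4L)),
    s2ZYI = as.numeric(vapply(parts, `[[`, "", 5L)),
    s3CN7 = as.numeric(vapply(parts, `[[`, "", 6L)),
    stringsAsFactors = FALSE)
}

#' Functionality and environmental-friendliness properties of DEP derivatives
#'
#' DFT-derived stability parameters (total energy in Hartree, HOMO-LUMO gap
#' in eV, lowest vibrational frequency in cm^-1) and predicted POP
#' characteristics (bio-toxicity logLC50, bioaccumulation logBCF,
#' persistence logt1/2, long-range migration logKOA) for DEP and its eight
#' double-substituted derivatives.  These values are inputs to the
#' screening stage; the package does not compute them.
#'
#' @return A data.frame, first row the DEP parent.
#' @export
dep_property_table <- function() {
  df <- utils::read.csv(text = "
id,energy_au,gap_ev,frequency,logLC50,logBCF,logt12,logKOA
DEP,-766.62,5.32,24.02,1.100,1.264,3.156,7.505
DEP-23,-919.26,5.15,15.09,0.781,1.879,3.271,8.540
DEP-24,-958.57,5.16,18.09,0.744,1.992,3.250,8.546
DEP-25,-997.89,5.14,17.65,0.737,2.041,3.230,8.563
DEP-26,-1037.2,5.06,15.38,0.672,2.116,3.215,8.766
DEP-27,-935.32,5.00,19.32,1.070,1.569,3.386,8.329
DEP-28,-974.64,4.97,16.33,1.047,1.600,3.378,8.352
DEP-29,-1013.95,4.96,16.24,1.038,1.653,3.357,8.374
DEP-30,-1053.26,4.94,15.99,0.923,1.716,3.349,8.489
", stringsAsFactors = FALSE)
  df
}

#' Degradation-pathway step energy barriers for DEP and three derivatives
#'
#' Reaction energy barriers (kJ/mol, DFT-computed inputs) for the microbial
#' degradation of DEP, DEP-27, DEP-28 and DEP-29 along the Gram-negative
#' route (`Path1`, 4,5-dioxygenation to protocatechuate) and the
#' Gram-positive route (`Path2`, 3,4-dihydroxylation), each a chain of
#' hydrolysis, oxidation and decarboxylation steps.
#'
#' @return A long-format data.frame with columns `compound`, `path`, `step`,
#'   `reactant`, `product`, `barrier`.
#' @export
dep_pathway_steps <- function() {
  mk <- function(compound, path, reactants, products, barriers)
    data.frame(compound = compound, path = path,
               step = seq_along(barriers), reactant = reactants,
               product = products, barrier = barriers,
               stringsAsFactors = FALSE)
  rbind(
    mk("DEP", "Path1", c("DEP", "M0-1", "M0-2", "M0-3"),
       c("M0-1", "M0-2", "M0-3", "M0-5"), c(27.57, 15.75, 53.82, 30.19)),
    mk("DEP", "Path2", c("DEP", "M0-1", "M0-2", "M0-4"),
       c("M0-1", "M0-2", "M0-4", "M0-5"), c(27.57, 15.75, 68.79, 27.57)),
    mk("DEP-27", "Path1", c("DEP-27", "M1-1", "M1-2", "M1-3"),
       c("M1-1", "M1-2", "M1-3", "M1-5"), c(28.88, 13.92, 56.97, 13.39)),
    mk("DEP-27", "Path2", c("DEP-27", "M1-1", "M1-2", "M1-4"),
       c("M1-1", "M1-2", "M1-4", "M1-5"), c(28.88, 13.92, 72.99, 11.29)),
    mk("DEP-28", "Path1", c("DEP-28", "M2-1", "M2-2", "M2-3"),
       c("M2-1", "M2-2", "M2-3", "M2-5"), c(24.94, 15.67, 56.97, 13.39)),
    mk("DEP-28", "Path2", c("DEP-28", "M2-1", "M2-2", "M2-4"),
       c("M2-1", "M2-2", "M2-4", "M2-5"), c(24.94, 15.67, 72.99, 11.29)),
    mk("DEP-29", "Path1", c("DEP-29", "M3-1", "M3-2", "M3-3"),
       c("M3-1", "M3-2", "M3-3", "M3-5"), c(17.07, 12.34, 56.97, 13.39)),
    mk("DEP-29", "Path2", c("DEP-29", "M3-1", "M3-2", "M3-4"),
       c("M3-1", "M3-2", "M3-4", "M3-5"), c(17.07, 12.34, 72.99, 11.29)))
}

#' Write the bundled reference tables as TSV fixture files
#'
#' Emits the docking-score table, derivative predictions, property table and
#' pathway step barriers to `dir` as tab-separated files, so external tools
#' (or the command line) can replay the published workflow offline.
#' Regeneration is deterministic: the same call always produces
#' byte-identical files.
#'
#' @param dir output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_fixture_tables <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    path <- file.path(dir, name)
    con <- file(path, "w", encoding = "UTF-8")
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    path
  }
  sm <- pae_docking_scores()
  scores_df <- data.frame(compound = sm$compound_ids, sm$X,
                          check.names = FALSE, stringsAsFactors = FALSE)
  out <- c(
    scores = wt(scores_df, "docking_scores.tsv"),
    derivatives = wt(dep_derivative_predictions(), "derivative_predictions.tsv"),
    properties = wt(dep_property_table(), "derivative_properties.tsv"),
    pathways = wt(dep_pathway_steps(), "pathway_barriers.tsv"))
  invisible(out)
}
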