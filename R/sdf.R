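#' Write molecules to an SDF V2000 file with a property sidecar
#'
#' Structures (elements + coordinates) go into the SDF via ChemmineR;
#' the probe-relevant per-atom properties (charge, vdW radius,
#' hydrophobicity, donor/acceptor flags), which V2000 atom blocks cannot
#' carry, travel in a tab-separated sidecar keyed by molecule id and atom
#' index.  Atoms are bonded as a simple chain purely to satisfy V2000
#' readers; connectivity is not used anywhere in the field computation.
#' Output is deterministic: the same molecules give byte-identical files.
#'
#' @param molecules list of [molecule()] objects.
#' @param sdf_path output SDF path.
#' @param props_path output sidecar TSV path (default: `sdf_path` with a
#'   `.props.tsv` extension); `NULL` suppresses the sidecar.
#' @return `sdf_path`, invisibly.
#' @export
write_molecules_sdf <- function(molecules, sdf_path,
                                props_path = default_props_path(sdf_path)) {
  if (!requireNamespace("ChemmineR", quietly = TRUE))
    stop("ChemmineR is required for SDF output", call. = FALSE)
  if (inherits(molecules, "molecule")) molecules <- list(molecules)
  sdfs <- lapply(molecules, function(m) {
    n <- nrow(m$atoms)
    ab <- cbind(round(mol_xyz(m), 4), matrix(0, n, 13))
    rownames(ab) <- paste0(m$atoms$element, "_", seq_len(n))
    colnames(ab) <- paste0("C", 1:16)
    nb <- max(0L, n - 1L)
    bb <- if (nb > 0L)
      cbind(seq_len(nb), seq_len(nb) + 1L, 1L,
            matrix(0L, nb, 4))
    else matrix(0L, 0L, 7L)
    colnames(bb) <- paste0("C", 1:7)
    if (nb > 0L) rownames(bb) <- as.character(seq_len(nb))
    methods::new(
      "SDF",
      header = c(Molecule_Name = m$id, Source = "paedeg synthetic",
                 Comment = "",
                 Counts_Line = sprintf(
                   "%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb)),
      atomblock = ab, bondblock = bb, datablock = character(0))
  })
  ids <- vapply(molecules, `[[`, "", "id")
  sdfset <- methods::new("SDFset", SDF = stats::setNames(sdfs, ids), ID = ids)
  ChemmineR::write.SDF(sdfset, sdf_path)
  if (!is.null(props_path)) {
    props <- do.call(rbind, lapply(molecules, function(m)
      cbind(data.frame(molecule = m$id, atom = seq_len(nrow(m$atoms)),
                       stringsAsFactors = FALSE),
            m$atoms[, c("charge", "vdw", "hydrophob", "donor", "acceptor")])))
    con <- file(props_path, "w", encoding = "UTF-8")
    utils::write.table(props, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
  }
  invisible(sdf_path)
}

default_props_path <- function(sdf_path)
  paste0(sub("\\.sdf$", "", sdf_path), ".props.tsv")

#' Read molecules from an SDF V2000 file with an optional property sidecar
#'
#' @param sdf_path SDF file.
#' @param props_path sidecar TSV as written by [write_molecules_sdf()];
#'   `NULL` (or a missing file) leaves the neutral property defaults.
#' @return List of [molecule()] objects.
#' @export
read_molecules_sdf <- function(sdf_path,
                               props_path = default_props_path(sdf_path)) {
  if (!requireNamespace("ChemmineR", quietly = TRUE))
    stop("ChemmineR is required for SDF input", call. = FALSE)
  sdfset <- ChemmineR::read.SDFset(sdf_path)
  props <- if (!is.null(props_path) && file.exists(props_path))
    utils::read.delim(props_path, stringsAsFactors = FALSE)
  else NULL
  lapply(seq_along(ChemmineR::sdfid(sdfset)), function(i) {
    sdf <- sdfset[[i]]
    id <- unname(ChemmineR::header(sdf)["Molecule_Name"])
    ab <- ChemmineR::atomblock(sdf)
    atoms <- data.frame(
      element = sub("_[0-9]+$", "", rownames(ab)),
      x = ab[, 1], y = ab[, 2], z = ab[, 3],
      stringsAsFactors = FALSE)
    if (!is.null(props)) {
      pm <- props[props$molecule == id, , drop = FALSE]
      pm <- pm[order(pm$atom), , drop = FALSE]
      if (nrow(pm) == nrow(atoms))
        atoms <- cbind(atoms,
                       pm[, c("charge", "vdw", "hydrophob", "donor",
                              "acceptor")])
    }
    rownames(atoms) <- NULL
    molecule(id, atoms)
  })
}
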