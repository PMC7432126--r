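#' Construct a compounds-by-endpoints score matrix
#'
#' Container for raw docking (or other) scores of a set of compounds against
#' a set of biodegradability endpoints, together with each endpoint's
#' orientation: `"benefit"` endpoints are better when larger (the usual case
#' for docking scores), `"cost"` endpoints are better when smaller.
#'
#' @param X numeric matrix, one row per compound, one column per endpoint.
#' @param compound_ids character vector of row labels; defaults to
#'   `rownames(X)`.
#' @param endpoint_ids character vector of column labels; defaults to
#'   `colnames(X)`.
#' @param orientation character vector, one of `"benefit"` or `"cost"` per
#'   endpoint, recycled if length one.
#' @return An object of class `score_matrix`.
#' @examples
#' sm <- score_matrix(matrix(c(0, 1, 2, 5, 3, 4), ncol = 2,
#'                           dimnames = list(c("a", "b", "c"), c("e1", "e2"))))
#' sm
#' @export
score_matrix <- function(X, compound_ids = rownames(X),
                         endpoint_ids = colnames(X),
                         orientation = "benefit") {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(compound_ids))
    compound_ids <- paste0("compound", seq_len(nrow(X)))
  if (is.null(endpoint_ids))
    endpoint_ids <- paste0("endpoint", seq_len(ncol(X)))
  orientation <- rep_len(match.arg(orientation, c("benefit", "cost"),
                                   several.ok = TRUE), ncol(X))
  if (nrow(X) < 2L)
    stop("a score matrix needs at least 2 compounds", call. = FALSE)
  if (ncol(X) < 1L)
    stop("a score matrix needs at least 1 endpoint", call. = FALSE)
  if (anyNA(X) || any(!is.finite(X)))
    stop("scores must be finite and non-missing", call. = FALSE)
  if (anyDuplicated(compound_ids))
    stop("duplicate compound ids: ",
         paste(unique(compound_ids[duplicated(compound_ids)]), collapse = ", "),
         call. = FALSE)
  rng <- apply(X, 2, range)
  flat <- which(rng[2, ] - rng[1, ] <= 0)
  if (length(flat))
    stop("constant endpoint column(s): ",
         paste(endpoint_ids[flat], collapse = ", "),
         "; range normalization is degenerate", call. = FALSE)
  dimnames(X) <- list(compound_ids, endpoint_ids)
  structure(list(X = X, compound_ids = compound_ids,
                 endpoint_ids = endpoint_ids, orientation = orientation),
            class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  cat("<score_matrix> ", nrow(x$X), " compounds x ", ncol(x$X),
      " endpoints\n", sep = "")
  cat("orientation:", paste(x$orientation, collapse = ", "), "\n")
  print(x$X, ...)
  invisible(x)
}

#' Read a score table from a delimited text file
#'
#' Expects a header row of endpoint ids and a first column of compound ids.
#' Both tab- and comma-separated files are accepted (the separator is
#' sniffed from the header line).  Unicode minus signs (U+2212), as produced
#' by some typesetters, are normalized to ASCII `-` before parsing.
#'
#' @param path path to a TSV/CSV file.
#' @param orientation per-endpoint orientation, as in [score_matrix()].
#' @return A [score_matrix()].
#' @export
read_score_table <- function(path, orientation = "benefit") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L)
    stop("score table needs a header and at least 2 data rows: ", path,
         call. = FALSE)
  sep <- if (grepl("\t", lines[[1L]])) "\t" else ","
  parts <- strsplit(lines, sep, fixed = TRUE)
  header <- trimws(parts[[1L]])
  ncol_exp <- length(header)
  rows <- parts[-1L]
  bad <- which(lengths(rows) != ncol_exp)
  if (length(bad))
    stop("malformed row at line ", bad[1L] + 1L, " of ", path,
         " (expected ", ncol_exp, " fields, found ",
         lengths(rows)[bad[1L]], ")", call. = FALSE)
  ids <- vapply(rows, function(r) trimws(r[[1L]]), character(1))
  num <- t(vapply(rows, function(r) parse_numbers(r[-1L]),
                  numeric(ncol_exp - 1L)))
  if (anyNA(num)) {
    bad <- which(apply(is.na(num), 1, any))[1L]
    stop("non-numeric value at line ", bad + 1L, " of ", path, call. = FALSE)
  }
  score_matrix(num, compound_ids = ids, endpoint_ids = header[-1L],
               orientation = orientation)
}

# Parse numbers tolerating unicode minus (U+2212) and stray percent signs.
parse_numbers <- function(x) {
  x <- gsub("−", "-", trimws(x))
  x <- sub("%$", "", x)
  suppressWarnings(as.numeric(x))
}
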