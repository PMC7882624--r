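## Tabular text I/O for every pipeline artifact.
##
## Dialect (fixed): tab-separated UTF-8, "." decimal separator, no
## thousands separators, one header row. In the abundance matrix a blank
## cell and "0" both mean "not detected"; there is no NA token. Protein
## accessions are opaque strings (no UniProt parsing).

PEPTIDE_COLUMNS <- c("protein", "peptide", "sample", "replicate", "intensity")
METADATA_COLUMNS <- c("sample", "group", "replicate")

#' Read a long-format peptide intensity table
#'
#' The table holds one row per measured peptide, with columns
#' \code{protein}, \code{peptide}, \code{sample}, \code{replicate} and
#' \code{intensity} (tab-separated, header row required). Row order is
#' preserved.
#'
#' @param path Path to a tab-separated file.
#' @return A \code{data.frame} of class \code{um_peptide_table}.
#' @export
read_peptide_table <- function(path) {
  um_check_file(path)
  raw <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  as_peptide_table(raw)
}

#' Validate a data frame as a peptide intensity table
#'
#' @param x A data frame with the five peptide-table columns.
#' @return \code{x}, classed as \code{um_peptide_table}.
#' @export
as_peptide_table <- function(x) {
  missing_cols <- setdiff(PEPTIDE_COLUMNS, names(x))
  if (length(missing_cols) > 0) {
    um_schema_error(sprintf(
      "peptide table lacks required column(s): %s",
      paste(missing_cols, collapse = ", ")))
  }
  x <- as.data.frame(x)[PEPTIDE_COLUMNS]
  x$intensity <- as.numeric(x$intensity)
  x$replicate <- as.integer(x$replicate)
  bad <- which(!is.finite(x$intensity) | x$intensity < 0)
  if (length(bad) > 0) {
    um_validation_error(sprintf(
      "negative or non-numeric intensity at row %d", bad[1]))
  }
  if (any(is.na(x$replicate) | x$replicate < 1)) {
    um_validation_error("replicate must be a positive integer")
  }
  key <- paste(x$protein, x$peptide, x$sample, x$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    um_validation_error(sprintf(
      "duplicated (protein, peptide, sample, replicate) at row %d",
      which(duplicated(key))[1]))
  }
  class(x) <- c("um_peptide_table", "data.frame")
  x
}

#' Write a peptide intensity table
#'
#' @param table A peptide table (see [read_peptide_table()]).
#' @param path Output path.
#' @export
write_peptide_table <- function(table, path) {
  write_results_table(as.data.frame(table), path)
}

#' Read sample metadata
#'
#' Expects columns \code{sample}, \code{group}, \code{replicate}; one row
#' per (sample, technical replicate). Groups must come from the closed set
#' NC, T2DM, VD, DVD.
#'
#' @param path Path to a tab-separated file.
#' @return A validated metadata \code{data.frame}.
#' @export
read_sample_metadata <- function(path) {
  um_check_file(path)
  raw <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  as_sample_metadata(raw)
}

#' Validate a sample metadata data frame
#'
#' @param x A data frame with columns sample, group, replicate.
#' @return The validated data frame.
#' @export
as_sample_metadata <- function(x) {
  missing_cols <- setdiff(METADATA_COLUMNS, names(x))
  if (length(missing_cols) > 0) {
    um_schema_error(sprintf(
      "metadata lacks required column(s): %s",
      paste(missing_cols, collapse = ", ")))
  }
  x <- as.data.frame(x)[METADATA_COLUMNS]
  x$sample <- as.character(x$sample)
  x$group <- as.character(x$group)
  x$replicate <- as.integer(x$replicate)
  if (any(!nzchar(x$sample))) um_validation_error("empty sample id")
  bad_group <- setdiff(unique(x$group), UM_GROUPS)
  if (length(bad_group) > 0) {
    um_validation_error(sprintf(
      "unknown group(s): %s (allowed: %s)",
      paste(bad_group, collapse = ", "), paste(UM_GROUPS, collapse = ", ")))
  }
  if (any(is.na(x$replicate) | x$replicate < 1)) {
    um_validation_error("replicate must be a positive integer")
  }
  key <- paste(x$sample, x$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    um_validation_error("duplicated (sample, replicate) in metadata")
  }
  ## a sample must not change group across replicates
  grp <- tapply(x$group, x$sample, function(g) length(unique(g)))
  if (any(grp > 1)) {
    um_validation_error("a sample is assigned to more than one group")
  }
  x
}

#' Write sample metadata
#' @param metadata A metadata data frame.
#' @param path Output path.
#' @export
write_sample_metadata <- function(metadata, path) {
  write_results_table(metadata, path)
}

#' Read a protein-by-sample abundance matrix
#'
#' First column = protein accession, remaining columns = sample (or
#' sample.replicate) ids. Blank cells are read as 0, the non-detection
#' sentinel.
#'
#' @param path Path to a tab-separated file.
#' @return A numeric matrix with protein rownames and sample colnames.
#' @export
read_abundance_matrix <- function(path) {
  um_check_file(path)
  raw <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character")
  if (ncol(raw) < 2) {
    um_schema_error("abundance matrix needs a protein column plus >=1 sample")
  }
  proteins <- raw[[1]]
  if (anyDuplicated(proteins)) {
    um_validation_error(sprintf(
      "duplicated protein accession: %s", proteins[duplicated(proteins)][1]))
  }
  if (anyDuplicated(names(raw)[-1])) {
    um_validation_error("duplicated sample column in abundance matrix")
  }
  vals <- as.matrix(raw[, -1, drop = FALSE])
  vals[vals == "" | is.na(vals)] <- "0"
  mat <- matrix(as.numeric(vals), nrow = nrow(vals), ncol = ncol(vals),
                dimnames = list(proteins, names(raw)[-1]))
  if (anyNA(mat)) um_validation_error("non-numeric abundance value")
  if (any(mat < 0)) um_validation_error("negative abundance value")
  mat
}

#' Write a protein-by-sample abundance matrix
#' @param matrix Numeric matrix, protein rownames, sample colnames.
#' @param path Output path.
#' @export
write_abundance_matrix <- function(matrix, path) {
  df <- data.frame(protein = rownames(matrix), matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_results_table(df, path)
}

#' Write any rectangular result collection as tab-separated text
#'
#' Deterministic column order (as given), one header row, full double
#' precision (at least 6 significant digits survive a round-trip).
#'
#' @param records A data frame (or coercible list of rows).
#' @param path Output path.
#' @export
write_results_table <- function(records, path) {
  df <- as.data.frame(records, stringsAsFactors = FALSE)
  dir_ok <- dir.exists(dirname(path))
  if (!dir_ok) um_io_error(sprintf("output directory does not exist: %s",
                                   dirname(path)))
  ok <- tryCatch({
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = TRUE, na = "")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) um_io_error(sprintf("cannot write to %s", path))
  invisible(path)
}

#' Read a results table written by [write_results_table()]
#' @param path Path to a tab-separated file with a header row.
#' @return A data frame.
#' @export
read_results_table <- function(path) {
  um_check_file(path)
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

um_check_file <- function(path) {
  if (!file.exists(path)) um_io_error(sprintf("file not found: %s", path))
  invisible(path)
}
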