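## Peptide-to-protein quantification: identification filter (>=2 unique
## peptides), Top-N aggregation per (protein, sample, replicate),
## summed-intensity normalization, replicate averaging, and per-group CV.

#' Drop proteins identified by too few unique peptides
#'
#' A protein is retained only if at least \code{min_unique_peptides}
#' distinct peptide sequences carry nonzero intensity in at least one
#' sample. The filter is idempotent.
#'
#' @param table A peptide table.
#' @param min_unique_peptides Minimum number of unique detected peptides
#'   (default 2).
#' @return The filtered peptide table (possibly empty).
#' @export
identification_filter <- function(table, min_unique_peptides = 2L) {
  table <- as_peptide_table(table)
  if (min_unique_peptides < 1) {
    um_config_error("min_unique_peptides must be >= 1")
  }
  dt <- data.table::as.data.table(table)
  counts <- dt[intensity > 0,
               list(n_pep = data.table::uniqueN(peptide)), by = "protein"]
  keep <- counts$protein[counts$n_pep >= min_unique_peptides]
  out <- table[table$protein %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("um_peptide_table", "data.frame")
  out
}

#' Top-N protein abundance per sample replicate
#'
#' For each (protein, sample, replicate): abundance is the mean (or sum) of
#' the \code{top_n} largest nonzero peptide intensities; if fewer than
#' \code{top_n} are detected, those available are used; if none, 0.
#'
#' @param table A (filtered) peptide table.
#' @param top_n How many peptides to aggregate (default 3).
#' @param statistic \code{"mean"} (default) or \code{"sum"}.
#' @return A numeric matrix, proteins x replicate columns. Columns are
#'   named \code{<sample>.<replicate>}; the sample/replicate map is kept in
#'   attribute \code{column_map}.
#' @export
top_n_abundance <- function(table, top_n = 3L, statistic = c("mean", "sum")) {
  table <- as_peptide_table(table)
  statistic <- match.arg(statistic)
  if (top_n < 1) um_config_error("top_n must be >= 1")
  dt <- data.table::as.data.table(table)
  if (nrow(dt) == 0) {
    mat <- matrix(numeric(), 0, 0)
    attr(mat, "column_map") <- data.frame(column = character(),
                                          sample = character(),
                                          replicate = integer())
    return(mat)
  }
  agg_fun <- if (statistic == "mean") mean else sum
  agg <- dt[, list(abundance = {
    v <- sort(intensity[intensity > 0], decreasing = TRUE)
    if (length(v) == 0) 0 else agg_fun(head(v, top_n))
  }), by = c("protein", "sample", "replicate")]

  proteins <- unique(dt$protein)
  cols <- unique(dt[, c("sample", "replicate")])
  data.table::setorder(cols, sample, replicate)
  col_id <- paste(cols$sample, cols$replicate, sep = UM_REP_SEP)
  mat <- matrix(0, length(proteins), nrow(cols),
                dimnames = list(proteins, col_id))
  mat[cbind(match(agg$protein, proteins),
            match(paste(agg$sample, agg$replicate, sep = UM_REP_SEP),
                  col_id))] <- agg$abundance
  attr(mat, "column_map") <- data.frame(column = col_id,
                                        sample = cols$sample,
                                        replicate = cols$replicate,
                                        stringsAsFactors = FALSE)
  mat
}

#' Normalize matrix columns to the summed intensity
#'
#' Each column is rescaled so its total equals the mean of the original
#' column totals; within-column ratios are preserved and values keep the
#' raw-intensity magnitude. All-zero columns are left as zero with a
#' warning.
#'
#' @param matrix Protein x sample (or replicate) abundance matrix.
#' @return The normalized matrix.
#' @export
normalize_summed_intensity <- function(matrix) {
  totals <- colSums(matrix)
  if (all(totals == 0)) um_validation_error("all columns sum to zero")
  if (any(totals == 0)) {
    warning(sprintf("%d all-zero column(s) left unnormalized",
                    sum(totals == 0)))
  }
  target <- mean(totals)
  scale <- ifelse(totals > 0, target / totals, 1)
  out <- sweep(matrix, 2, scale, `*`)
  attr(out, "column_map") <- attr(matrix, "column_map")
  out
}

#' Average technical replicate columns into one column per sample
#'
#' @param matrix Per-replicate abundance matrix whose columns are named
#'   \code{<sample>.<replicate>} (as produced by [top_n_abundance()]).
#' @param metadata Sample metadata with one row per (sample, replicate).
#' @return Protein x sample matrix, columns ordered as samples first appear
#'   in the metadata. Zero replicates participate in the mean (a zero is a
#'   measurement of non-detection).
#' @export
average_replicates <- function(matrix, metadata) {
  metadata <- as_sample_metadata(metadata)
  cmap <- attr(matrix, "column_map")
  if (is.null(cmap)) {
    cmap <- data.frame(column = colnames(matrix), stringsAsFactors = FALSE)
    cmap$sample <- sub(paste0("\\", UM_REP_SEP, "[0-9]+$"), "", cmap$column)
    cmap$replicate <- as.integer(sub(paste0("^.*\\", UM_REP_SEP), "",
                                     cmap$column))
  }
  samples <- unique(metadata$sample)
  out <- matrix(0, nrow(matrix), length(samples),
                dimnames = list(rownames(matrix), samples))
  for (s in samples) {
    reps <- metadata$replicate[metadata$sample == s]
    wanted <- paste(s, reps, sep = UM_REP_SEP)
    have <- intersect(wanted, cmap$column)
    if (length(have) == 0) {
      um_validation_error(sprintf("no replicate columns for sample %s", s))
    }
    out[, s] <- rowMeans(matrix[, have, drop = FALSE])
  }
  out
}

#' Per-group coefficient of variation over nonzero abundances
#'
#' CV is computed per (protein, group) over the group's nonzero values as
#' sd/mean; cells with fewer than two nonzero values are omitted. The
#' inverted definition mean/sd is available for comparison.
#'
#' @param matrix Replicate-averaged protein x sample abundance matrix.
#' @param metadata Sample metadata.
#' @param definition \code{"sd_over_mean"} (standard, default) or
#'   \code{"mean_over_sd"}.
#' @return Data frame with columns protein, group, n_nonzero, cv.
#' @export
protein_cv <- function(matrix, metadata,
                       definition = c("sd_over_mean", "mean_over_sd")) {
  metadata <- as_sample_metadata(metadata)
  definition <- match.arg(definition)
  smap <- unique(metadata[, c("sample", "group")])
  missing_s <- setdiff(colnames(matrix), smap$sample)
  if (length(missing_s) > 0) {
    um_validation_error(sprintf("samples absent from metadata: %s",
                                paste(missing_s, collapse = ", ")))
  }
  groups <- smap$group[match(colnames(matrix), smap$sample)]
  rows <- list()
  for (g in unique(groups)) {
    sub <- matrix[, groups == g, drop = FALSE]
    n_nz <- rowSums(sub > 0)
    ok <- which(n_nz >= 2)
    if (length(ok) == 0) next
    cv <- vapply(ok, function(i) {
      v <- sub[i, ]
      v <- v[v > 0]
      if (definition == "sd_over_mean") sd(v) / mean(v) else mean(v) / sd(v)
    }, numeric(1))
    rows[[g]] <- data.frame(protein = rownames(sub)[ok], group = g,
                            n_nonzero = n_nz[ok], cv = cv,
                            stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(protein = character(), group = character(),
                      n_nonzero = integer(), cv = numeric())
  }
  rownames(out) <- NULL
  out
}

#' Full peptide-to-matrix quantification chain
#'
#' identification filter -> Top-N aggregation per replicate ->
#' summed-intensity normalization -> replicate averaging.
#'
#' @inheritParams identification_filter
#' @inheritParams top_n_abundance
#' @param metadata Sample metadata.
#' @param normalization \code{"summed_intensity"} (default) or
#'   \code{"none"}.
#' @return Replicate-averaged protein x sample abundance matrix.
#' @export
quantify_peptides <- function(table, metadata, min_unique_peptides = 2L,
                              top_n = 3L,
                              normalization = c("summed_intensity", "none"),
                              statistic = c("mean", "sum")) {
  normalization <- match.arg(normalization)
  statistic <- match.arg(statistic)
  filtered <- identification_filter(table, min_unique_peptides)
  if (nrow(filtered) == 0) {
    return(matrix(numeric(), 0, 0))
  }
  per_rep <- top_n_abundance(filtered, top_n, statistic)
  if (normalization == "summed_intensity") {
    per_rep <- normalize_summed_intensity(per_rep)
  }
  average_replicates(per_rep, metadata)
}
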