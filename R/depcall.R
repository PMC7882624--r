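## Differential-expression calling for zero-inflated abundance matrices.
##
## Conventions: fold change uses group means INCLUDING zeros (a zero is a
## measurement after zero substitution), the t-test uses log2 of the
## NONZERO values only. "More than half" in the zero-pattern rule is
## strict (> 0.5): exactly 50% zeros fails both clauses.

#' Classify a protein's zero pattern across two groups
#'
#' Implements the group-specific rule: if more than half the case values
#' are zero while more than half the control values are nonzero, the
#' protein belongs to the control group (\code{control_specific}), and
#' mirrored for \code{case_specific}. Majority-nonzero in both groups is
#' \code{testable}; anything else is \code{untestable}.
#'
#' @param case_values,control_values Nonnegative numeric vectors.
#' @return One of \code{"testable"}, \code{"case_specific"},
#'   \code{"control_specific"}, \code{"untestable"}.
#' @export
zero_pattern_status <- function(case_values, control_values) {
  if (length(case_values) == 0 || length(control_values) == 0) {
    um_validation_error("both groups must be nonempty")
  }
  case_nz <- mean(case_values != 0)
  ctrl_nz <- mean(control_values != 0)
  if (case_nz > 0.5 && ctrl_nz > 0.5) return("testable")
  if (case_nz > 0.5 && (1 - ctrl_nz) > 0.5) return("case_specific")
  if (ctrl_nz > 0.5 && (1 - case_nz) > 0.5) return("control_specific")
  "untestable"
}

#' Fold change of group means (zeros included)
#'
#' @param case_values,control_values Nonnegative numeric vectors.
#' @return List with \code{fc} = mean(case)/mean(control) and
#'   \code{log2fc} = log2(fc). Control mean 0 gives \code{Inf}; both means
#'   0 gives \code{NA}.
#' @export
fold_change <- function(case_values, control_values) {
  mc <- mean(case_values)
  mk <- mean(control_values)
  if (mk == 0 && mc == 0) return(list(fc = NA_real_, log2fc = NA_real_))
  if (mk == 0) return(list(fc = Inf, log2fc = Inf))
  fc <- mc / mk
  list(fc = fc, log2fc = if (fc > 0) log2(fc) else -Inf)
}

#' Two-sample t-test on log2 of the nonzero values
#'
#' Pooled-variance (Student) by default, Welch behind a flag. Returns
#' \code{NA} when either group has fewer than two nonzero values (the
#' protein is then untestable).
#'
#' @param case_values,control_values Nonnegative numeric vectors.
#' @param var_equal Pooled variance if \code{TRUE} (default).
#' @return Two-sided p-value, or \code{NA_real_}.
#' @export
ttest_log2 <- function(case_values, control_values, var_equal = TRUE) {
  x <- log2(case_values[case_values > 0])
  y <- log2(control_values[control_values > 0])
  if (length(x) < 2 || length(y) < 2) return(NA_real_)
  if (var_equal) {
    nx <- length(x); ny <- length(y)
    sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
    if (sp2 == 0) return(if (mean(x) == mean(y)) 1 else 0)
    tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
    2 * pt(-abs(tstat), df = nx + ny - 2)
  } else {
    tryCatch(t.test(x, y, var.equal = FALSE)$p.value,
             error = function(e) if (mean(x) == mean(y)) 1 else 0)
  }
}

#' Call differentially expressed proteins for one contrast
#'
#' Regulation is \code{up} iff (p < \code{p_threshold} and fc >
#' \code{fc_up}) or the protein is case-specific; \code{down} iff (p <
#' \code{p_threshold} and fc < \code{fc_down}) or control-specific;
#' \code{none} otherwise. Group-specific proteins get p recorded as 0.
#'
#' @param matrix Replicate-averaged protein x sample abundance matrix.
#' @param metadata Sample metadata.
#' @param case_group,control_group Group labels of the contrast
#'   (case defaults to \code{"DVD"}).
#' @param p_threshold,fc_up,fc_down Decision thresholds (defaults 0.05,
#'   1.20, 0.83).
#' @param var_equal Pooled-variance t-test if \code{TRUE} (default).
#' @return Data frame with one row per protein: protein, fc, log2fc,
#'   p_value, p_bh (BH over the testable p-values, informational only),
#'   status, regulation, contrast.
#' @export
call_deps <- function(matrix, metadata, case_group = "DVD", control_group,
                      p_threshold = 0.05, fc_up = 1.20, fc_down = 0.83,
                      var_equal = TRUE) {
  metadata <- as_sample_metadata(metadata)
  if (!case_group %in% UM_GROUPS || !control_group %in% UM_GROUPS) {
    um_config_error("contrast groups must come from NC, T2DM, VD, DVD")
  }
  if (case_group == control_group) {
    um_config_error("case and control groups must differ")
  }
  smap <- unique(metadata[, c("sample", "group")])
  case_cols <- intersect(colnames(matrix),
                         smap$sample[smap$group == case_group])
  ctrl_cols <- intersect(colnames(matrix),
                         smap$sample[smap$group == control_group])
  if (length(case_cols) < 2 || length(ctrl_cols) < 2) {
    um_validation_error("each contrast group needs >= 2 sample columns")
  }
  np <- nrow(matrix)
  status <- character(np); fc <- numeric(np); lfc <- numeric(np)
  p <- rep(NA_real_, np)
  for (i in seq_len(np)) {
    cv <- matrix[i, case_cols]
    kv <- matrix[i, ctrl_cols]
    st <- zero_pattern_status(cv, kv)
    f <- fold_change(cv, kv)
    fc[i] <- f$fc; lfc[i] <- f$log2fc
    if (st == "testable") {
      pv <- ttest_log2(cv, kv, var_equal = var_equal)
      if (is.na(pv)) st <- "untestable" else p[i] <- pv
    } else if (st %in% c("case_specific", "control_specific")) {
      p[i] <- 0
    }
    status[i] <- st
  }
  regulation <- rep("none", np)
  testable <- status == "testable"
  regulation[testable & !is.na(p) & p < p_threshold &
               !is.na(fc) & fc > fc_up] <- "up"
  regulation[testable & !is.na(p) & p < p_threshold &
               !is.na(fc) & fc < fc_down] <- "down"
  regulation[status == "case_specific"] <- "up"
  regulation[status == "control_specific"] <- "down"
  p_bh <- rep(NA_real_, np)
  p_bh[testable] <- p.adjust(p[testable], method = "BH")
  data.frame(protein = rownames(matrix), fc = fc, log2fc = lfc,
             p_value = p, p_bh = p_bh, status = status,
             regulation = regulation,
             contrast = paste0(case_group, "_vs_", control_group),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Intersect DEP calls across contrasts
#'
#' @param results_by_contrast Named list of [call_deps()] result frames
#'   (>= 2 contrasts).
#' @return List with \code{common} (accessions differentially expressed in
#'   every contrast) and \code{counts} (per-contrast DEP total and
#'   exclusive count, for a Venn-style report).
#' @export
common_deps <- function(results_by_contrast) {
  if (length(results_by_contrast) < 2) {
    um_validation_error("need at least 2 contrasts")
  }
  sets <- lapply(results_by_contrast,
                 function(r) r$protein[r$regulation != "none"])
  common <- Reduce(intersect, sets)
  nm <- names(results_by_contrast) %||%
    paste0("contrast", seq_along(results_by_contrast))
  exclusive <- vapply(seq_along(sets), function(i) {
    others <- unique(unlist(sets[-i]))
    sum(!sets[[i]] %in% others)
  }, integer(1))
  counts <- data.frame(contrast = nm,
                       n_dep = lengths(sets),
                       n_exclusive = exclusive,
                       n_common = length(common),
                       stringsAsFactors = FALSE, row.names = NULL)
  list(common = common, counts = counts)
}

#' Volcano plot coordinates
#'
#' Testable proteins only; the group-specific p = 0 sentinel rows are
#' excluded (their count is kept in attribute \code{n_excluded}).
#'
#' @param results A [call_deps()] result frame.
#' @return Data frame with protein, log2fc, neg_log10_p, regulation.
#' @export
volcano_coordinates <- function(results) {
  keep <- results$status == "testable" & !is.na(results$p_value)
  out <- data.frame(protein = results$protein[keep],
                    log2fc = results$log2fc[keep],
                    neg_log10_p = -log10(results$p_value[keep]),
                    regulation = results$regulation[keep],
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_excluded") <- sum(!keep)
  out
}
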