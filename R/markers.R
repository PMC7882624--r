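## Diagnostic-marker evaluation: empirical ROC with the decision rule
## "score >= threshold => predicted case", tie-corrected Mann-Whitney AUC,
## DeLong (default) or Hanley-McNeil confidence intervals, the Euclidean
## closest-to-(0,1) cutpoint index E = (1-Se)^2 + (1-Sp)^2, sensitivity at
## fixed specificity, and two-marker logistic composites. Evaluation is
## in-sample (apparent performance).

check_labeled_scores <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    um_validation_error("scores and labels differ in length")
  }
  if (anyNA(scores) || anyNA(labels)) {
    um_validation_error("missing scores or labels")
  }
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) {
    um_validation_error("labels must be binary (1 = case, 0 = control)")
  }
  if (sum(labels == 1) < 1 || sum(labels == 0) < 1) {
    um_validation_error("need at least one case and one control")
  }
  labels
}

#' Empirical ROC curve
#'
#' One point per distinct score threshold under the rule "score >=
#' threshold predicts case", plus the endpoints (Se=1, Sp=0) at threshold
#' \code{-Inf} and (Se=0, Sp=1) at \code{+Inf}. Sensitivity is
#' nonincreasing in the threshold.
#'
#' @param scores Numeric marker scores.
#' @param labels Binary labels (1 = case, 0 = control).
#' @return Data frame with columns threshold, se, sp.
#' @export
roc_points <- function(scores, labels) {
  labels <- check_labeled_scores(scores, labels)
  cases <- scores[labels == 1]
  controls <- scores[labels == 0]
  thr <- c(-Inf, sort(unique(scores)), Inf)
  se <- vapply(thr, function(t) mean(cases >= t), numeric(1))
  sp <- vapply(thr, function(t) mean(controls < t), numeric(1))
  data.frame(threshold = thr, se = se, sp = sp, row.names = NULL)
}

#' Tie-corrected AUC with confidence interval and Wilcoxon p-value
#'
#' AUC is the Mann-Whitney statistic U/(n1*n0) counting ties as 1/2. The
#' confidence interval uses DeLong's placement-based variance by default
#' (Hanley-McNeil available); the p-value is the two-sided
#' normal-approximation Wilcoxon rank-sum test of case vs control scores.
#'
#' @inheritParams roc_points
#' @param ci_method \code{"delong"} (default) or \code{"hanley"}.
#' @param conf_level Confidence level (default 0.95).
#' @return List: auc, ci_low, ci_high, wilcoxon_p. With fewer than two
#'   cases or two controls the CI is \code{NA} and flagged via attribute
#'   \code{ci_defined = FALSE}.
#' @export
marker_auc <- function(scores, labels, ci_method = c("delong", "hanley"),
                       conf_level = 0.95) {
  labels <- check_labeled_scores(scores, labels)
  ci_method <- match.arg(ci_method)
  cases <- scores[labels == 1]
  controls <- scores[labels == 0]
  n1 <- length(cases); n0 <- length(controls)
  r <- rank(c(cases, controls))
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  wp <- suppressWarnings(
    wilcox.test(cases, controls, exact = FALSE, correct = FALSE)$p.value)
  if (is.na(wp)) wp <- 1  # all scores identical: zero-variance rank test
  z <- qnorm(1 - (1 - conf_level) / 2)
  if (n1 < 2 || n0 < 2) {
    out <- list(auc = auc, ci_low = NA_real_, ci_high = NA_real_,
                wilcoxon_p = wp)
    attr(out, "ci_defined") <- FALSE
    return(out)
  }
  if (ci_method == "delong") {
    psi <- outer(cases, controls,
                 function(x, y) (x > y) + 0.5 * (x == y))
    v10 <- rowMeans(psi)           # placement of each case
    v01 <- colMeans(psi)           # placement of each control
    v <- var(v10) / n1 + var(v01) / n0
  } else {
    q1 <- auc / (2 - auc)
    q2 <- 2 * auc^2 / (1 + auc)
    v <- (auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
            (n0 - 1) * (q2 - auc^2)) / (n1 * n0)
  }
  se <- sqrt(max(v, 0))
  out <- list(auc = auc, ci_low = max(0, auc - z * se),
              ci_high = min(1, auc + z * se), wilcoxon_p = wp)
  attr(out, "ci_defined") <- TRUE
  out
}

#' Euclidean closest-to-(0,1) cutpoint index
#'
#' The squared distance of an ROC point from the perfect classifier,
#' \eqn{E = (1 - Se)^2 + (1 - Sp)^2}. The optimal cutpoint minimizes it.
#'
#' @param se Sensitivity in \[0, 1\].
#' @param sp Specificity in \[0, 1\].
#' @return The index, in \[0, 2\].
#' @export
euclid_index <- function(se, sp) {
  if (any(se < 0 | se > 1) || any(sp < 0 | sp > 1)) {
    um_validation_error("se and sp must lie in [0, 1]")
  }
  (1 - se)^2 + (1 - sp)^2
}

#' Optimal cutpoint by the Euclidean index
#'
#' Scans the ROC curve for the threshold minimizing
#' \eqn{(1-Se)^2 + (1-Sp)^2}; ties are broken by higher sensitivity, then
#' lower threshold, so output is deterministic.
#'
#' @param curve A [roc_points()] data frame.
#' @return List: cutpoint, se, one_minus_sp, euclid_index.
#' @export
optimal_cutpoint_euclid <- function(curve) {
  if (nrow(curve) < 2) um_validation_error("degenerate ROC curve")
  e <- euclid_index(curve$se, curve$sp)
  ord <- order(e, -curve$se, curve$threshold)
  best <- ord[1]
  list(cutpoint = curve$threshold[best], se = curve$se[best],
       one_minus_sp = 1 - curve$sp[best], euclid_index = e[best])
}

#' Highest sensitivity attainable at a specificity floor
#'
#' @param curve A [roc_points()] data frame.
#' @param spec_floor Minimum specificity (default 0.95).
#' @return Maximum Se among points with Sp >= \code{spec_floor}; 0 if none.
#' @export
sensitivity_at_specificity <- function(curve, spec_floor = 0.95) {
  ok <- curve$sp >= spec_floor
  if (!any(ok)) return(0)
  max(curve$se[ok])
}

#' Two-marker logistic composite
#'
#' Both markers are z-standardized over all samples, then the label is fit
#' by maximum-likelihood logistic regression on the two standardized
#' scores. The composite score is the fitted probability (monotone in the
#' linear combination, hence ROC-equivalent to it). Perfect separation is
#' flagged and the diverging fitted probabilities are clamped.
#'
#' @param a,b Numeric score vectors of the two markers, same samples.
#' @param labels Binary labels (1 = case, 0 = control).
#' @return List of class \code{um_composite}: intercept, coef_a, coef_b,
#'   scores (fitted probabilities), separation flag, and the
#'   standardization parameters (mean_a, sd_a, mean_b, sd_b).
#' @export
fit_composite <- function(a, b, labels) {
  labels <- check_labeled_scores(a, labels)
  if (length(b) != length(a)) {
    um_validation_error("marker score vectors differ in length")
  }
  if (sd(a) == 0 || sd(b) == 0) {
    um_validation_error("constant marker cannot be standardized")
  }
  za <- (a - mean(a)) / sd(a)
  zb <- (b - mean(b)) / sd(b)
  separation <- FALSE
  fit <- withCallingHandlers(
    glm(labels ~ za + zb, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  ## glm's own warning can miss converged-at-the-boundary fits; fitted
  ## probabilities pinned to 0/1 are the operational symptom
  if (any(fitted(fit) > 1 - 1e-8) || any(fitted(fit) < 1e-8)) {
    separation <- TRUE
  }
  if (separation) {
    warning("possible separation in composite logistic fit; scores clamped")
  }
  eps <- 1e-12
  scores <- pmin(pmax(fitted(fit), eps), 1 - eps)
  cf <- coef(fit)
  structure(list(intercept = unname(cf[1]), coef_a = unname(cf[2]),
                 coef_b = unname(cf[3]), scores = unname(scores),
                 separation = separation,
                 mean_a = mean(a), sd_a = sd(a),
                 mean_b = mean(b), sd_b = sd(b)),
            class = "um_composite")
}

#' Evaluate one score vector as a diagnostic marker
#'
#' Computes the full ROC summary: AUC with CI and Wilcoxon p, Euclidean
#' optimal cutpoint with its Se / 1-Sp / index, and sensitivity at the
#' specificity floor. If the raw AUC is below 0.5 and \code{auto_flip} is
#' on, the score sign is flipped (rule becomes "score <= cutpoint") and the
#' flip is recorded.
#'
#' @inheritParams roc_points
#' @inheritParams marker_auc
#' @param spec_floor Specificity floor for \code{sens_at_spec}
#'   (default 0.95).
#' @param auto_flip Flip the score sign when AUC < 0.5 (default TRUE).
#' @return One-row data frame: cutpoint, sensitivity,
#'   one_minus_specificity, euclid_index, auc, ci_low, ci_high, p_value,
#'   sens_at_spec, flipped. A flipped marker's cutpoint is reported on the
#'   original score scale with direction "<= cutpoint".
#' @export
evaluate_marker <- function(scores, labels, spec_floor = 0.95,
                            auto_flip = TRUE,
                            ci_method = c("delong", "hanley")) {
  ci_method <- match.arg(ci_method)
  labels <- check_labeled_scores(scores, labels)
  a <- marker_auc(scores, labels, ci_method = ci_method)
  flipped <- FALSE
  work <- scores
  if (auto_flip && a$auc < 0.5) {
    flipped <- TRUE
    work <- -scores
    a <- marker_auc(work, labels, ci_method = ci_method)
  }
  curve <- roc_points(work, labels)
  opt <- optimal_cutpoint_euclid(curve)
  cut <- if (flipped) -opt$cutpoint else opt$cutpoint
  data.frame(cutpoint = cut, sensitivity = opt$se,
             one_minus_specificity = opt$one_minus_sp,
             euclid_index = opt$euclid_index,
             auc = a$auc, ci_low = a$ci_low, ci_high = a$ci_high,
             p_value = a$wilcoxon_p,
             sens_at_spec = sensitivity_at_specificity(curve, spec_floor),
             flipped = flipped, stringsAsFactors = FALSE, row.names = NULL)
}

#' Select candidate markers from the common DEPs
#'
#' Keeps common DEPs expressed in all groups (strictly less than 50% zeros
#' in every group) and splits them by the regulation direction shared
#' across all contrasts; direction-inconsistent proteins are excluded and
#' reported.
#'
#' @param common Accessions differentially expressed in every contrast
#'   (see [common_deps()]).
#' @param matrix Replicate-averaged protein x sample abundance matrix.
#' @param metadata Sample metadata.
#' @param results_by_contrast Named list of [call_deps()] result frames.
#' @return List: \code{up}, \code{down} (accession vectors) and
#'   \code{excluded} (data frame with a reason per dropped protein).
#' @export
candidate_filter <- function(common, matrix, metadata, results_by_contrast) {
  metadata <- as_sample_metadata(metadata)
  smap <- unique(metadata[, c("sample", "group")])
  groups <- smap$group[match(colnames(matrix), smap$sample)]
  up <- character(); down <- character()
  excluded <- data.frame(protein = character(), reason = character(),
                         stringsAsFactors = FALSE)
  for (p in common) {
    if (!p %in% rownames(matrix)) {
      excluded <- rbind(excluded, data.frame(protein = p,
                                             reason = "not in matrix"))
      next
    }
    v <- matrix[p, ]
    zero_frac <- vapply(unique(groups),
                        function(g) mean(v[groups == g] == 0), numeric(1))
    if (any(zero_frac >= 0.5)) {
      excluded <- rbind(excluded, data.frame(
        protein = p, reason = "expression zero in >=50% of a group"))
      next
    }
    dirs <- vapply(results_by_contrast, function(r) {
      r$regulation[match(p, r$protein)]
    }, character(1))
    if (all(dirs == "up")) {
      up <- c(up, p)
    } else if (all(dirs == "down")) {
      down <- c(down, p)
    } else {
      excluded <- rbind(excluded, data.frame(
        protein = p, reason = "inconsistent regulation direction"))
    }
  }
  if (nrow(excluded) > 0) {
    message(sprintf("candidate_filter: excluded %d protein(s)",
                    nrow(excluded)))
  }
  list(up = up, down = down, excluded = excluded)
}

#' Evaluate all single markers and all unordered pairs
#'
#' Case group vs all other samples pooled as controls. For k candidates
#' the report has k single rows plus k(k-1)/2 composite rows (e.g. 9
#' candidates give 36 pairs, 45 rows in total).
#'
#' @param candidates Accession vector of candidate markers.
#' @param matrix Replicate-averaged protein x sample abundance matrix.
#' @param metadata Sample metadata.
#' @param case_group The case group (default \code{"DVD"}).
#' @inheritParams evaluate_marker
#' @return Data frame with a \code{variable} column ("A" or "A+B") plus
#'   all [evaluate_marker()] columns, and a \code{kind} column
#'   (single/composite).
#' @export
evaluate_panel <- function(candidates, matrix, metadata,
                           case_group = "DVD", spec_floor = 0.95,
                           ci_method = c("delong", "hanley")) {
  ci_method <- match.arg(ci_method)
  metadata <- as_sample_metadata(metadata)
  smap <- unique(metadata[, c("sample", "group")])
  labels <- as.integer(
    smap$group[match(colnames(matrix), smap$sample)] == case_group)
  missing_p <- setdiff(candidates, rownames(matrix))
  if (length(missing_p) > 0) {
    um_validation_error(sprintf("candidates absent from matrix: %s",
                                paste(missing_p, collapse = ", ")))
  }
  rows <- list()
  for (p in candidates) {
    ev <- evaluate_marker(matrix[p, ], labels, spec_floor, TRUE, ci_method)
    rows[[length(rows) + 1]] <- cbind(
      data.frame(variable = p, kind = "single", stringsAsFactors = FALSE), ev)
  }
  if (length(candidates) >= 2) {
    pairs <- combn(candidates, 2)
    for (j in seq_len(ncol(pairs))) {
      pa <- pairs[1, j]; pb <- pairs[2, j]
      cmp <- fit_composite(matrix[pa, ], matrix[pb, ], labels)
      ev <- evaluate_marker(cmp$scores, labels, spec_floor, TRUE, ci_method)
      rows[[length(rows) + 1]] <- cbind(
        data.frame(variable = paste0(pa, "+", pb), kind = "composite",
                   stringsAsFactors = FALSE), ev)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(variable = character(), kind = character())
  }
  rownames(out) <- NULL
  out
}
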