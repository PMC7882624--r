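test_that("roc_points has endpoints, monotone Se, and lattice Se/Sp values", {
  scores <- c(5, 4, 3, 2, 1)
  labels <- c(1, 1, 0, 0, 0)
  cur <- roc_points(scores, labels)
  expect_equal(cur$se[1], 1); expect_equal(cur$sp[1], 0)
  expect_equal(cur$se[nrow(cur)], 0); expect_equal(cur$sp[nrow(cur)], 1)
  expect_true(all(diff(cur$se) <= 0))
  ## perfect separation passes through (Se=1, Sp=1)
  expect_true(any(cur$se == 1 & cur$sp == 1))

  ## attainable Se are multiples of 1/n_case, 1-Sp of 1/n_control
  set.seed(17)
  scores <- rnorm(30)
  labels <- rep(c(1, 0), c(12, 18))
  cur <- roc_points(scores, labels)
  expect_true(all(abs(cur$se * 12 - round(cur$se * 12)) < 1e-9))
  expect_true(all(abs((1 - cur$sp) * 18 - round((1 - cur$sp) * 18)) < 1e-9))

  expect_error(roc_points(1:3, c(1, 1, 1)), class = "um_validation_error")
  expect_error(roc_points(c(1, NA), c(1, 0)), class = "um_validation_error")
})

test_that("AUC equals exhaustive pair counting and trapezoid integration", {
  expect_equal(marker_auc(c(5, 6, 1, 2), c(1, 1, 0, 0))$auc, 1)
  expect_equal(marker_auc(c(1, 2, 3, 1, 2, 3), c(1, 1, 1, 0, 0, 0))$auc, 0.5)

  set.seed(23)
  for (i in 1:8) {
    cases <- sample(1:6, 8, replace = TRUE)   # ties likely
    controls <- sample(1:6, 8, replace = TRUE)
    scores <- c(cases, controls)
    labels <- rep(c(1, 0), each = 8)
    a <- marker_auc(scores, labels)
    expect_equal(a$auc, oracle_auc_pairs(cases, controls))
    ## reversing score sign maps AUC -> 1 - AUC
    expect_equal(marker_auc(-scores, labels)$auc, 1 - a$auc)
  }

  ## tie-free data: trapezoid area equals Mann-Whitney AUC to 1e-9
  for (i in 1:5) {
    scores <- rnorm(40)
    labels <- rep(c(1, 0), each = 20)
    a <- marker_auc(scores, labels)$auc
    expect_equal(oracle_auc_trapezoid(roc_points(scores, labels)), a,
                 tolerance = 1e-9)
  }
})

test_that("DeLong and Hanley CIs bracket the AUC; degenerate classes flagged", {
  set.seed(5)
  scores <- c(rnorm(20, 1), rnorm(30))
  labels <- rep(c(1, 0), c(20, 30))
  for (m in c("delong", "hanley")) {
    a <- marker_auc(scores, labels, ci_method = m)
    expect_lte(a$ci_low, a$auc); expect_gte(a$ci_high, a$auc)
    expect_gte(a$ci_low, 0); expect_lte(a$ci_high, 1)
  }
  one <- marker_auc(c(5, 1, 2, 3), c(1, 0, 0, 0))
  expect_true(is.na(one$ci_low))
  expect_false(attr(one, "ci_defined"))
  expect_true(is.finite(one$wilcoxon_p))
})

test_that("Euclidean cutpoint equals the exhaustive threshold scan", {
  ## perfect marker: E = 0
  cur <- roc_points(c(9, 8, 1, 2), c(1, 1, 0, 0))
  opt <- optimal_cutpoint_euclid(cur)
  expect_equal(opt$euclid_index, 0)
  expect_equal(opt$se, 1)
  expect_equal(opt$one_minus_sp, 0)

  set.seed(71)
  for (i in 1:6) {
    scores <- round(rnorm(30), 1)
    labels <- rbinom(30, 1, 0.4)
    if (sum(labels) == 0 || sum(labels) == 30) next
    cur <- roc_points(scores, labels)
    opt <- optimal_cutpoint_euclid(cur)
    ## brute force over every curve point, replicating the tie-break
    e <- (1 - cur$se)^2 + (1 - cur$sp)^2
    best_e <- min(e)
    expect_equal(opt$euclid_index, best_e)
    cand <- cur[e == best_e, ]
    cand <- cand[cand$se == max(cand$se), ]
    expect_equal(opt$cutpoint, min(cand$threshold))
  }
})

test_that("sensitivity at a specificity floor matches a brute-force scan", {
  perfect <- roc_points(c(9, 8, 1, 2), c(1, 1, 0, 0))
  expect_equal(sensitivity_at_specificity(perfect, 0.95), 1)
  flat <- roc_points(c(1, 1), c(1, 0))  # uninformative: all scores tied
  expect_equal(sensitivity_at_specificity(flat, 0.95), 0)

  set.seed(13)
  scores <- rnorm(60); labels <- rep(c(1, 0), 30)
  cur <- roc_points(scores, labels)
  for (floor in c(0.5, 0.9, 0.95)) {
    ok <- cur$sp >= floor
    expect_equal(sensitivity_at_specificity(cur, floor),
                 if (any(ok)) max(cur$se[ok]) else 0)
  }
})

test_that("euclid_index validates and reproduces by formula", {
  expect_equal(euclid_index(1, 1), 0)
  expect_equal(euclid_index(0.5, 0.5), 0.5)
  expect_error(euclid_index(1.2, 0.5), class = "um_validation_error")
})

test_that("composite of a marker with itself adds nothing", {
  set.seed(3)
  a <- c(rnorm(15, 1.2), rnorm(25))
  labels <- rep(c(1, 0), c(15, 25))
  cmp <- fit_composite(a, a + 0, labels)
  expect_true(all(cmp$scores > 0 & cmp$scores < 1))
  expect_equal(marker_auc(cmp$scores, labels)$auc,
               marker_auc(a, labels)$auc)
})

test_that("composite of two independent signals beats both singles", {
  set.seed(77)
  n <- 500
  labels <- rep(c(1, 0), each = n)
  a <- c(rnorm(n, 0.9), rnorm(n))
  b <- c(rnorm(n, 0.9), rnorm(n))
  cmp <- fit_composite(a, b, labels)
  auc_c <- marker_auc(cmp$scores, labels)$auc
  expect_gt(auc_c, marker_auc(a, labels)$auc)
  expect_gt(auc_c, marker_auc(b, labels)$auc)
})

test_that("perfect separation is flagged and scores stay in (0,1)", {
  labels <- rep(c(1, 0), each = 10)
  a <- c(rnorm(10, 50), rnorm(10))
  b <- rnorm(20)
  expect_warning(cmp <- fit_composite(a, b, labels), "separation")
  expect_true(cmp$separation)
  expect_true(all(cmp$scores > 0 & cmp$scores < 1))
  expect_error(fit_composite(rep(1, 20), b, labels),
               class = "um_validation_error")
})

test_that("evaluate_marker auto-flips anti-markers and reports a full row", {
  set.seed(41)
  scores <- c(rnorm(20, -1), rnorm(30))   # lower score = case
  labels <- rep(c(1, 0), c(20, 30))
  ev <- evaluate_marker(scores, labels)
  expect_true(ev$flipped)
  expect_gte(ev$auc, 0.5)
  expect_equal(ev$euclid_index,
               (1 - ev$sensitivity)^2 + ev$one_minus_specificity^2)
  noflip <- evaluate_marker(scores, labels, auto_flip = FALSE)
  expect_false(noflip$flipped)
  expect_equal(noflip$auc, 1 - ev$auc)
})

test_that("panel evaluation emits k singles plus k(k-1)/2 composites", {
  set.seed(55)
  md <- quad_metadata(5)
  samples <- unique(md$sample)
  groups <- md$group[match(samples, md$sample)]
  mat <- matrix(2^rnorm(4 * length(samples), 20, 1), 4,
                dimnames = list(c("M1", "M2", "M3", "M4"), samples))
  mat[, groups == "DVD"] <- mat[, groups == "DVD"] * 4
  p2 <- suppressWarnings(evaluate_panel(c("M1", "M2"), mat, md))
  expect_equal(nrow(p2), 3L)
  expect_equal(sum(p2$kind == "composite"), 1L)
  p1 <- evaluate_panel("M1", mat, md)
  expect_equal(nrow(p1), 1L)
  p4 <- suppressWarnings(evaluate_panel(rownames(mat), mat, md))
  expect_equal(nrow(p4), 4 + 6)
  expect_equal(p4$variable[p4$kind == "composite"][1], "M1+M2")
  expect_error(evaluate_panel("NOPE", mat, md),
               class = "um_validation_error")
})

test_that("candidate filter gates on per-group zero fractions and direction", {
  md <- quad_metadata(5)
  samples <- unique(md$sample)
  groups <- md$group[match(samples, md$sample)]
  set.seed(6)
  mat <- matrix(2^rnorm(3 * length(samples), 20, 0.5), 3,
                dimnames = list(c("GOOD", "ZEROY", "MIXED"), samples))
  ## ZEROY: 60% zeros in NC
  nc_cols <- which(groups == "NC")
  mat["ZEROY", nc_cols[1:3]] <- 0
  mk <- function(reg) lapply(1:3, function(i) {
    data.frame(protein = rownames(mat), regulation = reg[[i]],
               stringsAsFactors = FALSE)
  })
  res <- mk(list(c("up", "up", "up"), c("up", "up", "down"),
                 c("up", "up", "up")))
  suppressMessages(
    cand <- candidate_filter(rownames(mat), mat, md, res))
  expect_equal(cand$up, "GOOD")
  expect_true("ZEROY" %in% cand$excluded$protein)
  expect_true("MIXED" %in% cand$excluded$protein)

  res_dn <- mk(list(c("down", "up", "up"), c("down", "up", "down"),
                    c("down", "up", "up")))
  suppressMessages(
    cand2 <- candidate_filter("GOOD", mat, md, res_dn))
  expect_equal(cand2$down, "GOOD")
})
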