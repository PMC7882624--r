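## Four-group study simulator with planted ground truth.
##
## Model: per-protein baseline log2 abundance ~ N(baseline_log2_mean,
## baseline_log2_sd); per-sample biological noise N(0, within_group_log2_sd);
## per-replicate technical noise N(0, replicate_log2_sd). Planted DEPs shift
## the DVD group mean by a signed log2 fold change against all three other
## groups; group-specific proteins exist above detection only in their home
## group. Peptides split each replicate's protein intensity by fixed
## Dirichlet proportions drawn once per protein, so a Top-N average over
## peptides is a consistent (up to a protein-specific factor) estimator of
## protein abundance. Zeros arise from left-censoring at a detection
## threshold and from random dropout.

#' Build and validate a simulation configuration
#'
#' Defaults mirror a 69-subject four-group urinary proteomics study
#' (NC=21, T2DM=22, VD=14, DVD=12 subjects, two technical replicates) with
#' raw intensities around 1e8 (baseline log2 mean 27).
#'
#' @param group_sizes Named integer vector of subjects per group; names must
#'   be exactly NC, T2DM, VD, DVD; each at least 2.
#' @param n_proteins Number of simulated proteins.
#' @param peptide_range Integer range (min, max) of peptides per protein.
#' @param baseline_log2_mean,baseline_log2_sd Log2-scale population of
#'   per-protein baseline abundances.
#' @param within_group_log2_sd Biological (between-subject) log2 SD.
#' @param replicate_log2_sd Technical (between-replicate) log2 SD.
#' @param dep_fraction Fraction of proteins planted as DEPs (DVD-shifted).
#' @param dep_log2fc_range Magnitude range of planted |log2FC|; the lower
#'   bound must clear log2(1.20) so every planted DEP clears the
#'   fold-change dead zone (0.83, 1.20).
#' @param group_specific_fraction Fraction of proteins present in only one
#'   group.
#' @param detection_log2_threshold Log2 intensity below which a replicate
#'   measurement is censored to 0.
#' @param dropout_rate Probability that a (protein, sample, replicate)
#'   measurement is zeroed at random, on top of censoring.
#' @param marker_specs \code{NULL} or a data frame with columns
#'   \code{protein} (accession to assign) and \code{target_auc} in
#'   \[0.5, 1); each marker is planted as a DVD-upregulated protein whose
#'   single-marker AUC against the pooled other groups targets
#'   \code{target_auc}.
#' @param replicates Technical replicates per sample.
#' @param seed Integer seed governing all randomness.
#' @return A validated list of class \code{um_simulation_config}.
#' @export
simulation_config <- function(group_sizes = c(NC = 21, T2DM = 22, VD = 14, DVD = 12),
                              n_proteins = 2000,
                              peptide_range = c(2L, 8L),
                              baseline_log2_mean = 27,
                              baseline_log2_sd = 1.5,
                              within_group_log2_sd = 1.0,
                              replicate_log2_sd = 0.2,
                              dep_fraction = 0.10,
                              dep_log2fc_range = c(0.5, 3.0),
                              group_specific_fraction = 0.05,
                              detection_log2_threshold = 20,
                              dropout_rate = 0.05,
                              marker_specs = NULL,
                              replicates = 2L,
                              seed = 1L) {
  cfg <- list(group_sizes = group_sizes, n_proteins = as.integer(n_proteins),
              peptide_range = as.integer(peptide_range),
              baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd,
              within_group_log2_sd = within_group_log2_sd,
              replicate_log2_sd = replicate_log2_sd,
              dep_fraction = dep_fraction,
              dep_log2fc_range = dep_log2fc_range,
              group_specific_fraction = group_specific_fraction,
              detection_log2_threshold = detection_log2_threshold,
              dropout_rate = dropout_rate,
              marker_specs = marker_specs,
              replicates = as.integer(replicates),
              seed = as.integer(seed))
  validate_simulation_config(cfg)
}

validate_simulation_config <- function(cfg) {
  gs <- cfg$group_sizes
  if (!setequal(names(gs), UM_GROUPS)) {
    um_config_error("group_sizes must name exactly NC, T2DM, VD, DVD")
  }
  if (any(gs < 2)) um_config_error("every group needs at least 2 samples")
  if (cfg$n_proteins < 1) um_config_error("n_proteins must be positive")
  pr <- cfg$peptide_range
  if (length(pr) != 2 || pr[1] < 1 || pr[2] < pr[1]) {
    um_config_error("peptide_range must be an increasing positive pair")
  }
  if (cfg$baseline_log2_sd <= 0 || cfg$within_group_log2_sd <= 0) {
    um_config_error("log2 standard deviations must be positive")
  }
  if (cfg$replicate_log2_sd < 0) um_config_error("replicate_log2_sd < 0")
  if (cfg$dep_fraction < 0 || cfg$dep_fraction > 1) {
    um_config_error("dep_fraction must lie in [0, 1]")
  }
  dr <- cfg$dep_log2fc_range
  if (length(dr) != 2 || dr[2] < dr[1]) {
    um_config_error("dep_log2fc_range must be an increasing pair")
  }
  ## planted |log2FC| must clear the DEP dead zone (0.83, 1.20)
  if (dr[1] <= log2(1.20)) {
    um_config_error(sprintf(
      "dep_log2fc_range lower bound %.3f does not clear log2(1.20) = %.3f",
      dr[1], log2(1.20)))
  }
  if (cfg$group_specific_fraction < 0 || cfg$group_specific_fraction > 1) {
    um_config_error("group_specific_fraction must lie in [0, 1]")
  }
  if (cfg$dropout_rate < 0 || cfg$dropout_rate > 1) {
    um_config_error("dropout_rate must lie in [0, 1]")
  }
  if (!is.null(cfg$marker_specs)) {
    ms <- cfg$marker_specs
    if (!is.data.frame(ms) || !all(c("protein", "target_auc") %in% names(ms))) {
      um_config_error("marker_specs needs columns protein, target_auc")
    }
    if (any(ms$target_auc < 0.5 | ms$target_auc >= 1)) {
      um_config_error("target_auc must lie in [0.5, 1)")
    }
  }
  if (cfg$replicates < 1) um_config_error("replicates must be >= 1")
  class(cfg) <- "um_simulation_config"
  cfg
}

#' Log2 mean shift that yields a target AUC under the binormal model
#'
#' For equal-variance normal score distributions with common SD \code{sd},
#' an additive shift of \eqn{\Delta = \sqrt{2}\,\sigma\,\Phi^{-1}(AUC)}
#' between cases and controls yields the requested AUC.
#'
#' @param target_auc Target AUC in \[0.5, 1).
#' @param sd Common within-class standard deviation (log2 scale).
#' @return The log2 mean shift (nonnegative).
#' @export
plant_marker_shift <- function(target_auc, sd) {
  if (!is.numeric(target_auc) || any(target_auc < 0.5 | target_auc >= 1)) {
    um_validation_error("target_auc must lie in [0.5, 1)")
  }
  if (any(sd <= 0)) um_validation_error("sd must be positive")
  sqrt(2) * sd * qnorm(target_auc)
}

#' Simulate a four-group label-free proteomics study
#'
#' Generates a peptide-level intensity table, sample metadata and the
#' planted ground truth (DEPs with signed log2 fold changes, group-specific
#' proteins, diagnostic markers with target AUC). The run is fully
#' deterministic for a given \code{config$seed}.
#'
#' @param config A [simulation_config()].
#' @return A list with elements \code{peptides} (um_peptide_table),
#'   \code{metadata} (sample metadata data frame) and \code{truth} (list of
#'   data frames \code{dep}, \code{specific}, \code{markers}).
#' @export
simulate_study <- function(config) {
  cfg <- validate_simulation_config(unclass(config))
  set.seed(cfg$seed)

  gs <- cfg$group_sizes[UM_GROUPS]
  sample_ids <- unlist(lapply(UM_GROUPS, function(g) {
    sprintf("%s_%02d", g, seq_len(gs[[g]]))
  }), use.names = FALSE)
  sample_group <- rep(UM_GROUPS, times = gs)
  n_samp <- length(sample_ids)
  metadata <- data.frame(
    sample = rep(sample_ids, each = cfg$replicates),
    group = rep(sample_group, each = cfg$replicates),
    replicate = rep(seq_len(cfg$replicates), times = n_samp),
    stringsAsFactors = FALSE)

  np <- cfg$n_proteins
  proteins <- sprintf("PROT%05d", seq_len(np))

  ## --- role assignment (markers first so named accessions stick) -------
  n_marker <- if (is.null(cfg$marker_specs)) 0L else nrow(cfg$marker_specs)
  n_dep <- round(cfg$dep_fraction * np)
  n_spec <- round(cfg$group_specific_fraction * np)
  if (n_marker + n_dep + n_spec > np) {
    um_config_error("role fractions exceed the number of proteins")
  }
  idx <- sample.int(np, n_marker + n_dep + n_spec)
  marker_idx <- idx[seq_len(n_marker)]
  dep_idx <- idx[n_marker + seq_len(n_dep)]
  spec_idx <- idx[n_marker + n_dep + seq_len(n_spec)]
  if (n_marker > 0) proteins[marker_idx] <- as.character(cfg$marker_specs$protein)

  ## --- per-protein parameters -----------------------------------------
  baseline <- rnorm(np, cfg$baseline_log2_mean, cfg$baseline_log2_sd)
  delta <- numeric(np)  # DVD-vs-rest log2 shift
  if (n_dep > 0) {
    mag <- runif(n_dep, cfg$dep_log2fc_range[1], cfg$dep_log2fc_range[2])
    sgn <- sample(c(-1, 1), n_dep, replace = TRUE)
    delta[dep_idx] <- sgn * mag
  }
  if (n_marker > 0) {
    ## markers are DVD-upregulated DEPs by construction
    delta[marker_idx] <- plant_marker_shift(cfg$marker_specs$target_auc,
                                            cfg$within_group_log2_sd)
  }
  home_group <- rep(NA_character_, np)
  if (n_spec > 0) {
    home_group[spec_idx] <- sample(UM_GROUPS, n_spec, replace = TRUE)
  }

  ## --- protein x sample true log2 abundance ---------------------------
  mean_mat <- matrix(baseline, np, n_samp)
  is_dvd <- sample_group == "DVD"
  mean_mat[, is_dvd] <- mean_mat[, is_dvd] + delta
  log2_true <- mean_mat + matrix(rnorm(np * n_samp, 0, cfg$within_group_log2_sd),
                                 np, n_samp)
  ## group-specific proteins: absent (exact zero) outside the home group
  present <- matrix(TRUE, np, n_samp)
  if (n_spec > 0) {
    for (i in spec_idx) present[i, sample_group != home_group[i]] <- FALSE
  }

  ## --- peptide decomposition ------------------------------------------
  n_pep <- sample(seq(cfg$peptide_range[1], cfg$peptide_range[2]),
                  np, replace = TRUE)
  pep_protein_row <- rep(seq_len(np), n_pep)
  pep_id <- unlist(lapply(seq_len(np), function(i) {
    sprintf("%s_pep%02d", proteins[i], seq_len(n_pep[i]))
  }), use.names = FALSE)
  ## fixed flat-Dirichlet ionization proportions per protein
  g <- rgamma(length(pep_id), shape = 1)
  prop <- g / rep(tapply(g, pep_protein_row, sum), n_pep)

  ## --- replicate measurements -----------------------------------------
  reps <- seq_len(cfg$replicates)
  blocks <- vector("list", length(reps))
  for (r in reps) {
    log2_rep <- log2_true +
      matrix(rnorm(np * n_samp, 0, cfg$replicate_log2_sd), np, n_samp)
    raw <- 2^log2_rep
    raw[!present] <- 0
    raw[log2_rep < cfg$detection_log2_threshold] <- 0
    if (cfg$dropout_rate > 0) {
      drop <- matrix(runif(np * n_samp) < cfg$dropout_rate, np, n_samp)
      raw[drop] <- 0
    }
    ## expand to peptide level: intensity = protein raw * fixed proportion
    block <- data.table::data.table(
      protein = rep(proteins[pep_protein_row], times = n_samp),
      peptide = rep(pep_id, times = n_samp),
      sample = rep(sample_ids, each = length(pep_id)),
      replicate = r,
      intensity = as.vector(raw[pep_protein_row, ]) * rep(prop, times = n_samp))
    blocks[[r]] <- block
  }
  peptides <- data.table::rbindlist(blocks)
  data.table::setorder(peptides, protein, peptide, sample, replicate)
  peptides <- as.data.frame(peptides)
  class(peptides) <- c("um_peptide_table", "data.frame")

  truth <- list(
    baseline = data.frame(protein = proteins, baseline_log2 = baseline,
                          stringsAsFactors = FALSE),
    dep = data.frame(protein = proteins[c(marker_idx, dep_idx)],
                     true_log2fc = delta[c(marker_idx, dep_idx)],
                     is_marker = rep(c(TRUE, FALSE), c(n_marker, n_dep)),
                     stringsAsFactors = FALSE),
    specific = data.frame(protein = proteins[spec_idx],
                          group = home_group[spec_idx],
                          stringsAsFactors = FALSE),
    markers = if (n_marker > 0) {
      data.frame(protein = proteins[marker_idx],
                 target_auc = cfg$marker_specs$target_auc,
                 planted_log2_shift = delta[marker_idx],
                 stringsAsFactors = FALSE)
    } else {
      data.frame(protein = character(), target_auc = numeric(),
                 planted_log2_shift = numeric(), stringsAsFactors = FALSE)
    })

  list(peptides = peptides, metadata = as_sample_metadata(metadata),
       truth = truth)
}
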