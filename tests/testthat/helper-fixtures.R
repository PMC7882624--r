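## Fixture builders and independent oracles used across the suite.
## Oracles are deliberately naive (enumeration / direct definitions) and
## share no code with the implementation paths they check.

make_peptides <- function(protein, peptide, sample, replicate, intensity) {
  data.frame(protein = protein, peptide = peptide, sample = sample,
             replicate = replicate, intensity = intensity,
             stringsAsFactors = FALSE)
}

## one protein, one sample/replicate, given peptide intensities
one_protein_peptides <- function(intensities, protein = "P1",
                                 sample = "S1", replicate = 1L) {
  make_peptides(protein, sprintf("pep%02d", seq_along(intensities)),
                sample, replicate, intensities)
}

tiny_metadata <- function(samples, groups, replicates = 1L) {
  do.call(rbind, lapply(seq_along(samples), function(i) {
    data.frame(sample = samples[i], group = groups[i],
               replicate = seq_len(replicates), stringsAsFactors = FALSE)
  }))
}

## four-group metadata with n samples per group, single replicate
quad_metadata <- function(n = 4L) {
  groups <- c("NC", "T2DM", "VD", "DVD")
  tiny_metadata(unlist(lapply(groups, function(g) paste0(g, seq_len(n)))),
                rep(groups, each = n))
}

## --- oracles ----------------------------------------------------------

## AUC by exhaustive pair enumeration: (concordant + ties/2) / (n1*n0)
oracle_auc_pairs <- function(cases, controls) {
  total <- 0
  for (x in cases) for (y in controls) {
    total <- total + if (x > y) 1 else if (x == y) 0.5 else 0
  }
  total / (length(cases) * length(controls))
}

## same definition, vectorized for Monte-Carlo-sized inputs
oracle_auc_pairs_fast <- function(cases, controls) {
  mean(outer(cases, controls, ">") + 0.5 * outer(cases, controls, "=="))
}

## trapezoid area under the empirical ROC polygon
oracle_auc_trapezoid <- function(curve) {
  fpr <- 1 - curve$sp
  ord <- order(fpr, curve$se)
  x <- fpr[ord]; y <- curve$se[ord]
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

## Top-N by explicit sort-and-average of nonzero intensities
oracle_top_n <- function(intensities, top_n) {
  v <- sort(intensities[intensities > 0], decreasing = TRUE)
  if (length(v) == 0) return(0)
  mean(v[seq_len(min(top_n, length(v)))])
}

## hypergeometric upper-tail P(X >= k) by direct summation
oracle_hyper_tail <- function(k, K, n, N) {
  upper <- min(K, n)
  if (k > upper) return(0)
  sum(vapply(k:upper, function(i) {
    choose(K, i) * choose(N - K, n - i) / choose(N, n)
  }, numeric(1)))
}

## BH step-up straight from the definition
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, m / i * p[ord[i]])
    adj[ord[i]] <- min(running, 1)
  }
  adj
}

## BY = BH scaled by the harmonic sum, capped at 1
oracle_by <- function(p) {
  pmin(oracle_bh(p) * sum(1 / seq_along(p)), 1)
}

## Holm step-down straight from the definition
oracle_holm <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in 1:m) {
    running <- max(running, (m - i + 1) * p[ord[i]])
    adj[ord[i]] <- min(running, 1)
  }
  adj
}
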