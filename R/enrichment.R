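## Over-representation analysis of a study protein set against a
## user-supplied term -> protein annotation map. The background population
## is always an explicit input — there is no silent default.

#' Read a term -> protein annotation map
#'
#' Two-column TSV (term_id, protein); an optional names file maps term_id
#' to a readable term_name.
#'
#' @param path Path to the 2-column annotation TSV.
#' @param names_path Optional path to a 2-column (term_id, term_name) TSV.
#' @return Named list of accession vectors, with a \code{term_names}
#'   attribute when names were supplied.
#' @export
read_annotation_map <- function(path, names_path = NULL) {
  um_check_file(path)
  raw <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(raw) < 2) um_schema_error("annotation map needs 2 columns")
  anns <- split(as.character(raw[[2]]), as.character(raw[[1]]))
  anns <- lapply(anns, unique)
  if (!is.null(names_path)) {
    um_check_file(names_path)
    nm <- read.delim(names_path, stringsAsFactors = FALSE)
    attr(anns, "term_names") <- setNames(as.character(nm[[2]]),
                                         as.character(nm[[1]]))
  }
  anns
}

#' Fisher's exact over-representation test
#'
#' One-sided (enrichment) Fisher exact p-value per term from the 2x2 table
#' of study-set membership vs term membership, i.e. the hypergeometric
#' upper tail P(X >= k). Terms with no population hit are skipped.
#'
#' @param study Accession vector (the DEP set); must be a subset of
#'   \code{population}.
#' @param population Background accession vector. Required — the choice of
#'   background changes every p-value and is never defaulted.
#' @param annotations Named list term_id -> accession vector (see
#'   [read_annotation_map()]).
#' @param method Multiplicity correction (default \code{"bh"}).
#' @return Data frame: term_id, term_name, k, K, n, N, p_raw, p_adjusted,
#'   method, sorted by p_raw.
#' @export
fisher_ora <- function(study, population, annotations,
                       method = c("bh", "by", "holm", "bonferroni")) {
  method <- match.arg(method)
  study <- unique(as.character(study))
  population <- unique(as.character(population))
  if (length(population) == 0) um_validation_error("empty population")
  outside <- setdiff(study, population)
  if (length(outside) > 0) {
    um_validation_error(sprintf(
      "study proteins outside the population: %s",
      paste(head(outside, 5), collapse = ", ")))
  }
  N <- length(population)
  n <- length(study)
  term_names <- attr(annotations, "term_names")
  rows <- lapply(names(annotations), function(t) {
    hits <- intersect(annotations[[t]], population)
    K <- length(hits)
    if (K == 0) return(NULL)
    k <- length(intersect(study, hits))
    ## hypergeometric upper tail: P(X >= k)
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = t,
               term_name = if (!is.null(term_names) && t %in% names(term_names))
                 term_names[[t]] else t,
               k = k, K = K, n = n, N = N, p_raw = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(term_id = character(), term_name = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p_raw = numeric(),
                      p_adjusted = numeric(), method = character()))
  }
  out$p_adjusted <- adjust_p(out$p_raw, method)
  out$method <- method
  out <- out[order(out$p_raw), ]
  rownames(out) <- NULL
  out
}

#' Multiple-testing correction
#'
#' Bonferroni, Holm, Benjamini-Hochberg (step-up) or
#' Benjamini-Yekutieli; output order matches input order, values capped
#' at 1.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @param method One of \code{"bonferroni"}, \code{"holm"}, \code{"bh"},
#'   \code{"by"}.
#' @return Adjusted p-values in input order.
#' @export
adjust_p <- function(p_values, method = c("bh", "by", "holm", "bonferroni")) {
  if (!is.character(method) || length(method) < 1 ||
      !method[1] %in% c("bh", "by", "holm", "bonferroni")) {
    um_config_error("method must be one of bonferroni, holm, bh, by")
  }
  method <- method[1]
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    um_validation_error("p-values must lie in [0, 1]")
  }
  p.adjust(p_values,
           method = c(bh = "BH", by = "BY", holm = "holm",
                      bonferroni = "bonferroni")[[method]])
}
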