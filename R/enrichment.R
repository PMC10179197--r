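#' Permutation configuration
#'
#' @param n_permutations number of random same-size sample subsets drawn for
#'   the null (default 10000). At least 100 are required for p-value
#'   reporting.
#' @param seed integer seed; expanded to order-invariant per-(gene, tissue)
#'   substreams inside [run_enrichment()].
#' @param weight_exponent non-negative exponent on the ranked statistic in
#'   the hit increments; 1 (default) weights hits by the share magnitude, 0
#'   gives the classic unweighted Kolmogorov-Smirnov statistic.
#' @param min_set_size smallest tissue sample-set tested (default 3).
#' @param fdr_threshold q-value threshold for the significance flag
#'   (default 0.01).
#' @param exhaustive `"auto"` enumerates all subsets when `choose(N, k)` is
#'   at most `n_permutations`; `TRUE` forces enumeration (error if
#'   infeasible); `FALSE` always samples.
#' @return A `perm_config` list.
#' @export
perm_config <- function(n_permutations = 10000, seed = 1L,
                        weight_exponent = 1, min_set_size = 3,
                        fdr_threshold = 0.01, exhaustive = "auto") {
  if (n_permutations < 100)
    stop("n_permutations must be at least 100 for p-value reporting")
  if (weight_exponent < 0) stop("weight_exponent must be non-negative")
  structure(list(n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed),
                 weight_exponent = weight_exponent,
                 min_set_size = as.integer(min_set_size),
                 fdr_threshold = fdr_threshold,
                 exhaustive = exhaustive),
            class = "perm_config")
}

#' Rank samples by a gene's share
#'
#' @param shares a `share_matrix` (or any genes x samples matrix).
#' @param gene gene symbol present in the matrix.
#' @return A `ranked_samples` data frame with columns `sample`, `statistic`,
#'   sorted by statistic descending, ties broken by ascending sample
#'   identifier.
#' @export
rank_samples <- function(shares, gene) {
  if (!gene %in% rownames(shares))
    stop("gene '", gene, "' not present in the share matrix")
  stat <- shares[gene, ]
  if (any(!is.finite(stat))) stop("non-finite statistic for gene ", gene)
  ord <- order(-stat, colnames(shares), method = "radix")
  out <- data.frame(sample = colnames(shares)[ord],
                    statistic = unname(stat[ord]),
                    stringsAsFactors = FALSE)
  class(out) <- c("ranked_samples", "data.frame")
  out
}

#' Weighted running-sum enrichment score
#'
#' Walks down the ranked sample list; a hit (sample in the query set) at
#' position i adds `|statistic_i|^w / W` where `W` is the summed hit weight,
#' a miss subtracts `1/(N - k)`. The enrichment score is the running-sum
#' value of maximal absolute deviation from zero (signed); when the positive
#' and negative extremes tie in magnitude the positive one is taken. If all
#' hit statistics are zero the hits contribute uniform `1/k` increments.
#'
#' @param ranked a `ranked_samples` data frame.
#' @param set character vector of sample identifiers (the tissue's samples);
#'   must be a non-empty proper subset of the ranking.
#' @param weight_exponent non-negative weight exponent.
#' @return List with `es` (scalar in \[-1, 1\]) and `running` (length-N
#'   running-sum profile, ending at 0).
#' @export
enrichment_score <- function(ranked, set, weight_exponent = 1) {
  n <- nrow(ranked)
  hits <- ranked$sample %in% set
  k <- sum(hits)
  if (k != length(unique(set)))
    stop("set member(s) not present in the ranking")
  if (k == 0 || k == n)
    stop("set must be a non-empty proper subset of the ranked samples")
  w <- abs(ranked$statistic)^weight_exponent
  w[!hits] <- 0
  W <- sum(w)
  if (W == 0) {
    w[hits] <- 1
    W <- k
  }
  incr <- w / W
  incr[!hits] <- -1 / (n - k)
  running <- cumsum(incr)
  top <- max(running, 0)
  bottom <- min(running, 0)
  # tie between extremes resolved to the positive one; the comparison uses a
  # small tolerance so analytically exact ties are not flipped by summation
  # order
  es <- if (top >= -bottom - 1e-12) top else bottom
  list(es = es, running = running)
}

#' Permutation null for the enrichment score
#'
#' Draws uniformly random sample subsets of the given size (the ranked
#' statistic is held fixed, mirroring gene-set permutation in GSEA-family
#' tools) and records each subset's enrichment score. When `choose(N, k)` is
#' small the null is enumerated exhaustively instead.
#'
#' @param ranked a `ranked_samples` data frame.
#' @param set_size subset size (1 to N-1).
#' @param config a [perm_config()].
#' @return Numeric vector of null enrichment scores, with attribute
#'   `exhaustive` (logical).
#' @export
permutation_null <- function(ranked, set_size, config = perm_config()) {
  n <- nrow(ranked)
  if (set_size < 1 || set_size >= n)
    stop("set_size must be between 1 and N-1")
  n_subsets <- suppressWarnings(choose(n, set_size))
  use_exhaustive <- switch(as.character(config$exhaustive),
    "auto" = is.finite(n_subsets) && n_subsets <= config$n_permutations,
    "TRUE" = TRUE, "FALSE" = FALSE,
    stop("exhaustive must be 'auto', TRUE or FALSE"))
  stats_desc <- ranked$statistic
  if (use_exhaustive) {
    if (!is.finite(n_subsets) || n_subsets > 1e6)
      stop("exhaustive enumeration infeasible for choose(", n, ", ",
           set_size, ")")
    subsets <- combn(n, set_size)
    null_es <- apply(subsets, 2, function(pos)
      .calc_es_cpp(stats_desc, as.integer(pos), config$weight_exponent))
  } else {
    null_es <- .perm_null_cpp(stats_desc, as.integer(set_size),
                              config$n_permutations, config$weight_exponent)
  }
  attr(null_es, "exhaustive") <- use_exhaustive
  null_es
}

#' Normalized enrichment score and permutation p-value
#'
#' `nes = es / mean(|null es|)` over null values with the same sign as `es`.
#' For a sampled null, `pvalue = (1 + #same-sign null with |null| >= |es|) /
#' (1 + #same-sign null)` (the Monte-Carlo +1 correction, so p = 0 is
#' impossible). For an exhaustively enumerated null the p-value is the exact
#' probability `m / #same-sign`; when the observed set belongs to the
#' enumerated family its own score is in the null, so `m >= 1` (it is floored
#' at 1 regardless). `es = 0` yields `nes = 0`, `p = 1`. With no same-sign
#' null values the p-value floors at `1 / (1 + n_null)` and the NES is `NA`
#' (flagged undefined).
#'
#' @param es observed enrichment score.
#' @param null_es numeric vector of null scores, e.g. from
#'   [permutation_null()] (whose `exhaustive` attribute is honoured).
#' @param exhaustive whether `null_es` is a complete enumeration.
#' @return List with `nes`, `pvalue` and `n_same_sign` (the same-sign null
#'   count, which sets the p-value resolution).
#' @export
nes_and_pvalue <- function(es, null_es,
                           exhaustive = isTRUE(attr(null_es, "exhaustive"))) {
  if (length(null_es) == 0) stop("null distribution is empty")
  same_sign <- if (es > 0) null_es[null_es > 0] else
               if (es < 0) null_es[null_es < 0] else numeric(0)
  if (es == 0)
    return(list(nes = 0, pvalue = 1, n_same_sign = length(same_sign)))
  if (length(same_sign) == 0)
    return(list(nes = NA_real_, pvalue = 1 / (1 + length(null_es)),
                n_same_sign = 0L))
  m <- sum(abs(same_sign) >= abs(es))
  pvalue <- if (exhaustive) max(m, 1) / length(same_sign)
            else (1 + m) / (1 + length(same_sign))
  nes <- es / mean(abs(same_sign))
  list(nes = nes, pvalue = pvalue, n_same_sign = length(same_sign))
}

#' Benjamini-Hochberg adjustment across tissue labels
#'
#' Adjusts one gene's permutation p-values for the number of sample groups
#' (tissue labels) tested.
#'
#' @param records data frame with one row per tissue for a single gene,
#'   containing a `pvalue` column.
#' @return The records with a `qvalue` column added.
#' @export
fdr_over_tissues <- function(records) {
  records$qvalue <- p.adjust(records$pvalue, method = "BH")
  records
}

#' Tissue enrichment along share-ranked samples
#'
#' For every member gene of the share matrix and every tissue label with at
#' least `min_set_size` retained samples (and at least one sample outside
#' the tissue): ranks the retained samples by the gene's share, scores the
#' tissue's samples with the running-sum statistic, draws the permutation
#' null, and reports ES, NES, the permutation p-value and the BH q-value
#' across that gene's tissue family, plus a significance flag at
#' `qvalue < fdr_threshold`.
#'
#' Random substreams are derived per (gene, tissue) from `config$seed`, so
#' results do not depend on iteration order.
#'
#' @param shares a `share_matrix`.
#' @param annotation named character vector (sample -> tissue).
#' @param config a [perm_config()].
#' @param group optional group name recorded in the output.
#' @return Data frame with columns `group`, `gene`, `tissue`, `set_size`,
#'   `es`, `nes`, `pvalue`, `n_null_same_sign` (the same-sign null count
#'   that sets each p-value's resolution), `qvalue`, `significant`.
#' @export
run_enrichment <- function(shares, annotation, config = perm_config(),
                           group = NULL) {
  samples <- colnames(shares)
  unannotated <- setdiff(samples, names(annotation))
  if (length(unannotated) > 0)
    stop("retained sample(s) lack tissue annotation: ",
         paste(unannotated, collapse = ", "))
  tissues <- annotation[samples]
  sizes <- table(tissues)
  n <- length(samples)
  testable <- names(sizes)[sizes >= config$min_set_size & sizes < n]
  skipped <- setdiff(names(sizes), testable)
  if (length(skipped) > 0)
    warning("tissue(s) skipped (fewer than ", config$min_set_size,
            " retained samples or spanning all samples): ",
            paste(skipped, collapse = ", "))
  if (length(testable) == 0) {
    warning("no testable tissue groups; empty enrichment output")
    return(data.frame(group = character(0), gene = character(0),
                      tissue = character(0), set_size = integer(0),
                      es = numeric(0), nes = numeric(0),
                      pvalue = numeric(0), n_null_same_sign = integer(0),
                      qvalue = numeric(0), significant = logical(0)))
  }
  group_label <- group %||% attr(shares, "group") %||% NA_character_
  res <- vector("list", nrow(shares) * length(testable))
  idx <- 0L
  for (gene in rownames(shares)) {
    ranked <- rank_samples(shares, gene)
    gene_rows <- vector("list", length(testable))
    for (j in seq_along(testable)) {
      tt <- testable[j]
      set <- samples[tissues == tt]
      sc <- enrichment_score(ranked, set, config$weight_exponent)
      set.seed(derive_seed(config$seed, gene, tt))
      null_es <- permutation_null(ranked, length(set), config)
      np <- nes_and_pvalue(sc$es, null_es)
      gene_rows[[j]] <- data.frame(
        group = group_label, gene = gene, tissue = tt,
        set_size = length(set), es = sc$es, nes = np$nes,
        pvalue = np$pvalue, n_null_same_sign = np$n_same_sign,
        stringsAsFactors = FALSE)
    }
    gene_df <- fdr_over_tissues(do.call(rbind, gene_rows))
    idx <- idx + 1L
    res[[idx]] <- gene_df
  }
  out <- do.call(rbind, res[seq_len(idx)])
  out$significant <- out$qvalue < config$fdr_threshold
  rownames(out) <- NULL
  out
}
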