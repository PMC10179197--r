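#' Weighted total expression of a gene set per tissue
#'
#' Each member gene's values are normalized to the gene's mean across all
#' samples in the matrix, the normalized values are summed over members
#' within each sample, and the per-sample sums are aggregated per tissue
#' (mean by default). Genes with zero mean across samples carry no weight
#' and are excluded with a warning.
#'
#' @param mat abundance matrix.
#' @param members member gene symbols.
#' @param annotation named character vector (sample -> tissue).
#' @param set_name label recorded in the output.
#' @param tissue_statistic `"mean"` (default) or `"median"` aggregation of
#'   per-sample totals within a tissue.
#' @return Data frame of class `weighted_totals` with columns `tissue`,
#'   `set_name`, `weighted_total`, `n_samples`; attribute `per_sample` keeps
#'   the per-sample totals.
#' @export
weighted_total <- function(mat, members, annotation, set_name = "set",
                           tissue_statistic = c("mean", "median")) {
  tissue_statistic <- match.arg(tissue_statistic)
  matched <- intersect(members, rownames(mat))
  if (length(matched) == 0) stop("no member genes present in the matrix")
  sub <- mat[matched, , drop = FALSE]
  gene_means <- rowMeans(sub)
  zero <- gene_means == 0
  if (all(zero)) stop("all member genes have zero mean expression")
  if (any(zero)) {
    warning("member gene(s) with zero mean excluded: ",
            paste(matched[zero], collapse = ", "))
    sub <- sub[!zero, , drop = FALSE]
    gene_means <- gene_means[!zero]
  }
  per_sample <- colSums(sub / gene_means)
  unannotated <- setdiff(names(per_sample), names(annotation))
  if (length(unannotated) > 0)
    stop("sample(s) lack tissue annotation: ",
         paste(unannotated, collapse = ", "))
  tissues <- annotation[names(per_sample)]
  fun <- if (tissue_statistic == "median") median else mean
  out <- do.call(rbind, lapply(sort(unique(tissues)), function(tt) {
    vals <- per_sample[tissues == tt]
    data.frame(tissue = tt, set_name = set_name,
               weighted_total = fun(vals), n_samples = length(vals),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "per_sample") <- per_sample
  class(out) <- c("weighted_totals", "data.frame")
  out
}

#' Pearson correlation of two weighted-total profiles over shared tissues
#'
#' @param a,b `weighted_totals` data frames (e.g. a gene set and the
#'   ribosomal-protein reference).
#' @return List with `pearson_r`, `n_tissues`, `tissues`, `set_a`, `set_b`.
#'   Fewer than 3 shared tissues, or zero variance in either profile, is an
#'   error.
#' @export
correlate_with_reference <- function(a, b) {
  shared <- intersect(a$tissue, b$tissue)
  if (length(shared) < 3)
    stop("need at least 3 shared tissues, found ", length(shared))
  va <- a$weighted_total[match(shared, a$tissue)]
  vb <- b$weighted_total[match(shared, b$tissue)]
  if (sd(va) == 0 || sd(vb) == 0)
    stop("zero variance in a weighted-total profile")
  list(pearson_r = cor(va, vb, method = "pearson"),
       n_tissues = length(shared), tissues = shared,
       set_a = a$set_name[1], set_b = b$set_name[1])
}

#' Bundled ribosomal-protein gene list
#'
#' The standard human cytoplasmic ribosomal-protein gene symbols (RPS*/RPL*
#' families plus FAU and UBA52), used as the reference set for weighted-total
#' correlations. The list is a plain-text input and can be replaced.
#'
#' @param path optional path to a one-column TSV with header `symbol`.
#' @return Character vector of gene symbols.
#' @export
ribosomal_genes <- function(path = NULL) {
  if (is.null(path)) path <- bundled_path("ribosomal_genes.tsv")
  read.delim(path, stringsAsFactors = FALSE)$symbol
}
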