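#' Per-sample total expression of a gene group
#'
#' Sums abundance over the group's matched member genes in each sample.
#' Members absent from the matrix contribute zero (they should already have
#' been reported by [resolve_symbols()]).
#'
#' @param mat abundance matrix (genes x samples).
#' @param members character vector of member gene symbols.
#' @param group optional group name, used in error messages and carried as an
#'   attribute.
#' @return Named numeric vector of per-sample totals with attributes `group`
#'   and `members` (the matched members).
#' @export
group_totals <- function(mat, members, group = NULL) {
  matched <- intersect(members, rownames(mat))
  if (length(matched) == 0)
    stop("no member genes of group '", group %||% "(unnamed)",
         "' are present in the matrix")
  totals <- colSums(mat[matched, , drop = FALSE])
  attr(totals, "group") <- group
  attr(totals, "members") <- matched
  totals
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Half-mean sample exclusion
#'
#' Excludes samples whose group total expression is strictly less than half
#' the mean total across all samples. The threshold is computed once, in a
#' single pass.
#'
#' @param totals named numeric vector of per-sample group totals.
#' @return Character vector of retained sample identifiers.
#' @export
filter_low_total_samples <- function(totals) {
  if (length(totals) == 0) stop("no samples")
  m <- mean(totals)
  if (m == 0)
    stop("group '", attr(totals, "group") %||% "(unnamed)",
         "' has zero total expression in every sample")
  names(totals)[totals >= 0.5 * m]
}

#' Within-group share matrix
#'
#' For each retained sample, each member gene's share of the group's total
#' expression: `share(g, s) = abundance(g, s) / total(s)`. Columns sum to 1.
#' Shares are computed on the linear abundance scale.
#'
#' @param mat abundance matrix.
#' @param members member gene symbols (matched against the matrix).
#' @param retained retained sample identifiers (from
#'   [filter_low_total_samples()]); `NULL` keeps all samples with positive
#'   total.
#' @param group optional group name attribute.
#' @return A `share_matrix`: members x retained samples, with attributes
#'   `group`, `normalized = TRUE` and `statistic_label`.
#' @export
compute_shares <- function(mat, members, retained = NULL, group = NULL) {
  totals <- group_totals(mat, members, group = group)
  if (is.null(retained)) retained <- names(totals)[totals > 0]
  missing_samples <- setdiff(retained, names(totals))
  if (length(missing_samples) > 0)
    stop("retained sample(s) absent from matrix: ",
         paste(missing_samples, collapse = ", "))
  tot <- totals[retained]
  if (any(tot == 0))
    stop("retained sample(s) with zero group total: ",
         paste(retained[tot == 0], collapse = ", "))
  matched <- attr(totals, "members")
  shares <- sweep(mat[matched, retained, drop = FALSE], 2, tot, "/")
  structure(shares, group = group, normalized = TRUE,
            class = c("share_matrix", class(shares)))
}

#' Shares against an alternative denominator
#'
#' Normalizes numerator genes by the total expression of a *different* gene
#' set (e.g. eEF1A paralogs against the ribosomal-protein total). Columns
#' need not sum to 1; the result is flagged `normalized = FALSE`.
#'
#' @param mat abundance matrix.
#' @param numerator genes whose relative abundance is reported.
#' @param denominator genes whose summed expression is the denominator.
#' @param retained retained samples (`NULL` keeps samples with positive
#'   denominator total).
#' @param group optional label attribute.
#' @return A `share_matrix` with `normalized = FALSE`.
#' @export
share_to_alt_denominator <- function(mat, numerator, denominator,
                                     retained = NULL, group = NULL) {
  den <- group_totals(mat, denominator, group = group)
  if (is.null(retained)) retained <- names(den)[den > 0]
  tot <- den[retained]
  if (any(tot == 0))
    stop("retained sample(s) with zero denominator total: ",
         paste(retained[tot == 0], collapse = ", "))
  matched <- intersect(numerator, rownames(mat))
  if (length(matched) == 0) stop("no numerator genes present in the matrix")
  shares <- sweep(mat[matched, retained, drop = FALSE], 2, tot, "/")
  structure(shares, group = group, normalized = FALSE,
            class = c("share_matrix", class(shares)))
}

#' Per-tissue summary of shares
#'
#' Summarizes each gene's shares over the retained samples of each tissue.
#' The default central-tendency statistic is the median (robust to outlier
#' samples); the mean is also exposed.
#'
#' @param shares a `share_matrix`.
#' @param annotation named character vector (sample -> tissue); every
#'   retained sample must be annotated.
#' @param statistic `"median"` or `"mean"`.
#' @return Data frame with columns `gene`, `tissue`, `summary`, `n_samples`.
#'   Tissues present in the annotation but without retained samples are
#'   omitted with a warning.
#' @export
tissue_summary <- function(shares, annotation, statistic = c("median", "mean")) {
  statistic <- match.arg(statistic)
  samples <- colnames(shares)
  unannotated <- setdiff(samples, names(annotation))
  if (length(unannotated) > 0)
    stop("retained sample(s) lack tissue annotation: ",
         paste(unannotated, collapse = ", "))
  tissues <- annotation[samples]
  absent <- setdiff(unique(annotation), tissues)
  if (length(absent) > 0)
    warning("tissue(s) with zero retained samples omitted: ",
            paste(absent, collapse = ", "))
  fun <- if (statistic == "median") median else mean
  out <- do.call(rbind, lapply(sort(unique(tissues)), function(tt) {
    cols <- samples[tissues == tt]
    data.frame(gene = rownames(shares), tissue = tt,
               summary = apply(shares[, cols, drop = FALSE], 1, fun),
               n_samples = length(cols), stringsAsFactors = FALSE,
               row.names = NULL)
  }))
  out
}

#' One-call group share computation
#'
#' Convenience wrapper chaining [group_totals()], the half-mean
#' [filter_low_total_samples()] exclusion and [compute_shares()].
#'
#' @inheritParams compute_shares
#' @return A `share_matrix` over the retained samples, with attribute
#'   `excluded` listing the excluded sample identifiers.
#' @export
group_share_matrix <- function(mat, members, group = NULL) {
  totals <- group_totals(mat, members, group = group)
  retained <- filter_low_total_samples(totals)
  shares <- compute_shares(mat, members, retained = retained, group = group)
  attr(shares, "excluded") <- setdiff(names(totals), retained)
  shares
}
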