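#' Read a gene-level expression matrix (GCT 1.2 or plain TSV)
#'
#' GCT files carry a `#1.2` version line, a dimension line and `Name` /
#' `Description` columns; gene symbols are taken from `Description` when it
#' looks like a symbol (GTEx stores Ensembl IDs in `Name`), otherwise from
#' `Name`. A plain TSV has genes in the first column and one column per
#' sample. Duplicate gene rows are summed, mirroring the transcript-level
#' aggregation rule.
#'
#' @param path file path.
#' @param unit_label unit attached to the returned matrix.
#' @return An abundance matrix (genes x samples) with a `unit_label`
#'   attribute.
#' @export
read_gct <- function(path, unit_label = "TPM") {
  if (!file.exists(path)) stop("expression file not found: ", path)
  first <- readLines(path, n = 1L)
  if (startsWith(first, "#1.")) {
    lines <- readLines(path)
    if (length(lines) < 3) stop("malformed GCT: fewer than 3 lines")
    dims <- suppressWarnings(as.integer(strsplit(lines[2], "\t")[[1]]))
    if (length(dims) < 2 || any(is.na(dims[1:2])))
      stop("malformed GCT dimension line")
    header <- strsplit(lines[3], "\t")[[1]]
    n_samples <- length(header) - 2L
    if (n_samples != dims[2])
      stop(sprintf("GCT header declares %d samples but dimension line says %d",
                   n_samples, dims[2]))
    body <- lines[-(1:3)]
    body <- body[nzchar(body)]
    if (length(body) != dims[1])
      stop(sprintf("GCT has %d data rows but dimension line says %d",
                   length(body), dims[1]))
    fields <- strsplit(body, "\t")
    nf <- lengths(fields)
    if (any(nf != length(header)))
      stop("GCT row field count does not match header (first bad row: ",
           which(nf != length(header))[1], ")")
    name <- vapply(fields, `[[`, character(1), 1L)
    desc <- vapply(fields, `[[`, character(1), 2L)
    # Description is used when it looks like a gene symbol rather than a
    # versioned accession.
    looks_symbol <- nzchar(desc) & !grepl("^ENS[A-Z]*G\\d+", desc)
    gene <- ifelse(looks_symbol, desc, name)
    vals <- matrix(
      suppressWarnings(as.numeric(unlist(lapply(fields, `[`, -(1:2))))),
      nrow = length(body), ncol = n_samples, byrow = TRUE)
    if (any(is.na(vals))) stop("non-numeric value in GCT body")
    colnames(vals) <- header[-(1:2)]
    rownames(vals) <- gene
  } else {
    df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    gene <- as.character(df[[1]])
    vals <- as.matrix(df[, -1, drop = FALSE])
    rownames(vals) <- gene
  }
  if (any(!is.finite(vals))) stop("expression values must be finite")
  if (any(vals < 0)) stop("negative expression value in ", path)
  vals <- sum_duplicate_rows(vals)
  abundance_matrix(vals, unit_label = unit_label)
}

# Sum rows sharing a gene identifier (duplicate gene rows, e.g. collapsed
# transcripts distributed as separate rows).
sum_duplicate_rows <- function(vals) {
  if (!anyDuplicated(rownames(vals))) return(vals)
  agg <- rowsum(vals, group = rownames(vals), reorder = FALSE)
  agg
}

#' Read a transcript-level table with per-sample normalization factors
#'
#' @param path TSV with columns `transcript`, `gene`, then one column per
#'   sample (CAGE-style transcript TPM).
#' @param norm_factors either a named numeric vector (sample -> factor) or
#'   the path to a one-row TSV whose header names the samples.
#' @return A `transcript_table`: list with `data` (data frame) and
#'   `norm_factors` (named numeric).
#' @export
read_transcript_table <- function(path, norm_factors = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("transcript", "gene") %in% names(df)))
    stop("transcript table must have 'transcript' and 'gene' columns")
  samples <- setdiff(names(df), c("transcript", "gene"))
  if (is.character(norm_factors) && length(norm_factors) == 1) {
    nf_df <- read.delim(norm_factors, stringsAsFactors = FALSE,
                        check.names = FALSE)
    norm_factors <- unlist(nf_df[1, , drop = TRUE])
    norm_factors <- stats::setNames(as.numeric(norm_factors), names(nf_df))
  }
  if (is.null(norm_factors))
    norm_factors <- stats::setNames(rep(1, length(samples)), samples)
  transcript_table(df, norm_factors)
}

#' Construct a transcript table
#'
#' @param data data frame with `transcript`, `gene` and sample columns.
#' @param norm_factors named numeric vector of per-sample normalization
#'   factors (all > 0).
#' @return A `transcript_table` object.
#' @export
transcript_table <- function(data, norm_factors) {
  samples <- setdiff(names(data), c("transcript", "gene"))
  missing_nf <- setdiff(samples, names(norm_factors))
  if (length(missing_nf) > 0)
    stop("normalization factor missing for sample(s): ",
         paste(missing_nf, collapse = ", "))
  if (any(!is.finite(norm_factors)) || any(norm_factors <= 0))
    stop("normalization factors must be positive and finite")
  structure(list(data = data, norm_factors = norm_factors[samples]),
            class = "transcript_table")
}

#' Exclude samples with extreme normalization factors
#'
#' Samples whose normalization factor is below `low` or above `high` are
#' dropped; boundary values are retained (exclusion is strictly "less than" /
#' "higher than").
#'
#' @param table a `transcript_table`.
#' @param low,high retention bounds (defaults 0.7 and 1.4).
#' @return The filtered `transcript_table`.
#' @export
filter_by_norm_factor <- function(table, low = 0.7, high = 1.4) {
  stopifnot(inherits(table, "transcript_table"))
  nf <- table$norm_factors
  keep <- names(nf)[nf >= low & nf <= high]
  data <- table$data[, c("transcript", "gene", keep), drop = FALSE]
  transcript_table(data, nf[keep])
}

#' Aggregate transcript-level values to gene level
#'
#' Gene-level abundance is the sum of the gene's transcript values in each
#' sample. Transcripts without a gene mapping are excluded with a warning.
#'
#' @param table a `transcript_table`.
#' @param unit_label unit attached to the returned matrix.
#' @return An abundance matrix (genes x samples).
#' @export
aggregate_transcripts <- function(table, unit_label = "TPM") {
  stopifnot(inherits(table, "transcript_table"))
  df <- table$data
  samples <- setdiff(names(df), c("transcript", "gene"))
  unmapped <- is.na(df$gene) | !nzchar(trimws(as.character(df$gene)))
  if (any(unmapped)) {
    warning(sum(unmapped), " transcript(s) without gene mapping excluded")
    df <- df[!unmapped, , drop = FALSE]
  }
  if (nrow(df) == 0 || length(samples) == 0) {
    out <- matrix(numeric(0), nrow = 0, ncol = length(samples),
                  dimnames = list(character(0), samples))
    return(abundance_matrix(out, unit_label = unit_label))
  }
  vals <- as.matrix(df[, samples, drop = FALSE])
  agg <- rowsum(vals, group = df$gene, reorder = FALSE)
  abundance_matrix(agg, unit_label = unit_label)
}

#' Construct a probe table
#'
#' @param data data frame with `probe`, `gene` and sample columns.
#' @return A `probe_table` object.
#' @export
probe_table <- function(data) {
  if (!all(c("probe", "gene") %in% names(data)))
    stop("probe table must have 'probe' and 'gene' columns")
  if (anyDuplicated(data$probe)) stop("probe identifiers must be unique")
  structure(list(data = data), class = "probe_table")
}

#' Read a probe-level expression table
#'
#' @param path TSV with columns `probe`, `gene`, then one column per sample.
#' @return A `probe_table` object.
#' @export
read_probe_table <- function(path) {
  probe_table(read.delim(path, stringsAsFactors = FALSE, check.names = FALSE))
}

#' Aggregate probe-level values to gene level
#'
#' Gene-level expression is the arithmetic mean across the gene's probes in
#' each sample (the microarray aggregation rule).
#'
#' @param table a `probe_table`.
#' @param unit_label unit attached to the returned matrix.
#' @return An abundance matrix (genes x samples).
#' @export
aggregate_probes <- function(table, unit_label = "intensity") {
  stopifnot(inherits(table, "probe_table"))
  df <- table$data
  samples <- setdiff(names(df), c("probe", "gene"))
  vals <- as.matrix(df[, samples, drop = FALSE])
  sums <- rowsum(vals, group = df$gene, reorder = FALSE)
  counts <- as.vector(table(factor(df$gene, levels = rownames(sums))))
  abundance_matrix(sums / counts, unit_label = unit_label)
}

#' Read a sample-to-tissue annotation table
#'
#' @param path two-column TSV: sample identifier, tissue label. A repeated
#'   (sample, tissue) row is accepted once; the same sample with two
#'   different labels is an error.
#' @return Named character vector mapping sample -> tissue.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2) stop("annotation must have two columns (sample, tissue)")
  df <- unique(df[, 1:2])
  if (anyDuplicated(df[[1]])) {
    bad <- unique(df[[1]][duplicated(df[[1]])])
    stop("sample(s) annotated with conflicting tissue labels: ",
         paste(bad, collapse = ", "))
  }
  stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
}

#' Write an abundance matrix as TSV
#'
#' @param mat abundance matrix.
#' @param path output path; first column is `gene`.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a sample annotation as TSV
#'
#' @param annotation named character vector (sample -> tissue).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation_tsv <- function(annotation, path) {
  df <- data.frame(sample = names(annotation), tissue = unname(annotation),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
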