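#' Pipeline run configuration
#'
#' @param expression path to the expression file.
#' @param annotation path to the sample -> tissue annotation TSV.
#' @param dialect one of `"gene_tsv"`, `"gct"`, `"fantom_transcript"`,
#'   `"microarray_probe"`.
#' @param complexes path to a complex table (`NULL` = bundled).
#' @param aliases,chromosomes paths for the gene registry (`NULL` = bundled).
#' @param ribosomal path to the reference gene list (`NULL` = bundled).
#' @param norm_factors per-sample normalization factor file (required for the
#'   `fantom_transcript` dialect).
#' @param groups group names to run (`NULL` = all in the complex table).
#' @param enrichment a [perm_config()].
#' @param summary_statistic per-tissue central tendency for share summaries.
#' @param out_dir output directory (created if needed).
#' @return A `run_config` list.
#' @export
run_config <- function(expression, annotation,
                       dialect = c("gene_tsv", "gct", "fantom_transcript",
                                   "microarray_probe"),
                       complexes = NULL, aliases = NULL, chromosomes = NULL,
                       ribosomal = NULL, norm_factors = NULL, groups = NULL,
                       enrichment = perm_config(),
                       summary_statistic = c("median", "mean"),
                       out_dir = "results") {
  dialect <- match.arg(dialect)
  summary_statistic <- match.arg(summary_statistic)
  structure(list(expression = expression, annotation = annotation,
                 dialect = dialect, complexes = complexes, aliases = aliases,
                 chromosomes = chromosomes, ribosomal = ribosomal,
                 norm_factors = norm_factors, groups = groups,
                 enrichment = enrichment,
                 summary_statistic = summary_statistic, out_dir = out_dir),
            class = "run_config")
}

sanitize_filename <- function(x) {
  gsub("_+", "_", gsub("[^A-Za-z0-9.-]+", "_", x))
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full share/enrichment/weighted pipeline
#'
#' Orchestrates catalog loading, expression input, share computation with the
#' half-mean sample exclusion, tissue enrichment and weighted-total
#' correlations, and writes one TSV triple (shares, tissue summary,
#' enrichment) per group plus weighted-total and correlation tables and a
#' JSON run manifest recording the seed, permutation count, package version
#' and per-group exclusion counts. A group that fails does not abort the
#' others; `status` is nonzero only if every group failed.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with `status` (0 = at least one group
#'   succeeded), `enrichment` (combined data frame), `weighted`,
#'   `correlations` and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!file.exists(config$expression))
    stop("expression_io: expression file not found: ", config$expression)
  if (!file.exists(config$annotation))
    stop("expression_io: annotation file not found: ", config$annotation)

  mat <- switch(config$dialect,
    gene_tsv = ,
    gct = read_gct(config$expression),
    fantom_transcript = {
      tt <- read_transcript_table(config$expression, config$norm_factors)
      aggregate_transcripts(filter_by_norm_factor(tt))
    },
    microarray_probe = aggregate_probes(read_probe_table(config$expression)))
  annotation <- read_annotation(config$annotation)

  table <- load_complex_table(config$complexes)
  registry <- load_gene_registry(config$chromosomes, config$aliases)
  run_groups <- config$groups %||% names(table$groups)
  unknown <- setdiff(run_groups, names(table$groups))
  if (length(unknown) > 0)
    stop("catalog: unknown group(s): ", paste(unknown, collapse = ", "))
  resolved <- resolve_symbols(table, rownames(mat), registry)

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  enrich_all <- list()
  group_log <- list()
  failed <- character(0)
  for (g in run_groups) {
    res <- tryCatch({
      members <- resolved[[g]]$matched
      if (length(resolved[[g]]$missing) > 0)
        message("group '", g, "': missing gene(s): ",
                paste(resolved[[g]]$missing, collapse = ", "))
      shares <- group_share_matrix(mat, members, group = g)
      summ <- tissue_summary(shares, annotation,
                             statistic = config$summary_statistic)
      enr <- run_enrichment(shares, annotation, config$enrichment, group = g)
      stem <- sanitize_filename(g)
      sh_df <- data.frame(gene = rownames(shares),
                          as.data.frame(unclass(shares)),
                          check.names = FALSE)
      write_tsv(sh_df, file.path(config$out_dir,
                                 paste0("shares_", stem, ".tsv")))
      write_tsv(summ, file.path(config$out_dir,
                                paste0("tissue_summary_", stem, ".tsv")))
      write_tsv(enr, file.path(config$out_dir,
                               paste0("enrichment_", stem, ".tsv")))
      list(enr = enr,
           log = list(group = g,
                      n_members_matched = length(members),
                      missing_members = resolved[[g]]$missing,
                      n_samples_excluded = length(attr(shares, "excluded")),
                      n_samples_retained = ncol(shares)))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("group '", g, "' failed: ", conditionMessage(res))
      failed <- c(failed, g)
      group_log[[g]] <- list(group = g, error = conditionMessage(res))
    } else {
      enrich_all[[g]] <- res$enr
      group_log[[g]] <- res$log
    }
  }

  # weighted totals: each requested group plus the reference list
  ref_genes <- ribosomal_genes(config$ribosomal)
  wt_list <- list()
  ref_wt <- tryCatch(
    weighted_total(mat, ref_genes, annotation, set_name = "ribosomal"),
    error = function(e) NULL)
  if (is.null(ref_wt))
    warning("reference gene set not quantifiable in this matrix; ",
            "correlations skipped")
  correlations <- list()
  for (g in setdiff(run_groups, failed)) {
    wt <- tryCatch(
      weighted_total(mat, resolved[[g]]$matched, annotation, set_name = g),
      error = function(e) NULL)
    if (is.null(wt)) next
    wt_list[[g]] <- wt
    if (!is.null(ref_wt)) {
      cc <- tryCatch(correlate_with_reference(wt, ref_wt),
                     error = function(e) NULL)
      if (!is.null(cc))
        correlations[[g]] <- data.frame(
          set_a = cc$set_a, set_b = cc$set_b, n_tissues = cc$n_tissues,
          pearson_r = cc$pearson_r, stringsAsFactors = FALSE)
    }
  }
  weighted_df <- if (length(wt_list) > 0 || !is.null(ref_wt))
    do.call(rbind, c(unname(wt_list), list(ref_wt))) else NULL
  if (!is.null(weighted_df))
    write_tsv(weighted_df, file.path(config$out_dir, "weighted_totals.tsv"))
  corr_df <- if (length(correlations) > 0)
    do.call(rbind, unname(correlations)) else NULL
  if (!is.null(corr_df))
    write_tsv(corr_df, file.path(config$out_dir, "correlations.tsv"))

  manifest <- list(
    package_version = as.character(packageVersion("tagshares")),
    dialect = config$dialect,
    seed = config$enrichment$seed,
    permutations = config$enrichment$n_permutations,
    weight_exponent = config$enrichment$weight_exponent,
    min_set_size = config$enrichment$min_set_size,
    fdr_threshold = config$enrichment$fdr_threshold,
    n_genes_in_matrix = nrow(mat),
    n_samples_in_matrix = ncol(mat),
    groups = group_log,
    failed_groups = failed)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  status <- if (length(failed) == length(run_groups)) 1L else 0L
  invisible(list(status = status,
                 enrichment = if (length(enrich_all) > 0)
                   do.call(rbind, unname(enrich_all)) else NULL,
                 weighted = weighted_df, correlations = corr_df,
                 manifest = manifest))
}

#' Stacked per-tissue share bar chart
#'
#' One stacked bar per tissue showing the per-tissue summary share of each
#' member gene, with asterisks marking (gene, tissue) pairs whose enrichment
#' q-value is below the threshold.
#'
#' @param summary output of [tissue_summary()].
#' @param group group name used in the title.
#' @param path output image path (extension selects the device, e.g. `.png`).
#' @param enrichment optional [run_enrichment()] output supplying the
#'   significance flags.
#' @param fdr_threshold threshold for the asterisks (default 0.01).
#' @return `path` invisibly, or `NULL` (with a warning) for an empty summary.
#' @export
plot_tissue_shares <- function(summary, group, path, enrichment = NULL,
                               fdr_threshold = 0.01) {
  if (is.null(summary) || nrow(summary) == 0) {
    warning("empty tissue summary; no plot written")
    return(NULL)
  }
  df <- summary
  df$gene <- factor(df$gene)
  if (!is.null(enrichment) && nrow(enrichment) > 0) {
    key <- paste(enrichment$gene, enrichment$tissue)
    sig <- enrichment$qvalue < fdr_threshold
    df$star <- ifelse(sig[match(paste(df$gene, df$tissue), key)] %in% TRUE,
                      "*", "")
  } else df$star <- ""
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$tissue, y = .data$summary,
                                        fill = .data$gene)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::geom_text(ggplot2::aes(label = .data$star),
                       position = ggplot2::position_stack(vjust = 0.5),
                       size = 5) +
    ggplot2::labs(title = paste0("Share of group total: ", group),
                  x = "tissue", y = "share of group expression",
                  fill = "gene",
                  caption = paste0("*, FDR q < ", fdr_threshold)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  ggplot2::ggsave(path, p, width = 9, height = 5, dpi = 120)
  invisible(path)
}
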