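#' Load a complex/group definition table
#'
#' Reads a two-column tab-delimited table (`group`, `genes` with
#' comma-separated gene symbols) defining protein complexes and functional
#' groups of translation-associated genes. Duplicated symbols within a group
#' (e.g. the doubled EIF3J entry in the bundled catalog) are collapsed to a
#' single occurrence with a warning.
#'
#' @param path path to the table; `NULL` loads the bundled catalog of 18
#'   complexes and functional groups (initiation, elongation and termination
#'   factors, PABPC paralogs, aminoacyl-tRNA synthetases and the multi-ARSase
#'   complex).
#' @return An object of class `complex_table`: a list with `groups` (named
#'   list of character vectors) and `provenance` (named character).
#' @export
load_complex_table <- function(path = NULL) {
  if (is.null(path)) path <- bundled_path("complexes.tsv")
  if (!file.exists(path)) stop("complex table file not found: ", path)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE, quote = "")
  if (!all(c("group", "genes") %in% names(df)))
    stop("complex table must have columns 'group' and 'genes'")
  groups <- list()
  provenance <- character(0)
  for (i in seq_len(nrow(df))) {
    gname <- trimws(as.character(df$group[i]))
    raw <- as.character(df$genes[i])
    if (is.na(gname)) gname <- ""
    if (is.na(raw)) raw <- ""
    members <- trimws(strsplit(raw, ",", fixed = TRUE)[[1]])
    members <- members[nzchar(members)]
    if (!nzchar(gname) || length(members) == 0)
      stop("empty or unparseable complex-table row ", i)
    dup <- unique(members[duplicated(members)])
    if (length(dup) > 0) {
      warning(sprintf("group '%s': collapsed duplicated symbol(s): %s",
                      gname, paste(dup, collapse = ", ")))
      members <- unique(members)
    }
    if (length(members) < 2)
      stop("group '", gname, "' has fewer than 2 members after deduplication")
    groups[[gname]] <- members
    provenance[gname] <- if ("note" %in% names(df)) df$note[i] else ""
  }
  structure(list(groups = groups, provenance = provenance),
            class = "complex_table")
}

#' @export
print.complex_table <- function(x, ...) {
  cat("complex_table with", length(x$groups), "groups\n")
  sizes <- vapply(x$groups, length, integer(1))
  for (g in names(x$groups))
    cat(sprintf("  %-28s %d genes\n", g, sizes[[g]]))
  invisible(x)
}

#' Load the gene registry
#'
#' Builds the minimal gene-metadata registry: chromosome annotation for the
#' sex-linked translation-associated genes (all other genes default to
#' `"autosome"`) and symbol aliases bridging gene-nomenclature generations
#' (e.g. VARS/VARS1, TARSL2/TARS3).
#'
#' @param chromosome_path TSV with columns `symbol`, `chromosome`; `NULL`
#'   loads the bundled annotation.
#' @param alias_path TSV with columns `canonical`, `alias`; `NULL` loads the
#'   bundled alias table.
#' @param symbols extra symbols to register (given chromosome `"autosome"`).
#' @return A data frame of class `gene_registry` with columns `symbol`,
#'   `chromosome`, `aliases` (comma-separated string, possibly empty).
#' @export
load_gene_registry <- function(chromosome_path = NULL, alias_path = NULL,
                               symbols = character(0)) {
  if (is.null(chromosome_path)) chromosome_path <- bundled_path("gene_chromosomes.tsv")
  if (is.null(alias_path)) alias_path <- bundled_path("gene_aliases.tsv")
  chrom <- read.delim(chromosome_path, stringsAsFactors = FALSE)
  ali <- read.delim(alias_path, stringsAsFactors = FALSE)
  syms <- unique(c(chrom$symbol, ali$canonical, symbols))
  reg <- data.frame(symbol = syms, chromosome = "autosome",
                    aliases = "", stringsAsFactors = FALSE)
  reg$chromosome[match(chrom$symbol, reg$symbol)] <- chrom$chromosome
  for (i in seq_len(nrow(ali))) {
    j <- match(ali$canonical[i], reg$symbol)
    reg$aliases[j] <- if (nzchar(reg$aliases[j]))
      paste(reg$aliases[j], ali$alias[i], sep = ",") else ali$alias[i]
  }
  validate_gene_registry(reg)
  class(reg) <- c("gene_registry", "data.frame")
  reg
}

#' Validate a gene registry
#'
#' @param registry data frame with columns `symbol`, `chromosome`, `aliases`.
#' @return The registry, invisibly, if valid.
#' @export
validate_gene_registry <- function(registry) {
  if (any(!nzchar(registry$symbol))) stop("registry symbols must be non-empty")
  if (anyDuplicated(registry$symbol))
    stop("registry symbols must be unique")
  all_aliases <- unlist(strsplit(registry$aliases[nzchar(registry$aliases)], ","))
  clash <- intersect(all_aliases, registry$symbol)
  if (length(clash) > 0)
    stop("aliases collide with primary symbols: ", paste(clash, collapse = ", "))
  invisible(registry)
}

#' Genes on a chromosome
#'
#' @param registry a `gene_registry`.
#' @param chromosome chromosome label (`"X"`, `"Y"`, `"autosome"`, ...).
#' @return Lexicographically sorted symbols on that chromosome; an unknown
#'   label yields an empty vector.
#' @export
genes_on_chromosome <- function(registry, chromosome) {
  if (nrow(registry) == 0) return(character(0))
  sort(registry$symbol[registry$chromosome == chromosome])
}

#' Resolve catalog symbols against a matrix's gene identifiers
#'
#' Matches each group's members to the identifiers present in an abundance
#' matrix, trying registry aliases in both directions. Unmatched members are
#' reported as `missing`, never silently dropped.
#'
#' @param table a `complex_table`.
#' @param matrix_genes character vector of gene identifiers in the matrix.
#' @param registry a `gene_registry` (or `NULL` to skip alias resolution).
#' @return Named list, one entry per group, each a list with `matched` and
#'   `missing` character vectors.
#' @export
resolve_symbols <- function(table, matrix_genes, registry = NULL) {
  alias_map <- character(0)
  if (!is.null(registry)) {
    for (i in seq_len(nrow(registry))) {
      if (!nzchar(registry$aliases[i])) next
      for (a in strsplit(registry$aliases[i], ",")[[1]]) {
        alias_map[[registry$symbol[i]]] <- a  # canonical -> alias
        alias_map[[a]] <- registry$symbol[i]  # alias -> canonical
      }
    }
  }
  lapply(table$groups, function(members) {
    matched <- character(0)
    missing <- character(0)
    for (m in members) {
      if (m %in% matrix_genes) {
        matched <- c(matched, m)
      } else if (!is.na(alias_map[m]) && alias_map[m] %in% matrix_genes) {
        matched <- c(matched, unname(alias_map[m]))
      } else {
        missing <- c(missing, m)
      }
    }
    list(matched = matched, missing = missing)
  })
}
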