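#' Locate a bundled data file
#'
#' @param name file name under the package's `extdata` directory.
#' @return Absolute path to the bundled file.
#' @keywords internal
bundled_path <- function(name) {
  path <- system.file("extdata", name, package = "tagshares")
  if (!nzchar(path)) stop("bundled file not found: ", name)
  path
}

# Deterministic 31-bit string hash (polynomial rolling hash). Used to derive
# order-invariant RNG substreams keyed by gene and tissue names.
hash_string <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  codes <- utf8ToInt(x)
  h <- 0
  m <- 2147483647  # 2^31 - 1
  for (cc in codes) h <- (h * 131 + cc) %% m
  as.integer(h)
}

#' Derive a reproducible RNG substream seed
#'
#' Combines a base seed with identifying strings so that per-unit random
#' streams do not depend on iteration order.
#'
#' @param seed base integer seed.
#' @param ... character identifiers (e.g. gene and tissue names).
#' @return An integer seed below 2^31.
#' @keywords internal
derive_seed <- function(seed, ...) {
  parts <- paste(vapply(list(...), as.character, character(1)), collapse = "|")
  h <- hash_string(parts)
  as.integer((abs(as.numeric(seed)) + as.numeric(h)) %% 2147483647)
}

#' Validate a gene-by-sample abundance matrix
#'
#' Checks the abundance-matrix contract: a numeric matrix with unique,
#' non-empty gene row names and sample column names, all values finite and
#' non-negative.
#'
#' @param mat numeric matrix, genes in rows, samples in columns.
#' @return `mat`, invisibly, if valid; otherwise an error.
#' @export
validate_abundance_matrix <- function(mat) {
  if (!is.matrix(mat) || !is.numeric(mat))
    stop("abundance matrix must be a numeric matrix")
  if (nrow(mat) > 0 && (is.null(rownames(mat)) || anyDuplicated(rownames(mat))))
    stop("gene identifiers must be present and unique")
  if (ncol(mat) > 0 && (is.null(colnames(mat)) || anyDuplicated(colnames(mat))))
    stop("sample identifiers must be present and unique")
  if (any(!is.finite(mat))) stop("abundance values must be finite")
  if (any(mat < 0)) stop("abundance values must be non-negative")
  invisible(mat)
}

#' Construct an abundance matrix
#'
#' @param values numeric matrix (genes x samples) with dimnames.
#' @param unit_label free-text unit, e.g. `"TPM"` or `"intensity"`.
#' @return The validated matrix with a `unit_label` attribute.
#' @export
abundance_matrix <- function(values, unit_label = "TPM") {
  validate_abundance_matrix(values)
  attr(values, "unit_label") <- unit_label
  values
}
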