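# Shared fixture builders. All fixtures are constructed in code; file-based
# fixtures are written to tempfiles.

toy_matrix <- function() {
  m <- matrix(c(3, 1, 0,
                1, 3, 5,
                2, 2, 5), nrow = 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("s1", "s2", "s3")))
  abundance_matrix(m)
}

toy_ranked <- function(stats = c(4, 3, 2, 1)) {
  sh <- matrix(stats, nrow = 1,
               dimnames = list("g", paste0("s", seq_along(stats))))
  rank_samples(sh, "g")
}

write_gct_fixture <- function(values, names = rownames(values),
                              descriptions = rownames(values),
                              path = tempfile(fileext = ".gct"),
                              declared_dims = dim(values)) {
  lines <- c("#1.2",
             paste(declared_dims[1], declared_dims[2], sep = "\t"),
             paste(c("Name", "Description", colnames(values)), collapse = "\t"))
  for (i in seq_len(nrow(values)))
    lines <- c(lines, paste(c(names[i], descriptions[i], values[i, ]),
                            collapse = "\t"))
  writeLines(lines, path)
  path
}

write_tsv_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Plain-R reference implementation of the running-sum enrichment score,
# deliberately written as a position-by-position walk (independent of both
# the vectorized R path and the C++ kernel).
oracle_es <- function(stats_desc, hit_positions, weight_exponent = 1) {
  n <- length(stats_desc)
  k <- length(hit_positions)
  w <- abs(stats_desc)^weight_exponent
  W <- sum(w[hit_positions])
  running <- numeric(n)
  cur <- 0
  for (i in seq_len(n)) {
    if (i %in% hit_positions) {
      cur <- cur + (if (W > 0) w[i] / W else 1 / k)
    } else {
      cur <- cur - 1 / (n - k)
    }
    running[i] <- cur
  }
  top <- max(running, 0)
  bottom <- min(running, 0)
  if (top >= -bottom - 1e-12) top else bottom
}

# Exhaustive enumeration oracle: ES of every subset of the given size.
oracle_exhaustive_null <- function(stats_desc, set_size, weight_exponent = 1) {
  apply(combn(length(stats_desc), set_size), 2, function(pos)
    oracle_es(stats_desc, pos, weight_exponent))
}

# Exact enumeration p-value for an observed es, same-sign convention.
oracle_exact_p <- function(es, null_es) {
  same <- if (es > 0) null_es[null_es > 0] else null_es[null_es < 0]
  max(sum(abs(same) >= abs(es)), 1) / length(same)
}

# Minimal two-group complex table for synthetic specs.
toy_groups <- function() {
  structure(list(groups = list(G1 = c("A", "B"), G2 = c("B", "C", "D")),
                 provenance = c(G1 = "", G2 = "")),
            class = "complex_table")
}
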