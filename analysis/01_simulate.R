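#!/usr/bin/env Rscript
# Generate the three synthetic study conditions (GTEx-like with planted
# effects, a null version, and a sparse one-sample-per-tissue proteome-like
# set) and write them in the same TSV formats the readers consume, plus the
# YAML specs and the ground truth.

library(tagshares)

seed <- 1L
out <- "results/synthetic"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

for (preset in c("gtex_like", "null", "proteome_like")) {
  spec <- synthetic_preset(preset, seed = seed)
  d <- generate_dataset(spec)
  stem <- file.path(out, preset)
  write_expression_tsv(d$matrix, paste0(stem, "_expression.tsv"))
  write_annotation_tsv(d$annotation, paste0(stem, "_annotation.tsv"))
  write_synthetic_spec(spec, paste0(stem, "_spec.yaml"))
  if (!is.null(d$truth$effects))
    write.table(d$truth$effects, paste0(stem, "_planted_effects.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf(
    "%s: %d genes x %d samples, %d tissues, %d planted effects, %.1f%% zeros",
    preset, nrow(d$matrix), ncol(d$matrix), length(unique(d$annotation)),
    if (is.null(d$truth$effects)) 0L else nrow(d$truth$effects),
    100 * mean(d$matrix == 0)))
}

message("wrote synthetic datasets under ", out)
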