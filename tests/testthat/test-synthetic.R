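test_that("spec validation names the offending field", {
  g <- data.frame(symbol = c("A", "B", "C", "D"), log_mean = 0, log_sd = 0.1)
  grp <- toy_groups()
  expect_error(synthetic_spec(c(T1 = 5L), g, grp), "tissues")
  expect_error(synthetic_spec(c(T1 = 5L, T2 = 5L), g, grp, dropout = 1),
               "dropout")
  expect_error(synthetic_spec(c(T1 = 5L, T2 = 5L), g, grp,
                              effects = data.frame(gene = "A", tissue = "T1",
                                                   fold = 0)), "fold")
  expect_error(synthetic_spec(c(T1 = 5L, T2 = 5L), g, grp,
                              effects = data.frame(gene = "A", tissue = "T9",
                                                   fold = 2)), "tissue")
  g2 <- rbind(g, data.frame(symbol = "LONER", log_mean = 0, log_sd = 0.1))
  expect_error(synthetic_spec(c(T1 = 5L, T2 = 5L), g2, grp,
                              effects = data.frame(gene = "LONER",
                                                   tissue = "T1", fold = 2)),
               "no group")
})

test_that("the noise-free limit reproduces exp(log_mean) exactly", {
  g <- data.frame(symbol = c("A", "B"), log_mean = log(c(10, 4)), log_sd = 0)
  spec <- synthetic_spec(c(T1 = 3L, T2 = 2L), g, toy_groups(), seed = 4)
  d <- generate_dataset(spec)
  expect_equal(unname(d$matrix["A", ]), rep(10, 5))
  expect_equal(unname(d$matrix["B", ]), rep(4, 5))
  expect_equal(dim(d$matrix), c(2L, 5L))
  expect_identical(unname(d$annotation), rep(c("T1", "T2"), c(3, 2)))
})

test_that("hard tissue restriction zeroes expression outside the listed set", {
  g <- data.frame(symbol = c("A", "B"), log_mean = 1, log_sd = 0.3,
                  restrict_to = c("brain,heart", NA))
  spec <- synthetic_spec(c(brain = 4L, heart = 4L, liver = 4L), g,
                         toy_groups(), seed = 2)
  d <- generate_dataset(spec)
  outside <- d$annotation == "liver"
  expect_true(all(d$matrix["A", outside] == 0))
  expect_true(all(d$matrix["A", !outside] > 0))
  expect_true(all(d$matrix["B", ] > 0))
})

test_that("generation is reproducible and applies multiplicative effects", {
  g <- data.frame(symbol = c("A", "B", "C", "D"), log_mean = 2, log_sd = 0.4)
  eff <- data.frame(gene = "B", tissue = "T2", fold = 5)
  spec <- synthetic_spec(c(T1 = 6L, T2 = 6L), g, toy_groups(), effects = eff,
                         seed = 77)
  d1 <- generate_dataset(spec)
  d2 <- generate_dataset(spec)
  expect_identical(d1$matrix, d2$matrix)
  spec0 <- synthetic_spec(c(T1 = 6L, T2 = 6L), g, toy_groups(), seed = 77)
  base <- generate_dataset(spec0)
  inT2 <- d1$annotation == "T2"
  expect_equal(d1$matrix["B", inT2], base$matrix["B", inT2] * 5,
               tolerance = 1e-12)
  expect_equal(d1$matrix["B", !inT2], base$matrix["B", !inT2],
               tolerance = 1e-12)
  # ground truth marks the planted pair and same-group compensatory pairs
  aff <- d1$truth$affected
  expect_identical(aff$role[aff$gene == "B" & aff$group == "G1"], "planted")
  expect_true(all(aff$role[aff$gene != "B"] == "compensatory"))
  expect_setequal(aff$gene[aff$group == "G2"], c("B", "C", "D"))
})

test_that("gene-wise medians converge to exp(log_mean) at large n", {
  g <- data.frame(symbol = c("A", "B"), log_mean = log(c(50, 2)), log_sd = 0.5)
  spec <- synthetic_spec(c(T1 = 1000L, T2 = 1000L), g, toy_groups(), seed = 8)
  d <- generate_dataset(spec)
  expect_equal(median(d$matrix["A", ]), 50, tolerance = 0.05 * 50)
  expect_equal(median(d$matrix["B", ]), 2, tolerance = 0.05 * 2)
})

test_that("planted folds are recoverable from tissue median ratios", {
  g <- data.frame(symbol = c("A", "B"), log_mean = log(20), log_sd = 0.5)
  eff <- data.frame(gene = "A", tissue = "T1", fold = 5)
  spec <- synthetic_spec(c(T1 = 30L, T2 = 30L, T3 = 30L), g, toy_groups(),
                         effects = eff, seed = 15)
  d <- generate_dataset(spec)
  inT1 <- d$annotation == "T1"
  ratio <- median(d$matrix["A", inT1]) / median(d$matrix["A", !inT1])
  expect_equal(ratio, 5, tolerance = 0.2 * 5)
})

test_that("dropout zeroes approximately the configured fraction", {
  g <- data.frame(symbol = paste0("g", 1:10), log_mean = 3, log_sd = 0.2)
  grp <- structure(list(groups = list(G = paste0("g", 1:10)),
                        provenance = c(G = "")), class = "complex_table")
  spec <- synthetic_spec(c(T1 = 50L, T2 = 50L), g, grp, dropout = 0.3,
                         seed = 5)
  d <- generate_dataset(spec)
  expect_equal(mean(d$matrix == 0), 0.3, tolerance = 0.05)
})

test_that("presets encode the documented study conditions", {
  gtex <- synthetic_preset("gtex_like", seed = 3)
  expect_length(gtex$tissues, 12)
  expect_true(all(gtex$tissues == 30))
  expect_equal(nrow(gtex$genes), 40)
  expect_length(gtex$groups$groups, 4)
  expect_equal(nrow(gtex$effects), 6)
  expect_true(all(gtex$effects$fold >= 3 & gtex$effects$fold <= 10))

  nul <- synthetic_preset("null", seed = 3)
  expect_null(nul$effects)
  expect_equal(nrow(generate_dataset(nul)$truth$affected), 0)

  prot <- synthetic_preset("proteome_like", seed = 3)
  d <- generate_dataset(prot)
  expect_equal(ncol(d$matrix), 20)
  expect_equal(unname(table(d$annotation)), rep(1L, 20), ignore_attr = TRUE)
  expect_error(synthetic_preset("nope"), "arg")
})

test_that("synthetic specs round-trip through YAML", {
  spec <- synthetic_preset("gtex_like", seed = 9)
  path <- tempfile(fileext = ".yaml")
  write_synthetic_spec(spec, path)
  back <- read_synthetic_spec(path)
  expect_equal(back$tissues, spec$tissues)
  expect_equal(back$genes$symbol, spec$genes$symbol)
  expect_equal(back$genes$log_mean, spec$genes$log_mean)
  expect_equal(back$groups$groups, spec$groups$groups)
  expect_equal(back$effects, spec$effects)
  expect_equal(back$dropout, spec$dropout)
  # identical dataset from the reloaded spec
  expect_identical(generate_dataset(back)$matrix,
                   generate_dataset(spec)$matrix)
})
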