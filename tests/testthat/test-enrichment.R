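test_that("samples are ranked descending with deterministic ties", {
  sh <- matrix(c(0.5, 0.2, 0.9), 1, dimnames = list("g", c("s1", "s2", "s3")))
  expect_identical(rank_samples(sh, "g")$sample, c("s3", "s1", "s2"))
  tie <- matrix(c(0.3, 0.3, 0.3), 1, dimnames = list("g", c("s2", "s3", "s1")))
  expect_identical(rank_samples(tie, "g")$sample, c("s1", "s2", "s3"))
  single <- matrix(1, 1, dimnames = list("g", "s1"))
  expect_identical(rank_samples(single, "g")$sample, "s1")
  expect_error(rank_samples(sh, "nope"), "not present")
})

test_that("running-sum scores match the hand-evaluated worked instance", {
  r <- toy_ranked(c(4, 3, 2, 1))
  res <- enrichment_score(r, c("s1", "s2"))
  expect_equal(res$running, c(4 / 7, 1, 0.5, 0), tolerance = 1e-12)
  expect_equal(res$es, 1)
  expect_equal(enrichment_score(r, c("s3", "s4"))$es, -1)
  # unweighted top half of a tied ranking attains the KS maximum of 1
  req <- toy_ranked(rep(1, 6))
  expect_equal(enrichment_score(req, c("s1", "s2", "s3"),
                                weight_exponent = 0)$es, 1)
  expect_error(enrichment_score(r, character(0)), "non-empty")
  expect_error(enrichment_score(r, paste0("s", 1:4)), "proper subset")
  expect_error(enrichment_score(r, c("s1", "zz")), "not present")
})

test_that("the walk ends at zero and es stays within [-1, 1]", {
  set.seed(11)
  for (i in 1:40) {
    n <- sample(3:30, 1)
    stats <- round(rexp(n), 3)
    r <- toy_ranked(stats)
    k <- sample(seq_len(n - 1), 1)
    set <- sample(r$sample, k)
    res <- enrichment_score(r, set, weight_exponent = sample(c(0, 1, 2), 1))
    expect_lt(abs(res$running[n]), 1e-9)
    expect_lte(abs(res$es), 1 + 1e-12)
  }
})

test_that("R walk, C++ kernel and the independent oracle agree exactly", {
  set.seed(21)
  for (i in 1:40) {
    n <- sample(4:25, 1)
    stats <- sort(c(rexp(n - 1), 0), decreasing = TRUE)  # include a zero
    r <- toy_ranked(stats)
    k <- sample(seq_len(n - 1), 1)
    pos <- sort(sample(n, k))
    wexp <- sample(c(0, 1, 2), 1)
    es_r <- enrichment_score(r, r$sample[pos], weight_exponent = wexp)$es
    es_cpp <- tagshares:::.calc_es_cpp(stats, as.integer(pos), wexp)
    es_oracle <- oracle_es(stats, pos, wexp)
    expect_equal(es_r, es_cpp, tolerance = 1e-12)
    expect_equal(es_r, es_oracle, tolerance = 1e-12)
  }
})

test_that("scores agree with the reference GSEA implementation on tie-free inputs", {
  skip_if_not_installed("fgsea")
  set.seed(31)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    stats <- sort(rexp(n) + 1e-3, decreasing = TRUE)
    k <- sample(seq_len(n - 1), 1)
    pos <- sort(sample(n, k))
    es_pkg <- tagshares:::.calc_es_cpp(stats, as.integer(pos), 1)
    es_ref <- fgsea::calcGseaStat(stats, pos, gseaParam = 1)
    expect_equal(es_pkg, es_ref, tolerance = 1e-9)
  }
})

test_that("all-zero hit statistics fall back to uniform hit increments", {
  r <- toy_ranked(c(2, 1, 0, 0, 0))
  res <- enrichment_score(r, c("s4", "s5"), weight_exponent = 1)
  # same as the unweighted walk on those hits
  expect_equal(res$es, oracle_es(r$statistic, 4:5, 0))
})

test_that("exhaustive null enumerates every subset of the worked instance", {
  r <- toy_ranked(c(4, 3, 2, 1))
  cfg <- perm_config(n_permutations = 10000)
  null <- permutation_null(r, 2, cfg)
  expect_true(attr(null, "exhaustive"))
  expect_length(null, choose(4, 2))
  expect_equal(sort(null), sort(oracle_exhaustive_null(r$statistic, 2)),
               tolerance = 1e-12)
  # frozen oracle enumeration: positive scores 1, 0.8, 2/3, 0.5 and
  # negative scores -0.5, -1
  expect_equal(sort(null), c(-1, -0.5, 0.5, 2 / 3, 0.8, 1), tolerance = 1e-9)
  expect_error(permutation_null(r, 0, cfg), "set_size")
  expect_error(permutation_null(r, 4, cfg), "set_size")
  # boundary set size N-1 is valid
  expect_length(permutation_null(r, 3, cfg), choose(4, 3))
})

test_that("sampled null is reproducible and respects the forced modes", {
  r <- toy_ranked(c(4, 3, 2, 1))
  cfg <- perm_config(n_permutations = 500, exhaustive = FALSE)
  set.seed(99); a <- permutation_null(r, 2, cfg)
  set.seed(99); b <- permutation_null(r, 2, cfg)
  expect_identical(a, b)
  expect_false(attr(a, "exhaustive"))
  expect_length(a, 500)
  big <- toy_ranked(seq(100, 1, length.out = 100))
  expect_error(permutation_null(big, 50, perm_config(exhaustive = TRUE)),
               "infeasible")
})

test_that("exact p-values from enumeration match the oracle; worked instance p = 1/4", {
  r <- toy_ranked(c(4, 3, 2, 1))
  null <- permutation_null(r, 2, perm_config())
  np <- nes_and_pvalue(1.0, null)
  expect_equal(np$pvalue, oracle_exact_p(1.0, oracle_exhaustive_null(r$statistic, 2)))
  expect_equal(np$pvalue, 1 / 4)
  # NES normalizes by the same-sign mean magnitude
  expect_equal(np$nes, 1 / mean(c(1, 0.8, 2 / 3, 0.5)))
})

test_that("nes_and_pvalue handles signs, zero scores and empty same-sign nulls", {
  null <- c(0.5, -0.5, 0.25, -0.25)
  attr(null, "exhaustive") <- FALSE
  expect_equal(nes_and_pvalue(0.5, null)$nes, 0.5 / mean(c(0.5, 0.25)))
  # symmetric null at +/- x with es = x gives nes close to 1
  sym <- c(0.4, -0.4); attr(sym, "exhaustive") <- FALSE
  expect_equal(nes_and_pvalue(0.4, sym)$nes, 1)
  z <- nes_and_pvalue(0, null)
  expect_equal(z[c("nes", "pvalue")], list(nes = 0, pvalue = 1))
  onesided <- c(0.1, 0.2); attr(onesided, "exhaustive") <- FALSE
  res <- nes_and_pvalue(-0.3, onesided)
  expect_true(is.na(res$nes))
  expect_equal(res$pvalue, 1 / 3)
  # +1 correction keeps sampled p above the floor
  expect_gte(nes_and_pvalue(0.99, null)$pvalue, 1 / (1 + length(null)))
})

test_that("BH adjustment across tissues matches hand computation", {
  rec <- data.frame(pvalue = c(0.01, 0.02, 0.03))
  expect_equal(fdr_over_tissues(rec)$qvalue, c(0.03, 0.03, 0.03))
  expect_equal(fdr_over_tissues(data.frame(pvalue = 0.2))$qvalue, 0.2)
  expect_equal(fdr_over_tissues(data.frame(pvalue = c(1, 1)))$qvalue, c(1, 1))
  # q-values never fall below their p-value within the family
  set.seed(3)
  p <- runif(30)
  expect_true(all(fdr_over_tissues(data.frame(pvalue = p))$qvalue >= p))
})

test_that("reversing the ranking flips unweighted scores and keeps |es| order", {
  stats <- c(9, 7, 5, 3, 2, 1)
  r_fwd <- toy_ranked(stats)
  # tie-free sets: symmetric sets tie the two extremes, where the sign
  # convention (positive on ties) breaks exact antisymmetry by design
  sets <- list(c("s1", "s2"), c("s2", "s3"), c("s1", "s4"))
  # reversed ranking: same samples, statistics reversed so order inverts
  sh_rev <- matrix(rev(stats), 1,
                   dimnames = list("g", paste0("s", 1:6)))
  r_rev <- rank_samples(sh_rev, "g")
  es_fwd <- vapply(sets, function(s)
    enrichment_score(r_fwd, s, weight_exponent = 0)$es, numeric(1))
  es_rev <- vapply(sets, function(s)
    enrichment_score(r_rev, s, weight_exponent = 0)$es, numeric(1))
  expect_equal(es_rev, -es_fwd, tolerance = 1e-12)
  expect_identical(order(abs(es_fwd)), order(abs(es_rev)))
})

test_that("run_enrichment recovers a planted share shift and skips small tissues", {
  set.seed(7)
  n_per <- 10
  tissues <- rep(c("T", "U", "V"), each = n_per)
  samples <- sprintf("s%02d", seq_along(tissues))
  ann <- stats::setNames(tissues, samples)
  m <- matrix(rexp(2 * length(samples), rate = 1) + 0.5, nrow = 2,
              dimnames = list(c("A", "B"), samples))
  m["A", tissues == "T"] <- m["A", tissues == "T"] * 8
  sh <- compute_shares(abundance_matrix(m), c("A", "B"))
  cfg <- perm_config(n_permutations = 2000, seed = 42)
  res <- run_enrichment(sh, ann, cfg, group = "G")
  expect_setequal(names(res), c("group", "gene", "tissue", "set_size", "es",
                                "nes", "pvalue", "n_null_same_sign",
                                "qvalue", "significant"))
  hit <- res[res$gene == "A" & res$tissue == "T", ]
  expect_gt(hit$es, 0)
  expect_true(hit$significant)
  # the compensatory partner is depleted in T
  expect_lt(res[res$gene == "B" & res$tissue == "T", "es"], 0)
  # q-values are BH within each gene's tissue family
  for (g in c("A", "B")) {
    fam <- res[res$gene == g, ]
    expect_equal(fam$qvalue, p.adjust(fam$pvalue, "BH"))
  }
  # identical config and seed reproduce the table exactly
  res2 <- run_enrichment(sh, ann, cfg, group = "G")
  expect_identical(res, res2)

  # a tissue below min_set_size is skipped with a warning
  cfg_min <- perm_config(n_permutations = 200, seed = 1, min_set_size = 3)
  sh2 <- sh[, 1:12]
  ann2 <- c(stats::setNames(rep("T", 2), colnames(sh2)[1:2]),
            stats::setNames(rep("U", 10), colnames(sh2)[3:12]))
  expect_warning(run_enrichment(sh2, ann2, cfg_min), "skipped")

  # a single tissue spanning every sample leaves nothing testable
  one_tissue <- stats::setNames(rep("T", ncol(sh)), colnames(sh))
  out <- suppressWarnings(run_enrichment(sh, one_tissue, cfg_min))
  expect_equal(nrow(out), 0)
})

test_that("per-(gene, tissue) substreams make results order-invariant", {
  # permuting the columns (iteration order of samples) must not change the
  # p-value of a given (gene, tissue) pair
  set.seed(13)
  samples <- sprintf("s%02d", 1:24)
  ann <- stats::setNames(rep(c("T", "U", "V", "W"), each = 6), samples)
  m <- matrix(rexp(2 * 24) + 0.2, 2, dimnames = list(c("A", "B"), samples))
  sh <- compute_shares(abundance_matrix(m), c("A", "B"))
  cfg <- perm_config(n_permutations = 500, seed = 5)
  res1 <- run_enrichment(sh, ann, cfg)
  perm <- sample(ncol(sh))
  sh_perm <- sh[, perm]
  res2 <- run_enrichment(sh_perm, ann, cfg)
  key <- function(d) d[order(d$gene, d$tissue), c("gene", "tissue", "es", "pvalue")]
  expect_equal(key(res1), key(res2), ignore_attr = TRUE)
})
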