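---
title: "Within-complex shares and sample-ranked enrichment: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Within-complex shares and sample-ranked enrichment: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tagshares)
```

## The problem and the statistic

Absolute mRNA abundance of translation machinery components varies enormously
across human tissues, tracking overall translational demand rather than the
*composition* of the machinery. To ask whether the stoichiometry of a complex
differs between tissues, this package works with the **share**: for a defined
complex or functional group of genes (the bundled catalog carries 18 such
groups — initiation, elongation and termination factor sets, PABPC paralogs,
aminoacyl-tRNA synthetases and the multi-synthetase complex), each member
gene's fraction of the group's summed expression in each sample,

$$\mathrm{share}(g, s) = \frac{x_{gs}}{\sum_{g' \in G} x_{g's}},$$

computed on linear abundance (TPM or intensity), never on a log scale — a
fraction of a total is only meaningful on the linear scale. Shares are
invariant to per-sample scaling (sequencing depth, global translational
activity), sum to one over the group in every sample, and respond
compositionally: raising one member's expression necessarily lowers every
other member's share.

Before shares are computed, samples in which the group is essentially not
expressed are excluded: a sample is dropped when its group total is strictly
below half the mean group total across all samples. The threshold is computed
once, in a single pass — it is not re-applied iteratively, so the procedure
is deterministic and idempotent on its own output.

## Tissue enrichment along the share-ranked sample list

For each member gene, all retained samples are ranked by the gene's share
(descending; ties broken by ascending sample identifier for determinism).
Each tissue's samples form a *sample set*, and the question "is this gene's
share systematically high (or low) in this tissue?" becomes a set-enrichment
question on the ranked list — the GSEA running-sum statistic with the roles
of genes and samples swapped. Walking down the ranking, a hit (sample in the
tissue) at position $i$ adds $|r_i|^w / \sum_{\mathrm{hits}} |r|^w$ and a
miss subtracts $1/(N - k)$; the enrichment score (ES) is the running-sum
value of maximal absolute deviation from zero, signed. The walk always
returns to zero, and ES lies in $[-1, 1]$.

Numerical conventions, all of which are configurable or tested:

* **Weight exponent** $w$ defaults to 1 (hit increments proportional to the
  share), matching the default behaviour of the GSEA-family tools; $w = 0$
  gives the classic unweighted Kolmogorov–Smirnov statistic.
* **All-zero hit sets.** A tissue whose samples all have share exactly zero
  (hard tissue-restricted genes produce these) would give an undefined
  weighted increment; the implementation falls back to uniform $1/k$ hit
  increments in that case, in both the R and the C++ path.
* **Extreme ties.** When the maximal positive and negative deviations tie in
  magnitude, the positive extreme is taken, with a $10^{-12}$ tolerance so an
  analytically exact tie is not flipped by floating-point summation order.
  (The reference GSEA implementation returns 0 on such ties; ties are
  measure-zero for continuous shares and only arise on toy integer inputs.)

### Permutation null, NES, p-values

The null holds the ranked statistic fixed and draws uniformly random sample
subsets of the same size (set permutation, mirroring gene-set permutation in
ranked-list GSEA) — 10,000 permutations by default. The normalized
enrichment score divides the observed ES by the mean |ES| of same-sign null
values. P-values are same-sign:
$p = (1 + \#\{\text{same-sign null}, |ES_0| \ge |ES|\}) /
(1 + \#\text{same-sign null})$, so $p = 0$ is impossible and
$p \ge 1/(1+n_\mathrm{perm})$.

When $\binom{N}{k} \le n_\mathrm{perm}$ the null is enumerated exhaustively
instead, and the p-value is then the *exact* probability
$m / \#\text{same-sign}$ without the Monte-Carlo +1 correction: the
correction exists to guard a sampled estimate, and applying it to a complete
enumeration would bias the exact value (on a 4-sample ranking with set size
2 the two conventions give 0.4 vs the exact 0.25, and the sampled estimator
converges to the exact value, not the corrected one). The observed set
belongs to the enumerated family, so $m \ge 1$ by construction.

A consequence of the +1 correction worth spelling out: with $n_s$ same-sign
null draws the estimator only attains rejection levels of the form
$(1+m)/(1+n_s)$, so its exact type-I rate at nominal $\alpha$ is
$(\lceil \alpha (1+n_s) \rceil - 1)/(1+n_s)$ — about $0.049$ at nominal
$0.05$ with 1,000 permutations — never $\alpha$ itself. Calibration checks
in this package therefore compare empirical rejection rates against that
attainable level (computed from the reported `n_null_same_sign` column),
not against the unattainable nominal value; the enrichment results expose
the same-sign null count for exactly this purpose.

Per gene, p-values across tissue families are Benjamini–Hochberg adjusted
(the family is the number of tissue groups tested, 30 in the GTEx role, 12
in the synthetic presets), and pairs with $q < 0.01$ are flagged, the usual asterisk
convention in tissue-composition figures. Tissues with fewer than
`min_set_size = 3` retained samples are skipped with a warning — one or two
samples cannot carry a running-sum signal, so the smallest size that still
allows a meaningful two-sided walk was fixed up front.

Randomness is reproducible and order-invariant: the base seed is expanded
into a per-(gene, tissue) substream via a deterministic string hash, so the
result for a pair does not depend on which pairs are computed before it.
The running-sum inner loop of the permutation null is implemented in C++
(as the GSEA-family packages do); the observed ES uses a plain-R
implementation, and the two are tested for exact agreement against each
other, against an independently coded positional oracle, and against
`fgsea::calcGseaStat` on tie-free inputs.

## Weighted total expression and the ribosomal reference

To compare the overall output of a gene set between tissues without letting
one dominant gene swamp the sum, each gene is first normalized to its mean
across all samples (so every gene averages to 1), the normalized values are
summed over the set per sample, and per-sample sums are averaged per tissue.
Two identities pin the implementation down: the sample-mean of the
per-sample weighted total equals the number of quantified member genes
exactly, and the statistic is invariant to global rescaling of the matrix.
Profiles of two sets over shared tissues are compared by Pearson
correlation (at least 3 shared tissues, zero-variance profiles are errors).
The bundled reference set is the standard human cytoplasmic
ribosomal-protein gene list (RPS*/RPL*/RPLP*, FAU, UBA52), supplied as an
editable text file so alternative reference lists can be swapped in. Gene
means are global across all samples, not per tissue: a per-tissue mean would
erase exactly the between-tissue differences the statistic is meant to show.
Tissue aggregation uses the mean, with the median exposed as an option.

## Input handling

Three input flavours reduce to one gene-by-sample matrix:

* **GCT 1.2 / gene-level TSV** — symbols from the `Description` column when
  it looks like a symbol (GTEx stores Ensembl IDs in `Name`); duplicate gene
  rows are summed.
* **Transcript tables** (CAGE-style) — gene value = sum of transcript TPM;
  samples with normalization factors below 0.7 or above 1.4 are excluded
  (strict inequalities: boundary samples are retained); transcripts without
  a gene mapping are excluded with a warning.
* **Probe tables** (microarray) — gene value = mean across probes.

Mixed gene-nomenclature generations (VARS/VARS1, TARSL2/TARS3, ...) are
bridged by a bundled editable alias table; unmatched catalog members are
reported per group, never silently dropped. The catalog's duplicated EIF3J
entry is treated as a typographical duplicate and collapsed with a warning —
the eIF3 complex has at most 13 subunits (a–m). Chromosome annotation
covers the sex-linked catalog genes (EIF1AX/EIF1AY, DDX3X/DDX3Y, EIF2S3,
PABPC5); all other genes default to `"autosome"`, since genome-wide
annotation is out of scope.

## The synthetic data generator

`synthetic_preset()` encodes the study conditions used by the tests and the
acceptance script:

* `gtex_like` — 12 tissues × 30 samples, the 40 genes of four bundled groups
  (eIF3, eIF2B, ELONGATION, "eIF4, 4EBP"), log-normal noise with log-sd 0.5
  (a realistic dispersion for bulk TPM at gene level), and six planted
  single-tissue fold changes between 3 and 10, echoing well-described
  archetypes of tissue-specific translation factors: a muscle-shifted low-baseline eEF1A paralog (EEF1A2,
  fold 10), testis shifts of eIF5A2/eIF3g/eIF2Bδ, an ovary-elevated eIF4E
  family member (EIF4E1B, fold 8) and a brain shift of eIF4γ3. Baselines are
  fixed, not drawn: one dominant eEF1A paralog (~2000 TPM), abundant core
  factors (~200–800), moderate subunits (~60) and low tissue-specific
  paralogs (~3), so group totals and share scales resemble GTEx orders of
  magnitude.
* `null` — the same design with no planted effects (type-I calibration).
* `proteome_like` — 20 tissues × 1 sample with 30% dropout (sparse
  intensity-like data; enrichment is not applicable at one sample per tissue
  and such tissues are skipped by design).

Abundance is $\exp(\mathcal{N}(\mu_g, \sigma_g)) \times$ planted folds, with
optional hard zeros outside a gene's allowed tissue set — "exclusively
expressed" paralogs are modelled as exact zeros rather than tiny folds so
the zero-handling paths are genuinely exercised — followed by dropout
zeroing.

**Ground truth and compositional effects.** Planting a multiplicative effect
on one member gene mechanically shifts every other member's share in that
tissue through the denominator (the mirrored eEF1A1/eEF1A2 pattern arises
this way). The ground truth therefore distinguishes `planted` pairs from the
induced same-group, same-tissue `compensatory` pairs; recovery is assessed
on planted pairs and the false-flag rate on pairs outside both sets. What
the generator does *not* emulate: GTEx's 30 tissues and 11,688 samples,
unequal per-tissue sample counts, correlated expression between genes,
batch structure, or CAGE peak structure — so passing tests demonstrate the
statistical machinery, not performance on real GTEx data.

## Problem sizes and runtime choices

The permutation default is 10,000. The bundled
analysis scripts and the acceptance checks use sizes chosen to keep full
runs to minutes on one CPU while retaining resolution: type-I calibration
pools 200 null replicates at 1,000 permutations (p < 0.05 needs only ~1/500
resolution); recovery uses 50 replicates at 4,000 permutations, the
smallest round count whose minimal attainable q-value
($\approx 12/(1 + n_\mathrm{perm}/2)$ with 12 tissue families) sits
comfortably below the 0.01 flag threshold.

## Known limitations

* Enrichment p-values use the simple sampled-permutation estimator; no
  multilevel refinement for extreme p-values, so resolution is bounded by
  the permutation count.
* The FDR family is tissues-within-gene; a global
  correction across genes × tissues is not applied by default.
* Proteomic missingness is treated as zero intensity (flagged by the share
  of zeros), which understates shares of sparsely observed proteins.
* Leading-edge reporting is meaningless for sample sets and is deliberately
  absent.

## A minimal worked example

```{r example, eval = FALSE}
spec <- synthetic_preset("gtex_like", seed = 1)
d <- generate_dataset(spec)
sh <- group_share_matrix(d$matrix, spec$groups$groups$ELONGATION,
                         group = "ELONGATION")
enr <- run_enrichment(sh, d$annotation,
                      perm_config(n_permutations = 4000, seed = 1),
                      group = "ELONGATION")
subset(enr, significant)
```

The numbered scripts under `analysis/` run the full sequence (simulate →
shares → enrichment → weighted totals) and write their tables under
`results/`.
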