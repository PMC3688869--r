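# mircohort

Cohort-scale analysis of small RNA (miRNA) sequencing data: from per-sample
genome alignments to per-miRNA counts, differential expression between
clinical groups, survival association, clustering, platform concordance and
gene-set over-representation — plus a calibrated synthetic cohort generator
with known ground truth, so every stage can be validated end to end.

## The scientific problem

Mature miRNAs are ~19–23 nt and many derive from near-identical paralogous
loci, so a large fraction of sequencing reads align to several genomic
positions at once. Naive counting either discards those reads (biasing
paralog families downward) or double-counts them. Downstream, the questions
are cohort-level: which miRNAs differ between tumor groups, which predict
survival, and how reproducible the measurements are across runs and
platforms.

## Core algorithms

**Quantification.** Reads aligning to ≥ 10 genomic loci are excluded. When a
read has a perfect-match alignment, its mismatched alignments are dropped. An
alignment "hits" a mature miRNA if it is fully contained in the mature
interval, same strand, ≤ 1 mismatch. Reads hitting exactly one miRNA are
unique; a read hitting the set *S* of miRNAs is split fractionally across
*S* in proportion to each member's unique-read count:

    count(i) += n_shared * u_i / sum(u_j, j in S)

**Differential expression.** A SAM-style two-class permutation test,
d = (x̄₂ − x̄₁)/(s + s₀), with the null built from exhaustive label
enumeration when feasible (otherwise distinct random permutations) and
per-feature q-values from permutation exceedance counts.

**Survival.** Per-miRNA univariate Cox proportional-hazards models
(`survival::coxph`) with Benjamini–Hochberg adjustment, and an L1-penalized
Cox model over all miRNAs (`glmnet`) with event-stratified cross-validation;
the one-standard-error rule is the default penalty choice because it selects
nothing on simulated null cohorts, as it should.

**Clustering & concordance.** WPGMA (weighted average linkage) on Euclidean
distances, implemented directly with deterministic tie-breaking and verified
against `hclust(method = "mcquitty")`; replicate and qRT-PCR (2^−ΔCt)
regressions.

**Enrichment.** One-sided hypergeometric over-representation of target lists
in GMT gene sets, with an optional EASE-style discounted overlap.

## Worked example

Simulate a 20-patient cohort in which `mir-0005` is planted at 4-fold higher
expression in male patients, quantify it, and test for the effect:

```r
library(mircohort)

cfg <- sim_config(n_mirnas = 100, n_samples = 20, reads_per_sample = 20000,
                  seed = 42,
                  planted_expression = data.frame(
                    mirna = "mir-0005", covariate = "sex", level = "male",
                    fold_change = 4))
ann <- generate_annotation(cfg)
coh <- generate_cohort(ann, cfg)

q    <- build_count_matrix(coh$alignments, ann)
norm <- normalize_counts(q$counts, normalization_factors(q$sample_stats, "mirna"))
filt <- low_count_filter(norm, select_on = q$counts)
expr <- log2_transform(filt)

# recovered counts track the generator's truth
mean(sapply(1:20, function(s) cor(q$counts[, s], coh$true_counts[, s])))
#> [1] 0.9998

top_n_share(filt, 5)$share
#> [1] 53.5

lab <- ifelse(coh$clinical$sex == "male", "male", "other")
sam <- sam_two_class(expr, lab, n_perm = 10000, seed = 1)
head(sam$table[order(sam$table$q), ], 3)
#>    feature       d q significant
#> 5 mir-0005 -21.500 0        TRUE
#> 1 mir-0001   0.241 1       FALSE
#> 2 mir-0002   0.452 1       FALSE

fc <- fold_change(norm, lab)
fc[fc$feature == "mir-0005", ]
#>    feature mean1 mean2 fold_change undefined
#> 5 mir-0005  7070  1794       -3.94     FALSE
```

The planted miRNA is the only significant hit, and the signed fold change
(−3.94, i.e. ~4-fold higher in the first group, males) recovers the planted
effect. Survival screening works the same way on `coh$survival`:

```r
os  <- coh$survival[coh$survival$endpoint == "os", ]
scr <- cox_screen(expr, os$time, os$event)   # per-miRNA Cox + BH
las <- lasso_cox(expr, os$time, os$event)    # penalized model, all miRNAs
```

## Package layout

- `R/sim_config.R`, `R/annotation.R`, `R/simcohort.R` — generator
- `R/quantify.R` — exclusion, precedence, hit and rescue rules
- `R/normfilter.R` — normalization factors, low-count filter, shares
- `R/samtest.R` — permutation test, s₀ selection, q-values, fold changes
- `R/survcox.R` — univariate and penalized Cox, BH
- `R/concordance.R` — WPGMA, Newick export, replicate/qRT-PCR regressions
- `R/enrich.R` — GMT parsing and hypergeometric over-representation
- `R/io.R` — SAM/BED/GFF3/TSV readers and writers
- `vignettes/mircohort-methods.Rmd` — full methods description
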