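test_that("config validation rejects malformed inputs", {
  expect_error(sim_config(class_props = c(mature = 0.5, premature = 0.1,
                                          snoRNA = 0.1, intergenic = 0.1)),
               "sum to 1")
  expect_error(sim_config(n_samples = 0), "positive")
  expect_error(sim_config(multimap_frac = 1.5), "\\[0, 1\\]")
  expect_error(sim_config(n_mirnas = 10, n_paralog_groups = 5), "too large")
  expect_error(
    sim_config(planted_expression = data.frame(mirna = "x", covariate = "y",
                                               fold_change = -2, level = "z")),
    "positive")
})

test_that("annotation is deterministic, clustered and nested", {
  cfg <- sim_config(n_mirnas = 40, n_clusters = 3, n_paralog_groups = 3,
                    seed = 11)
  a1 <- generate_annotation(cfg)
  a2 <- generate_annotation(cfg)
  expect_identical(as.data.frame(a1), as.data.frame(a2))

  mat <- mature_mirnas(a1)
  # every mature interval inside its own hairpin
  hp <- a1[a1$class == "premature_miRNA"]
  hp <- hp[match(paste0(mat$name, "-pre"), hp$name)]
  expect_true(all(GenomicRanges::start(mat) >= GenomicRanges::start(hp)))
  expect_true(all(GenomicRanges::end(mat) <= GenomicRanges::end(hp)))
  expect_true(all(GenomicRanges::width(mat) >= 18 &
                    GenomicRanges::width(mat) <= 25))

  # exactly n_clusters adjacent mature pairs closer than 10 kb
  st <- sort(GenomicRanges::start(mat))
  expect_identical(sum(diff(st) < 10000), 3L)
})

test_that("annotation placement fails loudly when the genome is too small", {
  cfg <- sim_config(n_mirnas = 40, genome_length = 1000)
  expect_error(generate_annotation(cfg), "cannot be placed")
})

test_that("cohort generation is deterministic and conserves reads", {
  tc <- tiny_cohort(seed = 5)
  coh2 <- generate_cohort(tc$ann, tc$cfg)
  expect_identical(coh2$true_counts, tc$cohort$true_counts)
  expect_identical(coh2$alignments, tc$cohort$alignments)
  expect_identical(coh2$survival, tc$cohort$survival)

  # column sums of true counts = miRNA-class reads emitted
  mat <- mature_mirnas(tc$ann)
  for (s in names(tc$cohort$alignments)) {
    aln <- tc$cohort$alignments[[s]]
    gr <- GenomicRanges::GRanges(aln$chrom,
                                 IRanges::IRanges(aln$start + 1L, aln$end),
                                 strand = aln$strand)
    ov <- GenomicRanges::findOverlaps(gr, mat, type = "within")
    n_mirna_reads <- length(unique(aln$read_id[S4Vectors::queryHits(ov)]))
    expect_identical(sum(tc$cohort$true_counts[, s]), n_mirna_reads)
  }
})

test_that("planted effects referencing unknown names error", {
  cfg <- sim_config(n_mirnas = 20, n_samples = 4, reads_per_sample = 500,
                    n_paralog_groups = 2, n_clusters = 1,
                    planted_expression = data.frame(
                      mirna = "not-a-mirna", covariate = "localization",
                      level = "right", fold_change = 2))
  ann <- generate_annotation(cfg)
  expect_error(generate_cohort(ann, cfg), "unknown miRNA")

  cfg2 <- sim_config(n_mirnas = 20, n_samples = 4, reads_per_sample = 500,
                     n_paralog_groups = 2, n_clusters = 1,
                     planted_expression = data.frame(
                       mirna = "mir-0001", covariate = "shoe_size",
                       level = "44", fold_change = 2))
  expect_error(generate_cohort(generate_annotation(cfg2), cfg2),
               "unknown covariate")
})

test_that("planted expression effects shift the expected profile where told", {
  pe <- data.frame(mirna = "mir-0003", covariate = "sex", level = "male",
                   fold_change = 4)
  tc <- tiny_cohort(seed = 9, n_samples = 20, planted_expression = pe)
  male <- tc$cohort$clinical$sex == "male"
  W <- tc$cohort$expression_weights
  base <- W["mir-0003", !male][1]
  # weight ratio before renormalization is exactly the fold change
  expect_true(all(W["mir-0003", male] / base > 3.5))
  expect_true(all(abs(W["mir-0003", !male] - base) < 1e-12))
})

test_that("survival generation hits the target event rate and planted hazards", {
  tc <- tiny_cohort(seed = 13, n_samples = 200, reads = 1000)
  sv <- tc$cohort$survival
  expect_true(all(sv$time > 0))
  expect_true(all(sv$event %in% 0:1))
  for (ep in c("os", "mfs")) {
    er <- mean(sv$event[sv$endpoint == ep])
    expect_gt(er, 0.35); expect_lt(er, 0.65)
  }
})

test_that("per-sample class fractions sum to one over retained reads", {
  tc <- tiny_cohort(seed = 3)
  q <- build_count_matrix(tc$cohort$alignments, tc$ann)
  sums <- rowSums(q$class_freq[, -1])
  expect_true(all(abs(sums - 1) < 1e-9))
})
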