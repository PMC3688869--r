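# helper to build alignment rows tersely
aln_row <- function(read, start, end, nm = 0, strand = "+", chrom = "chr1") {
  n <- length(read)
  data.frame(read_id = read, chrom = rep_len(chrom, n), start = start,
             end = end, strand = rep_len(strand, n), nm = rep_len(nm, n))
}

toy_annotation <- function() {
  gr <- GenomicRanges::GRanges(
    "chr1",
    IRanges::IRanges(start = c(101, 501, 81, 481, 901),
                     end = c(122, 522, 162, 562, 1000)),
    strand = c("+", "+", "+", "+", "+"),
    name = c("mirA", "mirB", "mirA-pre", "mirB-pre", "sno-1"),
    class = c("mature_miRNA", "mature_miRNA", "premature_miRNA",
              "premature_miRNA", "snoRNA"),
    paralog_group = c(1L, 1L, NA, NA, NA))
  GenomeInfoDb::seqlengths(gr) <- c(chr1 = 100000)
  gr
}

test_that("multi-locus exclusion uses a strict >= 10 loci rule", {
  ten <- do.call(rbind, lapply(1:10, function(i)
    aln_row("r1", 1000 * i, 1000 * i + 22)))
  nine <- do.call(rbind, lapply(1:9, function(i)
    aln_row("r2", 1000 * i, 1000 * i + 22)))
  res <- exclude_multilocus_reads(rbind(ten, nine))
  expect_identical(res$n_excluded, 1L)
  expect_setequal(unique(res$retained$read_id), "r2")

  # identical duplicate coordinates merge before counting loci
  dup <- rbind(ten, ten[1, ])
  expect_identical(exclude_multilocus_reads(dup)$n_excluded, 1L)

  empty <- aln_row(character(0), integer(0), integer(0))
  res0 <- exclude_multilocus_reads(empty)
  expect_identical(nrow(res0$retained), 0L)
  expect_identical(res0$n_excluded, 0L)
})

test_that("perfect-match precedence drops mismatched loci only when a perfect one exists", {
  mixed <- rbind(aln_row("r1", 100, 122, nm = 0),
                 aln_row("r1", 500, 522, nm = 1))
  out <- apply_perfect_match_precedence(mixed)
  expect_identical(nrow(out), 1L)
  expect_equal(out$nm, 0)

  allmm <- rbind(aln_row("r2", 100, 122, nm = 1),
                 aln_row("r2", 500, 522, nm = 1))
  expect_identical(apply_perfect_match_precedence(allmm), allmm)

  allperf <- rbind(aln_row("r3", 100, 122, nm = 0),
                   aln_row("r3", 500, 522, nm = 0))
  expect_identical(apply_perfect_match_precedence(allperf), allperf)
})

test_that("hit rule: containment, strand and the one-mismatch boundary", {
  ann <- toy_annotation()
  # mirA spans 1-based [101,122] -> 0-based half-open [100,122)
  inside_1mm <- aln_row("r1", 100, 122, nm = 1)
  expect_identical(annotate_reads(inside_1mm, ann)$r1, "mirA")
  inside_2mm <- aln_row("r2", 100, 122, nm = 2)
  expect_length(annotate_reads(inside_2mm, ann), 0)
  overhang <- aln_row("r3", 99, 121, nm = 0)   # 1 nt before the mature start
  expect_length(annotate_reads(overhang, ann), 0)
  wrong_strand <- aln_row("r4", 100, 122, nm = 0, strand = "-")
  expect_length(annotate_reads(wrong_strand, ann), 0)
  # empty annotation: empty hit sets, not an error
  empty_ann <- ann[0]
  expect_length(annotate_reads(inside_1mm, empty_ann), 0)
})

test_that("multimap assignment follows the unique-read ratio exactly", {
  got <- assign_multimapped(c(A = 6, B = 2),
                            list(list(members = c("A", "B"), count = 4)))
  expect_equal(got, c(A = 3, B = 1))

  expect_warning(
    eq <- assign_multimapped(c(A = 0, B = 0),
                             list(list(members = c("A", "B"), count = 4))),
    "no unique reads")
  expect_equal(eq, c(A = 2, B = 2))

  got3 <- assign_multimapped(c(A = 1, B = 1, C = 2),
                             list(list(members = c("A", "B", "C"), count = 8)))
  expect_equal(got3, c(A = 2, B = 2, C = 4))

  expect_error(assign_multimapped(c(A = 1), list(list(members = "Z", count = 1))),
               "unknown miRNA")
})

test_that("assigned mass is conserved and shares are monotone in unique counts", {
  set.seed(42)
  for (rep in 1:20) {
    k <- sample(2:4, 1)
    u <- stats::setNames(sample(0:30, k), LETTERS[1:k])
    n <- sample(0:20, 1)
    res <- suppressWarnings(
      assign_multimapped(u, list(list(members = names(u), count = n))))
    expect_lt(abs(sum(res) - n), 1e-9)
    # bumping one member's unique count never lowers its share
    u2 <- u; u2[1] <- u2[1] + 5
    res2 <- suppressWarnings(
      assign_multimapped(u2, list(list(members = names(u), count = n))))
    expect_gte(res2[1] + 1e-12, res[1])
  }
})

test_that("fractional assignment equals the randomized per-read expectation", {
  set.seed(99)
  u <- c(A = 3, B = 7, C = 1)
  n <- 17
  got <- assign_multimapped(u, list(list(members = names(u), count = n)))
  B <- 1e5
  draws <- stats::rmultinom(B, n, u / sum(u))
  mean_counts <- rowMeans(draws)
  se <- sqrt(n * (u / sum(u)) * (1 - u / sum(u)) / B)
  expect_true(all(abs(got - mean_counts) <= 3 * se))
})

test_that("count matrix handles identity, empty and degenerate samples", {
  ann <- toy_annotation()
  one <- aln_row("r1", 100, 122, nm = 0)
  q <- build_count_matrix(list(s1 = one), ann)
  expect_equal(q$counts["mirA", "s1"], 1.0)
  expect_equal(q$counts["mirB", "s1"], 0.0)

  # a sample with no miRNA-class reads: zero column, class row still sums to 1
  intergenic <- aln_row("r1", 50000, 50022, nm = 0)
  q2 <- build_count_matrix(list(s1 = intergenic), ann)
  expect_true(all(q2$counts[, "s1"] == 0))
  expect_equal(sum(q2$class_freq[1, -1]), 1)

  expect_error(build_count_matrix(list(s1 = one, s1 = one), ann),
               "duplicate sample")
})

test_that("full pipeline splits shared reads by the observed unique ratio", {
  ann <- toy_annotation()
  # 6 unique A, 2 unique B, 4 reads shared between A and B
  aln <- rbind(
    do.call(rbind, lapply(1:6, function(i) aln_row(paste0("uA", i), 100, 122))),
    do.call(rbind, lapply(1:2, function(i) aln_row(paste0("uB", i), 500, 522))),
    do.call(rbind, lapply(1:4, function(i)
      rbind(aln_row(paste0("m", i), 100, 122), aln_row(paste0("m", i), 500, 522)))))
  q <- build_count_matrix(list(s1 = aln), ann)
  expect_equal(q$counts["mirA", "s1"], 9)  # 6 + 4 * 6/8
  expect_equal(q$counts["mirB", "s1"], 3)  # 2 + 4 * 2/8
  expect_equal(q$sample_stats$mirna_mapped, 12)
})

test_that("read-mass conservation holds on generated cohorts", {
  tc <- tiny_cohort(seed = 21)
  q <- build_count_matrix(tc$cohort$alignments, tc$ann)
  for (s in seq_along(tc$cohort$alignments)) {
    n_in <- length(unique(tc$cohort$alignments[[s]]$read_id))
    st <- q$sample_stats[s, ]
    expect_equal(st$total_reads, n_in)
    # excluded + retained = input (class_freq covers retained reads)
    expect_true(st$excluded >= 0)
  }
  # recovered counts track the generator's truth closely
  r <- vapply(seq_len(ncol(q$counts)), function(s)
    stats::cor(q$counts[, s], tc$cohort$true_counts[, s]), 0)
  expect_true(all(r > 0.99))
})
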