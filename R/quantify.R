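#' @title Read counting for small RNA alignments
#' @description
#' The counting pipeline applies, in order: exclusion of reads mapping to 10
#' or more genomic loci; perfect-match precedence (alignments with mismatches
#' are discarded whenever the same read also aligns perfectly somewhere);
#' annotation of the surviving alignments against mature miRNA intervals
#' (full containment, same strand, at most one mismatch); unique counting;
#' and proportional rescue of reads hitting several mature miRNAs using the
#' ratio of uniquely mapped reads.
#' @name quantify
NULL

# alignment tables: data.frame(read_id, chrom, start [0-based], end [half-open],
# strand, nm); `length` optional

#' Exclude reads mapping to too many genomic loci
#'
#' A read is retained only when its number of distinct genomic loci is
#' strictly below `max_loci`; with the default of 10, reads mapping to 10 or
#' more regions are discarded. Identical (chrom, start, end, strand)
#' duplicates are merged before counting loci.
#'
#' @param alignments Alignment data frame for one sample.
#' @param max_loci Loci threshold; reads with `>= max_loci` loci are dropped.
#' @return `list(retained = <data frame>, n_excluded = <count of reads>)`.
#' @export
exclude_multilocus_reads <- function(alignments, max_loci = 10) {
  if (nrow(alignments) == 0)
    return(list(retained = alignments, n_excluded = 0L))
  key <- paste(alignments$chrom, alignments$start, alignments$end,
               alignments$strand, sep = ":")
  dedup <- !duplicated(paste(alignments$read_id, key, sep = "|"))
  n_loci <- table(alignments$read_id[dedup])
  bad <- names(n_loci)[n_loci >= max_loci]
  list(retained = alignments[!alignments$read_id %in% bad, , drop = FALSE],
       n_excluded = length(bad))
}

#' Keep only perfect alignments for reads that have any
#'
#' When a read aligns perfectly (0 mismatches) to at least one locus, all of
#' its mismatched alignments are dropped; reads with no perfect alignment are
#' untouched.
#'
#' @param alignments Alignment data frame (any number of reads).
#' @return The filtered alignment data frame.
#' @export
apply_perfect_match_precedence <- function(alignments) {
  if (nrow(alignments) == 0) return(alignments)
  has_perfect <- alignments$read_id %in%
    alignments$read_id[alignments$nm == 0]
  alignments[!(has_perfect & alignments$nm > 0), , drop = FALSE]
}

#' Mature miRNA hits per read
#'
#' An alignment is a candidate hit when its interval is fully contained in a
#' mature miRNA interval on the same strand and carries at most `max_mismatch`
#' mismatches. Returns the set of distinct mature miRNAs hit by each read.
#'
#' @param alignments Alignment data frame (precedence already applied).
#' @param annotation An annotation `GRanges` (with a `class` column).
#' @param max_mismatch Maximum mismatches for a hit (default 1).
#' @return Named list: for each read id with at least one hit, the character
#'   vector of distinct mature miRNA names.
#' @export
annotate_reads <- function(alignments, annotation, max_mismatch = 1) {
  mat <- mature_mirnas(annotation)
  if (nrow(alignments) == 0 || length(mat) == 0)
    return(stats::setNames(list(), character(0)))
  ok <- alignments$nm <= max_mismatch
  aln <- alignments[ok, , drop = FALSE]
  if (nrow(aln) == 0) return(stats::setNames(list(), character(0)))
  gr <- GenomicRanges::GRanges(aln$chrom,
                               IRanges::IRanges(aln$start + 1L, aln$end),
                               strand = aln$strand)
  hits <- GenomicRanges::findOverlaps(gr, mat, type = "within")
  if (length(hits) == 0) return(stats::setNames(list(), character(0)))
  lapply(split(mat$name[S4Vectors::subjectHits(hits)],
               aln$read_id[S4Vectors::queryHits(hits)]), unique)
}

#' Proportional assignment of multi-mapped reads
#'
#' Reads shared by several mature miRNAs are divided according to the ratio of
#' uniquely mapped reads of those miRNAs: a group `G` with shared count `n`
#' and unique counts `u_i` gives miRNA `i` the fractional mass `n * u_i /
#' sum(u)`. When no member has unique reads the mass is split equally (with a
#' warning). Total assigned mass equals the total shared count exactly.
#'
#' @param unique_counts Named numeric vector of per-miRNA unique read counts.
#' @param multimap_groups List of `list(members = <character>, count = <n>)`.
#' @return Named numeric vector (same names as `unique_counts`) of the
#'   fractional counts assigned from the shared reads.
#' @export
#' @examples
#' assign_multimapped(c(A = 6, B = 2),
#'                    list(list(members = c("A", "B"), count = 4)))
assign_multimapped <- function(unique_counts, multimap_groups) {
  out <- stats::setNames(numeric(length(unique_counts)), names(unique_counts))
  for (g in multimap_groups) {
    unknown <- setdiff(g$members, names(unique_counts))
    if (length(unknown))
      stop("multimap group names unknown miRNA: ",
           paste(unknown, collapse = ", "))
    u <- unique_counts[g$members]
    if (sum(u) > 0) {
      out[g$members] <- out[g$members] + g$count * u / sum(u)
    } else {
      warning("multimap group {", paste(g$members, collapse = ","),
              "} has no unique reads; splitting ", g$count, " reads equally")
      out[g$members] <- out[g$members] + g$count / length(g$members)
    }
  }
  out
}

#' Build the raw miRNA count matrix and RNA-class frequency table
#'
#' Runs the full per-sample counting pipeline (exclusion, precedence,
#' annotation, unique counting, proportional multimap assignment) and
#' classifies every retained read into one RNA class with the priority
#' mature miRNA > premature miRNA > other annotated classes >
#' intronic/intergenic.
#'
#' @param alignments Named list of per-sample alignment data frames.
#' @param annotation An annotation `GRanges` (with a `class` column).
#' @param max_loci Passed to [exclude_multilocus_reads()].
#' @param max_mismatch Passed to [annotate_reads()].
#' @return A list of class `mir_quant`:
#'   \describe{
#'   \item{counts}{numeric matrix miRNA x sample (fractional after multimap
#'     assignment).}
#'   \item{class_freq}{data frame, one row per sample, of per-class read
#'     fractions (rows sum to 1 over retained reads).}
#'   \item{sample_stats}{per-sample denominators for normalization:
#'     `total_reads`, `genome_aligned_multi`, `genome_aligned_unique`,
#'     `mirna_mapped`, plus `excluded` (reads dropped by the locus filter).}
#'   }
#' @export
build_count_matrix <- function(alignments, annotation, max_loci = 10,
                               max_mismatch = 1) {
  if (anyDuplicated(names(alignments)))
    stop("duplicate sample ids in alignments")
  mat <- mature_mirnas(annotation)
  mir_names <- mat$name
  classes <- c("mature_miRNA", "premature_miRNA", "snoRNA",
               "intronic_intergenic")
  counts <- matrix(0, length(mir_names), length(alignments),
                   dimnames = list(mir_names, names(alignments)))
  class_freq <- matrix(0, length(alignments), length(classes),
                       dimnames = list(names(alignments), classes))
  stats_df <- data.frame(sample = names(alignments), total_reads = 0,
                         genome_aligned_multi = 0, genome_aligned_unique = 0,
                         mirna_mapped = 0, excluded = 0)

  other_ann <- annotation[annotation$class %in%
                            setdiff(unique(annotation$class), "mature_miRNA")]

  for (s in seq_along(alignments)) {
    aln <- alignments[[s]]
    n_total <- length(unique(aln$read_id))
    key <- paste(aln$chrom, aln$start, aln$end, aln$strand, sep = ":")
    dedup <- !duplicated(paste(aln$read_id, key, sep = "|"))
    loci_per_read <- table(aln$read_id[dedup])
    n_unique_locus <- sum(loci_per_read == 1)

    ex <- exclude_multilocus_reads(aln, max_loci)
    aln2 <- apply_perfect_match_precedence(ex$retained)
    hit_sets <- annotate_reads(aln2, annotation, max_mismatch)

    n_hits <- lengths(hit_sets)
    uniq <- unlist(hit_sets[n_hits == 1], use.names = FALSE)
    u_counts <- stats::setNames(numeric(length(mir_names)), mir_names)
    tab <- table(uniq)
    u_counts[names(tab)] <- as.numeric(tab)

    multi <- hit_sets[n_hits > 1]
    groups <- list()
    if (length(multi)) {
      keys <- vapply(multi, function(m) paste(sort(m), collapse = "\r"), "")
      kt <- table(keys)
      groups <- lapply(names(kt), function(k)
        list(members = strsplit(k, "\r", fixed = TRUE)[[1]],
             count = as.numeric(kt[[k]])))
    }
    assigned <- assign_multimapped(u_counts, groups)
    counts[, s] <- u_counts + assigned

    # class per retained read: mature > premature > other > intergenic
    retained_ids <- unique(aln2$read_id)
    cls <- classify_reads(aln2, retained_ids, names(hit_sets), other_ann,
                          max_mismatch)
    tab_c <- table(factor(cls, levels = classes))
    n_ret <- length(retained_ids)
    class_freq[s, ] <- if (n_ret > 0) as.numeric(tab_c) / n_ret else 0

    stats_df$total_reads[s] <- n_total
    stats_df$genome_aligned_multi[s] <- n_total
    stats_df$genome_aligned_unique[s] <- n_unique_locus
    stats_df$mirna_mapped[s] <- sum(u_counts) + sum(assigned)
    stats_df$excluded[s] <- ex$n_excluded
  }

  structure(list(counts = counts,
                 class_freq = data.frame(sample = rownames(class_freq),
                                         class_freq, row.names = NULL,
                                         check.names = FALSE),
                 sample_stats = stats_df),
            class = "mir_quant")
}

# one class per read; containment against non-mature features decides the rest
classify_reads <- function(aln, read_ids, mirna_read_ids, other_ann,
                           max_mismatch) {
  cls <- stats::setNames(rep("intronic_intergenic", length(read_ids)),
                         read_ids)
  cls[read_ids %in% mirna_read_ids] <- "mature_miRNA"
  rest <- aln[!aln$read_id %in% mirna_read_ids, , drop = FALSE]
  if (nrow(rest) > 0 && length(other_ann) > 0) {
    gr <- GenomicRanges::GRanges(rest$chrom,
                                 IRanges::IRanges(rest$start + 1L, rest$end),
                                 strand = rest$strand)
    ov <- GenomicRanges::findOverlaps(gr, other_ann, type = "within")
    if (length(ov)) {
      hit_cls <- other_ann$class[S4Vectors::subjectHits(ov)]
      rid <- rest$read_id[S4Vectors::queryHits(ov)]
      # priority: premature before any other annotated class
      p <- c(premature_miRNA = 1, snoRNA = 2)[hit_cls]
      p[is.na(p)] <- 3
      ord <- order(p)
      best <- tapply(hit_cls[ord], rid[ord], function(x) x[1])
      cls[names(best)] <- unname(best)
    }
  }
  cls
}

#' @export
print.mir_quant <- function(x, ...) {
  cat("miRNA count matrix:", nrow(x$counts), "miRNAs x",
      ncol(x$counts), "samples\n")
  cat("  median mature miRNA read fraction:",
      round(stats::median(x$class_freq$mature_miRNA), 3), "\n")
  invisible(x)
}
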