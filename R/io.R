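#' Write per-sample alignments as SAM
#'
#' Minimal single-end SAM with the mismatch count in the `NM` tag. Sequences
#' and qualities are not modelled (`*` placeholders); multi-mapped reads
#' appear as one primary record plus secondary records (flag 0x100).
#'
#' @param alignments Alignment data frame (`read_id`, `chrom`, `start`
#'   0-based, `end`, `strand`, `nm`).
#' @param path Output `.sam` path.
#' @param seqlengths Named vector of reference lengths for the header.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, path, seqlengths) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths),
                       as.integer(seqlengths))), con)
  if (nrow(alignments) > 0) {
    a <- alignments
    secondary <- duplicated(a$read_id)
    flag <- ifelse(a$strand == "-", 16L, 0L) + ifelse(secondary, 256L, 0L)
    len <- a$end - a$start
    writeLines(sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t*\t*\tNM:i:%d",
                       a$read_id, flag, a$chrom, a$start + 1L,
                       ifelse(secondary, 0L, 60L), len, a$nm), con)
  }
  invisible(path)
}

#' Read alignments from SAM/BAM into the package's alignment table
#'
#' SAM files are converted to BAM on the fly. The `NM` tag supplies the
#' mismatch count; records without it are treated as perfect matches with a
#' warning. Secondary alignments are kept (they encode multi-mapping).
#'
#' @param path A `.sam` or `.bam` file.
#' @return Alignment data frame (`read_id`, `chrom`, `start` 0-based, `end`,
#'   `strand`, `nm`, `length`).
#' @export
read_sam <- function(path) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  res <- Rsamtools::scanBam(
    bam, param = Rsamtools::ScanBamParam(
      what = c("qname", "rname", "pos", "qwidth", "strand", "cigar"),
      tag = "NM"))[[1]]
  wid <- GenomicAlignments_width(res$cigar)
  nm <- res$tag$NM
  if (is.null(nm)) nm <- rep(NA_integer_, length(res$qname))
  if (anyNA(nm)) {
    warning(sum(is.na(nm)), " record(s) without NM tag treated as 0 mismatches")
    nm[is.na(nm)] <- 0L
  }
  data.frame(read_id = res$qname,
             chrom = as.character(res$rname),
             start = res$pos - 1L,
             end = res$pos - 1L + wid,
             strand = as.character(res$strand),
             nm = nm,
             length = wid)
}

# reference width from simple CIGARs (our writer emits <n>M only)
GenomicAlignments_width <- function(cigar) {
  as.integer(sub("M$", "", cigar))
}

#' Write / read a count matrix as TSV
#'
#' Rows are miRNAs, columns samples; the first column holds the miRNA name.
#'
#' @param mat Numeric matrix with dimnames.
#' @param path File path.
#' @return `write_count_matrix` returns `path` invisibly; `read_count_matrix`
#'   returns the matrix.
#' @export
write_count_matrix <- function(mat, path) {
  df <- data.frame(mirna = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write a cohort to disk as plain-text files
#'
#' Annotation as BED (+ optional GFF3), per-sample alignments as SAM,
#' clinical covariates, survival outcomes and true counts as TSV.
#'
#' @param cohort A `mir_cohort` from [generate_cohort()].
#' @param annotation The matching annotation `GRanges`.
#' @param dir Output directory (created if needed).
#' @param gff3 Also write the annotation as GFF3 (default `FALSE`).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, annotation, dir, gff3 = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_annotation_bed(annotation, file.path(dir, "annotation.bed"))
  if (gff3) write_annotation_gff3(annotation, file.path(dir, "annotation.gff3"))
  sl <- GenomeInfoDb::seqlengths(annotation)
  for (s in names(cohort$alignments))
    write_sam(cohort$alignments[[s]], file.path(dir, paste0(s, ".sam")), sl)
  utils::write.table(cohort$clinical, file.path(dir, "clinical.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$survival, file.path(dir, "survival.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_count_matrix(cohort$true_counts, file.path(dir, "true_counts.tsv"))
  invisible(dir)
}
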