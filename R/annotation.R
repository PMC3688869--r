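#' Generate a synthetic small-RNA annotation
#'
#' Lays out mature miRNA intervals (each enclosed in a precursor hairpin),
#' snoRNA genes and intergenic space along a single synthetic chromosome.
#' `n_clusters` pairs of miRNA genes are placed fewer than 10,000 nt apart,
#' mimicking polycistronic miRNA gene clusters; all other neighbouring
#' features are separated by more than 10,000 nt. A subset of mature miRNAs
#' is organised into paralog groups of 2-4 members with identical mature
#' widths, representing paralogous miRNAs that share an identical mature
#' subsequence and therefore attract multi-mapped reads.
#'
#' @param config A [sim_config()] object.
#' @return A [GenomicRanges::GRanges] with metadata columns `name`, `class`
#'   (`mature_miRNA`, `premature_miRNA`, `snoRNA`) and `paralog_group`
#'   (integer, `NA` outside groups). Coordinates are 1-based closed, the
#'   native `GRanges` convention.
#' @export
#' @examples
#' ann <- generate_annotation(sim_config(n_mirnas = 20, n_clusters = 2))
#' table(ann$class)
generate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 17L)
  n <- config$n_mirnas

  # mature widths 21-25 nt; paralog group members share one width
  widths <- sample(21:25, n, replace = TRUE)
  paralog_group <- rep(NA_integer_, n)
  pool <- sample.int(n)
  gi <- 1L
  for (g in seq_len(config$n_paralog_groups)) {
    size <- sample(2:4, 1)
    members <- pool[gi:(gi + size - 1L)]
    gi <- gi + size
    paralog_group[members] <- g
    widths[members] <- widths[members[1]]
  }

  # cluster pairs drawn from miRNAs not already used up by anything else
  cluster_members <- matrix(sample(setdiff(seq_len(n), integer(0)),
                                   2L * config$n_clusters), ncol = 2)

  pad_l <- sample(30:60, n, replace = TRUE)
  pad_r <- sample(30:60, n, replace = TRUE)

  # layout units: single hairpins, clustered hairpin pairs, snoRNAs
  in_cluster <- seq_len(n) %in% as.vector(cluster_members)
  n_sno <- max(10L, n %/% 15L)
  sno_w <- sample(60:150, n_sno, replace = TRUE)

  units <- c(lapply(which(!in_cluster), function(i) list(type = "mir", i = i)),
             lapply(seq_len(config$n_clusters),
                    function(k) list(type = "cluster", i = cluster_members[k, ])),
             lapply(seq_len(n_sno), function(j) list(type = "sno", i = j)))
  units <- units[sample.int(length(units))]

  hp_start <- hp_end <- mat_start <- mat_end <- integer(n)
  sno_start <- integer(n_sno)
  pos <- 10000L
  for (u in units) {
    pos <- pos + sample(12000:20000, 1)  # > 10 kb keeps non-cluster pairs apart
    if (u$type == "mir") {
      i <- u$i
      hp_start[i] <- pos
      mat_start[i] <- pos + pad_l[i]
      mat_end[i] <- mat_start[i] + widths[i] - 1L
      hp_end[i] <- mat_end[i] + pad_r[i]
      pos <- hp_end[i]
    } else if (u$type == "cluster") {
      for (k in seq_along(u$i)) {
        i <- u$i[k]
        if (k > 1) pos <- pos + sample(1000:5000, 1)  # < 10 kb within cluster
        hp_start[i] <- pos
        mat_start[i] <- pos + pad_l[i]
        mat_end[i] <- mat_start[i] + widths[i] - 1L
        hp_end[i] <- mat_end[i] + pad_r[i]
        pos <- hp_end[i]
      }
    } else {
      j <- u$i
      sno_start[j] <- pos
      pos <- pos + sno_w[j]
    }
  }
  total_len <- pos + 15000L
  if (!is.null(config$genome_length)) {
    if (config$genome_length < total_len)
      stop("config infeasible: features cannot be placed in genome_length = ",
           config$genome_length, " (need ", total_len, ")")
    total_len <- as.integer(config$genome_length)
  }

  strand_mir <- sample(c("+", "-"), n, replace = TRUE)
  strand_sno <- sample(c("+", "-"), n_sno, replace = TRUE)
  mir_names <- sprintf("mir-%04d", seq_len(n))

  gr <- GenomicRanges::GRanges(
    seqnames = "chr1",
    ranges = IRanges::IRanges(
      start = c(mat_start, hp_start, sno_start),
      end = c(mat_end, hp_end, sno_start + sno_w - 1L)),
    strand = c(strand_mir, strand_mir, strand_sno),
    name = c(mir_names, paste0(mir_names, "-pre"),
             sprintf("sno-%03d", seq_len(n_sno))),
    class = rep(c("mature_miRNA", "premature_miRNA", "snoRNA"),
                c(n, n, n_sno)),
    paralog_group = c(paralog_group, rep(NA_integer_, n + n_sno)))
  GenomeInfoDb::seqlengths(gr) <- c(chr1 = total_len)
  gr
}

#' Mature miRNA intervals of an annotation
#' @param annotation A `GRanges` annotation with a `class` metadata column.
#' @return The subset of ranges whose class is `mature_miRNA`.
#' @export
mature_mirnas <- function(annotation) {
  annotation[annotation$class == "mature_miRNA"]
}

#' Write / read an annotation as BED with a class column
#'
#' BED uses 0-based half-open coordinates. Two extra columns carry the RNA
#' class and the paralog group id (`.` when absent).
#'
#' @param annotation An annotation `GRanges` (with a `class` column).
#' @param path Output/input file path.
#' @return `write_annotation_bed` returns `path` invisibly;
#'   `read_annotation_bed` returns the annotation as a `GRanges`.
#' @export
write_annotation_bed <- function(annotation, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(annotation)),
    start = GenomicRanges::start(annotation) - 1L,  # to 0-based half-open
    end = GenomicRanges::end(annotation),
    name = annotation$name,
    score = 0L,
    strand = as.character(GenomicRanges::strand(annotation)),
    class = annotation$class,
    paralog_group = ifelse(is.na(annotation$paralog_group), ".",
                           as.character(annotation$paralog_group)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation_bed
#' @export
read_annotation_bed <- function(path) {
  gr <- rtracklayer::import(
    path, format = "bed",
    extraCols = c(class = "character", paralog_group = "character"))
  gr$paralog_group <- suppressWarnings(as.integer(gr$paralog_group))
  gr$score <- NULL
  gr
}

#' Write an annotation as miRBase-style GFF3
#'
#' 1-based closed coordinates; mature and precursor records carry their class
#' in the `type` field and the paralog group as an attribute.
#'
#' @inheritParams write_annotation_bed
#' @export
write_annotation_gff3 <- function(annotation, path) {
  gr <- annotation
  names(S4Vectors::mcols(gr))[names(S4Vectors::mcols(gr)) == "class"] <- "type"
  gr$type <- c(mature_miRNA = "miRNA", premature_miRNA = "miRNA_primary_transcript",
               snoRNA = "snoRNA")[gr$type]
  gr$ID <- gr$name
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
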