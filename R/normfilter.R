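#' Per-sample normalization factor
#'
#' The factor is the chosen denominator read count divided by one million, so
#' dividing a raw count by it yields reads per million on that denominator.
#'
#' @param denominator_reads Read count(s), all strictly positive.
#' @return Numeric factor(s), `denominator_reads / 1e6`.
#' @export
normalization_factor <- function(denominator_reads) {
  bad <- which(denominator_reads <= 0)
  if (length(bad))
    stop("zero/negative denominator for sample(s): ",
         paste(if (!is.null(names(denominator_reads))) names(denominator_reads)[bad]
               else bad, collapse = ", "))
  denominator_reads / 1e6
}

#' Normalization factors for all four denominators of a quantified cohort
#'
#' @param sample_stats The `sample_stats` data frame of a [build_count_matrix()]
#'   result.
#' @param method One of `"total"` (all sequenced reads), `"genome_multi"`
#'   (reads aligned to the genome allowing multiple hits), `"genome_unique"`
#'   (reads aligned to a single locus), `"mirna"` (reads assigned to annotated
#'   mature miRNAs).
#' @return Named numeric vector of per-sample factors.
#' @export
normalization_factors <- function(sample_stats,
                                  method = c("mirna", "total", "genome_multi",
                                             "genome_unique")) {
  method <- match.arg(method)
  col <- c(total = "total_reads", genome_multi = "genome_aligned_multi",
           genome_unique = "genome_aligned_unique",
           mirna = "mirna_mapped")[[method]]
  normalization_factor(stats::setNames(sample_stats[[col]],
                                       sample_stats$sample))
}

#' Normalize a count matrix by per-sample factors
#'
#' @param counts miRNA x sample matrix of raw counts.
#' @param factors Named per-sample factors from [normalization_factors()].
#' @return Matrix of normalized expression values (reads per million on the
#'   chosen denominator).
#' @export
normalize_counts <- function(counts, factors) {
  missing <- setdiff(colnames(counts), names(factors))
  if (length(missing))
    stop("no normalization factor for sample(s): ",
         paste(missing, collapse = ", "))
  sweep(counts, 2, factors[colnames(counts)], "/")
}

#' Zero out miRNAs below the expression threshold
#'
#' A miRNA whose read count summed across all samples is below `threshold` is
#' set to zero in every sample; such miRNAs are considered "not expressed".
#' With `rule = "per_sample"` a miRNA is instead zeroed when no single sample
#' reaches the threshold. The decision can be taken on a different matrix
#' than the one being zeroed (`select_on`), e.g. decide on raw counts and
#' apply to the normalized matrix.
#'
#' @param mat Matrix to zero (usually normalized expression).
#' @param threshold Read-count threshold (default 10).
#' @param rule `"sum"` (default): zero when the row sum is `< threshold`;
#'   `"per_sample"`: zero when every sample is `< threshold`.
#' @param select_on Optional matrix (same dimnames) on which the filter
#'   decision is computed; defaults to `mat` itself.
#' @return `mat` with the failing rows zeroed; the zeroed miRNA names are in
#'   `attr(, "zeroed")`.
#' @export
low_count_filter <- function(mat, threshold = 10, rule = c("sum", "per_sample"),
                             select_on = NULL) {
  rule <- match.arg(rule)
  basis <- if (is.null(select_on)) mat else select_on
  stopifnot(identical(dim(basis), dim(mat)))
  drop <- if (rule == "sum") rowSums(basis) < threshold
          else apply(basis, 1, max) < threshold
  mat[drop, ] <- 0
  attr(mat, "zeroed") <- rownames(mat)[drop]
  mat
}

#' Names of expressed miRNAs (rows not identically zero)
#' @param mat Expression matrix.
#' @return Character vector of row names with any nonzero value.
#' @export
expressed_mirnas <- function(mat) {
  rownames(mat)[rowSums(mat != 0) > 0]
}

#' Log2 transform with a pseudocount
#'
#' `x -> log2(x + pseudocount)`; with the default pseudocount of 1, zeros map
#' to zero.
#'
#' @param mat Non-negative matrix.
#' @param pseudocount Added before taking logs (default 1).
#' @return Transformed matrix.
#' @export
log2_transform <- function(mat, pseudocount = 1) {
  if (any(mat < 0)) stop("log2_transform requires non-negative values")
  log2(mat + pseudocount)
}

#' Expression share of the top-n miRNAs
#'
#' Ranks miRNAs by total (or median) expression over samples and reports the
#' percentage of all miRNA reads carried by the top `n`.
#'
#' @param mat miRNA x sample count matrix (raw or normalized).
#' @param n Number of top miRNAs.
#' @param statistic Ranking statistic: `"total"` (default) or `"median"`
#'   across samples. The share itself is always computed on totals.
#' @return `list(share = <percentage>, mirnas = <ranked character vector>)`.
#' @export
top_n_share <- function(mat, n, statistic = c("total", "median")) {
  statistic <- match.arg(statistic)
  tot <- rowSums(mat)
  if (sum(tot) == 0) stop("top_n_share: all-zero matrix")
  rank_stat <- if (statistic == "total") tot else apply(mat, 1, stats::median)
  ord <- order(rank_stat, decreasing = TRUE)
  top <- ord[seq_len(min(n, nrow(mat)))]
  list(share = 100 * sum(tot[top]) / sum(tot),
       mirnas = rownames(mat)[top])
}

#' Mean percent difference between normalization methods
#'
#' For every pair of the four denominators, normalizes the matrix with each,
#' computes per-miRNA totals over samples, and reports the mean over miRNAs of
#' the symmetric percent difference `|a - b| / ((a + b)/2) * 100`.
#'
#' @param counts Raw miRNA x sample count matrix.
#' @param sample_stats `sample_stats` from [build_count_matrix()].
#' @return Symmetric matrix of mean percent differences, methods x methods.
#' @export
compare_normalization_methods <- function(counts, sample_stats) {
  methods <- c("total", "genome_multi", "genome_unique", "mirna")
  totals <- sapply(methods, function(m) {
    rowSums(normalize_counts(counts, normalization_factors(sample_stats, m)))
  })
  out <- matrix(0, 4, 4, dimnames = list(methods, methods))
  for (i in 1:3) for (j in (i + 1):4) {
    a <- totals[, i]; b <- totals[, j]
    keep <- (a + b) > 0
    out[i, j] <- out[j, i] <-
      mean(abs(a[keep] - b[keep]) / ((a[keep] + b[keep]) / 2) * 100)
  }
  out
}
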