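#' Euclidean distance matrix over rows or columns
#'
#' @param mat Complete numeric matrix (no missing values).
#' @param axis `"rows"` (default) or `"columns"`.
#' @return A symmetric `matrix` of Euclidean distances with a zero diagonal.
#' @export
euclidean_distances <- function(mat, axis = c("rows", "columns")) {
  axis <- match.arg(axis)
  if (anyNA(mat)) stop("euclidean_distances: matrix contains missing values")
  m <- if (axis == "rows") mat else t(mat)
  if (nrow(m) < 2) stop("need at least 2 items on the chosen axis")
  as.matrix(stats::dist(m, method = "euclidean"))
}

#' WPGMA (weighted average linkage) hierarchical clustering
#'
#' Agglomerative clustering with the weighted pair-group update
#' `d(A+B, C) = (d(A, C) + d(B, C)) / 2`. Ties in the minimum distance are
#' broken deterministically by the smallest pair of node indices (leaves in
#' input order, merged nodes in order of creation). The result is a standard
#' `hclust` object (usable with `plot`, `cutree`, `as.dendrogram`).
#'
#' @param d Symmetric distance matrix (or `dist`) with zero diagonal.
#' @return An object of class `hclust` with the full merge history.
#' @export
#' @examples
#' d <- matrix(c(0, 1, 4, 1, 0, 4, 4, 4, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' h <- wpgma_cluster(d)
#' h$height   # 1, 4
wpgma_cluster <- function(d) {
  d <- as.matrix(d)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-12)))
    stop("wpgma_cluster: distance matrix must be symmetric")
  n <- nrow(d)
  stopifnot(n >= 2)
  labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(n))

  # node bookkeeping: negative = leaf, positive = merge step
  id <- -seq_len(n)           # hclust codes for active nodes
  rank <- seq_len(n)          # creation order, used for tie-breaking
  next_rank <- n + 1L
  active <- rep(TRUE, n + 0L)
  D <- d
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)

  for (step in seq_len(n - 1)) {
    act <- which(active)
    best <- NULL; best_d <- Inf
    for (ii in seq_along(act)[-length(act)]) {
      for (jj in (ii + 1):length(act)) {
        a <- act[ii]; b <- act[jj]
        # order the candidate pair by node rank for the tie-break
        r <- sort(c(rank[a], rank[b]))
        dv <- D[a, b]
        if (dv < best_d - 1e-15 ||
            (abs(dv - best_d) <= 1e-15 && !is.null(best) &&
             (r[1] < best$r[1] || (r[1] == best$r[1] && r[2] < best$r[2])))) {
          best <- list(a = a, b = b, r = r); best_d <- dv
        }
      }
    }
    a <- best$a; b <- best$b
    # hclust convention: put the lower code first (leaves before merges)
    pair <- sort(c(id[a], id[b]))
    merge[step, ] <- pair
    height[step] <- best_d
    # WPGMA update stored in slot `a`; slot `b` retired
    for (k in which(active)) if (k != a && k != b) {
      D[a, k] <- D[k, a] <- (D[a, k] + D[b, k]) / 2
    }
    active[b] <- FALSE
    id[a] <- step
    rank[a] <- next_rank; next_rank <- next_rank + 1L
  }

  structure(list(merge = merge, height = height,
                 order = hclust_order(merge), labels = labels,
                 method = "wpgma", dist.method = "euclidean",
                 call = match.call()),
            class = "hclust")
}

# left-to-right leaf order from an hclust merge matrix
hclust_order <- function(merge) {
  walk <- function(i) {
    if (i < 0) return(-i)
    c(walk(merge[i, 1]), walk(merge[i, 2]))
  }
  walk(nrow(merge))
}

#' Two-way clustering of an expression matrix
#'
#' Independent WPGMA clusterings of the rows (miRNAs) and columns (samples)
#' of a log2 expression matrix, the arrangement behind a standard clustered
#' heatmap.
#'
#' @param mat Log2 expression matrix.
#' @return `list(rows = <hclust>, columns = <hclust>)`.
#' @export
two_way_cluster <- function(mat) {
  list(rows = wpgma_cluster(euclidean_distances(mat, "rows")),
       columns = wpgma_cluster(euclidean_distances(mat, "columns")))
}

#' Serialize a dendrogram as a Newick tree
#'
#' @param hc An `hclust` object.
#' @param path Optional file path; when `NULL` the Newick string is returned.
#' @return The Newick string (invisibly when written to file).
#' @export
as_newick <- function(hc, path = NULL) {
  tr <- ape::as.phylo(hc)
  if (is.null(path)) return(ape::write.tree(tr))
  ape::write.tree(tr, file = path)
  invisible(ape::write.tree(tr))
}

#' Technical-replicate concordance
#'
#' Ordinary least-squares regression of one sequencing run on the other,
#' computed on per-miRNA totals (normalized and log2 transformed).
#'
#' @param totals_run1,totals_run2 Numeric vectors over the same miRNAs.
#' @return `list(slope, intercept, r_squared, n)`.
#' @export
replicate_concordance <- function(totals_run1, totals_run2) {
  stopifnot(length(totals_run1) == length(totals_run2))
  if (length(totals_run1) < 3)
    stop("replicate_concordance: need at least 3 points")
  fit <- stats::lm(totals_run2 ~ totals_run1)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared,
       n = length(totals_run1))
}

#' Relative expression from qRT-PCR Ct values
#'
#' The 2^-dCt method against a reference assay: `2^-(Ct_target - Ct_ref)`.
#' Undetected targets (`NA` Ct) propagate as `NA`, never as zero.
#'
#' @param ct_target Ct values of the target miRNA.
#' @param ct_reference Ct values of the reference RNA (e.g. RNU44).
#' @return Relative expression values.
#' @export
delta_ct_expression <- function(ct_target, ct_reference) {
  2^(-(ct_target - ct_reference))
}

#' Cross-platform regression of sequencing on qRT-PCR
#'
#' Per-assay ordinary least-squares R-squared between paired per-sample
#' values from the two platforms, plus each platform's summed expression.
#'
#' @param qpcr Samples x assays matrix of qRT-PCR values (normalized Ct or
#'   2^-dCt); `NA` marks undetected measurements.
#' @param seq Samples x assays matrix of log2 sequencing values, same
#'   dimnames.
#' @return Data frame `assay`, `r_squared`, `n`, `sum_qpcr`, `sum_seq`;
#'   all-missing assays are skipped with a warning.
#' @export
platform_regression <- function(qpcr, seq) {
  stopifnot(identical(dim(qpcr), dim(seq)))
  assays <- colnames(qpcr)
  if (is.null(assays)) assays <- as.character(seq_len(ncol(qpcr)))
  rows <- lapply(seq_len(ncol(qpcr)), function(j) {
    ok <- !is.na(qpcr[, j]) & !is.na(seq[, j])
    if (sum(ok) < 3) {
      warning("assay ", assays[j], " has fewer than 3 paired values; skipped")
      return(NULL)
    }
    r2 <- if (stats::sd(seq[ok, j]) == 0 || stats::sd(qpcr[ok, j]) == 0) 0
          else summary(stats::lm(seq[ok, j] ~ qpcr[ok, j]))$r.squared
    data.frame(assay = assays[j], r_squared = r2, n = sum(ok),
               sum_qpcr = sum(qpcr[ok, j]), sum_seq = sum(seq[ok, j]))
  })
  do.call(rbind, rows)
}
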