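#' Regularized two-class d-statistic
#'
#' `d = (mean2 - mean1) / (s + s0)` where `s` is the pooled standard error of
#' the mean difference and `s0` a small positive "fudge" constant that
#' stabilizes the statistic for features with tiny variance.
#'
#' @param values Numeric vector (one feature) or matrix (features x samples)
#'   of log2 expression.
#' @param labels Two-level factor/vector over samples; group 1 is the first
#'   level, group 2 the second.
#' @param s0 Non-negative regularization constant.
#' @return Numeric d (scalar or per-row vector).
#' @export
d_statistic <- function(values, labels, s0 = 0) {
  x <- if (is.matrix(values)) values else matrix(values, nrow = 1)
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stop("labels must have exactly two levels")
  g2 <- labels == levels(labels)[2]
  n1 <- sum(!g2); n2 <- sum(g2)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 samples")
  m1 <- rowMeans(x[, !g2, drop = FALSE])
  m2 <- rowMeans(x[, g2, drop = FALSE])
  ss <- rowSums((x[, !g2, drop = FALSE] - m1)^2) +
        rowSums((x[, g2, drop = FALSE] - m2)^2)
  s <- sqrt((1 / n1 + 1 / n2) * ss / (n1 + n2 - 2))
  d <- (m2 - m1) / (s + s0)
  if (is.matrix(values)) d else as.numeric(d)
}

# Tusher-style automatic s0: the percentile of the per-feature standard
# errors minimizing the coefficient of variation of the d spread across
# 100 moving windows of s
choose_s0 <- function(r, s) {
  cand <- unique(stats::quantile(s, seq(0, 1, 0.05), names = FALSE))
  qs <- stats::quantile(s, seq(0, 1, 0.01), names = FALSE)
  win <- cut(s, unique(qs), include.lowest = TRUE)
  cv <- vapply(cand, function(s0) {
    d <- r / (s + s0)
    v <- tapply(d, win, stats::mad)
    v <- v[!is.na(v) & v > 0]
    if (length(v) < 2) return(Inf)
    stats::sd(v) / mean(v)
  }, 0)
  cand[which.min(cv)]
}

#' Two-class unpaired permutation test with q-values
#'
#' Computes the regularized d-statistic per feature, builds the null from
#' permutations of the group labels (all distinct assignments when fewer than
#' `n_perm` exist, otherwise `n_perm` assignments sampled without
#' replacement), and estimates per-feature false discovery rates as in the
#' significance-analysis-of-microarrays procedure: the median number of null
#' exceedances of `|d|`, scaled by an estimate of the true-null proportion
#' and divided by the observed exceedance count, then monotonized in `|d|`.
#'
#' @param x Features x samples matrix of log2 expression.
#' @param labels Two-level grouping over the columns of `x`.
#' @param n_perm Maximum number of label permutations (default 10000).
#' @param s0 Fudge constant; `NULL` (default) selects it automatically by the
#'   percentile rule.
#' @param q_threshold Features with `q < q_threshold` are flagged
#'   (default 0.05).
#' @param unlogged Optional matrix of normalized, un-logged expression with
#'   the same dimnames, used to attach signed fold changes.
#' @param seed Integer seed for permutation sampling.
#' @return An object of class `sam_result`: a list with `table` (data frame
#'   `feature`, `d`, `q`, `significant`, and `fold_change` when `unlogged`
#'   is given), `s0`, `n_perm_used`, `exhaustive` and `q_threshold`.
#' @export
sam_two_class <- function(x, labels, n_perm = 10000, s0 = NULL,
                          q_threshold = 0.05, unlogged = NULL, seed = 1L) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stop("labels must have exactly two levels")
  stopifnot(ncol(x) == length(labels))
  g2 <- labels == levels(labels)[2]
  n <- length(labels); n1 <- sum(!g2); n2 <- sum(g2)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 samples")
  m <- nrow(x)

  m1 <- rowMeans(x[, !g2, drop = FALSE]); m2 <- rowMeans(x[, g2, drop = FALSE])
  ss <- rowSums((x[, !g2, drop = FALSE] - m1)^2) +
        rowSums((x[, g2, drop = FALSE] - m2)^2)
  a <- 1 / n1 + 1 / n2
  s <- sqrt(a * ss / (n - 2))
  if (is.null(s0)) s0 <- choose_s0(m2 - m1, s)
  d_obs <- (m2 - m1) / (s + s0)

  # permutation null: columns of `assign` are group-1 index sets
  n_distinct <- choose(n, n1)
  exhaustive <- n_distinct <= n_perm
  if (exhaustive) {
    assign <- utils::combn(n, n1)
  } else {
    set.seed(seed)
    seen <- new.env(hash = TRUE, size = 2L * n_perm)
    cols <- vector("list", n_perm); got <- 0L
    while (got < n_perm) {
      idx <- sort(sample.int(n, n1))
      k <- paste(idx, collapse = ",")
      if (is.null(seen[[k]])) {
        seen[[k]] <- TRUE; got <- got + 1L; cols[[got]] <- idx
      }
    }
    assign <- do.call(cbind, cols)
  }
  P <- ncol(assign)

  ind1 <- matrix(0, n, P)
  ind1[cbind(as.vector(assign), rep(seq_len(P), each = n1))] <- 1
  tot <- rowSums(x); tot2 <- rowSums(x^2)
  S1 <- x %*% ind1
  M1 <- S1 / n1; M2 <- (tot - S1) / n2
  Q1 <- x^2 %*% ind1
  SSp <- (Q1 - n1 * M1^2) + ((tot2 - Q1) - n2 * M2^2)
  SSp[SSp < 0] <- 0
  Dp <- (M2 - M1) / (sqrt(a * SSp / (n - 2)) + s0)

  ad_obs <- abs(d_obs)
  ord_thr <- sort(ad_obs)
  # per-permutation counts of |d*| >= each observed |d|
  exceed <- matrix(0L, m, P)
  for (p in seq_len(P)) {
    sp <- sort(abs(Dp[, p]))
    exceed[, p] <- m - findInterval(ad_obs - 1e-12, sp)
  }
  med_null <- apply(exceed, 1, stats::median)
  obs_count <- m - findInterval(ad_obs - 1e-12, ord_thr)

  qq <- stats::quantile(Dp, c(0.25, 0.75))
  pi0 <- min(1, sum(d_obs >= qq[1] & d_obs <= qq[2]) / (0.5 * m))
  q_raw <- pmin(1, pi0 * med_null / obs_count)
  # monotone: a larger |d| never gets a larger q
  ord <- order(ad_obs, decreasing = TRUE)
  q <- numeric(m)
  q[ord] <- cummax(q_raw[ord])

  tab <- data.frame(feature = if (is.null(rownames(x))) seq_len(m) else rownames(x),
                    d = d_obs, q = q, significant = q < q_threshold,
                    row.names = NULL)
  if (!is.null(unlogged)) {
    fc <- fold_change(unlogged, labels)
    tab$fold_change <- fc$fold_change[match(tab$feature, fc$feature)]
  }
  structure(list(table = tab, s0 = s0, n_perm_used = P,
                 exhaustive = exhaustive, q_threshold = q_threshold),
            class = "sam_result")
}

#' Signed fold change between two groups
#'
#' The ratio `r = mean(group2) / mean(group1)` of normalized (un-logged)
#' expression, reported as `r` when `r >= 1` and `-1/r` otherwise, so the
#' magnitude is symmetric around +/-1 and a negative value means higher
#' expression in group 1. A zero group mean is handled by adding the log2
#' pseudocount (1) to both means; when both means are zero the fold change is
#' `NA` with `undefined = TRUE`.
#'
#' @param mat Features x samples matrix of normalized, un-logged expression
#'   (or a single-feature vector).
#' @param labels Two-level grouping over samples.
#' @return Data frame `feature`, `mean1`, `mean2`, `fold_change`, `undefined`.
#' @export
fold_change <- function(mat, labels) {
  x <- if (is.matrix(mat)) mat else matrix(mat, nrow = 1)
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stop("labels must have exactly two levels")
  g2 <- labels == levels(labels)[2]
  m1 <- rowMeans(x[, !g2, drop = FALSE])
  m2 <- rowMeans(x[, g2, drop = FALSE])
  undefined <- m1 == 0 & m2 == 0
  r <- ifelse(m1 > 0 & m2 > 0, m2 / m1, (m2 + 1) / (m1 + 1))
  fc <- ifelse(r >= 1, r, -1 / r)
  fc[undefined] <- NA_real_
  data.frame(feature = if (is.null(rownames(x))) seq_len(nrow(x)) else rownames(x),
             mean1 = m1, mean2 = m2, fold_change = fc, undefined = undefined,
             row.names = NULL)
}

#' @export
print.sam_result <- function(x, ...) {
  cat("Two-class permutation test:", nrow(x$table), "features,",
      x$n_perm_used, if (x$exhaustive) "permutations (exhaustive)"
      else "sampled permutations", "\n")
  cat("  s0 =", signif(x$s0, 4), "; significant at q <",
      x$q_threshold, ":", sum(x$table$significant), "\n")
  invisible(x)
}
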