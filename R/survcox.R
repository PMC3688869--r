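#' Univariate Cox proportional-hazards association for one feature
#'
#' Fits a single-covariate Cox model by partial-likelihood maximization
#' (Breslow tie handling by default) and reports the log hazard ratio, its
#' exponential and the Wald p-value.
#'
#' @param expression Numeric covariate per sample (e.g. log2 expression of one
#'   miRNA).
#' @param time Positive survival/censoring times.
#' @param event Event indicators (0 censored, 1 event).
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return `list(coef, hr, se, p, n, n_events)`.
#' @export
cox_univariate <- function(expression, time, event, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  stopifnot(length(expression) == length(time), length(time) == length(event),
            all(time > 0), all(event %in% c(0, 1)))
  if (sum(event) < 1)
    stop("cox_univariate: no events; the model is not identifiable")
  if (stats::sd(expression) == 0)
    stop("cox_univariate: constant covariate; the model is not identifiable")
  fit <- survival::coxph(survival::Surv(time, event) ~ expression,
                         ties = ties)
  sm <- summary(fit)
  list(coef = unname(stats::coef(fit)),
       hr = unname(exp(stats::coef(fit))),
       se = unname(sqrt(stats::vcov(fit)[1, 1])),
       p = unname(sm$coefficients[1, "Pr(>|z|)"]),
       n = length(time), n_events = sum(event))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvalues Numeric p-values in `[0, 1]`.
#' @return Adjusted p-values (FDR), in the input order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Per-miRNA univariate Cox screen with FDR control
#'
#' Applies [cox_univariate()] to every row of the expression matrix and
#' adjusts the Wald p-values with the Benjamini-Hochberg procedure. Rows with
#' constant expression are reported with `NA` statistics.
#'
#' @param x Features x samples matrix (log2 normalized expression).
#' @param time,event Survival data aligned with the columns of `x`.
#' @param ties Passed to [cox_univariate()].
#' @return Data frame `feature`, `coef`, `hr`, `p`, `p_adj`, sorted by
#'   adjusted p-value; class `cox_screen`.
#' @export
cox_screen <- function(x, time, event, ties = "breslow") {
  res <- lapply(seq_len(nrow(x)), function(i) {
    if (stats::sd(x[i, ]) == 0)
      return(list(coef = NA_real_, hr = NA_real_, p = NA_real_))
    cox_univariate(x[i, ], time, event, ties = ties)
  })
  out <- data.frame(
    feature = if (is.null(rownames(x))) seq_len(nrow(x)) else rownames(x),
    coef = vapply(res, `[[`, 0, "coef"),
    hr = vapply(res, `[[`, 0, "hr"),
    p = vapply(res, `[[`, 0, "p"), row.names = NULL)
  out$p_adj <- NA_real_
  ok <- !is.na(out$p)
  out$p_adj[ok] <- bh_adjust(out$p[ok])
  out <- out[order(out$p_adj), ]
  class(out) <- c("cox_screen", "data.frame")
  out
}

#' L1-penalized Cox regression over all miRNAs with cross-validated penalty
#'
#' Fits the lasso path of the Cox partial likelihood over all features
#' simultaneously and selects the penalty by 10-fold cross-validated partial
#' likelihood deviance. The default selection is the one-standard-error rule
#' (the sparsest model within one SE of the CV optimum); `rule = "min"` takes
#' the exact CV optimum. Folds are stratified on the event indicator so no
#' fold is left without events.
#'
#' @param x Features x samples matrix (log2 normalized expression); features
#'   may outnumber samples.
#' @param time,event Survival data aligned with the columns of `x`.
#' @param nfolds Number of CV folds (default 10, minimum 2).
#' @param rule `"1se"` (default) or `"min"`.
#' @param seed Integer seed controlling the fold assignment.
#' @return Object of class `lasso_cox`: list with `selected` (named vector of
#'   nonzero coefficients, possibly empty), `lambda` (chosen penalty),
#'   `cv` (data frame `lambda`, `cvm`, `cvsd`) and the underlying
#'   `cv.glmnet` fit.
#' @export
lasso_cox <- function(x, time, event, nfolds = 10, rule = c("1se", "min"),
                      seed = 1L) {
  rule <- match.arg(rule)
  stopifnot(nfolds >= 2, all(time > 0), all(event %in% c(0, 1)))
  if (sum(event) < 2) stop("lasso_cox: need at least 2 events")
  n <- length(time)
  set.seed(seed)
  foldid <- integer(n)
  for (g in c(0, 1)) {         # stratify folds on event status
    idx <- which(event == g)
    foldid[idx] <- sample(rep_len(seq_len(nfolds), length(idx)))
  }
  ev_per_fold <- tapply(event, foldid, sum)
  if (any(ev_per_fold == 0))
    stop("lasso_cox: a cross-validation fold has no events; reduce nfolds")
  cv <- glmnet::cv.glmnet(t(x), survival::Surv(time, event),
                          family = "cox", foldid = foldid,
                          type.measure = "deviance")
  lam <- if (rule == "1se") cv$lambda.1se else cv$lambda.min
  cf <- as.matrix(stats::coef(cv, s = lam))[, 1]
  structure(list(selected = cf[cf != 0], lambda = lam, rule = rule,
                 cv = data.frame(lambda = cv$lambda, cvm = cv$cvm,
                                 cvsd = cv$cvsd),
                 fit = cv),
            class = "lasso_cox")
}

#' @export
print.lasso_cox <- function(x, ...) {
  cat("Lasso Cox fit: penalty", signif(x$lambda, 4),
      "(", x$rule, "rule );", length(x$selected), "features selected\n")
  if (length(x$selected)) print(signif(x$selected, 4))
  invisible(x)
}
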