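#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path GMT file path.
#' @return Named list of character vectors of gene identifiers.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(parts, function(p) unique(p[-(1:2)])),
                  vapply(parts, `[[`, "", 1))
}

#' Hypergeometric gene-set over-representation test
#'
#' For each gene set, the one-sided probability of observing at least the
#' seen overlap between the target list and the set, given the universe. The
#' optional EASE variant discounts the overlap by one, penalizing sets
#' supported by a single gene. P-values are BH-adjusted across the tested
#' sets; sets overlapping fewer than `min_overlap` targets are excluded.
#'
#' @param targets Character vector of target gene identifiers.
#' @param gene_sets Named list of character vectors (e.g. from [read_gmt()]).
#' @param universe Background gene universe; defaults to the union of all
#'   genes in `gene_sets`. Targets outside the universe are dropped with a
#'   message.
#' @param min_overlap Minimum overlap for a set to be tested (default 2).
#' @param ease If `TRUE`, use the EASE-style discounted overlap.
#' @return Data frame `term`, `set_size`, `overlap`, `p`, `p_adj`, sorted by
#'   p-value.
#' @export
#' @examples
#' sets <- list(S = letters[1:5])
#' enrich(letters[1:5], sets, universe = letters[1:20])
enrich <- function(targets, gene_sets, universe = NULL, min_overlap = 2,
                   ease = FALSE) {
  if (length(targets) == 0) stop("empty target list")
  if (is.null(universe)) universe <- unique(unlist(gene_sets))
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty gene universe")
  dropped <- setdiff(targets, universe)
  if (length(dropped))
    message(length(dropped), " target(s) outside the universe dropped")
  targets <- unique(intersect(targets, universe))
  if (length(targets) == 0) stop("no targets left after universe filtering")

  N <- length(universe)
  n_t <- length(targets)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(gene_sets[[nm]], universe)
    k <- length(intersect(set, targets))
    if (k < min_overlap) return(NULL)
    k_eff <- if (ease) k - 1L else k
    p <- stats::phyper(k_eff - 1L, length(set), N - length(set), n_t,
                       lower.tail = FALSE)
    data.frame(term = nm, set_size = length(set), overlap = k, p = p)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(term = character(0), set_size = integer(0),
                      overlap = integer(0), p = numeric(0),
                      p_adj = numeric(0)))
  out$p_adj <- bh_adjust(out$p)
  out[order(out$p), ]
}
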