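# Independent brute-force oracles used across the suite. These deliberately
# re-derive results with the most literal possible code (scalar loops,
# enumeration) so the vectorized implementations are checked against
# something that cannot share their bugs.

# small cohort used by several files
tiny_cohort <- function(seed = 7, n_mirnas = 40, n_samples = 4,
                        reads = 4000, ...) {
  cfg <- sim_config(n_mirnas = n_mirnas, n_samples = n_samples,
                    reads_per_sample = reads, n_paralog_groups = 4,
                    n_clusters = 2, seed = seed, ...)
  ann <- generate_annotation(cfg)
  list(cfg = cfg, ann = ann, cohort = generate_cohort(ann, cfg))
}

# literal Cox partial log-likelihood (Breslow), no ties expected
oracle_cox_loglik <- function(beta, x, time, event) {
  ll <- 0
  for (i in seq_along(time)) {
    if (event[i] == 1) {
      risk <- which(time >= time[i])
      ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
    }
  }
  ll
}

# grid-search maximizer of the partial likelihood
oracle_cox_grid <- function(x, time, event, lo = -4, hi = 4, step = 1e-4) {
  grid <- seq(lo, hi, by = step)
  ll <- vapply(grid, oracle_cox_loglik, 0, x = x, time = time, event = event)
  grid[which.max(ll)]
}

# literal WPGMA: clusters held as index sets, pairwise scan each step
oracle_wpgma <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- lapply(seq_len(n), identity)
  cd <- d
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1) {
    k <- length(clusters)
    best <- c(Inf, 0, 0)
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      if (cd[i, j] < best[1] - 1e-15) best <- c(cd[i, j], i, j)
    }
    i <- best[2]; j <- best[3]
    heights <- c(heights, best[1])
    newd <- (cd[i, ] + cd[j, ]) / 2
    keep <- setdiff(seq_len(k), c(i, j))
    cd2 <- matrix(0, k - 1, k - 1)
    if (length(keep)) {
      cd2[seq_along(keep), seq_along(keep)] <- cd[keep, keep]
      cd2[k - 1, seq_along(keep)] <- cd2[seq_along(keep), k - 1] <- newd[keep]
    }
    clusters <- c(clusters[keep], list(c(clusters[[i]], clusters[[j]])))
    cd <- cd2
    partitions[[length(partitions) + 1]] <- clusters
  }
  list(heights = heights, partitions = partitions)
}

# canonical signature of a partition of 1..n (for comparing clusterings)
partition_signature <- function(membership) {
  groups <- split(seq_along(membership), membership)
  groups <- lapply(groups, sort)
  paste(sort(vapply(groups, paste, "", collapse = ",")), collapse = "|")
}

partition_from_sets <- function(sets, n) {
  mem <- integer(n)
  for (g in seq_along(sets)) mem[sets[[g]]] <- g
  partition_signature(mem)
}

# literal hypergeometric upper tail by enumeration over overlap counts
oracle_hyper_tail <- function(k, set_size, universe_size, n_targets) {
  tot <- choose(universe_size, n_targets)
  kk <- k:min(set_size, n_targets)
  sum(choose(set_size, kk) *
        choose(universe_size - set_size, n_targets - kk)) / tot
}

# literal two-class d over an explicit group-1 index set
oracle_d <- function(x, idx1) {
  n <- length(x)
  idx2 <- setdiff(seq_len(n), idx1)
  m1 <- mean(x[idx1]); m2 <- mean(x[idx2])
  ss <- sum((x[idx1] - m1)^2) + sum((x[idx2] - m2)^2)
  s <- sqrt((1 / length(idx1) + 1 / length(idx2)) * ss / (n - 2))
  list(d = function(s0) (m2 - m1) / (s + s0), s = s, num = m2 - m1)
}
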