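test_that("Euclidean distances reproduce hand values and metric axioms", {
  m <- matrix(c(0, 0,  3, 4), 2, byrow = TRUE,
              dimnames = list(c("a", "b"), NULL))
  d <- euclidean_distances(m)
  expect_equal(d["a", "b"], 5)                      # 3-4-5 triangle
  expect_equal(diag(d), c(a = 0, b = 0))

  set.seed(5)
  x <- matrix(stats::rnorm(5 * 4), 5, 4)
  d5 <- euclidean_distances(x)
  expect_equal(d5, t(d5))
  for (i in 1:5) for (j in 1:5) for (k in 1:5)
    expect_lte(d5[i, j], d5[i, k] + d5[k, j] + 1e-12)
  expect_equal(euclidean_distances(x, "columns"),
               euclidean_distances(t(x), "rows"))
  x[1, 1] <- NA
  expect_error(euclidean_distances(x), "missing")
})

test_that("WPGMA reproduces the three-leaf hand computation", {
  d <- matrix(c(0, 1, 4,
                1, 0, 4,
                4, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  h <- wpgma_cluster(d)
  # A,B merge at 1; then d({A,B},C) = (4+4)/2 = 4
  expect_equal(h$height, c(1, 4))
  expect_identical(sort(h$merge[1, ]), c(-2L, -1L))
  nwk <- as_newick(h)
  expect_identical(nwk, "(C:2,(B:0.5,A:0.5):1.5);")
  expect_error(wpgma_cluster(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("WPGMA tie-breaking is deterministic on an all-equal distance matrix", {
  d <- matrix(1, 4, 4); diag(d) <- 0
  dimnames(d) <- list(letters[1:4], letters[1:4])
  h1 <- wpgma_cluster(d)
  h2 <- wpgma_cluster(d)
  expect_identical(h1$merge, h2$merge)
  expect_equal(h1$height, rep(1, 3))
  # first merge takes the lowest-index pair
  expect_identical(sort(h1$merge[1, ]), c(-2L, -1L))
})

test_that("WPGMA agrees with a literal set-based oracle and with hclust mcquitty", {
  set.seed(14)
  for (rep in 1:10) {
    x <- matrix(stats::rnorm(6 * 5), 6, 5,
                dimnames = list(paste0("s", 1:6), NULL))
    d <- euclidean_distances(x)
    h <- wpgma_cluster(d)
    orc <- oracle_wpgma(d)
    expect_equal(h$height, orc$heights)
    # identical partition at every merge step
    for (step in 1:5) {
      got <- partition_signature(stats::cutree(h, k = 6 - step))
      expect_identical(got, partition_from_sets(orc$partitions[[step]], 6))
    }
    # independent established-library route
    hc <- stats::hclust(stats::as.dist(d), method = "mcquitty")
    expect_equal(sort(h$height), sort(hc$height))
    for (k in 2:5)
      expect_identical(partition_signature(stats::cutree(h, k)),
                       partition_signature(stats::cutree(hc, k)))
  }
})

test_that("two-way clustering returns row and column trees of the right size", {
  set.seed(2)
  m <- matrix(stats::rnorm(8 * 5), 8, 5,
              dimnames = list(paste0("mir", 1:8), paste0("s", 1:5)))
  tw <- two_way_cluster(m)
  expect_length(tw$rows$order, 8)
  expect_length(tw$columns$order, 5)
  expect_identical(tw$rows$labels, rownames(m))
})

test_that("replicate concordance recovers identity and known linear maps", {
  x <- c(1, 5, 9, 2, 7)
  # exact-fit fixtures trigger lm's "essentially perfect fit" warning
  id <- suppressWarnings(replicate_concordance(x, x))
  expect_equal(id$slope, 1)
  expect_equal(id$intercept, 0)
  expect_equal(id$r_squared, 1)

  # run2 has exactly twice the counts: on log2 scale slope 1, intercept 1
  counts <- c(10, 40, 160, 640, 2560)
  r <- suppressWarnings(replicate_concordance(log2(counts), log2(2 * counts)))
  expect_equal(r$slope, 1)
  expect_equal(r$intercept, 1)
  expect_equal(r$r_squared, 1)

  set.seed(77)
  noise <- replicate_concordance(stats::rnorm(500), stats::rnorm(500))
  expect_lt(noise$r_squared, 0.05)
  expect_error(replicate_concordance(1:2, 1:2), "at least 3")
})

test_that("2^-dCt converts Ct differences and propagates missing values", {
  expect_equal(delta_ct_expression(30, 25), 2^-5)
  expect_equal(delta_ct_expression(25, 25), 1)
  expect_equal(delta_ct_expression(23, 25), 4)
  expect_true(is.na(delta_ct_expression(NA, 25)))
})

test_that("platform regression reports exact fits, degenerate columns and moderate R2", {
  q <- cbind(perfect = c(1, 2, 3, 4), flat = c(2, 2, 2, 2))
  s <- cbind(perfect = c(2, 4, 6, 8), flat = c(1, 3, 2, 5))
  rownames(q) <- rownames(s) <- paste0("p", 1:4)
  res <- suppressWarnings(platform_regression(q, s))  # exact-fit column
  expect_equal(res$r_squared[res$assay == "perfect"], 1)
  expect_equal(res$r_squared[res$assay == "flat"], 0)
  expect_equal(res$sum_qpcr[res$assay == "perfect"], 10)

  # too few paired values -> warned and skipped
  q2 <- cbind(sparse = c(1, 2, NA, NA))
  s2 <- cbind(sparse = c(1, 2, 3, 4))
  expect_warning(out <- platform_regression(q2, s2), "fewer than 3")
  expect_null(out)

  # simulated signal with matched noise lands near the planned R2
  set.seed(55)
  n <- 2000
  truth <- stats::rnorm(n)
  qs <- cbind(a = truth + stats::rnorm(n))
  ss <- cbind(a = truth + stats::rnorm(n))
  r2 <- platform_regression(qs, ss)$r_squared
  # cor(qs, ss) ~ 0.5 so R2 ~ 0.25
  expect_gt(r2, 0.18); expect_lt(r2, 0.32)
})
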