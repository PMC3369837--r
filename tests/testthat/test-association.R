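# binary feature tibble helper
alt_tbl <- function(n, ...) {
  cols <- list(...)
  out <- tibble::tibble(sample_id = sprintf("S%02d", seq_len(n)))
  for (nm in names(cols)) {
    v <- integer(n)
    v[cols[[nm]]] <- 1L
    out[[nm]] <- v
  }
  out
}

test_that("hypergeometric tails are exact on the canonical 5/5/5 case", {
  x <- alt_tbl(10, a = 1:5, b = 1:5)
  res <- hypergeometric_pair_test(x, "a", "b")
  expect_equal(res$overlap, 5)
  expect_equal(res$p_positive, 1 / 252, tolerance = 1e-14)

  x0 <- alt_tbl(10, a = 1:5, b = 6:10)
  res0 <- hypergeometric_pair_test(x0, "a", "b")
  expect_equal(res0$p_negative, 1 / 252, tolerance = 1e-14)

  # a feature present in every sample forces the overlap
  xf <- alt_tbl(10, a = 1:10, b = 1:4)
  expect_equal(hypergeometric_pair_test(xf, "a", "b")$p_positive, 1)
})

test_that("hypergeometric tails match exhaustive carrier enumeration", {
  for (n in c(6, 9, 12)) {
    for (ka in c(2, floor(n / 2))) {
      for (kb in c(3, n - 2)) {
        for (k in max(0, ka + kb - n):min(ka, kb)) {
          expect_equal(hyper_tail(k, n, ka, kb, upper = TRUE),
                       oracle_hyper(n, ka, kb, k, upper = TRUE),
                       tolerance = 1e-12,
                       info = sprintf("N=%d Ka=%d Kb=%d k=%d", n, ka, kb, k))
          expect_equal(hyper_tail(k, n, ka, kb, upper = FALSE),
                       oracle_hyper(n, ka, kb, k, upper = FALSE),
                       tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("larger observed overlap never increases the positive-tail p", {
  for (k in 0:7) {
    expect_lte(hyper_tail(k + 1, 20, 8, 9, upper = TRUE),
               hyper_tail(k, 20, 8, 9, upper = TRUE))
  }
})

test_that("Bonferroni control follows min(1, m p) with strict alpha", {
  adj <- bonferroni_adjust(c(0.001, 0.01), alpha = 0.05, m = 19)
  expect_equal(adj$p_adj, c(0.019, 0.19))
  expect_equal(adj$significant, c(TRUE, FALSE))
  expect_equal(bonferroni_adjust(0.03)$p_adj, 0.03) # m = 1
  expect_error(bonferroni_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("Fisher group association detects enrichment and respects nulls", {
  x <- alt_tbl(30, f = c(1:8, 11))
  groups <- tibble::tibble(sample_id = sprintf("S%02d", 1:30),
                           group = rep(c("in", "out"), c(10, 20)))
  res <- fisher_group_association(x, "f", groups)
  expect_lt(res$p[res$group == "in"], 0.001)

  # same carrier frequency in both groups: two-sided p = 1
  x2 <- alt_tbl(30, f = c(1:5, 11:15))
  groups2 <- tibble::tibble(sample_id = sprintf("S%02d", 1:30),
                            group = rep(c("a", "b"), c(10, 20)))
  x2$f[11:30] <- rep(c(1L, 0L), 10)
  res2 <- fisher_group_association(
    alt_tbl(20, f = c(1:5, 11:15)), "f",
    tibble::tibble(sample_id = sprintf("S%02d", 1:20),
                   group = rep(c("a", "b"), each = 10)))
  expect_equal(res2$p, c(1, 1))
})

test_that("Jaccard distances and the feature MDS behave geometrically", {
  x <- alt_tbl(3, a = c(1, 3), b = c(1, 2))
  m <- as.matrix(x[-1])
  d <- as.matrix(jaccard_distances(m))
  expect_equal(d["a", "b"], 2 / 3)

  xid <- alt_tbl(4, a = 1:2, b = 1:2)
  expect_equal(as.matrix(jaccard_distances(as.matrix(xid[-1])))["a", "b"], 0)
  fit_id <- jaccard_mds(xid, dims = 1, min_freq = 0)
  expect_equal(fit_id$coordinates$dim1[1], fit_id$coordinates$dim1[2])

  # disjoint carrier sets: equilateral embedding, all pairwise distances 1
  xe <- alt_tbl(6, a = 1:2, b = 3:4, c = 5:6)
  fit <- jaccard_mds(xe, dims = 2, min_freq = 0)
  cd <- as.matrix(stats::dist(as.matrix(fit$coordinates[-1])))
  off <- cd[upper.tri(cd)]
  expect_lt(max(abs(off - 1)), 1e-9)

  # metric axioms on random binary fixtures
  set.seed(23)
  for (i in 1:8) {
    mm <- matrix(stats::rbinom(8 * 30, 1, 0.4), 30, 8,
                 dimnames = list(NULL, letters[1:8]))
    mm[, colSums(mm) == 0] <- 1L # avoid undefined empty-set distances
    dd <- as.matrix(jaccard_distances(mm))
    expect_equal(diag(dd), rep(0, 8), ignore_attr = TRUE)
    expect_equal(dd, t(dd))
    for (i1 in 1:8) for (j1 in 1:8) for (k1 in 1:8) {
      expect_lte(dd[i1, j1], dd[i1, k1] + dd[k1, j1] + 1e-12)
    }
  }
})

test_that("full-rank MDS reproduces Euclidean-embeddable distances", {
  set.seed(41)
  found <- 0
  for (i in 1:20) {
    mm <- matrix(stats::rbinom(5 * 40, 1, 0.5), 40, 5,
                 dimnames = list(NULL, letters[1:5]))
    if (any(colSums(mm) == 0)) next
    d <- jaccard_distances(mm)
    fit <- stats::cmdscale(d, k = 4, eig = TRUE)
    if (min(fit$eig) < -1e-8) next # not Euclidean-embeddable; skip fixture
    found <- found + 1
    expect_equal(as.vector(stats::dist(fit$points)), as.vector(d),
                 tolerance = 1e-6)
  }
  expect_gt(found, 0)
})

test_that("network assembly keeps only circuits of significant edges", {
  x <- alt_tbl(40, a = 1:12, b = 2:12, c = 25:40, d = c(1, 14, 22, 30))
  edges <- pairwise_associations(x, alpha = 0.05)
  net <- assemble_network(edges, alpha = 0.05)
  # a/b strongly co-occur; c avoids both; d is noise and must be absent
  expect_true(all(c("a", "b") %in% net$nodes$feature))
  expect_false("d" %in% net$nodes$feature)
  expect_equal(attr(edges, "m"), 2 * choose(4, 2))

  # no significant edges -> empty network
  none <- assemble_network(edges[edges$p_adj > 1, ], alpha = 0.05)
  expect_equal(nrow(none$nodes), 0)
  expect_equal(none$n_components, 0L)

  # one positive and one negative edge sharing a node form one component
  fake <- tibble::tibble(feature_a = c("x", "y"), feature_b = c("y", "z"),
                         overlap = c(5L, 0L),
                         direction = c("positive", "negative"),
                         p = c(1e-5, 1e-5), p_adj = c(1e-4, 1e-4),
                         significant = TRUE)
  net3 <- assemble_network(fake)
  expect_equal(net3$n_components, 1L)
  expect_equal(nrow(net3$nodes), 3)
  expect_setequal(net3$edges$direction, c("positive", "negative"))
})
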