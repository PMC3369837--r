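test_that("batch scaling matches geometric means to the reference batch", {
  # batch1 gene values {100, 400} (geomean 200), batch2 {50, 200} (geomean
  # 100): batch2 is scaled x2. The mirrored second gene makes every
  # column's sorted values identical, so quantile normalization is the
  # identity and the scaling is observable through the full pipeline.
  raw <- tibble::tibble(gene = c("g1", "g2"),
                        S1 = c(100, 400), S2 = c(400, 100),
                        S3 = c(50, 200), S4 = c(200, 50))
  batches <- tibble::tibble(sample_id = c("S1", "S2", "S3", "S4"),
                            batch = c("B1", "B1", "B2", "B2"))
  norm <- normalize_expression(raw, batches, sd_filter = NULL)
  m <- expr_matrix(norm)
  expect_equal(unname(m[, "S3"]), log2(c(100, 400) + 30))
  expect_equal(unname(m[, "S4"]), log2(c(400, 100) + 30))
})

test_that("quantile normalization equalizes column distributions", {
  raw <- tibble::tibble(gene = c("g1", "g2"), S1 = c(1, 3), S2 = c(2, 4))
  batches <- tibble::tibble(sample_id = c("S1", "S2"), batch = "B1")
  norm <- normalize_expression(raw, batches, offset = 0, sd_filter = NULL)
  m <- expr_matrix(norm)
  expect_equal(unname(m[, "S1"]), log2(c(1.5, 3.5)))
  expect_equal(unname(m[, "S2"]), log2(c(1.5, 3.5)))

  # random intensities: sorted columns identical to numerical precision,
  # and re-aligning the normalized stage changes nothing (idempotence)
  set.seed(13)
  big <- tibble::as_tibble(matrix(stats::rlnorm(200 * 10, 5, 1), 200,
                                  dimnames = list(NULL, sprintf("S%02d", 1:10))))
  big <- dplyr::bind_cols(tibble::tibble(gene = sprintf("g%03d", 1:200)), big)
  bt <- tibble::tibble(sample_id = sprintf("S%02d", 1:10),
                       batch = rep(c("B1", "B2"), 5))
  mnorm <- expr_matrix(normalize_expression(big, bt, sd_filter = NULL))
  sorted <- apply(mnorm, 2, sort)
  expect_lt(max(abs(sorted - sorted[, 1])), 1e-9)
  expect_equal(limma::normalizeQuantiles(mnorm), mnorm, tolerance = 1e-12)
})

test_that("the SD filter keeps genes strictly above the cutoff", {
  # mirrored gene pairs keep quantile normalization the identity; log2 SDs
  # are d/sqrt(2) for a gene alternating between x and x + d
  mk <- function(a, d) c(a, a + d)
  d_drop <- 0.20 * sqrt(2) # post-log2 SD 0.20 -> removed (<= 0.25)
  d_keep <- 0.30 * sqrt(2) # SD 0.30 -> kept
  raw <- tibble::tibble(
    gene = c("drop1", "drop2", "keep1", "keep2"),
    S1 = 2^c(5, 5 + d_drop, 8, 8 + d_keep),
    S2 = 2^c(5 + d_drop, 5, 8 + d_keep, 8)
  )
  bt <- tibble::tibble(sample_id = c("S1", "S2"), batch = "B1")
  norm <- normalize_expression(raw, bt, offset = 0, sd_filter = 0.25)
  expect_setequal(norm$gene, c("keep1", "keep2"))
})

test_that("well-separated expression groups are recovered exactly at k = 2", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 20
    # the group-b profile moves half the genes up and half down by 3 SD;
    # a uniform shift would be invisible to correlation distances
    m <- cbind(matrix(stats::rnorm(50 * n, 0, 1), 50),
               matrix(stats::rnorm(50 * n, rep(c(3, -3), 25), 1), 50))
    colnames(m) <- sprintf("S%02d", seq_len(2 * n))
    rownames(m) <- sprintf("g%02d", 1:50)
    fit <- hca_clusters(tibble::as_tibble(m, rownames = "gene"), k = 2)
    truth <- rep(c("a", "b"), each = n)
    expect_equal(ari(tidy(fit)$ms, truth), 1)
  }
})

test_that("degenerate clustering inputs behave as specified", {
  set.seed(4)
  m <- matrix(stats::rnorm(40), 10, 4,
              dimnames = list(sprintf("g%02d", 1:10), c("A", "B", "C", "D")))
  m[, "B"] <- m[, "A"] # duplicate sample
  expr <- tibble::as_tibble(m, rownames = "gene")
  fit <- hca_clusters(expr, k = 3)
  asg <- tidy(fit)
  expect_equal(asg$hc[asg$sample_id == "A"], asg$hc[asg$sample_id == "B"])

  fit_n <- hca_clusters(expr, k = 4)
  expect_equal(dplyr::n_distinct(tidy(fit_n)$hc), 4) # singletons at k = n

  m[, "C"] <- 1 # constant column
  expect_error(hca_clusters(tibble::as_tibble(m, rownames = "gene"), k = 2),
               "constant expression column.*C")
})

test_that("rank categorization partitions samples with ties going low", {
  expr <- tibble::as_tibble(matrix(as.numeric(1:9), 1,
                                   dimnames = list("FGFR3", sprintf("S%d", 1:9))),
                            rownames = "gene")
  expr$gene <- "FGFR3"
  cat3 <- categorize_gene_expression(expr, "FGFR3", c(1/3, 2/3))
  expect_equal(as.character(cat3$category),
               rep(c("low", "intermediate", "high"), each = 3))

  odd <- tibble::as_tibble(matrix(c(1, 2, 3), 1,
                                  dimnames = list("g", c("A", "B", "C"))),
                           rownames = "gene")
  odd$gene <- "g"
  cat2 <- categorize_gene_expression(odd, "g", 0.5)
  expect_equal(as.character(cat2$category[cat2$sample_id == "B"]), "low")

  flat <- tibble::as_tibble(matrix(rep(5, 4), 1,
                                   dimnames = list("g", sprintf("S%d", 1:4))),
                            rownames = "gene")
  flat$gene <- "g"
  expect_equal(as.character(categorize_gene_expression(flat, "g", 0.5)$category),
               rep("low", 4))

  expect_error(categorize_gene_expression(expr, "FGFR3", c(2/3, 1/3)),
               "strictly increasing")
  # higher expression never maps to a lower category
  ord <- order(cat3$value)
  expect_true(!is.unsorted(cat3$category[ord]))
})

test_that("the two-sample screen flags planted shifts and not nulls", {
  set.seed(17)
  n_genes <- 200
  m <- matrix(stats::rnorm(n_genes * 12, 8, 0.5), n_genes,
              dimnames = list(sprintf("g%03d", 1:n_genes), sprintf("S%02d", 1:12)))
  m[1:10, 1:6] <- m[1:10, 1:6] + 3 # strong shift in ten genes
  de <- differential_expression(tibble::as_tibble(m, rownames = "gene"),
                                sprintf("S%02d", 1:6), sprintf("S%02d", 7:12))
  expect_true(all(de$significant[1:10]))
  expect_true(all(de$direction[1:10] == "up"))
  expect_lt(sum(de$significant[-(1:10)]), 3)

  # m = 1: adjusted equals raw
  one <- differential_expression(tibble::as_tibble(m[1, , drop = FALSE],
                                                   rownames = "gene"),
                                 sprintf("S%02d", 1:6), sprintf("S%02d", 7:12))
  expect_equal(one$p_bonf, one$p)

  # zero-variance gene is reported flat, not NaN
  mz <- m
  mz[5, ] <- 3
  dez <- differential_expression(tibble::as_tibble(mz, rownames = "gene"),
                                 sprintf("S%02d", 1:6), sprintf("S%02d", 7:12))
  expect_equal(dez$p[5], 1)
  expect_true(dez$zero_variance[5])
})
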