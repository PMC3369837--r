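test_that("nFGA counts merged amplicons", {
  expect_equal(compute_nfga(empty_ev <- tibble::tibble(
    sample_id = character(), chrom = character(), kind = character(),
    from = integer(), to = integer(), start = integer(), end = integer(),
    n_probes = integer(), mean_log2 = numeric()
  ), samples = "S1")$nfga, 0L)

  ev <- tibble::tibble(
    sample_id = "S1", kind = "FGA", chrom = c("chr1", "chr1"),
    from = c(1L, 20L), to = c(5L, 24L),
    start = c(0, 1800000), end = c(1000000, 2300000), # gap 0.8 Mb
    n_probes = 5L, mean_log2 = 1
  )
  expect_equal(compute_nfga(ev)$nfga, 1L)
  ev$chrom[2] <- "chr2"
  expect_equal(compute_nfga(ev)$nfga, 2L)
})

test_that("fBAC is the altered-probe fraction with missing probes unaltered", {
  mk <- function(states) list(states = matrix(states, nrow = 1,
                                              dimnames = list("S1", NULL)))
  expect_equal(compute_fbac(mk(rep(c("GAIN", "NEUTRAL"), c(10, 40))))$fbac, 0.2)
  expect_equal(compute_fbac(mk(rep("NEUTRAL", 50)))$fbac, 0)
  expect_equal(compute_fbac(mk(rep("AMP", 50)))$fbac, 1)

  # probes with missing log2 are NEUTRAL, so they dilute the fraction
  pm <- make_pm(40)
  v <- c(rep(0.9, 10), rep(NA, 10), rep(0, 20))
  calls <- call_cna(make_profiles(list(S1 = v), pm), pm)
  expect_lte(compute_fbac(calls)$fbac, 0.5)
})

test_that("signature scores are mean gene-wise z-scores", {
  m <- matrix(c(1, 2, 3,
                6, 4, 2), nrow = 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), c("A", "B", "C")))
  sc <- signature_score(expr_tibble <- tibble::as_tibble(m, rownames = "gene"),
                        c("g1", "g2"))
  # sample B sits at both gene means
  expect_equal(sc$score[sc$sample_id == "B"], 0)
  # g1 and g2 move oppositely with equal magnitude: all scores are 0
  expect_equal(sc$score, c(0, 0, 0))

  # invariance under per-gene affine rescaling
  m2 <- m * c(10, 0.5) + c(100, -3)
  sc2 <- signature_score(tibble::as_tibble(m2, rownames = "gene"), c("g1", "g2"))
  expect_equal(sc2$score, sc$score)

  expect_error(signature_score(tibble::as_tibble(m, rownames = "gene"), "nope"),
               "none of the signature genes")
  expect_warning(signature_score(tibble::as_tibble(m, rownames = "gene"),
                                 c("g1", "nope")), "absent")
})

test_that("TP53/MDM2 status is the three-way disjunction", {
  mutations <- tibble::tibble(
    sample_id = rep(c("S1", "S2", "S3", "S4"), each = 1), gene = "TP53",
    status = c("mutated", "wildtype", "wildtype", "wildtype")
  )
  events <- tibble::tibble(sample_id = "S3", chrom = "chr12", kind = "FGA",
                           from = 100L, to = 110L, start = 0, end = 1,
                           n_probes = 11L, mean_log2 = 1.5)
  category <- tibble::tibble(sample_id = c("S1", "S2", "S3"),
                             category = c("low", "low", "low"))
  st <- classify_tp53_mdm2(mutations, events, category,
                           mdm2_interval = list(chrom = "chr12", from = 105L,
                                                to = 120L))
  expect_true(st$tp53_mdm2_altered[st$sample_id == "S1"])  # mutation only
  expect_false(st$tp53_mdm2_altered[st$sample_id == "S2"]) # all negative
  expect_true(st$tp53_mdm2_altered[st$sample_id == "S3"])  # MDM2 FGA only
  expect_true(is.na(st$tp53_mdm2_altered[st$sample_id == "S4"])) # no category
})

test_that("IHC protein scores multiply intensity by positive fraction", {
  two_cores <- tibble::tibble(sample_id = "S1", marker = "p16", core = 1:2,
                              intensity = c(3L, 2L), fraction = c(0.8, 0.6))
  expect_equal(ihc_score(two_cores)$score, 180) # (240 + 120) / 2
  one_core <- tibble::tibble(sample_id = "S1", marker = "p16", core = 1,
                             intensity = 1L, fraction = 1.0)
  expect_equal(ihc_score(one_core)$score, 100)
  zero <- tibble::tibble(sample_id = "S1", marker = "p16", core = 1,
                         intensity = 0L, fraction = 0.9)
  expect_equal(ihc_score(zero)$score, 0)
  off_grid <- tibble::tibble(sample_id = "S1", marker = "p16", core = 1,
                             intensity = 2L, fraction = 0.55)
  expect_error(ihc_score(off_grid), "10% grid")

  # bounds on random grid measurements
  set.seed(5)
  rand <- tibble::tibble(sample_id = sprintf("S%02d", 1:50), marker = "x",
                         core = 1, intensity = sample(0:3, 50, TRUE),
                         fraction = sample(seq(0, 1, 0.1), 50, TRUE))
  sc <- ihc_score(rand)$score
  expect_true(all(sc >= 0 & sc <= 300))
})

test_that("group tests behave on canonical inputs", {
  df <- tibble::tibble(v = c(1, 2, 3, 1, 2, 3), g = rep(c("a", "b"), each = 3))
  wt <- group_stats(df, "v", "g", "wilcoxon_rank_sum")
  expect_equal(wt$p_value, 1)

  dfp <- tibble::tibble(x = c(1, 2, 3), y = c(2, 4, 6))
  expect_equal(group_stats(dfp, "x", "y", "pearson_r")$estimate, 1)

  expect_error(group_stats(tibble::tibble(v = 1:3, g = c("a", "a", "b")),
                           "v", "g", "welch_t"), "at least 2")
})

test_that("ANOVA separates well-shifted groups essentially always", {
  set.seed(31)
  hits <- 0
  for (i in 1:100) {
    df <- tibble::tibble(v = c(stats::rnorm(50, 0), stats::rnorm(50, 5)),
                         g = rep(c("a", "b"), each = 50))
    if (group_stats(df, "v", "g", "one_way_anova")$p_value < 1e-6) hits <- hits + 1
  }
  expect_gte(hits, 99)
})

test_that("the CIN score tracks planted alteration burden", {
  co <- default_cohort()
  norm <- normalize_expression(co$expression, co$batches)
  cin <- signature_score(norm, grep("^CIN_", co$expression$gene, value = TRUE))
  joined <- dplyr::inner_join(cin, co$truth$burden, by = "sample_id")
  expect_gt(stats::cor(joined$score, joined$burden, method = "spearman"), 0.4)

  # and with the called complexity metrics (monotone consequences)
  calls <- call_cna(co$profiles, co$probe_map)
  cx <- complexity_profile(calls, norm,
                           grep("^CIN_", co$expression$gene, value = TRUE))
  expect_gt(stats::cor(cx$cin_score, cx$fbac, method = "spearman"), 0.3)
})
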