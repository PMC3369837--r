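test_that("recurrent regions require the kind's minimum support", {
  pm <- make_pm(30)
  three <- make_events(S1 = c(10, 20), S2 = c(10, 20), S3 = c(10, 20))
  reg <- detect_recurrent_regions(three, pm, "FGA")
  expect_equal(nrow(reg), 1)
  expect_equal(reg$core_from, 10L)
  expect_equal(reg$core_to, 20L)
  expect_equal(reg$max_support, 3L)
  expect_setequal(reg$members[[1]], c("S1", "S2", "S3"))

  two <- make_events(S1 = c(10, 20), S2 = c(15, 25))
  expect_equal(nrow(detect_recurrent_regions(two, pm, "FGA")), 0) # 2 < 3
  hd <- detect_recurrent_regions(two, pm, "HD")                    # 2 >= 2
  expect_equal(nrow(hd), 1)
  expect_equal(c(hd$core_from, hd$core_to), c(15L, 20L)) # shared interval
})

test_that("boundary extension includes cases within the slack", {
  counts <- c(1, 2, 4, 5, 5, 3, 2)
  expect_equal(extend_boundaries(counts, 4, 5, slack = 2), c(3, 6))
  expect_equal(extend_boundaries(c(5, 5, 5), 1, 3, slack = 2), c(1, 3)) # flat unit
  expect_equal(extend_boundaries(c(1, 3, 3, 2, 1), 2, 3, slack = 1), c(2, 4))
})

test_that("peak-and-extend matches exhaustive interval enumeration", {
  cfg <- cna_config()
  set.seed(99)
  for (i in 1:12) {
    pm <- make_pm(sample(20:60, 1), chroms = c("chr1", "chr2"))
    ev <- rand_events(pm, n_samples = sample(3:8, 1))
    for (kind in c("FGA", "HD")) {
      got <- detect_recurrent_regions(ev, pm, kind, cfg)
      expect_equal(dplyr::arrange(got[region_cols], core_from),
                   oracle_regions(ev, pm, kind, cfg),
                   info = paste("fixture", i, kind))
    }
  }
})

test_that("flat genome-wide support extends to the whole chromosome", {
  pm <- make_pm(25)
  ev <- make_events(S1 = c(1, 25), S2 = c(1, 25), S3 = c(1, 25))
  reg <- detect_recurrent_regions(ev, pm, "FGA")
  expect_equal(c(reg$ext_from, reg$ext_to), c(1L, 25L))
})

test_that("CNV masking removes regions with high covered fraction", {
  region <- tibble::tibble(
    kind = "MRD", chrom = "chr1", arm = "chr1p",
    core_from = 1L, core_to = 2L, ext_from = 1L, ext_to = 2L,
    core_start = 0L, core_end = 100000L, ext_start = 0L, ext_end = 100000L,
    max_support = 20L, n_members = 20L, members = list(character())
  )
  cnv_big <- tibble::tibble(chrom = "chr1", start = 0L, end = 60000L,
                            name = "cnv1")
  expect_equal(nrow(apply_cnv_mask(region, cnv_big, 0.5)), 0) # 60% > 50%
  cnv_small <- tibble::tibble(chrom = "chr1", start = 0L, end = 20000L,
                              name = "cnv1")
  expect_equal(nrow(apply_cnv_mask(region, cnv_small, 0.5)), 1) # 20% kept
  # overlapping CNVs are unioned, not double-counted
  cnv_dup <- dplyr::bind_rows(cnv_big, cnv_big)
  expect_equal(nrow(apply_cnv_mask(region, cnv_dup, 0.7)), 1)
  expect_warning(kept <- apply_cnv_mask(region, NULL, 0.5), "no CNV")
  expect_equal(nrow(kept), 1)
})

test_that("HD boundaries take precedence over overlapping MRDs", {
  pm <- make_pm(50, p_n = 50) # single arm so the deletion yields one MRD
  mrds <- detect_recurrent_regions(
    do.call(make_events, stats::setNames(rep(list(c(5, 40)), 15),
                                         sprintf("S%02d", 1:15))), pm, "MRD")
  hds <- detect_recurrent_regions(make_events(A = c(10, 20), B = c(10, 20)),
                                  pm, "HD")
  out <- resolve_mrd_hd_overlap(mrds, hds)
  expect_equal(out$kind, "HD")
  expect_equal(c(out$core_from, out$core_to), c(10L, 20L))

  hds_far <- detect_recurrent_regions(make_events(A = c(45, 48), B = c(45, 48)),
                                      pm, "HD")
  out2 <- resolve_mrd_hd_overlap(mrds, hds_far)
  expect_setequal(out2$kind, c("HD", "MRD"))

  # an MRD overlapping two HDs is replaced by both
  hds2 <- dplyr::bind_rows(
    detect_recurrent_regions(make_events(A = c(8, 12), B = c(8, 12)), pm, "HD"),
    detect_recurrent_regions(make_events(C = c(30, 34), D = c(30, 34)), pm, "HD")
  )
  out3 <- resolve_mrd_hd_overlap(mrds, hds2)
  expect_equal(sort(out3$kind), c("HD", "HD"))
})

test_that("arm-scale MRDs are suppressed by the strict fraction rule", {
  pm <- make_pm(100, p_n = 50) # two arms of 50 probes
  mk <- function(from, to) {
    detect_recurrent_regions(
      do.call(make_events, stats::setNames(rep(list(c(from, to)), 15),
                                           sprintf("S%02d", 1:15))), pm, "MRD")
  }
  expect_equal(nrow(suppress_arm_scale_mrds(mk(1, 40), pm, 0.5)), 0)  # 80%
  expect_equal(nrow(suppress_arm_scale_mrds(mk(10, 14), pm, 0.5)), 1) # 10%
  expect_equal(nrow(suppress_arm_scale_mrds(mk(1, 25), pm, 0.5)), 1)  # exactly 50%
})

test_that("arm recurrence needs strictly more than the sample fraction", {
  mk_calls <- function(n_carriers, n = 146) {
    tibble::tibble(sample_id = sprintf("S%03d", 1:n), chrom = "chr4",
                   arm = "chr4q",
                   call = rep(c("loss", "none"), c(n_carriers, n - n_carriers)))
  }
  expect_equal(nrow(recurrent_arm_regions(mk_calls(16))), 1) # 11.0% > 10%
  expect_equal(nrow(recurrent_arm_regions(mk_calls(14))), 0) # 9.6%
  expect_equal(nrow(recurrent_arm_regions(mk_calls(0))), 0)
})

test_that("the alteration matrix encodes carriage by extended-interval overlap", {
  co <- default_cohort()
  calls <- call_cna(co$profiles, co$probe_map)
  rec <- recurrent_alterations(calls)
  alt <- build_alteration_matrix(rec, calls, mutations = co$mutations)
  m <- alt$matrix
  expect_true(all(m %in% c(0L, 1L)))

  # carriage of the 6p22-like FGA feature equals event-interval overlap
  reg <- rec$regions[rec$regions$kind == "FGA" & rec$regions$chrom == "chr1", ][1, ]
  feat <- sprintf("FGA_%s:%d-%d", reg$chrom, reg$ext_start, reg$ext_end)
  ev <- calls$events
  carriers <- unique(ev$sample_id[ev$kind == "FGA" & ev$from <= reg$ext_to &
                                    ev$to >= reg$ext_from])
  expect_setequal(rownames(m)[m[, feat] == 1], carriers)
  # a sample with an FGA elsewhere on the chromosome is not a carrier
  elsewhere <- setdiff(unique(ev$sample_id[ev$kind == "FGA"]), carriers)
  if (length(elsewhere) > 0) expect_true(all(m[elsewhere, feat] == 0))

  # frequencies are column means; rare FGA/HD features flagged for MDS
  expect_equal(alt$features$freq,
               unname(colMeans(m)[alt$features$feature]))
  expect_equal(alt$features$excluded_mds,
               alt$features$kind %in% c("FGA", "HD") & alt$features$freq < 0.05)

  # mutation table with foreign sample ids is rejected
  bad_mut <- dplyr::bind_rows(co$mutations,
                              tibble::tibble(sample_id = "GHOST", gene = "TP53",
                                             status = "mutated"))
  expect_error(build_alteration_matrix(rec, calls, mutations = bad_mut), "GHOST")
})
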