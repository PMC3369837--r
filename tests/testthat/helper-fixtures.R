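# Shared fixtures and independent oracles for the test suite.

# tiny probe grid: probes 50 kb wide, 100 kb apart, p arm = first p_n probes
make_pm <- function(n_per_chrom = 20, chroms = "chr1", p_n = ceiling(n_per_chrom / 2),
                    spacing = 100000) {
  rows <- lapply(seq_along(chroms), function(i) {
    start <- (seq_len(n_per_chrom) - 1L) * spacing
    tibble::tibble(
      probe_id = sprintf("%s_p%03d", chroms[i], seq_len(n_per_chrom)),
      chrom = chroms[i], start = as.integer(start),
      end = as.integer(start + 50000L),
      arm = paste0(chroms[i], ifelse(seq_len(n_per_chrom) <= p_n, "p", "q"))
    )
  })
  probe_map(dplyr::bind_rows(rows))
}

# long profile tibble from a named list of per-sample value vectors
make_profiles <- function(values, pm) {
  dplyr::bind_rows(lapply(names(values), function(s) {
    tibble::tibble(sample_id = s, probe_id = pm$probe_id, log2 = values[[s]])
  }))
}

# events tibble from a list of c(from, to) per sample
make_events <- function(...) {
  args <- list(...)
  dplyr::bind_rows(lapply(names(args), function(s) {
    iv <- args[[s]]
    tibble::tibble(sample_id = s,
                   from = as.integer(iv[c(TRUE, FALSE)]),
                   to = as.integer(iv[c(FALSE, TRUE)]))
  }))
}

# Independent oracle for recurrent-region discovery: O(n^2) enumeration of
# all candidate intervals per scan unit, with support counted by a direct
# per-probe sample loop (a different code path from the package's
# difference-array scan).
oracle_regions <- function(events, pm, kind, config = cna_config()) {
  min_support <- switch(kind, FGA = config$fga_min_support,
                        HD = config$hd_min_support, MRD = config$mrd_min_support)
  slack <- if (kind == "HD") config$hd_slack else config$fga_slack
  np <- nrow(pm)
  support <- vapply(seq_len(np), function(p) {
    length(unique(events$sample_id[events$from <= p & events$to >= p]))
  }, 0L)
  units <- if (kind == "MRD") split(seq_len(np), pm$arm) else split(seq_len(np), pm$chrom)
  out <- list()
  for (idx in units) {
    sup <- support[idx]
    L <- length(idx)
    for (i in seq_len(L)) {
      for (j in i:L) {
        s <- sup[i]
        if (s < min_support) next
        if (!all(sup[i:j] == s)) next
        if (i > 1 && sup[i - 1] >= s) next
        if (j < L && sup[j + 1] >= s) next
        lo <- i
        while (lo > 1 && sup[lo - 1] >= s - slack) lo <- lo - 1
        hi <- j
        while (hi < L && sup[hi + 1] >= s - slack) hi <- hi + 1
        out[[length(out) + 1]] <- tibble::tibble(
          kind = kind, core_from = idx[i], core_to = idx[j],
          ext_from = idx[lo], ext_to = idx[hi], max_support = as.integer(s)
        )
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(kind = character(), core_from = integer(),
                          core_to = integer(), ext_from = integer(),
                          ext_to = integer(), max_support = integer()))
  }
  dplyr::arrange(dplyr::distinct(dplyr::bind_rows(out)), core_from)
}

region_cols <- c("kind", "core_from", "core_to", "ext_from", "ext_to", "max_support")

# Exhaustive hypergeometric tail by enumerating all carrier placements of
# feature a over N samples (b fixed); exact by exchangeability.
oracle_hyper <- function(n, ka, kb, k_obs, upper = TRUE) {
  placements <- utils::combn(n, ka)
  b <- seq_len(kb)
  ov <- apply(placements, 2, function(a) length(intersect(a, b)))
  if (upper) mean(ov >= k_obs) else mean(ov <= k_obs)
}

# Adjusted Rand index between two label vectors (closed form on the
# contingency table; independent of any clustering code in the package).
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# random event fixture on a probe map
rand_events <- function(pm, n_samples, max_events = 3, max_len = 15) {
  np <- nrow(pm)
  ci <- split(seq_len(np), pm$chrom)
  rows <- list()
  for (s in seq_len(n_samples)) {
    for (k in seq_len(sample(0:max_events, 1))) {
      idx <- ci[[sample(length(ci), 1)]]
      len <- sample(max_len, 1)
      at <- sample(max(1, length(idx) - len), 1)
      rows[[length(rows) + 1]] <- tibble::tibble(
        sample_id = sprintf("S%02d", s),
        from = idx[at], to = idx[min(length(idx), at + len - 1)]
      )
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(sample_id = character(), from = integer(), to = integer()))
  }
  # events of one sample must be disjoint: keep the first of any overlapping pair
  ev <- dplyr::bind_rows(rows)
  keep <- dplyr::bind_rows(lapply(split(ev, ev$sample_id), function(df) {
    df <- df[order(df$from), ]
    sel <- rep(TRUE, nrow(df))
    last_to <- -1L
    for (i in seq_len(nrow(df))) {
      if (df$from[i] <= last_to) sel[i] <- FALSE else last_to <- df$to[i]
    }
    df[sel, ]
  }))
  keep
}

default_cohort <- local({
  cache <- NULL
  function(seed = 1) {
    if (is.null(cache)) cache <<- generate_cohort(simulation_config(), seed = seed)
    cache
  }
})
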