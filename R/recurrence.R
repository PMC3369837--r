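#' Per-probe support counts
#'
#' Number of samples whose events cover each probe. Events of one sample
#' must be disjoint (maximal runs are), so the count equals the number of
#' distinct supporting samples.
#'
#' @param events Tibble with `sample_id`, `from`, `to` (probe-map row
#'   indices, inclusive).
#' @param probe_map A [probe_map()].
#' @return Tibble `probe_id`, `chrom`, `arm`, `support`, one row per map
#'   probe in map order.
#' @export
support_counts <- function(events, probe_map) {
  probe_map <- stopifnot_probe_map(probe_map)
  tibble::tibble(
    probe_id = probe_map$probe_id, chrom = probe_map$chrom,
    arm = probe_map$arm,
    support = support_vector(events, nrow(probe_map))
  )
}

support_vector <- function(events, n) {
  d <- integer(n + 1L)
  if (nrow(events) > 0) {
    from <- as.integer(events$from)
    to <- as.integer(events$to)
    stopifnot(all(from >= 1L), all(to <= n), all(from <= to))
    d_add <- tabulate(from, n + 1L)
    d_sub <- tabulate(to + 1L, n + 1L)
    d <- d_add - d_sub
  }
  cumsum(d)[seq_len(n)]
}

#' Detect recurrent regions by peak-and-extend
#'
#' Implements the recurrent-region discovery used for focal amplifications
#' (FGA), homozygous deletions (HD), and minimal regions of deletion (MRD):
#' per-probe support counts are computed per scan unit (chromosome for
#' FGA/HD, chromosome arm for MRD); every maximal plateau of locally
#' maximal support at or above the kind's minimum (FGA 3, HD 2, MRD 15)
#' becomes a core region; each core is widened to the surrounding
#' contiguous run of probes supported by at most two cases fewer than the
#' peak (one for HD), truncated at the scan-unit ends. A flat local
#' maximum yields one core spanning the plateau; scan-unit boundaries
#' count as lower neighbours.
#'
#' @param events Per-sample event tibble (`sample_id`, `from`, `to` probe
#'   indices): FGA or HD focal events, or maximal deleted runs (state LOSS
#'   or HD) for MRD — see [deletion_runs()].
#' @param probe_map A [probe_map()].
#' @param kind `"FGA"`, `"HD"`, or `"MRD"`.
#' @param config A [cna_config()].
#' @return Region tibble: `kind`, `chrom`, `arm`, probe-index intervals
#'   `core_from`/`core_to` and `ext_from`/`ext_to`, genomic intervals
#'   `core_start`/`core_end` and `ext_start`/`ext_end` (0-based half-open),
#'   `max_support`, `n_members`, and list-column `members` (sample ids
#'   whose events intersect the extended interval).
#' @export
detect_recurrent_regions <- function(events, probe_map, kind = c("FGA", "HD", "MRD"),
                                     config = cna_config()) {
  kind <- match.arg(kind)
  probe_map <- stopifnot_probe_map(probe_map)
  min_support <- min_support_for(kind, config)
  slack <- slack_for(kind, config)
  support <- support_vector(events, nrow(probe_map))
  units <- if (kind == "MRD") split(seq_len(nrow(probe_map)), probe_map$arm) else chrom_index(probe_map)

  res <- list()
  for (idx in units) {
    sup <- support[idx]
    if (max(sup) < min_support) next
    r <- rle(sup)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in seq_along(r$values)) {
      s <- r$values[k]
      if (s < min_support) next
      left <- if (k == 1L) -Inf else r$values[k - 1L]
      right <- if (k == length(r$values)) -Inf else r$values[k + 1L]
      if (left >= s || right >= s) next
      ext <- extend_boundaries(sup, starts[k], ends[k], slack)
      res[[length(res) + 1L]] <- tibble::tibble(
        core_from = idx[starts[k]], core_to = idx[ends[k]],
        ext_from = idx[ext[1L]], ext_to = idx[ext[2L]],
        max_support = as.integer(s)
      )
    }
  }
  regions <- if (length(res) == 0) {
    tibble::tibble(core_from = integer(), core_to = integer(),
                   ext_from = integer(), ext_to = integer(),
                   max_support = integer())
  } else {
    dplyr::distinct(dplyr::bind_rows(res))
  }
  finish_regions(regions, events, probe_map, kind)
}

finish_regions <- function(regions, events, pm, kind) {
  members <- lapply(seq_len(nrow(regions)), function(i) {
    hit <- events$from <= regions$ext_to[i] & events$to >= regions$ext_from[i]
    sort(unique(events$sample_id[hit]))
  })
  tibble::tibble(
    kind = rep(kind, nrow(regions)),
    chrom = pm$chrom[regions$core_from],
    arm = pm$arm[regions$core_from],
    core_from = regions$core_from, core_to = regions$core_to,
    ext_from = regions$ext_from, ext_to = regions$ext_to,
    core_start = pm$start[regions$core_from],
    core_end = pm$end[regions$core_to],
    ext_start = pm$start[regions$ext_from],
    ext_end = pm$end[regions$ext_to],
    max_support = regions$max_support,
    n_members = lengths(members),
    members = members
  )
}

#' Extend a core region's boundaries
#'
#' Given the support counts of one scan unit and a core plateau with peak
#' support, returns the maximal contiguous run containing the core whose
#' support is at least `peak - slack` (slack 2 for FGA/MRD, 1 for HD),
#' truncated at the ends of the vector.
#'
#' @param support Integer vector of per-probe support within one scan unit.
#' @param core_from,core_to Local indices of the core plateau.
#' @param slack Allowed drop from the peak support.
#' @return Integer vector `c(from, to)` in local indices.
#' @export
extend_boundaries <- function(support, core_from, core_to, slack) {
  thr <- support[core_from] - slack
  i <- core_from
  while (i > 1L && support[i - 1L] >= thr) i <- i - 1L
  j <- core_to
  while (j < length(support) && support[j + 1L] >= thr) j <- j + 1L
  c(i, j)
}

#' Maximal deleted runs per sample
#'
#' Runs of probes in state LOSS or HD (deletion of any depth), the input to
#' MRD detection and to MRD membership in the alteration matrix.
#'
#' @param calls A `cna_calls` object.
#' @return Event-like tibble `sample_id`, `chrom`, `from`, `to`.
#' @export
deletion_runs <- function(calls) {
  pm <- calls$probe_map
  ci <- chrom_index(pm)
  res <- list()
  for (s in rownames(calls$states)) {
    for (ch in names(ci)) {
      idx <- ci[[ch]]
      runs <- runs_of(calls$states[s, idx] %in% c("LOSS", "HD"))
      if (nrow(runs) == 0) next
      res[[length(res) + 1L]] <- tibble::tibble(
        sample_id = s, chrom = ch, from = idx[runs$from], to = idx[runs$to]
      )
    }
  }
  if (length(res) == 0) {
    return(tibble::tibble(sample_id = character(), chrom = character(),
                          from = integer(), to = integer()))
  }
  dplyr::bind_rows(res)
}

#' Remove regions with high germline-CNV overlap
#'
#' A region is removed when the fraction of its extended genomic interval
#' covered by known copy-number-variant intervals exceeds
#' `cnv_overlap_max`. With no CNV table supplied all regions are kept and a
#' warning is emitted.
#'
#' @param regions Region tibble from [detect_recurrent_regions()].
#' @param cnv Interval tibble (`chrom`, `start`, `end`) from [read_bed()],
#'   or `NULL`.
#' @param cnv_overlap_max Maximum tolerated covered fraction (default 0.5).
#' @return The filtered region tibble; removed regions in attribute
#'   `"removed"`.
#' @export
apply_cnv_mask <- function(regions, cnv, cnv_overlap_max = 0.5) {
  if (is.null(cnv) || nrow(cnv) == 0) {
    warning("no CNV intervals supplied; all regions kept", call. = FALSE)
    attr(regions, "removed") <- regions[0, ]
    return(regions)
  }
  frac <- vapply(seq_len(nrow(regions)), function(i) {
    covered_fraction(regions$chrom[i], regions$ext_start[i], regions$ext_end[i], cnv)
  }, 0)
  keep <- frac <= cnv_overlap_max
  out <- regions[keep, ]
  attr(out, "removed") <- regions[!keep, ]
  out
}

covered_fraction <- function(chrom, start, end, cnv) {
  iv <- cnv[cnv$chrom == chrom & cnv$end > start & cnv$start < end, ]
  if (nrow(iv) == 0) return(0)
  s <- pmax(iv$start, start)
  e <- pmin(iv$end, end)
  o <- order(s)
  s <- s[o]; e <- e[o]
  covered <- 0
  cur_s <- s[1]; cur_e <- e[1]
  for (i in seq_along(s)[-1]) {
    if (s[i] > cur_e) {
      covered <- covered + (cur_e - cur_s)
      cur_s <- s[i]; cur_e <- e[i]
    } else cur_e <- max(cur_e, e[i])
  }
  covered <- covered + (cur_e - cur_s)
  covered / (end - start)
}

#' Resolve overlaps between MRD and HD regions
#'
#' Where an MRD's extended interval intersects an HD's extended interval,
#' the HD-defined region takes precedence: the MRD is dropped and the HD
#' region(s) stand in for it. Non-overlapping MRDs are kept unchanged.
#'
#' @param mrds,hds Region tibbles on a shared probe map.
#' @return Combined region tibble (all HDs plus surviving MRDs).
#' @export
resolve_mrd_hd_overlap <- function(mrds, hds) {
  if (nrow(mrds) == 0) return(hds)
  overlapped <- vapply(seq_len(nrow(mrds)), function(i) {
    any(hds$chrom == mrds$chrom[i] &
          hds$ext_from <= mrds$ext_to[i] & hds$ext_to >= mrds$ext_from[i])
  }, TRUE)
  dplyr::bind_rows(hds, mrds[!overlapped, ])
}

#' Drop arm-scale MRDs
#'
#' Deletions covering most of an arm cannot define a meaningful minimal
#' region; an MRD whose extended interval covers more than
#' `max_arm_fraction` of its arm's probes is dropped and the event is left
#' to the arm-level call.
#'
#' @param mrds MRD region tibble.
#' @param probe_map A [probe_map()].
#' @param max_arm_fraction Strict cutoff on the covered arm fraction
#'   (default 0.5).
#' @return The filtered MRD tibble.
#' @export
suppress_arm_scale_mrds <- function(mrds, probe_map, max_arm_fraction = 0.5) {
  if (nrow(mrds) == 0) return(mrds)
  probe_map <- stopifnot_probe_map(probe_map)
  arm_n <- table(probe_map$arm)
  frac <- (mrds$ext_to - mrds$ext_from + 1) / as.integer(arm_n[mrds$arm])
  mrds[frac <= max_arm_fraction, ]
}

#' Recurrent arm-level features
#'
#' An arm gain/loss is a recurrent feature when strictly more than
#' `arm_recurrence_fraction` of samples carry it.
#'
#' @param arm_calls Tibble from [call_arm_events()].
#' @param config A [cna_config()].
#' @return Tibble `feature`, `chrom`, `arm`, `direction`, `n_carriers`,
#'   `freq`, list-column `members`.
#' @export
recurrent_arm_regions <- function(arm_calls, config = cna_config()) {
  n_samples <- dplyr::n_distinct(arm_calls$sample_id)
  out <- arm_calls |>
    dplyr::filter(.data$call != "none") |>
    dplyr::group_by(.data$chrom, .data$arm, direction = .data$call) |>
    dplyr::summarise(n_carriers = dplyr::n(),
                     members = list(sort(.data$sample_id)), .groups = "drop") |>
    dplyr::mutate(freq = .data$n_carriers / n_samples,
                  feature = paste0("ARM_", toupper(.data$direction), "_", .data$arm)) |>
    dplyr::filter(.data$freq > config$arm_recurrence_fraction)
  out[c("feature", "chrom", "arm", "direction", "n_carriers", "freq", "members")]
}

#' Run the full recurrent-alteration discovery
#'
#' FGA and HD regions from focal events, MRDs from deleted runs; arm-scale
#' MRD suppression, MRD/HD overlap resolution, optional CNV masking, and
#' recurrent arm features.
#'
#' @param calls A `cna_calls` object from [call_cna()].
#' @param cnv Optional CNV interval tibble for masking.
#' @param config A [cna_config()].
#' @return List with `regions` (FGA/HD/MRD region tibble), `arm_features`,
#'   `support` (per-probe support by kind), class `recurrent_alterations`.
#' @export
recurrent_alterations <- function(calls, cnv = NULL, config = cna_config()) {
  pm <- calls$probe_map
  ev <- calls$events
  fga <- detect_recurrent_regions(ev[ev$kind == "FGA", ], pm, "FGA", config)
  hd <- detect_recurrent_regions(ev[ev$kind == "HD", ], pm, "HD", config)
  del <- deletion_runs(calls)
  mrd <- detect_recurrent_regions(del, pm, "MRD", config)
  mrd <- suppress_arm_scale_mrds(mrd, pm, config$max_arm_fraction)
  del_regions <- resolve_mrd_hd_overlap(mrd, hd)
  regions <- dplyr::bind_rows(fga, del_regions) |>
    dplyr::distinct(.data$kind, .data$core_from, .data$core_to,
                    .data$ext_from, .data$ext_to, .keep_all = TRUE)
  if (!is.null(cnv)) regions <- apply_cnv_mask(regions, cnv, config$cnv_overlap_max)
  support <- dplyr::bind_rows(
    dplyr::mutate(support_counts(ev[ev$kind == "FGA", ], pm), kind = "FGA"),
    dplyr::mutate(support_counts(ev[ev$kind == "HD", ], pm), kind = "HD"),
    dplyr::mutate(support_counts(del, pm), kind = "MRD")
  )
  structure(list(regions = regions,
                 arm_features = recurrent_arm_regions(calls$arm_calls, config),
                 support = support, deletion_runs = del, config = config),
            class = "recurrent_alterations")
}

#' @export
print.recurrent_alterations <- function(x, ...) {
  cat("<recurrent_alterations>\n")
  print(table(x$regions$kind))
  cat("arm features:", nrow(x$arm_features), "\n")
  invisible(x)
}

#' Build the binary sample-by-alteration matrix
#'
#' One column per recurrent region, recurrent arm event, and mutation
#' feature. A sample carries a region feature when one of its focal events
#' (FGA/HD) or deleted runs (MRD) intersects the region's extended
#' interval; arm and mutation features are carried as called. FGA/HD
#' features rarer than `mds_min_freq` are flagged `excluded_mds` (kept for
#' all other analyses).
#'
#' @param recurrence A `recurrent_alterations` object (or a region tibble).
#' @param calls The `cna_calls` object the regions came from.
#' @param mutations Optional tibble `sample_id`, `gene`, `status`
#'   (`"wildtype"`/`"mutated"`); sample ids must be a subset of the called
#'   samples.
#' @param config A [cna_config()].
#' @return Object of class `alteration_matrix`: list with `matrix`
#'   (samples x features, 0/1) and `features` (metadata tibble with
#'   `feature`, `kind`, `chrom`, `freq`, `excluded_mds`).
#' @export
build_alteration_matrix <- function(recurrence, calls, mutations = NULL,
                                    config = cna_config()) {
  samples <- rownames(calls$states)
  regions <- if (inherits(recurrence, "recurrent_alterations")) recurrence$regions else recurrence
  arm_features <- if (inherits(recurrence, "recurrent_alterations")) {
    recurrence$arm_features
  } else {
    recurrent_arm_regions(calls$arm_calls, config)
  }
  cols <- list(); meta <- list()
  if (nrow(regions) > 0) {
    ev <- calls$events
    del <- if (inherits(recurrence, "recurrent_alterations") &&
               !is.null(recurrence$deletion_runs)) {
      recurrence$deletion_runs
    } else {
      deletion_runs(calls)
    }
    for (i in seq_len(nrow(regions))) {
      src <- if (regions$kind[i] == "MRD") del else ev[ev$kind == regions$kind[i], ]
      hit <- src$from <= regions$ext_to[i] & src$to >= regions$ext_from[i]
      carriers <- unique(src$sample_id[hit])
      nm <- sprintf("%s_%s:%d-%d", regions$kind[i], regions$chrom[i],
                    regions$ext_start[i], regions$ext_end[i])
      cols[[nm]] <- as.integer(samples %in% carriers)
      meta[[nm]] <- tibble::tibble(feature = nm, kind = regions$kind[i],
                                   chrom = regions$chrom[i])
    }
  }
  for (i in seq_len(nrow(arm_features))) {
    nm <- arm_features$feature[i]
    cols[[nm]] <- as.integer(samples %in% arm_features$members[[i]])
    meta[[nm]] <- tibble::tibble(feature = nm,
                                 kind = paste0("ARM_", toupper(arm_features$direction[i])),
                                 chrom = arm_features$chrom[i])
  }
  if (!is.null(mutations) && nrow(mutations) > 0) {
    offenders <- setdiff(unique(mutations$sample_id), samples)
    if (length(offenders) > 0) {
      stop("mutation table has sample id(s) absent from the calls: ",
           paste(utils::head(offenders, 10), collapse = ", "), call. = FALSE)
    }
    for (g in unique(mutations$gene)) {
      carriers <- mutations$sample_id[mutations$gene == g &
                                        mutations$status == "mutated"]
      nm <- paste0("MUT_", g)
      cols[[nm]] <- as.integer(samples %in% carriers)
      meta[[nm]] <- tibble::tibble(feature = nm, kind = "MUT", chrom = NA_character_)
    }
  }
  m <- if (length(cols) == 0) {
    matrix(integer(0), nrow = length(samples), ncol = 0,
           dimnames = list(samples, character(0)))
  } else {
    do.call(cbind, cols) |> `rownames<-`(samples)
  }
  features <- dplyr::bind_rows(meta)
  if (nrow(features) > 0) {
    features$freq <- unname(colMeans(m)[features$feature])
    features$excluded_mds <- features$kind %in% c("FGA", "HD") &
      features$freq < config$mds_min_freq
  } else {
    features <- tibble::tibble(feature = character(), kind = character(),
                               chrom = character(), freq = numeric(),
                               excluded_mds = logical())
  }
  structure(list(matrix = m, features = features), class = "alteration_matrix")
}

#' @export
print.alteration_matrix <- function(x, ...) {
  cat("<alteration_matrix> ", nrow(x$matrix), " samples x ", ncol(x$matrix),
      " features\n", sep = "")
  invisible(x)
}

#' @method tidy alteration_matrix
#' @export
tidy.alteration_matrix <- function(x, ...) {
  out <- tibble::as_tibble(x$matrix, rownames = "sample_id")
  tidyr::pivot_longer(out, -"sample_id", names_to = "feature",
                      values_to = "carrier")
}
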