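#' Smooth segmented profiles over a genomic window
#'
#' Replaces each probe's value by the mean of non-missing segmented values
#' of probes (same chromosome) whose midpoints lie within half the window
#' width of the probe's own midpoint. Gain/loss calling against the
#' sample-adaptive threshold operates on these smoothed values.
#'
#' @param profiles Long tibble `sample_id`, `probe_id`, `log2` aligned to
#'   `probe_map` (see [read_segmented_profiles()]).
#' @param probe_map A [probe_map()].
#' @param window_bp Window width in bp (default 250 kb, i.e. +/-125 kb).
#' @return The input tibble with an added `smoothed` column.
#' @export
smooth_profiles <- function(profiles, probe_map, window_bp = 250000) {
  probe_map <- stopifnot_probe_map(probe_map)
  m <- profiles_matrix(profiles, probe_map)
  sm <- smooth_matrix(m, probe_map, window_bp)
  out <- matrix_profiles(m, probe_map)
  out$smoothed <- as.vector(t(sm))
  out
}

# samples x probes matrix -> same-shape matrix of windowed means
smooth_matrix <- function(m, pm, window_bp) {
  half <- window_bp / 2
  mid <- probe_midpoints(pm)
  out <- matrix(NA_real_, nrow(m), ncol(m), dimnames = dimnames(m))
  for (idx in chrom_index(pm)) {
    cm <- mid[idx]
    lo <- findInterval(cm - half, cm, left.open = TRUE) + 1L
    hi <- findInterval(cm + half, cm)
    v <- m[, idx, drop = FALSE]
    ok <- !is.na(v)
    v0 <- v
    v0[!ok] <- 0
    cs <- cbind(0, t(apply(v0, 1, cumsum)))
    cn <- cbind(0, t(apply(ok, 1, cumsum)))
    tot <- cs[, hi + 1L, drop = FALSE] - cs[, lo, drop = FALSE]
    cnt <- cn[, hi + 1L, drop = FALSE] - cn[, lo, drop = FALSE]
    sm <- tot / cnt
    sm[cnt == 0] <- NA_real_
    out[, idx] <- sm
  }
  out
}

#' Estimate per-sample adaptive thresholds (SAT)
#'
#' The SAT is a per-sample noise-calibrated cutoff separating gain/loss
#' from neutral. It is defined here as `multiplier` times a robust noise
#' scale: the normal-consistent MAD of probe-to-probe first differences of
#' the segmented values (within chromosomes, adjacent non-missing probes),
#' each difference divided by sqrt(2). Because segmented profiles are
#' piecewise constant, most first differences are exactly zero and the
#' estimate collapses to `sat_floor`; the floor is then the operative
#' threshold. Input with residual probe-level scatter yields a genuinely
#' adaptive value.
#'
#' @inheritParams smooth_profiles
#' @param multiplier Multiplier on the robust noise scale (default 2.5).
#' @param sat_floor Minimum returned threshold (default 0.05).
#' @return Tibble `sample_id`, `sat`.
#' @export
estimate_sat <- function(profiles, probe_map, multiplier = 2.5, sat_floor = 0.05) {
  probe_map <- stopifnot_probe_map(probe_map)
  m <- profiles_matrix(profiles, probe_map)
  ci <- chrom_index(probe_map)
  sat <- apply(m, 1, function(v) sat_one(v, ci, multiplier, sat_floor))
  tibble::tibble(sample_id = rownames(m), sat = unname(sat))
}

sat_one <- function(v, ci, multiplier, sat_floor) {
  if (sum(!is.na(v)) < 30) {
    stop("SAT estimation needs at least 30 non-missing probes", call. = FALSE)
  }
  d <- unlist(lapply(ci, function(idx) diff(v[idx][!is.na(v[idx])])),
              use.names = FALSE) / sqrt(2)
  if (length(d) == 0) return(sat_floor)
  scale <- multiplier * 1.4826 * stats::median(abs(d - stats::median(d)))
  max(sat_floor, scale)
}

#' Call per-probe copy-number states
#'
#' Assigns each probe of each sample one of `AMP`, `GAIN`, `NEUTRAL`,
#' `LOSS`, `HD`. Gains and losses are called where the smoothed value
#' exceeds the sample's SAT in absolute value; amplifications and
#' homozygous deletions where the unsmoothed segmented value is at or
#' beyond `amp_log2` / `hd_log2` over a run of at least
#' `min_focal_probes` consecutive probes (shorter extreme runs remain
#' GAIN/LOSS). Extreme states dominate: a probe qualifying for both AMP
#' and GAIN is AMP. Probes with missing values are NEUTRAL.
#'
#' @inheritParams smooth_profiles
#' @param config A [cna_config()].
#' @return Long tibble `sample_id`, `probe_id`, `log2`, `smoothed`,
#'   `state` with the per-sample SAT in attribute `"sat"`.
#' @seealso [call_cna()] for the bundled calling result.
#' @export
call_probe_states <- function(profiles, probe_map, config = cna_config()) {
  calls <- call_cna(profiles, probe_map, config)
  out <- tidy(calls)
  attr(out, "sat") <- calls$sat
  out
}

#' Run the full copy-number calling step
#'
#' Smooths profiles, estimates SATs, calls probe states, extracts focal
#' events (FGA/HD runs) and arm-level gain/loss calls.
#'
#' @inheritParams call_probe_states
#' @return An object of class `cna_calls`: a list with `states` (samples x
#'   probes character matrix), `smoothed`, `sat`, `events` (focal event
#'   tibble), `arm_calls`, `probe_map`, `config`. Use [tidy()] for a long
#'   state tibble and [focal_events()] / [arm_calls()] for the pieces.
#' @export
call_cna <- function(profiles, probe_map, config = cna_config()) {
  probe_map <- stopifnot_probe_map(probe_map)
  m <- profiles_matrix(profiles, probe_map)
  sm <- smooth_matrix(m, probe_map, config$window_bp)
  sat_tbl <- estimate_sat(profiles, probe_map, config$sat_multiplier,
                          config$sat_floor)
  sat <- sat_tbl$sat[match(rownames(m), sat_tbl$sample_id)]
  ci <- chrom_index(probe_map)

  states <- matrix("NEUTRAL", nrow(m), ncol(m), dimnames = dimnames(m))
  states[!is.na(sm) & sm > sat] <- "GAIN"
  states[!is.na(sm) & sm < -sat] <- "LOSS"
  # focal extremes on unsmoothed values, run-length gated
  for (s in seq_len(nrow(m))) {
    for (idx in ci) {
      v <- m[s, idx]
      states[s, idx[extreme_run_probes(v >= config$amp_log2, config$min_focal_probes)]] <- "AMP"
      states[s, idx[extreme_run_probes(v <= config$hd_log2, config$min_focal_probes)]] <- "HD"
    }
  }
  states[, ][is.na(m)] <- "NEUTRAL"

  events <- extract_focal_events(states, m, probe_map)
  arms <- arm_calls_from_states(states, probe_map, config)
  structure(list(states = states, values = m, smoothed = sm, sat = sat_tbl,
                 events = events, arm_calls = arms,
                 probe_map = probe_map, config = config),
            class = "cna_calls")
}

# logical vector (NA = FALSE) -> local indices covered by runs of length >= k
extreme_run_probes <- function(flag, k) {
  flag[is.na(flag)] <- FALSE
  if (!any(flag)) return(integer(0))
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= k
  if (!any(keep)) return(integer(0))
  unlist(Map(seq.int, starts[keep], ends[keep]), use.names = FALSE)
}

# maximal AMP and HD runs per sample -> focal event tibble
extract_focal_events <- function(states, m, pm) {
  ci <- chrom_index(pm)
  chroms <- names(ci)
  res <- list()
  for (s in rownames(states)) {
    for (ch in chroms) {
      idx <- ci[[ch]]
      for (kind in c("FGA", "HD")) {
        st <- if (kind == "FGA") "AMP" else "HD"
        runs <- runs_of(states[s, idx] == st)
        if (nrow(runs) == 0) next
        from <- idx[runs$from]
        to <- idx[runs$to]
        res[[length(res) + 1L]] <- tibble::tibble(
          sample_id = s, chrom = ch, kind = kind,
          from = from, to = to,
          start = pm$start[from], end = pm$end[to],
          n_probes = to - from + 1L,
          mean_log2 = vapply(seq_along(from), function(i) {
            mean(m[s, from[i]:to[i]], na.rm = TRUE)
          }, 0)
        )
      }
    }
  }
  if (length(res) == 0) return(empty_events())
  dplyr::bind_rows(res)
}

empty_events <- function() {
  tibble::tibble(sample_id = character(), chrom = character(),
                 kind = character(), from = integer(), to = integer(),
                 start = integer(), end = integer(), n_probes = integer(),
                 mean_log2 = numeric())
}

runs_of <- function(flag) {
  flag[is.na(flag)] <- FALSE
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble::tibble(from = starts[keep], to = ends[keep])
}

#' Merge nearby amplicons
#'
#' Focal events of one kind on the same chromosome of the same sample whose
#' genomic gap is smaller than `merge_gap_bp` are unioned; the number of
#' merged events is the sample's amplicon count used for nFGA.
#'
#' @param events Focal event tibble (see [focal_events()]).
#' @param merge_gap_bp Maximum gap (strictly less than) for merging;
#'   default 1 Mbp.
#' @return Event tibble with merged intervals; `n_probes` is the number of
#'   probes in the merged span and `mean_log2` the event-length-weighted
#'   mean of the members.
#' @export
merge_amplicons <- function(events, merge_gap_bp = 1000000) {
  if (nrow(events) == 0) return(events)
  events |>
    dplyr::group_by(.data$sample_id, .data$kind, .data$chrom) |>
    dplyr::group_modify(function(df, key) merge_events_one(df, merge_gap_bp)) |>
    dplyr::ungroup()
}

merge_events_one <- function(df, gap) {
  df <- dplyr::arrange(df, .data$start)
  grp <- cumsum(c(0, as.integer(df$start[-1] - df$end[-nrow(df)] >= gap)))
  df |>
    dplyr::mutate(.grp = grp) |>
    dplyr::group_by(.data$.grp) |>
    dplyr::summarise(
      from = min(.data$from), to = max(.data$to),
      start = min(.data$start), end = max(.data$end),
      mean_log2 = stats::weighted.mean(.data$mean_log2, .data$n_probes),
      n_probes = max(.data$to) - min(.data$from) + 1L,
      .groups = "drop"
    ) |>
    dplyr::select(-".grp")
}

#' Call arm-level gains and losses
#'
#' An arm is called gained in a sample when the fraction of its probes in
#' state GAIN or AMP strictly exceeds `arm_probe_fraction` (default 0.5);
#' lost analogously with LOSS/HD. If both fractions pass, the larger wins;
#' a tie gives no call.
#'
#' @param calls A `cna_calls` object from [call_cna()], or a long state
#'   tibble with columns `sample_id`, `probe_id`, `state`.
#' @inheritParams call_probe_states
#' @return Tibble `sample_id`, `chrom`, `arm`, `call` (gain/loss/none),
#'   `frac_gain`, `frac_loss`.
#' @export
call_arm_events <- function(calls, probe_map = NULL, config = cna_config()) {
  if (inherits(calls, "cna_calls")) return(calls$arm_calls)
  probe_map <- stopifnot_probe_map(probe_map)
  states <- profiles_matrix(
    dplyr::rename(calls, log2 = "state") |>
      dplyr::mutate(log2 = as.numeric(factor(.data$log2, levels = state_levels()))),
    probe_map
  )
  chr <- matrix(state_levels()[states], nrow(states), ncol(states),
                dimnames = dimnames(states))
  arm_calls_from_states(chr, probe_map, config)
}

state_levels <- function() c("HD", "LOSS", "NEUTRAL", "GAIN", "AMP")

arm_calls_from_states <- function(states, pm, config) {
  arms <- split(seq_len(nrow(pm)), pm$arm)
  res <- lapply(names(arms), function(a) {
    idx <- arms[[a]]
    g <- rowMeans(states[, idx, drop = FALSE] == "GAIN" |
                    states[, idx, drop = FALSE] == "AMP")
    l <- rowMeans(states[, idx, drop = FALSE] == "LOSS" |
                    states[, idx, drop = FALSE] == "HD")
    call <- rep("none", length(g))
    call[g > config$arm_probe_fraction & g > l] <- "gain"
    call[l > config$arm_probe_fraction & l > g] <- "loss"
    tibble::tibble(sample_id = rownames(states), chrom = pm$chrom[idx[1]],
                   arm = a, call = call, frac_gain = unname(g),
                   frac_loss = unname(l))
  })
  dplyr::bind_rows(res) |> dplyr::arrange(.data$sample_id, .data$chrom, .data$arm)
}

#' @export
print.cna_calls <- function(x, ...) {
  cat("<cna_calls> ", nrow(x$states), " samples x ", ncol(x$states), " probes\n",
      sep = "")
  tab <- table(factor(x$states, levels = state_levels()))
  cat("  states:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  cat("  focal events:", nrow(x$events), " arm calls:",
      sum(x$arm_calls$call != "none"), "\n")
  invisible(x)
}

#' Accessors for `cna_calls` components
#'
#' @param calls A `cna_calls` object.
#' @return [focal_events()]: tibble of maximal AMP/HD runs (`sample_id`,
#'   `chrom`, `kind` FGA/HD, probe-index interval `from`/`to`, genomic
#'   `start`/`end`, `n_probes`, `mean_log2`). [arm_calls()]: per-sample
#'   arm-level call tibble.
#' @export
focal_events <- function(calls) calls$events

#' @rdname focal_events
#' @export
arm_calls <- function(calls) calls$arm_calls

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy cna_calls
#' @export
tidy.cna_calls <- function(x, ...) {
  out <- matrix_profiles(x$smoothed, x$probe_map, value_name = "smoothed")
  out$log2 <- as.vector(t(x$values))
  out$state <- as.vector(t(x$states))
  out[c("sample_id", "probe_id", "log2", "smoothed", "state")]
}

#' @method glance cna_calls
#' @export
glance.cna_calls <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$states), n_probes = ncol(x$states),
    n_focal_events = nrow(x$events),
    n_arm_events = sum(x$arm_calls$call != "none"),
    median_sat = stats::median(x$sat$sat)
  )
}
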