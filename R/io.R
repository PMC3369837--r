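#' Read segmented copy-number profiles
#'
#' Reads a tab-delimited table of per-probe segmented log2 ratios and aligns
#' it to a probe map. Two layouts are auto-detected:
#'
#' * long ("SEG-like"): columns `sample_id`, `probe_id`, `log2`;
#' * wide: a `probe_id` column followed by one numeric column per sample.
#'
#' Probes present in the map but absent from the file become missing values.
#' Probes present in the file but unknown to the map are dropped; if their
#' fraction exceeds `missing_tolerance` this is a hard error listing the
#' offending ids.
#'
#' @param path Tab-delimited file with a header line.
#' @param probe_map A [probe_map()].
#' @param missing_tolerance Maximum tolerated fraction of file probe ids not
#'   found in the probe map (default 0).
#' @return A long tibble `sample_id`, `probe_id`, `log2` with one row per
#'   sample x map probe, probes in map order within each sample.
#' @export
read_segmented_profiles <- function(path, probe_map, missing_tolerance = 0) {
  probe_map <- stopifnot_probe_map(probe_map)
  x <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  long <- all(c("sample_id", "probe_id", "log2") %in% names(x))
  if (!long && !"probe_id" %in% names(x)) {
    stop("cannot detect layout of ", path,
         ": need columns sample_id/probe_id/log2 (long) or probe_id + sample columns (wide)",
         call. = FALSE)
  }
  if (long) {
    dup <- duplicated(x[c("sample_id", "probe_id")])
    if (any(dup)) {
      d <- x[dup, ][1, ]
      stop("duplicated (sample, probe) row: (", d$sample_id, ", ", d$probe_id, ")",
           call. = FALSE)
    }
    x$log2 <- parse_log2(x$log2, path)
    prof <- x[c("sample_id", "probe_id", "log2")]
  } else {
    sample_cols <- setdiff(names(x), "probe_id")
    if (length(sample_cols) == 0) stop("wide table has no sample columns", call. = FALSE)
    if (anyDuplicated(x$probe_id)) {
      stop("duplicated probe_id row(s): ",
           paste(utils::head(unique(x$probe_id[duplicated(x$probe_id)]), 5), collapse = ", "),
           call. = FALSE)
    }
    prof <- tidyr::pivot_longer(x, -"probe_id", names_to = "sample_id",
                                values_to = "log2")
    prof$log2 <- parse_log2(prof$log2, path)
    prof <- prof[c("sample_id", "probe_id", "log2")]
  }
  unknown <- setdiff(unique(prof$probe_id), probe_map$probe_id)
  if (length(unknown) > 0) {
    frac <- length(unknown) / dplyr::n_distinct(prof$probe_id)
    if (frac > missing_tolerance) {
      stop("probe id(s) absent from probe map: ",
           paste(utils::head(sort(unknown), 10), collapse = ", "),
           call. = FALSE)
    }
    warning(length(unknown), " probe id(s) absent from probe map were dropped",
            call. = FALSE)
    prof <- prof[!prof$probe_id %in% unknown, ]
  }
  # align to map order, filling absent probes with NA
  samples <- unique(prof$sample_id)
  grid <- tidyr::expand_grid(sample_id = samples, probe_id = probe_map$probe_id)
  out <- dplyr::left_join(grid, prof, by = c("sample_id", "probe_id"))
  tibble::as_tibble(out)
}

parse_log2 <- function(v, path) {
  out <- suppressWarnings(as.numeric(v))
  bad <- which(!is.na(v) & v != "NA" & v != "" & is.na(out))
  if (length(bad) > 0) {
    stop("non-numeric log2 value ", dQuote(v[bad[1]]), " at data row ", bad[1],
         " of ", path, call. = FALSE)
  }
  if (any(!is.finite(out) & !is.na(out))) {
    stop("non-finite log2 value in ", path, call. = FALSE)
  }
  out
}

# profiles long tibble -> samples x probes matrix in map order
profiles_matrix <- function(profiles, probe_map) {
  probe_map <- stopifnot_probe_map(probe_map)
  samples <- unique(profiles$sample_id)
  m <- matrix(NA_real_, nrow = length(samples), ncol = nrow(probe_map),
              dimnames = list(samples, probe_map$probe_id))
  i <- match(profiles$sample_id, samples)
  j <- match(profiles$probe_id, probe_map$probe_id)
  keep <- !is.na(j)
  m[cbind(i[keep], j[keep])] <- profiles$log2[keep]
  m
}

matrix_profiles <- function(m, probe_map, value_name = "log2") {
  out <- tidyr::expand_grid(sample_id = rownames(m), probe_id = colnames(m))
  out[[value_name]] <- as.vector(t(m))
  out
}

#' Read a BED interval file
#'
#' Minimal BED reader (3-4 columns, 0-based half-open, no header). Intervals
#' are returned sorted within chromosome. Malformed rows produce
#' line-numbered errors.
#'
#' @param path BED file path.
#' @return Tibble `chrom`, `start`, `end`, `name` (name `NA` when absent).
#' @export
read_bed <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), name = character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(parts)
  if (any(n_fields < 3)) {
    stop("BED line ", which(n_fields < 3)[1], " has fewer than 3 fields",
         call. = FALSE)
  }
  chrom <- vapply(parts, `[[`, "", 1)
  start <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2)))
  end <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 3)))
  if (anyNA(start) || anyNA(end)) {
    stop("BED line ", which(is.na(start) | is.na(end))[1],
         " has a non-integer coordinate", call. = FALSE)
  }
  if (any(start >= end)) {
    stop("BED line ", which(start >= end)[1], " has start >= end", call. = FALSE)
  }
  name <- ifelse(n_fields >= 4, vapply(parts, function(p) p[min(4, length(p))], ""),
                 NA_character_)
  out <- tibble::tibble(chrom = chrom, start = start, end = end, name = name)
  dplyr::arrange(out, .data$chrom, .data$start, .data$end)
}

#' @rdname read_bed
#' @param intervals Tibble with `chrom`, `start`, `end` and optionally
#'   `name`, `score`.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  cols <- c("chrom", "start", "end",
            intersect(c("name", "score"), names(intervals)))
  readr::write_tsv(intervals[cols], path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Write and read recurrent-region tables
#'
#' TSV output carries all region fields (member sample ids joined by commas)
#' and round-trips losslessly through [read_region_table()]. BED output
#' keeps the extended genomic interval, `kind:chrom:core` as name and the
#' peak support as score.
#'
#' @param regions A region tibble as produced by
#'   [detect_recurrent_regions()].
#' @param path Output file.
#' @param format `"tsv"` (lossless) or `"bed"`.
#' @return `path`, invisibly.
#' @export
write_region_table <- function(regions, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "bed") {
    bed <- tibble::tibble(
      chrom = regions$chrom,
      start = regions$ext_start, end = regions$ext_end,
      name = paste0(regions$kind, ":", regions$chrom, ":",
                    regions$core_start, "-", regions$core_end),
      score = regions$max_support
    )
    return(write_bed(bed, path))
  }
  flat <- regions
  flat$members <- vapply(regions$members, paste, "", collapse = ",")
  readr::write_tsv(flat, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_region_table
#' @export
read_region_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(
                         kind = "c", chrom = "c", members = "c",
                         .default = readr::col_guess()
                       ))
  mem <- as.character(x$members)
  mem[is.na(mem)] <- ""
  x$members <- lapply(strsplit(mem, ","), function(v) v[nzchar(v)])
  if (nrow(x) == 0) x$members <- list()
  int_cols <- intersect(c("core_from", "core_to", "ext_from", "ext_to",
                          "core_start", "core_end", "ext_start", "ext_end",
                          "max_support", "n_members"), names(x))
  for (nm in int_cols) x[[nm]] <- as.integer(x[[nm]])
  tibble::as_tibble(x)
}
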