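#' Construct and validate a probe map
#'
#' The probe map is the ordered genomic grid on which every profile, call
#' matrix and recurrent region is defined. It mimics a tiling BAC-array
#' annotation: one row per probe (clone), with genomic coordinates and the
#' chromosome arm the probe belongs to. All genomic coordinates in the
#' package are 0-based, half-open (BED convention).
#'
#' Downstream code relies on the invariants enforced here: rows sorted by
#' (chrom, start), unique probe ids, `start < end`, and exactly one arm per
#' probe. Every per-probe vector in the package is aligned to the row order
#' of this table.
#'
#' @param x A data frame with columns `probe_id`, `chrom`, `start`, `end`,
#'   `arm`.
#' @return A tibble with the same columns, sorted by (chrom, start), of
#'   class `probe_map`.
#' @examples
#' probe_map(data.frame(
#'   probe_id = c("p1", "p2"), chrom = "chr1",
#'   start = c(0L, 100000L), end = c(50000L, 150000L), arm = "chr1p"
#' ))
#' @export
probe_map <- function(x) {
  required <- c("probe_id", "chrom", "start", "end", "arm")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop("probe map is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  x <- tibble::as_tibble(x)[required]
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  if (anyNA(x)) stop("probe map contains missing values", call. = FALSE)
  if (any(x$start >= x$end)) {
    bad <- x$probe_id[x$start >= x$end]
    stop("probe(s) with start >= end: ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(x$probe_id)) {
    dup <- unique(x$probe_id[duplicated(x$probe_id)])
    stop("duplicated probe id(s): ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  x <- dplyr::arrange(x, .data$chrom, .data$start)
  # an arm must not be split across chromosomes, nor interleave with the
  # other arm of the same chromosome
  arm_chrom <- unique(x[c("arm", "chrom")])
  if (anyDuplicated(arm_chrom$arm)) {
    stop("arm label assigned to more than one chromosome", call. = FALSE)
  }
  structure(x, class = c("probe_map", class(x)))
}

#' Read a probe map from a tab-delimited annotation file
#'
#' Expects a header line with columns `probe_id`, `chrom`, `start`, `end`,
#' `arm`; coordinates 0-based half-open.
#'
#' @param path Path to a tab-delimited file.
#' @return A validated [probe_map()] tibble.
#' @export
read_probe_map <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  probe_map(x)
}

# row indices of probes per chromosome, in map order
chrom_index <- function(pm) {
  split(seq_len(nrow(pm)), pm$chrom)
}

# probe midpoints (numeric, for window arithmetic)
probe_midpoints <- function(pm) {
  (as.numeric(pm$start) + as.numeric(pm$end)) / 2
}

stopifnot_probe_map <- function(pm) {
  if (!inherits(pm, "probe_map")) pm <- probe_map(pm)
  pm
}
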