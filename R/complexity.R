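#' Number of focal amplicons per sample (nFGA)
#'
#' Counts each sample's merged focal amplifications: FGAs less than
#' `merge_gap_bp` apart count as a single amplicon.
#'
#' @param events Focal event tibble ([focal_events()]); only `kind ==
#'   "FGA"` rows are used.
#' @param samples Optional character vector fixing the sample universe
#'   (samples without FGAs get 0).
#' @param merge_gap_bp Amplicon merge distance (default 1 Mbp).
#' @return Tibble `sample_id`, `nfga`.
#' @export
compute_nfga <- function(events, samples = NULL, merge_gap_bp = 1000000) {
  fga <- events[events$kind == "FGA", ]
  merged <- merge_amplicons(fga, merge_gap_bp)
  counts <- dplyr::count(merged, .data$sample_id, name = "nfga")
  if (is.null(samples)) samples <- unique(events$sample_id)
  out <- tibble::tibble(sample_id = samples)
  out <- dplyr::left_join(out, counts, by = "sample_id")
  out$nfga <- as.integer(dplyr::coalesce(out$nfga, 0L))
  out
}

#' Fraction of altered probes per sample (fBAC)
#'
#' The fraction of a sample's probes in any non-neutral state (GAIN, AMP,
#' LOSS, HD). Probes with missing input values are neutral by convention,
#' so they count in the denominator as unaltered.
#'
#' @param calls A `cna_calls` object.
#' @return Tibble `sample_id`, `fbac`.
#' @export
compute_fbac <- function(calls) {
  tibble::tibble(
    sample_id = rownames(calls$states),
    fbac = unname(rowMeans(calls$states != "NEUTRAL"))
  )
}

#' Per-sample signature expression score
#'
#' Mean over the signature genes of the gene's z-scored expression
#' (gene-wise standardization across samples). Used for the chromosome
#' instability (CIN) score and oncogenic-program signature scores; the gene
#' lists are inputs, not fixed constants.
#'
#' @param expression Normalized log2 expression: wide tibble with a `gene`
#'   column plus one column per sample.
#' @param genes Character vector of signature genes; members absent from
#'   the matrix are skipped with a warning, and having none present is an
#'   error.
#' @return Tibble `sample_id`, `score`.
#' @export
signature_score <- function(expression, genes) {
  m <- expr_matrix(expression)
  present <- intersect(genes, rownames(m))
  if (length(present) == 0) {
    stop("none of the signature genes are present in the expression matrix",
         call. = FALSE)
  }
  if (length(present) < length(genes)) {
    warning(length(genes) - length(present), " signature gene(s) absent, skipped",
            call. = FALSE)
  }
  z <- t(scale(t(m[present, , drop = FALSE])))
  z[is.nan(z)] <- 0 # zero-variance gene contributes nothing
  tibble::tibble(sample_id = colnames(m), score = unname(colMeans(z)))
}

# wide tibble (gene + sample columns) -> genes x samples matrix
expr_matrix <- function(expression) {
  if (is.matrix(expression)) return(expression)
  stopifnot("gene" %in% names(expression))
  m <- as.matrix(expression[setdiff(names(expression), "gene")])
  rownames(m) <- expression$gene
  m
}

expr_tibble <- function(m) tibble::as_tibble(m, rownames = "gene")

#' TP53/MDM2 alteration status
#'
#' A sample is TP53/MDM2-altered when it carries a TP53 mutation, a focal
#' amplification overlapping the MDM2 locus, or a high MDM2 expression
#' category. Samples missing any of the three inputs get `NA`.
#'
#' @param mutations Tibble `sample_id`, `gene`, `status` including TP53
#'   rows.
#' @param events Focal event tibble (FGA rows used).
#' @param mdm2_category Tibble `sample_id`, `category` with the rank-based
#'   MDM2 expression category (`"high"` triggers the call); see
#'   [categorize_gene_expression()].
#' @param mdm2_interval List or tibble row with `chrom`, `from`, `to`
#'   (probe-map indices of the MDM2-like locus).
#' @return Tibble `sample_id`, `tp53_mdm2_altered` (logical, `NA` when
#'   undetermined).
#' @export
classify_tp53_mdm2 <- function(mutations, events, mdm2_category, mdm2_interval) {
  tp53 <- mutations[mutations$gene == "TP53", ]
  samples <- unique(tp53$sample_id)
  fga <- events[events$kind == "FGA" & events$chrom == mdm2_interval$chrom &
                  events$from <= mdm2_interval$to &
                  events$to >= mdm2_interval$from, ]
  out <- tibble::tibble(sample_id = samples)
  out$tp53_mut <- samples %in% tp53$sample_id[tp53$status == "mutated"]
  out$mdm2_amp <- samples %in% fga$sample_id
  cat_map <- mdm2_category$category[match(samples, mdm2_category$sample_id)]
  out$mdm2_high <- cat_map == "high"
  known <- !is.na(cat_map)
  out$tp53_mdm2_altered <- ifelse(known,
                                  out$tp53_mut | out$mdm2_amp | out$mdm2_high,
                                  NA)
  out[c("sample_id", "tp53_mdm2_altered")]
}

#' Immunohistochemistry tumor-cell protein score
#'
#' Per core, intensity (0-3) times the fraction of positive tumor nuclei
#' (on a 10% grid), scaled to 0-300; per sample, the mean over its 1-2
#' cores.
#'
#' @param measurements Tibble `sample_id`, `marker`, `core`, `intensity`,
#'   `fraction`.
#' @return Tibble `sample_id`, `marker`, `score`.
#' @export
ihc_score <- function(measurements) {
  stopifnot(all(measurements$intensity %in% 0:3))
  on_grid <- abs(measurements$fraction * 10 - round(measurements$fraction * 10)) < 1e-9 &
    measurements$fraction >= 0 & measurements$fraction <= 1
  if (!all(on_grid)) {
    stop("IHC fraction off the 10% grid: ",
         paste(utils::head(measurements$fraction[!on_grid], 3), collapse = ", "),
         call. = FALSE)
  }
  measurements |>
    dplyr::mutate(core_score = .data$intensity * .data$fraction * 100) |>
    dplyr::group_by(.data$sample_id, .data$marker) |>
    dplyr::summarise(score = mean(.data$core_score), .groups = "drop")
}

#' Group comparison statistics
#'
#' Two-sided tests used throughout the complexity analyses: Wilcoxon
#' rank-sum (exact for small groups without ties), one-way ANOVA, Pearson
#' correlation, or Welch's t.
#'
#' @param data A data frame.
#' @param value Column name (string) of the numeric response; for
#'   `pearson_r` the first variable.
#' @param group Column name of the grouping factor; for `pearson_r` the
#'   second numeric variable.
#' @param test One of `"wilcoxon_rank_sum"`, `"one_way_anova"`,
#'   `"pearson_r"`, `"welch_t"`.
#' @return One-row tibble `test`, `statistic`, `p_value`, `estimate`.
#' @export
group_stats <- function(data, value, group,
                        test = c("wilcoxon_rank_sum", "one_way_anova",
                                 "pearson_r", "welch_t")) {
  test <- match.arg(test)
  v <- data[[value]]
  g <- data[[group]]
  if (test == "pearson_r") {
    ct <- stats::cor.test(v, g, method = "pearson")
    return(tibble::tibble(test = test, statistic = unname(ct$statistic),
                          p_value = ct$p.value, estimate = unname(ct$estimate)))
  }
  g <- factor(g)
  if (any(table(g) < 2)) stop("every group needs at least 2 observations",
                              call. = FALSE)
  if (test == "wilcoxon_rank_sum") {
    if (nlevels(g) != 2) stop("wilcoxon_rank_sum needs exactly 2 groups", call. = FALSE)
    exact <- all(table(g) <= 25) && !any(duplicated(v))
    wt <- stats::wilcox.test(v ~ g, exact = exact, correct = TRUE)
    est <- diff(rev(tapply(v, g, stats::median)))
    return(tibble::tibble(test = test, statistic = unname(wt$statistic),
                          p_value = wt$p.value, estimate = unname(est)))
  }
  if (test == "one_way_anova") {
    fit <- stats::aov(v ~ g)
    s <- summary(fit)[[1]]
    return(tibble::tibble(test = test, statistic = s[["F value"]][1],
                          p_value = s[["Pr(>F)"]][1],
                          estimate = NA_real_))
  }
  tt <- stats::t.test(v ~ g)
  tibble::tibble(test = test, statistic = unname(tt$statistic),
                 p_value = tt$p.value,
                 estimate = unname(diff(rev(tt$estimate))))
}

#' Per-sample genomic-complexity profile
#'
#' Convenience wrapper combining [compute_nfga()], [compute_fbac()] and,
#' when an expression matrix and CIN gene list are given, the CIN
#' signature score.
#'
#' @param calls A `cna_calls` object.
#' @param expression Optional normalized expression (wide tibble).
#' @param cin_genes Optional CIN signature gene list.
#' @return Tibble `sample_id`, `nfga`, `fbac` and optionally `cin_score`.
#' @export
complexity_profile <- function(calls, expression = NULL, cin_genes = NULL) {
  out <- dplyr::left_join(
    compute_nfga(calls$events, samples = rownames(calls$states),
                 merge_gap_bp = calls$config$merge_gap_bp),
    compute_fbac(calls), by = "sample_id"
  )
  out$nfga[is.na(out$nfga)] <- 0L
  if (!is.null(expression) && !is.null(cin_genes)) {
    cin <- signature_score(expression, cin_genes)
    out <- dplyr::left_join(out, dplyr::rename(cin, cin_score = "score"),
                            by = "sample_id")
  }
  out
}
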