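#' Normalize raw expression intensities
#'
#' The bead-array style pipeline: (1) per-probe scaling of each non-reference
#' labeling batch so its geometric mean matches the reference batch;
#' (2) subtraction of a background constant; (3) capping of negatives to
#' zero and addition of an intensity constant of 30; (4) quantile
#' normalization across samples; (5) log2 transform; (6) variance filter
#' keeping genes with SD strictly greater than `sd_filter`.
#'
#' Probes whose geometric mean is undefined in the reference batch (no
#' positive values) are dropped with a warning. The first batch label in
#' sorted order is the reference unless `ref_batch` says otherwise.
#'
#' @param expression Raw intensities: wide tibble with a `gene` column plus
#'   one column per sample.
#' @param batches Tibble `sample_id`, `batch`.
#' @param ref_batch Reference batch label (default: first sorted label).
#' @param background Background constant subtracted before capping
#'   (default 0).
#' @param offset Intensity constant added after capping (default 30).
#' @param sd_filter Post-log2 SD threshold; genes with SD `<= sd_filter`
#'   are removed. Set to `NULL` (or a negative value) to skip.
#' @return Normalized, filtered wide tibble (log2 scale), with attribute
#'   `"normalized" = TRUE`.
#' @export
normalize_expression <- function(expression, batches, ref_batch = NULL,
                                 background = 0, offset = 30,
                                 sd_filter = 0.25) {
  m <- expr_matrix(expression)
  b <- batches$batch[match(colnames(m), batches$sample_id)]
  if (anyNA(b)) {
    stop("batch label missing for sample(s): ",
         paste(utils::head(colnames(m)[is.na(b)], 5), collapse = ", "),
         call. = FALSE)
  }
  labels <- sort(unique(b))
  if (is.null(ref_batch)) ref_batch <- labels[1]
  stopifnot(ref_batch %in% labels)

  geomean <- function(x) {
    pos <- x[x > 0]
    if (length(pos) == 0) return(NA_real_)
    exp(mean(log(pos)))
  }
  ref_gm <- apply(m[, b == ref_batch, drop = FALSE], 1, geomean)
  drop <- is.na(ref_gm)
  if (any(drop)) {
    warning(sum(drop), " probe(s) without a positive reference-batch value dropped",
            call. = FALSE)
    m <- m[!drop, , drop = FALSE]
    ref_gm <- ref_gm[!drop]
  }
  for (lab in setdiff(labels, ref_batch)) {
    sel <- b == lab
    gm <- apply(m[, sel, drop = FALSE], 1, geomean)
    ratio <- ref_gm / gm
    ratio[!is.finite(ratio)] <- 1
    m[, sel] <- m[, sel, drop = FALSE] * ratio
  }
  m <- m - background
  m[m < 0] <- 0
  m <- m + offset
  m <- limma::normalizeQuantiles(m)
  m <- log2(m)
  if (!is.null(sd_filter) && sd_filter >= 0) {
    sds <- apply(m, 1, stats::sd)
    m <- m[sds > sd_filter, , drop = FALSE]
  }
  out <- expr_tibble(m)
  attr(out, "normalized") <- TRUE
  out
}

#' Hierarchical expression clustering into molecular subtypes
#'
#' Samples are clustered on 1 - Pearson correlation distances with Ward
#' linkage (`ward.D2`); the tree is cut at `k` clusters (HC groups) and at
#' 2 (the MS1/MS2 split). Cluster labels are ordered by decreasing mean
#' expression of `order_gene` when present (FGFR3 by default, mirroring
#' how urothelial subtypes are conventionally arranged), otherwise by
#' decreasing cluster size.
#'
#' @param expression Normalized wide expression tibble.
#' @param k Number of HC clusters (default 5).
#' @param order_gene Gene used to order cluster labels.
#' @return Object of class `hca_fit`: list with `assignments` (tibble
#'   `sample_id`, `hc`, `ms`), the `hclust` tree, `k`. `tidy()` returns
#'   the assignments, `glance()` a one-row summary.
#' @export
hca_clusters <- function(expression, k = 5, order_gene = "FGFR3") {
  m <- expr_matrix(expression)
  if (ncol(m) < 2 || k < 2 || k > ncol(m)) {
    stop("need 2 <= k <= number of samples", call. = FALSE)
  }
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant expression column (undefined correlation) for sample(s): ",
         paste(utils::head(colnames(m)[sds == 0], 5), collapse = ", "),
         call. = FALSE)
  }
  d <- stats::as.dist(1 - stats::cor(m))
  tree <- stats::hclust(d, method = "ward.D2")
  hc_raw <- stats::cutree(tree, k = k)
  ms_raw <- stats::cutree(tree, k = 2)
  hc <- relabel_clusters(hc_raw, m, order_gene, prefix = "HC")
  ms <- relabel_clusters(ms_raw, m, order_gene, prefix = "MS")
  structure(list(
    assignments = tibble::tibble(sample_id = colnames(m), hc = hc, ms = ms),
    tree = tree, k = k, order_gene = order_gene
  ), class = "hca_fit")
}

relabel_clusters <- function(raw, m, order_gene, prefix) {
  ids <- sort(unique(raw))
  key <- if (!is.null(order_gene) && order_gene %in% rownames(m)) {
    -vapply(ids, function(i) mean(m[order_gene, raw == i]), 0)
  } else {
    -vapply(ids, function(i) sum(raw == i), 0)
  }
  rank_map <- rank(key, ties.method = "first")
  paste0(prefix, rank_map[match(raw, ids)])
}

#' @export
print.hca_fit <- function(x, ...) {
  cat("<hca_fit> k =", x$k, "\n")
  print(table(x$assignments$hc))
  print(table(x$assignments$ms))
  invisible(x)
}

#' @method tidy hca_fit
#' @export
tidy.hca_fit <- function(x, ...) x$assignments

#' @method glance hca_fit
#' @export
glance.hca_fit <- function(x, ...) {
  tibble::tibble(k = x$k, n = nrow(x$assignments),
                 n_ms1 = sum(x$assignments$ms == "MS1"),
                 n_ms2 = sum(x$assignments$ms == "MS2"))
}

#' Rank-based categorization of a gene's expression
#'
#' Partitions samples into ordered categories (low/high, or
#' low/intermediate/high) by thresholds on the gene's expression, given
#' either as expression values or as sample-rank quantiles. A sample
#' exactly at a threshold goes to the lower category.
#'
#' @param expression Normalized wide expression tibble.
#' @param gene Gene to categorize.
#' @param thresholds Increasing numeric thresholds: length 1 gives
#'   low/high, length 2 low/intermediate/high.
#' @param type `"quantile"` (thresholds are rank quantiles in (0,1)) or
#'   `"value"` (thresholds on the expression scale).
#' @return Tibble `sample_id`, `value`, `category` (ordered factor), with
#'   the value-scale thresholds in attribute `"thresholds"`.
#' @export
categorize_gene_expression <- function(expression, gene, thresholds,
                                       type = c("quantile", "value")) {
  type <- match.arg(type)
  m <- expr_matrix(expression)
  if (!gene %in% rownames(m)) stop("gene not in expression matrix: ", gene,
                                   call. = FALSE)
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop("thresholds must be strictly increasing", call. = FALSE)
  }
  v <- m[gene, ]
  thr <- if (type == "quantile") {
    stopifnot(all(thresholds > 0), all(thresholds < 1))
    unname(stats::quantile(v, thresholds, type = 1))
  } else {
    thresholds
  }
  levels <- if (length(thr) == 1) c("low", "high") else c("low", "intermediate", "high")
  if (length(thr) > 2) stop("at most two thresholds supported", call. = FALSE)
  cat_idx <- 1L + vapply(v, function(x) sum(x > thr), 0L)
  out <- tibble::tibble(sample_id = colnames(m), value = unname(v),
                        category = factor(levels[cat_idx], levels = levels,
                                          ordered = TRUE))
  attr(out, "thresholds") <- thr
  out
}

#' Differential expression between two sample groups
#'
#' A plain two-sample screen: per-gene Welch's t statistic, two-sided p,
#' and Bonferroni-adjusted p; genes with adjusted p below `alpha` are
#' flagged significant. Genes with zero variance in both groups get p = 1
#' and a flag. This is a deliberately simple substitute for
#' moderated-statistic pipelines; the interface (a gene-level table) is
#' the same, so a moderated variant can drop in.
#'
#' @param expression Normalized wide expression tibble.
#' @param group_a,group_b Character vectors of sample ids (>= 3 each).
#' @param alpha Significance level on the Bonferroni-adjusted p.
#' @return Tibble `gene`, `mean_a`, `mean_b`, `t`, `df`, `p`, `p_bonf`,
#'   `direction` (`"up"` = higher in `group_a`), `significant`,
#'   `zero_variance`.
#' @export
differential_expression <- function(expression, group_a, group_b, alpha = 0.05) {
  m <- expr_matrix(expression)
  missing <- setdiff(c(group_a, group_b), colnames(m))
  if (length(missing) > 0) {
    stop("sample id(s) not in expression matrix: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  if (length(group_a) < 3 || length(group_b) < 3) {
    stop("each group needs at least 3 samples", call. = FALSE)
  }
  a <- m[, group_a, drop = FALSE]
  b <- m[, group_b, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  zero_var <- va == 0 & vb == 0
  tstat[zero_var] <- 0
  p[zero_var] <- 1
  df[zero_var] <- NA_real_
  p_bonf <- stats::p.adjust(p, method = "bonferroni")
  tibble::tibble(
    gene = rownames(m), mean_a = unname(ma), mean_b = unname(mb),
    t = unname(tstat), df = unname(df), p = unname(p),
    p_bonf = unname(p_bonf),
    direction = ifelse(ma >= mb, "up", "down"),
    significant = p_bonf < alpha,
    zero_variance = zero_var
  )
}
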