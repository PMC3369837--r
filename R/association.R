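#' Exact hypergeometric co-occurrence test for one feature pair
#'
#' For binary features a and b over N common samples with margins Ka and
#' Kb and observed overlap k, tests enrichment (co-occurrence) and
#' depletion (exclusivity) of carriers under the hypergeometric null:
#' `p_positive = P(X >= k)`, `p_negative = P(X <= k)` for
#' `X ~ Hypergeometric(N, Ka, Kb)`. Tail sums are accumulated in log
#' space, so tiny p-values stay exact.
#'
#' @param alterations An `alteration_matrix` (see
#'   [build_alteration_matrix()]) or a binary samples x features matrix /
#'   wide tibble with a `sample_id` column.
#' @param feature_a,feature_b Feature (column) names.
#' @return One-row tibble `feature_a`, `feature_b`, `n`, `k_a`, `k_b`,
#'   `overlap`, `p_positive`, `p_negative`.
#' @export
hypergeometric_pair_test <- function(alterations, feature_a, feature_b) {
  m <- alteration_binary(alterations)
  a <- m[, feature_a]
  b <- m[, feature_b]
  n <- length(a)
  ka <- sum(a); kb <- sum(b); k <- sum(a & b)
  tibble::tibble(
    feature_a = feature_a, feature_b = feature_b,
    n = n, k_a = ka, k_b = kb, overlap = k,
    p_positive = hyper_tail(k, n, ka, kb, upper = TRUE),
    p_negative = hyper_tail(k, n, ka, kb, upper = FALSE)
  )
}

# exact tail of Hypergeometric(N, Ka, Kb) via log-space summation
hyper_tail <- function(k, n, ka, kb, upper) {
  lo <- max(0L, ka + kb - n)
  hi <- min(ka, kb)
  xs <- if (upper) seq.int(k, hi) else seq.int(lo, k)
  lp <- stats::dhyper(xs, ka, n - ka, kb, log = TRUE)
  mx <- max(lp)
  min(1, exp(mx + log(sum(exp(lp - mx)))))
}

alteration_binary <- function(x) {
  if (inherits(x, "alteration_matrix")) return(x$matrix > 0)
  if (is.matrix(x)) return(x > 0)
  stopifnot(is.data.frame(x), "sample_id" %in% names(x))
  m <- as.matrix(x[setdiff(names(x), "sample_id")])
  rownames(m) <- x$sample_id
  m > 0
}

#' All pairwise co-occurrence / exclusivity tests
#'
#' Runs [hypergeometric_pair_test()] on every feature pair, reports both
#' tails per pair, and Bonferroni-adjusts all tail p-values jointly
#' (`m = 2 x` number of tested pairs). Features with empty carrier sets,
#' features carried by every sample, and (by default) FGA/HD features
#' rarer than `min_freq` are excluded before testing.
#'
#' @inheritParams hypergeometric_pair_test
#' @param alpha Significance level on adjusted p-values.
#' @param min_freq Minimum carrier frequency for FGA/HD features (uses the
#'   `excluded_mds` flag when `alterations` is an `alteration_matrix`).
#' @return Edge tibble: one row per pair and direction with `feature_a`,
#'   `feature_b`, `overlap`, `direction`, `p`, `p_adj`, `significant`;
#'   the Bonferroni `m` is recorded in attribute `"m"`.
#' @export
pairwise_associations <- function(alterations, alpha = 0.05, min_freq = 0) {
  m <- alteration_binary(alterations)
  if (inherits(alterations, "alteration_matrix")) {
    keep <- alterations$features$feature[!alterations$features$excluded_mds]
    m <- m[, intersect(colnames(m), keep), drop = FALSE]
  } else if (min_freq > 0) {
    m <- m[, colMeans(m) >= min_freq, drop = FALSE]
  }
  freq <- colMeans(m)
  degenerate <- freq == 0 | freq == 1
  if (any(degenerate)) {
    warning("feature(s) with empty or full carrier set excluded: ",
            paste(utils::head(colnames(m)[degenerate], 5), collapse = ", "),
            call. = FALSE)
    m <- m[, !degenerate, drop = FALSE]
  }
  feats <- colnames(m)
  if (length(feats) < 2) {
    out <- tibble::tibble(feature_a = character(), feature_b = character(),
                          overlap = integer(), direction = character(),
                          p = numeric(), p_adj = numeric(),
                          significant = logical())
    attr(out, "m") <- 0L
    return(out)
  }
  pairs <- utils::combn(feats, 2)
  n <- nrow(m)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- m[, pairs[1, i]]; b <- m[, pairs[2, i]]
    k <- sum(a & b)
    tibble::tibble(
      feature_a = pairs[1, i], feature_b = pairs[2, i],
      overlap = k,
      direction = c("positive", "negative"),
      p = c(hyper_tail(k, n, sum(a), sum(b), upper = TRUE),
            hyper_tail(k, n, sum(a), sum(b), upper = FALSE))
    )
  })
  out <- dplyr::bind_rows(rows)
  m_tests <- nrow(out)
  adj <- bonferroni_adjust(out$p, alpha = alpha, m = m_tests)
  out$p_adj <- adj$p_adj
  out$significant <- adj$significant
  attr(out, "m") <- m_tests
  out
}

#' Bonferroni adjustment with significance flags
#'
#' `p_adj = min(1, m * p)`; significant when `p_adj < alpha`.
#'
#' @param p Numeric p-values in [0, 1].
#' @param alpha Significance level.
#' @param m Number of tests (default `length(p)`).
#' @return Tibble `p`, `p_adj`, `significant`.
#' @export
bonferroni_adjust <- function(p, alpha = 0.05, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE) || anyNA(p)) {
    stop("p-values must be in [0, 1]", call. = FALSE)
  }
  p_adj <- pmin(1, m * p)
  tibble::tibble(p = p, p_adj = p_adj, significant = p_adj < alpha)
}

#' Fisher's exact association of a feature with sample groups
#'
#' For each group, a two-sided 2x2 Fisher exact test of feature carriage
#' against group membership.
#'
#' @inheritParams hypergeometric_pair_test
#' @param feature Feature name.
#' @param groups Tibble `sample_id`, `group`.
#' @return Tibble `group`, `n_in`, `carriers_in`, `carriers_out`,
#'   `odds_ratio`, `p`.
#' @export
fisher_group_association <- function(alterations, feature, groups) {
  m <- alteration_binary(alterations)
  carrier <- m[, feature]
  g <- groups$group[match(rownames(m), groups$sample_id)]
  res <- lapply(sort(unique(stats::na.omit(g))), function(lab) {
    inside <- !is.na(g) & g == lab
    if (sum(inside) == 0) return(NULL)
    tab <- matrix(c(sum(carrier & inside), sum(!carrier & inside),
                    sum(carrier & !inside), sum(!carrier & !inside)), 2)
    ft <- stats::fisher.test(tab)
    tibble::tibble(group = lab, n_in = sum(inside),
                   carriers_in = sum(carrier & inside),
                   carriers_out = sum(carrier & !inside),
                   odds_ratio = unname(ft$estimate), p = ft$p.value)
  })
  dplyr::bind_rows(res)
}

#' Jaccard-distance multidimensional scaling of alteration features
#'
#' Embeds alteration features (points are aberrations, as in genome-wide
#' co-occurrence maps) by classical (Torgerson) MDS on Jaccard distances
#' between carrier sets: `d(a, b) = 1 - |a n b| / |a u b|`. FGA/HD
#' features rarer than `min_freq` and features with empty carrier sets
#' are removed first.
#'
#' @inheritParams pairwise_associations
#' @param dims Number of embedding dimensions.
#' @return Object of class `mds_fit`: list with `coordinates` (tibble
#'   `feature`, `dim1`, ...), `eigenvalues`, `distances`.
#' @export
jaccard_mds <- function(alterations, dims = 2, min_freq = 0.05) {
  m <- alteration_binary(alterations)
  if (inherits(alterations, "alteration_matrix")) {
    keep <- alterations$features$feature[!alterations$features$excluded_mds]
    m <- m[, intersect(colnames(m), keep), drop = FALSE]
  } else if (min_freq > 0) {
    m <- m[, colMeans(m) >= min_freq, drop = FALSE]
  }
  empty <- colSums(m) == 0
  if (any(empty)) {
    warning("feature(s) with empty carrier set removed: ",
            paste(colnames(m)[empty], collapse = ", "), call. = FALSE)
    m <- m[, !empty, drop = FALSE]
  }
  d <- jaccard_distances(m)
  dims <- min(dims, ncol(m) - 1)
  fit <- suppressWarnings(stats::cmdscale(d, k = dims, eig = TRUE))
  pts <- fit$points
  if (ncol(pts) < dims) { # degenerate geometry: pad with zero coordinates
    pts <- cbind(pts, matrix(0, nrow(pts), dims - ncol(pts)))
  }
  colnames(pts) <- paste0("dim", seq_len(ncol(pts)))
  coords <- dplyr::bind_cols(tibble::tibble(feature = colnames(m)),
                             tibble::as_tibble(pts))
  structure(list(coordinates = coords, eigenvalues = fit$eig, distances = d),
            class = "mds_fit")
}

# features are columns; Jaccard distance between carrier sets
jaccard_distances <- function(m) {
  storage.mode(m) <- "integer"
  inter <- crossprod(m)
  sizes <- diag(inter)
  uni <- outer(sizes, sizes, "+") - inter
  d <- 1 - inter / uni
  d[uni == 0] <- NA_real_ # two empty sets: undefined
  stats::as.dist(d)
}

#' @method tidy mds_fit
#' @export
tidy.mds_fit <- function(x, ...) x$coordinates

#' Assemble the alteration co-occurrence network
#'
#' Keeps edges significant after Bonferroni control, retains only nodes
#' incident to at least one significant edge, and reports connected
#' components — the "genomic circuits".
#'
#' @param edges Edge tibble from [pairwise_associations()].
#' @param alpha Significance level on adjusted p-values (edges are re-run
#'   against it).
#' @return Object of class `assoc_network`: list with `edges` (significant
#'   ones), `nodes` (tibble `feature`, `component`), `n_components`, and
#'   the underlying `igraph` object.
#' @export
assemble_network <- function(edges, alpha = 0.05) {
  sig <- edges[edges$p_adj < alpha, ]
  if (nrow(sig) == 0) {
    return(structure(list(
      edges = sig, nodes = tibble::tibble(feature = character(),
                                          component = integer()),
      n_components = 0L, graph = igraph::make_empty_graph(directed = FALSE)
    ), class = "assoc_network"))
  }
  g <- igraph::graph_from_data_frame(
    sig[c("feature_a", "feature_b", "direction", "p_adj")], directed = FALSE
  )
  comp <- igraph::components(g)
  structure(list(
    edges = sig,
    nodes = tibble::tibble(feature = names(comp$membership),
                           component = unname(comp$membership)),
    n_components = comp$no, graph = g
  ), class = "assoc_network")
}

#' @export
print.assoc_network <- function(x, ...) {
  cat("<assoc_network> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " significant edges, ", x$n_components, " component(s)\n", sep = "")
  invisible(x)
}

#' @method tidy assoc_network
#' @export
tidy.assoc_network <- function(x, ...) x$edges

#' @method glance assoc_network
#' @export
glance.assoc_network <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
    n_components = x$n_components,
    n_positive = sum(x$edges$direction == "positive"),
    n_negative = sum(x$edges$direction == "negative")
  )
}
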