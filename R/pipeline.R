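#' Run the integrated cohort analysis
#'
#' Convenience wrapper chaining the whole pipeline on a cohort (typically
#' from [generate_cohort()]): copy-number calling, recurrent-alteration
#' discovery, the binary alteration matrix with mutation features,
#' per-sample complexity metrics with a CIN signature score, expression
#' normalization and hierarchical subtyping, pairwise hypergeometric
#' associations with network assembly, and survival stratification.
#'
#' @param cohort A list with `probe_map`, `profiles`, `expression`,
#'   `batches`, `mutations`, `clinical` (see [generate_cohort()] for the
#'   shapes).
#' @param config A [cna_config()].
#' @param cin_genes Gene list for the CIN score (default: the cohort's
#'   `CIN_*` genes when present).
#' @param k Number of HC expression clusters.
#' @param cnv Optional CNV mask intervals.
#' @param alpha Significance level for network edges.
#' @return List of class `circuit_analysis` with elements `calls`,
#'   `recurrence`, `alterations`, `complexity`, `expression`
#'   (normalized), `subtypes`, `edges`, `network`, `survival`.
#' @export
analyze_cohort <- function(cohort, config = cna_config(), cin_genes = NULL,
                           k = 5, cnv = NULL, alpha = 0.05) {
  calls <- call_cna(cohort$profiles, cohort$probe_map, config)
  rec <- recurrent_alterations(calls, cnv = cnv, config = config)
  alt <- build_alteration_matrix(rec, calls, mutations = cohort$mutations,
                                 config = config)
  norm <- normalize_expression(cohort$expression, cohort$batches)
  if (is.null(cin_genes)) {
    cin_genes <- grep("^CIN_", cohort$expression$gene, value = TRUE)
  }
  cx <- complexity_profile(calls, expression = norm,
                           cin_genes = if (length(cin_genes)) cin_genes else NULL)
  subtypes <- hca_clusters(norm, k = k)
  edges <- pairwise_associations(alt, alpha = alpha)
  network <- assemble_network(edges, alpha = alpha)

  surv <- NULL
  if (!is.null(cohort$clinical)) {
    grp <- define_survival_groups(cx, mode = "nfga_binary")
    recs <- dplyr::left_join(cohort$clinical, grp, by = "sample_id")
    surv <- km_curve(recs)
  }
  structure(list(calls = calls, recurrence = rec, alterations = alt,
                 complexity = cx, expression = norm, subtypes = subtypes,
                 edges = edges, network = network, survival = surv),
            class = "circuit_analysis")
}

#' @export
print.circuit_analysis <- function(x, ...) {
  cat("<circuit_analysis>\n")
  print(glance(x))
  invisible(x)
}

#' @method glance circuit_analysis
#' @export
glance.circuit_analysis <- function(x, ...) {
  reg <- x$recurrence$regions
  tibble::tibble(
    n_samples = nrow(x$calls$states),
    n_fga_regions = sum(reg$kind == "FGA"),
    n_hd_regions = sum(reg$kind == "HD"),
    n_mrd_regions = sum(reg$kind == "MRD"),
    n_arm_features = nrow(x$recurrence$arm_features),
    n_features = ncol(x$alterations$matrix),
    n_network_edges = nrow(x$network$edges),
    n_circuits = x$network$n_components
  )
}
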