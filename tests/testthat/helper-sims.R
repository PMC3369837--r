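# Memoised bank of replicate synthetic cohorts run through the pipeline.
# Several simulation-based checks draw on the same 20 replicates, so the
# expensive part is computed once per test run.

planted_circuits <- list(
  circuitA = c("ARM_LOSS_9qlike", "HD_CDKN2Alike", "MUT_FGFR3"),
  circuitB = c("FGA_6p22like", "HD_RB1like", "ARM_GAIN_5plike", "MRD_PTENlike")
)

# map a planted event (or mutation) to its alteration-matrix feature name
planted_feature_name <- function(nm, truth, regions) {
  if (nm == "MUT_FGFR3") return("MUT_FGFR3")
  if (nm == "ARM_GAIN_5plike") return("ARM_GAIN_chr2p")
  if (nm == "ARM_LOSS_9qlike") return("ARM_LOSS_chr4q")
  p <- truth$planted[truth$planted$name == nm, ]
  hit <- regions$kind == p$kind &
    regions$core_from <= p$g_to & regions$core_to >= p$g_from
  if (!any(hit)) return(NA_character_)
  r <- regions[which(hit)[1], ]
  sprintf("%s_%s:%d-%d", r$kind, r$chrom, r$ext_start, r$ext_end)
}

# independent per-region support recount straight from the event lists
recount_support <- function(regions, events, del_runs) {
  vapply(seq_len(nrow(regions)), function(i) {
    src <- if (regions$kind[i] == "MRD") del_runs else
      events[events$kind == regions$kind[i], ]
    length(unique(src$sample_id[src$from <= regions$core_from[i] &
                                  src$to >= regions$core_from[i]]))
  }, 0L)
}

replicate_sims <- local({
  cache <- NULL
  function(n_seeds = 20) {
    if (!is.null(cache)) return(cache)
    cfg <- simulation_config()
    res <- vector("list", n_seeds)
    for (i in seq_len(n_seeds)) {
      co <- generate_cohort(cfg, seed = 1000 + i)
      calls <- call_cna(co$profiles, co$probe_map)
      rec <- recurrent_alterations(calls)
      alt <- build_alteration_matrix(rec, calls, mutations = co$mutations)
      # rare mutation features can have empty carrier sets in a replicate;
      # their exclusion warning is expected behavior here
      edges <- suppressWarnings(pairwise_associations(alt, alpha = 0.05))
      norm <- normalize_expression(co$expression, co$batches)
      fit <- hca_clusters(norm, k = 5)
      truth_ms <- co$truth$groups$ms_class[
        match(tidy(fit)$sample_id, co$truth$groups$sample_id)]
      feature_map <- stats::setNames(
        vapply(unlist(planted_circuits), planted_feature_name, "",
               truth = co$truth, regions = rec$regions),
        unlist(planted_circuits)
      )
      res[[i]] <- list(
        truth = co$truth,
        regions = rec$regions,
        recount = recount_support(rec$regions, calls$events, rec$deletion_runs),
        edges = edges,
        features = alt$features,
        feature_map = feature_map,
        ms_ari = ari(tidy(fit)$ms, truth_ms)
      )
    }
    cache <<- res
    res
  }
})

min_support_of <- function(kind) {
  c(FGA = 3L, HD = 2L, MRD = 15L)[kind]
}

# is a significant positive edge between two features present?
has_positive_edge <- function(edges, fa, fb) {
  if (is.na(fa) || is.na(fb)) return(FALSE)
  hit <- ((edges$feature_a == fa & edges$feature_b == fb) |
            (edges$feature_a == fb & edges$feature_b == fa)) &
    edges$direction == "positive" & edges$significant
  any(hit)
}
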