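#' Simulation settings for the synthetic tumor cohort
#'
#' Describes a 146-sample urothelial-carcinoma-like cohort on a reduced
#' BAC-like probe grid: 3000 probes over four synthetic chromosomes with
#' p/q arms. Samples fall into four groups: `circuitA`
#' (FGFR3-mutant-like: 9q-arm-like loss, nested CDKN2A-like homozygous
#' deletions, high CCND1-like expression), `circuitB` (6p22-like focal
#' amplification, RB1-like homozygous deletion, 5p-like arm gain, low
#' FGFR3/PTEN expression), `keratinized` (keratin-program expression,
#' CCND1-like amplifications, worst survival), and `background`
#' (noise and random passengers only). Copy-number noise is one Gaussian
#' draw per segment, shared by the segment's probes — the input data model
#' is segmented, so probe-level scatter would be unrealistic. Expression
#' is generated on the raw intensity scale (log-normal) with a
#' multiplicative labeling-batch factor, so the normalization pipeline has
#' real work to do.
#'
#' @param n_samples Cohort size.
#' @param n_chroms,probes_per_chrom,probe_spacing_bp,probe_len_bp,p_fraction
#'   Probe-grid geometry; `p_fraction` of each chromosome's probes form the
#'   p arm.
#' @param group_props Named proportions for
#'   circuitA/circuitB/keratinized/background; must sum to 1.
#' @param planted_regions Tibble of planted events (see default): `name`,
#'   `chrom`, local probe interval `from`/`to`, `kind`, `target_log2`, one
#'   carrier-fraction column per group, and `nested_in` (carriers drawn
#'   within the parent event's circuitA carriers).
#' @param boundary_jitter_probes Uniform jitter applied to each focal/MRD
#'   boundary per carrier (in probes).
#' @param segment_noise_sd SD of the per-segment Gaussian noise (log2) for
#'   a segment of `noise_ref_probes` probes; longer segments get
#'   `segment_noise_sd * sqrt(noise_ref_probes / length)`, reflecting that
#'   a segment mean averages probe-level noise.
#' @param noise_ref_probes Reference segment length for the noise SD.
#' @param passenger_rate Poisson mean of random passenger focal events per
#'   sample.
#' @param mutation_rates Tibble `gene` x group columns of mutation
#'   probabilities.
#' @param n_genes,subtype_shift,gene_noise_sd,batch_factor Expression
#'   dimensions: total genes, log2 mean-shift of subtype signature genes,
#'   per-gene log2 noise SD, multiplicative raw-intensity factor for the
#'   second labeling batch.
#' @param n_ms2_genes,n_circuitA_genes,n_keratin_genes,n_cin_genes Sizes of
#'   the planted expression programs.
#' @param cin_effect Log2 expression shift of CIN-program genes per planted
#'   genomic event carried.
#' @param hazards Named per-month exponential death hazards per group.
#' @param censor_rate Probability that a sample's follow-up is censored
#'   before the event, in [0, 1).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_samples = 146,
                              n_chroms = 4,
                              probes_per_chrom = 750,
                              probe_spacing_bp = 100000,
                              probe_len_bp = 50000,
                              p_fraction = 0.4,
                              group_props = c(circuitA = 0.40, circuitB = 0.25,
                                              keratinized = 0.12, background = 0.23),
                              planted_regions = default_planted_regions(),
                              boundary_jitter_probes = 1,
                              segment_noise_sd = 0.08,
                              noise_ref_probes = 4,
                              passenger_rate = 0.3,
                              mutation_rates = default_mutation_rates(),
                              n_genes = 2000,
                              subtype_shift = 1.0,
                              gene_noise_sd = 0.5,
                              batch_factor = 1.3,
                              n_ms2_genes = 200,
                              n_circuitA_genes = 30,
                              n_keratin_genes = 50,
                              n_cin_genes = 40,
                              cin_effect = 0.3,
                              hazards = c(circuitA = 0.002, circuitB = 0.010,
                                          keratinized = 0.020, background = 0.004),
                              censor_rate = 0.3) {
  stopifnot(
    abs(sum(group_props) - 1) < 1e-8,
    setequal(names(group_props), c("circuitA", "circuitB", "keratinized", "background")),
    setequal(names(hazards), names(group_props)), all(hazards > 0),
    censor_rate >= 0, censor_rate < 1,
    segment_noise_sd >= 0, p_fraction > 0, p_fraction < 1
  )
  grp_cols <- names(group_props)
  stopifnot(all(grp_cols %in% names(planted_regions)))
  fr <- as.matrix(planted_regions[grp_cols])
  stopifnot(all(fr >= 0), all(fr <= 1))
  structure(list(
    n_samples = n_samples, n_chroms = n_chroms,
    probes_per_chrom = probes_per_chrom,
    probe_spacing_bp = probe_spacing_bp, probe_len_bp = probe_len_bp,
    p_fraction = p_fraction, group_props = group_props,
    planted_regions = planted_regions,
    boundary_jitter_probes = boundary_jitter_probes,
    segment_noise_sd = segment_noise_sd, noise_ref_probes = noise_ref_probes,
    passenger_rate = passenger_rate,
    mutation_rates = mutation_rates, n_genes = n_genes,
    subtype_shift = subtype_shift, gene_noise_sd = gene_noise_sd,
    batch_factor = batch_factor, n_ms2_genes = n_ms2_genes,
    n_circuitA_genes = n_circuitA_genes, n_keratin_genes = n_keratin_genes,
    n_cin_genes = n_cin_genes, cin_effect = cin_effect,
    hazards = hazards, censor_rate = censor_rate
  ), class = "simulation_config")
}

#' @rdname simulation_config
#' @export
default_planted_regions <- function() {
  tibble::tribble(
    ~name,          ~chrom, ~from, ~to,  ~kind,      ~target_log2, ~circuitA, ~circuitB, ~keratinized, ~background, ~nested_in,
    "FGA_6p22like", "chr1",  120L, 135L, "FGA",       1.4,          0.05,      0.75,      0.10,         0.02,        NA,
    "ARM_GAIN_5plike", "chr2", 1L, 300L, "ARM_GAIN",  0.45,         0.05,      0.65,      0.05,         0.05,        NA,
    "HD_RB1like",   "chr2",  500L, 508L, "HD",       -1.6,          0.01,      0.60,      0.05,         0.01,        NA,
    "FGA_CCND1like", "chr3",  80L,  92L, "FGA",       1.3,          0.10,      0.05,      0.45,         0.03,        NA,
    "MRD_PTENlike", "chr3",  380L, 420L, "MRD",      -0.5,          0.10,      0.60,      0.20,         0.10,        NA,
    "HD_CDKN2Alike", "chr4", 100L, 112L, "HD",       -1.5,          0.40,      0.02,      0.05,         0.02,        "ARM_LOSS_9qlike",
    "ARM_LOSS_9qlike", "chr4", 301L, 750L, "ARM_LOSS", -0.45,       0.75,      0.05,      0.10,         0.08,        NA
  )
}

#' @rdname simulation_config
#' @export
default_mutation_rates <- function() {
  tibble::tribble(
    ~gene,     ~circuitA, ~circuitB, ~keratinized, ~background,
    "FGFR3",    0.80,      0.05,      0.10,         0.15,
    "PIK3CA",   0.30,      0.08,      0.15,         0.10,
    "KRAS",     0.02,      0.04,      0.04,         0.02,
    "HRAS",     0.02,      0.03,      0.03,         0.02,
    "NRAS",     0.01,      0.02,      0.02,         0.01,
    "TP53",     0.15,      0.50,      0.70,         0.10,
    "CDKN2A",   0.02,      0.02,      0.02,         0.02
  )
}

#' Build the synthetic probe grid
#'
#' @param config A [simulation_config()].
#' @return A [probe_map()] for the synthetic genome.
#' @export
synthetic_probe_map <- function(config = simulation_config()) {
  n <- config$probes_per_chrom
  p_n <- round(config$p_fraction * n)
  per_chrom <- lapply(seq_len(config$n_chroms), function(c) {
    # 3-Mb centromeric probe gap so smoothing windows never span arms
    start <- (seq_len(n) - 1L) * config$probe_spacing_bp +
      ifelse(seq_len(n) <= p_n, 0L, 3000000L)
    tibble::tibble(
      probe_id = sprintf("chr%d_p%04d", c, seq_len(n)),
      chrom = paste0("chr", c),
      start = as.integer(start),
      end = as.integer(start + config$probe_len_bp),
      arm = paste0("chr", c, ifelse(seq_len(n) <= p_n, "p", "q"))
    )
  })
  probe_map(dplyr::bind_rows(per_chrom))
}

#' Plant a focal event into a profile
#'
#' Sets the segmented values of a probe interval to a target log2 level,
#' leaving everything else untouched. The interval must lie within one
#' chromosome.
#'
#' @param profile Long tibble `probe_id`, `log2` (single sample).
#' @param probe_map A [probe_map()].
#' @param from,to Probe-map row indices (inclusive).
#' @param target_log2 The level to plant.
#' @return The modified profile tibble.
#' @export
plant_focal_event <- function(profile, probe_map, from, to, target_log2) {
  probe_map <- stopifnot_probe_map(probe_map)
  stopifnot(from >= 1, to <= nrow(probe_map), from <= to)
  if (length(unique(probe_map$chrom[from:to])) > 1) {
    stop("planted interval spans more than one chromosome", call. = FALSE)
  }
  ids <- probe_map$probe_id[from:to]
  profile$log2[profile$probe_id %in% ids] <- target_log2
  profile
}

#' Simulate exponential disease-specific survival
#'
#' Event times are exponential with the group's hazard; censoring times are
#' independent exponentials calibrated so each record is censored with
#' probability `censor_rate`.
#'
#' @param groups Tibble `sample_id`, `group`.
#' @param hazards Named per-month hazards covering every group label.
#' @param censor_rate Censoring probability in [0, 1).
#' @param seed Optional RNG seed (uses the current RNG stream when `NULL`).
#' @return Tibble `sample_id`, `group`, `followup_months`, `dss_event`.
#' @export
simulate_survival <- function(groups, hazards, censor_rate = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (censor_rate < 0 || censor_rate >= 1) {
    stop("censor_rate must be in [0, 1)", call. = FALSE)
  }
  unknown <- setdiff(unique(groups$group), names(hazards))
  if (length(unknown) > 0) {
    stop("no hazard for group(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  lambda <- hazards[groups$group]
  t_event <- stats::rexp(nrow(groups), rate = lambda)
  if (censor_rate > 0) {
    lam_c <- lambda * censor_rate / (1 - censor_rate)
    t_cens <- stats::rexp(nrow(groups), rate = lam_c)
  } else {
    t_cens <- rep(Inf, nrow(groups))
  }
  tibble::tibble(
    sample_id = groups$sample_id, group = groups$group,
    followup_months = pmin(t_event, t_cens),
    dss_event = t_event <= t_cens
  )
}

#' Generate a full synthetic cohort with recorded ground truth
#'
#' Produces segmented copy-number profiles, raw expression intensities with
#' batch labels, mutation calls, clinical/survival records, IHC scores, and
#' the ground truth (group labels, planted-region carrier sets, planted
#' gene programs, hazards). Deterministic given `seed`.
#'
#' @param config A [simulation_config()].
#' @param seed Integer RNG seed.
#' @return A list of class `synthetic_cohort` with elements `probe_map`,
#'   `profiles`, `expression` (raw wide tibble, `gene` + sample columns),
#'   `batches`, `mutations`, `clinical`, `ihc`, `truth`.
#' @export
generate_cohort <- function(config = simulation_config(), seed = 1) {
  set.seed(seed)
  pm <- synthetic_probe_map(config)
  n <- config$n_samples
  samples <- sprintf("S%03d", seq_len(n))
  grp_names <- names(config$group_props)

  counts <- floor(config$group_props * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(config$group_props * n - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  group <- sample(rep(grp_names, counts))
  groups <- tibble::tibble(sample_id = samples, group = group,
                           ms_class = ifelse(group %in% c("circuitB", "keratinized"),
                                             "MS2", "MS1"))

  planted <- config$planted_regions
  chrom_offset <- (match(planted$chrom, paste0("chr", seq_len(config$n_chroms))) - 1L) *
    config$probes_per_chrom
  if (anyNA(chrom_offset) ||
      any(planted$to > config$probes_per_chrom) || any(planted$from < 1)) {
    stop("planted region outside the probe grid", call. = FALSE)
  }
  planted$g_from <- planted$from + chrom_offset
  planted$g_to <- planted$to + chrom_offset

  # carrier draws; nested regions are drawn inside their parent's circuitA carriers
  fr <- as.matrix(planted[grp_names])
  rownames(fr) <- planted$name
  carrier <- matrix(FALSE, n, nrow(planted), dimnames = list(samples, planted$name))
  ord <- order(!is.na(planted$nested_in)) # parents first
  for (i in ord) {
    p <- fr[i, group]
    draw <- stats::runif(n) < p
    if (!is.na(planted$nested_in[i])) {
      parent <- carrier[, planted$nested_in[i]]
      in_a <- group == "circuitA"
      p_cond <- pmin(1, fr[i, "circuitA"] / fr[planted$nested_in[i], "circuitA"])
      draw[in_a] <- parent[in_a] & (stats::runif(sum(in_a)) < p_cond)
    }
    carrier[, i] <- draw
  }

  profiles_m <- simulate_profiles(pm, samples, planted, carrier, config)
  mutations <- simulate_mutations(samples, group, config$mutation_rates)
  burden <- rowSums(carrier)
  expr <- simulate_expression(samples, group, groups$ms_class, carrier, burden,
                              mutations, config)
  clinical <- simulate_clinical(groups, config)
  ihc <- simulate_ihc(samples, group)

  truth <- list(
    groups = groups,
    planted = dplyr::mutate(planted,
                            carriers = lapply(seq_len(nrow(planted)),
                                              function(i) samples[carrier[, i]])),
    burden = tibble::tibble(sample_id = samples, burden = unname(burden)),
    gene_programs = expr$programs,
    hazards = config$hazards,
    seed = seed
  )
  structure(list(
    probe_map = pm, profiles = matrix_profiles(profiles_m, pm),
    expression = expr$raw, batches = expr$batches, mutations = mutations,
    clinical = clinical, ihc = ihc, truth = truth
  ), class = "synthetic_cohort")
}

simulate_profiles <- function(pm, samples, planted, carrier, config) {
  n <- length(samples)
  np <- nrow(pm)
  m <- matrix(0, n, np, dimnames = list(samples, pm$probe_id))
  arms <- split(seq_len(np), pm$arm)
  j <- config$boundary_jitter_probes
  ci <- chrom_index(pm)
  # segment-mean noise shrinks with segment length (segmentation averages
  # probe noise): sd(L) = segment_noise_sd * sqrt(ref / L)
  seg_sd <- function(len) {
    config$segment_noise_sd * sqrt(config$noise_ref_probes / len)
  }
  # passengers must not corrupt the planted truth: keep them clear of
  # planted focal/MRD loci
  focal <- planted[planted$kind %in% c("FGA", "HD", "MRD"), ]
  margin <- 5L
  clear_of_planted <- function(from, to) {
    !any(focal$g_from - margin <= to & focal$g_to + margin >= from)
  }
  for (s in seq_len(n)) {
    # background: one segment (one draw) per arm
    for (idx in arms) m[s, idx] <- stats::rnorm(1, 0, seg_sd(length(idx)))
    # passengers: short focal events at random positions off the planted loci
    for (k in seq_len(stats::rpois(1, config$passenger_rate))) {
      for (try in 1:20) {
        ch <- sample(names(ci), 1)
        len <- sample(4:12, 1)
        at <- sample(length(ci[[ch]]) - len, 1)
        from <- ci[[ch]][at]
        to <- ci[[ch]][at + len - 1L]
        if (clear_of_planted(from, to)) break
      }
      if (!clear_of_planted(from, to)) next
      lvl <- sample(c(-1, 1), 1) * stats::runif(1, 1.0, 1.6)
      m[s, from:to] <- lvl + stats::rnorm(1, 0, seg_sd(len))
    }
    # planted events for carriers (arm events first, focal on top)
    for (i in order(planted$kind %in% c("FGA", "HD", "MRD"))) {
      if (!carrier[s, i]) next
      from <- planted$g_from[i]
      to <- planted$g_to[i]
      if (j > 0 && planted$kind[i] %in% c("FGA", "HD", "MRD")) {
        from <- max(1L, from + sample(seq(-j, j), 1))
        to <- min(np, max(from, to + sample(seq(-j, j), 1)))
      }
      m[s, from:to] <- planted$target_log2[i] +
        stats::rnorm(1, 0, seg_sd(to - from + 1L))
    }
  }
  m
}

simulate_mutations <- function(samples, group, rates) {
  out <- tidyr::expand_grid(sample_id = samples, gene = rates$gene)
  out$group <- group[match(out$sample_id, samples)]
  r <- as.matrix(rates[-1])
  rownames(r) <- rates$gene
  p <- r[cbind(out$gene, out$group)]
  out$status <- ifelse(stats::runif(nrow(out)) < p, "mutated", "wildtype")
  out[c("sample_id", "gene", "status")]
}

simulate_expression <- function(samples, group, ms_class, carrier, burden,
                                mutations, config) {
  n <- length(samples)
  markers <- c("FGFR3", "CCND1", "RB1", "PTEN", "CDKN2A", "MDM2", "RAF1", "E2F3")
  program_genes <- c(
    markers,
    sprintf("MS2SIG_%03d", seq_len(config$n_ms2_genes)),
    sprintf("MS1SIG_%03d", seq_len(config$n_circuitA_genes)),
    sprintf("KRT_%03d", seq_len(config$n_keratin_genes)),
    sprintf("CIN_%03d", seq_len(config$n_cin_genes))
  )
  n_noise <- config$n_genes - length(program_genes)
  stopifnot(n_noise >= 0)
  genes <- c(program_genes, sprintf("G_%04d", seq_len(n_noise)))
  mu <- stats::rnorm(length(genes), mean = 9, sd = 1.2)
  names(mu) <- genes
  eff <- matrix(0, length(genes), n, dimnames = list(genes, samples))

  is_a <- group == "circuitA"; is_b <- group == "circuitB"
  is_k <- group == "keratinized"; is_ms2 <- ms_class == "MS2"
  sh <- config$subtype_shift
  eff[grep("^MS2SIG_", genes), is_ms2] <- sh
  eff[grep("^MS1SIG_", genes), is_a] <- sh
  eff[grep("^KRT_", genes), is_k] <- 1.5 * sh
  eff[grep("^CIN_", genes), ] <- matrix(rep(config$cin_effect * burden,
                                            each = config$n_cin_genes),
                                        config$n_cin_genes, n)
  eff["FGFR3", is_a] <- 1.5
  eff["FGFR3", is_b] <- -1.5
  eff["CCND1", is_a] <- 1.2
  eff["CCND1", is_k] <- 0.8
  eff["CCND1", carrier[, "FGA_CCND1like"]] <- 1.6
  eff["RB1", carrier[, "HD_RB1like"]] <- -1.8
  eff["PTEN", is_b] <- -1.0
  eff["PTEN", carrier[, "MRD_PTENlike"]] <-
    eff["PTEN", carrier[, "MRD_PTENlike"]] - 0.6
  eff["CDKN2A", is_b] <- 1.0
  eff["CDKN2A", carrier[, "HD_CDKN2Alike"]] <- -2.0
  eff["E2F3", carrier[, "FGA_6p22like"]] <- 1.5
  eff["RAF1", ] <- 0
  tp53_mut <- mutations$sample_id[mutations$gene == "TP53" &
                                    mutations$status == "mutated"]
  mdm2_high <- !samples %in% tp53_mut & (is_b | is_k) & stats::runif(n) < 0.3
  eff["MDM2", mdm2_high] <- 1.8

  log2_expr <- mu + eff + matrix(stats::rnorm(length(genes) * n, 0,
                                              config$gene_noise_sd),
                                 length(genes), n)
  raw <- 2^log2_expr
  batch <- sample(rep(c("B1", "B2"), length.out = n))
  raw[, batch == "B2"] <- raw[, batch == "B2"] * config$batch_factor
  raw_tbl <- tibble::as_tibble(raw, rownames = "gene")
  list(
    raw = raw_tbl,
    batches = tibble::tibble(sample_id = samples, batch = batch),
    programs = tibble::tibble(
      gene = genes,
      program = dplyr::case_when(
        genes %in% markers ~ "marker",
        grepl("^MS2SIG_", genes) ~ "ms2",
        grepl("^MS1SIG_", genes) ~ "circuitA",
        grepl("^KRT_", genes) ~ "keratin",
        grepl("^CIN_", genes) ~ "cin",
        TRUE ~ "noise"
      )
    ),
    mdm2_high = samples[mdm2_high]
  )
}

simulate_clinical <- function(groups, config) {
  surv <- simulate_survival(groups, config$hazards, config$censor_rate)
  stage_p <- list(
    circuitA = c(Ta = 0.60, T1 = 0.30, `>=T2` = 0.10),
    circuitB = c(Ta = 0.15, T1 = 0.40, `>=T2` = 0.45),
    keratinized = c(Ta = 0.05, T1 = 0.30, `>=T2` = 0.65),
    background = c(Ta = 0.45, T1 = 0.35, `>=T2` = 0.20)
  )
  grade_p <- list(
    circuitA = c(G1 = 0.30, G2 = 0.50, G3 = 0.20),
    circuitB = c(G1 = 0.02, G2 = 0.23, G3 = 0.75),
    keratinized = c(G1 = 0.01, G2 = 0.09, G3 = 0.90),
    background = c(G1 = 0.20, G2 = 0.45, G3 = 0.35)
  )
  surv$stage <- vapply(surv$group, function(g) {
    sample(names(stage_p[[g]]), 1, prob = stage_p[[g]])
  }, "")
  surv$grade <- vapply(surv$group, function(g) {
    sample(names(grade_p[[g]]), 1, prob = grade_p[[g]])
  }, "")
  surv[c("sample_id", "stage", "grade", "followup_months", "dss_event")]
}

simulate_ihc <- function(samples, group) {
  base <- list(
    FGFR3 = c(circuitA = 2.4, circuitB = 0.6, keratinized = 1.0, background = 1.4),
    CCND1 = c(circuitA = 2.2, circuitB = 1.0, keratinized = 1.8, background = 1.2),
    P16 = c(circuitA = 0.8, circuitB = 2.2, keratinized = 1.4, background = 1.2),
    E2F3 = c(circuitA = 0.9, circuitB = 2.3, keratinized = 1.4, background = 1.1),
    RB1 = c(circuitA = 2.0, circuitB = 0.7, keratinized = 1.5, background = 1.8)
  )
  grid <- tidyr::expand_grid(sample_id = samples,
                             marker = names(base), core = 1:2)
  grid$intensity <- vapply(seq_len(nrow(grid)), function(i) {
    g <- group[match(grid$sample_id[i], samples)]
    v <- round(stats::rnorm(1, base[[grid$marker[i]]][g], 0.6))
    as.integer(min(3, max(0, v)))
  }, 0L)
  grid$fraction <- round(pmin(1, pmax(0, stats::rnorm(nrow(grid), 0.7, 0.2))) * 10) / 10
  grid
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", nrow(x$truth$groups), " samples, ",
      nrow(x$probe_map), " probes, ", nrow(x$expression), " genes\n", sep = "")
  print(table(x$truth$groups$group))
  invisible(x)
}
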