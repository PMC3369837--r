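#' Configuration for copy-number calling and recurrence detection
#'
#' Bundles the numeric constants of the calling and recurrence rules.
#' Defaults follow the conventions of BAC-array tumor-cohort studies:
#' gains/losses are
#' called against a per-sample adaptive threshold (SAT) computed on 250-kb
#' smoothed segmented data; focal amplifications (FGA) and homozygous
#' deletions (HD) require unsmoothed segmented log2 ratios beyond +/-0.8
#' over more than three consecutive probes; FGAs less than 1 Mbp apart are
#' merged into one amplicon; an arm is gained/lost when more than half of
#' its probes exceed the SAT, and an arm event is recurrent when carried by
#' more than 10% of samples; recurrent FGA/HD/MRD regions require at least
#' 3/2/15 supporting samples respectively.
#'
#' @param window_bp Smoothing window width in bp (mean over probe midpoints
#'   within `window_bp / 2` on either side, same chromosome).
#' @param sat_multiplier Multiplier on the per-sample robust noise scale.
#' @param sat_floor Lower bound for the SAT; segmented (piecewise-constant)
#'   profiles have mostly-zero first differences, so the robust scale
#'   degenerates to 0 and the floor takes over.
#' @param amp_log2,hd_log2 Segmented log2 cutoffs for AMP / HD states.
#' @param min_focal_probes Minimum run length (in probes) for a focal
#'   event; "longer than three consecutive probes" means at least 4.
#' @param merge_gap_bp Amplicons closer than this are counted as one.
#' @param arm_probe_fraction Fraction of arm probes that must be beyond the
#'   SAT for an arm-level call (strict inequality).
#' @param arm_recurrence_fraction Fraction of samples that must carry an
#'   arm event for it to be recurrent (strict inequality).
#' @param fga_min_support,hd_min_support,mrd_min_support Minimum number of
#'   supporting samples at the peak of a recurrent region.
#' @param fga_slack,hd_slack Boundary extension slack: the core is widened
#'   to the surrounding run with support >= peak - slack. MRDs use
#'   `fga_slack`.
#' @param max_arm_fraction MRDs whose extended interval covers more than
#'   this fraction of their arm's probes are dropped (the event is carried
#'   by the arm-level call instead).
#' @param cnv_overlap_max Regions whose extended interval is covered by
#'   germline CNV intervals beyond this fraction are removed.
#' @param mds_min_freq FGA/HD features rarer than this are excluded from
#'   MDS / pairwise association (kept elsewhere).
#' @return A list of class `cna_config`.
#' @export
cna_config <- function(window_bp = 250000,
                       sat_multiplier = 2.5,
                       sat_floor = 0.05,
                       amp_log2 = 0.8,
                       hd_log2 = -0.8,
                       min_focal_probes = 4,
                       merge_gap_bp = 1000000,
                       arm_probe_fraction = 0.5,
                       arm_recurrence_fraction = 0.10,
                       fga_min_support = 3,
                       hd_min_support = 2,
                       mrd_min_support = 15,
                       fga_slack = 2,
                       hd_slack = 1,
                       max_arm_fraction = 0.5,
                       cnv_overlap_max = 0.5,
                       mds_min_freq = 0.05) {
  cfg <- list(
    window_bp = window_bp, sat_multiplier = sat_multiplier,
    sat_floor = sat_floor, amp_log2 = amp_log2, hd_log2 = hd_log2,
    min_focal_probes = as.integer(min_focal_probes),
    merge_gap_bp = merge_gap_bp,
    arm_probe_fraction = arm_probe_fraction,
    arm_recurrence_fraction = arm_recurrence_fraction,
    fga_min_support = as.integer(fga_min_support),
    hd_min_support = as.integer(hd_min_support),
    mrd_min_support = as.integer(mrd_min_support),
    fga_slack = as.integer(fga_slack), hd_slack = as.integer(hd_slack),
    max_arm_fraction = max_arm_fraction,
    cnv_overlap_max = cnv_overlap_max,
    mds_min_freq = mds_min_freq
  )
  stopifnot(
    cfg$window_bp > 0, cfg$sat_multiplier > 0, cfg$sat_floor >= 0,
    cfg$amp_log2 > 0, cfg$hd_log2 < 0,
    cfg$min_focal_probes >= 1, cfg$merge_gap_bp >= 0,
    cfg$arm_probe_fraction > 0, cfg$arm_probe_fraction < 1,
    cfg$arm_recurrence_fraction >= 0, cfg$arm_recurrence_fraction < 1,
    cfg$fga_min_support >= 1, cfg$hd_min_support >= 1,
    cfg$mrd_min_support >= 1, cfg$fga_slack >= 0, cfg$hd_slack >= 0,
    cfg$max_arm_fraction > 0, cfg$max_arm_fraction <= 1,
    cfg$cnv_overlap_max >= 0, cfg$cnv_overlap_max <= 1,
    cfg$mds_min_freq >= 0, cfg$mds_min_freq < 1
  )
  structure(cfg, class = "cna_config")
}

#' @export
print.cna_config <- function(x, ...) {
  cat("<cna_config>\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

min_support_for <- function(kind, config) {
  switch(kind,
    FGA = config$fga_min_support,
    HD = config$hd_min_support,
    MRD = config$mrd_min_support,
    stop("unknown region kind: ", kind, call. = FALSE)
  )
}

slack_for <- function(kind, config) {
  if (kind == "HD") config$hd_slack else config$fga_slack
}
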