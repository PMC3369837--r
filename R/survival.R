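#' Kaplan-Meier disease-specific survival curves
#'
#' Product-limit estimation of disease-specific survival (death of disease
#' is the event; other exits censor). Ties between events and censorings
#' at the same time are handled by the standard convention (events first).
#'
#' @param records Tibble with `followup_months` (>= 0), `dss_event`
#'   (logical), and optionally `group`.
#' @return Object of class `km_fit` wrapping a [survival::survfit] fit.
#'   `tidy()` gives the step table (`time`, `n_risk`, `n_event`,
#'   `n_censor`, `survival`, `group`), `glance()` counts plus the log-rank
#'   test when groups are present.
#' @export
km_curve <- function(records) {
  if (any(records$followup_months < 0)) {
    stop("negative follow-up time", call. = FALSE)
  }
  has_groups <- "group" %in% names(records) &&
    dplyr::n_distinct(records$group) > 1
  srv <- survival::Surv(records$followup_months, as.integer(records$dss_event))
  fit <- if (has_groups) {
    grp <- records$group
    survival::survfit(srv ~ grp)
  } else {
    survival::survfit(srv ~ 1)
  }
  structure(list(fit = fit, records = records, has_groups = has_groups),
            class = "km_fit")
}

#' @method tidy km_fit
#' @export
tidy.km_fit <- function(x, ...) {
  s <- summary(x$fit, censored = TRUE)
  group <- if (x$has_groups) sub("^grp=", "", as.character(s$strata)) else "all"
  tibble::tibble(
    time = s$time, n_risk = s$n.risk, n_event = s$n.event,
    n_censor = s$n.censor, survival = s$surv, group = group
  )
}

#' @method glance km_fit
#' @export
glance.km_fit <- function(x, ...) {
  out <- tibble::tibble(
    n = nrow(x$records), n_events = sum(x$records$dss_event),
    median_followup = stats::median(x$records$followup_months)
  )
  if (x$has_groups) {
    lr <- logrank_test(x$records)
    out$logrank_chi2 <- lr$chi2
    out$logrank_df <- lr$df
    out$logrank_p <- lr$p
  }
  out
}

#' @export
print.km_fit <- function(x, ...) {
  print(glance(x))
  invisible(x)
}

#' Log-rank comparison of survival between groups
#'
#' Standard log-rank chi-square with k - 1 degrees of freedom.
#'
#' @param records Tibble with `followup_months`, `dss_event`, `group`.
#' @return One-row tibble `chi2`, `df`, `p`.
#' @export
logrank_test <- function(records) {
  if (!"group" %in% names(records)) stop("records need a group column", call. = FALSE)
  tab <- table(records$group)
  if (length(tab) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(tab == 0)) stop("empty group", call. = FALSE)
  if (sum(records$dss_event) < 1) stop("need at least one event", call. = FALSE)
  grp <- records$group
  sd <- survival::survdiff(
    survival::Surv(records$followup_months, as.integer(records$dss_event)) ~ grp
  )
  df <- length(sd$n) - 1
  tibble::tibble(chi2 = sd$chisq, df = df,
                 p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Define survival strata from complexity metrics
#'
#' `nfga_binary` splits samples into 0 vs >= 1 focal amplicon;
#' `cin_median` splits at the median CIN score (the median sample goes to
#' the lower stratum); `custom_labels` passes a `label` column through.
#'
#' @param complexity Tibble with `sample_id` and `nfga`, `cin_score`, or
#'   `label` depending on `mode`.
#' @param mode One of `"nfga_binary"`, `"cin_median"`, `"custom_labels"`.
#' @return Tibble `sample_id`, `group`.
#' @export
define_survival_groups <- function(complexity,
                                   mode = c("nfga_binary", "cin_median",
                                            "custom_labels")) {
  mode <- match.arg(mode)
  out <- tibble::tibble(sample_id = complexity$sample_id)
  out$group <- switch(mode,
    nfga_binary = ifelse(complexity$nfga >= 1, "FGA>=1", "FGA=0"),
    cin_median = {
      med <- stats::median(complexity$cin_score)
      ifelse(complexity$cin_score > med, "CIN high", "CIN low")
    },
    custom_labels = complexity$label
  )
  out
}
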