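# Time-to-onset analysis: exclusion audit, Weibull fits with failure typing,
# KM cumulative incidence and Kruskal-Wallis subgroup comparisons.

#' Exclusion audit bookkeeping
#'
#' @param n_total cases entering the time-to-onset screen.
#' @param n_excluded_missing cases lacking day-level start or event dates.
#' @param n_excluded_invalid cases with non-positive onset intervals
#'   (event date on/before start date).
#' @return `exclusion_audit` list with `n_retained` and `exclusion_pct`
#'   (percent excluded, rounded half-up to one decimal).
#' @export
#' @examples
#' exclusion_audit(15374, 13021)$n_retained # 2353
exclusion_audit <- function(n_total, n_excluded_missing,
                            n_excluded_invalid = 0) {
  n_retained <- n_total - n_excluded_missing - n_excluded_invalid
  stopifnot(n_retained >= 0)
  structure(list(n_total = n_total,
                 n_excluded_missing = n_excluded_missing,
                 n_excluded_invalid = n_excluded_invalid,
                 n_retained = n_retained,
                 exclusion_pct = pct_of(n_excluded_missing +
                                          n_excluded_invalid, n_total)),
            class = "exclusion_audit")
}

#' @export
print.exclusion_audit <- function(x, ...) {
  cat(sprintf(
    "TTO exclusion audit: %d cases, %d excluded (%s%%: %d missing dates, %d invalid), %d retained\n",
    x$n_total, x$n_excluded_missing + x$n_excluded_invalid,
    format(x$exclusion_pct, nsmall = 1), x$n_excluded_missing,
    x$n_excluded_invalid, x$n_retained))
  invisible(x)
}

#' Compute time-to-onset records with the exclusion audit
#'
#' For every case and primary-suspect drug, onset = event date minus therapy
#' start date in days. Cases with missing or partial dates are excluded and
#' audited as missing; cases whose interval is zero or negative are audited
#' as invalid. The audit counts cases (one per report, using the earliest
#' start date across its suspect drugs); the record table carries one row per
#' (case, suspect drug) for drug-level fits, with `case_primary` marking the
#' earliest-start row per case for subgroup analyses (so patients are not
#' double-counted there).
#'
#' @param cases a `case_set`.
#' @param store the deduplicated `report_store`.
#' @param binning band spec as in [demographic_summary()] (labels the
#'   subgroup columns).
#' @return list with `records` (data.frame `report_id`, `drug`, `tto_days`,
#'   `sex`, `age_band`, `weight_band`, `case_primary`) and `audit`
#'   (an [exclusion_audit()]).
#' @export
compute_tto <- function(cases, store, binning = default_binning()) {
  ids <- cases$case_ids
  demo <- store$demo[match(ids, store$demo$primaryid), , drop = FALSE]
  ev <- demo$event_date
  ev[demo$event_partial] <- NA
  ps <- store$drug[store$drug$role == "primary-suspect" &
                     store$drug$primaryid %in% ids, , drop = FALSE]
  # earliest start per (report, drug)
  ord <- order(ps$primaryid, ps$drug_name, ps$start_date)
  ps <- ps[ord, , drop = FALSE]
  ps <- ps[!duplicated(paste(ps$primaryid, ps$drug_name, sep = "\r")), ,
           drop = FALSE]
  ev_of <- ev[match(ps$primaryid, ids)]
  tto <- as.integer(ev_of - ps$start_date)

  rec <- data.frame(report_id = ps$primaryid, drug = ps$drug_name,
                    tto_days = tto, stringsAsFactors = FALSE)
  d2 <- demo[match(rec$report_id, ids), , drop = FALSE]
  rec$sex <- d2$sex
  rec$age_band <- bin_label(d2$age_years, binning$age)
  rec$weight_band <- bin_label(d2$weight_kg, binning$weight)

  # case-level audit on the earliest start date per case
  min_start <- tapply(as.numeric(ps$start_date), ps$primaryid,
                      function(v) if (all(is.na(v))) NA_real_ else
                        min(v, na.rm = TRUE))
  st_case <- as.numeric(min_start[ids])
  ev_case <- as.numeric(ev)
  missing_case <- is.na(st_case) | is.na(ev_case)
  tto_case <- ev_case - st_case
  invalid_case <- !missing_case & tto_case <= 0
  audit <- exclusion_audit(length(ids), sum(missing_case), sum(invalid_case))

  # per-(case, drug) retention mirrors the same rules
  keep <- !is.na(rec$tto_days) & rec$tto_days >= 1
  rec <- rec[keep, , drop = FALSE]
  # mark the earliest-start row per retained case
  o <- order(rec$report_id, -rec$tto_days)  # longest tto = earliest start
  first <- !duplicated(rec$report_id[o])
  rec$case_primary <- logical(nrow(rec))
  rec$case_primary[o[first]] <- TRUE
  rownames(rec) <- NULL
  list(records = rec, audit = audit)
}

#' Fit a Weibull onset model to uncensored durations
#'
#' Maximum-likelihood fit (via [survival::survreg()], all events observed) of
#' durations in days. Scale \eqn{\alpha} and shape \eqn{\beta} get 95%
#' delta-method confidence intervals on the log-parameter scale. The model
#' median is \eqn{\alpha (\ln 2)^{1/\beta}}; the empirical median and IQR of
#' the raw durations are also reported, as onset tables conventionally print
#' the empirical quantiles.
#'
#' @param x positive durations (days), `n >= 3`.
#' @return object of class `weibull_tto` with elements `alpha`, `beta`,
#'   `ci_alpha`, `ci_beta`, `n`, `median_model`, `median_days`, `iqr_days`,
#'   `range_days`, `failure_type`, `degenerate`.
#' @export
fit_tto_weibull <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 3L)
    stop("Weibull onset fit requires at least 3 durations")
  if (any(is.na(x)) || any(x <= 0))
    stop("durations must be positive and non-missing")
  q <- unname(stats::quantile(x, c(0.25, 0.5, 0.75), type = 7))
  if (length(unique(x)) == 1L) {
    out <- structure(list(alpha = x[1], beta = Inf,
                          ci_alpha = c(NA, NA), ci_beta = c(NA, NA),
                          n = length(x), median_model = x[1],
                          median_days = q[2], iqr_days = q[c(1, 3)],
                          range_days = range(x), degenerate = TRUE),
                     class = "weibull_tto")
    out$failure_type <- "wear-out"
    return(out)
  }
  sr <- survival::survreg(survival::Surv(x, rep(1, length(x))) ~ 1,
                          dist = "weibull")
  alpha <- exp(unname(stats::coef(sr)[1]))
  beta <- 1 / sr$scale
  V <- stats::vcov(sr)  # (intercept, log sigma); log beta = -log sigma
  se_la <- sqrt(V[1, 1])
  se_lb <- sqrt(V[2, 2])
  out <- structure(list(
    alpha = alpha, beta = beta,
    ci_alpha = alpha * exp(c(-1, 1) * 1.96 * se_la),
    ci_beta = beta * exp(c(-1, 1) * 1.96 * se_lb),
    n = length(x),
    median_model = alpha * log(2)^(1 / beta),
    median_days = q[2], iqr_days = q[c(1, 3)],
    range_days = range(x), degenerate = FALSE), class = "weibull_tto")
  out$failure_type <- classify_failure(out)
  out
}

#' @export
print.weibull_tto <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Weibull onset fit (n = %d): scale %.2f days (95%% CI %.2f-%.2f), shape %.2f (95%% CI %.2f-%.2f)\n",
    x$n, x$alpha, x$ci_alpha[1], x$ci_alpha[2], x$beta, x$ci_beta[1],
    x$ci_beta[2]))
  cat(sprintf("empirical median %.1f days (IQR %.1f-%.1f); %s pattern\n",
              x$median_days, x$iqr_days[1], x$iqr_days[2], x$failure_type))
  invisible(x)
}

#' @export
coef.weibull_tto <- function(object, ...) {
  c(scale = object$alpha, shape = object$beta)
}

#' @export
confint.weibull_tto <- function(object, parm, level = 0.95, ...) {
  m <- rbind(scale = object$ci_alpha, shape = object$ci_beta)
  colnames(m) <- c("2.5 %", "97.5 %")
  m
}

#' Classify the hazard regime of a Weibull onset fit
#'
#' Point rule (default): shape below 1 is "early" failure (decreasing
#' hazard, events cluster soon after start), above 1 "wear-out" (increasing
#' hazard), exactly 1 "random". CI rule: classify by where the shape CI sits
#' relative to 1, "random" when it straddles.
#'
#' @param fit a `weibull_tto` (or a bare numeric shape value).
#' @param rule `"point"` or `"ci"`.
#' @return one of `"early"`, `"random"`, `"wear-out"`.
#' @export
#' @examples
#' classify_failure(0.93) # "early"
#' classify_failure(1.14) # "wear-out"
classify_failure <- function(fit, rule = c("point", "ci")) {
  rule <- match.arg(rule)
  if (is.numeric(fit)) {
    beta <- fit
    ci <- c(NA, NA)
  } else {
    beta <- fit$beta
    ci <- fit$ci_beta
  }
  if (rule == "point" || any(is.na(ci))) {
    if (beta < 1) "early" else if (beta > 1) "wear-out" else "random"
  } else {
    if (ci[2] < 1) "early" else if (ci[1] > 1) "wear-out" else "random"
  }
}

#' Per-drug Weibull onset table
#'
#' Fits [fit_tto_weibull()] for every drug with at least `min_n` retained
#' onset records, producing the usual onset summary table (n, empirical
#' median and IQR, min-max, scale and shape with CIs, failure type).
#'
#' @param records record table from [compute_tto()].
#' @param min_n minimum records per drug (default 3).
#' @param rule failure classification rule, see [classify_failure()].
#' @return data.frame sorted by descending n.
#' @export
tto_weibull_table <- function(records, min_n = 3, rule = "point") {
  sp <- split(records$tto_days, records$drug)
  sp <- sp[vapply(sp, length, 0L) >= min_n]
  rows <- lapply(names(sp), function(dr) {
    f <- fit_tto_weibull(sp[[dr]])
    data.frame(drug = dr, n = f$n, median_days = f$median_days,
               iqr_lo = f$iqr_days[1], iqr_hi = f$iqr_days[2],
               min_days = f$range_days[1], max_days = f$range_days[2],
               alpha = f$alpha, alpha_lcl = f$ci_alpha[1],
               alpha_ucl = f$ci_alpha[2],
               beta = f$beta, beta_lcl = f$ci_beta[1],
               beta_ucl = f$ci_beta[2],
               failure_type = classify_failure(f, rule),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(invisible(NULL))
  out <- out[order(-out$n, out$drug), ]
  rownames(out) <- NULL
  out
}

#' Kaplan-Meier cumulative incidence of onset by group
#'
#' With every onset observed (no censoring) the KM cumulative incidence
#' equals the empirical CDF; the computation still goes through
#' [survival::survfit()] so the machinery extends to censored inputs.
#' Empty groups are dropped with a warning.
#'
#' @param time positive onset durations.
#' @param group group labels (single group when omitted).
#' @return list with `curves` (data.frame `group`, `time`, `cum_inc`) and
#'   `medians` (named vector of per-group median onset).
#' @export
km_curve <- function(time, group = NULL) {
  stopifnot(all(time > 0))
  if (is.null(group)) group <- rep("all", length(time))
  if (is.factor(group)) {
    empty <- setdiff(levels(group), as.character(unique(group)))
    if (length(empty))
      warning("dropping empty group(s): ", paste(empty, collapse = ", "))
  }
  group <- as.character(group)
  sf <- survival::survfit(survival::Surv(time, rep(1, length(time))) ~ group)
  st <- summary(sf)
  grp <- if (is.null(st$strata)) rep(unique(group), length(st$time)) else
    sub("^group=", "", as.character(st$strata))
  curves <- data.frame(group = grp, time = st$time,
                       cum_inc = 1 - st$surv, stringsAsFactors = FALSE)
  medians <- tapply(time, group, stats::median)
  list(curves = curves, medians = medians)
}

#' Kruskal-Wallis comparison of onset distributions
#'
#' Midrank-based H with tie correction via [stats::kruskal.test()]; p-value
#' from the chi-square reference with k-1 df. When every value across all
#' groups is identical the statistic is defined as 0 with p = 1.
#'
#' @param groups list of numeric duration vectors (>= 2 groups).
#' @return list with `statistic` (H), `df`, `p_value`.
#' @export
#' @examples
#' kw_test(list(c(1, 2, 3), c(4, 5, 6))) # H = 3.857
kw_test <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2,
            all(vapply(groups, length, 0L) >= 1))
  all_v <- unlist(groups, use.names = FALSE)
  if (length(unique(all_v)) == 1L)
    return(list(statistic = 0, df = length(groups) - 1L, p_value = 1))
  kt <- stats::kruskal.test(groups)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value)
}
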