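# Per-drug 2x2 tables and the four-metric disproportionality panel:
# ROR (95% CI), PRR (chi-square), IC (IC025), EBGM (EBGM05), Fisher exact p
# with Bonferroni / Benjamini-Hochberg adjustment, positivity rules,
# volcano export, two-source comparison and PT composition profiles.

#' Build the drug x event 2x2 contingency table
#'
#' Counting unit is the unique deduplicated report. `a` = case reports whose
#' primary-suspect set contains the drug, `b` = non-case reports with the
#' drug as primary suspect, `c` = case reports without it, `d` = the rest;
#' the four cells always sum to the store size.
#'
#' @param cases a `case_set`.
#' @param store the deduplicated `report_store`.
#' @param drug normalized drug name. A drug absent from the store yields
#'   `a = b = 0` with `flagged = TRUE` rather than an error.
#' @return object of class `contingency_2x2`: list with `a`, `b`, `c`, `d`,
#'   `n`, `drug`, `flagged`.
#' @export
contingency_table <- function(cases, store, drug) {
  drug <- normalize_drug_name(drug)
  ps <- store$drug[store$drug$role == "primary-suspect", , drop = FALSE]
  exposed <- unique(ps$primaryid[ps$drug_name == drug])
  case_ids <- cases$case_ids
  n <- n_reports(store)
  a <- length(intersect(exposed, case_ids))
  b <- length(exposed) - a
  cc <- length(case_ids) - a
  d <- n - a - b - cc
  structure(list(a = a, b = b, c = cc, d = d, n = n, drug = drug,
                 flagged = (a + b) == 0L),
            class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  cat(sprintf("2x2 table for %s (N = %d)\n", x$drug %||% "?", x$n))
  m <- matrix(c(x$a, x$c, x$b, x$d), 2,
              dimnames = list(c("drug", "other drugs"),
                              c("event", "other events")))
  print(m)
  invisible(x)
}

#' Compute the disproportionality metric panel for one 2x2 table
#'
#' Closed forms, with `N = a+b+c+d`:
#' \deqn{ROR = ad/bc, \quad CI95 = \exp(\ln ROR \pm 1.96 \sqrt{1/a+1/b+1/c+1/d})}
#' \deqn{PRR = \frac{a/(a+b)}{c/(c+d)}, \quad
#'       \chi^2 = \frac{N(ad-bc)^2}{(a+b)(c+d)(a+c)(b+d)}}
#' \deqn{RRR = \frac{aN}{(a+b)(a+c)}, \quad IC = \log_2 RRR, \quad
#'       IC025 = IC - 1.96\sqrt{1/a+1/b+1/c+1/d}/\ln 2}
#' \deqn{EBGM = RRR, \quad EBGM05 = \exp(\ln EBGM - 1.64\sqrt{1/a+1/b+1/c+1/d})}
#' plus the two-sided Fisher exact p. The IC/EBGM forms are the simplified
#' observed-over-expected versions (no gamma-Poisson shrinkage); the IC025 is
#' a delta-method bound on the log2 scale.
#'
#' @param tab a `contingency_2x2`, or a numeric vector `c(a, b, c, d)`.
#' @param haldane apply the Haldane-Anscombe +0.5 correction to the ratio
#'   metrics when any cell is zero (default FALSE: affected metrics come back
#'   `NaN`/`Inf` and `undefined = TRUE`).
#' @param yates apply Yates continuity correction to the chi-square
#'   (default FALSE).
#' @return one-row data.frame with columns `drug`, `n_reports` (= a), `ror`,
#'   `ror_lcl`, `ror_ucl`, `prr`, `chi2`, `rrr`, `ic`, `ic025`, `ebgm`,
#'   `ebgm05`, `fisher_p`, `undefined`.
#' @export
#' @examples
#' disprop_metrics(c(5, 95, 50, 9850)) # ROR 10.37, PRR 9.90, IC 3.18
disprop_metrics <- function(tab, haldane = FALSE, yates = FALSE) {
  if (inherits(tab, "contingency_2x2")) {
    cells <- as.numeric(c(tab$a, tab$b, tab$c, tab$d)); drug <- tab$drug
  } else {
    cells <- as.numeric(tab); drug <- NA_character_
  }
  if (length(cells) != 4L || any(is.na(cells)))
    stop("need four cell counts a, b, c, d")
  if (any(cells < 0)) stop("negative cell counts")
  a0 <- cells[1]; b0 <- cells[2]; c0 <- cells[3]; d0 <- cells[4]
  nn <- a0 + b0 + c0 + d0
  if (nn <= 0) stop("empty table")
  zero <- any(cells == 0)
  undefined <- zero && !haldane
  k <- if (zero && haldane) 0.5 else 0
  a <- a0 + k; b <- b0 + k; cc <- c0 + k; d <- d0 + k
  n <- a + b + cc + d

  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  ror <- (a * d) / (b * cc)
  prr <- (a / (a + b)) / (cc / (cc + d))
  rrr <- a * n / ((a + b) * (a + cc))
  ic <- log2(rrr)
  ebgm <- rrr

  # chi-square always on the uncorrected counts
  num <- abs(a0 * d0 - b0 * c0)
  if (yates) num <- max(0, num - nn / 2)
  den <- (a0 + b0) * (c0 + d0) * (a0 + c0) * (b0 + d0)
  chi2 <- if (den > 0) nn * num^2 / den else NaN

  fisher_p <- fisher_p_2x2(a0, b0, c0, d0)

  data.frame(
    drug = drug, n_reports = a0,
    ror = ror, ror_lcl = exp(log(ror) - 1.96 * se),
    ror_ucl = exp(log(ror) + 1.96 * se),
    prr = prr, chi2 = chi2, rrr = rrr,
    ic = ic, ic025 = ic - 1.96 * se / log(2),
    ebgm = ebgm, ebgm05 = exp(log(ebgm) - 1.64 * se),
    fisher_p = fisher_p, undefined = undefined,
    stringsAsFactors = FALSE
  )
}

# two-sided Fisher exact p for one 2x2 table (the panel's p-value path)
fisher_p_2x2 <- function(a, b, c, d) {
  min(1, stats::fisher.test(matrix(c(a, c, b, d), 2))$p.value)
}

#' Signal positivity criteria
#'
#' Defaults are the standard screening thresholds: PRR method positive when
#' report count >= 3, PRR >= 2 and chi-square >= 4; ROR method positive when
#' the lower 95% CI bound exceeds 1; IC method positive when IC025 exceeds 0;
#' overall positive under the any-of combination rule.
#'
#' @param n_min,prr_min,chi2_min,ror_lcl_min,ic025_min thresholds.
#' @param rule `"any"` (default) or `"all"` combination of the three methods.
#' @return a `signal_criteria` list.
#' @export
signal_criteria <- function(n_min = 3, prr_min = 2, chi2_min = 4,
                            ror_lcl_min = 1, ic025_min = 0,
                            rule = c("any", "all")) {
  rule <- match.arg(rule)
  structure(list(n_min = n_min, prr_min = prr_min, chi2_min = chi2_min,
                 ror_lcl_min = ror_lcl_min, ic025_min = ic025_min,
                 rule = rule),
            class = "signal_criteria")
}

#' Evaluate signal positivity for a metric panel
#'
#' @param metrics data.frame from [disprop_metrics()] (any number of rows).
#' @param criteria a [signal_criteria()].
#' @return the input with logical columns `prr_positive`, `ror_positive`,
#'   `ic_positive`, `positive` appended.
#' @export
evaluate_signal <- function(metrics, criteria = signal_criteria()) {
  stopifnot(inherits(criteria, "signal_criteria"))
  ok <- function(x) !is.na(x) & is.finite(x)
  prr_pos <- metrics$n_reports >= criteria$n_min &
    ok(metrics$prr) & metrics$prr >= criteria$prr_min &
    ok(metrics$chi2) & metrics$chi2 >= criteria$chi2_min
  ror_pos <- ok(metrics$ror_lcl) & metrics$ror_lcl > criteria$ror_lcl_min
  ic_pos <- ok(metrics$ic025) & metrics$ic025 > criteria$ic025_min
  metrics$prr_positive <- prr_pos
  metrics$ror_positive <- ror_pos
  metrics$ic_positive <- ic_pos
  metrics$positive <- if (criteria$rule == "any")
    prr_pos | ror_pos | ic_pos else prr_pos & ror_pos & ic_pos
  metrics
}

#' Adjust p-values for multiplicity
#'
#' Thin validated wrapper over [stats::p.adjust()]: Bonferroni
#' (`min(1, m p)`) or Benjamini-Hochberg step-up with monotonicity
#' enforcement; the mapping is order-preserving.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param method `"bonferroni"` or `"BH"`.
#' @return adjusted p-values, same order as the input.
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "BH")) {
  method <- match.arg(method)
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = method)
}

#' Per-drug signal panel for a store
#'
#' Runs [contingency_table()] + [disprop_metrics()] for every drug (or a
#' given subset), evaluates positivity, and attaches both Bonferroni- and
#' BH-adjusted Fisher p-values.
#'
#' @param cases a `case_set`.
#' @param store the deduplicated `report_store`.
#' @param drugs drugs to evaluate; default = every primary-suspect drug in
#'   the store.
#' @param criteria a [signal_criteria()].
#' @param min_a only emit rows with at least this many case reports
#'   (default 1; 0 keeps all).
#' @param source label recorded in the `source` column.
#' @param haldane passed to [disprop_metrics()].
#' @return data.frame of class `signal_panel`, one row per drug, sorted by
#'   descending case count; columns of [disprop_metrics()] plus
#'   `p_adj` (Bonferroni), `p_fdr` (BH), positivity flags and `source`.
#' @export
signal_panel <- function(cases, store, drugs = NULL,
                         criteria = signal_criteria(), min_a = 1,
                         source = "FAERS-like", haldane = FALSE) {
  if (is.null(drugs)) {
    ps <- store$drug[store$drug$role == "primary-suspect", , drop = FALSE]
    drugs <- sort(unique(ps$drug_name))
  } else drugs <- normalize_drug_name(drugs)
  rows <- lapply(drugs, function(dr)
    disprop_metrics(contingency_table(cases, store, dr), haldane = haldane))
  out <- do.call(rbind, rows)
  out <- out[out$n_reports >= min_a, , drop = FALSE]
  out$p_adj <- adjust_pvalues(out$fisher_p, "bonferroni")
  out$p_fdr <- adjust_pvalues(out$fisher_p, "BH")
  out <- evaluate_signal(out, criteria)
  out$source <- source
  out <- out[order(-out$n_reports, out$drug), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("signal_panel", "data.frame")
  out
}

#' @export
print.signal_panel <- function(x, digits = 3, ...) {
  cat(sprintf("disproportionality panel: %d drugs, %d signal-positive (%s)\n",
              nrow(x), sum(x$positive), x$source[1] %||% ""))
  cols <- c("drug", "n_reports", "ror", "ror_lcl", "ror_ucl", "prr", "chi2",
            "ic", "ic025", "ebgm", "ebgm05", "p_adj", "positive")
  print.data.frame(head(as.data.frame(x)[, cols], 20), digits = digits,
                   row.names = FALSE)
  if (nrow(x) > 20) cat(sprintf("... and %d more rows\n", nrow(x) - 20))
  invisible(x)
}

#' Volcano-plot export table
#'
#' Emits `(drug, log2 ROR, -log10 adjusted p, n_reports)`. Zero adjusted
#' p-values are floored at the smallest representable double before the log.
#' `layout = "swapped"` exchanges the two coordinates (both axis conventions
#' are in circulation).
#'
#' @param panel a `signal_panel` (needs `p_adj`; set `p_col = "p_fdr"` for
#'   the FDR-adjusted variant).
#' @param p_col which adjusted-p column to use.
#' @param layout `"standard"` (x = log2 ROR, y = -log10 p) or `"swapped"`.
#' @return data.frame with columns `drug`, `x`, `y`, `n_reports`.
#' @export
volcano_table <- function(panel, p_col = "p_adj",
                          layout = c("standard", "swapped")) {
  layout <- match.arg(layout)
  if (nrow(panel) == 0L)
    return(data.frame(drug = character(0), x = numeric(0), y = numeric(0),
                      n_reports = integer(0)))
  p <- pmax(panel[[p_col]], .Machine$double.xmin)
  l2 <- log2(panel$ror)
  nl10 <- -log10(p)
  out <- if (layout == "standard")
    data.frame(drug = panel$drug, x = l2, y = nl10,
               n_reports = panel$n_reports, stringsAsFactors = FALSE)
  else
    data.frame(drug = panel$drug, x = nl10, y = l2,
               n_reports = panel$n_reports, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Compare signal panels from two sources
#'
#' Aligns two panels (e.g. a FAERS-like and a second spontaneous-report
#' source) computed under identical criteria, flags per-source positivity
#' and corroboration (positive in both), and lists discordant drugs.
#'
#' @param panel_a,panel_b `signal_panel` objects.
#' @return list with `comparison` (per-drug side-by-side data.frame including
#'   `corroborated`) and `discordant` (drugs positive in exactly one source).
#' @export
compare_sources <- function(panel_a, panel_b) {
  key <- c("drug", "n_reports", "ror", "ror_lcl", "ror_ucl", "prr", "chi2",
           "ic", "ic025", "ebgm", "ebgm05", "p_adj", "positive")
  a <- as.data.frame(panel_a)[, key]
  b <- as.data.frame(panel_b)[, key]
  names(a)[-1] <- paste0(names(a)[-1], "_a")
  names(b)[-1] <- paste0(names(b)[-1], "_b")
  cmp <- merge(a, b, by = "drug", all = TRUE)
  cmp$positive_a[is.na(cmp$positive_a)] <- FALSE
  cmp$positive_b[is.na(cmp$positive_b)] <- FALSE
  cmp$corroborated <- cmp$positive_a & cmp$positive_b
  disc <- cmp$drug[xor(cmp$positive_a, cmp$positive_b)]
  list(comparison = cmp, discordant = disc)
}

#' PT composition per drug class
#'
#' For each drug class, the share of each matched preferred term among all
#' matched-term occurrences in the class; shares sum to 1 within a class.
#' One occurrence is counted per (case, matched PT). Drugs without a class
#' mapping fall into `"other"`.
#'
#' @param cases a `case_set`.
#' @param class_map named character vector: drug name -> class label.
#' @return data.frame with columns `class`, `pt_name`, `n`, `share`.
#' @export
pt_composition <- function(cases, class_map = character(0)) {
  if (length(cases$case_ids) == 0L)
    return(data.frame(class = character(0), pt_name = character(0),
                      n = integer(0), share = numeric(0)))
  names(class_map) <- normalize_drug_name(names(class_map))
  rows <- do.call(rbind, lapply(cases$case_ids, function(id) {
    drugs <- cases$suspect_drugs[[id]]
    cls <- unique(ifelse(drugs %in% names(class_map),
                         unname(class_map[drugs]), "other"))
    expand.grid(class = cls, pt_name = cases$matched_terms[[id]],
                stringsAsFactors = FALSE)
  }))
  tab <- stats::aggregate(list(n = rep(1L, nrow(rows))),
                          rows[c("class", "pt_name")], sum)
  tot <- stats::ave(tab$n, tab$class, FUN = sum)
  tab$share <- tab$n / tot
  tab <- tab[order(tab$class, -tab$share, tab$pt_name), ]
  rownames(tab) <- NULL
  tab
}
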