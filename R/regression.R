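# Risk-factor cascade: univariate disproportionality screen -> LASSO with
# 10-fold cross-validation -> multivariable logistic regression -> forest
# export.

#' Univariate candidate screen
#'
#' Keeps drugs whose panel row passes all three thresholds: at least `min_n`
#' case reports, ROR lower CI bound above `ror_lcl_min`, and adjusted p
#' below `p_adj_max`. Per-drug pass/fail reasons are recorded.
#'
#' @param panel a `signal_panel`.
#' @param min_n minimum case-report count (default 3; the LASSO-entry stage
#'   conventionally re-screens at a strict `> 3`, i.e. `min_n = 4`).
#' @param ror_lcl_min ROR lower-bound threshold (default 1).
#' @param p_adj_max adjusted-p ceiling (default 0.05 at the screen stage;
#'   0.01 at the LASSO-entry stage).
#' @param p_col adjusted-p column to use (`"p_adj"` Bonferroni or `"p_fdr"`).
#' @return data.frame with `drug`, the screened quantities, `pass` and a
#'   semicolon-separated `fail_reasons` column.
#' @export
screen_candidates <- function(panel, min_n = 3, ror_lcl_min = 1,
                              p_adj_max = 0.05, p_col = "p_adj") {
  p <- panel[[p_col]]
  r_n <- panel$n_reports >= min_n
  r_ror <- !is.na(panel$ror_lcl) & is.finite(panel$ror_lcl) &
    panel$ror_lcl > ror_lcl_min
  r_p <- !is.na(p) & p < p_adj_max
  reasons <- mapply(function(n, ro, pp) {
    paste(c(if (!n) "count", if (!ro) "ror_lcl", if (!pp) "p_adj"),
          collapse = ";")
  }, r_n, r_ror, r_p)
  out <- data.frame(drug = panel$drug, n_reports = panel$n_reports,
                    ror_lcl = panel$ror_lcl, p = p,
                    pass = r_n & r_ror & r_p,
                    fail_reasons = reasons, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Build the report-level model matrix for the regression stages
#'
#' One row per deduplicated report. Outcome = case indicator; predictors are
#' screened-drug indicators (1 iff the drug is in the report's
#' primary-suspect set), age in years, sex (male indicator), weight in kg,
#' and `n_drugs`, the per-report count of distinct drug names across all
#' roles (the polypharmacy covariate).
#'
#' @param store the deduplicated `report_store`.
#' @param cases a `case_set`.
#' @param candidates character vector of screened drug names.
#' @param covariates subset of `c("age_years", "sex", "weight_kg",
#'   "n_drugs")` to include.
#' @param missing `"complete"` (drop rows with any missing modelled
#'   covariate; the default) or `"indicator"` (impute the median and add a
#'   `<var>_missing` indicator).
#' @return list of class `pv_model_matrix` with `x` (sparse Matrix), `y`
#'   (0/1 vector), `report_id`, and `n_dropped`.
#' @export
build_model_matrix <- function(store, cases, candidates,
                               covariates = c("age_years", "sex",
                                              "weight_kg", "n_drugs"),
                               missing = c("complete", "indicator")) {
  missing <- match.arg(missing)
  if (length(candidates) == 0L) stop("no candidate drugs supplied")
  candidates <- normalize_drug_name(candidates)
  demo <- store$demo
  n <- nrow(demo)
  y <- as.integer(demo$primaryid %in% cases$case_ids)

  ps <- store$drug[store$drug$role == "primary-suspect" &
                     store$drug$drug_name %in% candidates, , drop = FALSE]
  i <- match(ps$primaryid, demo$primaryid)
  j <- match(ps$drug_name, candidates)
  keep <- !is.na(i) & !is.na(j)
  xd <- Matrix::sparseMatrix(i = i[keep], j = j[keep], x = 1,
                             dims = c(n, length(candidates)),
                             dimnames = list(NULL, candidates))
  xd@x[] <- 1  # repeated PS rows must not accumulate

  covs <- list()
  if ("age_years" %in% covariates) covs$age_years <- demo$age_years
  if ("sex" %in% covariates)
    covs$sex_male <- ifelse(demo$sex == "male", 1,
                            ifelse(demo$sex == "female", 0, NA))
  if ("weight_kg" %in% covariates) covs$weight_kg <- demo$weight_kg
  if ("n_drugs" %in% covariates) {
    nd <- table(factor(store$drug$primaryid[
      !duplicated(paste(store$drug$primaryid, store$drug$drug_name))],
      levels = demo$primaryid))
    covs$n_drugs <- as.numeric(nd)
  }

  if (length(covs)) {
    cm <- do.call(cbind, covs)
    if (missing == "complete") {
      ok <- stats::complete.cases(cm)
    } else {
      ok <- rep(TRUE, n)
      for (v in colnames(cm)) {
        na <- is.na(cm[, v])
        if (any(na)) {
          cm <- cbind(cm, as.numeric(na))
          colnames(cm)[ncol(cm)] <- paste0(v, "_missing")
          cm[na, v] <- stats::median(cm[!na, v])
        }
      }
    }
    x <- cbind(xd[ok, , drop = FALSE], Matrix::Matrix(cm[ok, , drop = FALSE],
                                                      sparse = TRUE))
    y <- y[ok]
    ids <- demo$primaryid[ok]
    n_dropped <- n - sum(ok)
  } else {
    x <- xd; ids <- demo$primaryid; n_dropped <- 0L
  }
  if (nrow(x) == 0L) stop("no usable rows after missing-data handling")
  # constant columns carry no information and break standardization
  const <- apply(x, 2, function(v) min(v) == max(v))
  x <- x[, !const, drop = FALSE]
  structure(list(x = x, y = y, report_id = ids, n_dropped = n_dropped),
            class = "pv_model_matrix")
}

#' @export
print.pv_model_matrix <- function(x, ...) {
  cat(sprintf("model matrix: %d reports x %d predictors, %d cases (%d rows dropped)\n",
              nrow(x$x), ncol(x$x), sum(x$y), x$n_dropped))
  invisible(x)
}

#' LASSO variable selection with stratified 10-fold cross-validation
#'
#' L1-penalized logistic path over a decreasing lambda grid
#' (via [glmnet::cv.glmnet()]; continuous covariates are standardized
#' internally and coefficients reported on the original scale). Fold
#' assignment is stratified by outcome so rare cases appear in every fold,
#' and is deterministic given the seed. The cross-validation criterion is
#' the mean squared error of predicted probabilities by default; deviance is
#' available. The selected lambda minimizes the CV criterion.
#'
#' @param mm a `pv_model_matrix`.
#' @param nfolds number of CV folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @param criterion `"mse"` or `"deviance"`.
#' @param lambda optional user lambda grid.
#' @return object of class `lasso_screen`: list with `cv` (the cv.glmnet
#'   fit), `lambda_selected`, `selected` (variables with non-zero
#'   coefficients), `coef` (named vector at the selected lambda), `nfolds`,
#'   `seed`.
#' @export
lasso_select <- function(mm, nfolds = 10, seed = 1, criterion = c("mse",
                                                                  "deviance"),
                         lambda = NULL, ...) {
  criterion <- match.arg(criterion)
  y <- mm$y
  if (length(unique(y)) < 2L) stop("outcome has a single class")
  if (ncol(mm$x) < 2L) stop("need at least two candidate columns")
  set.seed(seed)
  foldid <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    foldid[idx] <- sample(rep_len(seq_len(nfolds), length(idx)))
  }
  cv <- glmnet::cv.glmnet(mm$x, y, family = "binomial", foldid = foldid,
                          type.measure = criterion, lambda = lambda,
                          standardize = TRUE, ...)
  co <- stats::coef(cv, s = "lambda.min")
  co <- stats::setNames(as.numeric(co), rownames(co))
  sel <- names(co)[co != 0 & names(co) != "(Intercept)"]
  structure(list(cv = cv, lambda_selected = cv$lambda.min, selected = sel,
                 coef = co, nfolds = nfolds, seed = seed,
                 criterion = criterion),
            class = "lasso_screen")
}

#' @export
print.lasso_screen <- function(x, ...) {
  cat(sprintf(
    "LASSO screen (%d-fold CV, %s): lambda = %.4g, %d variables selected\n",
    x$nfolds, x$criterion, x$lambda_selected, length(x$selected)))
  if (length(x$selected)) cat(paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Multivariable logistic regression on the selected variables
#'
#' Maximum-likelihood logistic fit with Wald 95% CIs on the odds-ratio
#' scale; per-term p-values are Bonferroni-adjusted over the number of
#' reported terms (the intercept is not reported). Collinear columns are
#' dropped with a warning. Quasi-separated terms (some fitted probability
#' within 1e-8 of 0/1 with a diverging coefficient) are flagged and reported
#' with an infinite-CI marker.
#'
#' @param mm a `pv_model_matrix`.
#' @param variables columns of `mm$x` to include (default: all; typically
#'   the LASSO selection).
#' @return data.frame of class `logistic_terms`, sorted by descending OR:
#'   `variable`, `coef`, `or`, `or_lcl`, `or_ucl`, `p`, `p_adj`,
#'   `separation`.
#' @export
fit_logistic <- function(mm, variables = colnames(mm$x)) {
  variables <- intersect(variables, colnames(mm$x))
  if (length(variables) == 0L) stop("no variables to fit")
  x <- as.matrix(mm$x[, variables, drop = FALSE])
  df <- data.frame(y = mm$y, x, check.names = FALSE)
  fit <- stats::glm(y ~ ., data = df, family = stats::binomial())
  co <- summary(fit)$coefficients
  aliased <- setdiff(variables, rownames(co))
  if (length(aliased))
    warning("dropping collinear column(s): ", paste(aliased, collapse = ", "))
  keep <- setdiff(rownames(co), "(Intercept)")
  est <- co[keep, "Estimate"]
  se <- co[keep, "Std. Error"]
  p <- co[keep, "Pr(>|z|)"]
  fitted <- stats::fitted(fit)
  near_bound <- any(fitted < 1e-8 | fitted > 1 - 1e-8)
  sep <- near_bound & abs(est) > 15
  out <- data.frame(
    variable = keep, coef = est, or = exp(est),
    or_lcl = ifelse(sep, 0, exp(est - 1.96 * se)),
    or_ucl = ifelse(sep, Inf, exp(est + 1.96 * se)),
    p = p, p_adj = adjust_pvalues(p, "bonferroni"),
    separation = sep, stringsAsFactors = FALSE
  )
  out <- out[order(-out$or), ]
  rownames(out) <- NULL
  attr(out, "fit") <- fit
  class(out) <- c("logistic_terms", "data.frame")
  out
}

#' @export
print.logistic_terms <- function(x, digits = 3, ...) {
  cat(sprintf("multivariable logistic model: %d terms\n", nrow(x)))
  print.data.frame(as.data.frame(x)[, c("variable", "or", "or_lcl", "or_ucl",
                                        "p_adj", "separation")],
                   digits = digits, row.names = FALSE)
  invisible(x)
}

#' Forest-plot export of logistic terms
#'
#' @param terms a `logistic_terms` table.
#' @param sig_level adjusted-p significance marker threshold (default 0.01).
#' @return data.frame `(variable, or, or_lcl, or_ucl, p_adj, significant)`
#'   sorted by descending OR.
#' @export
forest_table <- function(terms, sig_level = 0.01) {
  if (nrow(terms) == 0L)
    return(data.frame(variable = character(0), or = numeric(0),
                      or_lcl = numeric(0), or_ucl = numeric(0),
                      p_adj = numeric(0), significant = logical(0)))
  out <- data.frame(variable = terms$variable, or = terms$or,
                    or_lcl = terms$or_lcl, or_ucl = terms$or_ucl,
                    p_adj = terms$p_adj,
                    significant = terms$p_adj < sig_level,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$or), ]
  rownames(out) <- NULL
  out
}
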