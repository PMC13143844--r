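fixture_panel <- function() {
  data.frame(
    drug = c("STRONG", "TINY", "WEAK_LCL", "BIG_P"),
    n_reports = c(758L, 2L, 50L, 40L),
    ror_lcl = c(13.90, 8.0, 0.9, 2.0),
    p_adj = c(1e-200, 0.001, 0.001, 0.20),
    stringsAsFactors = FALSE
  )
}

test_that("univariate screen applies all three rules with reasons", {
  sc <- screen_candidates(fixture_panel(), min_n = 3, p_adj_max = 0.05)
  expect_equal(sc$drug[sc$pass], "STRONG")
  expect_match(sc$fail_reasons[sc$drug == "TINY"], "count")
  expect_match(sc$fail_reasons[sc$drug == "WEAK_LCL"], "ror_lcl")
  expect_match(sc$fail_reasons[sc$drug == "BIG_P"], "p_adj")
})

test_that("screen is monotone under threshold tightening", {
  panel <- fixture_panel()
  base <- screen_candidates(panel, min_n = 3, p_adj_max = 0.05)
  for (args in list(list(min_n = 10), list(ror_lcl_min = 5),
                    list(p_adj_max = 1e-5))) {
    tight <- do.call(screen_candidates, c(list(panel), args))
    expect_true(all(tight$drug[tight$pass] %in% base$drug[base$pass]))
  }
})

test_that("model matrix encodes exposures, polypharmacy and missing policy", {
  demo <- data.frame(
    primaryid = as.character(1:6), caseid = as.character(1:6),
    receipt_date = as.Date("2024-01-01"), event_date = as.Date(NA),
    event_partial = FALSE,
    sex = c("male", "female", "male", "unknown", "female", "male"),
    age_years = c(60, 55, NA, 40, 70, 50),
    weight_kg = c(80, 60, 70, 75, NA, 90),
    country = "US", report_year = 2024L, stringsAsFactors = FALSE)
  drug <- data.frame(
    primaryid = c("1", "1", "1", "2", "3", "4", "5", "6", "6"),
    drug_seq = "1",
    drug_name = c("CAND_A", "CAND_B", "OTHER", "CAND_A", "CAND_B",
                  "CAND_A", "CAND_A", "OTHER", "OTHER"),
    role = c("primary-suspect", "primary-suspect", "concomitant",
             "primary-suspect", "primary-suspect", "primary-suspect",
             "primary-suspect", "primary-suspect", "concomitant"),
    start_date = as.Date(NA), stringsAsFactors = FALSE)
  reac <- data.frame(primaryid = c("1", "2"), pt_code = "10014962",
                     pt_name = "eosinophilic pneumonia",
                     stringsAsFactors = FALSE)
  store <- report_store(demo, drug, reac)
  cases <- extract_cases(store, smq_eosinophilic_pneumonia())
  mm <- build_model_matrix(store, cases, c("CAND_A", "CAND_B"))
  # complete-case drops exactly the rows with a missing modelled covariate
  expect_equal(mm$n_dropped, 3L)
  expect_setequal(mm$report_id, c("1", "2", "6"))
  x <- as.matrix(mm$x)
  # report 1 exposed to both candidates; n_drugs counts distinct names
  r1 <- x[mm$report_id == "1", ]
  expect_equal(unname(r1["CAND_A"]), 1)
  expect_equal(unname(r1["CAND_B"]), 1)
  expect_gte(unname(r1["n_drugs"]), 2)
  expect_equal(unname(x[mm$report_id == "6", "n_drugs"]), 1) # dup name once
  # outcome marks the SMQ cases
  expect_equal(mm$y, as.integer(mm$report_id %in% c("1", "2")))
  # column means match brute-force recomputation on the kept rows
  kept <- demo$primaryid %in% mm$report_id
  expect_equal(unname(colMeans(x)[c("age_years", "weight_kg")]),
               c(mean(demo$age_years[kept]), mean(demo$weight_kg[kept])))
  # indicator mode keeps every row and adds missingness flags
  mi <- build_model_matrix(store, cases, c("CAND_A", "CAND_B"),
                           missing = "indicator")
  expect_equal(nrow(mi$x), 6)
  expect_true(any(grepl("_missing$", colnames(mi$x))))
})

test_that("penalty limit zeroes the path and lambda = 0 matches plain MLE", {
  set.seed(14)
  n <- 800
  x1 <- stats::rbinom(n, 1, 0.3)
  x2 <- stats::rnorm(n)
  y <- stats::rbinom(n, 1, stats::plogis(-1 + 1.2 * x1 + 0.5 * x2))
  mm <- structure(list(
    x = Matrix::Matrix(cbind(drug = x1, age = x2), sparse = TRUE),
    y = y, report_id = as.character(1:n), n_dropped = 0L),
    class = "pv_model_matrix")
  ls <- lasso_select(mm, seed = 2)
  # at the top of the default grid every penalized coefficient is zero
  path_top <- stats::coef(ls$cv$glmnet.fit, s = ls$cv$lambda[1])
  expect_true(all(abs(path_top[-1]) < 1e-12))
  # unpenalized end of the path agrees with the direct ML fit
  ls0 <- lasso_select(mm, seed = 2,
                      lambda = c(0.05, 0.01, 0.001, 0),
                      thresh = 1e-14)
  co0 <- stats::coef(ls0$cv$glmnet.fit, s = 0, exact = FALSE)
  ml <- stats::glm(y ~ x1 + x2, family = stats::binomial())
  expect_equal(as.numeric(co0), unname(stats::coef(ml)), tolerance = 1e-4)
})

test_that("LASSO selection count is monotone along the penalty path", {
  sim <- simulate_reports(planted_config(
    20000, seed = 19, missingness = list(age = 0.05, weight = 0.1,
                                         sex = 0.02)))
  store <- dedup_reports(as_report_store(sim))
  cases <- extract_cases(store, smq_eosinophilic_pneumonia())
  panel <- signal_panel(cases, store)
  sc <- screen_candidates(panel, min_n = 3, p_adj_max = 0.05)
  cands <- sc$drug[sc$pass]
  mm <- build_model_matrix(store, cases, cands)
  ls <- lasso_select(mm, seed = 23)
  nz <- ls$cv$glmnet.fit$df  # non-zero count along the decreasing grid
  expect_true(all(diff(nz) >= -1))
  # deterministic given the seed
  ls2 <- lasso_select(mm, seed = 23)
  expect_identical(ls$selected, ls2$selected)
  expect_equal(ls$lambda_selected, ls2$lambda_selected)
})

test_that("single-class outcome is refused", {
  mm <- structure(list(x = Matrix::Matrix(diag(4), sparse = TRUE),
                       y = rep(0L, 4), report_id = as.character(1:4),
                       n_dropped = 0L), class = "pv_model_matrix")
  expect_error(lasso_select(mm), "single class")
})

test_that("logistic OR on one binary predictor equals the 2x2 odds ratio", {
  set.seed(8)
  n <- 2000
  x <- stats::rbinom(n, 1, 0.2)
  y <- stats::rbinom(n, 1, stats::plogis(-2 + 1.5 * x))
  mm <- structure(list(x = Matrix::Matrix(cbind(DRUG = x), sparse = TRUE),
                       y = y, report_id = as.character(1:n),
                       n_dropped = 0L), class = "pv_model_matrix")
  lt <- fit_logistic(mm)
  a <- sum(x == 1 & y == 1); b <- sum(x == 1 & y == 0)
  cc <- sum(x == 0 & y == 1); d <- sum(x == 0 & y == 0)
  expect_equal(lt$or, (a * d) / (b * cc), tolerance = 1e-6)
  # and matches the disproportionality cross-product on the same data
  m <- disprop_metrics(c(a, b, cc, d))
  expect_equal(lt$or, m$ror, tolerance = 1e-6)
})

test_that("planted per-year age effect of 1.01 is recovered", {
  cfg <- sim_config(50000,
                    drugs = list(drug_spec("D", 0.01, 4)),
                    background_event_rate = 0.02,
                    missingness = list(age = 0, weight = 0.1, sex = 0),
                    covariate_log_or = c(age_years = 0.01),
                    seed = 55)
  store <- dedup_reports(as_report_store(simulate_reports(cfg)))
  cases <- extract_cases(store, smq_eosinophilic_pneumonia())
  mm <- build_model_matrix(store, cases, "D")
  lt <- fit_logistic(mm, c("D", "age_years"))
  or_age <- lt$or[lt$variable == "age_years"]
  expect_true(lt$or_lcl[lt$variable == "age_years"] < 1.01 &
                lt$or_ucl[lt$variable == "age_years"] > 1.01)
  expect_equal(or_age, 1.01, tolerance = 0.005)
})

test_that("separation is flagged with an infinite-CI marker", {
  x <- c(rep(1, 20), rep(0, 180))
  y <- c(rep(1, 20), rep(0, 180))  # perfect separation on the indicator
  mm <- structure(list(x = Matrix::Matrix(cbind(SEP = x), sparse = TRUE),
                       y = y, report_id = as.character(1:200),
                       n_dropped = 0L), class = "pv_model_matrix")
  lt <- suppressWarnings(fit_logistic(mm))
  expect_true(lt$separation[lt$variable == "SEP"])
  expect_equal(lt$or_ucl[lt$variable == "SEP"], Inf)
})

test_that("forest export sorts by OR with a significance marker", {
  terms <- structure(data.frame(
    variable = c("daptomycin-like", "mid", "null"),
    coef = log(c(12.50, 3.0, 1.0)),
    or = c(12.50, 3.0, 1.0),
    or_lcl = c(9.40, 2.0, 0.8), or_ucl = c(16.75, 4.5, 1.3),
    p = c(1e-30, 1e-5, 0.4), p_adj = c(3e-30, 3e-5, 1),
    separation = FALSE, stringsAsFactors = FALSE),
    class = c("logistic_terms", "data.frame"))
  ft <- forest_table(terms)
  expect_equal(ft$variable, c("daptomycin-like", "mid", "null"))
  expect_equal(ft$significant, c(TRUE, TRUE, FALSE))
  expect_equal(ft$or[1], 12.50)
  empty <- forest_table(terms[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("full cascade ranks planted effects concordantly with truth", {
  planted <- c(DRUG_A = 12.5, DRUG_B = 5, DRUG_C = 3, DRUG_D = 1, DRUG_E = 1)
  rhos <- vapply(1:5, function(s) {
    cfg <- sim_config(
      50000,
      drugs = mapply(function(nm, m) drug_spec(nm, 0.01, m),
                     names(planted), planted, SIMPLIFY = FALSE),
      background_event_rate = 0.01,
      missingness = list(age = 0.05, weight = 0.1, sex = 0.02),
      seed = 500 + s)
    store <- dedup_reports(as_report_store(simulate_reports(cfg)))
    cases <- extract_cases(store, smq_eosinophilic_pneumonia())
    panel <- signal_panel(cases, store)
    sc <- screen_candidates(panel, min_n = 4, p_adj_max = 0.01)
    cands <- sc$drug[sc$pass]
    est <- stats::setNames(rep(1, length(planted)), names(planted))
    if (length(cands)) {
      mm <- build_model_matrix(store, cases, cands)
      ls <- lasso_select(mm, seed = 900 + s)
      if (length(ls$selected)) {
        lt <- fit_logistic(mm, ls$selected)
        hit <- intersect(lt$variable, names(planted))
        est[hit] <- lt$or[match(hit, lt$variable)]
      }
    }
    stats::cor(est, planted, method = "spearman")
  }, numeric(1))
  expect_gte(mean(rhos), 0.9)
})
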