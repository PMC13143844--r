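# independent oracle: the same closed forms evaluated through a different
# algebraic arrangement (all in log space)
oracle_metrics <- function(a, b, c, d) {
  n <- a + b + c + d
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  lror <- (log(a) + log(d)) - (log(b) + log(c))
  lprr <- (log(a) - log(a + b)) - (log(c) - log(c + d))
  lrrr <- log(a) + log(n) - log(a + b) - log(a + c)
  chi2 <- exp(log(n) + 2 * log(abs(a * d - b * c)) -
                (log(a + b) + log(c + d) + log(a + c) + log(b + d)))
  list(ror = exp(lror), ror_lcl = exp(lror - 1.96 * se),
       ror_ucl = exp(lror + 1.96 * se),
       prr = exp(lprr), chi2 = chi2, ic = lrrr / log(2),
       ic025 = (lrrr - 1.96 * se) / log(2),
       ebgm = exp(lrrr), ebgm05 = exp(lrrr - 1.64 * se))
}

# two-sided Fisher exact p by hypergeometric enumeration
oracle_fisher <- function(a, b, c, d) {
  n <- a + b + c + d
  r1 <- a + b
  c1 <- a + c
  support <- max(0, r1 + c1 - n):min(r1, c1)
  pr <- stats::dhyper(support, c1, n - c1, r1)
  p0 <- stats::dhyper(a, c1, n - c1, r1)
  sum(pr[pr <= p0 * (1 + 1e-7)])
}

test_that("null table gives the symmetric fixed point", {
  m <- disprop_metrics(c(10, 10, 10, 10))
  expect_equal(m$ror, 1)
  expect_equal(m$prr, 1)
  expect_equal(m$ic, 0)
  expect_equal(m$chi2, 0)
  expect_equal(m$fisher_p, 1)
  st <- evaluate_signal(m)
  expect_false(st$prr_positive || st$ror_positive || st$ic_positive ||
                 st$positive)
})

test_that("metric panel matches the frozen closed-form oracle", {
  m <- disprop_metrics(c(5, 95, 50, 9850))
  expect_equal(m$ror, 10.3684, tolerance = 1e-4)
  expect_equal(m$ror_lcl, 4.0451, tolerance = 1e-4)
  expect_equal(m$ror_ucl, 26.5770, tolerance = 1e-4)
  expect_equal(m$prr, 9.9, tolerance = 1e-4)
  expect_equal(m$chi2, 36.5694, tolerance = 1e-4)
  expect_equal(m$ic, log2(50000 / 5500), tolerance = 1e-10)
  expect_equal(m$ebgm, 9.090909, tolerance = 1e-6)
  expect_equal(m$ebgm05, 4.1358, tolerance = 1e-4)
})

test_that("metrics agree with the log-space oracle on random tables", {
  set.seed(42)
  n_tab <- 2000
  cells <- matrix(sample(1:5000, 4 * n_tab, replace = TRUE), ncol = 4)
  for (i in seq_len(n_tab)) {
    a <- cells[i, 1]; b <- cells[i, 2]; cc <- cells[i, 3]; d <- cells[i, 4]
    m <- disprop_metrics(c(a, b, cc, d))
    o <- oracle_metrics(a, b, cc, d)
    for (f in names(o)) {
      expect_lt(abs(m[[f]] - o[[f]]) / max(abs(o[[f]]), 1e-300), 1e-10)
    }
  }
})

test_that("direction concordance and magnitude ordering hold", {
  set.seed(7)
  for (i in 1:2000) {
    cells <- sample(1:400, 4, replace = TRUE)
    m <- disprop_metrics(cells)
    expect_equal(sign(m$ror - 1), sign(m$prr - 1))
    expect_equal(sign(m$ror - 1), sign(m$ic))
    if (m$ror > 1) {
      expect_gte(m$ror, m$prr - 1e-12)
      expect_gte(m$prr, 1)
    }
    # transposing drug/event labels preserves the cross-product ratio
    mt <- disprop_metrics(cells[c(1, 3, 2, 4)])
    expect_equal(m$ror, mt$ror, tolerance = 1e-12)
  }
})

test_that("Fisher p matches hypergeometric enumeration on random tables", {
  set.seed(99)
  for (i in 1:200) {
    cells <- sample(0:30, 4, replace = TRUE)
    if (sum(cells) == 0) cells[1] <- 1
    m <- disprop_metrics(cells, haldane = TRUE)
    expect_equal(m$fisher_p, oracle_fisher(cells[1], cells[2], cells[3],
                                           cells[4]),
                 tolerance = 1e-12)
  }
})

test_that("zero cells flag undefined metrics unless Haldane correction on", {
  m <- disprop_metrics(c(0, 10, 5, 100))
  expect_true(m$undefined)
  expect_false(is.na(m$fisher_p))
  expect_true(m$fisher_p >= 0 && m$fisher_p <= 1)
  h <- disprop_metrics(c(0, 10, 5, 100), haldane = TRUE)
  expect_false(h$undefined)
  # +0.5 on every cell
  expect_equal(h$ror, (0.5 * 100.5) / (10.5 * 5.5), tolerance = 1e-12)
  # correction never fires on a complete table
  full <- disprop_metrics(c(2, 10, 5, 100), haldane = TRUE)
  expect_equal(full$ror, (2 * 100) / (10 * 5), tolerance = 1e-12)
})

test_that("signal thresholds reproduce the published daptomycin call", {
  # panel row with n = 758, PRR 13.17, chi2 8187.51, ROR LCL 13.90, IC025 3.38
  row <- data.frame(n_reports = 758, prr = 13.17, chi2 = 8187.51,
                    ror_lcl = 13.90, ic025 = 3.38)
  st <- evaluate_signal(row)
  expect_true(st$prr_positive && st$ror_positive && st$ic_positive &&
                st$positive)
  # count rule blocks the PRR method but the ROR rule can still fire
  tiny <- evaluate_signal(disprop_metrics(c(2, 3, 10, 10000)))
  expect_false(tiny$prr_positive)
  expect_true(tiny$ror_positive)
  expect_true(tiny$positive)
})

test_that("p-value adjustment follows the closed forms", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03), "bonferroni"),
               c(0.03, 0.06, 0.09))
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03), "BH"),
               c(0.03, 0.03, 0.03))
  expect_equal(adjust_pvalues(0.2, "bonferroni"), 0.2)
  expect_equal(adjust_pvalues(0.2, "BH"), 0.2)
  expect_error(adjust_pvalues(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("volcano export computes both coordinates and handles p = 0", {
  panel <- data.frame(drug = c("X", "Y"), ror = c(1, 15.03),
                      p_adj = c(1, 1e-10), n_reports = c(5L, 50L))
  v <- volcano_table(panel)
  expect_equal(v$x, c(0, log2(15.03)))
  expect_equal(v$y, c(0, 10))
  sw <- volcano_table(panel, layout = "swapped")
  expect_equal(sw$x, v$y)
  expect_equal(sw$y, v$x)
  z <- volcano_table(data.frame(drug = "Z", ror = 2, p_adj = 0,
                                n_reports = 3L))
  expect_true(is.finite(z$y))
  expect_identical(nrow(volcano_table(panel[0, ])), 0L)
})

test_that("two-source comparison flags corroboration and discordance", {
  sim <- simulate_reports(planted_config(20000, seed = 21))
  store <- dedup_reports(as_report_store(sim))
  cases <- extract_cases(store, smq_eosinophilic_pneumonia())
  pa <- signal_panel(cases, store, source = "FAERS-like")
  # identical inputs corroborate every positive
  cmp <- compare_sources(pa, pa)
  expect_equal(cmp$comparison$corroborated, cmp$comparison$positive_a)
  expect_length(cmp$discordant, 0L)
  # independent second source still corroborates the strongly planted drug
  sim2 <- simulate_reports(planted_config(20000, seed = 22))
  store2 <- dedup_reports(as_report_store(sim2))
  pb <- signal_panel(extract_cases(store2, smq_eosinophilic_pneumonia()),
                     store2, source = "second-source")
  cmp2 <- compare_sources(pa, pb)
  expect_true(cmp2$comparison$corroborated[cmp2$comparison$drug == "DRUG_A"])
  # a drug positive on one side only lands in the discordance list
  pb2 <- pb
  pb2$positive[pb2$drug == "DRUG_A"] <- FALSE
  expect_true("DRUG_A" %in% compare_sources(pa, pb2)$discordant)
})

test_that("PT composition shares are normalized within class", {
  cases <- structure(list(
    case_ids = c("1", "2", "3"),
    matched_terms = list(`1` = "pneumonitis", `2` = "pneumonitis",
                         `3` = c("eosinophilic pneumonia",
                                 "pulmonary eosinophilia")),
    suspect_drugs = list(`1` = "MAB_A", `2` = "MAB_A", `3` = "ABX_B")),
    class = "case_set")
  comp <- pt_composition(cases, c(MAB_A = "monoclonal antibody",
                                  ABX_B = "antibacterial"))
  mono <- comp[comp$class == "monoclonal antibody", ]
  expect_equal(mono$pt_name, "pneumonitis")
  expect_equal(mono$share, 1)  # class matched solely by pneumonitis
  abx <- comp[comp$class == "antibacterial", ]
  expect_equal(sort(abx$share), c(0.5, 0.5))
  shares <- tapply(comp$share, comp$class, sum)
  expect_true(all(abs(shares - 1) < 1e-12))
  # unmapped drug falls into "other"
  comp2 <- pt_composition(cases, c(MAB_A = "monoclonal antibody"))
  expect_true("other" %in% comp2$class)
})

test_that("absent drug yields a flagged all-zero exposure table", {
  sim <- simulate_reports(planted_config(1000, seed = 13))
  store <- dedup_reports(as_report_store(sim))
  cases <- extract_cases(store, smq_eosinophilic_pneumonia())
  ct <- contingency_table(cases, store, "NO_SUCH_DRUG")
  expect_equal(ct$a + ct$b, 0)
  expect_true(ct$flagged)
  expect_equal(ct$a + ct$b + ct$c + ct$d, n_reports(store))
})

test_that("null synthetic data keeps BH-adjusted positives rare", {
  n_seeds <- 20L
  ok <- 0L
  frac_any <- numeric(n_seeds)
  for (s in seq_len(n_seeds)) {
    cfg <- sim_config(
      30000,
      drugs = lapply(1:100, function(i)
        drug_spec(sprintf("N%03d", i), 0.005, 1)),
      background_event_rate = 0.02, seed = 3000 + s)
    store <- as_report_store(simulate_reports(cfg))
    cases <- extract_cases(store, smq_eosinophilic_pneumonia())
    panel <- signal_panel(cases, store,
                          drugs = sprintf("N%03d", 1:100))
    frac_any[s] <- mean(panel$positive)
    bh_pos <- mean(panel$p_fdr < 0.05)
    ok <- ok + (bh_pos <= 0.10)
  }
  # the raw any-of rule fires more often than the BH-controlled screen
  expect_lt(mean(frac_any), 0.25)
  expect_gte(ok, 18L)
})
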