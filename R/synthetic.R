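# Synthetic spontaneous-report generator with planted ground truth.
# Emulates the seven FAERS quarterly tables well enough that the full
# pipeline (parse -> dedup -> SMQ cases -> signals -> TTO -> regression)
# runs end-to-end with known answers.

BACKGROUND_PTS <- data.frame(
  pt_code = sprintf("9%07d", 1:40),
  pt_name = c("nausea", "headache", "rash", "diarrhoea", "fatigue", "pyrexia",
              "dizziness", "vomiting", "pruritus", "dyspnoea", "anaemia",
              "arthralgia", "insomnia", "constipation", "cough", "oedema",
              "hypertension", "myalgia", "alopecia", "dysgeusia",
              "neutropenia", "thrombocytopenia", "asthenia", "anorexia",
              "hyperglycaemia", "hypokalaemia", "tremor", "palpitations",
              "dry mouth", "back pain", "chills", "weight decreased",
              "abdominal pain", "somnolence", "epistaxis", "stomatitis",
              "urticaria", "flushing", "malaise", "paraesthesia"),
  stringsAsFactors = FALSE
)

# default mix of target PTs among synthetic cases; pneumonitis predominates,
# mirroring the composition seen in real spontaneous reports of this SMQ
TARGET_PT_WEIGHTS <- c(
  "pneumonitis" = 0.45,
  "eosinophilic pneumonia" = 0.20,
  "pulmonary eosinophilia" = 0.12,
  "eosinophilic pneumonia acute" = 0.06,
  "eosinophilic pneumonia chronic" = 0.04,
  "hypereosinophilic syndrome" = 0.05,
  "eosinophilic granulomatosis with polyangiitis" = 0.04,
  "loffler's syndrome" = 0.02,
  "eosinophilic pleural effusion" = 0.02
)

#' Specify a planted drug for the synthetic generator
#'
#' @param name drug name (uppercased).
#' @param prevalence probability a report lists this drug as primary suspect.
#' @param ep_odds_multiplier planted reporting odds ratio of the target event
#'   versus background exposure (1 = null).
#' @param tto_shape,tto_scale Weibull shape/scale (days) of the planted
#'   time-to-onset distribution for cases on this drug.
#' @return a `drug_spec` list.
#' @export
drug_spec <- function(name, prevalence, ep_odds_multiplier = 1,
                      tto_shape = 1, tto_scale = 60) {
  stopifnot(prevalence > 0, prevalence < 1, ep_odds_multiplier > 0,
            tto_shape > 0, tto_scale > 0)
  structure(list(name = toupper(name), prevalence = prevalence,
                 ep_odds_multiplier = ep_odds_multiplier,
                 tto_shape = tto_shape, tto_scale = tto_scale),
            class = "drug_spec")
}

#' Configuration for the synthetic report generator
#'
#' Defaults emulate the marginal structure of the real reporting stream:
#' demographic mixes and missingness follow the published characteristics
#' table of the full database, and date completeness is set so that roughly
#' 85 percent of cases lack the day-level dates needed for time-to-onset
#' work, as observed in practice.
#'
#' @param n_reports number of reports to draw.
#' @param drugs list of [drug_spec()] objects; their prevalences must sum to
#'   less than 1 (the remainder receives background drugs).
#' @param background_event_rate probability a background-exposed report
#'   carries the target event.
#' @param duplicate_rate fraction of reports cloned as same-case duplicates
#'   with a later receipt date (exercises deduplication).
#' @param missingness named list of per-field missing probabilities:
#'   `age`, `weight`, `sex`, `country`, `receipt_date`, `event_date`,
#'   `start_date`.
#' @param invalid_tto_rate fraction of dated cases whose event date is moved
#'   before the start date (exercises the exclusion audit).
#' @param covariate_log_or named numeric: planted log-odds effects of
#'   `age_years`, `weight_kg`, `n_drugs`, `sex_male` on the target event
#'   (default all zero).
#' @param n_background_drugs size of the background drug pool.
#' @param concomitant_lambda Poisson mean of concomitant drug rows per report.
#' @param window character vector of two dates bounding therapy start dates
#'   (uniform accrual).
#' @param seed default seed used by [simulate_reports()] when none is given.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_reports,
                       drugs = list(),
                       background_event_rate = 0.01,
                       duplicate_rate = 0,
                       missingness = list(),
                       invalid_tto_rate = 0.02,
                       covariate_log_or = c(age_years = 0, weight_kg = 0,
                                            n_drugs = 0, sex_male = 0),
                       n_background_drugs = 20,
                       concomitant_lambda = 1.5,
                       window = c("2014-01-01", "2025-03-31"),
                       seed = 1L) {
  stopifnot(n_reports > 0, background_event_rate > 0,
            background_event_rate < 1,
            duplicate_rate >= 0, duplicate_rate < 1)
  if (length(drugs) && !all(vapply(drugs, inherits, TRUE, "drug_spec")))
    stop("drugs must be a list of drug_spec objects")
  prev <- if (length(drugs)) sum(vapply(drugs, `[[`, 0, "prevalence")) else 0
  if (prev >= 1) stop("drug prevalences must sum to < 1")
  miss <- utils::modifyList(
    list(age = 0.376, weight = 0.764, sex = 0.152, country = 0,
         receipt_date = 0, event_date = 0.62, start_date = 0.60),
    missingness)
  co <- c(age_years = 0, weight_kg = 0, n_drugs = 0, sex_male = 0)
  co[names(covariate_log_or)] <- covariate_log_or
  structure(list(n_reports = as.integer(n_reports), drugs = drugs,
                 background_event_rate = background_event_rate,
                 duplicate_rate = duplicate_rate, missingness = miss,
                 invalid_tto_rate = invalid_tto_rate,
                 covariate_log_or = co,
                 n_background_drugs = as.integer(n_background_drugs),
                 concomitant_lambda = concomitant_lambda,
                 window = as.Date(window), seed = as.integer(seed)),
            class = "sim_config")
}

sample_band <- function(n, weights, lo, hi) {
  band <- sample.int(length(weights), n, replace = TRUE, prob = weights)
  lo[band] + stats::runif(n) * (hi[band] - lo[band])
}

#' Generate a synthetic spontaneous-report dataset
#'
#' Draws demographics, one primary-suspect drug per report, target-event
#' status with the planted odds multipliers, Weibull onset times, concomitant
#' drugs, outcomes, duplicates and missingness. Deterministic given the seed.
#'
#' For a report on drug \eqn{d} with covariates \eqn{x}, the target event is
#' Bernoulli with \eqn{logit(p) = logit(p_0) + \log m_d + \gamma'(x - x_c)}
#' where \eqn{p_0} is the background event rate, \eqn{m_d} the planted odds
#' multiplier and \eqn{x_c} a fixed centering point, so the report-level odds
#' of the event given drug versus background equal \eqn{m_d} when
#' \eqn{\gamma = 0}.
#'
#' @param config a [sim_config()].
#' @param seed integer; defaults to `config$seed`.
#' @return a `faers_sim`: list with `tables` (data.frames `demo`, `drug`,
#'   `reac`, `outc`, `ther`, `indi`, `rpsr` in the FAERS dialect), `truth`
#'   (planted per-drug parameters) and `config`.
#' @export
simulate_reports <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  n <- config$n_reports
  miss <- config$missingness

  # --- demographics ------------------------------------------------------
  sex <- sample(c("M", "F"), n, replace = TRUE, prob = c(0.42, 0.58))
  age <- sample_band(n, c(0.062, 0.137, 0.366, 0.261, 0.174),
                     lo = c(0, 18, 45, 65, 75), hi = c(18, 45, 65, 75, 95))
  weight <- exp(stats::rnorm(n, log(75), 0.25))
  country <- sample(c("US", "JP", "CA", "DE", "GB", "ES", "IT", "FR", "CN",
                      "AU", "BR", "IN"), n, replace = TRUE,
                    prob = c(0.413, 0.081, 0.084, 0.045, 0.046, 0.019, 0.035,
                             0.062, 0.033, 0.06, 0.06, 0.062))

  # --- exposure ----------------------------------------------------------
  specs <- config$drugs
  prev <- vapply(specs, `[[`, 0, "prevalence")
  drug_names <- vapply(specs, `[[`, "", "name")
  bg_names <- sprintf("BGDRUG%02d", seq_len(config$n_background_drugs))
  pick <- sample.int(length(specs) + 1L, n, replace = TRUE,
                     prob = c(prev, 1 - sum(prev)))
  is_bg <- pick > length(specs)
  ps_drug <- character(n)
  ps_drug[!is_bg] <- drug_names[pick[!is_bg]]
  ps_drug[is_bg] <- sample(bg_names, sum(is_bg), replace = TRUE)

  # --- target event ------------------------------------------------------
  mult <- rep(1, n)
  mult[!is_bg] <- vapply(specs, `[[`, 0, "ep_odds_multiplier")[pick[!is_bg]]
  gam <- config$covariate_log_or
  center <- c(age_years = 60, weight_kg = 75, n_drugs = 2, sex_male = 0.5)
  n_conc <- stats::rpois(n, config$concomitant_lambda)
  lin <- stats::qlogis(config$background_event_rate) + log(mult) +
    gam[["age_years"]] * (age - center[["age_years"]]) +
    gam[["weight_kg"]] * (weight - center[["weight_kg"]]) +
    gam[["n_drugs"]] * (1 + n_conc - center[["n_drugs"]]) +
    gam[["sex_male"]] * ((sex == "M") - center[["sex_male"]])
  is_case <- stats::runif(n) < stats::plogis(lin)

  # --- dates -------------------------------------------------------------
  span <- as.integer(config$window[2] - config$window[1])
  start_date <- config$window[1] + floor(stats::runif(n) * (span + 1))
  shp <- rep(1, n); scl <- rep(60, n)
  if (length(specs)) {
    shp[!is_bg] <- vapply(specs, `[[`, 0, "tto_shape")[pick[!is_bg]]
    scl[!is_bg] <- vapply(specs, `[[`, 0, "tto_scale")[pick[!is_bg]]
  }
  tto <- pmax(1, ceiling(stats::rweibull(n, shape = shp, scale = scl)))
  event_date <- start_date + tto
  flip <- is_case & stats::runif(n) < config$invalid_tto_rate
  event_date[flip] <- start_date[flip] - sample(1:30, sum(flip), TRUE)
  receipt_date <- event_date + stats::rpois(n, 40)

  # --- events ------------------------------------------------------------
  smq <- smq_eosinophilic_pneumonia()
  tw <- TARGET_PT_WEIGHTS[smq$pt_name]
  target_pt <- sample(smq$pt_name, n, replace = TRUE, prob = tw)
  bg_idx1 <- sample.int(nrow(BACKGROUND_PTS), n, replace = TRUE)
  bg_idx2 <- sample.int(nrow(BACKGROUND_PTS), n, replace = TRUE)
  extra_bg <- stats::runif(n) < 0.3

  # --- duplicates --------------------------------------------------------
  pid <- sprintf("%d", 100000000L + seq_len(n))
  caseid <- sprintf("%d", 50000000L + seq_len(n))
  n_dup <- floor(config$duplicate_rate * n)
  dup_src <- if (n_dup > 0) sample.int(n, n_dup) else integer(0)

  # --- missingness masks -------------------------------------------------
  mask <- function(p) stats::runif(n) < p
  age_m <- mask(miss$age); wt_m <- mask(miss$weight); sex_m <- mask(miss$sex)
  ev_m <- mask(miss$event_date); st_m <- mask(miss$start_date)
  rc_m <- mask(miss$receipt_date); co_m <- mask(miss$country)

  fmt_d <- function(d, m) ifelse(m | is.na(d), "", format(d, "%Y%m%d"))
  demo <- data.frame(
    primaryid = pid, caseid = caseid,
    fda_dt = fmt_d(receipt_date, rc_m),
    event_dt = fmt_d(event_date, ev_m),
    age = ifelse(age_m, "", sprintf("%d", as.integer(floor(age)))),
    age_cod = ifelse(age_m, "", "YR"),
    sex = ifelse(sex_m, "UNK", sex),
    wt = ifelse(wt_m, "", sprintf("%.1f", weight)),
    wt_cod = ifelse(wt_m, "", "KG"),
    occr_country = ifelse(co_m, "", country),
    stringsAsFactors = FALSE
  )

  # drug table: PS row + concomitant rows
  conc_pid <- rep(pid, n_conc)
  conc_name <- sample(bg_names, length(conc_pid), replace = TRUE)
  drug <- data.frame(
    primaryid = c(pid, conc_pid),
    drug_seq = c(rep("1", n),
                 unlist(lapply(n_conc[n_conc > 0], function(k) as.character(1 + seq_len(k))),
                        use.names = FALSE)),
    role_cod = c(rep("PS", n), rep("C", length(conc_pid))),
    drugname = c(ps_drug, conc_name),
    stringsAsFactors = FALSE
  )

  reac <- rbind(
    data.frame(primaryid = pid[is_case],
               pt_cod = smq$pt_code[match(target_pt[is_case], smq$pt_name)],
               pt = target_pt[is_case], stringsAsFactors = FALSE),
    data.frame(primaryid = pid[!is_case],
               pt_cod = BACKGROUND_PTS$pt_code[bg_idx1[!is_case]],
               pt = BACKGROUND_PTS$pt_name[bg_idx1[!is_case]],
               stringsAsFactors = FALSE),
    data.frame(primaryid = pid[extra_bg],
               pt_cod = BACKGROUND_PTS$pt_code[bg_idx2[extra_bg]],
               pt = BACKGROUND_PTS$pt_name[bg_idx2[extra_bg]],
               stringsAsFactors = FALSE)
  )

  has_outc <- stats::runif(n) < 0.6
  outc <- data.frame(
    primaryid = pid[has_outc],
    outc_cod = sample(c("HO", "OT", "DE", "LT", "DS", "DC", "RI"),
                      sum(has_outc), replace = TRUE,
                      prob = c(0.242, 0.349, 0.161, 0.040, 0.196, 0.011,
                               0.001)),
    stringsAsFactors = FALSE
  )

  ther <- data.frame(primaryid = pid, dsg_drug_seq = "1",
                     start_dt = fmt_d(start_date, st_m),
                     stringsAsFactors = FALSE)
  indi <- data.frame(primaryid = pid, indi_drug_seq = "1",
                     indi_pt = sample(c("infection", "neoplasm", "arrhythmia",
                                        "autoimmune disorder"), n, TRUE),
                     stringsAsFactors = FALSE)
  rpsr <- data.frame(primaryid = pid,
                     rpsr_cod = sample(c("FGN", "HP", "CSM"), n, TRUE,
                                       prob = c(0.3, 0.5, 0.2)),
                     stringsAsFactors = FALSE)

  if (n_dup > 0) {
    clone <- function(df, newid_of) {
      i <- which(df$primaryid %in% pid[dup_src])
      cl <- df[i, , drop = FALSE]
      cl$primaryid <- newid_of[cl$primaryid]
      cl
    }
    new_pid <- sprintf("%d", 100000000L + n + seq_len(n_dup))
    map <- stats::setNames(new_pid, pid[dup_src])
    dup_demo <- demo[dup_src, , drop = FALSE]
    dup_demo$primaryid <- new_pid
    later <- as.Date(ifelse(dup_demo$fda_dt == "", NA,
                            as.Date(dup_demo$fda_dt, "%Y%m%d")),
                     origin = "1970-01-01") + 30
    later[is.na(later)] <- config$window[2]
    dup_demo$fda_dt <- format(later, "%Y%m%d")
    demo <- rbind(demo, dup_demo)
    drug <- rbind(drug, clone(drug, map))
    reac <- rbind(reac, clone(reac, map))
    outc <- rbind(outc, clone(outc, map))
    ther <- rbind(ther, clone(ther, map))
    indi <- rbind(indi, clone(indi, map))
    rpsr <- rbind(rpsr, clone(rpsr, map))
  }

  truth <- data.frame(
    drug = drug_names %||% character(0),
    prevalence = prev,
    ep_odds_multiplier = vapply(specs, `[[`, 0, "ep_odds_multiplier"),
    tto_shape = vapply(specs, `[[`, 0, "tto_shape"),
    tto_scale = vapply(specs, `[[`, 0, "tto_scale"),
    stringsAsFactors = FALSE
  )

  structure(list(tables = list(demo = demo, drug = drug, reac = reac,
                               outc = outc, ther = ther, indi = indi,
                               rpsr = rpsr),
                 truth = truth, config = config, seed = seed),
            class = "faers_sim")
}

#' @export
print.faers_sim <- function(x, ...) {
  cat(sprintf("synthetic report set: %d reports (%d planted drugs, seed %d)\n",
              nrow(x$tables$demo), nrow(x$truth), x$seed))
  invisible(x)
}

#' Write synthetic tables in the FAERS ASCII dialect
#'
#' @param sim a `faers_sim` from [simulate_reports()].
#' @param dir output directory (created if absent).
#' @param sep field delimiter (default `"$"`).
#' @return named character vector of the written paths (plus `truth.csv`).
#' @export
write_faers_tables <- function(sim, dir, sep = "$") {
  stopifnot(inherits(sim, "faers_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (t in names(sim$tables)) {
    p <- file.path(dir, paste0(toupper(t), ".txt"))
    utils::write.table(sim$tables[[t]], p, sep = sep, quote = FALSE,
                       row.names = FALSE, na = "")
    paths[t] <- p
  }
  tp <- file.path(dir, "truth.csv")
  utils::write.csv(sim$truth, tp, row.names = FALSE)
  paths["truth"] <- tp
  invisible(paths)
}

#' Convert a synthetic dataset to a report store in memory
#'
#' Equivalent to writing the tables with [write_faers_tables()] and reading
#' them back with [parse_faers_tables()], without touching disk; the
#' round-trip equivalence is part of the test suite.
#'
#' @param sim a `faers_sim`.
#' @return a `report_store`.
#' @export
as_report_store <- function(sim) {
  stopifnot(inherits(sim, "faers_sim"))
  tb <- sim$tables
  n <- nrow(tb$demo)
  rd <- parse_faers_date(tb$demo$fda_dt)
  ed <- parse_faers_date(tb$demo$event_dt)
  demo <- data.frame(
    primaryid = tb$demo$primaryid, caseid = tb$demo$caseid,
    receipt_date = rd$date, event_date = ed$date, event_partial = ed$partial,
    sex = ifelse(tb$demo$sex == "M", "male",
          ifelse(tb$demo$sex == "F", "female", "unknown")),
    age_years = convert_age_years(tb$demo$age, tb$demo$age_cod),
    weight_kg = convert_weight_kg(tb$demo$wt, tb$demo$wt_cod),
    country = tb$demo$occr_country, report_year = rd$year,
    stringsAsFactors = FALSE
  )
  sd <- parse_faers_date(tb$ther$start_dt)
  key_th <- paste(tb$ther$primaryid, tb$ther$dsg_drug_seq, sep = "\r")
  start_map <- stats::setNames(sd$date, key_th)
  drug <- data.frame(
    primaryid = tb$drug$primaryid, drug_seq = tb$drug$drug_seq,
    drug_name = normalize_drug_name(tb$drug$drugname),
    role = unname(ROLE_MAP[tb$drug$role_cod]),
    stringsAsFactors = FALSE
  )
  drug$start_date <- as.Date(
    unname(start_map[paste(drug$primaryid, drug$drug_seq, sep = "\r")]),
    origin = "1970-01-01")
  reac <- data.frame(primaryid = tb$reac$primaryid, pt_code = tb$reac$pt_cod,
                     pt_name = tolower(tb$reac$pt), stringsAsFactors = FALSE)
  outc <- data.frame(primaryid = tb$outc$primaryid,
                     outcome = unname(OUTCOME_MAP[tb$outc$outc_cod]),
                     stringsAsFactors = FALSE)
  report_store(demo = demo, drug = drug, reac = reac, outc = outc,
               audit = list(rows_read = lapply(tb, nrow)))
}
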