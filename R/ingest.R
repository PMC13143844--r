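# FAERS-dialect ingestion: $-delimited quarterly ASCII tables -> normalized
# report store -> FDA-style deduplication -> SMQ case extraction.

ROLE_MAP <- c(PS = "primary-suspect", SS = "secondary-suspect",
              C = "concomitant", I = "interacting")

OUTCOME_MAP <- c(HO = "hospitalization", DE = "death", LT = "life-threatening",
                 DS = "disability", DC = "discontinued",
                 RI = "required-intervention", OT = "other",
                 CA = "other")

# canonical column -> accepted header aliases (case-insensitive)
COLUMN_ALIASES <- list(
  demo = list(primaryid = c("primaryid", "primary_id", "isr"),
              caseid = c("caseid", "case_id", "case"),
              fda_dt = c("fda_dt", "receipt_date"),
              event_dt = c("event_dt", "event_date"),
              age = "age", age_cod = "age_cod",
              sex = c("sex", "gndr_cod"),
              wt = c("wt", "weight"), wt_cod = c("wt_cod", "weight_cod"),
              country = c("occr_country", "reporter_country", "country")),
  drug = list(primaryid = c("primaryid", "primary_id", "isr"),
              drug_seq = c("drug_seq", "dsg_drug_seq"),
              role_cod = c("role_cod", "role"),
              drugname = c("drugname", "drug_name")),
  reac = list(primaryid = c("primaryid", "primary_id", "isr"),
              pt = c("pt", "pt_name"),
              pt_cod = c("pt_cod", "pt_code")),
  outc = list(primaryid = c("primaryid", "primary_id", "isr"),
              outc_cod = c("outc_cod", "outc_code", "outcome")),
  ther = list(primaryid = c("primaryid", "primary_id", "isr"),
              drug_seq = c("dsg_drug_seq", "drug_seq"),
              start_dt = c("start_dt", "start_date")),
  indi = list(primaryid = c("primaryid", "primary_id", "isr"),
              drug_seq = c("indi_drug_seq", "drug_seq"),
              indi_pt = "indi_pt"),
  rpsr = list(primaryid = c("primaryid", "primary_id", "isr"),
              rpsr_cod = c("rpsr_cod", "rpsr_code"))
)

# default salt/ester suffixes stripped during drug-name normalization
DEFAULT_SALT_SUFFIXES <- c(
  "SODIUM", "HYDROCHLORIDE", "HCL", "SULFATE", "SULPHATE", "MESYLATE",
  "TARTRATE", "CITRATE", "PHOSPHATE", "ACETATE", "MALEATE", "BESYLATE",
  "FUMARATE", "SUCCINATE", "CALCIUM", "POTASSIUM"
)

#' Normalize free-text drug names
#'
#' Uppercases, trims, collapses internal whitespace and strips trailing salt
#' suffixes (editable via `salts`). Spontaneous-report drug names are
#' free text, so active-ingredient strings must be canonicalized before any
#' per-drug counting.
#'
#' @param x character vector of drug names.
#' @param salts character vector of suffix words to strip.
#' @return normalized character vector.
#' @export
#' @examples
#' normalize_drug_name("  daptomycin sodium ") # "DAPTOMYCIN"
normalize_drug_name <- function(x, salts = DEFAULT_SALT_SUFFIXES) {
  x <- toupper(trimws(as.character(x)))
  x <- gsub("[[:space:]]+", " ", x)
  pat <- paste0(" (", paste(salts, collapse = "|"), ")$")
  repeat {
    y <- sub(pat, "", x)
    if (identical(y, x)) break
    x <- y
  }
  x
}

read_dialect_file <- function(path, sep = "$", quote = "") {
  utils::read.table(path, header = TRUE, sep = sep, quote = quote,
                    comment.char = "", stringsAsFactors = FALSE,
                    colClasses = "character", fill = TRUE,
                    strip.white = TRUE, na.strings = character(0))
}

resolve_columns <- function(df, table) {
  aliases <- COLUMN_ALIASES[[table]]
  nm <- tolower(names(df))
  out <- list()
  unknown <- setdiff(nm, tolower(unlist(aliases)))
  if (length(unknown))
    warning(sprintf("table %s: ignoring unknown column(s): %s",
                    table, paste(unknown, collapse = ", ")), call. = FALSE)
  for (canon in names(aliases)) {
    hit <- which(nm %in% tolower(aliases[[canon]]))
    out[[canon]] <- if (length(hit)) df[[hit[1]]] else NULL
  }
  out
}

convert_age_years <- function(age, age_cod) {
  a <- suppressWarnings(as.numeric(age))
  cod <- toupper(trimws(ifelse(is.na(age_cod) | age_cod == "", "YR", age_cod)))
  f <- c(YR = 1, DEC = 10, MON = 1 / 12, WK = 1 / 52.1775, DY = 1 / 365.25,
         HR = 1 / 8766)
  mult <- unname(f[cod])
  mult[is.na(mult)] <- 1
  out <- a * mult
  out[!is.na(out) & out < 0] <- NA
  out
}

convert_weight_kg <- function(wt, wt_cod) {
  w <- suppressWarnings(as.numeric(wt))
  cod <- toupper(trimws(ifelse(is.na(wt_cod) | wt_cod == "", "KG", wt_cod)))
  w[cod %in% c("LBS", "LB")] <- w[cod %in% c("LBS", "LB")] * LB_TO_KG
  w[!is.na(w) & w <= 0] <- NA
  w
}

#' Parse FAERS-dialect ASCII tables into a report store
#'
#' Reads the quarterly `$`-delimited tables (DEMO, DRUG, REAC mandatory;
#' OUTC, THER, INDI, RPSR optional), joins them by report id, and returns a
#' normalized `report_store`. One record is produced per DEMO row.
#' Unparseable dates and non-numeric ages/weights become missing and are
#' counted in the parse audit; they never fail the row. THER start dates are
#' joined onto drug rows by (report id, drug sequence).
#'
#' @param paths named list/vector of file paths; names among
#'   `demo, drug, reac, outc, ther, indi, rpsr`. `demo`, `drug` and `reac`
#'   are mandatory.
#' @param sep field delimiter (default `"$"`, the FAERS dialect).
#' @param quote quote character (default none).
#' @param salts salt-suffix table passed to [normalize_drug_name()].
#' @return a `report_store`: list with data.frames `demo`, `drug`, `reac`,
#'   `outc` and an `audit` list (rows read, rows dropped, fields nulled).
#' @export
parse_faers_tables <- function(paths, sep = "$", quote = "",
                               salts = DEFAULT_SALT_SUFFIXES) {
  paths <- as.list(paths)
  for (t in c("demo", "drug", "reac"))
    if (is.null(paths[[t]]))
      stop(sprintf("mandatory table '%s' not supplied", t))
  for (t in names(paths))
    if (!file.exists(paths[[t]]))
      stop(sprintf("table '%s': file not found: %s", t, paths[[t]]))

  audit <- list(rows_read = list(), rows_dropped = list(), fields_nulled = list())

  raw <- lapply(paths, read_dialect_file, sep = sep, quote = quote)
  for (t in names(raw)) audit$rows_read[[t]] <- nrow(raw[[t]])

  d <- resolve_columns(raw$demo, "demo")
  if (is.null(d$primaryid)) stop("DEMO table lacks a primary id column")
  n <- length(d$primaryid)
  rd <- parse_faers_date(d$fda_dt %||% rep(NA, n))
  ed <- parse_faers_date(d$event_dt %||% rep(NA, n))
  sex_raw <- toupper(trimws(d$sex %||% rep("", n)))
  sex <- ifelse(sex_raw %in% c("M", "MALE"), "male",
         ifelse(sex_raw %in% c("F", "FEMALE"), "female", "unknown"))
  age <- convert_age_years(d$age %||% rep(NA, n), d$age_cod %||% rep(NA, n))
  wt <- convert_weight_kg(d$wt %||% rep(NA, n), d$wt_cod %||% rep(NA, n))
  demo <- data.frame(
    primaryid = as.character(d$primaryid),
    caseid = as.character(d$caseid %||% d$primaryid),
    receipt_date = rd$date,
    event_date = ed$date,
    event_partial = ed$partial,
    sex = sex,
    age_years = age,
    weight_kg = wt,
    country = trimws(d$country %||% rep(NA_character_, n)),
    report_year = rd$year,
    stringsAsFactors = FALSE
  )
  dup_pid <- duplicated(demo$primaryid)
  if (any(dup_pid)) {
    audit$rows_dropped$demo_duplicate_primaryid <- sum(dup_pid)
    demo <- demo[!dup_pid, , drop = FALSE]
  }
  audit$fields_nulled$age <- sum(is.na(demo$age_years))
  audit$fields_nulled$weight <- sum(is.na(demo$weight_kg))
  audit$fields_nulled$receipt_date <- sum(is.na(demo$receipt_date))
  audit$fields_nulled$event_date <- sum(is.na(demo$event_date))

  ids <- demo$primaryid

  g <- resolve_columns(raw$drug, "drug")
  drug <- data.frame(
    primaryid = as.character(g$primaryid),
    drug_seq = as.character(g$drug_seq %||% seq_along(g$primaryid)),
    drug_name = normalize_drug_name(g$drugname, salts),
    role = unname(ROLE_MAP[toupper(trimws(g$role_cod %||% ""))]),
    stringsAsFactors = FALSE
  )
  drug$role[is.na(drug$role)] <- "concomitant"
  keep <- drug$primaryid %in% ids & !is.na(drug$drug_name) & drug$drug_name != ""
  audit$rows_dropped$drug_orphan <- sum(!keep)
  drug <- drug[keep, , drop = FALSE]

  if (!is.null(paths$ther)) {
    th <- resolve_columns(raw$ther, "ther")
    sd <- parse_faers_date(th$start_dt)
    key_th <- paste(th$primaryid, th$drug_seq, sep = "\r")
    first <- !duplicated(key_th)
    start_map <- sd$date[first]
    names(start_map) <- key_th[first]
    drug$start_date <- as.Date(
      unname(start_map[paste(drug$primaryid, drug$drug_seq, sep = "\r")]),
      origin = "1970-01-01")
  } else {
    drug$start_date <- as.Date(rep(NA, nrow(drug)))
  }

  r <- resolve_columns(raw$reac, "reac")
  reac <- data.frame(
    primaryid = as.character(r$primaryid),
    pt_code = trimws(as.character(r$pt_cod %||% rep(NA_character_,
                                                    length(r$primaryid)))),
    pt_name = tolower(trimws(as.character(r$pt %||% rep(NA_character_,
                                                        length(r$primaryid))))),
    stringsAsFactors = FALSE
  )
  keep <- reac$primaryid %in% ids
  audit$rows_dropped$reac_orphan <- sum(!keep)
  reac <- reac[keep, , drop = FALSE]

  if (!is.null(paths$outc)) {
    o <- resolve_columns(raw$outc, "outc")
    oc <- toupper(trimws(o$outc_cod))
    outc <- data.frame(primaryid = as.character(o$primaryid),
                       outcome = unname(ifelse(oc %in% names(OUTCOME_MAP),
                                               OUTCOME_MAP[oc], "other")),
                       stringsAsFactors = FALSE)
    outc <- outc[outc$primaryid %in% ids, , drop = FALSE]
  } else {
    outc <- data.frame(primaryid = character(0), outcome = character(0),
                       stringsAsFactors = FALSE)
  }

  report_store(demo = demo, drug = drug, reac = reac, outc = outc,
               audit = audit)
}

#' Construct a report store
#'
#' Low-level constructor validating the normalized safety-report container
#' produced by [parse_faers_tables()] or [simulate_reports()].
#'
#' @param demo,drug,reac,outc component data.frames (see
#'   [parse_faers_tables()] for their columns).
#' @param audit list of parse/dedup bookkeeping.
#' @return object of class `report_store`.
#' @export
report_store <- function(demo, drug, reac, outc = NULL, audit = list()) {
  stopifnot(is.data.frame(demo), is.data.frame(drug), is.data.frame(reac))
  if (anyDuplicated(demo$primaryid)) stop("report ids must be unique")
  if (is.null(outc))
    outc <- data.frame(primaryid = character(0), outcome = character(0))
  structure(list(demo = demo, drug = drug, reac = reac, outc = outc,
                 audit = audit),
            class = "report_store")
}

#' @export
print.report_store <- function(x, ...) {
  cat(sprintf(
    "FAERS-style report store: %d reports, %d drug rows, %d event rows\n",
    nrow(x$demo), nrow(x$drug), nrow(x$reac)))
  invisible(x)
}

#' Number of reports in a store
#' @param store a `report_store`.
#' @return integer count of reports.
#' @export
n_reports <- function(store) nrow(store$demo)

# numeric ordering key for report ids ("largest Primary ID" tiebreaks);
# falls back to lexicographic rank when ids are not numeric
id_rank <- function(ids) {
  num <- suppressWarnings(as.numeric(ids))
  if (!anyNA(num)) num else as.numeric(factor(ids, levels = sort(unique(ids))))
}

subset_store <- function(store, keep_ids) {
  report_store(
    demo = store$demo[store$demo$primaryid %in% keep_ids, , drop = FALSE],
    drug = store$drug[store$drug$primaryid %in% keep_ids, , drop = FALSE],
    reac = store$reac[store$reac$primaryid %in% keep_ids, , drop = FALSE],
    outc = store$outc[store$outc$primaryid %in% keep_ids, , drop = FALSE],
    audit = store$audit
  )
}

# sorted unique sets per report, collapsed to a single key string
collapse_sets <- function(df, id_col, val_col, ids) {
  sp <- split(df[[val_col]], factor(df[[id_col]], levels = ids))
  vapply(sp, function(v) paste(sort(unique(v)), collapse = "|"), character(1))
}

#' Deduplicate a report store with the FDA case-id rules
#'
#' Two passes. First, records sharing a case id are merged by keeping the one
#' with the most recent FDA receipt date; ties are broken by the largest
#' report id, and records with a missing receipt date are treated as older
#' than any dated record. Second, among survivors, records identical on
#' (age in years, sex, event date, sorted PT set, sorted primary-suspect drug
#' set) are collapsed to the largest report id — this emulates the manual
#' secondary pass and only applies to records whose age, sex and event date
#' are all present.
#'
#' @param store a `report_store`.
#' @param demographic_pass logical; run the secondary demographic-key pass
#'   (default TRUE).
#' @return deduplicated `report_store`; `$audit$dedup` holds kept/removed
#'   counts per rule.
#' @export
dedup_reports <- function(store, demographic_pass = TRUE) {
  demo <- store$demo
  if (nrow(demo) == 0L) {
    store$audit$dedup <- list(n_in = 0L, removed_caseid = 0L,
                              removed_demographic = 0L, n_out = 0L)
    return(store)
  }
  rk <- id_rank(demo$primaryid)
  date_key <- as.numeric(demo$receipt_date)
  date_key[is.na(date_key)] <- -Inf  # missing receipt dates lose
  ord <- order(demo$caseid, date_key, rk)  # last within case wins
  last <- !duplicated(demo$caseid[ord], fromLast = TRUE)
  keep1 <- demo$primaryid[ord][last]
  removed_caseid <- nrow(demo) - length(keep1)

  removed_demo <- 0L
  keep2 <- keep1
  if (demographic_pass && length(keep1) > 1L) {
    d2 <- demo[match(keep1, demo$primaryid), , drop = FALSE]
    complete <- !is.na(d2$age_years) & d2$sex %in% c("male", "female") &
      !is.na(d2$event_date)
    key <- paste(d2$age_years, d2$sex, as.numeric(d2$event_date), sep = "\r")
    key[!complete] <- paste0("UNIQ\r", seq_along(key)[!complete])
    # the expensive PT/drug set keys are only needed inside collision groups
    coll <- key %in% key[duplicated(key)]
    if (any(coll)) {
      cids <- d2$primaryid[coll]
      ps <- store$drug[store$drug$role == "primary-suspect" &
                         store$drug$primaryid %in% cids, , drop = FALSE]
      pt_key <- collapse_sets(store$reac[store$reac$primaryid %in% cids, ,
                                         drop = FALSE],
                              "primaryid", "pt_name", cids)
      ps_key <- collapse_sets(ps, "primaryid", "drug_name", cids)
      key[coll] <- paste(key[coll], pt_key[cids], ps_key[cids], sep = "\r")
    }
    ord2 <- order(key, id_rank(d2$primaryid))
    last2 <- !duplicated(key[ord2], fromLast = TRUE)
    keep2 <- d2$primaryid[ord2][last2]
    removed_demo <- length(keep1) - length(keep2)
  }

  out <- subset_store(store, keep2)
  out$audit$dedup <- list(n_in = nrow(demo),
                          removed_caseid = removed_caseid,
                          removed_demographic = removed_demo,
                          n_out = length(keep2))
  out
}

#' Extract eosinophilic-pneumonia cases via an SMQ term set
#'
#' A report is a case iff at least one of its events belongs to the SMQ term
#' set (matched by PT code when the store carries codes, otherwise by
#' case-insensitive exact name) AND at least one of its drugs has the
#' primary-suspect role.
#'
#' @param store a deduplicated `report_store`.
#' @param smq an `smq_term_set`.
#' @return object of class `case_set`: list with `case_ids`,
#'   `matched_terms` (report id -> matched PT names) and `suspect_drugs`
#'   (report id -> primary-suspect drug names).
#' @export
extract_cases <- function(store, smq) {
  if (!inherits(smq, "smq_term_set") || nrow(smq) == 0L)
    stop("empty or invalid SMQ term set")
  reac <- store$reac
  has_code <- !is.na(reac$pt_code) & reac$pt_code != ""
  hit <- (has_code & reac$pt_code %in% smq$pt_code) |
    (!has_code & reac$pt_name %in% smq$pt_name)
  # rows matched by code still report the canonical term name
  name_of <- smq$pt_name[match(reac$pt_code, smq$pt_code)]
  matched_name <- ifelse(has_code & hit, name_of, reac$pt_name)

  ps <- store$drug[store$drug$role == "primary-suspect", , drop = FALSE]
  ids <- intersect(unique(reac$primaryid[hit]), unique(ps$primaryid))
  ids <- store$demo$primaryid[store$demo$primaryid %in% ids]  # store order

  mt <- split(matched_name[hit & reac$primaryid %in% ids],
              factor(reac$primaryid[hit & reac$primaryid %in% ids],
                     levels = ids))
  sd <- split(ps$drug_name[ps$primaryid %in% ids],
              factor(ps$primaryid[ps$primaryid %in% ids], levels = ids))
  structure(list(case_ids = ids,
                 matched_terms = lapply(mt, function(v) sort(unique(v))),
                 suspect_drugs = lapply(sd, function(v) sort(unique(v)))),
            class = "case_set")
}

#' @export
print.case_set <- function(x, ...) {
  cat(sprintf("SMQ case set: %d case reports, %d distinct suspect drugs\n",
              length(x$case_ids),
              length(unique(unlist(x$suspect_drugs)))))
  invisible(x)
}

default_binning <- function() {
  list(
    weight = data.frame(label = c("<50 kg", "50-70 kg", "70-90 kg",
                                  "90-110 kg", ">110 kg"),
                        lo = c(-Inf, 50, 70, 90, 110),
                        hi = c(50, 70, 90, 110, Inf)),
    age = data.frame(label = c("<18", "18-44", "45-64", "65-74", ">75"),
                     lo = c(-Inf, 18, 45, 65, 75),
                     hi = c(18, 45, 65, 75, Inf)),
    year = data.frame(label = c("2014-2020", "2021", "2022", "2023", "2024",
                                "2025"),
                      lo = c(2014, 2021, 2022, 2023, 2024, 2025),
                      hi = c(2021, 2022, 2023, 2024, 2025, 2026)),
    countries = c("US", "JP", "CA", "DE", "GB", "ES", "IT", "FR", "CN")
  )
}

check_bins <- function(b, what) {
  if (any(b$hi <= b$lo)) stop(sprintf("invalid %s bins", what))
  o <- order(b$lo)
  if (any(b$hi[o][-nrow(b)] > b$lo[o][-1]))
    stop(sprintf("overlapping %s bins", what))
  b
}

bin_label <- function(x, bins) {
  out <- rep("Unknown", length(x))
  for (i in seq_len(nrow(bins))) {
    inb <- !is.na(x) & x >= bins$lo[i] & x < bins$hi[i]
    out[inb] <- bins$label[i]
  }
  out
}

#' Demographic summary of a case subset against the full store
#'
#' Tabulates sex, weight band, age band, reporting-year band, country and
#' serious-outcome categories for the case subset and the full store, with
#' counts and percentages (denominator = subset size; rounded half-up to one
#' decimal, the convention of published characteristics tables).
#'
#' @param cases a `case_set` (or character vector of report ids).
#' @param store the `report_store` the cases came from.
#' @param binning list with elements `weight`, `age`, `year` (data.frames
#'   `label, lo, hi`; intervals are left-closed `[lo, hi)`) and `countries`
#'   (codes reported individually; the rest pool into "Other"). Defaults to
#'   the published bands. Overlapping bins raise an error.
#' @return data.frame with columns `characteristic`, `category`, `n_cases`,
#'   `pct_cases`, `n_all`, `pct_all`.
#' @export
demographic_summary <- function(cases, store, binning = default_binning()) {
  for (w in c("weight", "age", "year")) check_bins(binning[[w]], w)
  ids <- if (inherits(cases, "case_set")) cases$case_ids else as.character(cases)
  demo <- store$demo
  in_case <- demo$primaryid %in% ids
  n_case <- sum(in_case)
  n_all <- nrow(demo)

  one <- function(characteristic, cat_case, cat_all, levels) {
    data.frame(
      characteristic = characteristic,
      category = levels,
      n_cases = as.integer(table(factor(cat_case, levels = levels))),
      pct_cases = pct_of(as.integer(table(factor(cat_case, levels = levels))),
                         n_case),
      n_all = as.integer(table(factor(cat_all, levels = levels))),
      pct_all = pct_of(as.integer(table(factor(cat_all, levels = levels))),
                       n_all),
      stringsAsFactors = FALSE
    )
  }

  sex_lv <- c("male", "female", "unknown")
  wt_b <- bin_label(demo$weight_kg, binning$weight)
  ag_b <- bin_label(demo$age_years, binning$age)
  yr_b <- bin_label(demo$report_year, binning$year)
  co <- ifelse(is.na(demo$country) | demo$country == "", "Unknown",
        ifelse(demo$country %in% binning$countries, demo$country, "Other"))

  out <- rbind(
    one("sex", demo$sex[in_case], demo$sex, sex_lv),
    one("weight", wt_b[in_case], wt_b, c(binning$weight$label, "Unknown")),
    one("age", ag_b[in_case], ag_b, c(binning$age$label, "Unknown")),
    one("report_year", yr_b[in_case], yr_b, c(binning$year$label, "Unknown")),
    one("country", co[in_case], co,
        c(binning$countries, "Other", "Unknown"))
  )

  if (nrow(store$outc)) {
    oc <- store$outc[!duplicated(paste(store$outc$primaryid,
                                       store$outc$outcome)), , drop = FALSE]
    lv <- unname(unique(OUTCOME_MAP))
    out <- rbind(out, one("outcome", oc$outcome[oc$primaryid %in% ids],
                          oc$outcome, lv))
  }
  rownames(out) <- NULL
  out
}

#' Serialize a report store to CSV plus a JSON audit
#'
#' @param store a `report_store`.
#' @param dir output directory (created if absent).
#' @return invisibly, the written file paths.
#' @export
write_report_store <- function(store, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(demo = file.path(dir, "demo.csv"),
             drug = file.path(dir, "drug.csv"),
             reac = file.path(dir, "reac.csv"),
             outc = file.path(dir, "outc.csv"),
             audit = file.path(dir, "audit.json"))
  for (t in c("demo", "drug", "reac", "outc"))
    utils::write.csv(store[[t]], paths[[t]], row.names = FALSE)
  jsonlite::write_json(store$audit, paths[["audit"]], auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(paths)
}
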