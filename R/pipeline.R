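# End-to-end orchestration: input (parsed FAERS-dialect tables or the
# synthetic generator) -> dedup -> SMQ cases -> signal panel -> TTO ->
# univariate screen -> LASSO -> logistic, with one seed, CSV artifacts and
# a JSON manifest.

#' Assemble a pipeline run configuration
#'
#' @param input either a [sim_config()] (synthetic mode) or a named
#'   list/vector of FAERS-dialect table paths as taken by
#'   [parse_faers_tables()].
#' @param smq SMQ term set (default: the eosinophilic-pneumonia set).
#' @param criteria signal positivity criteria.
#' @param screen_p,screen_min_n univariate screen thresholds.
#' @param lasso_p,lasso_min_n stricter LASSO-entry thresholds (the
#'   conventional cascade screens at p < 0.05 then enters LASSO at p < 0.01
#'   with more than three reports).
#' @param covariates covariates for the regression stages.
#' @param folds CV folds for the LASSO stage.
#' @param seed global seed, fanned out to per-stage seeds via
#'   [derive_seed()].
#' @param out_dir artifact directory.
#' @return a `run_config` list.
#' @export
run_config <- function(input, smq = smq_eosinophilic_pneumonia(),
                       criteria = signal_criteria(),
                       screen_p = 0.05, screen_min_n = 3,
                       lasso_p = 0.01, lasso_min_n = 4,
                       covariates = c("age_years", "sex", "weight_kg",
                                      "n_drugs"),
                       folds = 10, seed = 1, out_dir = tempfile("pvep_run_")) {
  mode <- if (inherits(input, "sim_config")) "synthetic" else "faers"
  structure(list(mode = mode, input = input, smq = smq, criteria = criteria,
                 screen_p = screen_p, screen_min_n = screen_min_n,
                 lasso_p = lasso_p, lasso_min_n = lasso_min_n,
                 covariates = covariates, folds = folds,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Expects top-level keys `input` (either `sim:` with [sim_config()] fields,
#' including an optional `drugs:` list of [drug_spec()] fields, or `paths:`
#' with table paths), and optionally `seed`, `folds`, `screen_p`,
#' `screen_min_n`, `lasso_p`, `lasso_min_n`, `out_dir`.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$input$sim)) {
    s <- y$input$sim
    drugs <- lapply(s$drugs, function(d) do.call(drug_spec, d))
    s$drugs <- drugs
    input <- do.call(sim_config, s)
  } else if (!is.null(y$input$paths)) {
    input <- y$input$paths
  } else stop("config must provide input$sim or input$paths")
  args <- y[setdiff(names(y), "input")]
  do.call(run_config, c(list(input = input), args))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full pharmacovigilance pipeline
#'
#' Executes every stage in order, writes the tabular artifacts
#' (`signal_metrics.csv`, `volcano.csv`, `tto_records.csv`,
#' `weibull_fits.csv`, `candidates.csv`, `logistic_terms.csv`,
#' `forest.csv`, `exclusion_audit.json`) plus a JSON `manifest.json` with a
#' config hash, per-stage row counts and md5 checksums of every artifact.
#' Identical config and seed reproduce identical checksums.
#'
#' @param config a [run_config()] (or a YAML path, routed through
#'   [read_run_config()]).
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()

  store <- stage("input", {
    if (config$mode == "synthetic") {
      sim <- simulate_reports(config$input,
                              seed = derive_seed(config$seed, "simulate"))
      as_report_store(sim)
    } else {
      parse_faers_tables(config$input)
    }
  })
  counts$reports_in <- n_reports(store)

  store <- stage("dedup", dedup_reports(store))
  counts$reports_after_dedup <- n_reports(store)

  cases <- stage("cases", extract_cases(store, config$smq))
  counts$cases <- length(cases$case_ids)

  panel <- stage("signals",
                 signal_panel(cases, store, criteria = config$criteria))
  counts$drugs_evaluated <- nrow(panel)
  counts$drugs_signal_positive <- sum(panel$positive)

  tto <- stage("tto", compute_tto(cases, store))
  wtab <- stage("tto", tto_weibull_table(tto$records))
  counts$tto_retained <- tto$audit$n_retained

  screen <- stage("screen", screen_candidates(
    panel, min_n = config$screen_min_n, p_adj_max = config$screen_p))
  entry <- stage("screen", screen_candidates(
    panel, min_n = config$lasso_min_n, p_adj_max = config$lasso_p))
  candidates <- entry$drug[entry$pass]
  counts$candidates_univariate <- sum(screen$pass)
  counts$candidates_lasso_entry <- length(candidates)

  lasso <- NULL; terms <- NULL; forest <- NULL
  if (length(candidates) >= 1L) {
    mm <- stage("riskmodel", build_model_matrix(
      store, cases, candidates, covariates = config$covariates))
    if (ncol(mm$x) >= 2L && length(unique(mm$y)) == 2L) {
      lasso <- stage("riskmodel", lasso_select(
        mm, nfolds = config$folds,
        seed = derive_seed(config$seed, "lasso")))
      if (length(lasso$selected)) {
        terms <- stage("riskmodel", fit_logistic(mm, lasso$selected))
        forest <- forest_table(terms)
      }
    }
  }
  counts$selected_by_lasso <- length(lasso$selected %||% character(0))
  counts$final_terms <- if (is.null(terms)) 0L else nrow(terms)

  # ---- artifacts --------------------------------------------------------
  paths <- c()
  wr <- function(obj, file) {
    p <- file.path(config$out_dir, file)
    utils::write.csv(obj, p, row.names = FALSE)
    p
  }
  paths["signal_metrics"] <- wr(as.data.frame(panel), "signal_metrics.csv")
  paths["volcano"] <- wr(volcano_table(panel, p_col = "p_fdr"), "volcano.csv")
  paths["tto_records"] <- wr(tto$records, "tto_records.csv")
  if (!is.null(wtab)) paths["weibull_fits"] <- wr(wtab, "weibull_fits.csv")
  paths["candidates"] <- wr(entry, "candidates.csv")
  if (!is.null(terms))
    paths["logistic_terms"] <- wr(as.data.frame(terms), "logistic_terms.csv")
  if (!is.null(forest)) paths["forest"] <- wr(forest, "forest.csv")
  pa <- file.path(config$out_dir, "exclusion_audit.json")
  jsonlite::write_json(unclass(tto$audit), pa, auto_unbox = TRUE)
  paths["exclusion_audit"] <- pa

  cfg_file <- tempfile()
  writeLines(deparse(config[setdiff(names(config), "out_dir")]), cfg_file)
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_file)),
    seed = config$seed,
    counts = counts,
    checksums = as.list(tools::md5sum(unname(paths)))
  )
  unlink(cfg_file)
  names(manifest$checksums) <- names(paths)
  mp <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE)

  invisible(list(store = store, cases = cases, panel = panel, tto = tto,
                 weibull = wtab, screen = screen, candidates = candidates,
                 lasso = lasso, terms = terms, forest = forest,
                 manifest = manifest, out_dir = config$out_dir))
}
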