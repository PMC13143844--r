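# Shared fixtures built in code.

# write a tiny hand-rolled FAERS-dialect quarter and return the paths
write_toy_quarter <- function(dir = tempfile("toy_")) {
  dir.create(dir)
  w <- function(file, lines) {
    writeLines(lines, file.path(dir, file))
    file.path(dir, file)
  }
  list(
    demo = w("DEMO.txt", c(
      "primaryid$caseid$fda_dt$event_dt$age$age_cod$sex$wt$wt_cod$occr_country",
      "101$9001$20240110$20240120$63$YR$M$80$KG$US",
      "102$9002$20240215$$UNK$$F$150$LBS$JP",
      "103$9003$20240301$20240228$45$YR$F$$$DE")),
    drug = w("DRUG.txt", c(
      "primaryid$drug_seq$role_cod$drugname",
      "101$1$PS$Daptomycin Sodium",
      "101$2$C$BGDRUG01",
      "102$1$PS$AMIODARONE",
      "103$1$C$BGDRUG02")),
    reac = w("REAC.txt", c(
      "primaryid$pt_cod$pt",
      "101$10014962$Eosinophilic pneumonia",
      "102$90000001$nausea",
      "103$10035742$Pneumonitis")),
    ther = w("THER.txt", c(
      "primaryid$dsg_drug_seq$start_dt",
      "101$1$20240101",
      "102$1$20240201",
      "103$1$20240210")),
    outc = w("OUTC.txt", c(
      "primaryid$outc_cod",
      "101$HO",
      "103$DE"))
  )
}

# small planted-signal scenario reused across modules
planted_config <- function(n = 20000, dup = 0, seed = 1, ...) {
  sim_config(
    n,
    drugs = list(
      drug_spec("DRUG_A", 0.01, 12, tto_shape = 0.8, tto_scale = 40),
      drug_spec("DRUG_B", 0.01, 5, tto_shape = 1.3, tto_scale = 90),
      drug_spec("DRUG_C", 0.01, 3)
    ),
    background_event_rate = 0.01,
    duplicate_rate = dup,
    seed = seed,
    ...
  )
}

# independent brute-force 2x2 tabulation straight from the raw dialect
# tables (set algebra; never touches contingency_table/extract_cases)
brute_force_2x2 <- function(sim, drug) {
  smq <- smq_eosinophilic_pneumonia()
  tb <- sim$tables
  case_ids <- unique(tb$reac$primaryid[tb$reac$pt_cod %in% smq$pt_code])
  ps <- tb$drug[tb$drug$role_cod == "PS", ]
  case_ids <- intersect(case_ids, unique(ps$primaryid))
  exposed <- unique(ps$primaryid[toupper(ps$drugname) == drug])
  all_ids <- tb$demo$primaryid
  a <- length(intersect(case_ids, exposed))
  b <- length(setdiff(exposed, case_ids))
  c <- length(setdiff(case_ids, exposed))
  d <- length(all_ids) - a - b - c
  c(a = a, b = b, c = c, d = d)
}
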