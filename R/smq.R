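#' Eosinophilic-pneumonia SMQ term set
#'
#' Builds the Standardized MedDRA Query term set used as the case definition.
#' The default ships the nine published Preferred Terms of SMQ 20000159
#' ("Eosinophilic pneumonia"); the full SMQ holds further licensed terms, so
#' the table is user-extendable via `extra_terms`.
#'
#' @param extra_terms optional data.frame with columns `pt_code`, `pt_name`
#'   appended to the default table.
#' @return object of class `smq_term_set`: a data.frame with columns
#'   `pt_code` (character) and `pt_name` (lower-case character), plus an
#'   `smq_id` attribute.
#' @export
#' @examples
#' smq <- smq_eosinophilic_pneumonia()
#' nrow(smq) # 9 published terms
smq_eosinophilic_pneumonia <- function(extra_terms = NULL) {
  terms <- data.frame(
    pt_code = c("10014962", "10052832", "10052833", "10024794", "10035742",
                "10037382", "10048643", "10078117", "10080148"),
    pt_name = c("eosinophilic pneumonia",
                "eosinophilic pneumonia acute",
                "eosinophilic pneumonia chronic",
                "loffler's syndrome",
                "pneumonitis",
                "pulmonary eosinophilia",
                "hypereosinophilic syndrome",
                "eosinophilic granulomatosis with polyangiitis",
                "eosinophilic pleural effusion"),
    stringsAsFactors = FALSE
  )
  if (!is.null(extra_terms)) {
    stopifnot(all(c("pt_code", "pt_name") %in% names(extra_terms)))
    terms <- rbind(terms, data.frame(pt_code = as.character(extra_terms$pt_code),
                                     pt_name = tolower(extra_terms$pt_name),
                                     stringsAsFactors = FALSE))
  }
  smq_term_set(terms, smq_id = "20000159")
}

#' Construct an SMQ term set
#'
#' @param terms data.frame with columns `pt_code`, `pt_name`.
#' @param smq_id identifier of the query.
#' @return `smq_term_set` object.
#' @export
smq_term_set <- function(terms, smq_id = NA_character_) {
  stopifnot(is.data.frame(terms), all(c("pt_code", "pt_name") %in% names(terms)))
  if (nrow(terms) == 0L) stop("SMQ term set must be non-empty")
  terms$pt_code <- as.character(terms$pt_code)
  terms$pt_name <- tolower(trimws(terms$pt_name))
  if (anyDuplicated(terms$pt_code[!is.na(terms$pt_code) & terms$pt_code != ""]))
    stop("duplicate PT codes in SMQ term set")
  structure(terms, class = c("smq_term_set", "data.frame"), smq_id = smq_id)
}

#' @export
print.smq_term_set <- function(x, ...) {
  cat(sprintf("SMQ term set %s: %d preferred terms\n",
              attr(x, "smq_id"), nrow(x)))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
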