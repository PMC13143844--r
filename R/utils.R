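#' Round half-up
#'
#' Rounds to `digits` decimals with ties going away from zero, the convention
#' used for printed percentage tables in regulatory summaries (base [round()]
#' uses banker's rounding, which turns 0.415 into 0.41, not 0.42).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector.
#' @export
#' @examples
#' round_half_up(41.55, 1) # 41.6, where round() gives 41.5
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percentage of a count, rounded half-up to one decimal
#'
#' @param n count (numeric vector).
#' @param total denominator; a total of 0 yields 0.0.
#' @param digits decimals to keep (default 1, table convention).
#' @return numeric percentage on the 0-100 scale.
#' @export
#' @examples
#' pct_of(6382, 15374) # 41.5
pct_of <- function(n, total, digits = 1) {
  t <- rep_len(total, length(n))
  out <- numeric(length(n))
  pos <- t > 0
  out[pos] <- round_half_up(100 * n[pos] / t[pos], digits)
  out
}

# Parse FAERS-style date strings. Full dates are YYYYMMDD; YYYYMM / YYYY are
# partial and cannot support day-level arithmetic, so they come back NA with
# partial = TRUE. Anything else is simply missing.
parse_faers_date <- function(x) {
  x <- trimws(as.character(x))
  x[is.na(x) | x == "" | x == "NA"] <- NA_character_
  digits_only <- !is.na(x) & grepl("^[0-9]+$", x)
  full <- digits_only & nchar(x) == 8L
  partial <- digits_only & nchar(x) %in% c(4L, 6L)
  out <- rep(as.Date(NA), length(x))
  if (any(full)) {
    d <- as.Date(x[full], format = "%Y%m%d")
    out[full] <- d
    # impossible calendar dates (e.g. 20231301) fall through to NA
  }
  list(date = out, partial = partial,
       year = ifelse(digits_only, suppressWarnings(as.integer(substr(x, 1, 4))),
                     NA_integer_))
}

#' Derive a reproducible per-stage seed from a global seed
#'
#' Fans one user-facing seed out to independent stage seeds so each pipeline
#' stage is individually reproducible. The stage name is hashed with a small
#' polynomial rolling hash; results stay below 2^31.
#'
#' @param seed integer global seed.
#' @param stage character stage label.
#' @return integer seed.
#' @export
derive_seed <- function(seed, stage) {
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% 2147483647
  as.integer((as.numeric(seed) * 2654435761 + h) %% 2147483647 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# kg per pound, used when weights arrive coded in LBS
LB_TO_KG <- 0.45359237
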