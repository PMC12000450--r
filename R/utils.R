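# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG seed without disturbing the caller's
# random number stream.
local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

# Per-trial seed derivation: one master seed plus a trial counter, kept inside
# 32-bit integer range. Documented so experiment trials are individually
# reproducible.
derive_seed <- function(master, counter) {
  as.integer((as.numeric(master) * 10007 + as.numeric(counter)) %% 2147483647)
}

#' @import data.table
NULL

# quiet R CMD check notes for data.table NSE column names
utils::globalVariables(c(
  ".", ".N", "patient_id", "icd_code", "encounter_type", "first_date",
  "code", "code_a", "code_b", "m", "label", "n", "domain", "d_a", "d_b",
  "icd_code_a", "icd_code_b", "first_date_a", "first_date_b", "eim",
  "row_label", "count_total", "display_size", "display_width"
))

icd_pattern <- "^[A-Z][0-9]{2}(\\.[0-9]{1,2})?$"

encounter_types <- c("hospitalization", "physician_claim", "ambulatory")

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}
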