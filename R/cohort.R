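#' Administrative case definition for IBD
#'
#' A patient is an IBD case if, within some 2-year (730-day) window, they have
#' at least two hospitalizations, or four physician claims, or two ambulatory
#' care contacts carrying an IBD diagnostic code. Each clause is evaluated
#' independently on a sliding window anchored at each IBD-coded encounter.
#'
#' @param window_days window length in days (default 730; two years with leap
#'   days ignored, for determinism).
#' @param min_hospitalizations,min_physician_claims,min_ambulatory_contacts
#'   per-clause encounter thresholds.
#' @param ibd_prefixes code prefixes that count as IBD index codes. The
#'   default accepts ICD-10-CA (K50/K51) and ICD-9-CA (555/556) coding.
#' @return an object of class `case_definition`.
#' @export
case_definition <- function(window_days = 730,
                            min_hospitalizations = 2,
                            min_physician_claims = 4,
                            min_ambulatory_contacts = 2,
                            ibd_prefixes = c("K50", "K51", "555", "556")) {
  assert_that(window_days >= 1, "window_days must be >= 1")
  assert_that(min_hospitalizations >= 1 && min_physician_claims >= 1 &&
                min_ambulatory_contacts >= 1, "all thresholds must be >= 1")
  structure(list(window_days = window_days,
                 min_hospitalizations = min_hospitalizations,
                 min_physician_claims = min_physician_claims,
                 min_ambulatory_contacts = min_ambulatory_contacts,
                 ibd_prefixes = ibd_prefixes),
            class = "case_definition")
}

is_ibd_code <- function(codes, prefixes = c("K50", "K51", "555", "556")) {
  out <- rep(FALSE, length(codes))
  for (p in prefixes) out <- out | startsWith(codes, p)
  out
}

# TRUE if any run of `k` sorted dates spans <= `w` days
count_in_window <- function(dates, k, w) {
  if (length(dates) < k) return(FALSE)
  d <- sort(as.numeric(dates))
  i <- seq_len(length(d) - k + 1)
  any(d[i + k - 1] - d[i] <= w)
}

#' Classify one patient's encounter stream against the case definition
#'
#' Only IBD-coded encounters (per `defn$ibd_prefixes`) count toward the
#' clauses; the three clauses are evaluated independently and any one
#' suffices.
#'
#' @param records encounter rows for a single patient.
#' @param defn a [case_definition()].
#' @return `"case"` or `"excluded"`. An empty record stream is `"excluded"`.
#' @export
classify_patient <- function(records, defn = case_definition()) {
  stopifnot(inherits(defn, "case_definition"))
  if (NROW(records) == 0) return("excluded")
  rec <- data.table::as.data.table(records)
  rec <- rec[is_ibd_code(icd_code, defn$ibd_prefixes)]
  if (nrow(rec) == 0) return("excluded")
  w <- defn$window_days
  hit <-
    count_in_window(rec[encounter_type == "hospitalization", date],
                    defn$min_hospitalizations, w) ||
    count_in_window(rec[encounter_type == "physician_claim", date],
                    defn$min_physician_claims, w) ||
    count_in_window(rec[encounter_type == "ambulatory", date],
                    defn$min_ambulatory_contacts, w)
  if (hit) "case" else "excluded"
}

#' Assign an IBD subtype to a classified case
#'
#' A documented stand-in for the registry's proprietary subtype scoring:
#' Crohn's disease (CD) if a strict majority of the patient's IBD-coded
#' encounters carry a CD prefix, ulcerative colitis (UC) if a strict majority
#' carry a UC prefix, and IBD-unclassified (IBDU) on ties or mixed streams
#' without a majority.
#'
#' @param records encounter rows for one case patient.
#' @param cd_prefixes,uc_prefixes code prefixes identifying each subtype.
#' @return one of `"CD"`, `"UC"`, `"IBDU"`.
#' @export
assign_subtype <- function(records,
                           cd_prefixes = c("K50", "555"),
                           uc_prefixes = c("K51", "556")) {
  rec <- data.table::as.data.table(records)
  cd_n <- sum(is_ibd_code(rec$icd_code, cd_prefixes))
  uc_n <- sum(is_ibd_code(rec$icd_code, uc_prefixes))
  tot <- cd_n + uc_n
  if (cd_n * 2 > tot && cd_n > 0) return("CD")
  if (uc_n * 2 > tot && uc_n > 0) return("UC")
  "IBDU"
}

#' Age stratum at first encounter
#'
#' Fractional ages are floored before stratum assignment: `<18` years is
#' `child`, 18 through 64 is `adult`, 65 and over is `senior`.
#'
#' @param age_years non-negative age(s) in years.
#' @return character vector of strata (`child`, `adult`, `senior`).
#' @export
age_group <- function(age_years) {
  assert_that(all(age_years >= 0), "age must be non-negative")
  a <- floor(age_years)
  ifelse(a < 18, "child", ifelse(a <= 64, "adult", "senior"))
}

#' Build the labelled cohort from encounter records
#'
#' Applies [classify_patient()] to every patient, [assign_subtype()] to the
#' cases, and (when a demographics table is supplied) computes age at first
#' encounter and its stratum.
#'
#' @param records full encounter table.
#' @param defn a [case_definition()].
#' @param demographics optional table with `patient_id`, `sex`, `birth_date`.
#' @return `data.table` with columns `patient_id`, `label`
#'   (CD/UC/IBDU/excluded) and, when demographics are given, `sex`, `age`,
#'   `age_group`.
#' @export
build_cohort <- function(records, defn = case_definition(),
                         demographics = NULL) {
  rec <- data.table::as.data.table(records)
  if (nrow(rec) == 0) {
    return(data.table::data.table(patient_id = character(),
                                  label = character()))
  }
  cls <- rec[, .(label = classify_patient(.SD, defn)), by = patient_id]
  cases <- cls$patient_id[cls$label == "case"]
  if (length(cases) > 0) {
    sub <- rec[patient_id %in% cases,
               .(sub = assign_subtype(.SD)), by = patient_id]
    cls[sub, label := i.sub, on = "patient_id"]
  }
  if (!is.null(demographics)) {
    dem <- data.table::as.data.table(demographics)
    first <- rec[, .(first_date = min(date)), by = patient_id]
    cls <- merge(cls, dem, by = "patient_id", all.x = TRUE)
    cls <- merge(cls, first, by = "patient_id", all.x = TRUE)
    cls[, age := as.numeric(first_date - as.Date(birth_date)) / 365.25]
    cls[, age_group := age_group(age)]
    cls[, c("first_date", "birth_date") := NULL]
  }
  data.table::setorder(cls, patient_id)
  cls[]
}

utils::globalVariables(c("age", "birth_date", "sub", "i.sub"))
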