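#' Percentage at three decimals
#'
#' `100 * numerator / denominator`, rounded half-to-even at 3 decimal places
#' (the convention of base R's [round()]), matching the descriptive tables'
#' 3-decimal style.
#'
#' @param numerator,denominator non-negative counts with
#'   `numerator <= denominator` and `denominator > 0`.
#' @return numeric percent.
#' @export
percent <- function(numerator, denominator) {
  assert_that(all(denominator > 0), "denominator must be > 0")
  assert_that(all(numerator >= 0) && all(numerator <= denominator),
              "need 0 <= numerator <= denominator")
  round(100 * numerator / denominator, 3)
}

#' Chi-square comparison of two proportions
#'
#' Pearson chi-square on the 2x2 table `[(a, n1-a), (b, n2-b)]` with Yates
#' continuity correction by default (df = 1, two-sided). The correction is
#' on by default because it is the convention under which the package's
#' regression fixtures for published binary comparisons reproduce; it can be
#' disabled. No multiple-testing adjustment is applied anywhere in this
#' module.
#'
#' @param a,n1 successes and group size for group 1.
#' @param b,n2 successes and group size for group 2.
#' @param correct apply Yates continuity correction (default `TRUE`).
#' @return list with `statistic` and `p_value`.
#' @export
chi_square_2x2 <- function(a, n1, b, n2, correct = TRUE) {
  assert_that(n1 > 0 && n2 > 0, "both group sizes must be positive")
  assert_that(a >= 0 && b >= 0 && a <= n1 && b <= n2,
              "need 0 <= a <= n1 and 0 <= b <= n2")
  tab <- matrix(c(a, n1 - a, b, n2 - b), nrow = 2, byrow = TRUE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 1)) {
    warning("expected cell count below 1; chi-square approximation unreliable")
  }
  res <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(res$statistic), p_value = unname(res$p.value))
}

#' Median and interquartile range
#'
#' Quartiles use linear interpolation between order statistics
#' ([stats::quantile()] type 7).
#'
#' @param values non-empty numeric vector.
#' @return list with `median` and `iqr`.
#' @export
median_iqr <- function(values) {
  assert_that(length(values) > 0 && all(is.finite(values)),
              "values must be a non-empty finite numeric vector")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(median = q[2], iqr = q[3] - q[1])
}

#' Events per patient-year
#'
#' @param event_count non-negative event count.
#' @param patient_years positive person-time denominator.
#' @return rate (events per patient-year).
#' @export
utilization_rate <- function(event_count, patient_years) {
  assert_that(all(patient_years > 0), "patient_years must be > 0")
  event_count / patient_years
}

#' Default ICD-10 chapter map for grouping EIM/AID codes
#'
#' An ordered table of code-root ranges mapping ICD-10 codes to organ-system
#' domains. Order matters: specific overrides (the cerebrovascular group,
#' which pools I60-I69 stroke with I80-I82 phlebitis/embolism/thrombosis, and
#' the IBD index codes K50-K51) precede the general WHO chapters, and the
#' first matching range wins. The `eim` flag marks domains whose codes count
#' as extraintestinal manifestations / associated immune disorders; the IBD
#' index entry is excluded from EIM tabulation. The exact code membership of
#' each published organ-system grouping is not enumerated in the source
#' tables, so this map is a best reconstruction and is user-editable
#' ([read_domain_map()] / [write_domain_map()]).
#'
#' @return `data.table` with columns `domain`, `from`, `to`, `eim`.
#' @export
default_domain_map <- function() {
  data.table::data.table(
    domain = c(
      "IBD index",
      "Cerebrovascular diseases",
      "Cerebrovascular diseases",
      "Certain infectious and parasitic diseases",
      "Neoplasms",
      "Diseases of the blood and blood-forming organs and certain disorders involving the immune mechanism",
      "Endocrine, nutritional and metabolic diseases",
      "Mental, behavioral and neurodevelopmental disorders",
      "Diseases of the nervous system",
      "Diseases of the eye and adnexa",
      "Diseases of the ear and mastoid process",
      "Diseases of the circulatory system",
      "Diseases of the respiratory system",
      "Diseases of the digestive system",
      "Diseases of the skin and subcutaneous tissue",
      "Diseases of the musculoskeletal system and connective tissue",
      "Diseases of the genitourinary system",
      "Symptoms, signs and abnormal clinical and laboratory findings, not elsewhere classified"
    ),
    from = c("K50", "I60", "I80", "A00", "C00", "D50", "E00", "F00", "G00",
             "H00", "H60", "I00", "J00", "K00", "L00", "M00", "N00", "R00"),
    to   = c("K51", "I69", "I82", "B99", "D48", "D89", "E90", "F99", "G99",
             "H59", "H95", "I99", "J99", "K93", "L99", "M99", "N99", "R99"),
    eim  = c(FALSE, rep(TRUE, 17))
  )
}

#' @rdname default_domain_map
#' @param path CSV file with columns `domain,from,to,eim`.
#' @param map a domain map table.
#' @export
read_domain_map <- function(path) {
  map <- data.table::fread(path, colClasses = list(character = c(
    "domain", "from", "to"), logical = "eim"))
  assert_that(all(c("domain", "from", "to", "eim") %in% names(map)),
              "domain map needs columns domain, from, to, eim")
  map
}

#' @rdname default_domain_map
#' @export
write_domain_map <- function(map, path) {
  data.table::fwrite(map, path)
  invisible(path)
}

#' Map ICD codes to organ-system domains
#'
#' The code's 3-character root is compared against each range in order; the
#' first match wins, and codes matching nothing fall through to
#' `"unmapped"`.
#'
#' @param codes character vector of ICD codes.
#' @param map a domain map (default [default_domain_map()]).
#' @return character vector of domain names.
#' @export
map_code_to_domain <- function(codes, map = default_domain_map()) {
  root <- substr(codes, 1, 3)
  out <- rep("unmapped", length(codes))
  todo <- rep(TRUE, length(codes))
  for (i in seq_len(nrow(map))) {
    hit <- todo & root >= map$from[i] & root <= map$to[i]
    out[hit] <- map$domain[i]
    todo <- todo & !hit
  }
  out
}

#' Descriptive frequency table over organ-system domains
#'
#' For each EIM domain (and a final "Number of patients with any EIM & AID"
#' summary row), counts the unique patients per disease group carrying at
#' least one code in the domain, expresses each count as a percentage of the
#' per-disease cohort size at 3 decimals, and tests CD vs UC with the
#' Yates-corrected chi-square. A patient counts once per domain regardless
#' of how many of its codes they carry. Rows are ordered by total frequency,
#' descending.
#'
#' @param records encounter table.
#' @param cohort labelled cohort from [build_cohort()].
#' @param map domain map; codes in non-EIM domains (the IBD index codes) and
#'   unmapped codes are excluded.
#' @param correct passed to [chi_square_2x2()].
#' @return `data.table` of `FrequencyRow`s: `row_label`, per-group counts and
#'   percents, and `p_UC_vs_CD`.
#' @export
frequency_table <- function(records, cohort, map = default_domain_map(),
                            correct = TRUE) {
  rec <- data.table::as.data.table(records)
  coh <- data.table::as.data.table(cohort)[label %in% c("CD", "UC", "IBDU")]
  denom <- c(CD = sum(coh$label == "CD"), UC = sum(coh$label == "UC"),
             IBDU = sum(coh$label == "IBDU"))
  denom <- c(denom, total = sum(denom))
  assert_that(denom[["total"]] > 0, "cohort contains no cases")

  rec <- merge(rec[, .(patient_id, icd_code)], coh[, .(patient_id, label)],
               by = "patient_id")
  rec <- unique(rec[, .(patient_id, icd_code, label)])
  rec[, domain := map_code_to_domain(icd_code, map)]
  eim_domains <- unique(map$domain[map$eim])
  rec <- rec[domain %in% eim_domains]

  count_row <- function(sub, lab) {
    data.table::data.table(
      row_label = lab,
      count_CD = length(unique(sub[label == "CD", patient_id])),
      count_UC = length(unique(sub[label == "UC", patient_id])),
      count_IBDU = length(unique(sub[label == "IBDU", patient_id]))
    )
  }
  rows <- data.table::rbindlist(c(
    lapply(eim_domains, function(d) count_row(rec[domain == d], d)),
    list(count_row(rec, "Number of patients with any EIM & AID"))
  ))
  rows[, count_total := count_CD + count_UC + count_IBDU]
  rows[, `:=`(
    pct_CD = percent(count_CD, denom[["CD"]]),
    pct_UC = percent(count_UC, denom[["UC"]]),
    pct_IBDU = if (denom[["IBDU"]] > 0) percent(count_IBDU, denom[["IBDU"]])
               else NA_real_,
    pct_total = percent(count_total, denom[["total"]])
  )]
  rows[, p_UC_vs_CD := vapply(seq_len(.N), function(i) {
    chi_square_2x2(count_CD[i], denom[["CD"]],
                   count_UC[i], denom[["UC"]], correct = correct)$p_value
  }, numeric(1))]
  summary_row <- rows[row_label == "Number of patients with any EIM & AID"]
  body <- rows[row_label != "Number of patients with any EIM & AID"]
  data.table::setorder(body, -count_total, row_label)
  out <- data.table::rbindlist(list(body, summary_row))
  out[]
}

utils::globalVariables(c("count_CD", "count_UC", "count_IBDU",
                         "pct_CD", "pct_UC", "pct_IBDU", "pct_total",
                         "p_UC_vs_CD"))
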