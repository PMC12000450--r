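#' Simulation configuration for the synthetic EHR generator
#'
#' Bundles and validates all knobs of the synthetic encounter-stream
#' generator. The defaults describe the standard benchmark cohort used
#' throughout the package's tests: 2000 patients, four planted code
#' communities of 25 codes each, within-community carriage probability 0.3
#' against a 0.01 background, and no sub-threshold ("noise") case streams.
#'
#' @param n_patients number of patients to simulate.
#' @param disease_mix named proportions over `CD`, `UC`, `IBDU`, `non-case`;
#'   must sum to 1.
#' @param n_communities number of planted code communities (blocks).
#' @param codes_per_community number of diagnosis codes per block.
#' @param p_within probability that a patient carries a given code from their
#'   assigned block.
#' @param p_between probability per code that a patient carries a code from
#'   another block.
#' @param case_noise fraction of IBD-labelled patients whose encounter stream
#'   is deliberately kept below every clause of the case definition, to
#'   exercise the classifier's reject path.
#' @param temporal_bias probability in \[0.5, 1\] that, for a designated
#'   ordered code pair carried by the same patient, the "cause" code's first
#'   diagnosis date strictly precedes the "effect" code's.
#' @param date_start,date_end calendar bounds (coerced with [as.Date()]) for
#'   all generated encounter dates.
#' @param repeat_prob probability that a carried code generates a second,
#'   later encounter (exercises first-date deduplication downstream).
#' @param frequency_spread ratio between the most and least common code's
#'   carriage propensity within each block (geometric profile, normalized so
#'   the block average stays `p_within`/`p_between`). Real ICD code
#'   frequencies are strongly heterogeneous; the default 5 emulates that so
#'   frequency-quartile analyses have signal. Set to 1 for homogeneous
#'   carriage.
#' @param seed integer seed; identical seeds give byte-identical output.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_patients = 2000,
                       disease_mix = c(CD = 0.42, UC = 0.31,
                                       IBDU = 0.07, `non-case` = 0.20),
                       n_communities = 4,
                       codes_per_community = 25,
                       p_within = 0.3,
                       p_between = 0.01,
                       case_noise = 0,
                       temporal_bias = 0.9,
                       date_start = "2002-01-01",
                       date_end = "2019-12-31",
                       repeat_prob = 0.1,
                       frequency_spread = 5,
                       seed = 1L) {
  assert_that(length(n_patients) == 1 && n_patients >= 0 &&
                n_patients == floor(n_patients),
              "n_patients must be a single non-negative integer")
  assert_that(is.numeric(disease_mix) && length(disease_mix) == 4 &&
                all(c("CD", "UC", "IBDU", "non-case") %in% names(disease_mix)),
              "disease_mix must be named proportions over CD, UC, IBDU, non-case")
  assert_that(all(disease_mix >= 0) && abs(sum(disease_mix) - 1) <= 1e-9,
              "disease_mix proportions must be non-negative and sum to 1")
  assert_that(n_communities >= 1 && codes_per_community >= 1 &&
                n_communities * codes_per_community >= 2,
              "need at least 2 planted codes (n_communities x codes_per_community)")
  for (p in list(p_within = p_within, p_between = p_between,
                 case_noise = case_noise, repeat_prob = repeat_prob)) {
    assert_that(length(p) == 1 && p >= 0 && p <= 1,
                "probabilities must lie in [0, 1]")
  }
  assert_that(temporal_bias >= 0.5 && temporal_bias <= 1,
              "temporal_bias must lie in [0.5, 1]")
  assert_that(length(frequency_spread) == 1 && frequency_spread >= 1,
              "frequency_spread must be >= 1")
  date_start <- as.Date(date_start)
  date_end <- as.Date(date_end)
  assert_that(date_end > date_start + 730,
              "date span must exceed the 2-year case-definition window")
  structure(
    list(n_patients = as.integer(n_patients),
         disease_mix = disease_mix[c("CD", "UC", "IBDU", "non-case")],
         n_communities = as.integer(n_communities),
         codes_per_community = as.integer(codes_per_community),
         p_within = p_within, p_between = p_between,
         case_noise = case_noise, temporal_bias = temporal_bias,
         date_start = date_start, date_end = date_end,
         repeat_prob = repeat_prob, frequency_spread = frequency_spread,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Synthesize a universe of ICD-10-style codes spread over realistic chapters
# (mental, musculoskeletal, genitourinary, circulatory, ...). The digestive
# K-chapter is deliberately avoided so no synthetic code collides with the
# K50.x/K51.x IBD index codes. Chapters are interleaved across the planted
# blocks so that chapter grouping and community structure cut across each
# other.
eim_code_universe <- function(n_codes) {
  chapters <- c("F", "M", "N", "I", "J", "G", "L", "E", "H", "D", "R")
  ch <- chapters[((seq_len(n_codes) - 1) %% length(chapters)) + 1]
  idx <- stats::ave(seq_len(n_codes), ch, FUN = seq_along) - 1L
  sprintf("%s%02d.%d", ch, 10 + idx %/% 10, idx %% 10)
}

empty_records <- function() {
  data.table::data.table(patient_id = character(),
                         date = as.Date(character()),
                         icd_code = character(),
                         encounter_type = character())
}

#' Generate a synthetic patient cohort with planted community structure
#'
#' Produces a long-format encounter table (one dated diagnosis per row) for a
#' mixed cohort of Crohn's disease (CD), ulcerative colitis (UC),
#' IBD-unclassified (IBDU) and non-case patients, together with the ground
#' truth used to score downstream stages.
#'
#' IBD-labelled patients (unless selected as `case_noise`) receive an index
#' encounter stream guaranteed to satisfy one clause of the administrative
#' case definition (two hospitalizations, four physician claims, or two
#' ambulatory contacts with an IBD code inside a 730-day window); which
#' clause is rotated per patient so all three are exercised. Noise patients
#' receive a stream below every clause. Extra-intestinal codes are carried
#' per planted block with probabilities `p_within` / `p_between`, each
#' carried code receiving a first-diagnosis date uniform over the configured
#' span, then adjusted so designated ordered code pairs respect
#' `temporal_bias`.
#'
#' @param config a [sim_config()] object.
#' @return a list with elements
#'   \describe{
#'     \item{records}{`data.table` with columns `patient_id`, `date`,
#'       `icd_code`, `encounter_type`.}
#'     \item{truth}{list with `patient_labels` (named character),
#'       `code_communities` (named integer, 0-based), `ordered_pairs`
#'       (data.table `earlier`, `later`), `patient_communities`, and a
#'       `demographics` table (`patient_id`, `sex`, `birth_date`).}
#'   }
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  local_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  n <- config$n_patients
  n_codes <- config$n_communities * config$codes_per_community
  codes <- eim_code_universe(n_codes)
  code_comm <- rep(seq_len(config$n_communities) - 1L,
                   each = config$codes_per_community)
  names(code_comm) <- codes
  ordered_pairs <- ordered_pairs_for(codes, code_comm)

  if (n == 0) {
    return(list(
      records = empty_records(),
      truth = list(patient_labels = stats::setNames(character(0), character(0)),
                   code_communities = code_comm,
                   ordered_pairs = ordered_pairs,
                   patient_communities = stats::setNames(integer(0), character(0)),
                   demographics = data.table::data.table(
                     patient_id = character(), sex = character(),
                     birth_date = as.Date(character())))
    ))
  }

  pid <- sprintf("P%06d", seq_len(n))
  labels <- sample(names(config$disease_mix), n, replace = TRUE,
                   prob = config$disease_mix)
  names(labels) <- pid
  patient_comm <- sample(config$n_communities, n, replace = TRUE) - 1L
  names(patient_comm) <- pid
  is_ibd <- labels != "non-case"
  is_noise <- is_ibd & (stats::runif(n) < config$case_noise)

  span_start <- as.numeric(config$date_start)
  span_end <- as.numeric(config$date_end)
  # index encounters must leave room for a 730-day forward window
  anchor <- floor(stats::runif(n, span_start, span_end - 731))

  idx_records <- ibd_index_stream(pid, labels, is_ibd, is_noise, anchor)
  eim_records <- eim_stream(pid, patient_comm, codes, code_comm, config,
                            span_start, span_end, ordered_pairs)

  records <- data.table::rbindlist(list(idx_records, eim_records))
  records[, date := as.Date(date, origin = "1970-01-01")]
  data.table::setorder(records, patient_id, date, icd_code, encounter_type)
  data.table::setcolorder(records,
                          c("patient_id", "date", "icd_code", "encounter_type"))

  demographics <- data.table::data.table(
    patient_id = pid,
    sex = sample(c("female", "male"), n, replace = TRUE, prob = c(0.52, 0.48)),
    # births precede the encounter span, so age at first encounter is
    # positive; spread gives a wide mix of child/adult/senior strata
    birth_date = as.Date(span_start -
                           floor(stats::runif(n, 1 * 365.25, 75 * 365.25)),
                         origin = "1970-01-01")
  )

  list(records = records,
       truth = list(patient_labels = labels,
                    code_communities = code_comm,
                    ordered_pairs = ordered_pairs,
                    patient_communities = patient_comm,
                    demographics = demographics))
}

# consecutive codes within each block form the designated (earlier, later)
# pairs used by the temporal-bias machinery
ordered_pairs_for <- function(codes, code_comm) {
  out <- lapply(split(codes, code_comm), function(cc) {
    k <- length(cc) %/% 2
    if (k == 0) return(NULL)
    data.table::data.table(earlier = cc[2 * seq_len(k) - 1],
                           later = cc[2 * seq_len(k)])
  })
  pairs <- data.table::rbindlist(out)
  if (nrow(pairs) == 0) {
    pairs <- data.table::data.table(earlier = character(), later = character())
  }
  pairs
}

# IBD index encounters (K50.x / K51.x). Clause rotation guarantees every
# arm of the case definition is represented; noise streams stay below all
# three thresholds in any window.
ibd_index_stream <- function(pid, labels, is_ibd, is_noise, anchor) {
  rows <- vector("list", length(pid))
  cd_codes <- c("K50.0", "K50.1", "K50.8", "K50.9")
  uc_codes <- c("K51.0", "K51.2", "K51.8", "K51.9")
  for (i in seq_along(pid)) {
    if (!is_ibd[i]) {
      # half the non-cases get a single, sub-threshold IBD claim
      if (stats::runif(1) < 0.5) {
        rows[[i]] <- list(patient_id = pid[i], date = anchor[i],
                          icd_code = sample(c("K50.9", "K51.9"), 1),
                          encounter_type = "physician_claim")
      }
      next
    }
    lab <- labels[i]
    pick <- function(k) {
      if (lab == "CD") sample(cd_codes, k, replace = TRUE,
                              prob = c(.2, .2, .1, .5))
      else if (lab == "UC") sample(uc_codes, k, replace = TRUE,
                                   prob = c(.2, .2, .1, .5))
      else rep(c("K50.9", "K51.9"), length.out = k)  # balanced -> tie -> IBDU
    }
    if (is_noise[i]) {
      # 1 hospitalization + 2 claims + 1 ambulatory: below every clause
      d <- anchor[i] + sort(sample(0:700, 4))
      rows[[i]] <- list(patient_id = rep(pid[i], 4), date = d,
                        icd_code = pick(4),
                        encounter_type = c("hospitalization", "physician_claim",
                                           "physician_claim", "ambulatory"))
      next
    }
    clause <- i %% 3
    if (clause == 0) {           # >= 2 hospitalizations within 730 days
      d <- anchor[i] + sort(sample(0:600, 2))
      et <- rep("hospitalization", 2); k <- 2
    } else if (clause == 1) {    # >= 4 physician claims within 730 days
      d <- anchor[i] + sort(sample(0:700, 4))
      et <- rep("physician_claim", 4); k <- 4
    } else {                     # >= 2 ambulatory contacts within 730 days
      d <- anchor[i] + sort(sample(0:600, 2))
      et <- rep("ambulatory", 2); k <- 2
    }
    code <- pick(k)
    if (lab == "IBDU" && k %% 2 == 1) code[k] <- "K50.9"
    rows[[i]] <- list(patient_id = rep(pid[i], k), date = d,
                      icd_code = code, encounter_type = et)
  }
  data.table::rbindlist(rows[!vapply(rows, is.null, logical(1))])
}

# Extra-intestinal code carriage: Bernoulli per (patient, code) with
# block-dependent probability; one first-diagnosis encounter per carried
# code plus an optional later repeat.
eim_stream <- function(pid, patient_comm, codes, code_comm, config,
                       span_start, span_end, ordered_pairs) {
  n <- length(pid)
  n_codes <- length(codes)
  # heavy-tailed per-code carriage propensity: a geometric profile within
  # each block spanning frequency_spread from most to least common code,
  # normalized so the block mean equals p_within / p_between
  C <- config$codes_per_community
  prof <- if (C == 1) 1 else {
    s <- config$frequency_spread
    s^(0.5 - (seq_len(C) - 1) / (C - 1))
  }
  prof <- prof / mean(prof)
  mult <- prof[stats::ave(seq_len(n_codes), code_comm, FUN = seq_along)]
  pmat <- matrix(rep(pmin(config$p_between * mult, 1), each = n),
                 nrow = n, ncol = n_codes)
  for (k in unique(code_comm)) {
    pmat[patient_comm == k, code_comm == k] <-
      rep(pmin(config$p_within * mult[code_comm == k], 0.95),
          each = sum(patient_comm == k))
  }
  carried <- matrix(stats::runif(n * n_codes) < pmat, nrow = n)
  idx <- which(carried, arr.ind = TRUE)
  if (nrow(idx) == 0) return(empty_records())

  first_date <- floor(stats::runif(nrow(idx), span_start, span_end + 1))
  # dates keyed by (patient row, code column) for temporal adjustment
  key <- paste(idx[, 1], idx[, 2])
  dmap <- stats::setNames(first_date, key)
  code_col <- stats::setNames(seq_along(codes), codes)

  if (nrow(ordered_pairs) > 0) {
    for (r in seq_len(nrow(ordered_pairs))) {
      ce <- code_col[[ordered_pairs$earlier[r]]]
      cl <- code_col[[ordered_pairs$later[r]]]
      both <- which(carried[, ce] & carried[, cl])
      if (length(both) == 0) next
      forward <- stats::runif(length(both)) < config$temporal_bias
      ke <- paste(both, ce); kl <- paste(both, cl)
      de <- dmap[ke]; dl <- dmap[kl]
      lo <- pmin(de, dl); hi <- pmax(de, dl)
      tie <- lo == hi
      hi[tie & hi < span_end] <- hi[tie & hi < span_end] + 1
      lo[tie & hi == lo] <- lo[tie & hi == lo] - 1
      dmap[ke] <- ifelse(forward, lo, hi)
      dmap[kl] <- ifelse(forward, hi, lo)
    }
  }

  first_date <- unname(dmap[key])
  et <- sample(c("physician_claim", "ambulatory"), nrow(idx),
               replace = TRUE, prob = c(0.7, 0.3))
  rec <- data.table::data.table(patient_id = pid[idx[, 1]],
                                date = first_date,
                                icd_code = codes[idx[, 2]],
                                encounter_type = et)
  rep_sel <- stats::runif(nrow(idx)) < config$repeat_prob
  if (any(rep_sel)) {
    rep_date <- pmin(first_date[rep_sel] +
                       sample(30:400, sum(rep_sel), replace = TRUE),
                     span_end)
    reps <- data.table::data.table(patient_id = pid[idx[rep_sel, 1]],
                                   date = rep_date,
                                   icd_code = codes[idx[rep_sel, 2]],
                                   encounter_type = et[rep_sel])
    rec <- data.table::rbindlist(list(rec, reps))
  }
  rec
}

#' Write / read encounter records as CSV
#'
#' The on-disk format is a plain CSV with header
#' `patient_id,date,icd_code,encounter_type` and ISO-8601 dates; the
#' round trip `read_records(write_records(x))` is lossless.
#'
#' @param records encounter `data.table` as produced by [generate_cohort()].
#' @param path file path.
#' @return `write_records` returns `path` invisibly; `read_records` returns a
#'   validated encounter `data.table`.
#' @export
write_records <- function(records, path) {
  stopifnot(all(c("patient_id", "date", "icd_code", "encounter_type")
                %in% names(records)))
  out <- data.table::as.data.table(records)
  out <- out[, .(patient_id, date = format(as.Date(date), "%Y-%m-%d"),
                 icd_code, encounter_type)]
  data.table::fwrite(out, path)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  raw <- data.table::fread(path, colClasses = "character")
  expected <- c("patient_id", "date", "icd_code", "encounter_type")
  assert_that(identical(names(raw), expected),
              sprintf("expected header %s", paste(expected, collapse = ",")))
  if (nrow(raw) == 0) return(empty_records())
  dates <- as.Date(raw$date, format = "%Y-%m-%d")
  bad <- which(is.na(dates) | !grepl(icd_pattern, raw$icd_code) |
                 !(raw$encounter_type %in% encounter_types))
  if (length(bad) > 0) {
    stop(sprintf("malformed record at line %d of %s", bad[1] + 1L, path),
         call. = FALSE)
  }
  data.table::data.table(patient_id = raw$patient_id, date = dates,
                         icd_code = raw$icd_code,
                         encounter_type = raw$encounter_type)
}

#' Write / read the simulation ground truth as JSON
#'
#' @param truth the `truth` element of [generate_cohort()]'s result.
#' @param path file path.
#' @export
write_ground_truth <- function(truth, path) {
  payload <- list(
    patient_labels = as.list(truth$patient_labels),
    code_communities = as.list(truth$code_communities),
    ordered_pairs = truth$ordered_pairs
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path)
  list(
    patient_labels = unlist(x$patient_labels),
    code_communities = vapply(x$code_communities, as.integer, integer(1)),
    ordered_pairs = data.table::rbindlist(x$ordered_pairs)
  )
}
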