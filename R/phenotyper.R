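# Rule-based HTCP classification: WET_AMD / DRY_AMD / CONTROL / UNCLASSIFIED.
#
# Two rule versions are supported. V1 is the pilot rule set: any qualifying
# AMD diagnosis makes a case, and any anti-VEGF injection or order makes a
# case "wet". V2 is the refined, chart-review-validated rule set: >= 2
# distinct diagnosis dates, age >= 60 at the first, and a same-date 362.5x
# diagnosis partnered with the injection for wet status.

PHENOTYPE_LABELS <- c("WET_AMD", "DRY_AMD", "CONTROL", "UNCLASSIFIED")

#' Default anti-VEGF medication names
#'
#' Generic and trade names for the intravitreal anti-VEGF agents whose
#' orders identify wet AMD treatment: ranibizumab (Lucentis), bevacizumab
#' (Avastin), aflibercept (Eylea).
#' @return Character vector of lower-case drug names.
#' @export
default_wet_medications <- function() {
  c("ranibizumab", "lucentis", "bevacizumab", "avastin",
    "aflibercept", "eylea")
}

#' Configure the HTCP phenotyping algorithm
#'
#' Bundles every code set and threshold the classifier uses. The defaults
#' are the reference configuration: AMD ICD-9 codes 362.50, 362.51, 362.52,
#' 362.16, 362.57 entered by an ophthalmologist; anti-VEGF HCPCS J-codes
#' J2778, J9035, J3490, J3590 (stored in the same namespace as CPT
#' procedure codes); a 362.5-prefix diagnosis required on the injection
#' date for wet status (V2); two distinct diagnosis dates and age >= 60 at
#' the first (V2); controls need an ophthalmology visit within the last
#' two years before `index_date`, age >= 60 at that visit, and no AMD or
#' AMD-associated diagnosis ever (the non-specific codes bare "362" and
#' "377.21" never disqualify).
#'
#' @param version `"V2"` (refined rules, default) or `"V1"` (pilot rules:
#'   one diagnosis suffices, no age gate, no same-date requirement).
#' @param index_date Query date anchoring the control lookback window; must
#'   be supplied explicitly (`Date` or ISO-8601 string).
#' @param amd_dx_codes [code_set()] of qualifying AMD diagnosis codes.
#' @param wet_proc_codes [code_set()] of anti-VEGF injection procedure codes.
#' @param wet_med_names Character vector of anti-VEGF drug names
#'   (case-insensitive).
#' @param wet_same_date_dx [code_set()] the injection-date diagnosis must
#'   match for wet status under V2.
#' @param min_amd_dx_dates Minimum distinct diagnosis dates for case status;
#'   defaults to 2 under V2, 1 under V1.
#' @param min_age_years Minimum age (completed years) at first AMD diagnosis
#'   (cases) and at the qualifying visit (controls).
#' @param control_lookback_years Length of the control visit window, ending
#'   at `index_date` (half-open: `(index_date - lookback, index_date]`).
#' @param control_exclusion_codes [code_set()] of diagnoses that disqualify
#'   a patient from control status; defaults to the AMD codes plus prefix
#'   362.5. Extend it with locally defined AMD-associated codes as needed.
#' @param require_ophthalmologist_dx Require `provider_specialty ==
#'   "OPHTHALMOLOGY"` on qualifying AMD diagnoses?
#' @return An object of class `htcp_config`.
#' @examples
#' cfg <- htcp_config(index_date = "2014-01-01")
#' @export
htcp_config <- function(version = c("V2", "V1"),
                        index_date,
                        amd_dx_codes = code_set(
                          "amd_dx",
                          exact = c("362.50", "362.51", "362.52",
                                    "362.16", "362.57")),
                        wet_proc_codes = code_set(
                          "wet_proc",
                          exact = c("J2778", "J9035", "J3490", "J3590")),
                        wet_med_names = default_wet_medications(),
                        wet_same_date_dx = code_set("wet_same_date_dx",
                                                    prefix = "362.5"),
                        min_amd_dx_dates = NULL,
                        min_age_years = 60,
                        control_lookback_years = 2,
                        control_exclusion_codes = NULL,
                        require_ophthalmologist_dx = TRUE) {
  version <- match.arg(version)
  if (missing(index_date) || is.null(index_date)) {
    stop("index_date must be set explicitly (no implicit 'today')",
         call. = FALSE)
  }
  index_date <- as.Date(index_date)
  if (is.na(index_date)) stop("invalid index_date", call. = FALSE)
  if (is.null(min_amd_dx_dates)) {
    min_amd_dx_dates <- if (version == "V2") 2L else 1L
  }
  if (min_amd_dx_dates < 1L) stop("min_amd_dx_dates must be >= 1",
                                  call. = FALSE)
  if (control_lookback_years <= 0) stop("control_lookback_years must be > 0",
                                        call. = FALSE)
  if (is.null(control_exclusion_codes)) {
    control_exclusion_codes <- code_set_union(
      amd_dx_codes, code_set("amd_spectrum", prefix = "362.5"),
      name = "control_exclusion")
  }
  structure(
    list(version = version,
         index_date = index_date,
         amd_dx_codes = amd_dx_codes,
         wet_proc_codes = wet_proc_codes,
         wet_med_names = tolower(trimws(wet_med_names)),
         wet_same_date_dx = wet_same_date_dx,
         min_amd_dx_dates = as.integer(min_amd_dx_dates),
         min_age_years = as.integer(min_age_years),
         control_lookback_years = control_lookback_years,
         control_exclusion_codes = control_exclusion_codes,
         require_ophthalmologist_dx = isTRUE(require_ophthalmologist_dx)),
    class = "htcp_config")
}

#' @export
print.htcp_config <- function(x, ...) {
  cat("<htcp_config>", x$version, "| index date", format(x$index_date),
      "| >=", x$min_amd_dx_dates, "dx date(s)",
      if (x$version == "V2") paste("| age >=", x$min_age_years), "\n")
  invisible(x)
}

# calendar shift by whole years (Feb 29 -> Feb 28 in non-leap years)
add_years <- function(date, years) {
  lt <- as.POSIXlt(date)
  lt$year <- lt$year + years
  out <- as.Date(lt)
  feb29 <- !is.na(date) & format(date, "%m-%d") == "02-29" & is.na(out)
  if (any(feb29)) {
    lt2 <- as.POSIXlt(date[feb29])
    lt2$year <- lt2$year + years
    lt2$mday <- 28
    out[feb29] <- as.Date(lt2)
  }
  out
}

#' Age in completed years at a date
#'
#' Floor-of-completed-years clinical convention: the day before the 60th
#' birthday counts as 59.
#'
#' @param birth_date,date `Date` vectors (recycled).
#' @return Integer vector of completed years.
#' @export
age_at <- function(birth_date, date) {
  birth_date <- as.Date(birth_date)
  date <- as.Date(date)
  if (any(date < birth_date)) {
    stop("date precedes birth_date", call. = FALSE)
  }
  by <- as.integer(format(birth_date, "%Y"))
  dy <- as.integer(format(date, "%Y"))
  had_birthday <- format(date, "%m%d") >= format(birth_date, "%m%d")
  # Feb 29 birthdays: anniversary taken as Mar 1 in non-leap years is the
  # conservative reading; "%m%d" comparison already yields that behaviour.
  as.integer(dy - by - !had_birthday)
}

# events for one patient, as a data.frame subset
events_for <- function(events, patient_id) {
  events[events$patient_id == patient_id, , drop = FALSE]
}

#' Distinct qualifying AMD diagnosis dates
#'
#' The distinct calendar dates on which a patient carries a DIAGNOSIS event
#' matching the configured AMD codes (and, if required, entered by an
#' ophthalmologist). Distinct dates stand in for distinct visits: EMRs
#' duplicate codes within an encounter.
#'
#' @param events Event table for a single patient.
#' @param config An [htcp_config()].
#' @return Sorted `Date` vector (possibly empty).
#' @export
amd_diagnosis_dates <- function(events, config) {
  dx <- events[events$kind == "DIAGNOSIS" &
                 code_matches(events$code, config$amd_dx_codes), ,
               drop = FALSE]
  if (config$require_ophthalmologist_dx) {
    dx <- dx[dx$provider_specialty == "OPHTHALMOLOGY", , drop = FALSE]
  }
  sort(unique(dx$event_date))
}

criterion <- function(name, satisfied, detail = "") {
  data.frame(criterion = name, satisfied = satisfied, detail = detail,
             stringsAsFactors = FALSE)
}

#' Case criterion: qualifying AMD diagnosis history
#'
#' V2: at least `min_amd_dx_dates` distinct qualifying diagnosis dates and
#' age at the first of them at least `min_age_years`. V1 (pilot): at least
#' one qualifying diagnosis, no age gate.
#'
#' @inheritParams amd_diagnosis_dates
#' @param patient One-row patient data frame.
#' @return Logical; `attr(, "evidence")` lists each evaluated criterion and
#'   `attr(, "first_amd_dx_date")` carries the first qualifying date.
#' @export
is_amd_case <- function(patient, events, config) {
  dates <- amd_diagnosis_dates(events, config)
  n_ok <- length(dates) >= config$min_amd_dx_dates
  ev <- criterion(sprintf(">=%d distinct AMD dx dates",
                          config$min_amd_dx_dates),
                  n_ok, sprintf("%d date(s)", length(dates)))
  age_ok <- TRUE
  if (config$version == "V2") {
    age <- if (length(dates)) age_at(patient$birth_date, dates[1]) else NA_integer_
    age_ok <- !is.na(age) && age >= config$min_age_years
    ev <- rbind(ev, criterion(
      sprintf("age >= %d at first AMD dx", config$min_age_years),
      age_ok, if (is.na(age)) "no dx" else sprintf("age %d", age)))
  }
  out <- n_ok && age_ok
  attr(out, "evidence") <- ev
  attr(out, "first_amd_dx_date") <- if (length(dates)) dates[1] else
    as.Date(NA)
  out
}

#' Wet-AMD criterion: anti-VEGF treatment evidence
#'
#' Treatment evidence is a PROCEDURE matching the injection J-codes or a
#' MEDICATION order matching the anti-VEGF drug names. Under V2 the
#' treatment date must also carry a diagnosis matching the 362.5x family;
#' under V1 any treatment event suffices. Only established cases should be
#' tested for wet status (see [classify_patient()]).
#'
#' @inheritParams is_amd_case
#' @return Logical with an `evidence` attribute.
#' @export
is_wet <- function(patient, events, config) {
  proc <- events$kind == "PROCEDURE" &
    code_matches(events$code, config$wet_proc_codes)
  med <- events$kind == "MEDICATION" &
    tolower(events$code) %in% config$wet_med_names
  rx_dates <- unique(events$event_date[proc | med])
  if (config$version == "V1") {
    out <- length(rx_dates) > 0L
    attr(out, "evidence") <- criterion("anti-VEGF injection or order", out,
                                       sprintf("%d date(s)", length(rx_dates)))
    return(out)
  }
  dx_dates <- unique(events$event_date[
    events$kind == "DIAGNOSIS" &
      code_matches(events$code, config$wet_same_date_dx)])
  hit <- rx_dates[rx_dates %in% dx_dates]
  out <- length(hit) > 0L
  attr(out, "evidence") <- rbind(
    criterion("anti-VEGF injection or order", length(rx_dates) > 0L,
              sprintf("%d date(s)", length(rx_dates))),
    criterion("362.5x diagnosis on treatment date", out,
              sprintf("%d matching date(s)", length(hit))))
  out
}

#' Control criterion: recent ophthalmology care without AMD codes
#'
#' A control has at least one ophthalmology-attributed event in the
#' half-open window `(index_date - lookback, index_date]`, is at least
#' `min_age_years` old at that event, and never carries a diagnosis
#' matching the control exclusion codes. Bare `"362"` and `"377.21"` are
#' deliberately absent from the default exclusion set.
#'
#' @inheritParams is_amd_case
#' @return Logical with an `evidence` attribute.
#' @export
is_control <- function(patient, events, config) {
  lb <- config$control_lookback_years
  lower <- if (lb == round(lb)) add_years(config$index_date, -as.integer(lb))
           else config$index_date - round(lb * 365.25)
  oph <- events[events$provider_specialty == "OPHTHALMOLOGY" &
                  events$event_date > lower &
                  events$event_date <= config$index_date, , drop = FALSE]
  visit_ok <- nrow(oph) > 0L
  age_ok <- visit_ok &&
    any(age_at(patient$birth_date, oph$event_date) >= config$min_age_years)
  excl <- events$kind == "DIAGNOSIS" &
    code_matches(events$code, config$control_exclusion_codes)
  no_amd <- !any(excl)
  out <- visit_ok && age_ok && no_amd
  attr(out, "evidence") <- rbind(
    criterion(sprintf("ophthalmology visit within %s y of index", lb),
              visit_ok, sprintf("%d event(s) in window", nrow(oph))),
    criterion(sprintf("age >= %d at qualifying visit", config$min_age_years),
              age_ok, ""),
    criterion("no AMD or AMD-associated diagnosis ever", no_amd,
              sprintf("%d disqualifying event(s)", sum(excl))))
  out
}

#' Classify one patient
#'
#' Case criteria are evaluated first; wet status is only tested for
#' established cases, so treatment codes alone never yield `WET_AMD`.
#' Cases failing the wet criteria are `DRY_AMD`; non-cases meeting the
#' control criteria are `CONTROL`; everyone else is `UNCLASSIFIED`.
#'
#' @inheritParams is_amd_case
#' @return A list of class `phenotype_label`: `label`,
#'   `first_amd_dx_date`, `evidence` (criteria with satisfied flags).
#' @export
classify_patient <- function(patient, events, config) {
  case <- is_amd_case(patient, events, config)
  evidence <- attr(case, "evidence")
  first_dx <- attr(case, "first_amd_dx_date")
  if (case) {
    wet <- is_wet(patient, events, config)
    evidence <- rbind(evidence, attr(wet, "evidence"))
    label <- if (wet) "WET_AMD" else "DRY_AMD"
  } else {
    ctrl <- is_control(patient, events, config)
    evidence <- rbind(evidence, attr(ctrl, "evidence"))
    label <- if (ctrl) "CONTROL" else "UNCLASSIFIED"
  }
  structure(list(label = label, first_amd_dx_date = first_dx,
                 evidence = evidence),
            class = "phenotype_label")
}

#' @export
print.phenotype_label <- function(x, ...) {
  cat("<phenotype_label>", x$label, "\n")
  print(x$evidence, row.names = FALSE)
  invisible(x)
}

#' Classify every patient in a cohort
#'
#' Deterministic and order-independent: the output is sorted by
#' `patient_id` and permuting the input rows does not change it.
#'
#' @param cohort An `emr_cohort` from [read_cohort()] or
#'   [simulate_cohort()], or a list with `patients` and `events`.
#' @param config An [htcp_config()].
#' @param include_evidence Add an `evidence_json` column (one JSON object
#'   per patient)? Off by default; linear cost in cohort size.
#' @return Data frame `patient_id`, `label`, `first_amd_dx_date` (and
#'   `evidence_json` on request), with a `counts` attribute: a named count
#'   per label summing to the cohort size.
#' @export
classify_cohort <- function(cohort, config, include_evidence = FALSE) {
  patients <- cohort$patients
  events <- cohort$events
  if (anyDuplicated(patients$patient_id)) {
    stop("duplicate patient_id in cohort", call. = FALSE)
  }
  patients <- patients[order(patients$patient_id), , drop = FALSE]
  n <- nrow(patients)
  birth <- patients$birth_date
  f <- match(events$patient_id, patients$patient_id)
  keep <- !is.na(f)
  events <- events[keep, , drop = FALSE]
  f <- f[keep]
  tab_any <- function(idx) tabulate(f[idx], nbins = n) > 0L

  # case criteria: distinct qualifying diagnosis dates, age at the first
  is_dx <- events$kind == "DIAGNOSIS"
  amd <- is_dx & code_matches(events$code, config$amd_dx_codes)
  if (config$require_ophthalmologist_dx) {
    amd <- amd & events$provider_specialty == "OPHTHALMOLOGY"
  }
  sub <- which(amd)
  sub <- sub[!duplicated(paste(f[sub], events$event_date[sub]))]
  n_dx <- tabulate(f[sub], nbins = n)
  first_dx <- rep(as.Date(NA), n)
  if (length(sub)) {
    agg <- tapply(as.numeric(events$event_date[sub]), f[sub], min)
    first_dx[as.integer(names(agg))] <- as.Date(as.numeric(agg),
                                                origin = "1970-01-01")
  }
  age_first <- rep(NA_integer_, n)
  hasdx <- !is.na(first_dx)
  if (any(hasdx)) age_first[hasdx] <- age_at(birth[hasdx], first_dx[hasdx])
  case <- n_dx >= config$min_amd_dx_dates
  if (config$version == "V2") {
    case <- case & !is.na(age_first) & age_first >= config$min_age_years
  }

  # wet criteria: treatment evidence (+ same-date 362.5x partner under V2)
  rx <- (events$kind == "PROCEDURE" &
           code_matches(events$code, config$wet_proc_codes)) |
    (events$kind == "MEDICATION" &
       tolower(events$code) %in% config$wet_med_names)
  if (config$version == "V1") {
    wet <- tab_any(which(rx))
  } else {
    partner <- is_dx & code_matches(events$code, config$wet_same_date_dx)
    key <- paste(f, events$event_date)
    wet <- tab_any(which(rx & key %in% key[partner]))
  }

  # control criteria: recent ophthalmology care, age, no exclusion dx
  lb <- config$control_lookback_years
  lower <- if (lb == round(lb)) add_years(config$index_date, -as.integer(lb))
           else config$index_date - round(lb * 365.25)
  win <- which(events$provider_specialty == "OPHTHALMOLOGY" &
                 events$event_date > lower &
                 events$event_date <= config$index_date)
  visit_ok <- tab_any(win)
  old_enough <- win[age_at(birth[f[win]], events$event_date[win]) >=
                      config$min_age_years]
  age_ok <- tab_any(old_enough)
  n_excl <- tabulate(
    f[is_dx & code_matches(events$code, config$control_exclusion_codes)],
    nbins = n)
  control <- visit_ok & age_ok & n_excl == 0L

  label <- ifelse(case, ifelse(wet, "WET_AMD", "DRY_AMD"),
                  ifelse(control, "CONTROL", "UNCLASSIFIED"))
  out <- data.frame(patient_id = patients$patient_id,
                    label = label,
                    first_amd_dx_date = first_dx,
                    stringsAsFactors = FALSE)
  if (include_evidence) {
    has_rx <- tab_any(which(rx))
    out$evidence_json <- vapply(seq_len(n), function(i) {
      ev <- if (case[i]) {
        data.frame(
          criterion = c(sprintf(">=%d distinct AMD dx dates",
                                config$min_amd_dx_dates),
                        sprintf("age >= %d at first AMD dx",
                                config$min_age_years),
                        "anti-VEGF injection or order",
                        "362.5x diagnosis on treatment date"),
          satisfied = c(TRUE, TRUE, has_rx[i], wet[i]),
          stringsAsFactors = FALSE)
      } else {
        data.frame(
          criterion = c(sprintf(">=%d distinct AMD dx dates",
                                config$min_amd_dx_dates),
                        "ophthalmology visit in lookback window",
                        sprintf("age >= %d at qualifying visit",
                                config$min_age_years),
                        "no AMD or AMD-associated diagnosis ever"),
          satisfied = c(n_dx[i] >= config$min_amd_dx_dates,
                        visit_ok[i], age_ok[i], n_excl[i] == 0L),
          stringsAsFactors = FALSE)
      }
      as.character(jsonlite::toJSON(ev, auto_unbox = TRUE))
    }, character(1))
  }
  counts <- table(factor(out$label, levels = PHENOTYPE_LABELS))
  attr(out, "counts") <- stats::setNames(as.integer(counts), names(counts))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
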