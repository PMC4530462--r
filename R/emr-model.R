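# Domain types and code-matching semantics for EMR extracts.
#
# Patients and clinical events are plain data frames with validated columns;
# diagnosis / procedure / medication codes live in a single string namespace
# (ICD-9 decimal strings, HCPCS Level II J-codes, normalized drug names).

EVENT_KINDS <- c("DIAGNOSIS", "PROCEDURE", "MEDICATION", "VISIT")
SPECIALTIES <- c("OPHTHALMOLOGY", "OTHER", "UNKNOWN")
SEX_LEVELS <- c("female", "male", "unknown")

#' Normalize a clinical code string
#'
#' Strips all whitespace and upper-cases the code, preserving decimal points.
#' ICD-9 codes are kept as decimal strings (`"362.50"`), never numbers, so
#' that `"362.50"` and `"362.5"` remain distinct. Idempotent.
#'
#' @param raw Character vector of raw codes.
#' @return Character vector of normalized codes.
#' @examples
#' normalize_code(c(" 362.50 ", "j2778"))
#' @export
normalize_code <- function(raw) {
  if (length(raw) == 0L) stop("malformed code: empty input", call. = FALSE)
  if (!is.character(raw)) raw <- as.character(raw)
  out <- toupper(gsub("[[:space:]]+", "", raw))
  if (anyNA(out) || any(!nzchar(out))) {
    stop("malformed code: blank or missing entries at position(s) ",
         paste(which(is.na(out) | !nzchar(out)), collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Build a set of clinical codes with exact or prefix matching
#'
#' A code set is a named collection of patterns, each matched either
#' exactly (`"362"` matches only the bare three-digit code) or as a prefix
#' (`"362.5"` matches `"362.50"` through `"362.57"`).
#'
#' @param name Short label for the set.
#' @param exact Character vector of exact-match patterns.
#' @param prefix Character vector of prefix-match patterns.
#' @return An object of class `code_set`.
#' @examples
#' amd <- code_set("amd_dx", exact = c("362.50", "362.51", "362.52"))
#' code_matches("362.51", amd)
#' @export
code_set <- function(name, exact = character(), prefix = character()) {
  if (length(exact) + length(prefix) == 0L) {
    stop("code set '", name, "' must contain at least one pattern",
         call. = FALSE)
  }
  norm <- function(x) toupper(gsub("[[:space:]]+", "", as.character(x)))
  exact <- if (length(exact)) normalize_code(exact) else character()
  prefix <- if (length(prefix)) norm(prefix) else character()
  if (any(!nzchar(prefix))) {
    warning("code set '", name,
            "' contains an empty prefix pattern; it matches every code",
            call. = FALSE)
  }
  structure(
    list(name = name,
         entries = rbind(
           if (length(exact)) data.frame(pattern = exact,
                                         match_mode = "EXACT",
                                         stringsAsFactors = FALSE),
           if (length(prefix)) data.frame(pattern = prefix,
                                          match_mode = "PREFIX",
                                          stringsAsFactors = FALSE))),
    class = "code_set")
}

#' @export
print.code_set <- function(x, ...) {
  cat("<code_set>", x$name, "\n")
  print(x$entries, row.names = FALSE)
  invisible(x)
}

#' Union of two code sets
#' @param a,b `code_set` objects.
#' @param name Name for the combined set.
#' @return A `code_set` containing all entries of both.
#' @export
code_set_union <- function(a, b, name = paste(a$name, b$name, sep = "+")) {
  stopifnot(inherits(a, "code_set"), inherits(b, "code_set"))
  entries <- unique(rbind(a$entries, b$entries))
  structure(list(name = name, entries = entries), class = "code_set")
}

#' Test codes against a code set
#'
#' `EXACT` entries require full-string equality; `PREFIX` entries match the
#' leading characters of the code. Vectorized over `code`.
#'
#' @param code Character vector of normalized codes (see [normalize_code()]).
#' @param set A [code_set()].
#' @return Logical vector, `TRUE` where any entry matches.
#' @export
code_matches <- function(code, set) {
  stopifnot(inherits(set, "code_set"))
  if (length(code) == 0L) return(logical())
  hit <- rep(FALSE, length(code))
  for (i in seq_len(nrow(set$entries))) {
    p <- set$entries$pattern[i]
    hit <- hit | if (set$entries$match_mode[i] == "EXACT") code == p
                 else startsWith(code, p)
  }
  hit
}

# ---- cohort tables ---------------------------------------------------------

patient_columns <- c("patient_id", "birth_date", "sex", "ancestry_european",
                     "bmi", "smoking_ever")
event_columns <- c("patient_id", "event_date", "kind", "code",
                   "provider_specialty")

parse_iso_date <- function(x, what, file = NULL) {
  d <- as.Date(as.character(x), format = "%Y-%m-%d")
  bad <- which(is.na(d) & !is.na(x) & nzchar(as.character(x)))
  if (length(bad)) {
    stop("load error", if (!is.null(file)) paste0(" in ", file),
         ": unparseable ", what, " at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) " ...", call. = FALSE)
  }
  d
}

check_columns <- function(df, required, file) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("load error in ", file, ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}

as_logical_flag <- function(x) {
  if (is.logical(x)) return(x)
  x <- tolower(as.character(x))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1", "yes")] <- TRUE
  out[x %in% c("false", "f", "0", "no")] <- FALSE
  out
}

#' Validate a patient table
#'
#' Checks column presence, ID uniqueness, date parsing and factor levels.
#'
#' @param patients Data frame with columns `patient_id`, `birth_date`,
#'   `sex`, `ancestry_european`, `bmi`, `smoking_ever`.
#' @return The validated data frame (dates as `Date`, flags as logical).
#' @export
validate_patients <- function(patients) {
  check_columns(patients, patient_columns, "patients table")
  patients$patient_id <- as.character(patients$patient_id)
  if (anyDuplicated(patients$patient_id)) {
    stop("duplicate patient_id: ",
         paste(unique(patients$patient_id[duplicated(patients$patient_id)]),
               collapse = ", "), call. = FALSE)
  }
  patients$birth_date <- parse_iso_date(patients$birth_date, "birth_date",
                                        "patients table")
  if (anyNA(patients$birth_date)) {
    stop("load error: missing birth_date", call. = FALSE)
  }
  bad_sex <- !patients$sex %in% SEX_LEVELS
  if (any(bad_sex)) {
    stop("invalid sex at row(s) ", paste(which(bad_sex), collapse = ", "),
         call. = FALSE)
  }
  patients$ancestry_european <- as_logical_flag(patients$ancestry_european)
  patients$smoking_ever <- as_logical_flag(patients$smoking_ever)
  patients$bmi <- suppressWarnings(as.numeric(patients$bmi))
  patients
}

#' Validate an event table against its patients
#'
#' Structural problems (unknown kind, unparseable date, blank code on a
#' coded event) raise an error. Rows violating the birth-order invariant
#' (event dated before the patient's birth) or referring to an unknown
#' patient are rejected and reported, not silently kept.
#'
#' @param events Data frame with columns `patient_id`, `event_date`, `kind`,
#'   `code`, `provider_specialty`.
#' @param patients A validated patient table, used to enforce that every
#'   event postdates its patient's birth.
#' @return The validated event table; rejected rows are attached as
#'   `attr(, "rejected")`, a data frame with a row number and reason.
#' @export
validate_events <- function(events, patients = NULL) {
  check_columns(events, event_columns, "events table")
  events$patient_id <- as.character(events$patient_id)
  events$event_date <- parse_iso_date(events$event_date, "event_date",
                                      "events table")
  bad_kind <- !events$kind %in% EVENT_KINDS
  if (any(bad_kind)) {
    stop("invalid event kind at row(s) ",
         paste(which(bad_kind), collapse = ", "), call. = FALSE)
  }
  bad_spec <- !events$provider_specialty %in% SPECIALTIES
  if (any(bad_spec)) {
    stop("invalid provider_specialty at row(s) ",
         paste(which(bad_spec), collapse = ", "), call. = FALSE)
  }
  events$code <- as.character(events$code)
  events$code[is.na(events$code)] <- ""
  coded <- events$kind != "VISIT"
  if (any(coded & !nzchar(gsub("[[:space:]]", "", events$code)))) {
    stop("blank code on non-VISIT event at row(s) ",
         paste(which(coded & !nzchar(gsub("[[:space:]]", "", events$code))),
               collapse = ", "), call. = FALSE)
  }
  # billing codes are uppercased; medication names are free-text drug
  # names and normalize to lower case instead
  med <- events$kind == "MEDICATION"
  events$code[coded & !med] <- normalize_code(events$code[coded & !med])
  events$code[med] <- tolower(trimws(events$code[med]))
  events$code[!coded] <- ""

  rejected <- data.frame(row = integer(), reason = character(),
                         stringsAsFactors = FALSE)
  if (!is.null(patients)) {
    idx <- match(events$patient_id, patients$patient_id)
    unknown <- which(is.na(idx))
    before_birth <- which(!is.na(idx) &
                            events$event_date < patients$birth_date[idx])
    if (length(unknown)) {
      rejected <- rbind(rejected,
                        data.frame(row = unknown, reason = "unknown patient_id",
                                   stringsAsFactors = FALSE))
    }
    if (length(before_birth)) {
      rejected <- rbind(rejected,
                        data.frame(row = before_birth,
                                   reason = "event_date precedes birth_date",
                                   stringsAsFactors = FALSE))
    }
    if (nrow(rejected)) {
      events <- events[-rejected$row, , drop = FALSE]
      rownames(events) <- NULL
    }
  }
  attr(events, "rejected") <- rejected
  events
}

#' Read an EMR cohort from CSV extracts
#'
#' @param patients_path Path to `patients.csv`
#'   (`patient_id,birth_date,sex,ancestry_european,bmi,smoking_ever`,
#'   dates ISO-8601).
#' @param events_path Path to `events.csv`
#'   (`patient_id,event_date,kind,code,provider_specialty`).
#' @return A list of class `emr_cohort` with elements `patients`, `events`;
#'   rows rejected by invariant checks are reported via
#'   `attr(cohort$events, "rejected")`.
#' @export
read_cohort <- function(patients_path, events_path) {
  for (p in c(patients_path, events_path)) {
    if (!file.exists(p)) stop("load error: file not found: ", p, call. = FALSE)
  }
  patients <- utils::read.csv(patients_path, colClasses = "character")
  events <- utils::read.csv(events_path, colClasses = "character")
  patients <- validate_patients(patients)
  events <- validate_events(events, patients)
  structure(list(patients = patients, events = events), class = "emr_cohort")
}

#' Write an EMR cohort to CSV extracts
#'
#' Inverse of [read_cohort()]; a write-then-read round trip preserves all
#' fields.
#'
#' @param cohort An `emr_cohort` (or list with `patients` and `events`).
#' @param dir Output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pp <- file.path(dir, "patients.csv")
  ep <- file.path(dir, "events.csv")
  p <- cohort$patients
  p$birth_date <- format(p$birth_date, "%Y-%m-%d")
  e <- cohort$events
  e$event_date <- format(e$event_date, "%Y-%m-%d")
  utils::write.csv(p[patient_columns], pp, row.names = FALSE, na = "")
  utils::write.csv(e[event_columns], ep, row.names = FALSE, na = "")
  invisible(c(patients = pp, events = ep))
}

#' @export
print.emr_cohort <- function(x, ...) {
  cat("<emr_cohort>", nrow(x$patients), "patients,",
      nrow(x$events), "events\n")
  invisible(x)
}
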