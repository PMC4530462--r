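# Synthetic EMR cohort generator with planted ground truth.
#
# Emulates the kind of EMR-linked biorepository the phenotyper targets:
# true dry and wet AMD patients, mimicker retinal diseases that generate
# the documented confusion modes (diabetic retinopathy, pattern dystrophy,
# central serous chorioretinopathy, polypoidal choroidal vasculopathy,
# macular scar), and healthy patients with routine ophthalmology care.
# Coding noise is configurable: AMD miscoding of mimickers, missed second
# diagnosis dates, injections without a same-date 362.5x code, diagnoses
# entered by non-ophthalmologists.
#
# Each patient consumes an independent RNG stream derived from
# (seed, patient index), so growing n extends a cohort instead of
# reshuffling it, and noise-rate changes perturb only the patients they
# touch.

MIMICKER_CODES <- c(
  diabetic_retinopathy = "362.02",
  pattern_dystrophy = "362.76",
  central_serous_chorioretinopathy = "362.41",
  polypoidal_choroidal_vasculopathy = "362.43",
  macular_scar = "363.32")

DRY_AMD_CODES <- c("362.50", "362.51", "362.57")
WET_AMD_CODES <- c("362.52", "362.16")
AMD_DX_CODES <- c("362.50", "362.51", "362.52", "362.16", "362.57")
WET_PROC_CODES <- c("J2778", "J9035", "J3490", "J3590")

#' Configure the synthetic EMR cohort generator
#'
#' Defaults describe an ophthalmology-enriched biorepository: 3.5% true
#' AMD (dry-leaning), 3% mimicker retinal disease, the rest healthy; ages
#' from a truncated normal spanning 40-95 so the age gates are exercised,
#' with true AMD restricted to older patients (AMD is age-related, and
#' case-control age gaps of ~9 years are typical of such cohorts); modest
#' coding noise.
#'
#' @param n_patients Cohort size.
#' @param seed Mandatory integer seed.
#' @param index_date Query date; all events fall in the preceding 10 years.
#' @param age_distribution Named numeric: `mean`, `sd`, `min`, `max` years.
#' @param prevalence Named probabilities for `true_dry`, `true_wet`,
#'   `mimicker`, `healthy`; must sum to 1.
#' @param mimicker_types Subset of `names(MIMICKER_CODES)` to draw from.
#' @param p_miscode_amd Probability a mimicker also receives AMD ICD-9
#'   codes (a polypoidal choroidal vasculopathy mimicker additionally
#'   receives wet-like injection coding).
#' @param p_missed_second_visit Probability a true case has only one coded
#'   AMD diagnosis date.
#' @param p_injection_coded_same_date Probability an injection carries a
#'   same-date 362.5x diagnosis.
#' @param visit_rate Mean ophthalmology visits per patient-year.
#' @param p_specialty_other Probability a diagnosis is attributed to a
#'   non-ophthalmology provider.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_patients,
                       seed,
                       index_date = as.Date("2014-01-01"),
                       age_distribution = c(mean = 70, sd = 12,
                                            min = 40, max = 95),
                       prevalence = c(true_dry = 0.020, true_wet = 0.015,
                                      mimicker = 0.030, healthy = 0.935),
                       mimicker_types = names(MIMICKER_CODES),
                       p_miscode_amd = 0.05,
                       p_missed_second_visit = 0.10,
                       p_injection_coded_same_date = 0.90,
                       visit_rate = 1.5,
                       p_specialty_other = 0.05) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  probs <- c(p_miscode_amd, p_missed_second_visit,
             p_injection_coded_same_date, p_specialty_other)
  if (any(probs < 0 | probs > 1)) {
    stop("config error: probabilities must lie in [0, 1]", call. = FALSE)
  }
  need <- c("true_dry", "true_wet", "mimicker", "healthy")
  if (!all(need %in% names(prevalence)) ||
      abs(sum(prevalence[need]) - 1) > 1e-8 || any(prevalence[need] < 0)) {
    stop("config error: prevalence must be non-negative over ",
         paste(need, collapse = "/"), " and sum to 1", call. = FALSE)
  }
  stopifnot(all(mimicker_types %in% names(MIMICKER_CODES)),
            visit_rate >= 0, n_patients >= 1)
  structure(list(
    n_patients = as.integer(n_patients), seed = as.integer(seed),
    index_date = as.Date(index_date),
    age_distribution = age_distribution,
    prevalence = prevalence[need],
    mimicker_types = mimicker_types,
    p_miscode_amd = p_miscode_amd,
    p_missed_second_visit = p_missed_second_visit,
    p_injection_coded_same_date = p_injection_coded_same_date,
    visit_rate = visit_rate,
    p_specialty_other = p_specialty_other),
    class = "sim_config")
}

# deterministic 32-bit stream seed for patient/replicate i under master seed
stream_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + as.double(i) * 16807) %% 2147483647)
}

# run expr with a temporary RNG state seeded at `seed`
with_stream <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

rtnorm1 <- function(mean, sd, lo, hi) {
  stats::qnorm(stats::runif(1, stats::pnorm(lo, mean, sd),
                            stats::pnorm(hi, mean, sd)), mean, sd)
}

# expected output of the reference V2 rules, computed by direct arithmetic
# on one patient's events (independent of the phenotyper implementation)
reference_expected_label <- function(ev, birth, index) {
  is_amd_dx <- ev$kind == "DIAGNOSIS" & ev$code %in% AMD_DX_CODES &
    ev$specialty == "OPHTHALMOLOGY"
  dxd <- sort(unique(ev$date[is_amd_dx]))
  case <- length(dxd) >= 2 && age_at(birth, dxd[1]) >= 60
  if (case) {
    rx <- ev$date[(ev$kind == "PROCEDURE" & ev$code %in% WET_PROC_CODES) |
                    (ev$kind == "MEDICATION" &
                       tolower(ev$code) %in% default_wet_medications())]
    partner <- ev$date[ev$kind == "DIAGNOSIS" &
                         startsWith(ev$code, "362.5")]
    return(if (length(intersect(rx, partner))) "WET_AMD" else "DRY_AMD")
  }
  lower <- add_years(index, -2L)
  oph <- ev$date[ev$specialty == "OPHTHALMOLOGY" &
                   ev$date > lower & ev$date <= index]
  visit_ok <- length(oph) > 0 && any(age_at(birth, oph) >= 60)
  disq <- any(ev$kind == "DIAGNOSIS" &
                (ev$code %in% AMD_DX_CODES | startsWith(ev$code, "362.5")))
  if (visit_ok && !disq) "CONTROL" else "UNCLASSIFIED"
}

#' Simulate an EMR cohort with planted phenotypes
#'
#' Deterministic given the config seed; byte-identical on repeated calls,
#' and the first `k` patients of an `n`-patient cohort equal the `k`-patient
#' cohort under the same seed.
#'
#' @param config A [sim_config()].
#' @return A list of class `emr_cohort` with `patients`, `events`, and
#'   `truth` (columns `patient_id`, `true_phenotype`, `mimicker_type`,
#'   `expected_label`). `expected_label` is the output the reference V2
#'   rules should give this patient's realized (noise-included) record,
#'   derived arithmetically by the generator.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  index <- config$index_date
  window_days <- 3652L            # 10 years of history
  ad <- config$age_distribution
  prev <- cumsum(config$prevalence)
  n <- config$n_patients

  pts <- vector("list", n)
  evs <- vector("list", n)

  for (i in seq_len(n)) {
    rec <- with_stream(stream_seed(config$seed, i), {
      pid <- sprintf("S%05d", i)
      u <- stats::runif(1)
      cls <- c("TRUE_DRY", "TRUE_WET", "MIMICKER", "HEALTHY")[
        findInterval(u, prev, left.open = TRUE) + 1L]
      mtype <- if (cls == "MIMICKER") sample(config$mimicker_types, 1)
               else NA_character_
      is_case <- cls %in% c("TRUE_DRY", "TRUE_WET")
      lo <- if (is_case) max(62, ad[["min"]]) else ad[["min"]]
      age <- floor(rtnorm1(ad[["mean"]], ad[["sd"]], lo, ad[["max"]]))
      birth <- add_years(index, -as.integer(age)) -
        (sample.int(365L, 1) - 1L)
      sex <- sample(c("female", "male"), 1, prob = c(0.7, 0.3))
      ancestry <- stats::runif(1) < 0.85
      bmi <- round(min(50, max(16, stats::rnorm(1, 27, 4.5))), 1)
      smoking <- stats::runif(1) < 0.5

      date <- numeric(0); kind <- character(0)
      code <- character(0); spec <- character(0)
      push <- function(d, k, c_, s) {
        date <<- c(date, as.numeric(d)); kind <<- c(kind, k)
        code <<- c(code, c_); spec <<- c(spec, s)
      }
      rdates <- function(m, min_offset = 0L, max_offset = window_days - 1L) {
        if (m <= 0 || max_offset < min_offset) return(as.Date(character()))
        pool <- min_offset:max_offset
        index - sample(pool, min(m, length(pool)))
      }
      dx_spec <- function(m) ifelse(stats::runif(m) < config$p_specialty_other,
                                    "OTHER", "OPHTHALMOLOGY")

      # routine ophthalmology visits over the 10-year window
      n_vis <- stats::rpois(1, config$visit_rate * 10)
      vis_dates <- rdates(n_vis)
      for (d in as.list(vis_dates)) push(d, "VISIT", "", "OPHTHALMOLOGY")

      # qualifying AMD diagnosis dates are only coded at ages >= 60
      min_off_60 <- 0L
      date60 <- add_years(birth, 60L)
      min_off_60 <- max(0L, as.integer(index - date60) - (window_days - 1L))
      max_off_60 <- min(window_days - 1L, as.integer(index - date60))

      plant_amd_dx <- function(codeset) {
        n_dx <- if (stats::runif(1) < config$p_missed_second_visit) 1L
                else 2L + stats::rpois(1, 1)
        dd <- rdates(n_dx, 0L, max_off_60)
        sp <- dx_spec(length(dd))
        cc <- sample(codeset, length(dd), replace = TRUE)
        for (j in seq_along(dd)) push(dd[j], "DIAGNOSIS", cc[j], sp[j])
        dd
      }
      plant_injections <- function(n_inj) {
        dd <- rdates(n_inj, 0L, max_off_60)
        for (j in seq_along(dd)) {
          if (stats::runif(1) < 0.5) {
            push(dd[j], "PROCEDURE", sample(WET_PROC_CODES, 1),
                 "OPHTHALMOLOGY")
          } else {
            push(dd[j], "MEDICATION",
                 sample(c("ranibizumab", "bevacizumab", "aflibercept"), 1),
                 "OPHTHALMOLOGY")
          }
          if (stats::runif(1) < config$p_injection_coded_same_date) {
            push(dd[j], "DIAGNOSIS", "362.52", dx_spec(1))
          }
        }
        dd
      }

      if (cls == "TRUE_DRY") {
        plant_amd_dx(DRY_AMD_CODES)
      } else if (cls == "TRUE_WET") {
        plant_amd_dx(WET_AMD_CODES)
        plant_injections(1L + stats::rpois(1, 2))
      } else if (cls == "MIMICKER") {
        md <- rdates(1L + stats::rpois(1, 1))
        for (d in as.list(md)) push(d, "DIAGNOSIS", MIMICKER_CODES[[mtype]],
                                    "OPHTHALMOLOGY")
        if (stats::runif(1) < config$p_miscode_amd) {
          if (age >= 61 && max_off_60 >= 1L) plant_amd_dx(DRY_AMD_CODES)
          else {
            d <- rdates(1L)
            if (length(d)) push(d, "DIAGNOSIS", sample(DRY_AMD_CODES, 1),
                                dx_spec(1))
          }
          if (mtype == "polypoidal_choroidal_vasculopathy") {
            plant_injections(1L + stats::rpois(1, 1))
          }
        }
      } else {                                   # HEALTHY
        if (length(vis_dates)) {
          if (stats::runif(1) < 0.6) {
            push(vis_dates[1], "DIAGNOSIS", "366.16", "OPHTHALMOLOGY")
          }
          if (stats::runif(1) < 0.15) {
            push(vis_dates[length(vis_dates)], "DIAGNOSIS", "362",
                 "OPHTHALMOLOGY")
          }
          if (stats::runif(1) < 0.08) {
            push(vis_dates[1], "DIAGNOSIS", "377.21", "OPHTHALMOLOGY")
          }
        }
      }

      ev <- list(date = as.Date(date, origin = "1970-01-01"),
                 kind = kind, code = code,
                 specialty = spec)
      expected <- reference_expected_label(ev, birth, index)
      list(pid = pid, birth = birth, sex = sex, ancestry = ancestry,
           bmi = bmi, smoking = smoking, ev = ev,
           cls = cls, mtype = mtype, expected = expected)
    })
    pts[[i]] <- rec
    evs[[i]] <- rec$ev
  }

  patients <- data.frame(
    patient_id = vapply(pts, `[[`, character(1), "pid"),
    birth_date = as.Date(vapply(pts, function(r) as.numeric(r$birth),
                                numeric(1)), origin = "1970-01-01"),
    sex = vapply(pts, `[[`, character(1), "sex"),
    ancestry_european = vapply(pts, `[[`, logical(1), "ancestry"),
    bmi = vapply(pts, `[[`, numeric(1), "bmi"),
    smoking_ever = vapply(pts, `[[`, logical(1), "smoking"),
    stringsAsFactors = FALSE)
  n_ev <- vapply(evs, function(e) length(e$date), integer(1))
  events <- data.frame(
    patient_id = rep(patients$patient_id, n_ev),
    event_date = as.Date(unlist(lapply(evs, function(e) as.numeric(e$date))),
                         origin = "1970-01-01"),
    kind = unlist(lapply(evs, `[[`, "kind")),
    code = unlist(lapply(evs, `[[`, "code")),
    provider_specialty = unlist(lapply(evs, `[[`, "specialty")),
    stringsAsFactors = FALSE)
  events <- events[order(events$patient_id, events$event_date,
                         events$kind, events$code), , drop = FALSE]
  rownames(events) <- rownames(patients) <- NULL
  truth <- data.frame(
    patient_id = patients$patient_id,
    true_phenotype = vapply(pts, `[[`, character(1), "cls"),
    mimicker_type = vapply(pts, `[[`, character(1), "mtype"),
    expected_label = vapply(pts, `[[`, character(1), "expected"),
    stringsAsFactors = FALSE)
  structure(list(patients = patients, events = events, truth = truth),
            class = "emr_cohort")
}

#' Map planted phenotypes to expert chart-review labels
#'
#' `TRUE_DRY` -> `DRY_AMD`, `TRUE_WET` -> `WET_AMD`, mimickers and healthy
#' patients -> `NOT_AMD`.
#'
#' @param truth Truth table from [simulate_cohort()] (or a character vector
#'   of `true_phenotype` values).
#' @return Character vector of expert labels (with `patient_id` names when
#'   a truth table is given).
#' @export
truth_to_expert_labels <- function(truth) {
  pheno <- if (is.data.frame(truth)) truth$true_phenotype else truth
  out <- ifelse(pheno == "TRUE_DRY", "DRY_AMD",
                ifelse(pheno == "TRUE_WET", "WET_AMD", "NOT_AMD"))
  if (is.data.frame(truth)) names(out) <- truth$patient_id
  out
}

#' Pair algorithm output with planted expert labels
#'
#' Builds a [labeled_pairs()] table for the patients the algorithm
#' classified (UNCLASSIFIED patients are omitted, mirroring a chart review
#' that only sees algorithm-selected charts).
#'
#' @param labels Output of [classify_cohort()].
#' @param truth Truth table from [simulate_cohort()].
#' @return A [labeled_pairs()] table.
#' @export
truth_pairs <- function(labels, truth) {
  keep <- labels$label != "UNCLASSIFIED"
  expert <- truth_to_expert_labels(truth)
  labeled_pairs(labels$patient_id[keep],
                labels$label[keep],
                unname(expert[labels$patient_id[keep]]))
}

#' Write a simulated cohort (with truth) to a directory
#' @param cohort Result of [simulate_cohort()].
#' @param dir Output directory.
#' @return Invisibly, the file paths.
#' @export
write_simulated_cohort <- function(cohort, dir) {
  paths <- write_cohort(cohort, dir)
  tp <- file.path(dir, "truth.csv")
  utils::write.csv(cohort$truth, tp, row.names = FALSE, na = "")
  invisible(c(paths, truth = tp))
}
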