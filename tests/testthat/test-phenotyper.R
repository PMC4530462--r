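test_that("age_at uses completed whole years with birthday boundaries", {
  expect_equal(age_at("1950-06-01", "2010-05-31"), 59L)
  expect_equal(age_at("1950-06-01", "2010-06-01"), 60L)
  expect_equal(age_at("1940-01-01", "2014-12-31"), 74L)
  expect_error(age_at("1950-06-01", "1949-01-01"), "precedes")
  # vectorized, and leap-day births resolve conservatively
  expect_equal(age_at(as.Date(c("1952-02-29", "1952-02-29")),
                      as.Date(c("2012-02-28", "2012-02-29"))),
               c(59L, 60L))
})

test_that("diagnosis dates are distinct, specialty-filtered, sorted", {
  cfg <- v2_cfg()
  e <- ev_bind(
    make_events("a", c("2013-03-04", "2013-03-04"), "DIAGNOSIS", "362.51"),
    make_events("a", "2012-01-01", "DIAGNOSIS", "362.50", "OTHER"),
    make_events("a", "2011-06-15", "DIAGNOSIS", "362.57"),
    make_events("a", "2012-08-20", "DIAGNOSIS", "362.16"),
    make_events("a", "2013-05-01", "DIAGNOSIS", "365.11"))
  d <- amd_diagnosis_dates(e, cfg)
  expect_equal(d, as.Date(c("2011-06-15", "2012-08-20", "2013-03-04")))
  cfg_any <- v2_cfg(require_ophthalmologist_dx = FALSE)
  expect_length(amd_diagnosis_dates(e, cfg_any), 4L)
})

test_that("case criteria: date count and age gate, V1 vs V2", {
  p <- make_patients("a", "1952-06-01")  # 60 on 2012-06-01
  two_dx <- ev_bind(
    make_events("a", "2012-05-30", "DIAGNOSIS", "362.50"),
    make_events("a", "2013-02-01", "DIAGNOSIS", "362.51"))
  # age 59 at first dx: V2 fails on the age gate
  expect_false(is_amd_case(p, two_dx, v2_cfg()))
  # same history, first dx moved past the 60th birthday: V2 passes
  later <- two_dx
  later$event_date[1] <- as.Date("2012-06-02")
  expect_true(is_amd_case(p, later, v2_cfg()))
  # one date: V2 fails, V1 passes
  one_dx <- make_events("a", "2013-02-01", "DIAGNOSIS", "362.51")
  expect_false(is_amd_case(p, one_dx, v2_cfg()))
  expect_true(is_amd_case(p, one_dx, v1_cfg()))
  ev <- attr(is_amd_case(p, two_dx, v2_cfg()), "evidence")
  expect_true(any(grepl("distinct AMD dx dates", ev$criterion)))
  expect_true(any(grepl("age >=", ev$criterion)))
})

test_that("wet criterion needs a same-date 362.5x partner under V2 only", {
  p <- make_patients("a", "1940-01-01")
  base <- ev_bind(
    make_events("a", "2012-01-10", "DIAGNOSIS", "362.52"),
    make_events("a", "2013-03-04", "DIAGNOSIS", "362.52"))
  same_day <- rbind(base, make_events("a", "2013-03-04", "PROCEDURE", "J2778"))
  expect_true(is_wet(p, same_day, v2_cfg()))
  # nearest 362.5x diagnosis one day away: V2 false, V1 true
  off_day <- rbind(base, make_events("a", "2013-03-05", "PROCEDURE", "J2778"))
  expect_false(is_wet(p, off_day, v2_cfg()))
  expect_true(is_wet(p, off_day, v1_cfg()))
  # medication order with only a same-date 362.16 (fails the 362.5 prefix)
  med <- ev_bind(
    make_events("a", "2012-01-10", "DIAGNOSIS", "362.16"),
    make_events("a", "2013-03-04", "DIAGNOSIS", "362.16"),
    make_events("a", "2013-03-04", "MEDICATION", "bevacizumab"))
  expect_false(is_wet(p, med, v2_cfg()))
  expect_true(is_wet(p, med, v1_cfg()))
})

test_that("control criteria: lookback window, age, exclusion whitelist", {
  p <- make_patients("a", "1945-01-01")
  visit <- function(d) make_events("a", d, "VISIT", "")
  # recent visit + only a 377.21 diagnosis: still a control
  ok <- rbind(visit("2013-01-15"),
              make_events("a", "2013-01-15", "DIAGNOSIS", "377.21"))
  expect_true(is_control(p, ok, v2_cfg()))
  # bare 362 is also whitelisted
  ok2 <- rbind(visit("2013-01-15"),
               make_events("a", "2010-05-01", "DIAGNOSIS", "362"))
  expect_true(is_control(p, ok2, v2_cfg()))
  # visit outside the two-year window
  expect_false(is_control(p, visit("2011-06-01"), v2_cfg()))
  # window is half-open: exactly two years before index is excluded
  expect_false(is_control(p, visit("2012-01-01"), v2_cfg()))
  expect_true(is_control(p, visit("2012-01-02"), v2_cfg()))
  # a single AMD diagnosis ever disqualifies
  one_amd <- rbind(visit("2013-01-15"),
                   make_events("a", "2006-03-01", "DIAGNOSIS", "362.50",
                               "OTHER"))
  expect_false(is_control(p, one_amd, v2_cfg()))
  # too young at the qualifying visit
  young <- make_patients("y", "1980-01-01")
  yv <- make_events("y", "2013-01-15", "VISIT", "")
  expect_false(is_control(young, yv, v2_cfg()))
})

test_that("classification precedence and the UNCLASSIFIED fallthrough", {
  cfg <- v2_cfg()
  # established dry case: case criteria met, no injections
  p <- make_patients("a", "1940-01-01")
  dry <- ev_bind(
    make_events("a", "2012-01-10", "DIAGNOSIS", "362.50"),
    make_events("a", "2013-03-04", "DIAGNOSIS", "362.51"))
  expect_equal(classify_patient(p, dry, cfg)$label, "DRY_AMD")
  # 70-year-old with recent visit and no AMD codes
  ctl <- make_events("a", "2013-06-01", "VISIT", "")
  expect_equal(classify_patient(p, ctl, cfg)$label, "CONTROL")
  # 45-year-old with 2 AMD dx dates: fails case age gate AND control gate
  young <- make_patients("b", "1968-06-01")
  ydx <- ev_bind(
    make_events("b", "2012-01-10", "DIAGNOSIS", "362.50"),
    make_events("b", "2013-03-04", "DIAGNOSIS", "362.51"),
    make_events("b", "2013-03-04", "VISIT", ""))
  expect_equal(classify_patient(young, ydx, cfg)$label, "UNCLASSIFIED")
  # injections without case status never yield WET_AMD
  inj_only <- ev_bind(
    make_events("c", "2013-03-04", "PROCEDURE", "J2778"),
    make_events("c", "2013-03-04", "DIAGNOSIS", "362.52"))
  pc <- make_patients("c", "1940-01-01")
  expect_false(classify_patient(pc, inj_only, cfg)$label == "WET_AMD")
})

test_that("classify_cohort is order-independent and matches classify_patient", {
  co <- simulate_cohort(sim_config(n_patients = 120, seed = 11))
  cfg <- v2_cfg()
  lab <- classify_cohort(co, cfg)
  expect_equal(nrow(lab), 120L)
  expect_equal(sum(attr(lab, "counts")), 120L)
  # permuted inputs give identical output
  perm <- list(patients = co$patients[sample.int(120), ],
               events = co$events[sample.int(nrow(co$events)), ])
  expect_equal(classify_cohort(perm, cfg), lab, ignore_attr = TRUE)
  # vectorized path agrees with the per-patient path
  for (pid in sample(co$patients$patient_id, 25)) {
    pl <- classify_patient(
      co$patients[co$patients$patient_id == pid, , drop = FALSE],
      co$events[co$events$patient_id == pid, , drop = FALSE], cfg)
    expect_equal(pl$label, lab$label[lab$patient_id == pid])
  }
  dup <- list(patients = rbind(co$patients, co$patients[1, ]),
              events = co$events)
  expect_error(classify_cohort(dup, cfg), "duplicate")
  # empty cohort
  empty <- list(patients = co$patients[0, ], events = co$events[0, ])
  expect_equal(nrow(classify_cohort(empty, cfg)), 0L)
})

test_that("adding AMD diagnoses is monotone: never case -> control", {
  cfg <- v2_cfg()
  co <- simulate_cohort(sim_config(n_patients = 150, seed = 21))
  lab <- classify_cohort(co, cfg)
  extra <- make_events(co$patients$patient_id, "2013-09-09", "DIAGNOSIS",
                       "362.50")
  lab2 <- classify_cohort(list(patients = co$patients,
                               events = rbind(co$events, extra)), cfg)
  was_case <- lab$label %in% c("WET_AMD", "DRY_AMD")
  expect_true(all(lab2$label[was_case] %in% c("WET_AMD", "DRY_AMD")))
  expect_false(any(lab2$label == "CONTROL"))  # everyone now carries AMD codes
})

test_that("V2 cases are a subset of V1 cases on noisy cohorts", {
  co <- simulate_cohort(sim_config(n_patients = 400, seed = 31,
                                   p_miscode_amd = 0.3,
                                   p_missed_second_visit = 0.3,
                                   p_injection_coded_same_date = 0.5,
                                   p_specialty_other = 0.2))
  v2 <- classify_cohort(co, v2_cfg())
  v1 <- classify_cohort(co, v1_cfg())
  case2 <- v2$patient_id[v2$label %in% c("WET_AMD", "DRY_AMD")]
  case1 <- v1$patient_id[v1$label %in% c("WET_AMD", "DRY_AMD")]
  expect_true(all(case2 %in% case1))
  expect_gt(length(case1), length(case2))
})
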