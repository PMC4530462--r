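# In-code builders for tiny EMR fixtures.

make_patients <- function(ids, births, sex = "female",
                          ancestry = TRUE, bmi = 27, smoking = FALSE) {
  data.frame(patient_id = ids, birth_date = as.Date(births),
             sex = sex, ancestry_european = ancestry, bmi = bmi,
             smoking_ever = smoking, stringsAsFactors = FALSE)
}

make_events <- function(ids, dates, kind, code = "",
                        specialty = "OPHTHALMOLOGY") {
  data.frame(patient_id = ids, event_date = as.Date(dates), kind = kind,
             code = code, provider_specialty = specialty,
             stringsAsFactors = FALSE)
}

ev_bind <- function(...) do.call(rbind, list(...))

v2_cfg <- function(...) htcp_config(index_date = "2014-01-01", ...)
v1_cfg <- function(...) htcp_config(version = "V1",
                                    index_date = "2014-01-01", ...)

# brute-force PPV/NPV/FNR by counting raw pairs (oracle for binary_metrics)
brute_metrics <- function(pairs, pos_alg, pos_exp) {
  test_pos <- pairs$algorithm_label %in% pos_alg
  dis_pos <- pairs$expert_label %in% pos_exp
  tp <- sum(test_pos & dis_pos); fp <- sum(test_pos & !dis_pos)
  fn <- sum(!test_pos & dis_pos); tn <- sum(!test_pos & !dis_pos)
  list(ppv = tp / (tp + fp), npv = tn / (tn + fn), fnr = fn / (fn + tp),
       tp = tp, fp = fp, tn = tn, fn = fn)
}

random_pairs <- function(n) {
  labeled_pairs(sprintf("c%d", seq_len(n)),
                sample(c("DRY_AMD", "WET_AMD", "CONTROL"), n, TRUE),
                sample(c("DRY_AMD", "WET_AMD", "NOT_AMD"), n, TRUE))
}
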