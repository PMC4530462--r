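# End-to-end orchestration: simulate -> phenotype -> validate -> associate,
# with a run manifest for reproducibility. The same functions back the
# thin command-line wrapper shipped in inst/cli/htcp.R.

#' Default pipeline configuration
#'
#' The reference configuration: the published code sets and thresholds for
#' the phenotyper, the default synthetic-cohort conditions, and the
#' candidate-SNP association settings (11-test Bonferroni family at
#' family-wise alpha 0.05).
#'
#' @param seed Master seed for every stochastic stage.
#' @param n_patients Synthetic cohort size.
#' @param index_date Query date.
#' @return Nested configuration list (serializable to YAML).
#' @export
default_pipeline_config <- function(seed = 1L, n_patients = 2000L,
                                    index_date = "2014-01-01") {
  list(
    seed = as.integer(seed),
    index_date = as.character(index_date),
    simulate = list(n_patients = as.integer(n_patients)),
    phenotype = list(version = "V2", min_age_years = 60,
                     min_amd_dx_dates = 2, control_lookback_years = 2,
                     require_ophthalmologist_dx = TRUE),
    associate = list(raf_population = 0.363, or_per_allele = 2.43,
                     prevalence = 0.05, alpha = 0.05, m = 11,
                     covariates = c("age", "sex", "bmi", "smoking_ever")))
}

#' Run the full pipeline on a synthetic cohort
#'
#' Stages: (1) simulate an EMR cohort; (2) classify it with the HTCP
#' rules; (3) validate the labels against the planted expert labels;
#' (4) simulate genotypes for the classified cases and controls at the
#' configured risk-allele frequency and odds ratio and run the adjusted
#' association. Each stage writes its outputs into `out_dir`, and a
#' manifest records the config, seed, file digests and package version.
#' Reruns with the same config produce identical outputs.
#'
#' @param config Configuration list (see [default_pipeline_config()]) or a
#'   path to a YAML file with the same structure.
#' @param out_dir Fresh output directory (created; must be empty unless
#'   `overwrite = TRUE`).
#' @param overwrite Allow writing into a non-empty directory?
#' @return Invisibly, a list with the per-stage results (`cohort`,
#'   `labels`, `report`, `association`, `manifest`).
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir, overwrite = FALSE) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  validate_pipeline_config(config)
  if (dir.exists(out_dir) && length(dir(out_dir)) && !overwrite) {
    stop("output directory is not empty: ", out_dir, call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  cohort <- stage("simulate", {
    sc <- sim_config(n_patients = config$simulate$n_patients,
                     seed = config$seed,
                     index_date = as.Date(config$index_date))
    co <- simulate_cohort(sc)
    write_simulated_cohort(co, out_dir)
    co
  })

  labels <- stage("phenotype", {
    ph <- config$phenotype
    cfg <- htcp_config(version = ph$version,
                       index_date = as.Date(config$index_date),
                       min_amd_dx_dates = ph$min_amd_dx_dates,
                       min_age_years = ph$min_age_years,
                       control_lookback_years = ph$control_lookback_years,
                       require_ophthalmologist_dx =
                         ph$require_ophthalmologist_dx)
    lb <- classify_cohort(cohort, cfg, include_evidence = TRUE)
    utils::write.csv(lb, file.path(out_dir, "labels.csv"),
                     row.names = FALSE, na = "")
    lb
  })

  report <- stage("validate", {
    pairs <- truth_pairs(labels, cohort$truth)
    rep <- table1_report(pairs)
    write_report_json(rep, file.path(out_dir, "report.json"))
    rep
  })

  association <- stage("associate", {
    ac <- config$associate
    status <- ifelse(labels$label %in% c("WET_AMD", "DRY_AMD"), "CASE",
                     ifelse(labels$label == "CONTROL", "CONTROL", NA))
    analyzed <- labels$patient_id[!is.na(status)]
    sim <- simulate_case_control_genotypes(
      n_cases = sum(status == "CASE", na.rm = TRUE),
      n_controls = sum(status == "CONTROL", na.rm = TRUE),
      raf_population = ac$raf_population,
      or_per_allele = ac$or_per_allele,
      prevalence = ac$prevalence,
      seed = config$seed)
    # carry the EMR covariates of the analyzed patients
    pm <- cohort$patients[match(analyzed, cohort$patients$patient_id), ]
    ord <- order(status[!is.na(status)] != "CASE")
    pheno <- data.frame(
      sample_id = sim$pheno$sample_id,
      status = sim$pheno$status,
      age = age_at(pm$birth_date[ord], as.Date(config$index_date)),
      sex = pm$sex[ord],
      bmi = pm$bmi[ord],
      smoking_ever = pm$smoking_ever[ord],
      ancestry_european = pm$ancestry_european[ord],
      stringsAsFactors = FALSE)
    res <- pool_and_associate(sim$geno, NULL, pheno,
                              covariates = ac$covariates,
                              alpha = ac$alpha, m = ac$m)
    utils::write.table(res, file.path(out_dir, "association.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    res
  })

  manifest <- stage("manifest", {
    outputs <- c("patients.csv", "events.csv", "truth.csv", "labels.csv",
                 "report.json", "association.tsv")
    mf <- list(
      tool = "htcpamd",
      version = as.character(utils::packageVersion("htcpamd")),
      command = "run_pipeline",
      seed = config$seed,
      config = config,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      output_digests = as.list(
        tools::md5sum(file.path(out_dir, outputs))))
    names(mf$output_digests) <- outputs
    jsonlite::write_json(mf, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    mf
  })

  invisible(list(cohort = cohort, labels = labels, report = report,
                 association = association, manifest = manifest))
}

validate_pipeline_config <- function(config) {
  need <- c("seed", "index_date", "simulate", "phenotype", "associate")
  missing <- setdiff(need, names(config))
  if (length(missing)) {
    stop("config schema violation: missing section(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (is.null(config$simulate$n_patients) ||
      config$simulate$n_patients < 1) {
    stop("config schema violation: simulate$n_patients must be >= 1",
         call. = FALSE)
  }
  invisible(TRUE)
}
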