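# Reference HTCP configuration: the published code sets and thresholds.
# Edit copies of this file to adapt the algorithm to a local EMR.
phenotype:
  version: V2                  # V1 = pilot rules (1 dx, no age gate)
  amd_dx_codes:                # qualifying AMD ICD-9 diagnoses (EXACT)
    exact: ["362.50", "362.51", "362.52", "362.16", "362.57"]
  wet_proc_codes:              # anti-VEGF injection HCPCS J-codes (EXACT)
    exact: ["J2778", "J9035", "J3490", "J3590"]
  wet_med_names:               # anti-VEGF order/prescription names
    ["ranibizumab", "lucentis", "bevacizumab", "avastin",
     "aflibercept", "eylea"]
  wet_same_date_dx:            # diagnosis required on the injection date (V2)
    prefix: ["362.5"]
  min_amd_dx_dates: 2          # distinct diagnosis dates (V1: 1)
  min_age_years: 60            # at first AMD dx (cases) / at visit (controls)
  control_lookback_years: 2    # ophthalmology visit window before index_date
  control_exclusion_codes:     # disqualify controls; bare "362" and "377.21"
    exact: ["362.50", "362.51", "362.52", "362.16", "362.57"]  # never included
    prefix: ["362.5"]
  require_ophthalmologist_dx: true
association:
  alpha: 0.05
  m: 11                        # candidate-SNP family size: 0.05/11 ~ 4.5e-3
  covariates: ["age", "sex", "bmi", "smoking_ever"]
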