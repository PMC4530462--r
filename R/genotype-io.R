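# Readers for genotype dosages: VCF (DS dosage or GT hard calls) and a
# plain TSV matrix with a risk-allele sidecar.

#' Read risk-allele dosages from a VCF
#'
#' Uses the per-sample `DS` (expected dosage) field when present,
#' otherwise counts alternate alleles in `GT`. Dosages are expressed on
#' the declared risk allele: if the risk allele is the ALT allele the
#' value is kept, if it is the REF allele the dosage is reflected
#' (`2 - x`). Matching is strand-literal; a risk allele that is neither
#' REF nor ALT is an error.
#'
#' @param path VCF file (plain or bgzipped).
#' @param risk_alleles Optional named character vector (SNP ID -> risk
#'   allele). Defaults to the ALT allele of every record.
#' @return A [dosage_matrix()] (samples x SNPs).
#' @export
read_dosage_vcf <- function(path, risk_alleles = NULL) {
  if (!file.exists(path)) stop("load error: file not found: ", path,
                               call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  snp_ids <- fix[, "ID"]
  if (anyNA(snp_ids) || anyDuplicated(snp_ids)) {
    stop("VCF records need unique non-missing IDs", call. = FALSE)
  }
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  if (any(grepl(",", alt))) {
    stop("multi-allelic records are not supported", call. = FALSE)
  }
  has_ds <- all(grepl("DS", v@gt[, "FORMAT"]))
  if (has_ds) {
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    ds <- apply(gt, c(1, 2), function(x) {
      if (is.na(x) || grepl("\\.", x)) return(NA_real_)
      sum(as.integer(strsplit(x, "[/|]")[[1]]))
    })
  }
  # rows = variants, columns = samples -> transpose to samples x SNPs
  dos <- t(ds)
  colnames(dos) <- snp_ids
  if (is.null(risk_alleles)) {
    risk_alleles <- stats::setNames(alt, snp_ids)
  }
  for (j in seq_along(snp_ids)) {
    s <- snp_ids[j]
    ra <- risk_alleles[[s]]
    if (is.null(ra) || is.na(ra)) {
      stop("no risk allele declared for ", s, call. = FALSE)
    }
    if (ra == alt[j]) {
      # already counts ALT copies
    } else if (ra == ref[j]) {
      dos[, j] <- 2 - dos[, j]
    } else {
      stop("risk allele ", ra, " for ", s,
           " matches neither REF nor ALT (strand-literal matching)",
           call. = FALSE)
    }
    risk_alleles[[s]] <- ra
  }
  dosage_matrix(dos, unlist(risk_alleles)[snp_ids])
}

#' Read a dosage matrix from TSV
#'
#' @param path TSV: first column `sample_id`, remaining columns one per
#'   SNP (header row of SNP IDs), values risk-allele dosages in `[0, 2]`
#'   (blank for missing).
#' @param risk_allele_path Sidecar TSV with columns `snp_id`,
#'   `risk_allele`.
#' @return A [dosage_matrix()].
#' @export
read_dosage_tsv <- function(path, risk_allele_path) {
  for (p in c(path, risk_allele_path)) {
    if (!file.exists(p)) stop("load error: file not found: ", p,
                              call. = FALSE)
  }
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character")
  if (names(df)[1] != "sample_id") {
    stop("first column of the dosage TSV must be sample_id", call. = FALSE)
  }
  m <- as.matrix(df[-1])
  storage.mode(m) <- "double"
  rownames(m) <- df$sample_id
  ra <- utils::read.delim(risk_allele_path, colClasses = "character")
  check_columns(ra, c("snp_id", "risk_allele"), risk_allele_path)
  dosage_matrix(m, stats::setNames(ra$risk_allele, ra$snp_id))
}

#' Write a dosage matrix to TSV (with risk-allele sidecar)
#'
#' @param geno A [dosage_matrix()].
#' @param path Output TSV path; the sidecar is written next to it as
#'   `<path>.risk_alleles.tsv` unless overridden.
#' @param risk_allele_path Optional sidecar path.
#' @return Invisibly, the two paths.
#' @export
write_dosage_tsv <- function(geno, path,
                             risk_allele_path =
                               paste0(path, ".risk_alleles.tsv")) {
  df <- data.frame(sample_id = geno$sample_ids,
                   geno$dosages, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "")
  utils::write.table(
    data.frame(snp_id = geno$snp_ids,
               risk_allele = unname(geno$risk_allele),
               stringsAsFactors = FALSE),
    risk_allele_path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(dosages = path, risk_alleles = risk_allele_path))
}
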