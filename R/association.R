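# Case-control SNP association: risk allele frequencies, additive
# allelic-dosage logistic regression (IRLS, with separation diagnostics),
# Wald inference, pooled allelic 2x2 odds ratios with Woolf confidence
# intervals, Bonferroni thresholding, demographic comparison, and a
# retrospective case-control genotype simulator for parameter-recovery
# testing.

#' Construct a genotype dosage matrix
#'
#' Dosages count copies of the declared risk allele, in `[0, 2]`; hard
#' calls are integers, imputed dosages may be fractional and are never
#' rounded.
#'
#' @param dosages Numeric matrix, samples x SNPs, with sample IDs as row
#'   names and SNP IDs as column names; `NA` for missing.
#' @param risk_alleles Named character vector (one allele label per SNP).
#' @return Object of class `dosage_matrix`.
#' @export
dosage_matrix <- function(dosages, risk_alleles) {
  stopifnot(is.matrix(dosages), !is.null(rownames(dosages)),
            !is.null(colnames(dosages)))
  rng <- range(dosages, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) {
    stop("dosages must lie in [0, 2]", call. = FALSE)
  }
  if (!all(colnames(dosages) %in% names(risk_alleles))) {
    stop("every SNP needs a declared risk allele", call. = FALSE)
  }
  hard <- apply(dosages, 2, function(x) {
    x <- x[!is.na(x)]
    length(x) == 0 || all(x == round(x))
  })
  structure(list(dosages = dosages,
                 sample_ids = rownames(dosages),
                 snp_ids = colnames(dosages),
                 risk_allele = risk_alleles[colnames(dosages)],
                 hard_call = hard),
            class = "dosage_matrix")
}

#' @export
print.dosage_matrix <- function(x, ...) {
  cat("<dosage_matrix>", length(x$sample_ids), "samples x",
      length(x$snp_ids), "SNPs;",
      sum(x$hard_call), "hard-call SNP(s)\n")
  invisible(x)
}

#' Risk allele frequency
#'
#' `sum(dosages) / (2 * n_nonmissing)`; valid for fractional (imputed)
#' dosages.
#'
#' @param dosages Numeric vector of risk-allele dosages in `[0, 2]`.
#' @param group_mask Optional logical mask selecting the group.
#' @return Proportion in `[0, 1]`.
#' @export
risk_allele_frequency <- function(dosages, group_mask = NULL) {
  if (!is.null(group_mask)) dosages <- dosages[group_mask]
  dosages <- dosages[!is.na(dosages)]
  if (length(dosages) == 0) {
    stop("undefined frequency: no non-missing dosages in group",
         call. = FALSE)
  }
  sum(dosages) / (2 * length(dosages))
}

#' Additive allelic-dosage logistic regression
#'
#' Maximum-likelihood logistic fit of case/control status on risk-allele
#' dosage (entering linearly: the additive genetic model) plus optional
#' covariates, by iteratively reweighted least squares. Convergence when
#' the largest absolute score component falls below `1e-8` or the relative
#' log-likelihood change below `1e-10`; at most 50 iterations. Complete or
#' quasi-complete separation on the dosage axis, and diverging fits, raise
#' a diagnosed error instead of returning runaway estimates; constant
#' predictors raise a rank-deficiency error.
#'
#' @param dosage Numeric vector in `[0, 2]`.
#' @param status `"CASE"`/`"CONTROL"` character, factor, or 0/1 numeric.
#' @param covariates Optional numeric matrix or data frame (one column per
#'   covariate).
#' @return List: `coef` (named: `(Intercept)`, `dosage`, covariates), `se`,
#'   `vcov`, `loglik`, `n_iter`, `converged`.
#' @export
fit_logistic_additive <- function(dosage, status, covariates = NULL) {
  y <- status_to_binary(status)
  if (length(dosage) != length(y)) stop("length mismatch", call. = FALSE)
  keep <- !is.na(dosage) & !is.na(y)
  X <- cbind(`(Intercept)` = 1, dosage = dosage)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    storage.mode(covariates) <- "double"
    keep <- keep & stats::complete.cases(covariates)
    X <- cbind(X, covariates)
  }
  X <- X[keep, , drop = FALSE]
  y <- y[keep]
  if (sum(y == 1) < 1 || sum(y == 0) < 1) {
    stop("need at least one case and one control", call. = FALSE)
  }
  if (qr(X)$rank < ncol(X)) {
    stop("rank-deficient design (constant or collinear predictor)",
         call. = FALSE)
  }
  # complete separation on the focal predictor; quasi-complete and
  # multivariate separation are caught by the divergence guard below
  if (max(X[y == 0, "dosage"]) < min(X[y == 1, "dosage"]) ||
      min(X[y == 0, "dosage"]) > max(X[y == 1, "dosage"])) {
    stop("complete separation: dosage perfectly predicts status",
         call. = FALSE)
  }
  beta <- rep(0, ncol(X))
  ll_old <- -Inf
  for (iter in seq_len(50L)) {
    eta <- drop(X %*% beta)
    if (any(abs(eta) > 30)) {
      stop("diverging fit: separation or near-separation detected",
           call. = FALSE)
    }
    mu <- stats::plogis(eta)
    score <- drop(crossprod(X, y - mu))
    w <- mu * (1 - mu)
    info <- crossprod(X * sqrt(w))
    ll <- sum(y * eta - log1p(exp(eta)))
    if (max(abs(score)) < 1e-8 ||
        (is.finite(ll_old) && abs(ll - ll_old) <
           1e-10 * (abs(ll_old) + 1e-10))) {
      vc <- solve(info)
      return(list(coef = stats::setNames(beta, colnames(X)),
                  se = stats::setNames(sqrt(diag(vc)), colnames(X)),
                  vcov = vc, loglik = ll, n_iter = iter, converged = TRUE))
    }
    ll_old <- ll
    beta <- beta + drop(solve(info, score))
  }
  stop("IRLS failed to converge in 50 iterations", call. = FALSE)
}

status_to_binary <- function(status) {
  if (is.numeric(status)) {
    if (!all(status %in% c(0, 1, NA))) stop("numeric status must be 0/1",
                                            call. = FALSE)
    return(status)
  }
  s <- toupper(as.character(status))
  if (!all(s %in% c("CASE", "CONTROL", NA))) {
    stop("status must be CASE/CONTROL", call. = FALSE)
  }
  as.numeric(s == "CASE")
}

#' Wald odds ratio, confidence interval and P value
#'
#' @param beta Log-odds estimate.
#' @param se Standard error (> 0).
#' @param alpha Two-sided level for the confidence interval.
#' @return List: `or_`, `ci95` (length 2), `p`.
#' @export
wald_inference <- function(beta, se, alpha = 0.05) {
  if (!is.finite(se) || se <= 0) stop("se must be positive", call. = FALSE)
  z <- stats::qnorm(1 - alpha / 2)
  list(or_ = exp(beta),
       ci95 = exp(beta + c(-1, 1) * z * se),
       p = 2 * stats::pnorm(-abs(beta / se)))
}

#' Allelic odds ratio from a 2x2 allele count table
#'
#' The table counts risk / non-risk alleles (rows) in cases / controls
#' (columns). The odds ratio is the cross-product ratio, with a 0.5
#' continuity correction added to every cell only when some cell is zero;
#' the confidence interval uses Woolf's log method and the P value a 1-df
#' Pearson chi-squared without continuity correction.
#'
#' @param t 2x2 numeric matrix or length-4 vector `(a, b, c, d)` read
#'   row-wise: `a` = risk alleles in cases, `b` = risk alleles in controls,
#'   `c` = non-risk in cases, `d` = non-risk in controls.
#' @param alpha Level for the confidence interval.
#' @return List: `or_`, `ci95`, `p`, `corrected` (was the continuity
#'   correction applied?).
#' @export
allelic_or_2x2 <- function(t, alpha = 0.05) {
  t <- matrix(as.numeric(t), 2, 2, byrow = is.null(dim(t)))
  if (any(t < 0)) stop("negative cell count", call. = FALSE)
  if (any(rowSums(t) == 0) || any(colSums(t) == 0)) {
    stop("undefined odds ratio: zero row or column total", call. = FALSE)
  }
  corrected <- any(t == 0)
  tc <- if (corrected) t + 0.5 else t
  a <- tc[1, 1]; b <- tc[1, 2]; c_ <- tc[2, 1]; d <- tc[2, 2]
  or_ <- (a * d) / (b * c_)
  se_log <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  z <- stats::qnorm(1 - alpha / 2)
  chi <- suppressWarnings(stats::chisq.test(t, correct = FALSE))
  list(or_ = or_,
       ci95 = exp(log(or_) + c(-1, 1) * z * se_log),
       p = unname(chi$p.value),
       corrected = corrected)
}

#' Bonferroni significance threshold
#'
#' @param alpha Family-wise level.
#' @param m Number of tests (>= 1).
#' @return `alpha / m`.
#' @export
bonferroni <- function(alpha, m) {
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  alpha / m
}

#' Flag results significant at a threshold
#'
#' @param results Data frame with a `p` column.
#' @param threshold P-value threshold (e.g. [bonferroni()] output).
#' @return `results` with a logical `significant` column.
#' @export
flag_significance <- function(results, threshold) {
  results$significant <- !is.na(results$p) & results$p < threshold
  results
}

#' Merge and analyze imputed plus directly genotyped samples
#'
#' Applies the European-ancestry filter (when the phenotype table carries
#' an `ancestry_european` column), merges the two dosage sources over the
#' union of their SNPs (a SNP absent from one source is analyzed on the
#' samples that have it, with a warning), drops per-SNP samples with
#' missing dosage or covariates, and per SNP computes risk allele
#' frequencies, the covariate-adjusted additive regression, Wald
#' inference, and a Bonferroni significance flag.
#'
#' @param imputed,genotyped [dosage_matrix()] objects with disjoint
#'   samples; `genotyped` may be `NULL`.
#' @param pheno Data frame with `sample_id`, `status` and covariate
#'   columns (plus optional `ancestry_european`).
#' @param covariates Character vector of covariate column names (complete
#'   cases per model); use `character()` for an unadjusted fit.
#' @param alpha Family-wise significance level.
#' @param m Number of tests for the Bonferroni correction; defaults to the
#'   number of SNPs analyzed.
#' @param method `"regression"` (adjusted dosage regression, default) or
#'   `"allelic"` (pooled 2x2 allele-count odds ratio, unadjusted).
#' @return Data frame, one row per SNP: `snp_id`, `risk_allele`,
#'   `raf_cases`, `raf_controls`, `beta`, `se`, `or_`, `ci_low`, `ci_high`,
#'   `p`, `n_cases`, `n_controls`, `significant`. Attributes:
#'   `ancestry_excluded` (named count), `threshold`.
#' @export
pool_and_associate <- function(imputed, genotyped = NULL, pheno,
                               covariates = c("age", "sex", "bmi",
                                              "smoking_ever"),
                               alpha = 0.05, m = NULL,
                               method = c("regression", "allelic")) {
  method <- match.arg(method)
  mats <- Filter(Negate(is.null), list(imputed, genotyped))
  ids <- unlist(lapply(mats, `[[`, "sample_ids"))
  if (anyDuplicated(ids)) {
    stop("overlapping sample ids between dosage sources", call. = FALSE)
  }
  all_snps <- unique(unlist(lapply(mats, `[[`, "snp_ids")))
  for (mt in mats) {
    absent <- setdiff(all_snps, mt$snp_ids)
    if (length(absent)) {
      warning("SNP(s) absent from one dosage source, analyzed on available ",
              "samples: ", paste(absent, collapse = ", "), call. = FALSE)
    }
  }
  risk <- do.call(c, lapply(mats, `[[`, "risk_allele"))
  risk <- risk[!duplicated(names(risk))]
  dos <- matrix(NA_real_, length(ids), length(all_snps),
                dimnames = list(ids, all_snps))
  for (mt in mats) dos[mt$sample_ids, mt$snp_ids] <- mt$dosages

  pheno <- pheno[match(ids, pheno$sample_id), , drop = FALSE]
  if (anyNA(pheno$sample_id)) {
    stop("samples missing from phenotype table", call. = FALSE)
  }
  excluded <- c(cases = 0L, controls = 0L)
  if ("ancestry_european" %in% names(pheno)) {
    drop <- !pheno$ancestry_european %in% TRUE
    excluded <- c(cases = sum(drop & pheno$status == "CASE"),
                  controls = sum(drop & pheno$status == "CONTROL"))
    pheno <- pheno[!drop, , drop = FALSE]
    dos <- dos[!drop, , drop = FALSE]
  }
  y <- pheno$status
  covm <- NULL
  if (length(covariates)) {
    covm <- pheno[covariates]
    for (cn in covariates) {
      if (!is.numeric(covm[[cn]])) {
        covm[[cn]] <- covariate_to_numeric(covm[[cn]], cn)
      }
    }
    covm <- as.matrix(covm)
  }
  threshold <- bonferroni(alpha, if (is.null(m)) length(all_snps) else m)

  rows <- lapply(all_snps, function(s) {
    d <- dos[, s]
    keep <- !is.na(d)
    if (!is.null(covm)) keep <- keep & stats::complete.cases(covm)
    d <- d[keep]; ys <- y[keep]
    cm <- if (!is.null(covm)) covm[keep, , drop = FALSE]
    n_ca <- sum(ys == "CASE"); n_co <- sum(ys == "CONTROL")
    raf_ca <- risk_allele_frequency(d, ys == "CASE")
    raf_co <- risk_allele_frequency(d, ys == "CONTROL")
    if (method == "regression") {
      fit <- fit_logistic_additive(d, ys, cm)
      wi <- wald_inference(fit$coef[["dosage"]], fit$se[["dosage"]], alpha)
      beta <- fit$coef[["dosage"]]; se <- fit$se[["dosage"]]
    } else {
      a <- sum(d[ys == "CASE"]); b <- sum(d[ys == "CONTROL"])
      tab <- matrix(c(a, b, 2 * n_ca - a, 2 * n_co - b), 2, byrow = TRUE)
      wi <- allelic_or_2x2(tab, alpha)
      beta <- log(wi$or_); se <- NA_real_
    }
    data.frame(snp_id = s, risk_allele = unname(risk[s]),
               raf_cases = raf_ca, raf_controls = raf_co,
               beta = beta, se = se, or_ = wi$or_,
               ci_low = wi$ci95[1], ci_high = wi$ci95[2], p = wi$p,
               n_cases = n_ca, n_controls = n_co,
               stringsAsFactors = FALSE)
  })
  out <- flag_significance(do.call(rbind, rows), threshold)
  rownames(out) <- NULL
  attr(out, "ancestry_excluded") <- excluded
  attr(out, "threshold") <- threshold
  out
}

covariate_to_numeric <- function(x, name) {
  if (is.logical(x)) return(as.numeric(x))
  v <- tolower(as.character(x))
  if (all(v %in% c("female", "male", NA))) return(as.numeric(v == "male"))
  if (all(v %in% c("true", "false", NA))) return(as.numeric(v == "true"))
  suppressWarnings(out <- as.numeric(x))
  if (anyNA(out) && !anyNA(x)) {
    stop("cannot code covariate '", name, "' numerically", call. = FALSE)
  }
  out
}

#' Apply the European-ancestry exclusion to a phenotype table
#'
#' Drops samples whose `ancestry_european` flag is not `TRUE` and reports
#' the case/control bookkeeping.
#'
#' @param pheno Data frame with `sample_id`, `status`,
#'   `ancestry_european`.
#' @return List: `pheno` (filtered), `n_cases`, `n_controls`,
#'   `excluded_cases`, `excluded_controls`.
#' @export
apply_ancestry_filter <- function(pheno) {
  stopifnot(all(c("status", "ancestry_european") %in% names(pheno)))
  keep <- pheno$ancestry_european %in% TRUE
  list(pheno = pheno[keep, , drop = FALSE],
       n_cases = sum(keep & pheno$status == "CASE"),
       n_controls = sum(keep & pheno$status == "CONTROL"),
       excluded_cases = sum(!keep & pheno$status == "CASE"),
       excluded_controls = sum(!keep & pheno$status == "CONTROL"))
}

#' Simulate case-control genotypes under an additive logistic model
#'
#' Genotypes are Hardy-Weinberg in the source population at the given risk
#' allele frequency; disease status follows the additive logistic model
#' with the intercept tuned so the population prevalence matches
#' `prevalence`; cases and controls are then sampled retrospectively to
#' the requested sizes. Without covariates the conditional genotype
#' distributions are drawn exactly; with a covariate model, batches of the
#' population are simulated until the quotas are met.
#'
#' @param n_cases,n_controls Sample sizes.
#' @param raf_population Population risk allele frequency in `(0, 1)`.
#' @param or_per_allele Odds ratio per risk allele copy (> 0).
#' @param prevalence Target population disease prevalence.
#' @param covariate_model Optional named list; each element is
#'   `list(beta = , draw = function(n) ...)`. Covariate effects enter the
#'   linear predictor additively.
#' @param seed Mandatory integer seed.
#' @param snp_id Label for the simulated SNP.
#' @return List: `geno` (a [dosage_matrix()] with one SNP), `pheno`
#'   (`sample_id`, `status`, any covariates, plus neutral `age`, `sex`,
#'   `bmi`, `smoking_ever` columns when no covariate model is given).
#' @export
simulate_case_control_genotypes <- function(n_cases, n_controls,
                                            raf_population, or_per_allele,
                                            prevalence = 0.05,
                                            covariate_model = NULL,
                                            seed, snp_id = "snp1") {
  stopifnot(raf_population > 0, raf_population < 1, or_per_allele > 0,
            prevalence > 0, prevalence < 1)
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  beta_g <- log(or_per_allele)
  pg <- stats::dbinom(0:2, 2, raf_population)

  with_stream(stream_seed(seed, 104729L), {
    if (is.null(covariate_model)) {
      b0 <- stats::uniroot(function(b0) {
        sum(pg * stats::plogis(b0 + beta_g * (0:2))) - prevalence
      }, c(-40, 10), tol = 1e-12)$root
      pcase_g <- stats::plogis(b0 + beta_g * (0:2))
      g_cases <- sample(0:2, n_cases, replace = TRUE, prob = pg * pcase_g)
      g_controls <- sample(0:2, n_controls, replace = TRUE,
                           prob = pg * (1 - pcase_g))
      g <- c(g_cases, g_controls)
      status <- rep(c("CASE", "CONTROL"), c(n_cases, n_controls))
      covs <- data.frame(
        age = round(stats::rnorm(n_cases + n_controls, 74, 8), 1),
        sex = sample(c("female", "male"), n_cases + n_controls, TRUE,
                     prob = c(0.7, 0.3)),
        bmi = round(stats::rnorm(n_cases + n_controls, 27, 4), 1),
        smoking_ever = stats::runif(n_cases + n_controls) < 0.5,
        stringsAsFactors = FALSE)
    } else {
      draw_lin <- function(n) {
        cv <- lapply(covariate_model, function(cmx) cmx$draw(n))
        lin <- Reduce(`+`, Map(function(cmx, x) cmx$beta * x,
                               covariate_model, cv), rep(0, n))
        list(cov = as.data.frame(cv, stringsAsFactors = FALSE), lin = lin)
      }
      tune <- draw_lin(200000L)
      gt <- sample(0:2, 200000L, replace = TRUE, prob = pg)
      b0 <- stats::uniroot(function(b0) {
        mean(stats::plogis(b0 + beta_g * gt + tune$lin)) - prevalence
      }, c(-40, 10), tol = 1e-10)$root
      g <- integer(0); status <- character(0)
      covs <- NULL
      max_batches <- 200L
      batch <- max(5000L, ceiling(
        max(n_cases / prevalence, n_controls / (1 - prevalence)) / 20))
      for (b in seq_len(max_batches)) {
        need_ca <- n_cases - sum(status == "CASE")
        need_co <- n_controls - sum(status == "CONTROL")
        if (need_ca <= 0 && need_co <= 0) break
        gb <- sample(0:2, batch, replace = TRUE, prob = pg)
        db <- draw_lin(batch)
        yb <- stats::runif(batch) < stats::plogis(b0 + beta_g * gb + db$lin)
        take_ca <- utils::head(which(yb), max(0, need_ca))
        take_co <- utils::head(which(!yb), max(0, need_co))
        take <- c(take_ca, take_co)
        g <- c(g, gb[take])
        status <- c(status, ifelse(yb[take], "CASE", "CONTROL"))
        covs <- rbind(covs, db$cov[take, , drop = FALSE])
      }
      if (sum(status == "CASE") < n_cases ||
          sum(status == "CONTROL") < n_controls) {
        stop("unattainable sample sizes at this prevalence", call. = FALSE)
      }
      ord <- order(status != "CASE")
      g <- g[ord]; status <- status[ord]
      covs <- covs[ord, , drop = FALSE]
    }
    ids <- sprintf("G%05d", seq_along(g))
    dm <- matrix(as.numeric(g), ncol = 1,
                 dimnames = list(ids, snp_id))
    pheno <- cbind(data.frame(sample_id = ids, status = status,
                              stringsAsFactors = FALSE), covs)
    rownames(pheno) <- NULL
    list(geno = dosage_matrix(dm, stats::setNames("A", snp_id)),
         pheno = pheno)
  })
}

#' Compare demographics between cases and controls
#'
#' Continuous variables are compared with a two-sample Student t-test
#' (pooled variance); binary variables with a Pearson chi-squared test
#' without continuity correction. A zero-variance continuous variable (or
#' a degenerate 2x2 table) yields an undefined-test marker (`NA`
#' statistic and P) rather than an error.
#'
#' @param pheno Data frame with `status` (`CASE`/`CONTROL`) and the
#'   variables to compare.
#' @param variables Character vector of column names; defaults to every
#'   column except `sample_id` and `status`.
#' @return Data frame: `variable`, `type`, `cases`, `controls` (means or
#'   proportions), `statistic`, `p`.
#' @export
demographic_comparison <- function(pheno, variables = NULL) {
  stopifnot("status" %in% names(pheno))
  grp <- pheno$status
  if (length(unique(grp[!is.na(grp)])) != 2 || min(table(grp)) < 2) {
    stop("need >= 2 samples in each of two groups", call. = FALSE)
  }
  if (is.null(variables)) {
    variables <- setdiff(names(pheno),
                         c("sample_id", "status", "ancestry_european"))
  }
  rows <- lapply(variables, function(v) {
    x <- pheno[[v]]
    if (is.character(x) || is.factor(x) || is.logical(x)) {
      x <- covariate_to_numeric(x, v)
    }
    ok <- !is.na(x) & !is.na(grp)
    xs <- x[ok]; gs <- grp[ok]
    binary <- all(xs %in% c(0, 1))
    if (binary) {
      tab <- table(factor(gs, c("CASE", "CONTROL")), factor(xs, c(0, 1)))
      props <- tab[, "1"] / rowSums(tab)
      if (any(colSums(tab) == 0)) {
        stat <- p <- NA_real_
      } else {
        ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
        stat <- unname(ct$statistic); p <- unname(ct$p.value)
      }
      data.frame(variable = v, type = "proportion",
                 cases = unname(props["CASE"]),
                 controls = unname(props["CONTROL"]),
                 statistic = stat, p = p, stringsAsFactors = FALSE)
    } else {
      m_ca <- mean(xs[gs == "CASE"]); m_co <- mean(xs[gs == "CONTROL"])
      if (stats::sd(xs[gs == "CASE"]) == 0 &&
          stats::sd(xs[gs == "CONTROL"]) == 0) {
        stat <- p <- NA_real_
      } else {
        tt <- stats::t.test(xs[gs == "CASE"], xs[gs == "CONTROL"],
                            var.equal = TRUE)
        stat <- unname(tt$statistic); p <- unname(tt$p.value)
      }
      data.frame(variable = v, type = "mean",
                 cases = m_ca, controls = m_co,
                 statistic = stat, p = p, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
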