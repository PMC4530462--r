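test_that("risk allele frequency handles hard and fractional dosages", {
  expect_equal(risk_allele_frequency(c(2, 1, 1, 0)), 0.5)
  expect_equal(risk_allele_frequency(c(0, 0, 0)), 0)
  expect_equal(risk_allele_frequency(c(1.5, 0.5, NA)), 0.5)
  expect_equal(risk_allele_frequency(c(2, 2, 0, 0), c(TRUE, TRUE, FALSE,
                                                      FALSE)), 1)
  expect_error(risk_allele_frequency(c(NA_real_, NA_real_)), "undefined")
  # binomial sampling: 10,000 draws at the planted frequency
  set.seed(1)
  draws <- stats::rbinom(10000, 2, 0.363)
  se <- sqrt(0.363 * (1 - 0.363) / (2 * 10000))
  expect_lt(abs(risk_allele_frequency(draws) - 0.363), 3 * se)
})

test_that("IRLS logistic matches glm and the 2x2 closed form", {
  dos <- c(rep(1, 30), rep(0, 20), rep(1, 10), rep(0, 40))
  y <- rep(c("CASE", "CONTROL"), c(50, 50))
  fit <- fit_logistic_additive(dos, y)
  expect_equal(exp(fit$coef[["dosage"]]), 6, tolerance = 1e-8)
  # random datasets with covariates: agree with glm to high precision
  set.seed(31)
  for (rep in 1:10) {
    n <- 400
    g <- stats::rbinom(n, 2, 0.3)
    age <- stats::rnorm(n, 70, 8)
    sex <- stats::rbinom(n, 1, 0.5)
    pr <- stats::plogis(-1 + 0.5 * g + 0.02 * (age - 70) + 0.3 * sex)
    yy <- stats::rbinom(n, 1, pr)
    if (min(table(yy)) < 5) next
    fit <- fit_logistic_additive(g, yy, cbind(age = age, sex = sex))
    ref <- stats::glm(yy ~ g + age + sex, family = stats::binomial)
    expect_equal(unname(fit$coef), unname(stats::coef(ref)),
                 tolerance = 1e-6)
    expect_equal(unname(fit$se),
                 unname(sqrt(diag(stats::vcov(ref)))), tolerance = 1e-5)
    expect_equal(fit$loglik, as.numeric(stats::logLik(ref)),
                 tolerance = 1e-8)
  }
})

test_that("degenerate designs raise diagnosed errors", {
  expect_error(fit_logistic_additive(c(2, 2, 2, 0, 0, 0),
                                     c(1, 1, 1, 0, 0, 0)),
               "separation")
  expect_error(fit_logistic_additive(rep(1, 10), rep(c(0, 1), 5)),
               "rank-deficient")
  expect_error(fit_logistic_additive(c(0, 1, 2), c(1, 1, 1)),
               "at least one case and one control")
})

test_that("dosage effect is invariant to affine covariate rescaling", {
  set.seed(5)
  n <- 500
  g <- stats::rbinom(n, 2, 0.35)
  age <- stats::rnorm(n, 70, 8)
  y <- stats::rbinom(n, 1, stats::plogis(-0.5 + 0.4 * g + 0.03 * age))
  f1 <- fit_logistic_additive(g, y, cbind(age = age))
  f2 <- fit_logistic_additive(g, y, cbind(age = (age - 70) / 10))
  expect_equal(f1$coef[["dosage"]], f2$coef[["dosage"]], tolerance = 1e-7)
  expect_equal(f1$coef[["age"]] * 10, f2$coef[["age"]], tolerance = 1e-6)
  # and to sample reordering
  o <- sample.int(n)
  f3 <- fit_logistic_additive(g[o], y[o], cbind(age = age[o]))
  expect_equal(f1$coef, f3$coef, tolerance = 1e-9)
})

test_that("Wald inference: identities, anchors, monotonicity", {
  w0 <- wald_inference(0, 1)
  expect_equal(w0$or_, 1)
  expect_equal(w0$p, 1)
  # invert a published-style CI to recover the SE and reproduce it
  se <- (log(3.79) - log(1.55)) / (2 * stats::qnorm(0.975))
  w <- wald_inference(log(2.43), se)
  expect_equal(w$ci95, c(1.55, 3.79), tolerance = 1e-2)
  expect_true(w$ci95[1] <= w$or_ && w$or_ <= w$ci95[2])
  ps <- vapply(seq(0, 3, by = 0.25),
               function(b) wald_inference(b, 1)$p, numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_error(wald_inference(1, 0), "positive")
})

test_that("allelic 2x2 odds ratio matches a logistic-regression oracle", {
  expect_equal(allelic_or_2x2(c(10, 10, 10, 10))$or_, 1)
  expect_equal(allelic_or_2x2(c(30, 20, 10, 40))$or_, 6)
  expect_error(allelic_or_2x2(c(0, 0, 5, 5)), "zero row")
  set.seed(11)
  for (rep in 1:25) {
    t <- matrix(sample(1:60, 4, TRUE), 2)
    got <- allelic_or_2x2(t)
    # unadjusted binary-exposure logistic fit on the expanded table
    y <- rep(c(1, 0, 1, 0), c(t[1, 1], t[1, 2], t[2, 1], t[2, 2]))
    x <- rep(c(1, 1, 0, 0), c(t[1, 1], t[1, 2], t[2, 1], t[2, 2]))
    ref <- stats::glm(y ~ x, family = stats::binomial)
    expect_equal(got$or_, exp(unname(stats::coef(ref)[2])),
                 tolerance = 1e-6)
    # P value equals the squared two-proportion z-test chi-squared
    expect_equal(got$p,
                 suppressWarnings(stats::chisq.test(t,
                                                    correct = FALSE))$p.value)
  }
  # zero cell engages the continuity correction instead of failing
  cc <- allelic_or_2x2(c(0, 5, 10, 10))
  expect_true(cc$corrected)
  expect_gt(cc$or_, 0)
})

test_that("Bonferroni threshold and monotone flagging", {
  expect_equal(bonferroni(0.05, 11), 0.05 / 11)
  expect_equal(bonferroni(0.05, 1), 0.05)
  expect_error(bonferroni(0.05, 0), ">= 1")
  res <- data.frame(p = c(2.3e-4, 9.6e-3, 0.04, NA))
  fl <- flag_significance(res, bonferroni(0.05, 11))
  expect_equal(fl$significant, c(TRUE, FALSE, FALSE, FALSE))
  # lowering alpha never adds significant results
  for (a in c(0.05, 0.01, 0.001)) {
    lo <- flag_significance(res, bonferroni(a / 5, 11))$significant
    hi <- flag_significance(res, bonferroni(a, 11))$significant
    expect_true(all(!lo | hi))
  }
})

test_that("genotype simulator: HWE, determinism, error on bad input", {
  sim <- simulate_case_control_genotypes(5000, 5000, 0.363, 1.0, seed = 41)
  g <- sim$geno$dosages[, 1]
  n <- length(g)
  for (k in 0:2) {
    pk <- stats::dbinom(k, 2, 0.363)
    se <- sqrt(n * pk * (1 - pk))
    expect_lt(abs(sum(g == k) - n * pk), 3 * se)
  }
  sim2 <- simulate_case_control_genotypes(5000, 5000, 0.363, 1.0, seed = 41)
  expect_identical(sim, sim2)
  expect_error(simulate_case_control_genotypes(10, 10, 1.5, 2, seed = 1))
})

test_that("planted odds ratios are recovered across a grid", {
  set.seed(0)
  for (or_true in c(1, 1.5, 2, 2.76)) {
    est <- vapply(1:60, function(r) {
      sim <- simulate_case_control_genotypes(
        2000, 2000, 0.3, or_true, seed = 7000 + 100 * or_true + r)
      fit <- fit_logistic_additive(sim$geno$dosages[, 1], sim$pheno$status)
      exp(fit$coef[["dosage"]])
    }, numeric(1))
    expect_lt(abs(stats::median(est) - or_true) / or_true, 0.10)
  }
})

test_that("covariate-model simulation recovers the dosage effect", {
  covm <- list(
    age = list(beta = 0.03, draw = function(n) stats::rnorm(n, 70, 8)),
    sex = list(beta = 0.4, draw = function(n) stats::rbinom(n, 1, 0.5)))
  sim <- simulate_case_control_genotypes(2000, 2000, 0.3, 2.0,
                                         covariate_model = covm, seed = 55)
  fit <- fit_logistic_additive(sim$geno$dosages[, 1], sim$pheno$status,
                               sim$pheno[c("age", "sex")])
  se <- fit$se[["dosage"]]
  expect_lt(abs(fit$coef[["dosage"]] - log(2)), 3 * se)
})

test_that("pooling imputed and genotyped samples, with bookkeeping", {
  sim <- simulate_case_control_genotypes(80, 160, 0.4, 2.0, seed = 61,
                                         snp_id = "rs0001")
  geno <- sim$geno
  pheno <- sim$pheno
  pheno$ancestry_european <- TRUE
  full <- pool_and_associate(geno, NULL, pheno, covariates = character())
  # split the matrix into disjoint halves: identical results
  half <- seq_len(120)
  d1 <- dosage_matrix(geno$dosages[half, , drop = FALSE],
                      stats::setNames(geno$risk_allele, geno$snp_ids))
  d2 <- dosage_matrix(geno$dosages[-half, , drop = FALSE],
                      stats::setNames(geno$risk_allele, geno$snp_ids))
  merged <- pool_and_associate(d1, d2, pheno, covariates = character())
  expect_equal(merged$or_, full$or_, tolerance = 1e-10)
  expect_equal(merged$p, full$p, tolerance = 1e-10)
  # overlapping sample ids are rejected
  expect_error(pool_and_associate(d1, d1, pheno), "overlapping")
  # a missing dosage reduces that SNP's n only
  dos2 <- cbind(geno$dosages,
                rs0002 = geno$dosages[, 1])
  dos2[1, "rs0002"] <- NA
  dm <- dosage_matrix(dos2, c(rs0001 = "A", rs0002 = "A"))
  res <- pool_and_associate(dm, NULL, pheno, covariates = character())
  expect_equal(res$n_cases[res$snp_id == "rs0001"], 80L)
  expect_equal(res$n_cases[res$snp_id == "rs0002"], 79L)
  # ancestry exclusion bookkeeping
  pheno2 <- pheno
  pheno2$ancestry_european[c(1, 2, 81, 82, 83)] <- FALSE
  res2 <- pool_and_associate(dm, NULL, pheno2, covariates = character())
  expect_equal(attr(res2, "ancestry_excluded"),
               c(cases = 2L, controls = 3L))
  expect_equal(res2$n_cases[1], 78L)
  # SNP missing from one source warns but analyzes available samples
  mixed <- c(1:40, 121:180)  # cases and controls in both sources
  d3 <- dosage_matrix(geno$dosages[mixed, 1, drop = FALSE],
                      c(rs0001 = "A"))
  d4 <- dosage_matrix(dos2[-mixed, , drop = FALSE],
                      c(rs0001 = "A", rs0002 = "A"))
  expect_warning(res3 <- pool_and_associate(d3, d4, pheno,
                                            covariates = character()),
                 "rs0002")
  expect_equal(res3$n_cases[res3$snp_id == "rs0001"] +
                 res3$n_controls[res3$snp_id == "rs0001"], 240L)
})

test_that("regression and allelic methods agree on hard-call data", {
  sim <- simulate_case_control_genotypes(300, 300, 0.35, 1.8, seed = 71)
  res_r <- pool_and_associate(sim$geno, NULL, sim$pheno,
                              covariates = character())
  res_a <- pool_and_associate(sim$geno, NULL, sim$pheno,
                              covariates = character(),
                              method = "allelic")
  # allelic OR and unadjusted regression OR estimate the same quantity
  expect_equal(res_r$or_, res_a$or_, tolerance = 0.15)
  expect_equal(res_r$raf_cases, res_a$raf_cases)
})

test_that("ancestry filter reproduces narrated case/control bookkeeping", {
  pheno <- data.frame(
    sample_id = sprintf("s%03d", 1:228),
    status = rep(c("CASE", "CONTROL"), c(61, 167)),
    ancestry_european = c(rep(c(FALSE, TRUE), c(4, 57)),
                          rep(c(FALSE, TRUE), c(25, 142))),
    stringsAsFactors = FALSE)
  out <- apply_ancestry_filter(pheno)
  expect_equal(out$n_cases, 57L)
  expect_equal(out$n_controls, 142L)
  expect_equal(out$excluded_cases, 4L)
  expect_equal(out$excluded_controls, 25L)
})

test_that("demographic comparison: identities and planted differences", {
  pheno <- data.frame(
    status = rep(c("CASE", "CONTROL"), each = 50),
    smoking_ever = rep(c(TRUE, FALSE), 50),
    bmi = rep(c(27, 27.5), 50))
  cmp <- demographic_comparison(pheno, c("smoking_ever", "bmi"))
  expect_equal(cmp$p[cmp$variable == "smoking_ever"], 1)
  # chi-squared from a 2x2 equals the squared two-proportion z statistic
  set.seed(3)
  x <- stats::rbinom(200, 1, 0.4)
  grp <- rep(c("CASE", "CONTROL"), each = 100)
  cmp2 <- demographic_comparison(data.frame(status = grp, v = x), "v")
  p1 <- mean(x[grp == "CASE"]); p2 <- mean(x[grp == "CONTROL"])
  pp <- mean(x)
  z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / 100 + 1 / 100))
  expect_equal(cmp2$statistic, z^2, tolerance = 1e-9)
  # a planted 9-year age gap at large n is overwhelmingly significant
  set.seed(4)
  big <- data.frame(status = rep(c("CASE", "CONTROL"), each = 2000),
                    age = c(stats::rnorm(2000, 78.3, 8),
                            stats::rnorm(2000, 69.3, 8)))
  cmp3 <- demographic_comparison(big, "age")
  expect_lt(cmp3$p, 1e-10)
  # zero-variance variable yields an undefined marker
  flat <- data.frame(status = rep(c("CASE", "CONTROL"), each = 5),
                     v = rep(1.5, 10))
  expect_true(is.na(demographic_comparison(flat, "v")$p))
})
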