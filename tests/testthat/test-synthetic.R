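reg <- load_registry()

test_that("synthetic configuration validates its stated world", {
  cfg <- synthetic_config(n_units = 10, seed = 1, registry = reg)
  expect_s3_class(cfg, "mcc_sim_config")
  expect_equal(names(cfg$prevalence), condition_ids(reg))

  bad_p <- default_prevalence(reg); bad_p[1] <- 1
  expect_error(synthetic_config(prevalence = bad_p, registry = reg),
               "strictly in \\(0, 1\\)")
  expect_error(synthetic_config(prevalence = c(a = 0.5), registry = reg),
               "named vector")

  # a non-positive-semidefinite association matrix names the eigenvalue
  A <- diag(20); A[1, 2] <- A[2, 1] <- 0.9
  A[1, 3] <- A[3, 1] <- 0.9; A[2, 3] <- A[3, 2] <- -0.9
  expect_error(synthetic_config(association = A, registry = reg),
               "eigenvalue")
})

test_that("truth simulation is reproducible bit-for-bit", {
  cfg <- synthetic_config(n_units = 500, seed = 42, registry = reg)
  t1 <- simulate_truth(cfg)
  t2 <- simulate_truth(cfg)
  expect_identical(t1$flags, t2$flags)
  t3 <- simulate_truth(synthetic_config(n_units = 500, seed = 43,
                                        registry = reg))
  expect_false(identical(t1$flags, t3$flags))
})

test_that("marginal prevalences match the copula's targets", {
  p <- stats::setNames(rep(0.5, 20), condition_ids(reg))
  cfg <- synthetic_config(n_units = 100000, prevalence = p, seed = 7,
                          registry = reg)
  truth <- simulate_truth(cfg)
  emp <- colMeans(truth$flags)
  # binomial standard error ~ 0.0016 at n = 100,000
  expect_true(all(abs(emp - 0.5) < 0.01))

  # identity association: pairwise odds ratios ~ 1
  f <- truth$flags
  for (pair in list(c(1, 2), c(5, 11), c(3, 17))) {
    a <- sum(f[, pair[1]] & f[, pair[2]])
    b <- sum(f[, pair[1]] & !f[, pair[2]])
    cc <- sum(!f[, pair[1]] & f[, pair[2]])
    d <- sum(!f[, pair[1]] & !f[, pair[2]])
    log_or <- log(a * d / (b * cc))
    se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
    expect_lt(abs(log_or), 3 * se)
  }
})

test_that("positive latent correlation induces positive co-occurrence", {
  A <- diag(20); A[1, 2] <- A[2, 1] <- 0.6
  p <- stats::setNames(rep(0.3, 20), condition_ids(reg))
  cfg <- synthetic_config(n_units = 50000, prevalence = p, association = A,
                          seed = 12, registry = reg)
  f <- simulate_truth(cfg)$flags
  or <- (sum(f[, 1] & f[, 2]) * sum(!f[, 1] & !f[, 2])) /
        (sum(f[, 1] & !f[, 2]) * sum(!f[, 1] & f[, 2]))
  expect_gt(or, 2)
  # the odds-ratio converter is monotone and anchored at independence
  expect_equal(latent_corr_from_or(1), 0, tolerance = 1e-12)
  expect_true(latent_corr_from_or(5) > latent_corr_from_or(2))
  expect_lt(latent_corr_from_or(0.2), 0)
})

test_that("claims emission respects availability and code-set closure", {
  # a hand-built truth: one unit with diabetes only
  cfg <- synthetic_config(n_units = 1, seed = 3, extraneous_code_rate = 0,
                          claims_per_unit = 6, registry = reg)
  flags <- matrix(FALSE, 1, 20,
                  dimnames = list("U000001", condition_ids(reg)))
  flags[1, "diabetes"] <- TRUE
  truth <- structure(list(unit_id = "U000001", flags = flags, config = cfg),
                     class = "mcc_truth")
  claims <- emit_claims(truth, reg, "CMS")
  expect_gte(nrow(claims), 1L)
  dia <- condition_codes(reg, "diabetes", "CMS")
  expect_true(all(code_in_set(claims$code, dia)))

  # conditions the dialect does not measure emit no codes
  flags2 <- flags; flags2[1, ] <- FALSE
  flags2[1, "schizophrenia"] <- TRUE  # unavailable in CMS
  truth2 <- structure(list(unit_id = "U000001", flags = flags2, config = cfg),
                      class = "mcc_truth")
  expect_equal(nrow(emit_claims(truth2, reg, "CMS")), 0L)

  expect_error(emit_claims(truth, reg, "NHIS"), "emit_survey")
  expect_error(emit_survey(truth, reg, "CMS"), "emit_claims")
})

test_that("decoy codes never collide with the scheme", {
  for (system in c("icd9cm", "ccs")) {
    decoys <- decoy_codes(reg, system)
    expect_gt(length(decoys), 50L)
    for (cid in condition_ids(reg)) {
      for (did in c("CMS", "MEPS", "NIS")) {
        cs <- condition_codes(reg, cid, did)
        if (!is.null(cs) && cs$kind == system) {
          expect_length(intersect(decoys, cs$members), 0L)
        }
      }
    }
  }
})

test_that("claims pipeline recovers true prevalence exactly at zero noise", {
  cfg <- synthetic_config(n_units = 2000, seed = 21, extraneous_code_rate = 0,
                          claims_per_unit = 3, registry = reg)
  truth <- simulate_truth(cfg)
  av <- availability(reg)
  # CMS: every measured condition retains unambiguous codes -> exact identity
  claims <- emit_claims(truth, reg, "CMS")
  prof <- code_population(claims, reg, "CMS", units = truth$unit_id)
  meas <- rownames(av)[av[, "CMS"] == "measured"]
  got <- flags_matrix(prof)[truth$unit_id, meas]
  expect_identical(got == TRUE, truth$flags[, meas] == TRUE)
  est <- compute_indicators(prof)$per_condition_prevalence
  expect_equal(est[meas], colMeans(truth$flags[, meas]))

  # NIS: CCS 108 is printed for both congestive heart failure and chronic
  # kidney disease, so those two are irreducibly confounded; every other
  # condition still recovers exactly
  claims_nis <- emit_claims(truth, reg, "NIS")
  prof_nis <- code_population(claims_nis, reg, "NIS", units = truth$unit_id)
  confounded <- c("congestive_heart_failure", "chronic_kidney_disease")
  clean <- setdiff(rownames(av)[av[, "NIS"] == "measured"], confounded)
  got_nis <- flags_matrix(prof_nis)[truth$unit_id, clean]
  expect_identical(got_nis == TRUE, truth$flags[, clean] == TRUE)
  # the shared code makes both flags equal to the union of the two truths
  either <- truth$flags[, confounded[1]] | truth$flags[, confounded[2]]
  for (cid in confounded) {
    expect_identical(unname(flags_matrix(prof_nis)[truth$unit_id, cid]),
                     unname(either))
  }
})

test_that("extraneous decoy codes do not perturb recovered prevalence", {
  cfg <- synthetic_config(n_units = 1000, seed = 22,
                          extraneous_code_rate = 0.3, claims_per_unit = 4,
                          registry = reg)
  truth <- simulate_truth(cfg)
  claims <- emit_claims(truth, reg, "CMS")
  prof <- code_population(claims, reg, "CMS", units = truth$unit_id)
  av <- availability(reg)
  meas <- rownames(av)[av[, "CMS"] == "measured"]
  got <- flags_matrix(prof)[truth$unit_id, meas]
  expect_identical(got == TRUE, truth$flags[, meas] == TRUE)
})

test_that("survey misclassification follows the closed form", {
  s <- 0.85; cc <- 0.97
  p <- stats::setNames(rep(0.2, 20), condition_ids(reg))
  cfg <- synthetic_config(n_units = 100000, prevalence = p, seed = 31,
                          self_report_sensitivity = s,
                          self_report_specificity = cc, registry = reg)
  truth <- simulate_truth(cfg)
  survey <- emit_survey(truth, reg, "NHIS")
  prof <- code_population(survey, reg, "NHIS", units = truth$unit_id)
  est <- compute_indicators(prof)$per_condition_prevalence
  av <- availability(reg)
  meas <- rownames(av)[av[, "NHIS"] %in% c("measured", "related_proxy")]
  expected <- 0.2 * s + 0.8 * (1 - cc)
  se <- sqrt(expected * (1 - expected) / cfg$n_units)
  for (cid in meas) {
    expect_lt(abs(est[[cid]] - expected), 3 * se)
  }
  # perfect measurement reproduces truth exactly
  cfg2 <- synthetic_config(n_units = 2000, seed = 32,
                           self_report_sensitivity = 1,
                           self_report_specificity = 1, registry = reg)
  truth2 <- simulate_truth(cfg2)
  prof2 <- code_population(emit_survey(truth2, reg, "NHIS"), reg, "NHIS",
                           units = truth2$unit_id)
  est2 <- compute_indicators(prof2)$per_condition_prevalence
  expect_equal(est2[meas], colMeans(truth2$flags[, meas]))
})

test_that("raising one prevalence weakly raises MCC prevalence (CRN)", {
  p_lo <- default_prevalence(reg)
  p_hi <- p_lo; p_hi["hypertension"] <- min(0.9, p_lo[["hypertension"]] * 2)
  mk <- function(p) {
    cfg <- synthetic_config(n_units = 5000, prevalence = p, seed = 55,
                            registry = reg)
    mean(rowSums(simulate_truth(cfg)$flags) >= 2)
  }
  # identical seed = common random numbers: flags are pointwise monotone
  expect_gte(mk(p_hi), mk(p_lo))
})

test_that("emission is deterministic under the configured seed", {
  cfg <- synthetic_config(n_units = 200, seed = 9, registry = reg)
  truth <- simulate_truth(cfg)
  expect_identical(emit_claims(truth, reg, "CMS"),
                   emit_claims(truth, reg, "CMS"))
  expect_identical(emit_survey(truth, reg, "NHIS"),
                   emit_survey(truth, reg, "NHIS"))
  # different dialects draw from different streams
  expect_false(identical(emit_claims(truth, reg, "CMS")$code,
                         emit_claims(truth, reg, "MEPS")$code))
})
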