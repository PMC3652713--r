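reg <- load_registry()

test_that("one overlapping claim code sets every owning condition flag", {
  claims <- data.frame(unit_id = "p1", record_id = "c1", code = "40201")
  prof <- code_claims_unit(claims, reg, "CMS")
  expect_true(prof$flags[["hypertension"]])
  expect_true(prof$flags[["congestive_heart_failure"]])
  expect_equal(prof$n_conditions, 2L)
  expect_setequal(names(prof$evidence),
                  c("hypertension", "congestive_heart_failure"))
})

test_that("distinct codes flag their conditions; unknown codes flag none", {
  claims <- data.frame(unit_id = "p2", record_id = c("c1", "c2"),
                       code = c("4019", "25000"))
  prof <- code_claims_unit(claims, reg, "CMS")
  expect_setequal(names(prof$flags)[prof$flags], c("hypertension", "diabetes"))
  expect_equal(prof$n_conditions, 2L)

  none <- code_claims_unit(
    data.frame(unit_id = "p3", record_id = "c1", code = "00188"), reg, "CMS")
  expect_equal(none$n_conditions, 0L)
  expect_false(any(none$flags))
})

test_that("min_records_per_condition thresholds distinct records", {
  one <- data.frame(unit_id = "p1", record_id = "c1", code = "4280")
  cfg2 <- coding_config(min_records_per_condition = 2)
  expect_false(code_claims_unit(one, reg, "CMS", cfg2)$flags[[
    "congestive_heart_failure"]])
  two <- rbind(one, data.frame(unit_id = "p1", record_id = "c2",
                               code = "428.1"))
  expect_true(code_claims_unit(two, reg, "CMS", cfg2)$flags[[
    "congestive_heart_failure"]])
  # two codes on the same record are still one record
  same <- rbind(one, data.frame(unit_id = "p1", record_id = "c1",
                                code = "428.1"))
  expect_false(code_claims_unit(same, reg, "CMS", cfg2)$flags[[
    "congestive_heart_failure"]])
})

test_that("mixed unit ids and unparseable codes follow the contract", {
  mixed <- data.frame(unit_id = c("a", "b"), record_id = c("c1", "c2"),
                      code = "4019")
  expect_error(code_claims_unit(mixed, reg, "CMS"), "exactly one unit")

  junk <- data.frame(unit_id = "a", record_id = c("c1", "c2"),
                     code = c("4019", "NOTACODE"))
  expect_warning(p <- code_population(junk, reg, "CMS"), "unparseable")
  expect_true(p[p$unit_id == "a", "hypertension"])
  expect_equal(attr(p, "summary")$n_quarantined, 1L)
  expect_error(
    code_population(junk, reg, "CMS",
                    coding_config(unknown_code_policy = "error")),
    "unparseable")
  expect_silent(
    code_population(junk, reg, "CMS",
                    coding_config(unknown_code_policy = "ignore")))

  # declared code_system contradicting the dialect quarantines the record
  ccs_in_cms <- data.frame(unit_id = "a", record_id = c("c1", "c2"),
                           code = c("4019", "128"),
                           code_system = c("icd9cm", "ccs"))
  expect_warning(p2 <- code_population(ccs_in_cms, reg, "CMS"),
                 "code_system")
  expect_equal(attr(p2, "summary")$n_quarantined, 1L)
})

test_that("survey coding follows item registration and availability", {
  rec <- list(unit_id = "s1", items = c(hypertension = "yes", asthma = "no"))
  prof <- code_survey_unit(rec, reg, "NHIS")
  expect_true(prof$flags[["hypertension"]])
  expect_false(prof$flags[["asthma"]])
  expect_equal(prof$n_conditions, 1L)

  # depression is not collected by NHIS: unregistered item, flag stays false
  dep <- list(unit_id = "s2", items = c(depression = "yes"))
  expect_warning(p2 <- code_survey_unit(dep, reg, "NHIS"), "not registered")
  expect_false(p2$flags[["depression"]])
  expect_equal(p2$n_conditions, 0L)

  # all missing -> no conditions
  mis <- list(unit_id = "s3", items = c(hypertension = "missing",
                                        asthma = "missing"))
  expect_equal(code_survey_unit(mis, reg, "NHIS")$n_conditions, 0L)

  # the kidney proxy reports under chronic kidney disease by default...
  kid <- list(unit_id = "s4", items = c(weak_or_failing_kidneys = "yes"))
  expect_true(code_survey_unit(kid, reg, "NHIS")$flags[[
    "chronic_kidney_disease"]])
  # ...and not when proxies are excluded
  noprox <- coding_config(count_proxies = FALSE)
  expect_false(code_survey_unit(kid, reg, "NHIS", noprox)$flags[[
    "chronic_kidney_disease"]])
})

test_that("population coding is deterministic and permutation invariant", {
  claims <- random_claims(10, reg, "CMS", seed = 11)
  base <- code_population(claims, reg, "CMS")
  expect_equal(nrow(base), length(unique(claims$unit_id)))
  expect_equal(base$unit_id, sort(unique(claims$unit_id)))
  set.seed(99)
  for (i in 1:100) {
    shuf <- claims[sample(nrow(claims)), ]
    again <- code_population(shuf, reg, "CMS")
    expect_identical(flags_matrix(again), flags_matrix(base))
    expect_identical(again$n_conditions, base$n_conditions)
  }
  # duplicated rows change nothing under the any-match rule
  dup <- code_population(rbind(claims, claims), reg, "CMS")
  expect_identical(flags_matrix(dup), flags_matrix(base))
})

test_that("adding a record never turns a flag off (monotonicity)", {
  set.seed(5)
  for (i in 1:10) {
    claims <- random_claims(6, reg, "MEPS", seed = 100 + i)
    before <- flags_matrix(code_population(claims, reg, "MEPS"))
    extra_unit <- sample(unique(claims$unit_id), 1)
    cs <- condition_codes(reg, sample(condition_ids(reg), 1), "MEPS")
    extra_code <- if (is.null(cs) || cs$kind != "ccs") "999" else
      sample(cs$members, 1)
    more <- rbind(claims, data.frame(unit_id = extra_unit,
                                     record_id = "extra-r1",
                                     code = extra_code))
    after <- flags_matrix(code_population(more, reg, "MEPS"))
    expect_true(all(after[rownames(before), ] >= before))
  }
})

test_that("flags over unavailable conditions are identically false", {
  av <- availability(reg)
  for (did in c("CMS", "MEPS", "NIS")) {
    claims <- random_claims(15, reg, did, seed = 77)
    prof <- code_population(claims, reg, did)
    unavail <- rownames(av)[av[, did] == "unavailable"]
    if (length(unavail)) {
      expect_false(any(as.matrix(as.data.frame(prof)[, unavail])))
    }
  }
  # NHIS: survey input cannot flag conditions the system does not collect
  surv <- data.frame(unit_id = "x", item = "hypertension", response = "yes")
  prof <- code_population(surv, reg, "NHIS")
  unavail <- rownames(av)[av[, "NHIS"] == "unavailable"]
  expect_false(any(as.matrix(as.data.frame(prof)[, unavail])))
})

test_that("coder agrees with the brute-force oracle on small populations", {
  for (did in c("CMS", "MEPS")) {
    claims <- random_claims(50, reg, did, seed = match(did, dialect_ids(reg)))
    prof <- code_population(claims, reg, did)
    oracle <- oracle_code_population(claims, did)
    got <- flags_matrix(prof)[rownames(oracle), colnames(oracle)]
    expect_identical(got == TRUE, oracle == TRUE)
    # conditions outside the oracle's code cells must all be false
    rest <- setdiff(condition_ids(reg), colnames(oracle))
    if (length(rest)) {
      expect_false(any(as.matrix(as.data.frame(prof)[, rest])))
    }
  }
})

test_that("the unit roster fills in all-false profiles for silent units", {
  claims <- data.frame(unit_id = "a", record_id = "r", code = "4019")
  prof <- code_population(claims, reg, "CMS", units = c("a", "b", "c"))
  expect_equal(prof$unit_id, c("a", "b", "c"))
  expect_equal(prof$n_conditions, c(1L, 0L, 0L))
})
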