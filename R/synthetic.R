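# Synthetic multimorbid populations with known truth, plus dialect-specific
# measurement layers: claims emission with extraneous coding noise, and
# survey self-report with imperfect sensitivity/specificity.  All randomness
# derives from a single configured seed, split into fixed per-stage streams,
# so results are reproducible across module boundaries.

.SEED_MOD <- 2147483647  # 2^31 - 1; keep derived seeds in integer range

.stage_seed <- function(seed, stage, dialect_id = NULL) {
  offs <- c(truth = 1L, claims = 100L, survey = 200L)[[stage]]
  d <- if (is.null(dialect_id)) 0L else match(dialect_id, .DIALECTS)
  as.integer((as.numeric(seed) + offs + d) %% .SEED_MOD)
}

#' Default per-condition prevalences for simulation
#'
#' Plausible adult population prevalences for the 20 conditions (order of
#' magnitude of published US adult estimates: common cardiometabolic and
#' musculoskeletal conditions in the 5--30% range, severe mental illness and
#' infectious conditions around or below 1%). These are a stated simulation
#' world, not estimates; see the package vignette.
#'
#' @param registry An `mcc_registry` (supplies the condition ids).
#' @return Named numeric vector over the 20 condition ids.
#' @export
default_prevalence <- function(registry = load_registry()) {
  p <- c(hypertension = 0.30, congestive_heart_failure = 0.02,
         coronary_artery_disease = 0.06, cardiac_arrhythmias = 0.03,
         hyperlipidemia = 0.25, stroke = 0.03, arthritis = 0.23,
         asthma = 0.08, autism_spectrum_disorder = 0.015, cancer = 0.06,
         chronic_kidney_disease = 0.03, copd = 0.06, dementia = 0.015,
         depression = 0.08, diabetes = 0.10, hepatitis = 0.01, hiv = 0.005,
         osteoporosis = 0.05, schizophrenia = 0.01,
         substance_use_disorders = 0.08)
  ids <- condition_ids(registry)
  if (!setequal(names(p), ids)) {
    # a custom registry: spread a generic 5% across its conditions
    p <- stats::setNames(rep(0.05, length(ids)), ids)
  }
  p[ids]
}

#' Latent correlation approximating a pairwise odds ratio
#'
#' Convenience converter for parameterizing the association matrix from a
#' target pairwise odds ratio between two condition indicators, using the
#' classical tetrachoric approximation `rho = cos(pi / (1 + OR^(3/4)))`.
#' The approximation is exact only at OR = 1 (rho = 0) and degrades for
#' extreme prevalences; it is meant for setting plausible association
#' strengths, not for inference.
#'
#' @param or Positive odds ratio(s).
#' @return Latent correlation(s) in (-1, 1).
#' @export
latent_corr_from_or <- function(or) {
  stopifnot(all(or > 0))
  cos(pi / (1 + or^0.75))
}

#' Configuration of a synthetic population
#'
#' Describes the simulated world: marginal condition prevalences, pairwise
#' latent association, claims volume and coding noise, and survey
#' misclassification.
#'
#' @param n_units Number of analysis units (persons/visits/hospitalizations).
#' @param prevalence Named vector of per-condition prevalences in (0, 1);
#'   default [default_prevalence()].
#' @param association Latent correlation matrix (symmetric, unit diagonal,
#'   positive semidefinite) over the conditions; `NULL` means independence.
#' @param claims_per_unit Mean of the Poisson count of additional claims a
#'   unit generates beyond the one guaranteed claim per true measured
#'   condition.
#' @param extraneous_code_rate Proportion of additional emitted codes drawn
#'   from a decoy list of valid-format codes that belong to none of the 20
#'   conditions.
#' @param self_report_sensitivity P(yes | condition present) for survey
#'   items.
#' @param self_report_specificity P(no | condition absent) for survey items.
#' @param seed Integer master seed; every stage derives its stream from it.
#' @param registry An `mcc_registry`.
#' @return An object of class `mcc_sim_config`.
#' @export
synthetic_config <- function(n_units = 10000L,
                             prevalence = default_prevalence(registry),
                             association = NULL,
                             claims_per_unit = 4,
                             extraneous_code_rate = 0.1,
                             self_report_sensitivity = 0.85,
                             self_report_specificity = 0.97,
                             seed = 1L,
                             registry = load_registry()) {
  ids <- condition_ids(registry)
  n_units <- as.integer(n_units)
  stopifnot(n_units >= 1L)
  if (is.null(names(prevalence)) || !setequal(names(prevalence), ids)) {
    stop("prevalence must be a named vector over the registry's ",
         length(ids), " condition ids", call. = FALSE)
  }
  prevalence <- prevalence[ids]
  if (any(prevalence <= 0) || any(prevalence >= 1)) {
    stop("prevalences must lie strictly in (0, 1)", call. = FALSE)
  }
  k <- length(ids)
  if (is.null(association)) association <- diag(k)
  association <- as.matrix(association)
  if (!all(dim(association) == k)) {
    stop("association matrix must be ", k, " x ", k, call. = FALSE)
  }
  if (max(abs(association - t(association))) > 1e-8 ||
      max(abs(diag(association) - 1)) > 1e-8) {
    stop("association must be symmetric with unit diagonal", call. = FALSE)
  }
  ev <- eigen(association, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("association matrix is not positive semidefinite ",
         "(smallest eigenvalue ", signif(min(ev), 4), ")", call. = FALSE)
  }
  dimnames(association) <- list(ids, ids)
  stopifnot(claims_per_unit >= 0,
            extraneous_code_rate >= 0, extraneous_code_rate <= 1,
            self_report_sensitivity >= 0, self_report_sensitivity <= 1,
            self_report_specificity >= 0, self_report_specificity <= 1)
  structure(
    list(n_units = n_units, prevalence = prevalence,
         association = association, claims_per_unit = claims_per_unit,
         extraneous_code_rate = extraneous_code_rate,
         self_report_sensitivity = self_report_sensitivity,
         self_report_specificity = self_report_specificity,
         seed = as.integer(seed)),
    class = "mcc_sim_config")
}

#' Simulate true condition status
#'
#' Draws correlated binary condition indicators via a Gaussian copula: a
#' latent multivariate standard normal with the configured correlation matrix
#' is thresholded at the quantile matching each marginal prevalence, so
#' marginals are exact in expectation and pairwise dependence is governed by
#' the latent correlations. Bit-for-bit reproducible from `(config, seed)`.
#'
#' @param config An [synthetic_config()].
#' @return An object of class `mcc_truth`: list with `unit_id`, `flags`
#'   (n x 20 logical matrix), and `config`.
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "mcc_sim_config"))
  set.seed(.stage_seed(config$seed, "truth"))
  k <- length(config$prevalence)
  n <- config$n_units
  fac <- tryCatch(chol(config$association), error = function(e) NULL)
  z <- matrix(stats::rnorm(n * k), n, k)
  z <- if (!is.null(fac)) {
    z %*% fac
  } else {
    # positive semidefinite but singular: eigen square root
    e <- eigen(config$association, symmetric = TRUE)
    z %*% (e$vectors %*% diag(sqrt(pmax(e$values, 0))) %*% t(e$vectors))
  }
  thresh <- stats::qnorm(1 - config$prevalence)
  flags <- sweep(z, 2L, thresh, ">")
  colnames(flags) <- names(config$prevalence)
  unit_id <- sprintf("U%06d", seq_len(n))
  rownames(flags) <- unit_id
  structure(list(unit_id = unit_id, flags = flags, config = config),
            class = "mcc_truth")
}

#' @export
print.mcc_truth <- function(x, ...) {
  cat("<mcc_truth>", nrow(x$flags), "unit(s) x", ncol(x$flags),
      "conditions | mean count", round(mean(rowSums(x$flags)), 3),
      "| seed", x$config$seed, "\n")
  invisible(x)
}

#' Decoy diagnosis codes
#'
#' Valid-format codes guaranteed to belong to none of the scheme's 20 code
#' sets in the given system, used as extraneous-coding noise. ICD-9-CM decoys
#' additionally avoid any three-digit root the scheme lists, so they stay
#' non-colliding even under prefix matching.
#'
#' @param registry An `mcc_registry`.
#' @param system `"icd9cm"` or `"ccs"`.
#' @return Character vector of normalized decoy codes.
#' @export
decoy_codes <- function(registry, system = c("icd9cm", "ccs")) {
  system <- match.arg(system)
  used <- unlist(lapply(registry$conditions, function(cn) {
    lapply(cn$mappings, function(m) {
      if (!is.null(m$codeset) && m$codeset$kind == system) m$codeset$members
    })
  }), use.names = FALSE)
  if (system == "icd9cm") {
    cand <- paste0(sprintf("%03d", 1:999), "88")
    roots <- unique(substr(used, 1L, 3L))
    cand <- cand[!substr(cand, 1L, 3L) %in% roots]
  } else {
    cand <- as.character(900:999)
  }
  setdiff(cand, used)
}

#' Emit claim records from a true population
#'
#' For every unit, each true condition that the dialect measures through
#' codes yields one guaranteed claim carrying a code drawn uniformly from
#' that condition's registry code set, preferring codes that belong to no
#' other condition in the dialect (the scheme's lists overlap; emitting a
#' shared code would flag a condition the unit does not have, making exact
#' parameter recovery impossible by construction). Conditions whose entire
#' code set is shared — congestive heart failure and chronic kidney disease
#' both map to CCS 108 in MEPS/NIS — fall back to the full set, and their
#' recovered prevalences are irreducibly confounded in those dialects. On
#' top, each unit generates
#' `Poisson(claims_per_unit)` additional claims, each carrying, with
#' probability `extraneous_code_rate`, a decoy code (see [decoy_codes()]) and
#' otherwise a code from one of the unit's true measured conditions. Units
#' with no true measured condition emit additional claims only as decoys, so
#' at extraneous rate 0 they emit nothing — pass the roster to
#' [code_population()]'s `units` argument when coding.
#'
#' @param truth An `mcc_truth` from [simulate_truth()].
#' @param registry An `mcc_registry`.
#' @param dialect_id A dialect with code-based mappings (`MEPS`, `NIS`,
#'   `CMS`).
#' @return Data frame of claim rows: `unit_id`, `record_id`, `code`,
#'   `code_system`, sorted by unit and record.
#' @export
emit_claims <- function(truth, registry = load_registry(), dialect_id) {
  stopifnot(inherits(truth, "mcc_truth"))
  .check_dialect(registry, dialect_id)
  system <- .dialect_code_system(
    registry$dialects[dialect_id, "condition_data_kind"])
  if (is.na(system)) {
    stop("dialect ", dialect_id, " has no code-based mapping; use ",
         "emit_survey()", call. = FALSE)
  }
  config <- truth$config
  set.seed(.stage_seed(config$seed, "claims", dialect_id))

  conds <- colnames(truth$flags)
  codesets <- lapply(conds, function(cid) {
    cs <- registry$conditions[[cid]]$mappings[[dialect_id]]$codeset
    if (!is.null(cs) && cs$kind == system) cs$members else NULL
  })
  names(codesets) <- conds
  # prefer codes that identify exactly one condition in this dialect
  code_count <- table(unlist(codesets))
  codesets <- lapply(codesets, function(m) {
    if (is.null(m)) return(NULL)
    uniq <- m[code_count[m] == 1L]
    if (length(uniq)) uniq else m
  })
  meas <- conds[!vapply(codesets, is.null, logical(1))]

  n <- nrow(truth$flags)
  tm <- truth$flags[, meas, drop = FALSE]

  # guaranteed claim per true measured condition
  idx <- which(tm, arr.ind = TRUE)
  g_unit <- truth$unit_id[idx[, 1L]]
  g_cond <- meas[idx[, 2L]]

  # additional claims
  n_extra <- stats::rpois(n, config$claims_per_unit)
  e_unit_i <- rep(seq_len(n), n_extra)
  n_true <- rowSums(tm)
  is_decoy <- stats::runif(length(e_unit_i)) < config$extraneous_code_rate
  keep <- is_decoy | n_true[e_unit_i] > 0L
  e_unit_i <- e_unit_i[keep]
  is_decoy <- is_decoy[keep]

  true_list <- apply(tm, 1L, function(r) which(r), simplify = FALSE)
  pick <- integer(length(e_unit_i))
  r <- stats::runif(length(e_unit_i))
  for (ii in seq_along(e_unit_i)) {
    if (is_decoy[ii]) next
    tl <- true_list[[e_unit_i[ii]]]
    pick[ii] <- tl[ceiling(r[ii] * length(tl))]
  }
  e_unit <- truth$unit_id[e_unit_i]
  e_cond <- rep(NA_character_, length(e_unit_i))
  e_cond[!is_decoy] <- meas[pick[!is_decoy]]

  all_unit <- c(g_unit, e_unit)
  all_cond <- c(g_cond, e_cond)
  codes <- character(length(all_cond))
  for (cid in meas) {
    rows <- which(!is.na(all_cond) & all_cond == cid)
    if (length(rows)) {
      codes[rows] <- sample(codesets[[cid]], length(rows), replace = TRUE)
    }
  }
  decoy_rows <- which(is.na(all_cond))
  if (length(decoy_rows)) {
    pool <- decoy_codes(registry, system)
    codes[decoy_rows] <- sample(pool, length(decoy_rows), replace = TRUE)
  }

  if (length(all_unit) == 0L) {
    return(data.frame(unit_id = character(0), record_id = character(0),
                      code = character(0), code_system = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- data.frame(unit_id = all_unit, code = codes, code_system = system,
                    stringsAsFactors = FALSE)
  out <- out[order(out$unit_id), , drop = FALSE]
  seq_in_unit <- stats::ave(seq_len(nrow(out)), out$unit_id, FUN = seq_along)
  out$record_id <- sprintf("%s-c%03d", out$unit_id, seq_in_unit)
  rownames(out) <- NULL
  out[, c("unit_id", "record_id", "code", "code_system")]
}

#' Emit survey responses from a true population
#'
#' Each item registered for the dialect is answered `"yes"` with probability
#' `self_report_sensitivity` when the mapped condition is truly present and
#' `1 - self_report_specificity` when absent, independently across items and
#' units, so the expected observed prevalence follows the classical
#' misclassification form `p*s + (1 - p)*(1 - c)`.
#'
#' @param truth An `mcc_truth`.
#' @param registry An `mcc_registry`.
#' @param dialect_id A survey-type dialect (`NHIS`, `NAMCS`).
#' @return Long data frame: `unit_id`, `item`, `response` (`"yes"`/`"no"`).
#' @export
emit_survey <- function(truth, registry = load_registry(), dialect_id) {
  stopifnot(inherits(truth, "mcc_truth"))
  .check_dialect(registry, dialect_id)
  kind <- registry$dialects[dialect_id, "condition_data_kind"]
  if (!kind %in% c("self_report", "checkbox")) {
    stop("dialect ", dialect_id, " is not survey-type; use emit_claims()",
         call. = FALSE)
  }
  config <- truth$config
  set.seed(.stage_seed(config$seed, "survey", dialect_id))
  items <- .dialect_items(registry, dialect_id)
  n <- nrow(truth$flags)
  s <- config$self_report_sensitivity
  cc <- config$self_report_specificity
  out <- lapply(names(items), function(lbl) {
    true <- truth$flags[, items[[lbl]]]
    p_yes <- ifelse(true, s, 1 - cc)
    data.frame(unit_id = truth$unit_id, item = lbl,
               response = ifelse(stats::rbinom(n, 1L, p_yes) == 1L,
                                 "yes", "no"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$unit_id, out$item), , drop = FALSE]
  rownames(out) <- NULL
  out
}
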