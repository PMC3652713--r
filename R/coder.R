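# The coding engine: applies the scheme's per-dialect mappings to
# person/visit/hospitalization records and produces condition profiles
# (one boolean per condition plus the condition count).

#' Coding configuration
#'
#' Parameters governing how records are turned into condition flags. The
#' default rule is "any single qualifying record": one record carrying a
#' member code sets the flag. `min_records_per_condition` generalizes this to
#' claim-count style rules (a condition must be seen on at least k distinct
#' records). Claim-count/reference-period algorithms of specific warehouses
#' are deliberately not reproduced here.
#'
#' @param min_records_per_condition Integer >= 1; distinct records required
#'   before a condition flag is set (claims dialects only).
#' @param prefix_matching If `TRUE`, a listed ICD-9-CM code also matches more
#'   specific codes extending it. Default `FALSE` (exact match on normalized
#'   codes), because the scheme enumerates codes at mixed specificity.
#' @param unknown_code_policy What to do with records whose code does not
#'   parse under the dialect's code system (or whose declared `code_system`
#'   contradicts the dialect): `"warn"` quarantines them with a warning,
#'   `"ignore"` quarantines silently, `"error"` stops.
#' @param count_proxies If `TRUE` (default), conditions measured through a
#'   related proxy (the NHIS weak-or-failing-kidneys question for chronic
#'   kidney disease) are reported under the target condition; if `FALSE`
#'   proxy-measured conditions are never flagged.
#' @return An object of class `mcc_coding_config`.
#' @export
coding_config <- function(min_records_per_condition = 1L,
                          prefix_matching = FALSE,
                          unknown_code_policy = c("warn", "ignore", "error"),
                          count_proxies = TRUE) {
  unknown_code_policy <- match.arg(unknown_code_policy)
  min_records_per_condition <- as.integer(min_records_per_condition)
  stopifnot(length(min_records_per_condition) == 1L,
            min_records_per_condition >= 1L,
            is.logical(prefix_matching), length(prefix_matching) == 1L,
            is.logical(count_proxies), length(count_proxies) == 1L)
  structure(list(min_records_per_condition = min_records_per_condition,
                 prefix_matching = prefix_matching,
                 unknown_code_policy = unknown_code_policy,
                 count_proxies = count_proxies),
            class = "mcc_coding_config")
}

.flaggable_conditions <- function(registry, dialect_id, config) {
  ok_states <- if (config$count_proxies) c("measured", "related_proxy")
               else "measured"
  conds <- condition_ids(registry)
  conds[vapply(conds, function(cid)
    registry$conditions[[cid]]$mappings[[dialect_id]]$state %in% ok_states,
    logical(1))]
}

.quarantine <- function(rows, reason, policy) {
  if (length(rows) == 0L) return(invisible())
  msg <- paste0("quarantining ", length(rows), " record(s): ", reason)
  switch(policy,
         error = stop(msg, call. = FALSE),
         warn = warning(msg, call. = FALSE),
         ignore = invisible())
}

#' Code a population of records into condition profiles
#'
#' The main entry point of the coding engine. For a claims-type dialect
#' (`MEPS`, `NIS`, `CMS`) the input is a data frame of one row per diagnosis
#' code with columns `unit_id`, `record_id`, `code` (and optionally
#' `code_system`); for a survey-type dialect (`NHIS`, `NAMCS`) it is long
#' format with columns `unit_id`, `item`, `response` (`"yes"`, `"no"`,
#' `"missing"`). Output order is deterministic (sorted by `unit_id`)
#' regardless of input order.
#'
#' A condition flag is set when at least `min_records_per_condition` distinct
#' records carry a member code (claims), or when a registered item mapped to
#' the condition has response `"yes"` (survey). One code may set several
#' flags where the scheme's code lists overlap. Conditions the dialect does
#' not measure are identically `FALSE`.
#'
#' @param data Input records (see Details above).
#' @param registry An `mcc_registry`; default [load_registry()].
#' @param dialect_id One of [dialect_ids()].
#' @param config An [coding_config()].
#' @param units Optional character vector of the full unit roster; units with
#'   no records receive an all-`FALSE` profile. Needed when absence of
#'   records is informative (e.g. simulated populations where healthy units
#'   generate no claims).
#' @return An `mcc_profiles` data frame: `unit_id`, 20 logical condition
#'   columns, `n_conditions`; attributes `dialect_id`, `evidence` (data frame
#'   of unit/condition/code/record matches), `summary` (units, records,
#'   quarantined counts) and `condition_ids`.
#' @examples
#' reg <- load_registry()
#' claims <- data.frame(unit_id = "p1", record_id = "c1", code = "402.01")
#' code_population(claims, reg, "CMS")
#' @export
code_population <- function(data, registry = load_registry(), dialect_id,
                            config = coding_config(), units = NULL) {
  stopifnot(inherits(registry, "mcc_registry"),
            inherits(config, "mcc_coding_config"), is.data.frame(data))
  .check_dialect(registry, dialect_id)
  kind <- registry$dialects[dialect_id, "condition_data_kind"]
  if (kind %in% c("icd9_codes", "ccs_codes")) {
    .code_claims(data, registry, dialect_id, config, units)
  } else {
    .code_survey(data, registry, dialect_id, config, units)
  }
}

.profiles_frame <- function(unit_ids, flags, registry, dialect_id, evidence,
                            summary) {
  conds <- condition_ids(registry)
  df <- data.frame(unit_id = unit_ids, stringsAsFactors = FALSE)
  df[conds] <- as.data.frame(flags)
  df$n_conditions <- as.integer(rowSums(flags))
  structure(df, class = c("mcc_profiles", "data.frame"),
            dialect_id = dialect_id, condition_ids = conds,
            evidence = evidence, summary = summary,
            scheme_version = registry$version,
            registry_checksum = registry$checksum)
}

.code_claims <- function(data, registry, dialect_id, config, units) {
  need <- c("unit_id", "record_id", "code")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("claims input must have columns ",
         paste(need, collapse = ", "), " (missing: ",
         paste(miss, collapse = ", "), ")", call. = FALSE)
  }
  system <- .dialect_code_system(
    registry$dialects[dialect_id, "condition_data_kind"])
  data$unit_id <- as.character(data$unit_id)
  data$record_id <- as.character(data$record_id)
  data$code <- as.character(data$code)

  n_quar <- 0L
  if ("code_system" %in% names(data)) {
    bad <- which(!is.na(data$code_system) & data$code_system != system)
    if (length(bad)) {
      .quarantine(bad, paste0("declared code_system differs from the ",
                              dialect_id, " dialect's (", system, ")"),
                  config$unknown_code_policy)
      n_quar <- n_quar + length(bad)
      data <- data[-bad, , drop = FALSE]
    }
  }

  uc <- unique(data$code)
  norm <- vapply(uc, function(cd)
    tryCatch(normalize_code(cd, system), error = function(e) NA_character_),
    character(1))
  bad_codes <- uc[is.na(norm)]
  if (length(bad_codes)) {
    bad_rows <- which(data$code %in% bad_codes)
    .quarantine(bad_rows,
                paste0("unparseable ", system, " code(s): ",
                       paste(utils::head(sQuote(bad_codes), 5L),
                             collapse = ", ")),
                config$unknown_code_policy)
    n_quar <- n_quar + length(bad_rows)
    data <- data[!data$code %in% bad_codes, , drop = FALSE]
  }
  data$norm <- unname(norm[match(data$code, uc)])

  all_units <- sort(unique(c(data$unit_id, as.character(units))))
  conds <- condition_ids(registry)
  flags <- matrix(FALSE, length(all_units), length(conds),
                  dimnames = list(all_units, conds))

  # match unique codes against each flaggable condition's code set
  uniq <- unique(data$norm)
  ev_list <- list()
  for (cid in .flaggable_conditions(registry, dialect_id, config)) {
    cs <- registry$conditions[[cid]]$mappings[[dialect_id]]$codeset
    if (is.null(cs) || !cs$kind %in% c("icd9cm", "ccs")) next
    hit_codes <- uniq[code_in_set(uniq, cs, prefix = config$prefix_matching)]
    if (!length(hit_codes)) next
    sub <- data[data$norm %in% hit_codes,
                c("unit_id", "record_id", "norm"), drop = FALSE]
    n_rec <- tapply(sub$record_id, sub$unit_id,
                    function(r) length(unique(r)))
    hit_units <- names(n_rec)[n_rec >= config$min_records_per_condition]
    flags[hit_units, cid] <- TRUE
    if (nrow(sub)) {
      sub$condition_id <- cid
      ev_list[[cid]] <- sub
    }
  }
  evidence <- if (length(ev_list)) {
    ev <- do.call(rbind, ev_list)
    rownames(ev) <- NULL
    names(ev)[names(ev) == "norm"] <- "code"
    ev[order(ev$unit_id, ev$condition_id, ev$record_id), ]
  } else {
    data.frame(unit_id = character(0), record_id = character(0),
               code = character(0), condition_id = character(0))
  }
  .profiles_frame(all_units, flags, registry, dialect_id, evidence,
                  list(n_units = length(all_units),
                       n_records = length(unique(paste(data$unit_id,
                                                       data$record_id))),
                       n_quarantined = n_quar))
}

.code_survey <- function(data, registry, dialect_id, config, units) {
  need <- c("unit_id", "item", "response")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("survey input must have columns ",
         paste(need, collapse = ", "), " (missing: ",
         paste(miss, collapse = ", "), ")", call. = FALSE)
  }
  data$unit_id <- as.character(data$unit_id)
  data$item <- as.character(data$item)
  data$response <- tolower(as.character(data$response))
  data$response[is.na(data$response)] <- "missing"
  bad_resp <- which(!data$response %in% c("yes", "no", "missing"))
  if (length(bad_resp)) {
    stop("survey responses must be yes/no/missing; offending value(s): ",
         paste(unique(sQuote(data$response[bad_resp])), collapse = ", "),
         call. = FALSE)
  }

  items <- .dialect_items(registry, dialect_id)
  n_quar <- 0L
  unreg <- which(!data$item %in% names(items))
  if (length(unreg)) {
    .quarantine(unreg, paste0("item(s) not registered for ", dialect_id, ": ",
                              paste(unique(sQuote(data$item[unreg])),
                                    collapse = ", ")),
                config$unknown_code_policy)
    n_quar <- n_quar + length(unreg)
    data <- data[-unreg, , drop = FALSE]
  }

  flaggable <- .flaggable_conditions(registry, dialect_id, config)
  all_units <- sort(unique(c(data$unit_id, as.character(units))))
  conds <- condition_ids(registry)
  flags <- matrix(FALSE, length(all_units), length(conds),
                  dimnames = list(all_units, conds))
  yes <- data[data$response == "yes", , drop = FALSE]
  if (nrow(yes)) {
    yes$condition_id <- unname(items[yes$item])
    yes <- yes[yes$condition_id %in% flaggable, , drop = FALSE]
    if (nrow(yes)) {
      flags[cbind(yes$unit_id, yes$condition_id)] <- TRUE
    }
  }
  evidence <- if (nrow(yes)) {
    data.frame(unit_id = yes$unit_id, record_id = NA_character_,
               code = yes$item, condition_id = yes$condition_id,
               stringsAsFactors = FALSE)
  } else {
    data.frame(unit_id = character(0), record_id = character(0),
               code = character(0), condition_id = character(0))
  }
  .profiles_frame(all_units, flags, registry, dialect_id, evidence,
                  list(n_units = length(all_units),
                       n_records = nrow(data), n_quarantined = n_quar))
}

#' Code the claim records of a single analysis unit
#'
#' Convenience wrapper around [code_population()] for one unit.
#'
#' @param records Data frame of claim rows (`unit_id`, `record_id`, `code`),
#'   all with the same `unit_id`.
#' @inheritParams code_population
#' @return An `mcc_profile`: list with `unit_id`, `dialect_id`, `flags`
#'   (named logical over the 20 conditions), `n_conditions`, and `evidence`
#'   (matching codes per flagged condition).
#' @export
code_claims_unit <- function(records, registry = load_registry(), dialect_id,
                             config = coding_config()) {
  stopifnot(is.data.frame(records))
  uids <- unique(as.character(records$unit_id))
  if (length(uids) != 1L) {
    stop("code_claims_unit() expects records for exactly one unit, got ",
         length(uids), call. = FALSE)
  }
  prof <- code_population(records, registry, dialect_id, config, units = uids)
  .as_single_profile(prof, uids)
}

#' Code the survey responses of a single analysis unit
#'
#' @param record Either a long data frame (`unit_id`, `item`, `response`) for
#'   one unit, or a list with elements `unit_id` and `items` (named vector of
#'   `"yes"`/`"no"`/`"missing"`).
#' @inheritParams code_population
#' @return An `mcc_profile` (see [code_claims_unit()]).
#' @export
code_survey_unit <- function(record, registry = load_registry(), dialect_id,
                             config = coding_config()) {
  if (!is.data.frame(record)) {
    stopifnot(is.list(record), !is.null(record$unit_id),
              !is.null(record$items))
    record <- data.frame(unit_id = as.character(record$unit_id),
                         item = names(record$items),
                         response = as.character(unlist(record$items)),
                         stringsAsFactors = FALSE)
  }
  uids <- unique(as.character(record$unit_id))
  if (length(uids) != 1L) {
    stop("code_survey_unit() expects records for exactly one unit, got ",
         length(uids), call. = FALSE)
  }
  prof <- code_population(record, registry, dialect_id, config, units = uids)
  .as_single_profile(prof, uids)
}

.as_single_profile <- function(profiles, unit_id) {
  conds <- attr(profiles, "condition_ids")
  row <- profiles[profiles$unit_id == unit_id, , drop = FALSE]
  ev <- attr(profiles, "evidence")
  ev <- ev[ev$unit_id == unit_id, , drop = FALSE]
  structure(
    list(unit_id = unit_id, dialect_id = attr(profiles, "dialect_id"),
         flags = stats::setNames(as.logical(row[1, conds]), conds),
         n_conditions = row$n_conditions[1],
         evidence = split(ev$code, ev$condition_id)),
    class = "mcc_profile")
}

#' @export
print.mcc_profile <- function(x, ...) {
  cat("<mcc_profile>", x$unit_id, "under", x$dialect_id, "-",
      x$n_conditions, "condition(s)\n")
  if (x$n_conditions > 0L) {
    cat("  ", paste(names(x$flags)[x$flags], collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
print.mcc_profiles <- function(x, ...) {
  s <- attr(x, "summary")
  cat("<mcc_profiles>", nrow(x), "unit(s) under", attr(x, "dialect_id"))
  if (!is.null(s)) cat(" |", s$n_records, "record(s),",
                       s$n_quarantined, "quarantined")
  cat("\n")
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("... (", nrow(x) - 6L, " more unit(s))\n", sep = "")
  invisible(x)
}
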