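# File plumbing.  Delimited text in and out: claims and survey records come
# in as CSV (or JSON-lines), profiles and indicator reports go out as CSV /
# JSON with a metadata header (scheme version, registry checksum, config
# echo, seed) so any output can be traced back to its inputs.

.meta_header <- function(meta) {
  fields <- vapply(names(meta), function(k)
    paste0(k, "=", meta[[k]]), character(1))
  paste0("# oash20 ", paste(fields, collapse = " "))
}

.check_writable <- function(file, force) {
  if (file.exists(file) && !force) {
    stop("output file exists (use force = TRUE to overwrite): ",
         sQuote(file), call. = FALSE)
  }
  invisible(file)
}

#' Read claim records from CSV
#'
#' Expects a header row with at least `unit_id`, `record_id`, `code`
#' (optionally `code_system`); comma-separated, UTF-8, `#` comment lines
#' ignored.
#'
#' @param file Path to the CSV.
#' @return Data frame of character columns.
#' @export
read_claims_csv <- function(file) {
  if (!file.exists(file)) stop("input not found: ", sQuote(file),
                               call. = FALSE)
  utils::read.csv(file, comment.char = "#", colClasses = "character")
}

#' Read long-format survey records from CSV
#'
#' Expects columns `unit_id`, `item`, `response`.
#'
#' @param file Path to the CSV.
#' @return Data frame of character columns.
#' @export
read_survey_csv <- function(file) {
  read_claims_csv(file)
}

#' Write condition profiles to CSV
#'
#' One row per unit: `unit_id`, the 20 condition flag columns, and
#' `n_conditions`, preceded by a `#` metadata line embedding the scheme
#' version, registry checksum and dialect.
#'
#' @param profiles An `mcc_profiles` data frame.
#' @param file Output path.
#' @param force Overwrite an existing file.
#' @param extra_meta Named list merged into the metadata line (e.g. seed,
#'   config echo).
#' @return `file`, invisibly.
#' @export
write_profiles_csv <- function(profiles, file, force = FALSE,
                               extra_meta = list()) {
  stopifnot(inherits(profiles, "mcc_profiles"))
  .check_writable(file, force)
  meta <- c(list(scheme_version = attr(profiles, "scheme_version"),
                 registry_md5 = attr(profiles, "registry_checksum"),
                 dialect = attr(profiles, "dialect_id")),
            extra_meta)
  con <- file(file, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(.meta_header(meta), con)
  utils::write.csv(as.data.frame(profiles), con, row.names = FALSE)
  invisible(file)
}

#' Read condition profiles back from CSV
#'
#' @param file Path written by [write_profiles_csv()].
#' @return An `mcc_profiles` data frame (dialect and version restored from
#'   the metadata line when present).
#' @export
read_profiles_csv <- function(file) {
  if (!file.exists(file)) stop("input not found: ", sQuote(file),
                               call. = FALSE)
  first <- readLines(file, n = 1L)
  meta <- list()
  if (startsWith(first, "# oash20")) {
    kv <- regmatches(first, gregexpr("[a-z_]+=[^ ]+", first))[[1]]
    meta <- stats::setNames(
      as.list(sub("^[a-z_]+=", "", kv)), sub("=.*$", "", kv))
  }
  df <- utils::read.csv(file, comment.char = "#")
  conds <- setdiff(names(df), c("unit_id", "n_conditions"))
  df$unit_id <- as.character(df$unit_id)
  for (cn in conds) df[[cn]] <- as.logical(df[[cn]])
  structure(df, class = c("mcc_profiles", "data.frame"),
            dialect_id = meta$dialect %||% NA_character_,
            condition_ids = conds,
            scheme_version = meta$scheme_version %||% NA_character_,
            registry_checksum = meta$registry_md5 %||% NA_character_)
}

#' Write condition profiles as JSON-lines with evidence
#'
#' First line is a metadata object; each following line is one unit's
#' profile, including the matching codes/items per flagged condition.
#'
#' @inheritParams write_profiles_csv
#' @return `file`, invisibly.
#' @export
write_profiles_jsonl <- function(profiles, file, force = FALSE,
                                 extra_meta = list()) {
  stopifnot(inherits(profiles, "mcc_profiles"))
  .check_writable(file, force)
  conds <- attr(profiles, "condition_ids")
  ev <- attr(profiles, "evidence")
  meta <- c(list(scheme_version = attr(profiles, "scheme_version"),
                 registry_md5 = attr(profiles, "registry_checksum"),
                 dialect = attr(profiles, "dialect_id")),
            extra_meta)
  con <- file(file, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(c(list(meta = TRUE), meta), auto_unbox = TRUE),
             con)
  ev_split <- if (!is.null(ev) && nrow(ev)) split(ev, ev$unit_id) else list()
  for (i in seq_len(nrow(profiles))) {
    uid <- profiles$unit_id[i]
    uev <- ev_split[[uid]]
    obj <- list(
      unit_id = uid,
      flags = as.list(stats::setNames(as.logical(profiles[i, conds]), conds)),
      n_conditions = profiles$n_conditions[i],
      evidence = if (is.null(uev)) stats::setNames(list(), character(0))
                 else lapply(split(uev$code, uev$condition_id), unique)
    )
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE), con)
  }
  invisible(file)
}

#' Write an indicator report as JSON
#'
#' @param indicators An `mcc_indicators` object.
#' @param file Output path.
#' @param force Overwrite an existing file.
#' @param extra_meta Named list merged into the report's `meta` element.
#' @return `file`, invisibly.
#' @export
write_indicators_json <- function(indicators, file, force = FALSE,
                                  extra_meta = list()) {
  stopifnot(inherits(indicators, "mcc_indicators"))
  .check_writable(file, force)
  obj <- list(
    meta = c(list(dialect = indicators$dialect_id), extra_meta),
    n_units = indicators$n_units,
    mcc_threshold = indicators$mcc_threshold,
    mcc_prevalence = indicators$mcc_prevalence,
    per_condition_prevalence = as.list(indicators$per_condition_prevalence),
    count_distribution = as.list(indicators$count_distribution),
    dyads = indicators$dyads,
    weights_used = indicators$weights_used
  )
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Write a coverage report as CSV
#'
#' @param coverage An `mcc_coverage` object from [coverage_report()].
#' @param file Output path.
#' @param force Overwrite an existing file.
#' @return `file`, invisibly.
#' @export
write_coverage_csv <- function(coverage, file, force = FALSE) {
  stopifnot(inherits(coverage, "mcc_coverage"))
  .check_writable(file, force)
  df <- as.data.frame(coverage)
  tot <- attr(coverage, "totals")
  totals_row <- df[1, , drop = FALSE]
  totals_row$condition_id <- "measured_total"
  for (d in setdiff(names(df), "condition_id")) {
    totals_row[[d]] <- as.character(tot[[d]])
  }
  df <- rbind(df, totals_row)
  con <- file(file, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(.meta_header(list(
    scheme_version = attr(coverage, "scheme_version"))), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(file)
}

#' Write the true condition table of a synthetic population to CSV
#'
#' One row per unit with the 20 true condition indicators, for parameter
#' recovery tests.
#'
#' @param truth An `mcc_truth`.
#' @param file Output path.
#' @param force Overwrite an existing file.
#' @return `file`, invisibly.
#' @export
write_truth_csv <- function(truth, file, force = FALSE) {
  stopifnot(inherits(truth, "mcc_truth"))
  .check_writable(file, force)
  df <- data.frame(unit_id = truth$unit_id, truth$flags,
                   stringsAsFactors = FALSE)
  con <- file(file, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(.meta_header(list(seed = truth$config$seed,
                               n_units = truth$config$n_units)), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(file)
}
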