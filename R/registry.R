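# The packaged classification scheme: 20 chronic conditions, each mapped into
# the five HHS data-system dialects (NHIS, NAMCS, MEPS, NIS, CMS).  The JSON
# resource under inst/extdata is the single source of truth; no condition or
# code literal lives in package code.

.DIALECTS <- c("NHIS", "NAMCS", "MEPS", "NIS", "CMS")

.dialect_code_system <- function(condition_data_kind) {
  switch(condition_data_kind,
         icd9_codes = "icd9cm",
         ccs_codes = "ccs",
         NA_character_)
}

#' Load the packaged classification scheme
#'
#' Reads and validates the machine-readable registry of the OASH 20-condition
#' scheme. Every mapping cell of the source table is represented as a parsed
#' code set (ICD-9-CM or CCS, ranges expanded, codes normalized), a
#' survey/checkbox item, or an unavailability marker; the verbatim cell text is
#' retained as provenance. Non-fatal oddities of the source (a code printed
#' under two conditions, cross-system anomalies, dropped transcription
#' artifacts) are collected in the `validation` field rather than raised.
#'
#' @param path Path to a registry JSON resource; default is the packaged one.
#' @param quiet If `FALSE`, validation notes are printed as messages.
#' @return An object of class `mcc_registry`: a list with elements `scheme`,
#'   `version`, `dialects` (data frame mirroring the data-system
#'   characteristics table), `conditions` (named list of condition
#'   definitions, each with parsed per-dialect mappings), `definitions`
#'   (chronic-condition definition feature records), `schemes` (classification
#'   scheme catalog), `mcc_threshold_default`, `validation` (character vector
#'   of collected warnings), `path` and `checksum` (MD5 of the resource).
#' @examples
#' reg <- load_registry()
#' reg
#' @export
load_registry <- function(path = NULL, quiet = TRUE) {
  if (is.null(path)) {
    path <- system.file("extdata", "oash20_registry.json", package = "oash20")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("registry resource not found: ", sQuote(path), call. = FALSE)
  }
  raw <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop("registry is not valid JSON: ",
                             conditionMessage(e), call. = FALSE)
  )

  required <- c("scheme", "version", "dialects", "conditions", "definitions",
                "schemes", "mcc_threshold_default")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("registry schema violation: missing top-level key(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }

  dialects <- do.call(rbind, lapply(raw$dialects, function(d) {
    as.data.frame(d[c("dialect_id", "name", "unit_of_analysis",
                      "condition_data_kind", "operator", "sampling_frame",
                      "data_source")], stringsAsFactors = FALSE)
  }))
  if (!setequal(dialects$dialect_id, .DIALECTS)) {
    stop("registry schema violation: dialects must be exactly ",
         paste(.DIALECTS, collapse = ", "), call. = FALSE)
  }
  rownames(dialects) <- dialects$dialect_id

  if (length(raw$conditions) != 20L) {
    stop("registry schema violation: expected 20 conditions, found ",
         length(raw$conditions), " (",
         paste(vapply(raw$conditions, `[[`, "", "condition_id"),
               collapse = ", "), ")", call. = FALSE)
  }

  validation <- character(0)
  conditions <- list()
  for (cn in raw$conditions) {
    need <- setdiff(c("condition_id", "display_name", "sub_conditions",
                      "mappings"), names(cn))
    if (length(need)) {
      stop("registry schema violation: condition entry missing ",
           paste(need, collapse = ", "), call. = FALSE)
    }
    bad_dialect <- setdiff(names(cn$mappings), .DIALECTS)
    if (length(bad_dialect)) {
      stop("registry schema violation: unknown dialect(s) ",
           paste(bad_dialect, collapse = ", "), " in condition ",
           cn$condition_id, call. = FALSE)
    }
    mappings <- list()
    for (did in .DIALECTS) {
      m <- cn$mappings[[did]]
      if (is.null(m)) {
        stop("registry schema violation: condition ", cn$condition_id,
             " has no mapping for dialect ", did, call. = FALSE)
      }
      codeset <- NULL
      if (m$kind %in% c("icd9cm", "ccs")) {
        drop_invalid <- isTRUE(m$drop_invalid_tokens)
        parsed <- lapply(unlist(m$cells), function(cell) {
          withCallingHandlers(
            parse_codeset_spec(cell, m$kind, drop_invalid = drop_invalid),
            warning = function(w) {
              validation <<- c(validation, paste0(cn$condition_id, "/", did,
                                                  ": ", conditionMessage(w)))
              invokeRestart("muffleWarning")
            }
          )
        })
        members <- sort(unique(unlist(lapply(parsed, `[[`, "members"))))
        codeset <- new_codeset(m$kind, members = members,
                               source_note = paste(unlist(m$cells),
                                                   collapse = "; "))
      } else if (m$kind %in% c("survey_item", "checkbox")) {
        codeset <- new_codeset(m$kind, item_label = m$item_label,
                               source_note = m$source_cell %||% "")
      }
      if (!is.null(m$anomaly)) {
        validation <- c(validation,
                        paste0(cn$condition_id, "/", did, ": ", m$anomaly,
                               " anomaly - ", m$note %||% ""))
      }
      mappings[[did]] <- list(
        state = m$state, kind = m$kind, codeset = codeset,
        item_label = if (!is.null(codeset)) codeset$item_label else NA_character_,
        source_cell = m$source_cell %||%
          paste(unlist(m$cells), collapse = "; "),
        note = m$note %||% ""
      )
    }
    sub <- do.call(rbind, lapply(cn$sub_conditions, function(s) {
      data.frame(name = s$name, alias_of = s$alias_of %||% NA_character_,
                 stringsAsFactors = FALSE)
    }))
    conditions[[cn$condition_id]] <- list(
      condition_id = cn$condition_id,
      display_name = cn$display_name,
      scope_note = cn$scope_note %||% "",
      sub_conditions = sub,
      mappings = mappings
    )
  }

  # cross-condition duplicate codes within a dialect (e.g. hypertensive heart
  # and kidney disease codes shared between conditions) are legitimate overlap
  # in CMS, but a flat duplicate in a CCS column is a source oddity
  for (did in .DIALECTS) {
    tab <- table(unlist(lapply(conditions, function(cn) {
      cs <- cn$mappings[[did]]$codeset
      if (!is.null(cs) && cs$kind %in% c("icd9cm", "ccs")) cs$members
    })))
    dup <- names(tab[tab > 1L])
    if (length(dup)) {
      validation <- c(validation,
                      paste0(did, ": code(s) mapped to more than one ",
                             "condition: ", paste(dup, collapse = ", ")))
    }
  }

  definitions <- do.call(rbind, lapply(raw$definitions, function(d) {
    as.data.frame(d[c("source", "year", "duration_criterion",
                      "functional_limitation", "ongoing_care")],
                  stringsAsFactors = FALSE)
  }))
  if (nrow(definitions) != 10L) {
    stop("registry schema violation: expected 10 definition records, found ",
         nrow(definitions), call. = FALSE)
  }
  schemes <- do.call(rbind, lapply(raw$schemes, function(s) {
    as.data.frame(s[c("scheme_name", "source", "first_year", "n_conditions",
                      "method")], stringsAsFactors = FALSE)
  }))
  if (nrow(schemes) != 5L) {
    stop("registry schema violation: expected 5 scheme records, found ",
         nrow(schemes), call. = FALSE)
  }

  reg <- structure(
    list(scheme = raw$scheme, version = raw$version, dialects = dialects,
         conditions = conditions, definitions = definitions,
         schemes = schemes,
         mcc_threshold_default = as.integer(raw$mcc_threshold_default),
         validation = validation, path = path,
         checksum = unname(tools::md5sum(path))),
    class = "mcc_registry"
  )
  if (!quiet && length(validation)) {
    message("registry validation notes:\n  ",
            paste(validation, collapse = "\n  "))
  }
  reg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mcc_registry <- function(x, ...) {
  cat("<mcc_registry>", x$scheme, "(version", paste0(x$version, ")\n"))
  cat("  ", length(x$conditions), "conditions x", nrow(x$dialects),
      "data-system dialects\n")
  cat("  measured per dialect:",
      paste(vapply(rownames(x$dialects), function(d)
        paste0(d, "=", count_measured(x, d)), character(1)), collapse = " "),
      "\n")
  if (length(x$validation)) {
    cat("  ", length(x$validation), "validation note(s); see $validation\n")
  }
  invisible(x)
}

#' Condition identifiers of the scheme
#' @param registry An `mcc_registry`.
#' @return Character vector of the 20 condition ids, in scheme order.
#' @export
condition_ids <- function(registry) {
  stopifnot(inherits(registry, "mcc_registry"))
  names(registry$conditions)
}

#' Dialect identifiers
#' @param registry An `mcc_registry`.
#' @return Character vector of the 5 dialect ids.
#' @export
dialect_ids <- function(registry) {
  stopifnot(inherits(registry, "mcc_registry"))
  rownames(registry$dialects)
}

.check_dialect <- function(registry, dialect_id) {
  if (!is.character(dialect_id) || length(dialect_id) != 1L ||
      !dialect_id %in% dialect_ids(registry)) {
    stop("unknown dialect: ", sQuote(dialect_id), " (expected one of ",
         paste(dialect_ids(registry), collapse = ", "), ")", call. = FALSE)
  }
  dialect_id
}

#' Flattened code set of a condition in a dialect
#'
#' @param registry An `mcc_registry`.
#' @param condition_id One of [condition_ids()].
#' @param dialect_id One of [dialect_ids()].
#' @return An `mcc_codeset`, or `NULL` when the condition has no code/item
#'   mapping in the dialect.
#' @export
condition_codes <- function(registry, condition_id, dialect_id) {
  stopifnot(inherits(registry, "mcc_registry"))
  .check_dialect(registry, dialect_id)
  cn <- registry$conditions[[condition_id]]
  if (is.null(cn)) stop("unknown condition: ", sQuote(condition_id),
                        call. = FALSE)
  cn$mappings[[dialect_id]]$codeset
}

#' Availability matrix of the scheme
#'
#' Derives the 20 x 5 map of measurement availability. Each cell is one of
#' the three mapping patterns: `"measured"` (a direct measure exists),
#' `"related_proxy"` (a related measure is mapped onto the condition, e.g.
#' the NHIS weak-or-failing-kidneys question standing in for chronic kidney
#' disease), or `"unavailable"`.
#'
#' @param registry An `mcc_registry`.
#' @return A character matrix (conditions x dialects) of class
#'   `mcc_availability`, with a `"provenance"` attribute carrying the verbatim
#'   source cell and encoding note per cell.
#' @export
availability <- function(registry) {
  stopifnot(inherits(registry, "mcc_registry"))
  conds <- condition_ids(registry)
  dials <- dialect_ids(registry)
  states <- matrix(NA_character_, length(conds), length(dials),
                   dimnames = list(conds, dials))
  prov <- states
  for (cid in conds) {
    for (did in dials) {
      m <- registry$conditions[[cid]]$mappings[[did]]
      states[cid, did] <- m$state
      prov[cid, did] <- trimws(paste(m$source_cell, m$note, sep = " | "))
    }
  }
  structure(states, provenance = prov, class = "mcc_availability")
}

#' @export
print.mcc_availability <- function(x, ...) {
  key <- c(measured = "M", related_proxy = "P", unavailable = ".")
  m <- matrix(key[x], nrow(x), ncol(x), dimnames = dimnames(x))
  print(as.table(m))
  tot <- colSums(x == "measured" | x == "related_proxy")
  cat("measured (incl. proxy):",
      paste(names(tot), tot, sep = "=", collapse = "  "), "\n")
  cat("M = measured, P = related proxy, . = unavailable\n")
  invisible(x)
}

#' Number of conditions a data system measures
#'
#' Counts conditions whose availability state is `measured` or
#' `related_proxy` in the dialect (proxies count, matching how the scheme's
#' own per-system totals are tallied).
#'
#' @param registry An `mcc_registry`.
#' @param dialect_id One of [dialect_ids()].
#' @return Integer count out of 20.
#' @examples
#' reg <- load_registry()
#' count_measured(reg, "NHIS")
#' @export
count_measured <- function(registry, dialect_id) {
  stopifnot(inherits(registry, "mcc_registry"))
  .check_dialect(registry, dialect_id)
  av <- availability(registry)
  sum(av[, dialect_id] %in% c("measured", "related_proxy"))
}

#' Reverse lookup: conditions containing a code
#'
#' Returns the set of conditions whose code set in the given dialect contains
#' the code. The result can have more than one element: the scheme's lists
#' overlap (hypertensive heart disease codes, for example, appear under both
#' hypertension and congestive heart failure).
#'
#' @param registry An `mcc_registry`.
#' @param code A single diagnosis code (raw or normalized).
#' @param dialect_id A dialect with a code-based mapping (`MEPS`, `NIS`,
#'   `CMS`); survey dialects raise an error.
#' @param prefix Use prefix matching (see [code_in_set()]).
#' @return Character vector of condition ids (possibly empty).
#' @examples
#' reg <- load_registry()
#' conditions_for_code(reg, "402.01", "CMS")
#' @export
conditions_for_code <- function(registry, code, dialect_id, prefix = FALSE) {
  stopifnot(inherits(registry, "mcc_registry"))
  .check_dialect(registry, dialect_id)
  kind <- registry$dialects[dialect_id, "condition_data_kind"]
  system <- .dialect_code_system(kind)
  if (is.na(system)) {
    stop("dialect ", dialect_id, " has no code-based mapping (condition data: ",
         kind, ")", call. = FALSE)
  }
  stopifnot(length(code) == 1L)
  hits <- vapply(registry$conditions, function(cn) {
    cs <- cn$mappings[[dialect_id]]$codeset
    !is.null(cs) && cs$kind == system && code_in_set(code, cs, prefix = prefix)
  }, logical(1))
  names(hits)[hits]
}

#' Feature matrix of published chronic-condition definitions
#'
#' One row per definition source, with the key components each definition
#' requires: a duration criterion, functional limitation, and need for
#' ongoing medical care.
#'
#' @param registry An `mcc_registry`.
#' @return A data frame with 10 rows.
#' @export
definition_feature_matrix <- function(registry) {
  stopifnot(inherits(registry, "mcc_registry"))
  registry$definitions
}

#' Catalog of chronic-condition classification schemes
#'
#' @param registry An `mcc_registry`.
#' @return A data frame with one row per scheme (source, first year, number
#'   of conditions, development method).
#' @export
scheme_catalog <- function(registry) {
  stopifnot(inherits(registry, "mcc_registry"))
  registry$schemes
}

#' Audit export of the registry
#'
#' Writes one row per condition x dialect x code (or item / unavailability
#' marker) so the full scheme can be reviewed outside R.
#'
#' @param registry An `mcc_registry`.
#' @param file Path of the CSV to write.
#' @return The exported data frame, invisibly.
#' @export
registry_audit_csv <- function(registry, file) {
  stopifnot(inherits(registry, "mcc_registry"))
  rows <- list()
  for (cid in condition_ids(registry)) {
    for (did in dialect_ids(registry)) {
      m <- registry$conditions[[cid]]$mappings[[did]]
      cs <- m$codeset
      if (!is.null(cs) && cs$kind %in% c("icd9cm", "ccs")) {
        disp <- if (cs$kind == "icd9cm") format_icd9(cs$members) else cs$members
        rows[[length(rows) + 1L]] <- data.frame(
          condition_id = cid, dialect_id = did, state = m$state,
          kind = cs$kind, code = cs$members, code_display = disp,
          source_cell = cs$source_note, stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          condition_id = cid, dialect_id = did, state = m$state,
          kind = m$kind, code = NA_character_,
          code_display = if (!is.null(cs)) cs$item_label else NA_character_,
          source_cell = m$source_cell, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  utils::write.csv(out, file, row.names = FALSE)
  invisible(out)
}

# item label -> condition id lookup for a survey-type dialect
.dialect_items <- function(registry, dialect_id) {
  items <- character(0)
  for (cid in condition_ids(registry)) {
    m <- registry$conditions[[cid]]$mappings[[dialect_id]]
    if (m$kind %in% c("survey_item", "checkbox") &&
        m$state %in% c("measured", "related_proxy")) {
      items[m$codeset$item_label] <- cid
    }
  }
  items
}
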