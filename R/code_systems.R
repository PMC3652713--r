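# Diagnosis-code vocabularies used by the scheme: ICD-9-CM (claims) and the
# AHRQ Clinical Classifications Software (CCS) integer categories.  A code is
# carried around in *normalized compact form*: ICD-9-CM with the decimal point
# removed ("402.01" -> "40201", "V10.3" -> "V103"), CCS as a plain positive
# integer rendered as text.

.ICD9_DOTTED <- "^(V[0-9]{2}|[0-9]{3})(\\.[0-9]{1,2})?$"
.ICD9_COMPACT <- "^(V[0-9]{2}|[0-9]{3})([0-9]{1,2})?$"

#' Normalize ICD-9-CM diagnosis codes
#'
#' Converts dotted or compact ICD-9-CM diagnosis codes to the compact
#' normalized form used throughout the package: whitespace stripped, a lower
#' case leading `v` folded to `V`, and the decimal point removed, leaving a
#' three-character root (`"016"`, `"V10"`) plus up to two decimal digits.
#' Normalization is idempotent, and the dotted and compact spellings of a code
#' normalize identically.
#'
#' E-codes (external-cause codes) are rejected: none appear in the 20-condition
#' scheme, so their presence signals a data-quality problem worth surfacing.
#'
#' @param raw Character vector of diagnosis codes, dotted or compact.
#' @return Character vector of normalized compact codes.
#' @seealso [format_icd9()] for the inverse (dotted display form).
#' @examples
#' normalize_icd9(c("402.01", "V10.3", "585", "40201"))
#' @export
normalize_icd9 <- function(raw) {
  if (length(raw) == 0L) return(character(0))
  x <- gsub("[[:space:]]+", "", as.character(raw))
  x <- sub("^v", "V", x)
  bad <- !grepl(.ICD9_DOTTED, x) & !grepl(.ICD9_COMPACT, x)
  if (any(bad)) {
    stop("invalid ICD-9-CM diagnosis code(s): ",
         paste(sQuote(unique(raw[bad])), collapse = ", "),
         call. = FALSE)
  }
  gsub(".", "", x, fixed = TRUE)
}

#' Format normalized ICD-9-CM codes for display
#'
#' Inverse of [normalize_icd9()]: re-inserts the decimal point after the
#' three-character root. Three-character codes (e.g. `"585"`, `"412"`) have no
#' fractional part and are returned unchanged.
#'
#' @param code Character vector of normalized compact ICD-9-CM codes.
#' @return Character vector in dotted display form.
#' @examples
#' format_icd9(c("40201", "585", "V103"))
#' @export
format_icd9 <- function(code) {
  code <- as.character(code)
  ok <- grepl(.ICD9_COMPACT, code)
  if (any(!ok)) {
    stop("not normalized ICD-9-CM code(s): ",
         paste(sQuote(unique(code[!ok])), collapse = ", "), call. = FALSE)
  }
  ifelse(nchar(code) > 3L,
         paste0(substr(code, 1L, 3L), ".", substr(code, 4L, nchar(code))),
         code)
}

#' Normalize CCS category codes
#'
#' CCS categories are positive integers; normalization strips whitespace and
#' leading zeros and renders the value as text.
#'
#' @param raw Character or integer vector of CCS categories.
#' @return Character vector of normalized CCS codes.
#' @export
normalize_ccs <- function(raw) {
  if (length(raw) == 0L) return(character(0))
  x <- gsub("[[:space:]]+", "", as.character(raw))
  bad <- !grepl("^[0-9]+$", x) | suppressWarnings(as.numeric(x)) < 1
  bad[is.na(bad)] <- TRUE
  if (any(bad)) {
    stop("invalid CCS category code(s): ",
         paste(sQuote(unique(raw[bad])), collapse = ", "), call. = FALSE)
  }
  as.character(as.integer(x))
}

#' Normalize codes under a named code system
#'
#' @param raw Character vector of codes.
#' @param system `"icd9cm"` or `"ccs"`.
#' @return Character vector of normalized codes.
#' @export
normalize_code <- function(raw, system = c("icd9cm", "ccs")) {
  system <- match.arg(system)
  if (system == "icd9cm") normalize_icd9(raw) else normalize_ccs(raw)
}

new_codeset <- function(kind, members = character(0), item_label = NA_character_,
                        alias_of = NA_character_, source_note = "") {
  stopifnot(kind %in% c("icd9cm", "ccs", "survey_item", "checkbox",
                        "unavailable", "alias"))
  if (kind %in% c("icd9cm", "ccs") && length(members) == 0L) {
    stop("a ", kind, " code set must have at least one member", call. = FALSE)
  }
  if (!kind %in% c("icd9cm", "ccs") && length(members) > 0L) {
    stop("only icd9cm/ccs code sets carry code members", call. = FALSE)
  }
  structure(
    list(kind = kind, members = members, item_label = item_label,
         alias_of = alias_of, source_note = source_note),
    class = "mcc_codeset"
  )
}

#' @export
print.mcc_codeset <- function(x, ...) {
  cat("<mcc_codeset> kind:", x$kind)
  if (length(x$members)) {
    shown <- utils::head(x$members, 8L)
    cat(" |", length(x$members), "code(s):",
        paste(shown, collapse = ", "),
        if (length(x$members) > 8L) "..." else "")
  }
  if (!is.na(x$item_label)) cat(" | item:", x$item_label)
  if (!is.na(x$alias_of)) cat(" | alias of:", x$alias_of)
  cat("\n")
  invisible(x)
}

.SENTINEL_UNAVAILABLE <- c("Not applicable", "—", "-", "--", "NA")

#' Parse one mapping cell of the classification table
#'
#' A cell is either a comma-separated list of codes and/or inclusive integer
#' ranges (en dash or hyphen, CCS only), or a sentinel: `"Not applicable"` /
#' an em dash (condition unavailable in the data system), `"Self-reported"`,
#' `"Checkbox"`/`"Checkbox for <x>"` (survey-type items), or
#' `"Included in <condition>"` (the row's codes belong to another condition).
#'
#' Ranges expand inclusively (`"105-106"` has 2 members, `"11-43"` has 33);
#' duplicates are removed. Descending range bounds are an error, as is a range
#' in an ICD-9-CM cell.
#'
#' @param cell Character scalar, the verbatim cell text.
#' @param system `"ccs"` or `"icd9cm"` — the code system the column declares.
#' @param drop_invalid If `TRUE`, a token that does not parse under `system`
#'   is dropped with a warning instead of raising an error (used for a known
#'   transcription artifact in the packaged resource).
#' @return An `mcc_codeset`: `kind` is the code system for code cells, or
#'   `"survey_item"`, `"checkbox"`, `"unavailable"` or `"alias"` for sentinels.
#' @examples
#' parse_codeset_spec("105-106", "ccs")
#' parse_codeset_spec("272.0, 272.1, 272.2", "icd9cm")
#' parse_codeset_spec("Included in coronary artery disease", "ccs")
#' @export
parse_codeset_spec <- function(cell, system = c("ccs", "icd9cm"),
                               drop_invalid = FALSE) {
  system <- match.arg(system)
  stopifnot(is.character(cell), length(cell) == 1L)
  trimmed <- trimws(cell)

  if (trimmed %in% .SENTINEL_UNAVAILABLE) {
    return(new_codeset("unavailable", source_note = cell))
  }
  if (identical(trimmed, "Self-reported")) {
    return(new_codeset("survey_item", item_label = trimmed, source_note = cell))
  }
  if (identical(trimmed, "Checkbox") || startsWith(trimmed, "Checkbox for ")) {
    return(new_codeset("checkbox", item_label = trimmed, source_note = cell))
  }
  if (startsWith(trimmed, "Included in ")) {
    target <- trimws(sub("^Included in ", "", trimmed))
    return(new_codeset("alias", alias_of = target, source_note = cell))
  }

  tokens <- unlist(strsplit(trimmed, ","))
  # a malformed cell can hide extra tokens behind internal whitespace
  tokens <- unlist(strsplit(trimws(tokens), "[[:space:]]+"))
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0L) {
    stop("empty code cell: ", sQuote(cell), call. = FALSE)
  }

  range_re <- "^([0-9]+)[–—-]([0-9]+)$"
  members <- character(0)
  for (tok in tokens) {
    if (grepl(range_re, tok)) {
      if (system != "ccs") {
        stop("code ranges are only defined for CCS cells: ", sQuote(tok),
             call. = FALSE)
      }
      lo <- as.integer(sub(range_re, "\\1", tok))
      hi <- as.integer(sub(range_re, "\\2", tok))
      if (hi < lo) {
        stop("descending range bounds in ", sQuote(tok), call. = FALSE)
      }
      members <- c(members, as.character(lo:hi))
    } else {
      norm <- tryCatch(normalize_code(tok, system), error = function(e) e)
      if (inherits(norm, "error")) {
        if (drop_invalid) {
          warning("dropping invalid token ", sQuote(tok), " in cell ",
                  sQuote(cell), call. = FALSE)
          next
        }
        stop(conditionMessage(norm), " (in cell ", sQuote(cell), ")",
             call. = FALSE)
      }
      members <- c(members, norm)
    }
  }
  if (length(members) == 0L) {
    stop("no valid codes remain in cell ", sQuote(cell), call. = FALSE)
  }
  new_codeset(system, members = sort(unique(members)), source_note = cell)
}

#' Test code membership in a code set
#'
#' Default semantics are exact match on normalized codes: the scheme
#' enumerates codes explicitly at mixed specificity (a list may carry both
#' `"585"` and `"585.1"`), so prefix expansion would silently widen some
#' definitions. With `prefix = TRUE`, a listed code also matches any more
#' specific code that extends it (so a listed `"585"` matches `"5853"`).
#'
#' @param code Character vector of raw or normalized codes.
#' @param codeset An `mcc_codeset` with kind `"icd9cm"` or `"ccs"`.
#' @param prefix Use prefix matching (default `FALSE`).
#' @return Logical vector.
#' @export
code_in_set <- function(code, codeset, prefix = FALSE) {
  stopifnot(inherits(codeset, "mcc_codeset"))
  if (!codeset$kind %in% c("icd9cm", "ccs")) {
    stop("code membership is only defined for icd9cm/ccs code sets, not ",
         sQuote(codeset$kind), call. = FALSE)
  }
  norm <- normalize_code(code, codeset$kind)
  if (!prefix || codeset$kind == "ccs") {
    return(norm %in% codeset$members)
  }
  vapply(norm, function(cd) any(startsWith(cd, codeset$members)), logical(1),
         USE.NAMES = FALSE)
}
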