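# Population-level chronic-condition indicators: per-condition prevalence,
# MCC prevalence (2+ concurrent conditions by default), the condition-count
# distribution, dyad co-occurrence, and the cross-system coverage report.

#' Multimorbidity test
#'
#' `TRUE` exactly when a unit has at least `threshold` concurrent chronic
#' conditions. The default threshold of 2 follows the common definition of
#' "multiple" as 2 or more concurrent chronic conditions.
#'
#' @param x An `mcc_profiles` data frame, a single `mcc_profile`, or a
#'   numeric vector of condition counts.
#' @param threshold Integer >= 1, default 2.
#' @return Logical vector.
#' @export
has_mcc <- function(x, threshold = 2L) {
  stopifnot(length(threshold) == 1L, threshold >= 1L)
  counts <- if (inherits(x, "mcc_profile")) x$n_conditions
            else if (is.data.frame(x)) x$n_conditions
            else as.numeric(x)
  if (is.null(counts)) stop("cannot find condition counts in input",
                            call. = FALSE)
  counts >= threshold
}

#' Compute population indicators from condition profiles
#'
#' Turns per-unit condition profiles into the indicator set of the conceptual
#' model: (weighted) per-condition prevalence, MCC prevalence at a threshold
#' (default: 2 or more concurrent conditions), the condition-count
#' distribution (top-coded at `"4+"` by default), and dyad co-occurrence
#' counts.
#'
#' @param profiles An `mcc_profiles` data frame from [code_population()], or
#'   any data frame with `unit_id`, logical condition columns and
#'   `n_conditions`.
#' @param mcc_threshold Integer >= 1; default 2.
#' @param weights Optional nonnegative per-unit weights (plain analysis
#'   weights; design-based variance estimation is out of scope). Equal
#'   weights reduce exactly to the unweighted estimator.
#' @param count_bins Integer vector of exact-count bins; counts above the
#'   maximum are pooled into a `"<max+1>+"` bin.
#' @return An object of class `mcc_indicators`: list with `dialect_id`,
#'   `n_units`, `per_condition_prevalence`, `mcc_threshold`,
#'   `mcc_prevalence`, `count_distribution`, `dyads` (data frame of unordered
#'   condition pairs with weighted co-occurrence counts), `weights_used`.
#' @examples
#' reg <- load_registry()
#' claims <- data.frame(unit_id = c("a", "a", "b"),
#'                      record_id = c("r1", "r2", "r3"),
#'                      code = c("401.9", "250.00", "428.0"))
#' ind <- compute_indicators(code_population(claims, reg, "CMS"))
#' ind$mcc_prevalence
#' @export
compute_indicators <- function(profiles, mcc_threshold = 2L, weights = NULL,
                               count_bins = 0:3) {
  stopifnot(is.data.frame(profiles))
  if (nrow(profiles) == 0L) {
    stop("cannot compute indicators for an empty population", call. = FALSE)
  }
  mcc_threshold <- as.integer(mcc_threshold)
  stopifnot(length(mcc_threshold) == 1L, mcc_threshold >= 1L)
  conds <- attr(profiles, "condition_ids") %||%
    setdiff(names(profiles), c("unit_id", "n_conditions"))
  flags <- as.matrix(as.data.frame(profiles)[, conds, drop = FALSE])
  storage.mode(flags) <- "numeric"
  counts <- if ("n_conditions" %in% names(profiles)) profiles$n_conditions
            else rowSums(flags)

  if (is.null(weights)) {
    w <- rep(1, nrow(profiles))
    weights_used <- FALSE
  } else {
    w <- as.numeric(weights)
    if (length(w) != nrow(profiles)) {
      stop("weights must align with units: ", length(w), " weights for ",
           nrow(profiles), " units", call. = FALSE)
    }
    if (any(is.na(w)) || any(w < 0)) {
      stop("weights must be nonnegative and non-missing", call. = FALSE)
    }
    if (sum(w) == 0) stop("weights must not all be zero", call. = FALSE)
    weights_used <- TRUE
  }
  W <- sum(w)

  prev <- colSums(flags * w) / W
  mcc_prev <- sum(w[counts >= mcc_threshold]) / W

  count_bins <- sort(unique(as.integer(count_bins)))
  top <- max(count_bins)
  bin_labels <- c(as.character(count_bins), paste0(top + 1L, "+"))
  dist <- vapply(count_bins, function(k) sum(w[counts == k]) / W, numeric(1))
  dist <- c(dist, sum(w[counts > top]) / W)
  names(dist) <- bin_labels

  co <- t(flags * w) %*% flags
  pairs <- which(upper.tri(co) & co > 0, arr.ind = TRUE)
  dyads <- data.frame(
    condition_a = conds[pairs[, 1L]],
    condition_b = conds[pairs[, 2L]],
    count = co[pairs],
    stringsAsFactors = FALSE
  )
  dyads <- dyads[order(-dyads$count, dyads$condition_a, dyads$condition_b), ]
  rownames(dyads) <- NULL

  structure(
    list(dialect_id = attr(profiles, "dialect_id") %||% NA_character_,
         n_units = nrow(profiles),
         per_condition_prevalence = prev,
         mcc_threshold = mcc_threshold,
         mcc_prevalence = mcc_prev,
         count_distribution = dist,
         dyads = dyads,
         weights_used = weights_used),
    class = "mcc_indicators")
}

#' @export
print.mcc_indicators <- function(x, digits = 3, ...) {
  cat("<mcc_indicators>", x$n_units, "unit(s)")
  if (!is.na(x$dialect_id)) cat(" under", x$dialect_id)
  if (x$weights_used) cat(" (weighted)")
  cat("\n  MCC prevalence (>=", x$mcc_threshold, "conditions):",
      round(x$mcc_prevalence, digits), "\n")
  cat("  condition count distribution:\n")
  print(round(x$count_distribution, digits))
  top <- utils::head(sort(x$per_condition_prevalence, decreasing = TRUE), 5L)
  cat("  top prevalences:",
      paste(names(top), round(top, digits), sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' Cross-system coverage report
#'
#' Renders the 20 x 5 availability matrix with the three mapping-pattern
#' labels and per-system totals (proxy-measured conditions count toward a
#' system's total).
#'
#' @param registry An `mcc_registry`.
#' @return An object of class `mcc_coverage`: data frame of one row per
#'   condition with a label per dialect, plus a `totals` attribute.
#' @examples
#' coverage_report(load_registry())
#' @export
coverage_report <- function(registry) {
  stopifnot(inherits(registry, "mcc_registry"))
  av <- availability(registry)
  df <- data.frame(condition_id = rownames(av),
                   unclass(as.data.frame(unclass(av))),
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  totals <- colSums(av == "measured" | av == "related_proxy")
  structure(df, class = c("mcc_coverage", "data.frame"),
            totals = totals, scheme_version = registry$version)
}

#' @export
print.mcc_coverage <- function(x, ...) {
  df <- as.data.frame(x)
  dialects <- setdiff(names(df), "condition_id")
  wide <- max(nchar(df$condition_id))
  key <- c(measured = "measured", related_proxy = "proxy",
           unavailable = "-")
  cat(formatC("condition", width = wide + 2, flag = "-"),
      paste(formatC(dialects, width = 9), collapse = ""), "\n")
  for (i in seq_len(nrow(df))) {
    cat(formatC(df$condition_id[i], width = wide + 2, flag = "-"),
        paste(formatC(unname(key[unlist(df[i, dialects])]), width = 9),
              collapse = ""), "\n")
  }
  tot <- attr(x, "totals")
  cat(formatC("measured (of 20)", width = wide + 2, flag = "-"),
      paste(formatC(tot[dialects], width = 9), collapse = ""), "\n")
  invisible(x)
}

#' Compare indicator reports across data-system dialects
#'
#' Quantifies how the same underlying population is seen through different
#' measurement dialects: per-condition prevalence differences and the MCC
#' prevalence difference for every pair of reports. Conditions measurable in
#' one dialect of a pair but not the other are flagged structurally
#' incomparable — a prevalence difference there reflects the instrument, not
#' the population.
#'
#' @param reports List of at least two `mcc_indicators` objects.
#' @param registry An `mcc_registry` (used for availability states).
#' @return A data frame of class `mcc_dialect_comparison` with columns
#'   `dialect_a`, `dialect_b`, `measure` (condition id or `"mcc"`),
#'   `value_a`, `value_b`, `difference`, `structurally_incomparable`.
#' @export
compare_dialects <- function(reports, registry = load_registry()) {
  if (!is.list(reports) || length(reports) < 2L ||
      !all(vapply(reports, inherits, logical(1), "mcc_indicators"))) {
    stop("compare_dialects() needs a list of >= 2 mcc_indicators reports",
         call. = FALSE)
  }
  av <- availability(registry)
  out <- list()
  for (i in seq_len(length(reports) - 1L)) {
    for (j in seq((i + 1L), length(reports))) {
      a <- reports[[i]]; b <- reports[[j]]
      conds <- union(names(a$per_condition_prevalence),
                     names(b$per_condition_prevalence))
      pa <- a$per_condition_prevalence[conds]
      pb <- b$per_condition_prevalence[conds]
      incomp <- rep(FALSE, length(conds))
      if (!is.na(a$dialect_id) && !is.na(b$dialect_id) &&
          all(conds %in% rownames(av))) {
        ma <- av[conds, a$dialect_id] != "unavailable"
        mb <- av[conds, b$dialect_id] != "unavailable"
        incomp <- xor(ma, mb)
      }
      out[[length(out) + 1L]] <- data.frame(
        dialect_a = a$dialect_id, dialect_b = b$dialect_id,
        measure = c(conds, "mcc"),
        value_a = c(unname(pa), a$mcc_prevalence),
        value_b = c(unname(pb), b$mcc_prevalence),
        difference = c(unname(pa - pb), a$mcc_prevalence - b$mcc_prevalence),
        structurally_incomparable = c(incomp, FALSE),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("mcc_dialect_comparison", "data.frame")
  res
}
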