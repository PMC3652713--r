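# Independent brute-force oracle: scans the raw printed mapping cells of the
# registry resource with plain string operations (no package parsing/coding
# code), and codes a population by linear search.  Deliberately primitive so
# it cannot share a defect with the implementation under test.

registry_json_path <- function() {
  system.file("extdata", "oash20_registry.json", package = "oash20")
}

# condition -> set of compact code tokens, straight from the printed cells
oracle_cells <- function(dialect) {
  raw <- jsonlite::fromJSON(registry_json_path(), simplifyVector = FALSE)
  out <- list()
  for (cn in raw$conditions) {
    m <- cn$mappings[[dialect]]
    if (is.null(m) || !m$kind %in% c("icd9cm", "ccs")) next
    toks <- character(0)
    for (cell in unlist(m$cells)) {
      for (tok in strsplit(cell, "[,[:space:]]+")[[1]]) {
        if (!nzchar(tok)) next
        if (grepl("^[0-9]+[–—-][0-9]+$", tok)) {
          bounds <- as.integer(strsplit(tok, "[–—-]")[[1]])
          toks <- c(toks, as.character(seq(bounds[1], bounds[2])))
        } else {
          toks <- c(toks, toupper(gsub(".", "", tok, fixed = TRUE)))
        }
      }
    }
    out[[cn$condition_id]] <- toks
  }
  out
}

# flags by linear scan; any single matching record sets the flag
oracle_code_population <- function(claims, dialect, units = NULL) {
  cells <- oracle_cells(dialect)
  all_units <- sort(unique(c(as.character(claims$unit_id),
                             as.character(units))))
  flags <- matrix(FALSE, length(all_units), length(cells),
                  dimnames = list(all_units, names(cells)))
  for (u in all_units) {
    codes <- toupper(gsub(".", "",
                          claims$code[claims$unit_id == u], fixed = TRUE))
    for (cid in names(cells)) {
      flags[u, cid] <- any(codes %in% cells[[cid]])
    }
  }
  flags
}

# small random claims population over scheme + decoy codes
random_claims <- function(n_units, registry, dialect, seed,
                          codes_per_unit = 4) {
  set.seed(seed)
  system <- if (dialect == "CMS") "icd9cm" else "ccs"
  pool <- unlist(lapply(condition_ids(registry), function(cid) {
    cs <- condition_codes(registry, cid, dialect)
    if (!is.null(cs) && cs$kind == system) cs$members
  }))
  pool <- c(pool, decoy_codes(registry, system))
  units <- sprintf("u%03d", seq_len(n_units))
  rows <- lapply(units, function(u) {
    k <- sample(0:codes_per_unit, 1)
    if (k == 0) return(NULL)
    data.frame(unit_id = u, record_id = paste0(u, "-r", seq_len(k)),
               code = sample(pool, k, replace = TRUE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

flags_matrix <- function(profiles) {
  conds <- attr(profiles, "condition_ids")
  m <- as.matrix(as.data.frame(profiles)[, conds])
  rownames(m) <- profiles$unit_id
  m
}
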