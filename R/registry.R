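# Harmful-VOC compound panel: loading, validation, exact mass, exposure limits.

#' Hazard classes recognised in the harmful-VOC panel
#'
#' @format Character vector of the seven hazard flags a panel compound may
#'   carry: carcinogenic, mutagenic, teratogenic, acute_toxic, corrosive,
#'   irritant, odor.
#' @export
HAZARD_CLASSES <- c("carcinogenic", "mutagenic", "teratogenic",
                    "acute_toxic", "corrosive", "irritant", "odor")

.registry_columns <- c("name", "cas", "formula", "mw_g_mol", "hazards",
                       "limit_osha_ppb", "limit_niosh_ppb", "limit_suspect",
                       "avg_ppb_paper", "max_ppb_paper")

#' Load a harmful-VOC compound registry
#'
#' Reads a compound panel from a CSV registry file and validates it. The
#' packaged panel (`path = "packaged"`) transcribes the 32-compound harmful
#' panel measured at surgeon level without smoke evacuation in a thoracic-OR
#' PTR-TOF-MS study: compound identity (name, CAS), hazard classes, OSHA and
#' NIOSH permissible exposure limits where assessed, and the study's average
#' and maximum detected concentrations (ppb by volume). Molecular formulas
#' and weights are supplied from compound identity (the source table lists
#' CAS numbers only); rows whose PTR-MS signal covers several isobaric
#' compounds are kept as one record with all CAS numbers attached and the
#' molecular weight of the first-listed compound.
#'
#' Two limit cells are transcribed verbatim but carry `limit_suspect = TRUE`
#' because their unit scale is doubtful (methanol "4200", ethanol "100,0000";
#' regulatory limits for both are conventionally quoted in ppm). Downstream
#' exceedance screening evaluates suspect limits but reports them separately.
#'
#' @param path Path to a registry CSV, or `"packaged"` for the built-in panel.
#' @return A `compound_table`: a data.frame with one row per compound and
#'   columns `name`, `cas` (semicolon-joined), `formula`, `mw_g_mol`,
#'   `hazards` (semicolon-joined flags), `limit_osha_ppb`, `limit_niosh_ppb`
#'   (NA = not assessed), `limit_suspect`, `avg_ppb_paper`, `max_ppb_paper`.
#' @examples
#' reg <- load_registry()
#' nrow(reg)                  # 32
#' reg$name[1]                # "Hydrogen cyanide"
#' @export
load_registry <- function(path = "packaged") {
  if (identical(path, "packaged")) {
    path <- system.file("extdata", "harmful_voc_panel.csv", package = "orsmoke",
                        mustWork = TRUE)
    version <- "packaged-1"
  } else {
    version <- basename(path)
  }
  if (!file.exists(path)) {
    stop("registry file not found: ", path)
  }
  raw <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE,
                    colClasses = c(limit_suspect = "logical")),
    error = function(e) stop("registry format error: ", conditionMessage(e))
  )
  missing_cols <- setdiff(.registry_columns, names(raw))
  if (length(missing_cols) > 0) {
    stop("registry format error: missing required column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(raw) == 0) {
    stop("registry format error: no compound rows")
  }
  raw <- raw[.registry_columns]
  for (col in c("mw_g_mol", "limit_osha_ppb", "limit_niosh_ppb",
                "avg_ppb_paper", "max_ppb_paper")) {
    raw[[col]] <- suppressWarnings(as.numeric(raw[[col]]))
  }
  validate_registry(raw)
  structure(raw, class = c("compound_table", "data.frame"), version = version)
}

# Row-level validation; reports the first offending row by number.
validate_registry <- function(tbl) {
  dup <- duplicated(tbl$name)
  if (any(dup)) {
    stop("registry validation error: duplicate compound name '",
         tbl$name[which(dup)[1]], "' at row ", which(dup)[1])
  }
  for (i in seq_len(nrow(tbl))) {
    r <- tbl[i, ]
    if (is.na(r$name) || !nzchar(r$name)) {
      stop("registry validation error at row ", i, ": empty name")
    }
    if (is.na(r$mw_g_mol) || r$mw_g_mol <= 0) {
      stop("registry validation error at row ", i, " (", r$name,
           "): molecular weight must be > 0")
    }
    flags <- hazard_flags(r$hazards)
    if (length(flags) == 0) {
      stop("registry validation error at row ", i, " (", r$name,
           "): hazard flags must be non-empty")
    }
    bad <- setdiff(flags, HAZARD_CLASSES)
    if (length(bad) > 0) {
      stop("registry validation error at row ", i, " (", r$name,
           "): unknown hazard flag(s) ", paste(bad, collapse = ", "))
    }
    for (lim in c("limit_osha_ppb", "limit_niosh_ppb")) {
      if (!is.na(r[[lim]]) && r[[lim]] <= 0) {
        stop("registry validation error at row ", i, " (", r$name,
             "): ", lim, " must be > 0 when present")
      }
    }
    if (!is.na(r$avg_ppb_paper) && !is.na(r$max_ppb_paper) &&
        r$avg_ppb_paper > r$max_ppb_paper) {
      stop("registry validation error at row ", i, " (", r$name,
           "): average concentration exceeds maximum")
    }
  }
  invisible(tbl)
}

#' Write a compound registry to CSV
#'
#' Inverse of [load_registry()]: a written table reloads with every field
#' identical.
#'
#' @param tbl A `compound_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(tbl, path) {
  stopifnot(inherits(tbl, "compound_table"))
  utils::write.csv(as.data.frame(tbl)[.registry_columns], path,
                   row.names = FALSE, na = "")
  invisible(path)
}

#' Split a semicolon-joined hazard string into flags
#'
#' @param hazards Character scalar or vector of semicolon-joined hazard flags.
#' @return Character vector of flags (for a scalar input), or a list.
#' @export
hazard_flags <- function(hazards) {
  out <- lapply(strsplit(as.character(hazards), ";", fixed = TRUE),
                function(x) x[nzchar(x)])
  if (length(out) == 1) out[[1]] else out
}

# Monoisotopic masses (u) of the elements that occur in the panel.
.monoisotopic <- c(C = 12.0, H = 1.007825, N = 14.003074, O = 15.994915,
                   S = 31.972071, F = 18.998403, Cl = 34.968853)
.proton_mass <- 1.00728

#' Protonated monoisotopic mass of a molecular formula
#'
#' PTR-MS detects most VOCs as the protonated molecule MH+; compounds are
#' identified by the exact (monoisotopic) mass of that ion. This computes the
#' neutral monoisotopic mass from a molecular formula restricted to the
#' elements C, H, N, O, S, F and Cl, and adds one proton mass (1.00728 u).
#'
#' @param formula Molecular formula string, e.g. `"C2H4O"`. Vectorised.
#' @return Numeric m/z of MH+ in Th.
#' @examples
#' protonated_mass("C2H4O")  # acetaldehyde, 45.0335
#' protonated_mass("C6H6")   # benzene, 79.0542
#' @export
protonated_mass <- function(formula) {
  vapply(as.character(formula), function(f) {
    if (is.na(f) || !nzchar(f)) {
      stop("formula parse error: empty formula")
    }
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
    tokens <- regmatches(f, list(m))[[1]]
    if (sum(attr(m, "match.length")) != nchar(f)) {
      stop("formula parse error: cannot parse '", f, "'")
    }
    total <- 0
    for (tok in tokens) {
      el <- sub("[0-9]*$", "", tok)
      cnt <- sub("^[A-Za-z]+", "", tok)
      cnt <- if (nzchar(cnt)) as.integer(cnt) else 1L
      if (!el %in% names(.monoisotopic)) {
        stop("formula parse error: unknown element '", el, "' in '", f, "'")
      }
      total <- total + .monoisotopic[[el]] * cnt
    }
    total + .proton_mass
  }, numeric(1), USE.NAMES = FALSE)
}

#' Most stringent applicable exposure limit
#'
#' Returns, per compound, the minimum of the OSHA and NIOSH permissible
#' exposure limits when both are assessed, the single limit when only one is,
#' and `NA` ("unassessed") when neither is listed.
#'
#' @param tbl A `compound_table` or any data.frame with `limit_osha_ppb` and
#'   `limit_niosh_ppb` columns (one or more rows).
#' @return Named numeric vector of limits in ppb; `NA` = unassessed.
#' @examples
#' reg <- load_registry()
#' applicable_limit(reg[reg$name == "Formaldehyde", ])  # 16 (NIOSH beats OSHA 750)
#' @export
applicable_limit <- function(tbl) {
  stopifnot(all(c("limit_osha_ppb", "limit_niosh_ppb") %in% names(tbl)))
  lim <- pmin(tbl$limit_osha_ppb, tbl$limit_niosh_ppb, na.rm = TRUE)
  names(lim) <- tbl$name
  lim
}

#' @export
print.compound_table <- function(x, ...) {
  cat("Harmful-VOC compound panel (", nrow(x), " compounds, version ",
      attr(x, "version"), ")\n", sep = "")
  NextMethod()
}

# Per-cigarette emitted mass references (ug) used for cigarette equivalence.
# Matching is by case-insensitive substring so that panel labels such as
# "1,3-butadiene/1-Butyne" resolve to the butadiene reference.
.cigarette_reference <- data.frame(
  key = c("acetaldehyde", "butadiene"),
  ug_per_cigarette = c(2000, 130),
  stringsAsFactors = FALSE
)
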