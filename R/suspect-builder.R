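# Suspect-list curation: load raw CSV lists (CompTox-like schema), strip
# counter-ions from salts, classify ionizability from predicted pKa, and
# build the curated list with recomputed masses, isotopologues and
# descriptors.

#' Counter-cation registry
#'
#' Monovalent cations recognised by [strip_counterion()]. Multivalent salts
#' are deliberately unsupported and fall back to neutral-parent treatment
#' with a warning, to avoid fabricating charge states.
#'
#' @return Named list mapping cation name to its formula string.
#' @export
counterion_registry <- function() {
  list(Na = "Na", K = "K", Li = "Li", Cs = "Cs", Ag = "Ag", NH4 = "H4N")
}

#' Load a raw suspect list from CSV
#'
#' The file must have a header whose first column is exactly
#' `"Molecular formula"`. Optional columns (matched case- and
#' punctuation-insensitively): an identifier (`id`/`DTXSID`), `SMILES`,
#' `InChIKey`, `IUPAC name`, `QC level` (integer 1–5), `pKa acidic`,
#' `pKa basic` and `charge`. Missing optional fields become `NA`; formula
#' validity is checked later by [build_suspect_list()], which collects
#' unparseable rows in a rejects report rather than failing.
#'
#' @param path Path to a CSV file.
#' @return A tibble of raw suspect records with columns `id`, `formula_text`,
#'   `smiles`, `inchikey`, `iupac_name`, `qc_level`, `pka_acidic`,
#'   `pka_basic`, `charge`.
#' @export
load_raw_list <- function(path) {
  if (!file.exists(path)) stop_data("suspect list file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) == 0L || nrow(raw) == 0L) stop_data("empty suspect list: ", path)
  if (names(raw)[1L] != "Molecular formula") {
    stop_schema("first column must be labeled 'Molecular formula', found '",
                names(raw)[1L], "'")
  }
  norm <- function(x) gsub("[^a-z0-9]", "", tolower(x))
  nm <- norm(names(raw))
  pick <- function(keys) {
    i <- which(nm %in% keys)
    if (length(i)) raw[[i[1L]]] else rep(NA, nrow(raw))
  }
  id <- pick(c("id", "dtxsid", "identifier"))
  id <- as.character(id)
  if (all(is.na(id))) id <- sprintf("S%04d", seq_len(nrow(raw)))
  qc <- suppressWarnings(as.integer(pick(c("qclevel", "qc"))))
  if (any(!is.na(qc) & (qc < 1L | qc > 5L))) {
    stop_data("QC level outside 1..5 in ", path)
  }
  tibble::tibble(
    id = id,
    formula_text = as.character(raw[[1L]]),
    smiles = as.character(pick("smiles")),
    inchikey = as.character(pick("inchikey")),
    iupac_name = as.character(pick(c("iupacname", "name"))),
    qc_level = qc,
    pka_acidic = suppressWarnings(as.numeric(pick(c("pkaacidic", "pka")))),
    pka_basic = suppressWarnings(as.numeric(pick("pkabasic"))),
    charge = suppressWarnings(as.integer(pick("charge")))
  )
}

# split a formula string on salt dot notation ("." or the middle dot)
split_salt_components <- function(formula_text) {
  strsplit(formula_text, "[.·]")[[1L]]
}

#' Strip the counter-cation from a salt record
#'
#' Detects salts from dot-separated formula components (e.g. `"C8F17O3S.K"`)
#' or dot-separated SMILES, removes exactly one recognised monovalent
#' counter-cation (see [counterion_registry()]) and returns the anion
#' composition. The neutral parent used for mass arithmetic is the anion plus
#' one hydrogen, so a salt and its free acid collapse to the identical
#' charged mass. Records with no recognisable counter-ion are kept and
#' treated as neutral parents, with a warning.
#'
#' @param formula_text Formula string, possibly in salt dot notation.
#' @param smiles Optional SMILES; used only to detect dot components.
#' @inheritParams parse_formula
#' @return A list with `is_salt` (logical), `counterion` (name or `NA`),
#'   `anion` (count vector or `NULL`) and `neutral` (count vector of the
#'   neutral parent).
#' @export
strip_counterion <- function(formula_text, smiles = NA_character_,
                             isotopes = isotope_table()) {
  comps <- split_salt_components(formula_text)
  dotted_smiles <- !is.na(smiles) && grepl("\\.", smiles)
  if (length(comps) == 1L && !dotted_smiles) {
    return(list(is_salt = FALSE, counterion = NA_character_, anion = NULL,
                neutral = parse_formula(formula_text, isotopes)))
  }
  if (length(comps) == 1L) {
    # salt visible only in SMILES; formula holds the combined composition and
    # cannot be decomposed reliably -> conservative neutral-parent fallback
    warning("salt detected from SMILES but formula '", formula_text,
            "' has no dot components; treating as neutral parent",
            call. = FALSE)
    return(list(is_salt = TRUE, counterion = NA_character_, anion = NULL,
                neutral = parse_formula(formula_text, isotopes)))
  }
  registry <- lapply(counterion_registry(), parse_formula, isotopes = isotopes)
  parsed <- lapply(comps, parse_formula, isotopes = isotopes)
  is_cation <- vapply(parsed, function(p) {
    any(vapply(registry, identical, logical(1L), y = p))
  }, logical(1L))
  if (sum(is_cation) != 1L || length(comps) != 2L) {
    warning("unrecognised counter-ion in '", formula_text,
            "'; treating as neutral parent", call. = FALSE)
    merged <- Reduce(merge_counts, parsed)
    return(list(is_salt = TRUE, counterion = NA_character_, anion = NULL,
                neutral = merged))
  }
  cation_idx <- which(is_cation)
  cation_name <- names(which(vapply(registry, identical, logical(1L),
                                    y = parsed[[cation_idx]])))[1L]
  anion <- parsed[[setdiff(1:2, cation_idx)]]
  neutral <- merge_counts(anion, c(H = 1L))
  list(is_salt = TRUE, counterion = cation_name, anion = anion,
       neutral = hill_order(neutral))
}

# add two element-count vectors
merge_counts <- function(a, b) {
  el <- union(names(a), names(b))
  out <- stats::setNames(integer(length(el)), el)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] + b
  hill_order(out)
}

#' Classify ionizability from predicted pKa
#'
#' `acidic` if an acidic pKa is present, `electropositive` if only a basic
#' pKa is present (ionizable in positive mode only), `non_ionizable` if
#' neither is present (e.g. perfluorohexane, which lacks acidic sites).
#'
#' @param pka_acidic,pka_basic Numeric vectors (NA = absent).
#' @return Character vector of classes.
#' @export
classify_ionizability <- function(pka_acidic, pka_basic) {
  ifelse(!is.na(pka_acidic), "acidic",
         ifelse(!is.na(pka_basic), "electropositive", "non_ionizable"))
}

#' Build a curated suspect list
#'
#' Per raw record: the neutral mass is recomputed from the formula (input
#' masses are never trusted), the deprotonated charged mass is derived
#' (counter-ions stripped first for salts; identity for records with
#' `charge == -1`), single-substitution isotopologues and elemental
#' descriptors are attached, and the ionizability class is assigned.
#' Unparseable rows are collected in a rejects report, never silently
#' dropped.
#'
#' @param records Raw records from [load_raw_list()].
#' @inheritParams parse_formula
#' @return A `suspect_list` object: a list with `entries` (one row per
#'   suspect, with an `isotopologues` list-column), `long` (one row per
#'   monoisotopic mass plus one per isotopologue, linked by `parent_id`) and
#'   `rejects` (rows that failed with the reason).
#' @export
build_suspect_list <- function(records, isotopes = isotope_table()) {
  if (anyDuplicated(records$id)) {
    stop_data("duplicate suspect ids: ",
              paste(unique(records$id[duplicated(records$id)]), collapse = ", "))
  }
  entries <- list()
  rejects <- list()
  for (i in seq_len(nrow(records))) {
    rec <- records[i, ]
    parsed <- tryCatch(
      strip_counterion(rec$formula_text, rec$smiles, isotopes),
      error = function(e) e
    )
    if (inherits(parsed, "error")) {
      rejects[[length(rejects) + 1L]] <- tibble::tibble(
        id = rec$id, formula_text = rec$formula_text,
        reason = conditionMessage(parsed))
      next
    }
    neutral <- parsed$neutral
    neutral_mass <- monoisotopic_mass(neutral, isotopes)
    already_charged <- !is.na(rec$charge) && rec$charge == -1L
    chg <- if (already_charged) {
      charged_mass(neutral_mass, ion_form("M-"))
    } else {
      charged_mass(neutral_mass, ion_form("[M-H]-"))
    }
    iso <- isotopologues(neutral, isotopes)
    desc <- descriptors(neutral, m = chg, isotopes = isotopes)
    entries[[length(entries) + 1L]] <- tibble::tibble(
      id = rec$id,
      formula = format_formula(neutral),
      neutral_mass = neutral_mass,
      charged_mass = chg,
      is_salt = parsed$is_salt,
      counterion = parsed$counterion,
      qc_level = rec$qc_level,
      pka_acidic = rec$pka_acidic,
      pka_basic = rec$pka_basic,
      ionizability = classify_ionizability(rec$pka_acidic, rec$pka_basic),
      desc,
      isotopologues = list(iso)
    )
  }
  entries <- if (length(entries)) do.call(rbind, entries) else
    tibble::tibble(id = character())
  rejects <- if (length(rejects)) do.call(rbind, rejects) else
    tibble::tibble(id = character(), formula_text = character(),
                   reason = character())
  structure(list(entries = entries, long = suspect_long_table(entries),
                 rejects = rejects),
            class = "suspect_list")
}

# long-format table: one row per monoisotopic mass plus one per isotopologue,
# isotopologue rows linked to their parent by parent_id
suspect_long_table <- function(entries) {
  if (nrow(entries) == 0L) {
    return(tibble::tibble(row_id = character(), parent_id = character(),
                          label = character()))
  }
  rows <- lapply(seq_len(nrow(entries)), function(i) {
    e <- entries[i, ]
    iso <- e$isotopologues[[1L]]
    mono <- tibble::tibble(
      row_id = e$id, parent_id = e$id, label = "mono",
      formula = e$formula, neutral_mass = e$neutral_mass,
      charged_mass = e$charged_mass, mass_shift = 0,
      relative_abundance = 1)
    if (nrow(iso)) {
      isorows <- tibble::tibble(
        row_id = paste(e$id, iso$label, sep = "|"),
        parent_id = e$id, label = iso$label, formula = e$formula,
        neutral_mass = e$neutral_mass + iso$mass_shift,
        charged_mass = e$charged_mass + iso$mass_shift,
        mass_shift = iso$mass_shift,
        relative_abundance = iso$relative_abundance)
      mono <- rbind(mono, isorows)
    }
    extra <- e[c("qc_level", "pka_acidic", "pka_basic", "ionizability",
                 "is_salt", "counterion", "f_c", "h_c", "hf_c", "o_c",
                 "h_hal_c", "ospn_c", "n_elements", "n_atoms", "dbe",
                 "dbe_o", "mass_defect")]
    cbind(mono, extra[rep(1L, nrow(mono)), ])
  })
  tibble::as_tibble(do.call(rbind, rows))
}

#' @export
print.suspect_list <- function(x, ...) {
  cat("<suspect_list> ", nrow(x$entries), " suspects (",
      nrow(x$long), " rows incl. isotopologues), ",
      nrow(x$rejects), " rejected\n", sep = "")
  invisible(x)
}

#' Write the curated suspect list (long format) to CSV
#'
#' One row per monoisotopic mass plus one per isotopologue, the
#' machine-readable list consumed by downstream screening tools.
#'
#' @param x A `suspect_list`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_suspect_list <- function(x, path) {
  long <- x$long
  names(long)[names(long) == "formula"] <- "Molecular formula"
  long <- long[c("Molecular formula",
                 setdiff(names(long), "Molecular formula"))]
  utils::write.csv(long, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write suspect entries back to the raw-template CSV schema
#'
#' Exports the monoisotopic entries in the input schema accepted by
#' [load_raw_list()] ("Molecular formula" first column), so a list can be
#' rebuilt from its own export.
#'
#' @inheritParams write_suspect_list
#' @return `path`, invisibly.
#' @export
write_raw_list <- function(x, path) {
  e <- x$entries
  formula_text <- ifelse(e$is_salt & !is.na(e$counterion),
                         paste(vapply(seq_len(nrow(e)), function(i) {
                           format_formula(merge_counts(
                             parse_formula(e$formula[i]), c(H = -1L)))
                         }, character(1L)), e$counterion, sep = "."),
                         e$formula)
  out <- data.frame(check.names = FALSE,
    `Molecular formula` = formula_text,
    id = e$id, SMILES = NA_character_, InChIKey = NA_character_,
    `IUPAC name` = NA_character_, `QC level` = e$qc_level,
    `pKa acidic` = e$pka_acidic, `pKa basic` = e$pka_basic)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
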