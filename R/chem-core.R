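# Exact-mass chemistry engine: molecular-formula parsing, monoisotopic and
# isotopologue masses, ion-form arithmetic, elemental descriptors and Kendrick
# mass analysis.

# proton mass used for [M-H]- deconvolution; the literal constant of the
# deprotonation convention (accurate mass = m/z - 1.007277)
.PROTON_MASS <- 1.007277

#' Parse a molecular formula
#'
#' Reads Hill-style formula strings such as `"C8HF17O3S"` into a named count
#' vector. Element symbols are one uppercase letter plus an optional lowercase
#' letter; an absent count means 1; repeated symbols accumulate. Salt ("dot")
#' notation is *not* accepted here — see [strip_counterion()].
#'
#' @param text A single formula string.
#' @param isotopes Isotope table, see [isotope_table()].
#' @return A named integer vector of element counts in Hill order
#'   (C first, then H, then remaining elements alphabetically).
#' @export
#' @examples
#' parse_formula("C8HF17O3S")
#' parse_formula("C11H6Cl2F6N2")
parse_formula <- function(text, isotopes = isotope_table()) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop_data("molecular formula must be a single character string")
  }
  text <- trimws(text)
  if (!nzchar(text)) stop_data("empty molecular formula")
  m <- gregexpr("[A-Z][a-z]?[0-9]*", text)[[1L]]
  tokens <- regmatches(text, gregexpr("[A-Z][a-z]?[0-9]*", text))[[1L]]
  covered <- sum(attr(m, "match.length"))
  if (m[1L] == -1L || covered != nchar(text)) {
    residue <- if (m[1L] == -1L) text else {
      keep <- rep(TRUE, nchar(text))
      for (i in seq_along(m)) {
        keep[seq(m[i], length.out = attr(m, "match.length")[i])] <- FALSE
      }
      paste(strsplit(text, "")[[1L]][keep], collapse = "")
    }
    stop_data("malformed molecular formula '", text,
              "': cannot read '", residue, "'")
  }
  elements <- sub("[0-9]*$", "", tokens)
  counts <- as.integer(ifelse(grepl("[0-9]+$", tokens),
                              sub("^[A-Za-z]+", "", tokens), "1"))
  known <- unique(isotopes$element)
  bad <- setdiff(elements, known)
  if (length(bad)) {
    stop_data("unknown element symbol '", bad[1L], "' in formula '", text, "'")
  }
  if (any(counts < 1L)) {
    stop_data("element counts must be positive in formula '", text, "'")
  }
  out <- tapply(counts, elements, sum)
  out <- stats::setNames(as.integer(out), names(out))
  hill_order(out)
}

# Hill ordering: C, H, then alphabetical; without C, all alphabetical
hill_order <- function(counts) {
  el <- names(counts)
  if ("C" %in% el) {
    ord <- c(intersect(c("C", "H"), el), sort(setdiff(el, c("C", "H"))))
  } else {
    ord <- sort(el)
  }
  counts[ord]
}

#' Format a formula count vector as a Hill-order string
#'
#' Round-trips with [parse_formula()]: `format_formula(parse_formula(x))`
#' returns the canonical spelling of `x`.
#'
#' @param counts Named integer vector of element counts.
#' @return A single character string.
#' @export
format_formula <- function(counts) {
  counts <- hill_order(counts[counts > 0])
  paste0(names(counts), ifelse(counts == 1L, "", counts), collapse = "")
}

#' Monoisotopic mass of a formula
#'
#' Sum over elements of count times the exact mass of the element's principal
#' (most abundant) isotope.
#'
#' @param f Named count vector from [parse_formula()], or a formula string.
#' @inheritParams parse_formula
#' @return Mass in Da.
#' @export
#' @examples
#' monoisotopic_mass("C8HF17O3S")  # PFOS free acid, 499.93749 Da
monoisotopic_mass <- function(f, isotopes = isotope_table()) {
  if (is.character(f)) f <- parse_formula(f, isotopes)
  pm <- principal_masses(isotopes)
  bad <- setdiff(names(f), names(pm))
  if (length(bad)) stop_data("unknown element symbol '", bad[1L], "'")
  sum(f * pm[names(f)])
}

#' Ion forms
#'
#' Registered ion-formation arithmetic. `"[M-H]-"` is deprotonation
#' (mass delta −1.007277 Da, charge −1); `"M-"` is the identity used for
#' suspects already stored as anions; `"none"` leaves the neutral mass
#' untouched.
#'
#' @param name Ion-form name.
#' @return A list with `name`, `mass_delta` (Da) and `charge`.
#' @export
ion_form <- function(name = c("[M-H]-", "M-", "none")) {
  name <- match.arg(name)
  switch(name,
    "[M-H]-" = list(name = "[M-H]-", mass_delta = -.PROTON_MASS, charge = -1L),
    "M-"     = list(name = "M-", mass_delta = 0, charge = -1L),
    "none"   = list(name = "none", mass_delta = 0, charge = 0L)
  )
}

#' Charged (ionized) mass
#'
#' Applies an ion form to a neutral monoisotopic mass. For `"[M-H]-"` this is
#' the deprotonation rule `neutral − 1.007277`; for already-charged species
#' use the identity form `"M-"`.
#'
#' @param neutral Neutral monoisotopic mass in Da (> 0).
#' @param ion An [ion_form()] or its name.
#' @return The ionized mass in Da.
#' @export
#' @examples
#' charged_mass(499.93749)  # PFOS [M-H]- = 498.93022 Da
charged_mass <- function(neutral, ion = ion_form("[M-H]-")) {
  if (is.character(ion)) ion <- ion_form(ion)
  if (any(neutral <= 0)) stop_data("neutral mass must be positive")
  out <- neutral + ion$mass_delta
  if (any(out <= 0)) stop_data("ionized mass is not positive")
  out
}

#' Single-substitution isotopologues of a formula
#'
#' For each element of C, S, O, Cl, Br, Si present in the formula, returns one
#' isotopologue in which a single atom is replaced by that element's most
#' abundant heavy isotope (13C, 34S, 18O, 37Cl, 81Br, 29Si). The mass shift is
#' the heavy-minus-light isotope mass difference and the relative abundance
#' (fraction of the monoisotopic peak intensity) is
#' `count * abundance_heavy / abundance_light`.
#'
#' @inheritParams monoisotopic_mass
#' @return A tibble with columns `label`, `element`, `mass_shift` (Da) and
#'   `relative_abundance`; zero rows if no eligible element is present.
#' @export
#' @examples
#' isotopologues("C8HF17O3S")
isotopologues <- function(f, isotopes = isotope_table()) {
  if (is.character(f)) f <- parse_formula(f, isotopes)
  els <- intersect(.isotopologue_elements, names(f))
  rows <- lapply(els, function(el) {
    light <- isotopes[isotopes$element == el & isotopes$principal, ]
    heavy <- heavy_isotope(el, isotopes)
    tibble::tibble(
      label = paste0(heavy$mass_number, el),
      element = el,
      mass_shift = heavy$mass - light$mass,
      relative_abundance = unname(f[el]) * heavy$abundance / light$abundance
    )
  })
  if (!length(rows)) {
    return(tibble::tibble(label = character(), element = character(),
                          mass_shift = numeric(),
                          relative_abundance = numeric()))
  }
  do.call(rbind, rows)
}

#' Elemental descriptors of a formula
#'
#' Elemental ratios, double-bond equivalents and mass defect used for
#' candidate filtering and the elemental-ratio plots. DBE counts Si as
#' tetravalent, N and P as trivalent and the halogens as monovalent:
#' `DBE = 1 + C + Si - (H + F + Cl + Br + I)/2 + (N + P)/2`. The mass defect
#' is the signed deviation from the nearest integer, `m - round(m)`, so that
#' typical highly fluorinated anions have negative values.
#'
#' @inheritParams monoisotopic_mass
#' @param m Mass (Da) used for the mass defect; conventionally the charged
#'   mass for screening in negative mode.
#' @return A one-row tibble with columns `f_c`, `h_c`, `hf_c`, `o_c`,
#'   `h_hal_c` ((H+Cl+Br+F+I)/C), `ospn_c` ((O+S+P+N)/C), `n_elements`,
#'   `n_atoms`, `dbe`, `dbe_o` and `mass_defect`. Ratios are `NA` when the
#'   formula contains no carbon.
#' @export
#' @examples
#' descriptors("C8HF17O3S", charged_mass(monoisotopic_mass("C8HF17O3S")))
descriptors <- function(f, m = monoisotopic_mass(f, isotopes),
                        isotopes = isotope_table()) {
  if (is.character(f)) f <- parse_formula(f, isotopes)
  n <- function(el) if (el %in% names(f)) unname(f[[el]]) else 0
  C <- n("C")
  dbe <- 1 + C + n("Si") - (n("H") + n("F") + n("Cl") + n("Br") + n("I")) / 2 +
    (n("N") + n("P")) / 2
  ratio <- function(x) if (C > 0) x / C else NA_real_
  tibble::tibble(
    f_c = ratio(n("F")),
    h_c = ratio(n("H")),
    hf_c = ratio(n("H") + n("F")),
    o_c = ratio(n("O")),
    h_hal_c = ratio(n("H") + n("Cl") + n("Br") + n("F") + n("I")),
    ospn_c = ratio(n("O") + n("S") + n("P") + n("N")),
    n_elements = length(f),
    n_atoms = sum(f),
    dbe = dbe,
    dbe_o = dbe - n("O"),
    mass_defect = m - round(m)
  )
}

#' Kendrick mass and Kendrick mass defect
#'
#' Rescales masses so that a chosen repeat unit (CF2 for PFAS homologous
#' series) has integer mass: `KM = m * nominal(base) / exact(base)` and
#' `KMD = round(KM) - KM`. Members of a homologous series differing by whole
#' repeat units share a KMD.
#'
#' @param m Numeric vector of masses (Da), all > 0.
#' @param base Repeat-unit formula, default `"CF2"`.
#' @inheritParams parse_formula
#' @return A tibble with columns `mz`, `kendrick_mass` and `kmd`.
#' @export
#' @examples
#' kendrick(c(412.96642, 462.96323))  # PFOA / PFNA [M-H]-, same KMD
kendrick <- function(m, base = "CF2", isotopes = isotope_table()) {
  if (any(m <= 0)) stop_data("masses must be positive")
  f <- parse_formula(base, isotopes)
  exact <- monoisotopic_mass(f, isotopes)
  principal <- isotopes[isotopes$principal, ]
  nominal <- sum(f * stats::setNames(principal$mass_number,
                                     principal$element)[names(f)])
  if (exact <= 0) stop_data("Kendrick base must have positive exact mass")
  km <- m * nominal / exact
  tibble::tibble(mz = m, kendrick_mass = km, kmd = round(km) - km)
}
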