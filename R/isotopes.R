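# Embedded isotope table (CODATA/IUPAC standard atomic masses and natural
# abundances). Covers the elements encountered in PFAS suspect lists plus the
# monovalent counter-cations recognised by the salt stripper.

.isotope_data <- local({
  rec <- function(element, mass_number, mass, abundance) {
    data.frame(element = element, mass_number = mass_number,
               mass = mass, abundance = abundance,
               stringsAsFactors = FALSE)
  }
  tab <- rbind(
    rec("H",   1,   1.0078250319, 0.999885),
    rec("H",   2,   2.0141017780, 0.000115),
    rec("C",  12,  12.0000000000, 0.9893),
    rec("C",  13,  13.0033548378, 0.0107),
    rec("N",  14,  14.0030740052, 0.99636),
    rec("N",  15,  15.0001088984, 0.00364),
    rec("O",  16,  15.9949146221, 0.99757),
    rec("O",  17,  16.9991315000, 0.00038),
    rec("O",  18,  17.9991604000, 0.00205),
    rec("F",  19,  18.9984032000, 1.0),
    rec("Na", 23,  22.9897692800, 1.0),
    rec("Si", 28,  27.9769265327, 0.92223),
    rec("Si", 29,  28.9764946653, 0.04685),
    rec("Si", 30,  29.9737701370, 0.03092),
    rec("P",  31,  30.9737615120, 1.0),
    rec("S",  32,  31.9720706912, 0.9499),
    rec("S",  33,  32.9714585000, 0.0075),
    rec("S",  34,  33.9678668311, 0.0425),
    rec("S",  36,  35.9670808000, 0.0001),
    rec("Cl", 35,  34.9688527100, 0.7576),
    rec("Cl", 37,  36.9659026000, 0.2424),
    rec("K",  39,  38.9637064900, 0.932581),
    rec("K",  41,  40.9618252600, 0.067302),
    rec("Br", 79,  78.9183376000, 0.5069),
    rec("Br", 81,  80.9162906000, 0.4931),
    rec("I", 127, 126.9044730000, 1.0),
    rec("Li",  6,   6.0151228874, 0.0759),
    rec("Li",  7,   7.0160034366, 0.9241),
    rec("Cs", 133, 132.9054519330, 1.0),
    rec("Ag", 107, 106.9050930000, 0.51839),
    rec("Ag", 109, 108.9047560000, 0.48161)
  )
  # mark the principal (most abundant, "light") isotope of every element
  tab$principal <- stats::ave(tab$abundance, tab$element,
                              FUN = function(a) a == max(a)) > 0
  tab
})

# elements for which a single-substitution isotopologue is generated, in the
# order their rows appear in suspect-list exports
.isotopologue_elements <- c("C", "S", "O", "Cl", "Br", "Si")

#' Isotope table
#'
#' The table of exact isotope masses and natural abundances used by all mass
#' arithmetic in the package. Per element the most abundant ("principal")
#' isotope defines the monoisotopic mass; for the isotopologue elements
#' (C, S, O, Cl, Br, Si) the most abundant heavy isotope defines the
#' single-substitution isotopologue.
#'
#' @param path Optional path to a CSV with columns `element`, `mass_number`,
#'   `mass`, `abundance` overriding the embedded table.
#' @return A tibble with columns `element`, `mass_number`, `mass` (Da),
#'   `abundance` (fraction) and `principal` (logical).
#' @export
#' @examples
#' head(isotope_table())
isotope_table <- function(path = NULL) {
  if (is.null(path)) return(tibble::as_tibble(.isotope_data))
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("element", "mass_number", "mass", "abundance")
  if (!all(need %in% names(tab))) {
    stop_schema("isotope table CSV must have columns: ",
                paste(need, collapse = ", "))
  }
  if (any(tab$mass <= 0)) stop_data("isotope masses must be strictly positive")
  ab_sum <- tapply(tab$abundance, tab$element, sum)
  if (any(ab_sum > 1.000001)) {
    stop_data("isotope abundances exceed 1 for element(s): ",
              paste(names(ab_sum)[ab_sum > 1.000001], collapse = ", "))
  }
  tab$principal <- stats::ave(tab$abundance, tab$element,
                              FUN = function(a) a == max(a)) > 0
  tibble::as_tibble(tab[c(need, "principal")])
}

#' Export the embedded isotope table to CSV
#'
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_isotope_table <- function(path) {
  utils::write.csv(.isotope_data[c("element", "mass_number", "mass", "abundance")],
                   path, row.names = FALSE)
  invisible(path)
}

# principal-isotope mass per element, as a named vector
principal_masses <- function(isotopes = isotope_table()) {
  p <- isotopes[isotopes$principal, ]
  stats::setNames(p$mass, p$element)
}

# most abundant heavy (non-principal) isotope for one element, or NULL
heavy_isotope <- function(element, isotopes = isotope_table()) {
  rows <- isotopes[isotopes$element == element & !isotopes$principal, ]
  if (nrow(rows) == 0L) return(NULL)
  rows[which.max(rows$abundance), ]
}
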