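# Element data: atomic numbers and single-bond covalent radii (Angstrom).
# Radii follow the widely used Cordero compilation; they only enter bond
# detection through the scaled sum r_cov(i) + r_cov(j).
.element_table <- data.frame(
  symbol = c("H", "He", "B", "C", "N", "O", "F", "Na", "Mg", "Si", "P", "S",
             "Cl", "K", "Ca", "Mn", "Fe", "Co", "Ni", "Cu", "Zn", "Se", "Br",
             "I"),
  Z = c(1L, 2L, 5L, 6L, 7L, 8L, 9L, 11L, 12L, 14L, 15L, 16L,
        17L, 19L, 20L, 25L, 26L, 27L, 28L, 29L, 30L, 34L, 35L,
        53L),
  r_cov = c(0.31, 0.28, 0.84, 0.76, 0.71, 0.66, 0.57, 1.66, 1.41, 1.11, 1.07,
            1.05, 1.02, 2.03, 1.76, 1.39, 1.32, 1.26, 1.24, 1.32, 1.22, 1.20,
            1.20, 1.39),
  stringsAsFactors = FALSE
)

#' Look up atomic numbers for element symbols
#'
#' @param element character vector of element symbols (case-sensitive,
#'   e.g. `"Fe"`).
#' @return integer vector of atomic numbers.
#' @export
atomic_number <- function(element) {
  idx <- match(element, .element_table$symbol)
  if (anyNA(idx)) {
    stop("unrecognized element symbol(s): ",
         paste(unique(element[is.na(idx)]), collapse = ", "))
  }
  .element_table$Z[idx]
}

#' Look up covalent radii for element symbols
#'
#' @inheritParams atomic_number
#' @return numeric vector of covalent radii in Angstrom.
#' @export
covalent_radius <- function(element) {
  idx <- match(element, .element_table$symbol)
  if (anyNA(idx)) {
    stop("unrecognized element symbol(s): ",
         paste(unique(element[is.na(idx)]), collapse = ", "))
  }
  .element_table$r_cov[idx]
}

# Normalize a raw element string ("FE", "fe", " C") to a table symbol, or NA.
.normalize_element <- function(x) {
  x <- gsub("[^A-Za-z]", "", x)
  x <- ifelse(nchar(x) == 0, NA_character_,
              paste0(toupper(substr(x, 1, 1)), tolower(substr(x, 2, 2))))
  ifelse(x %in% .element_table$symbol, x, NA_character_)
}
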