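#' Canonicalize species binomials
#'
#' Normalizes binomial names so that tables and trees key on the same string:
#' underscores become spaces, runs of whitespace collapse to one space, the
#' genus is capitalized and the epithet (and anything after it) lower-cased.
#' No synonym resolution is attempted.
#'
#' @param x character vector of species names.
#' @return character vector of canonical binomials.
#' @examples
#' canonical_species(c("quercus  ilex", "Quercus_ilex")) # both "Quercus ilex"
#' @export
canonical_species <- function(x) {
  x <- gsub("_", " ", as.character(x))
  x <- gsub("\\s+", " ", trimws(x))
  x <- tolower(x)
  substr(x, 1L, 1L) <- toupper(substr(x, 1L, 1L))
  x
}

#' Genus of a binomial
#' @param x character vector of species names.
#' @return character vector of genus names (first token).
#' @export
species_genus <- function(x) {
  vapply(strsplit(canonical_species(x), " ", fixed = TRUE),
         `[[`, character(1), 1L)
}

## attach a named list as the curation report of a data.frame
set_report <- function(x, report) {
  attr(x, "pqreg_report") <- report
  x
}

#' Retrieve the curation report attached to a filtered table
#'
#' Every curation filter records how many rows it dropped and why; this
#' accessor returns that record (a named list), or NULL if none is attached.
#'
#' @param x a data.frame returned by a curation function.
#' @return named list, or NULL.
#' @export
curation_report <- function(x) attr(x, "pqreg_report")
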