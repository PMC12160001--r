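# Element tables: Cordero 2008 single-bond covalent radii, Bondi/Mantina
# van-der-Waals radii, IUPAC standard atomic weights. Shipped as plain text
# under inst/extdata so users can inspect or extend them.

.solv_env <- new.env(parent = emptyenv())

#' Element property tables
#'
#' Returns the packaged element table with one row per element: symbol,
#' covalent radius (Angstrom), van der Waals radius (Angstrom) and atomic
#' mass (amu). The table is read once per session and cached.
#'
#' @return A data.frame with columns `symbol`, `covalent_radius`,
#'   `vdw_radius`, `mass`.
#' @export
element_tables <- function() {
  if (is.null(.solv_env$elements)) {
    path <- system.file("extdata", "elements.tsv", package = "solvmode",
                        mustWork = TRUE)
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    stopifnot(all(tab$covalent_radius > 0), all(tab$vdw_radius > 0),
              all(tab$mass > 0))
    rownames(tab) <- tab$symbol
    .solv_env$elements <- tab
  }
  .solv_env$elements
}

.element_lookup <- function(symbols, column) {
  tab <- element_tables()
  idx <- match(symbols, tab$symbol)
  if (anyNA(idx)) {
    bad <- unique(symbols[is.na(idx)])
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  stats::setNames(tab[[column]][idx], symbols)
}

#' Covalent radius of an element
#'
#' @param symbol Element symbol(s), e.g. `"O"`.
#' @return Covalent radius in Angstrom (vectorised).
#' @examples
#' covalent_radius("H")  # 0.31
#' @export
covalent_radius <- function(symbol) .element_lookup(symbol, "covalent_radius")

#' Van der Waals radius of an element
#'
#' @inheritParams covalent_radius
#' @return Van der Waals radius in Angstrom (vectorised).
#' @export
vdw_radius <- function(symbol) .element_lookup(symbol, "vdw_radius")

#' Standard atomic mass of an element
#'
#' @inheritParams covalent_radius
#' @return Atomic mass in amu (vectorised).
#' @export
atomic_mass <- function(symbol) .element_lookup(symbol, "mass")
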