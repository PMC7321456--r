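#' Element constants used by the descriptor engine
#'
#' One row per supported element: atomic number `Z`, valence-electron count
#' `Zv`, principal quantum number of the valence shell `L`, and standard
#' atomic weight `mass` (IUPAC 2021 conventional values). All atomic
#' constants used anywhere in the package come from this single table, so
#' numeric tolerances in examples are traceable to it.
#'
#' @return A data frame with columns `symbol`, `Z`, `Zv`, `L`, `mass`.
#' @examples
#' element_table()
#' @export
element_table <- function() {
  data.frame(
    symbol = c("H", "B", "C", "N", "O", "F",
               "Si", "P", "S", "Cl", "Br", "I"),
    Z    = c(1, 5, 6, 7, 8, 9, 14, 15, 16, 17, 35, 53),
    Zv   = c(1, 3, 4, 5, 6, 7, 4, 5, 6, 7, 7, 7),
    L    = c(1, 2, 2, 2, 2, 2, 3, 3, 3, 3, 4, 5),
    mass = c(1.008, 10.81, 12.011, 14.007, 15.999, 18.998,
             28.085, 30.974, 32.06, 35.45, 79.904, 126.904),
    stringsAsFactors = FALSE
  )
}

# Fast lookup: returns row indices into element_table() or stops naming the
# unsupported element.
element_index <- function(symbols) {
  tab <- element_table()
  idx <- match(symbols, tab$symbol)
  if (anyNA(idx)) {
    bad <- unique(symbols[is.na(idx)])
    stop("unsupported element(s): ", paste(bad, collapse = ", "),
         "; supported: ", paste(tab$symbol, collapse = ", "), call. = FALSE)
  }
  idx
}
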