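# Elemental reference data and compositions.

.porospr_cache <- new.env(parent = emptyenv())

#' Elemental reference table
#'
#' Returns the packaged table of elements (symbol, atomic number `Z`,
#' relative atomic mass `A` in g/mol, mean excitation energy `I_eV` in eV,
#' condensed-phase convention).  Bragg additivity over these `I` values
#' reproduces 75.3 eV for liquid water.
#'
#' @return A data frame with columns `symbol`, `Z`, `A`, `I_eV`.
#' @export
element_table <- function() {
  if (is.null(.porospr_cache$elements)) {
    path <- system.file("extdata", "elements.csv", package = "porospr",
                        mustWork = TRUE)
    .porospr_cache$elements <- utils::read.csv(path, comment.char = "#",
                                               stringsAsFactors = FALSE)
  }
  .porospr_cache$elements
}

#' Build an elemental composition
#'
#' An elemental composition is a set of (element, mass fraction) entries with
#' the element's `Z`, `A` and mean excitation energy attached from the
#' packaged element table.  Mass fractions must be non-negative and sum to 1
#' within 1e-9 (or set `normalize = TRUE`).
#'
#' @param elements Character vector of element symbols (e.g. `c("H", "O")`).
#' @param mass_fractions Numeric vector of mass fractions, same length.
#' @param normalize If `TRUE`, rescale the fractions to sum to 1.
#' @return An object of class `elemental_composition`: a data frame with
#'   columns `element`, `Z`, `A`, `w`, `I_eV`.
#' @examples
#' water <- composition(c("H", "O"), c(0.1119, 0.8881))
#' @export
composition <- function(elements, mass_fractions, normalize = FALSE) {
  stopifnot(length(elements) == length(mass_fractions))
  tab <- element_table()
  idx <- match(elements, tab$symbol)
  if (anyNA(idx)) {
    stop("unknown element(s): ", paste(elements[is.na(idx)], collapse = ", "))
  }
  w <- as.numeric(mass_fractions)
  if (any(w < 0)) stop("mass fractions must be non-negative")
  if (normalize) w <- w / sum(w)
  if (abs(sum(w) - 1) > 1e-9) {
    stop("mass fractions sum to ", format(sum(w), digits = 12),
         ", not 1 (use normalize = TRUE to rescale)")
  }
  out <- data.frame(element = elements, Z = tab$Z[idx], A = tab$A[idx],
                    w = w, I_eV = tab$I_eV[idx], stringsAsFactors = FALSE)
  class(out) <- c("elemental_composition", "data.frame")
  out
}

is_composition <- function(x) inherits(x, "elemental_composition")

# Sum of w_i Z_i / A_i (mol electrons per gram, up to Avogadro's number).
electron_sum <- function(comp) sum(comp$w * comp$Z / comp$A)

# Electron-fraction weights lambda_i, normalized to sum to 1.
electron_fractions <- function(comp) {
  lam <- comp$w * comp$Z / comp$A
  s <- sum(lam)
  if (s <= 0) stop("composition has no electrons (all-zero weights)")
  lam / s
}
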