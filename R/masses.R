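## Monoisotopic mass arithmetic on elemental formulas.
## Formulas are named numeric vectors over the elements below; all masses in Da.

#' Monoisotopic atomic masses
#'
#' Monoisotopic masses (Da) of the elements used by the lipid mass
#' arithmetic, plus the proton mass used for `[M+H]+` / `[M-H]-` adducts.
#'
#' @format Named numeric vector with elements `C`, `H`, `N`, `O`, `P`.
#' @export
ATOMIC_MASS <- c(
  C = 12.000000,
  H = 1.0078250319,
  N = 14.0030740052,
  O = 15.9949146221,
  P = 30.97376151
)

#' @rdname ATOMIC_MASS
#' @export
PROTON_MASS <- 1.00727646

#' @rdname ATOMIC_MASS
#' @export
WATER_MASS <- 2 * ATOMIC_MASS[["H"]] + ATOMIC_MASS[["O"]]

## [M+NH4]+ shift: neutral NH3 plus a proton
AMMONIUM_SHIFT <- ATOMIC_MASS[["N"]] + 3 * ATOMIC_MASS[["H"]] + PROTON_MASS

elemental_formula <- function(C = 0, H = 0, N = 0, O = 0, P = 0) {
  c(C = C, H = H, N = N, O = O, P = P)
}

formula_add <- function(a, b) {
  out <- elemental_formula()
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] + b
  out
}

formula_subtract <- function(a, b) {
  formula_add(a, -b)
}

#' Monoisotopic mass of an elemental formula
#'
#' @param formula Named numeric vector of element counts (subset of
#'   `C`, `H`, `N`, `O`, `P`), e.g. `c(C = 16, H = 32, O = 2)`.
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' formula_mass(c(C = 16, H = 32, O = 2)) # palmitic acid, 256.2402
#' @export
formula_mass <- function(formula) {
  bad <- setdiff(names(formula), names(ATOMIC_MASS))
  if (length(bad) > 0) {
    stop("unknown element(s): ", paste(bad, collapse = ", "))
  }
  sum(ATOMIC_MASS[names(formula)] * formula)
}

## Fixed building blocks
FORMULA_H2O        <- elemental_formula(H = 2, O = 1)
FORMULA_CARNITINE  <- elemental_formula(C = 7, H = 15, N = 1, O = 3)
FORMULA_CHOLESTEROL <- elemental_formula(C = 27, H = 46, O = 1)
FORMULA_PHOSPHOCHOLINE <- elemental_formula(C = 5, H = 14, N = 1, O = 4, P = 1)
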