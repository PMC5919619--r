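## Lipid shorthand nomenclature and monoisotopic mass arithmetic.
##
## Species are held as light S3 lists. Ceramides are modelled at the
## sphingoid-base/N-acyl level; glycerophospholipids and sphingomyelins at the
## sum-composition level (total acyl carbons : double bonds), since
## flow-injection MRM scans cannot resolve sn-positions.

#' Construct an acyl chain
#'
#' An acyl chain is described by its carbon count, number of C=C double bonds
#' and number of hydroxyl substituents (0 = non-hydroxy "N", 1 = alpha-hydroxy
#' "A" in ceramide shorthand).
#'
#' @param carbons Integer >= 2.
#' @param double_bonds Integer >= 0; at most `carbons - 1`.
#' @param hydroxyls 0, 1 or 2.
#' @return An object of class `acyl_chain`.
#' @examples
#' acyl_chain(16, 0)      # palmitic
#' acyl_chain(24, 0, 1)   # 2-hydroxy-lignoceric
#' @export
acyl_chain <- function(carbons, double_bonds = 0, hydroxyls = 0) {
  carbons <- as.integer(carbons)
  double_bonds <- as.integer(double_bonds)
  hydroxyls <- as.integer(hydroxyls)
  if (is.na(carbons) || carbons < 2) stop("acyl chain needs >= 2 carbons")
  if (is.na(double_bonds) || double_bonds < 0 ||
      2 * double_bonds > 2 * carbons - 2) {
    stop("invalid double bond count for ", carbons, " carbons")
  }
  if (!hydroxyls %in% 0:2) stop("hydroxyls must be 0, 1 or 2")
  structure(list(carbons = carbons, double_bonds = double_bonds,
                 hydroxyls = hydroxyls),
            class = "acyl_chain")
}

#' @export
format.acyl_chain <- function(x, ...) {
  paste0(x$carbons, ":", x$double_bonds,
         if (x$hydroxyls == 1) "(OH)" else if (x$hydroxyls == 2) "(2OH)" else "")
}

#' @export
print.acyl_chain <- function(x, ...) {
  cat("<acyl chain ", format(x), ">\n", sep = "")
  invisible(x)
}

acyl_formula <- function(chain) {
  elemental_formula(C = chain$carbons,
                    H = 2 * chain$carbons - 2 * chain$double_bonds,
                    O = 2 + chain$hydroxyls)
}

#' Monoisotopic mass of a free fatty acid
#'
#' Neutral monoisotopic mass of the free fatty acid CnH(2n-2d)O(2+h)
#' corresponding to an acyl chain.
#'
#' @param chain An [acyl_chain()].
#' @return Mass in Da.
#' @examples
#' acyl_mass(acyl_chain(16, 0))     # 256.2402 (palmitic acid)
#' acyl_mass(acyl_chain(24, 0, 1))  # 384.3603 (2-hydroxy-tetracosanoic acid)
#' @export
acyl_mass <- function(chain) {
  stopifnot(inherits(chain, "acyl_chain"))
  formula_mass(acyl_formula(chain))
}

#' Construct a sphingoid base
#'
#' Sphingoid backbones of ceramides: sphingosine (`d<n>:1`, two hydroxyls, one
#' double bond), sphinganine (`d<n>:0`) and phytosphingosine (`t<n>:0`, three
#' hydroxyls). The backbone carbon count defaults to 18.
#'
#' @param kind `"sphingosine"`, `"sphinganine"` or `"phytosphingosine"`, or a
#'   shorthand code such as `"d18:1"`, `"d18:0"`, `"t18:0"`.
#' @param carbons Backbone carbons (default 18; ignored when `kind` is a
#'   shorthand code carrying its own count).
#' @return An object of class `sphingoid_base`.
#' @export
sphingoid_base <- function(kind = "sphingosine", carbons = 18) {
  if (grepl("^[dt][0-9]+:[0-9]$", kind)) {
    hyd <- if (substr(kind, 1, 1) == "t") 3L else 2L
    parts <- strsplit(sub("^[dt]", "", kind), ":", fixed = TRUE)[[1]]
    carbons <- as.integer(parts[1])
    db <- as.integer(parts[2])
    if (hyd == 3 && db != 0) stop("phytosphingosine bases are saturated: ", kind)
    kind <- if (hyd == 3) "phytosphingosine" else if (db == 1) "sphingosine"
            else if (db == 0) "sphinganine"
            else stop("unsupported sphingoid base code: ", kind)
  }
  kind <- match.arg(kind, c("sphingosine", "sphinganine", "phytosphingosine"))
  carbons <- as.integer(carbons)
  if (carbons < 12 || carbons > 24) stop("implausible sphingoid backbone length")
  db <- if (kind == "sphingosine") 1L else 0L
  hyd <- if (kind == "phytosphingosine") 3L else 2L
  structure(list(kind = kind, carbons = carbons, double_bonds = db,
                 hydroxyls = hyd),
            class = "sphingoid_base")
}

base_code <- function(base) {
  paste0(if (base$hydroxyls == 3) "t" else "d",
         base$carbons, ":", base$double_bonds)
}

#' @export
format.sphingoid_base <- function(x, ...) base_code(x)

#' @export
print.sphingoid_base <- function(x, ...) {
  cat("<", x$kind, " ", base_code(x), ">\n", sep = "")
  invisible(x)
}

base_formula <- function(base) {
  elemental_formula(C = base$carbons,
                    H = 2 * base$carbons + 3 - 2 * base$double_bonds,
                    N = 1, O = base$hydroxyls)
}

## Ceramide sub-class letters: hydroxylation of the N-acyl (N = non-hydroxy,
## A = alpha-hydroxy) then the base letter (S, DS, P).
ceramide_base_letter <- function(base) {
  switch(base$kind,
         sphingosine = "S", sphinganine = "DS", phytosphingosine = "P")
}

#' Diagnostic sphingoid fragment m/z
#'
#' The `[base + H - 2 H2O]+` cation monitored by the ceramide precursor-ion
#' scans: nominal m/z 264 for sphingosine, 266 for sphinganine and 282 for
#' phytosphingosine (18-carbon backbones).
#'
#' @param base A [sphingoid_base()].
#' @return An [mz_value()] in positive mode.
#' @examples
#' base_fragment_mz(sphingoid_base("d18:1")) # 264.2686
#' @export
base_fragment_mz <- function(base) {
  stopifnot(inherits(base, "sphingoid_base"))
  mz_value(formula_mass(base_formula(base)) + PROTON_MASS - 2 * WATER_MASS, "+")
}

#' Mass-to-charge value
#'
#' @param mz Positive m/z in Da per unit charge.
#' @param polarity `"+"` or `"-"`.
#' @return An object of class `mz_value`.
#' @export
mz_value <- function(mz, polarity = c("+", "-")) {
  polarity <- match.arg(polarity)
  if (!is.numeric(mz) || length(mz) != 1 || is.na(mz) || mz <= 0) {
    stop("mz must be a single positive number")
  }
  structure(list(mz = as.numeric(mz), polarity = polarity), class = "mz_value")
}

#' @export
print.mz_value <- function(x, ...) {
  cat("<m/z ", format(x$mz, digits = 7), " [", x$polarity, "]>\n", sep = "")
  invisible(x)
}

LIPID_CLASSES <- c("Cer", "FFA", "AC", "CE", "PC", "ePC", "pPC", "SM",
                   "PE", "PS", "PI", "PG")

#' Construct a lipid species
#'
#' @param lipid_class One of `"Cer"`, `"FFA"`, `"AC"`, `"CE"`, `"PC"`, `"ePC"`
#'   (alkyl-ether PC), `"pPC"` (plasmalogen PC), `"SM"`, `"PE"`, `"PS"`,
#'   `"PI"`, `"PG"`.
#' @param chain An [acyl_chain()]. For the sum-composition classes (PC family,
#'   SM, PE, PS, PI, PG) the chain holds the *total* acyl carbons and double
#'   bonds; for SM the totals include the sphingoid backbone.
#' @param base A [sphingoid_base()]; required for ceramides, ignored otherwise.
#' @return An object of class `lipid_species`.
#' @examples
#' lipid_species("Cer", acyl_chain(16, 0), sphingoid_base("d18:1"))
#' lipid_species("PC", acyl_chain(34, 1))
#' @export
lipid_species <- function(lipid_class, chain, base = NULL) {
  lipid_class <- match.arg(lipid_class, LIPID_CLASSES)
  stopifnot(inherits(chain, "acyl_chain"))
  if (lipid_class == "Cer") {
    if (is.null(base)) stop("a ceramide needs a sphingoid base")
    stopifnot(inherits(base, "sphingoid_base"))
  } else {
    base <- NULL
  }
  structure(list(lipid_class = lipid_class, chain = chain, base = base),
            class = "lipid_species")
}

#' @export
format.lipid_species <- function(x, ...) {
  ch <- x$chain
  cd <- paste0(ch$carbons, ":", ch$double_bonds)
  switch(x$lipid_class,
    Cer = paste0("Cer",
                 if (ch$hydroxyls > 0) "A" else "N",
                 ceramide_base_letter(x$base),
                 "(", base_code(x$base), "/", cd, ")",
                 if (ch$hydroxyls > 0) "2OH" else ""),
    FFA = paste0("FFA(", cd, ")", if (ch$hydroxyls > 0) "OH" else ""),
    AC  = paste0("AC(", cd, ")", if (ch$hydroxyls > 0) "OH" else ""),
    CE  = paste0("CE(", cd, ")"),
    SM  = paste0("SM(d", cd, ")"),
    paste0(x$lipid_class, "(", cd, ")"))
}

#' @export
print.lipid_species <- function(x, ...) {
  cat("<lipid ", format(x), ">\n", sep = "")
  invisible(x)
}

#' Elemental formula of a lipid species
#'
#' @param species A [lipid_species()].
#' @return Named numeric vector of element counts for the neutral molecule.
#' @export
species_formula <- function(species) {
  stopifnot(inherits(species, "lipid_species"))
  ch <- species$chain
  n <- ch$carbons; d <- ch$double_bonds; h <- ch$hydroxyls
  switch(species$lipid_class,
    FFA = acyl_formula(ch),
    Cer = formula_subtract(
            formula_add(base_formula(species$base), acyl_formula(ch)),
            FORMULA_H2O),
    AC  = formula_subtract(formula_add(FORMULA_CARNITINE, acyl_formula(ch)),
                           FORMULA_H2O),
    CE  = formula_subtract(formula_add(FORMULA_CHOLESTEROL, acyl_formula(ch)),
                           FORMULA_H2O),
    PC  = elemental_formula(C = n + 8, H = 2 * n - 2 * d + 16, N = 1, O = 8,
                            P = 1),
    ## alkyl ether: one ester oxygen replaced by an ether linkage (-O +H2)
    ePC = elemental_formula(C = n + 8, H = 2 * n - 2 * d + 18, N = 1, O = 7,
                            P = 1),
    ## 1Z-alkenyl ether (plasmalogen): -O relative to diacyl
    pPC = elemental_formula(C = n + 8, H = 2 * n - 2 * d + 16, N = 1, O = 7,
                            P = 1),
    ## SM sum composition: totals n:d include a di-hydroxy (d-) backbone
    SM  = elemental_formula(C = n + 5, H = 2 * n + 13 - 2 * d, N = 2, O = 6,
                            P = 1),
    PE  = elemental_formula(C = n + 5, H = 2 * n - 2 * d + 10, N = 1, O = 8,
                            P = 1),
    PS  = elemental_formula(C = n + 6, H = 2 * n - 2 * d + 10, N = 1, O = 10,
                            P = 1),
    PI  = elemental_formula(C = n + 9, H = 2 * n - 2 * d + 15, N = 0, O = 13,
                            P = 1),
    PG  = elemental_formula(C = n + 6, H = 2 * n - 2 * d + 11, N = 0, O = 10,
                            P = 1),
    stop("no formula model for class ", species$lipid_class))
}

#' Neutral monoisotopic mass of a lipid species
#'
#' @param species A [lipid_species()].
#' @return Mass in Da.
#' @export
species_mass <- function(species) {
  formula_mass(species_formula(species))
}

SUPPORTED_ADDUCTS <- c("[M+H]+", "[M-H]-", "[M+H-H2O]+", "[M+NH4]+")

## which adducts make sense for each class under ESI flow injection
class_adducts <- function(lipid_class) {
  switch(lipid_class,
    FFA = "[M-H]-",
    CE  = "[M+NH4]+",
    Cer = c("[M+H]+", "[M+H-H2O]+"),
    c("[M+H]+"))
}

#' Precursor (parent ion) m/z of a lipid species
#'
#' Neutral monoisotopic mass shifted by the adduct: `[M+H]+` and `[M-H]-` use
#' the proton mass (1.00728 Da); `[M+H-H2O]+` additionally subtracts one water
#' (in-source dehydration, common for phytosphingosine and sphinganine
#' ceramides); `[M+NH4]+` is used for cholesteryl esters.
#'
#' @param species A [lipid_species()].
#' @param adduct One of `"[M+H]+"`, `"[M-H]-"`, `"[M+H-H2O]+"`, `"[M+NH4]+"`.
#' @return An [mz_value()].
#' @examples
#' cer <- lipid_species("Cer", acyl_chain(16, 0), sphingoid_base("d18:1"))
#' precursor_mz(cer, "[M+H]+") # 538.519
#' @export
precursor_mz <- function(species, adduct = "[M+H]+") {
  stopifnot(inherits(species, "lipid_species"))
  adduct <- match.arg(adduct, SUPPORTED_ADDUCTS)
  if (!adduct %in% class_adducts(species$lipid_class)) {
    stop("adduct ", adduct, " is not supported for class ",
         species$lipid_class)
  }
  m <- species_mass(species)
  switch(adduct,
    "[M+H]+"     = mz_value(m + PROTON_MASS, "+"),
    "[M+H-H2O]+" = mz_value(m + PROTON_MASS - WATER_MASS, "+"),
    "[M+NH4]+"   = mz_value(m + AMMONIUM_SHIFT, "+"),
    "[M-H]-"     = mz_value(m - PROTON_MASS, "-"))
}

## ---------------------------------------------------------------------------
## Shorthand parsing

parse_cd <- function(txt, token) {
  m <- regmatches(txt, regexec("^([0-9]+):([0-9]+)$", txt))[[1]]
  if (length(m) == 0) stop("cannot parse chain token '", token, "'")
  c(as.integer(m[2]), as.integer(m[3]))
}

#' Parse lipid shorthand nomenclature
#'
#' Accepts the shorthand dialects used for MRM-profiling attribution tables:
#' ceramides such as `"CerAS(d18:1/16:0)2OH"`, `"CerNP(t18:0/16:0)"` or
#' `"CerDS(18:0/10:0)"` (bare sphinganine backbone); glycerophospholipids at
#' sum composition (`"PC(34:1)"`, `"ePC(34:1)"`, `"pPC(34:0)"`, `"PE(34:1)"`,
#' ...); sphingomyelins as `"SM(d18:1/16:0)"`, `"SM(16:0)"` (d18:1 backbone
#' implied) or `"SM(d34:1)"`; acylcarnitines `"AC(16:0)"`, `"AC(12:1)OH"`;
#' cholesteryl esters `"CE(18:1)"`; free fatty acids `"FFA(26:0)"`, `"C26:0"`,
#' `"22:6"` or `"16-hydroxy(16:0)"`.
#'
#' @param name Shorthand text.
#' @return A [lipid_species()] whose canonical formatting re-parses to an
#'   identical species.
#' @examples
#' parse_lipid("CerAS(d18:1/16:0)2OH")
#' parse_lipid("PC(34:1)")
#' @export
parse_lipid <- function(name) {
  if (!is.character(name) || length(name) != 1 || !nzchar(trimws(name))) {
    stop("lipid name must be a non-empty string")
  }
  txt <- gsub("\\s+", "", name)

  ## ceramides: Cer[N|A][S|DS|P](base/chain)[2OH]
  m <- regmatches(txt, regexec(
    "^Cer(N|A)?(S|DS|P)?\\(([dt]?[0-9]+:[0-9]+)/([0-9]+:[0-9]+)\\)(2?OH)?$",
    txt))[[1]]
  if (length(m) > 0) {
    hydroxy_letter <- m[2]; base_letter <- m[3]
    base_tok <- m[4]; chain_tok <- m[5]; oh_suffix <- m[6]
    if (!grepl("^[dt]", base_tok)) {
      ## bare backbone as in "CerDS(18:0/10:0)": prefix from the base letter
      base_tok <- paste0(if (identical(base_letter, "P")) "t" else "d",
                         base_tok)
    }
    base <- sphingoid_base(base_tok)
    if (nzchar(base_letter) &&
        !identical(base_letter, ceramide_base_letter(base))) {
      stop("base letter '", base_letter, "' contradicts backbone '",
           base_tok, "' in '", name, "'")
    }
    cd <- parse_cd(chain_tok, name)
    h <- if (nzchar(oh_suffix) || identical(hydroxy_letter, "A")) 1L else 0L
    return(lipid_species("Cer", acyl_chain(cd[1], cd[2], h), base))
  }

  ## PC family / glycerophospholipids at sum composition
  m <- regmatches(txt, regexec(
    "^(ePC|pPC|e-PC|p-PC|PC|PE|PS|PI|PG|CE)\\(([0-9]+:[0-9]+)\\)$", txt))[[1]]
  if (length(m) > 0) {
    cls <- sub("-", "", m[2], fixed = TRUE)
    cd <- parse_cd(m[3], name)
    return(lipid_species(cls, acyl_chain(cd[1], cd[2], 0)))
  }

  ## sphingomyelin: SM(d18:1/16:0) | SM(16:0) | SM(d34:1)
  m <- regmatches(txt, regexec(
    "^SM\\((?:(d[0-9]+:[0-9]+)/)?(d?)([0-9]+:[0-9]+)\\)$", txt))[[1]]
  if (length(m) > 0) {
    cd <- parse_cd(m[4], name)
    if (nzchar(m[2])) {            # explicit backbone: totals = base + acyl
      b <- parse_cd(sub("^d", "", m[2]), name)
      cd <- cd + b
    } else if (!nzchar(m[3])) {    # acyl only: d18:1 backbone implied
      cd <- cd + c(18L, 1L)
    }                              # "d34:1": already a total
    return(lipid_species("SM", acyl_chain(cd[1], cd[2], 0)))
  }

  ## acylcarnitine: AC(16:0), AC(12:1)OH
  m <- regmatches(txt, regexec("^AC\\(([0-9]+:[0-9]+)\\)(OH)?$", txt))[[1]]
  if (length(m) > 0) {
    cd <- parse_cd(m[2], name)
    return(lipid_species("AC", acyl_chain(cd[1], cd[2],
                                          if (nzchar(m[3])) 1L else 0L)))
  }

  ## free fatty acids: FFA(26:0)[OH] | C26:0 | 26:0 | 16-hydroxy(16:0)
  m <- regmatches(txt, regexec("^FFA\\(([0-9]+:[0-9]+)\\)(2?OH)?$", txt))[[1]]
  if (length(m) > 0) {
    cd <- parse_cd(m[2], name)
    return(lipid_species("FFA", acyl_chain(cd[1], cd[2],
                                           if (nzchar(m[3])) 1L else 0L)))
  }
  m <- regmatches(txt, regexec("^C?([0-9]+:[0-9]+)$", txt))[[1]]
  if (length(m) > 0) {
    cd <- parse_cd(m[2], name)
    return(lipid_species("FFA", acyl_chain(cd[1], cd[2], 0)))
  }
  m <- regmatches(txt, regexec(
    "^[0-9]+-hydroxy\\(?([0-9]+:[0-9]+)\\)?$", txt))[[1]]
  if (length(m) > 0) {
    cd <- parse_cd(m[2], name)
    return(lipid_species("FFA", acyl_chain(cd[1], cd[2], 1L)))
  }

  tok <- regmatches(txt, regexpr("^[A-Za-z-]+", txt))
  stop("cannot parse lipid shorthand '", name, "'",
       if (length(tok) > 0 && nzchar(tok))
         paste0(": unknown token '", tok, "'") else "")
}

#' Test whether two species denote the same molecular composition
#'
#' Ceramides compare on base code and N-acyl composition; the PC/SM family and
#' other glycerophospholipids compare on class family and sum composition.
#'
#' @param a,b [lipid_species()] objects.
#' @return Logical scalar.
#' @export
same_species <- function(a, b) {
  if (!inherits(a, "lipid_species") || !inherits(b, "lipid_species")) {
    return(FALSE)
  }
  if (!identical(a$lipid_class, b$lipid_class)) return(FALSE)
  if (identical(a$lipid_class, "Cer") &&
      !identical(base_code(a$base), base_code(b$base))) {
    return(FALSE)
  }
  identical(unclass(a$chain), unclass(b$chain))
}

#' Tabulate species names, formulas and masses
#'
#' Builds the packaged species table (name, class, formula string, neutral
#' monoisotopic mass) for a list of species.
#'
#' @param species List of [lipid_species()] objects.
#' @return A `data.frame` with columns `name`, `class`, `formula`, `mass`.
#' @export
species_table <- function(species) {
  stopifnot(is.list(species))
  rows <- lapply(species, function(sp) {
    f <- species_formula(sp)
    f <- f[f != 0]
    data.frame(name = format(sp), class = sp$lipid_class,
               formula = paste0(names(f), ifelse(f == 1, "", f),
                                collapse = ""),
               mass = formula_mass(f), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
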