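## Transition classification by diagnostic fragment, species attribution by
## neutral-mass matching within +-0.5 Da, and MS/MS product-ion
## interpretation.

#' Default candidate-grid bounds for species attribution
#'
#' Chain grids are even-carbon (straight-chain fatty acyls of mammalian
#' lipids are overwhelmingly even-numbered); ceramide N-acyls allow at most
#' two double bonds (epidermal amide-linked fatty acids are saturated or
#' mono/di-unsaturated); free fatty acids allow up to six (through
#' docosahexaenoate); PC/SM sum compositions allow odd totals (odd-chain
#' acyls such as 15:0 and 17:0 occur in sphingomyelins). All bounds are
#' config-exposed here.
#'
#' @return Named list of grid bounds.
#' @export
attribution_grid <- function() {
  list(
    acyl_carbons = seq(2, 36, by = 2),
    cer_double_bonds = 0:2,
    ffa_double_bonds = 0:6,
    ## polyunsaturation needs chain length: at most 3 double bonds below C18,
    ## 4 at C18 (stearidonate), 5 at C20 (eicosapentaenoate), 6 from C22
    ## (docosahexaenoate)
    ffa_max_db = function(n) if (n < 18) 3 else if (n < 20) 4
                             else if (n < 22) 5 else 6,
    ffa_oh_double_bonds = 0:1,
    hydroxyls = 0:1,
    pc_totals = 24:44, pc_double_bonds = 0:6,
    sm_totals = 28:44, sm_double_bonds = 0:3,
    ether_totals = seq(24, 44, by = 2),
    pl_totals = seq(24, 44, by = 2), pl_double_bonds = 0:6,
    ce_carbons = seq(12, 24, by = 2), ce_double_bonds = 0:6
  )
}

FRAGMENT_CLASS_BASES <- c("Cer[S]" = "d18:1", "Cer[DS]" = "d18:0",
                          "Cer[P]" = "t18:0")

#' Classify a transition by its diagnostic fragment
#'
#' Q3 within 0.5 Da of a class fragment key (sphingoid bases 264/266/282,
#' phosphocholine 184, acylcarnitine 85, cholestadiene 369) assigns that
#' class; negative-mode transitions with Q1 == Q3 are free fatty acid SIM;
#' a Q1 - Q3 difference within 0.5 Da of a neutral-loss key (141/185/277
#' for PE/PS/PI, 299/321 for oleate/arachidonate acyl residues) assigns the
#' neutral-loss class. Anything else is `"unknown"` (a value, not an error).
#'
#' @param q1,q3 Parent and fragment m/z.
#' @param polarity `"+"` or `"-"`.
#' @param tolerance Matching window in Da.
#' @return Class label string.
#' @examples
#' classify_transition(666.35, 264.1, "+") # "Cer[S]"
#' classify_transition(271.3, 271.3, "-")  # "FFA"
#' @export
classify_transition <- function(q1, q3, polarity = c("+", "-"),
                                tolerance = 0.5) {
  polarity <- match.arg(polarity)
  if (polarity == "-") {
    return(if (abs(q1 - q3) <= 0.01) "FFA" else "unknown")
  }
  keys <- fragment_key_table()
  hit <- which(abs(keys$key_mz - q3) <= tolerance)
  if (length(hit) > 0) {
    return(keys$class[hit[which.min(abs(keys$key_mz[hit] - q3))]])
  }
  nl <- neutral_loss_table()
  loss <- q1 - q3
  hit <- which(abs(nl$loss - loss) <= tolerance)
  if (length(hit) > 0) {
    return(nl$class[hit[which.min(abs(nl$loss[hit] - loss))]])
  }
  "unknown"
}

## Enumerate candidate (species, adduct) pairs for one class call.
candidate_species <- function(class_call, grid = attribution_grid()) {
  sp <- list(); ad <- character(0)
  push <- function(species, adduct) {
    sp[[length(sp) + 1]] <<- species
    ad[length(ad) + 1] <<- adduct
  }
  if (class_call %in% names(FRAGMENT_CLASS_BASES)) {
    base <- sphingoid_base(FRAGMENT_CLASS_BASES[[class_call]])
    ## in-source dehydration is prominent for phytosphingosine and
    ## sphinganine ceramides; sphingosine ceramides fly as [M+H]+
    adducts <- class_adducts("Cer")
    if (base$kind == "sphingosine") adducts <- "[M+H]+"
    for (n in grid$acyl_carbons) for (d in grid$cer_double_bonds) {
      if (2 * d > 2 * n - 2) next
      for (h in grid$hydroxyls) for (a in adducts) {
        push(lipid_species("Cer", acyl_chain(n, d, h), base), a)
      }
    }
  } else if (class_call == "FFA") {
    for (n in grid$acyl_carbons) for (d in grid$ffa_double_bonds) {
      if (2 * d > 2 * n - 2 || d > grid$ffa_max_db(n)) next
      for (h in grid$hydroxyls) {
        if (h > 0 && !d %in% grid$ffa_oh_double_bonds) next
        push(lipid_species("FFA", acyl_chain(n, d, h)), "[M-H]-")
      }
    }
  } else if (class_call == "AC") {
    for (n in grid$acyl_carbons) for (d in grid$cer_double_bonds) {
      if (2 * d > 2 * n - 2) next
      for (h in grid$hydroxyls) {
        push(lipid_species("AC", acyl_chain(n, d, h)), "[M+H]+")
      }
    }
  } else if (class_call == "CE") {
    for (n in grid$ce_carbons) for (d in grid$ce_double_bonds) {
      if (2 * d > 2 * n - 2) next
      push(lipid_species("CE", acyl_chain(n, d, 0)), "[M+NH4]+")
    }
  } else if (class_call %in% c("PC", "SM")) {
    for (n in grid$pc_totals) for (d in grid$pc_double_bonds) {
      push(lipid_species("PC", acyl_chain(n, d, 0)), "[M+H]+")
    }
    for (n in grid$sm_totals) for (d in grid$sm_double_bonds) {
      push(lipid_species("SM", acyl_chain(n, d, 0)), "[M+H]+")
    }
    for (n in grid$ether_totals) for (d in grid$pc_double_bonds) {
      push(lipid_species("ePC", acyl_chain(n, d, 0)), "[M+H]+")
      push(lipid_species("pPC", acyl_chain(n, d, 0)), "[M+H]+")
    }
  } else if (class_call %in% c("PE", "PS", "PI")) {
    for (n in grid$pl_totals) for (d in grid$pl_double_bonds) {
      push(lipid_species(class_call, acyl_chain(n, d, 0)), "[M+H]+")
    }
  }
  list(species = sp, adduct = ad)
}

candidate_frame <- function(cands) {
  if (length(cands$species) == 0) {
    return(data.frame(name = character(0), adduct = character(0),
                      mz = numeric(0), stringsAsFactors = FALSE))
  }
  data.frame(
    name = vapply(cands$species, format, ""),
    adduct = cands$adduct,
    mz = mapply(function(s, a) precursor_mz(s, a)$mz, cands$species,
                cands$adduct),
    stringsAsFactors = FALSE)
}

#' Attribute a transition to candidate lipid species
#'
#' Enumerates candidate species of the called class over the bounded chain
#' grid, computes each candidate's expected precursor m/z, and keeps those
#' within the tolerance of the observed Q1, ranked by absolute mass error.
#' Exact m/z ties (isomeric/isobaric formulas) are broken toward fewer
#' double bonds, then fewer hydroxyls. Candidates whose error is within
#' 0.1 Da of the best are co-candidates and flag the result `"ambiguous"`,
#' mirroring multi-name attribution cells. For the PC/SM family, a candidate
#' whose M+1 isotope would land on Q1 is reported as an isotope note.
#'
#' @param q1 Observed parent m/z.
#' @param class_call Class label from [classify_transition()].
#' @param tolerance Matching window in Da (default 0.5).
#' @param grid Grid bounds from [attribution_grid()].
#' @param ambiguity_window Da; co-candidates closer than this to the best
#'   are reported together.
#' @return An object of class `attribution_result`: list with `q1`,
#'   `class_call`, `status` (`"attributed"`, `"ambiguous"`,
#'   `"not_attributed"`), `candidates` (`data.frame` of `name`, `adduct`,
#'   `mz`, `delta`), `co_candidates` (names within the ambiguity window) and
#'   `isotope_note`.
#' @examples
#' attribute_species(538.3, "Cer[S]")$candidates[1, "name"]
#' @export
attribute_species <- function(q1, class_call, tolerance = 0.5,
                              grid = attribution_grid(),
                              ambiguity_window = 0.1) {
  cands <- candidate_frame(candidate_species(class_call, grid))
  cands$delta <- cands$mz - q1
  cands <- cands[abs(cands$delta) <= tolerance, , drop = FALSE]
  iso <- character(0)
  if (class_call %in% c("PC", "SM") && nrow(cands) >= 0) {
    all_c <- candidate_frame(candidate_species(class_call, grid))
    ## M+1 isotopologue: one 13C (+1.00336)
    iso_hit <- abs(all_c$mz + 1.00336 - q1) <= tolerance
    iso <- setdiff(all_c$name[iso_hit], cands$name)
  }
  if (nrow(cands) == 0) {
    return(structure(list(q1 = q1, class_call = class_call,
                          status = "not_attributed",
                          candidates = cands, co_candidates = character(0),
                          isotope_note = iso),
                     class = "attribution_result"))
  }
  ## tie keys: |error|, then fewer double bonds, then fewer hydroxyls
  db <- vapply(cands$name, function(n) {
    s <- parse_lipid(n); s$chain$double_bonds
  }, numeric(1))
  oh <- vapply(cands$name, function(n) {
    s <- parse_lipid(n); s$chain$hydroxyls
  }, numeric(1))
  ord <- order(round(abs(cands$delta), 6), db, oh, cands$name)
  cands <- cands[ord, , drop = FALSE]
  rownames(cands) <- NULL
  co <- cands$name[abs(cands$delta) - abs(cands$delta[1]) < ambiguity_window]
  structure(list(q1 = q1, class_call = class_call,
                 status = if (length(co) > 1) "ambiguous" else "attributed",
                 candidates = cands, co_candidates = co,
                 isotope_note = iso),
            class = "attribution_result")
}

#' @export
print.attribution_result <- function(x, ...) {
  cat("<attribution ", format(x$q1), " [", x$class_call, "]: ", x$status,
      sep = "")
  if (nrow(x$candidates) > 0) {
    cat(" -> ", x$candidates$name[1],
        sprintf(" (delta %+.3f)", x$candidates$delta[1]), sep = "")
  }
  cat(">\n")
  invisible(x)
}

#' Attribute every transition of a screening method
#'
#' @param method A `screening_method`.
#' @param tolerance Matching window in Da.
#' @param grid Grid bounds.
#' @return `data.frame` with one row per transition: `transition`, `q1`,
#'   `q3`, `polarity`, `class_call`, `status`, `attribution` (top candidate
#'   name or `NA`), `mass_error`, `co_candidates` and `isotope_note`
#'   (`;`-joined).
#' @export
attribute_method <- function(method, tolerance = 0.5,
                             grid = attribution_grid()) {
  stopifnot(inherits(method, "screening_method"))
  tr <- method$transitions
  rows <- lapply(seq_len(nrow(tr)), function(i) {
    cls <- classify_transition(tr$q1[i], tr$q3[i], tr$polarity[i], tolerance)
    res <- attribute_species(tr$q1[i], cls, tolerance, grid)
    data.frame(
      transition = transition_id(tr[i, , drop = FALSE]),
      q1 = tr$q1[i], q3 = tr$q3[i], polarity = tr$polarity[i],
      class_call = cls, status = res$status,
      attribution = if (nrow(res$candidates) > 0) res$candidates$name[1]
                    else NA_character_,
      mass_error = if (nrow(res$candidates) > 0) res$candidates$delta[1]
                   else NA_real_,
      co_candidates = paste(res$co_candidates, collapse = ";"),
      isotope_note = paste(res$isotope_note, collapse = ";"),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Interpret a ceramide MS/MS product-ion spectrum
#'
#' Reads a product-ion peak list the way ceramide attributions are
#' confirmed: the water-loss peak (parent - 18.011), the sphingoid-base
#' fragment (264/266/282 keys), their difference as the fatty-acyl residue
#' mass, and the acyl chain whose free-fatty-acid mass matches that residue
#' within tolerance.
#'
#' @param parent_mz Parent ion m/z.
#' @param fragments Numeric vector of product-ion m/z values.
#' @param tolerance Matching window in Da.
#' @return An object of class `msms_evidence`: list with `parent_mz`,
#'   `water_loss_peak`, `base_peak`, `base_kind`, `fa_residue_mass`,
#'   `matched_fa` (an [acyl_chain()] or `NULL`) and `found` status flags.
#' @examples
#' ev <- interpret_msms(666.3, c(648.3, 264.1))
#' ev$fa_residue_mass # 384.2
#' @export
interpret_msms <- function(parent_mz, fragments, tolerance = 0.5) {
  if (length(fragments) == 0) stop("fragment list is empty")
  expected_wl <- parent_mz - WATER_MASS
  wl_i <- which(abs(fragments - expected_wl) <= tolerance)
  water_loss_peak <- if (length(wl_i) > 0) {
    fragments[wl_i[which.min(abs(fragments[wl_i] - expected_wl))]]
  } else NA_real_
  keys <- fragment_key_table()
  keys <- keys[keys$class %in% names(FRAGMENT_CLASS_BASES), , drop = FALSE]
  base_peak <- NA_real_; base_kind <- NA_character_
  for (i in seq_len(nrow(keys))) {
    hit <- which(abs(fragments - keys$key_mz[i]) <= tolerance)
    if (length(hit) > 0) {
      base_peak <- fragments[hit[which.min(abs(fragments[hit] -
                                               keys$key_mz[i]))]]
      base_kind <- keys$class[i]
      break
    }
  }
  fa_residue_mass <- if (!is.na(water_loss_peak) && !is.na(base_peak)) {
    water_loss_peak - base_peak
  } else NA_real_
  matched_fa <- NULL
  if (!is.na(fa_residue_mass)) {
    grid <- attribution_grid()
    best <- Inf
    for (n in grid$acyl_carbons) for (d in grid$cer_double_bonds) {
      if (2 * d > 2 * n - 2) next
      for (h in grid$hydroxyls) {
        ch <- acyl_chain(n, d, h)
        err <- abs(acyl_mass(ch) - fa_residue_mass)
        if (err <= tolerance && err < best) {
          best <- err
          matched_fa <- ch
        }
      }
    }
  }
  structure(list(parent_mz = parent_mz, fragments = fragments,
                 water_loss_peak = water_loss_peak, base_peak = base_peak,
                 base_kind = base_kind, fa_residue_mass = fa_residue_mass,
                 matched_fa = matched_fa,
                 found = c(water_loss = !is.na(water_loss_peak),
                           base = !is.na(base_peak))),
            class = "msms_evidence")
}

#' @export
print.msms_evidence <- function(x, ...) {
  cat("<MS/MS parent ", x$parent_mz, ": residue ",
      if (is.na(x$fa_residue_mass)) "not found"
      else format(x$fa_residue_mass),
      if (!is.null(x$matched_fa)) paste0(" -> ", format(x$matched_fa)) else "",
      ">\n", sep = "")
  invisible(x)
}
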