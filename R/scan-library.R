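## Discovery scans (Prec/NL/SIM), MRM transitions and screening methods.

## Class-diagnostic fragment keys. `key_mz` is the exact computed value used
## for arithmetic; `setpoint` is the instrument-style nominal value the
## screening tables print. Both sit inside the 0.5 Da matching window.
fragment_key_table <- function() {
  keys <- data.frame(
    class = c("Cer[S]", "Cer[DS]", "Cer[P]", "PC", "AC", "CE"),
    key_mz = c(
      base_fragment_mz(sphingoid_base("d18:1"))$mz,
      base_fragment_mz(sphingoid_base("d18:0"))$mz,
      base_fragment_mz(sphingoid_base("t18:0"))$mz,
      ## phosphocholine head-group cation C5H15NO4P+
      formula_mass(elemental_formula(C = 5, H = 14, N = 1, O = 4, P = 1)) +
        PROTON_MASS,
      ## acylium-derived carnitine fragment C4H5O2+
      formula_mass(elemental_formula(C = 4, H = 4, O = 2)) + PROTON_MASS,
      ## cholestadiene cation C27H45+
      formula_mass(elemental_formula(C = 27, H = 44)) + PROTON_MASS),
    setpoint = c(264.1, 266.1, 282.1, 184.1, 85.1, 369.1),
    stringsAsFactors = FALSE)
  keys
}

## Neutral-loss keys (Da) with the lipid class they diagnose.
neutral_loss_table <- function() {
  data.frame(
    class = c("PE", "PS", "PI", "NL-oleate", "NL-arachidonate"),
    loss = c(141, 185, 277, 299, 321),
    stringsAsFactors = FALSE)
}

#' Construct a discovery scan definition
#'
#' @param mode `"precursor_ion"`, `"neutral_loss"`, `"single_ion"` or `"mrm"`.
#' @param key_mz Diagnostic fragment m/z (precursor-ion scans) or neutral-loss
#'   mass in Da (neutral-loss scans); ignored for single-ion monitoring.
#' @param polarity `"+"` or `"-"`.
#' @param target_class Lipid class label the scan profiles.
#' @param q1_range Two-element numeric, the Q1 scan window.
#' @return An object of class `scan_definition`.
#' @export
scan_definition <- function(mode = c("precursor_ion", "neutral_loss",
                                     "single_ion", "mrm"),
                            key_mz = NA_real_, polarity = c("+", "-"),
                            target_class = "unknown",
                            q1_range = if (polarity == "+") c(200, 1000)
                                       else c(199, 600)) {
  mode <- match.arg(mode)
  polarity <- match.arg(polarity)
  if (mode %in% c("precursor_ion", "neutral_loss")) {
    if (is.na(key_mz) || key_mz <= 0) stop("key_mz must be positive")
  }
  if (length(q1_range) != 2 || q1_range[1] >= q1_range[2]) {
    stop("q1_range must be an increasing [low, high] pair")
  }
  structure(list(mode = mode, key_mz = key_mz, polarity = polarity,
                 target_class = target_class, q1_range = q1_range),
            class = "scan_definition")
}

#' @export
print.scan_definition <- function(x, ...) {
  cat("<scan ", x$mode, " ", if (!is.na(x$key_mz)) x$key_mz else "",
      " [", x$polarity, "] -> ", x$target_class, ">\n", sep = "")
  invisible(x)
}

#' The discovery scan panel
#'
#' The class-supervised scans used to discover lipid features in epidermis
#' extracts: precursor-ion m/z 184 (PC/SM), neutral losses 141/185/277
#' (PE/PS/PI), precursor-ion 264.3/266.4/282.4 (sphingosine, sphinganine and
#' phytosphingosine ceramides), precursor-ion 85 (acylcarnitines), 369.1
#' (cholesteryl esters), neutral losses 299/321 plus precursor-ion 303.1
#' (oleate/arachidonate acyl residues), and negative-mode free fatty acid
#' single-ion monitoring.
#'
#' @return Named list of [scan_definition()] objects.
#' @export
build_discovery_scans <- function() {
  list(
    prec_184   = scan_definition("precursor_ion", 184,   "+", "PC"),
    nl_141     = scan_definition("neutral_loss",  141,   "+", "PE"),
    nl_185     = scan_definition("neutral_loss",  185,   "+", "PS"),
    nl_277     = scan_definition("neutral_loss",  277,   "+", "PI"),
    prec_264   = scan_definition("precursor_ion", 264.3, "+", "Cer[S]"),
    prec_266   = scan_definition("precursor_ion", 266.4, "+", "Cer[DS]"),
    prec_282   = scan_definition("precursor_ion", 282.4, "+", "Cer[P]"),
    prec_85    = scan_definition("precursor_ion", 85,    "+", "AC"),
    prec_369   = scan_definition("precursor_ion", 369.1, "+", "CE"),
    nl_299     = scan_definition("neutral_loss",  299,   "+", "NL-oleate"),
    nl_321     = scan_definition("neutral_loss",  321,   "+",
                                 "NL-arachidonate"),
    prec_303   = scan_definition("precursor_ion", 303.1, "+",
                                 "NL-arachidonate"),
    sim_ffa    = scan_definition("single_ion", polarity = "-",
                                 target_class = "FFA")
  )
}

#' Construct a transition table
#'
#' @param q1,q3 Parent and fragment m/z (numeric vectors).
#' @param polarity `"+"` or `"-"`, recycled.
#' @param class_hint Lipid class label, recycled; `"unknown"` if absent.
#' @param collision_energy,fragmentor Voltages; filled by
#'   [assemble_screening_methods()] when `NA`.
#' @return A `data.frame` with one row per transition.
#' @export
transition_table <- function(q1, q3, polarity = "+", class_hint = "unknown",
                             collision_energy = NA_real_, fragmentor = 100) {
  if (length(q3) == 1) q3 <- rep_len(q3, length(q1))
  stopifnot(length(q1) == length(q3), all(q1 > 0), all(q3 > 0))
  df <- data.frame(q1 = as.numeric(q1), q3 = as.numeric(q3),
                   polarity = rep_len(as.character(polarity), length(q1)),
                   class_hint = rep_len(as.character(class_hint), length(q1)),
                   collision_energy = rep_len(as.numeric(collision_energy),
                                              length(q1)),
                   fragmentor = rep_len(as.numeric(fragmentor), length(q1)),
                   stringsAsFactors = FALSE)
  neg_sim <- df$polarity == "-" & df$class_hint == "FFA"
  if (any(abs(df$q1[neg_sim] - df$q3[neg_sim]) > 1e-9)) {
    stop("negative-mode FFA single-ion transitions must have q1 == q3")
  }
  df
}

#' Transition identifier strings
#'
#' Stable ids of the form `"666.35/264.1+"` used to key feature matrices,
#' effects maps and statistics tables.
#'
#' @param transitions Transition `data.frame` (columns `q1`, `q3`,
#'   `polarity`).
#' @return Character vector.
#' @export
transition_id <- function(transitions) {
  paste0(sprintf("%.10g", transitions$q1), "/",
         sprintf("%.10g", transitions$q3), transitions$polarity)
}

#' Collision energy for a lipid class
#'
#' The screening-method collision-energy map: ceramides, PE and oleate /
#' arachidonate acyl-residue transitions at 22 V, PC and SM at 20 V, PS and
#' PI at 16 V, cholesteryl esters at 17 V, acylcarnitines at 30 V; every
#' negative-mode transition at 2 V. The fragmentor is fixed at 100 V.
#'
#' @param class_hint Lipid class label.
#' @param polarity `"+"` or `"-"`.
#' @return Collision energy in volts.
#' @export
collision_energy_for <- function(class_hint, polarity = c("+", "-")) {
  polarity <- match.arg(polarity)
  if (polarity == "-") return(2)
  ce_map <- c("Cer[S]" = 22, "Cer[DS]" = 22, "Cer[P]" = 22, "Cer" = 22,
              "PE" = 22, "NL-oleate" = 22, "NL-arachidonate" = 22,
              "PC" = 20, "SM" = 20, "PS" = 16, "PI" = 16, "CE" = 17,
              "AC" = 30)
  if (!class_hint %in% names(ce_map)) {
    stop("no collision energy mapped for positive-mode class '", class_hint,
         "'")
  }
  unname(ce_map[class_hint])
}

#' Detect features in a discovery scan profile
#'
#' Local maxima of the scan profile above a fraction of the base peak become
#' MRM transitions: Q3 is the scan's fragment key for precursor-ion scans,
#' `Q1 - loss` for neutral-loss scans, and Q1 itself for single-ion
#' monitoring.
#'
#' @param spectrum `data.frame` with columns `mz` and `intensity`.
#' @param scan A [scan_definition()].
#' @param min_rel_intensity Acceptance threshold as a fraction of the base
#'   peak (default 0.01).
#' @return Transition `data.frame` (see [transition_table()]).
#' @export
detect_features <- function(spectrum, scan, min_rel_intensity = 0.01) {
  stopifnot(inherits(scan, "scan_definition"))
  if (!is.data.frame(spectrum) || nrow(spectrum) == 0 ||
      !all(c("mz", "intensity") %in% names(spectrum))) {
    stop("spectrum must be a non-empty data.frame with mz and intensity")
  }
  if (min_rel_intensity <= 0 || min_rel_intensity >= 1) {
    stop("min_rel_intensity must be in (0, 1)")
  }
  spectrum <- spectrum[order(spectrum$mz), , drop = FALSE]
  base_peak <- max(spectrum$intensity)
  if (base_peak <= 0) stop("spectrum carries no signal")
  y <- spectrum$intensity
  n <- length(y)
  left <- c(-Inf, y[-n]); right <- c(y[-1], -Inf)
  is_max <- y >= left & y > right | (y > left & y >= right)
  keep <- is_max & y >= min_rel_intensity * base_peak
  mz <- spectrum$mz[keep]
  mz <- mz[mz >= scan$q1_range[1] & mz <= scan$q1_range[2]]
  if (scan$mode == "neutral_loss") mz <- mz[mz > scan$key_mz]
  if (length(mz) == 0) {
    return(transition_table(numeric(0), numeric(0)))
  }
  q3 <- switch(scan$mode,
    precursor_ion = rep(scan$key_mz, length(mz)),
    neutral_loss  = mz - scan$key_mz,
    single_ion    = mz,
    mrm           = stop("mrm scans carry explicit transitions"))
  transition_table(mz, q3, scan$polarity, scan$target_class)
}

#' Assemble screening methods from a transition list
#'
#' Deduplicates transitions (identical (Q1, Q3) to one decimal within a
#' polarity), fills class-mapped collision energies and the 100 V fragmentor,
#' and splits the list into one positive-mode and one negative-mode
#' flow-injection method of 2 min acquisition each.
#'
#' @param transitions Transition `data.frame`.
#' @param acquisition_time Minutes of data acquisition per method (default 2).
#' @return List with elements `positive` and `negative`, each a
#'   `screening_method` (or `NULL` when that polarity is absent).
#' @export
assemble_screening_methods <- function(transitions, acquisition_time = 2) {
  stopifnot(is.data.frame(transitions),
            all(c("q1", "q3", "polarity") %in% names(transitions)))
  if (!"class_hint" %in% names(transitions)) transitions$class_hint <- "unknown"
  key <- paste(round(transitions$q1, 1), round(transitions$q3, 1),
               transitions$polarity)
  transitions <- transitions[!duplicated(key), , drop = FALSE]
  transitions$collision_energy <- mapply(collision_energy_for,
                                         transitions$class_hint,
                                         transitions$polarity)
  transitions$fragmentor <- 100
  out <- list(positive = NULL, negative = NULL)
  for (pol in c("+", "-")) {
    sub <- transitions[transitions$polarity == pol, , drop = FALSE]
    if (nrow(sub) == 0) next
    sub <- sub[order(sub$q1, sub$q3), , drop = FALSE]
    rownames(sub) <- NULL
    slot <- if (pol == "+") "positive" else "negative"
    out[[slot]] <- structure(list(polarity = pol, transitions = sub,
                                  acquisition_time = acquisition_time),
                             class = "screening_method")
  }
  out
}

#' @export
print.screening_method <- function(x, ...) {
  cat("<screening method [", x$polarity, "] ", nrow(x$transitions),
      " transitions, ", x$acquisition_time, " min>\n", sep = "")
  invisible(x)
}

#' Read / write screening-method TSV files
#'
#' The on-disk method format is a TSV with columns `q1`, `q3`, `polarity`,
#' `collision_energy`, `fragmentor`, `class_hint` and optional `attribution`.
#'
#' @param method A `screening_method`.
#' @param path File path.
#' @return `read_method_tsv()` returns a `screening_method`;
#'   `write_method_tsv()` returns `path` invisibly.
#' @export
write_method_tsv <- function(method, path) {
  stopifnot(inherits(method, "screening_method"))
  utils::write.table(method$transitions, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_method_tsv
#' @export
read_method_tsv <- function(path) {
  if (!file.exists(path)) stop("method file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("q1", "q3", "polarity")
  if (!all(need %in% names(df))) {
    stop("method file lacks required columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  pol <- unique(df$polarity)
  if (length(pol) != 1) stop("a method file must be polarity-pure")
  methods <- assemble_screening_methods(df)
  if (pol == "+") methods$positive else methods$negative
}
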