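## Packaged assay defaults: the curated significant-feature table for the
## cpdm-vs-WT mouse epidermis assay, and a synthetic reconstruction of the two
## screening methods (217 positive + 83 negative transitions).

#' Curated significant-feature table of the cpdm epidermis assay
#'
#' The published list of transitions that discriminate cpdm from wild-type
#' epidermis (volcano selection at p <= 0.05 and at least two-fold change),
#' with tentative attributions, cpdm/WT fold changes and p-values. Multi-name
#' attribution cells are `;`-separated; `"Not attributed"` marks transitions
#' with no candidate; `isotope_note` carries a possible isotope co-assignment.
#'
#' @return A `data.frame` with columns `parent_mz`, `fragment_mz`, `polarity`,
#'   `scan`, `attribution`, `isotope_note`, `fold_change`, `p_value`.
#' @export
significant_features <- function() {
  path <- system.file("extdata", "cpdm_epidermis_significant_features.tsv",
                      package = "lipidmrm", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(isotope_note = "character"))
}

## Default cpdm/WT effects map: named fold-change vector keyed by transition id
#' Fold-change effects of the cpdm phenotype
#'
#' The per-transition cpdm/WT fold changes of the significant-feature table,
#' keyed by transition id (`"666.35/264.1+"`); the default `effects` of
#' [cohort_config()].
#'
#' @return Named numeric vector of fold changes.
#' @export
reference_effects <- function() {
  tab <- significant_features()
  ids <- transition_id(data.frame(q1 = tab$parent_mz, q3 = tab$fragment_mz,
                                  polarity = tab$polarity))
  stats::setNames(tab$fold_change, ids)
}

cer_filler <- function(base_code_txt, chains, hydroxyls, q3_setpoint,
                       class_hint) {
  base <- sphingoid_base(base_code_txt)
  dehydrate <- base$kind %in% c("phytosphingosine", "sphinganine")
  q1 <- vapply(chains, function(cd) {
    sp <- lipid_species("Cer", acyl_chain(cd[1], cd[2], hydroxyls), base)
    precursor_mz(sp, if (dehydrate) "[M+H-H2O]+" else "[M+H]+")$mz
  }, numeric(1))
  transition_table(round(q1, 1), q3_setpoint, "+", class_hint)
}

sum_class_filler <- function(cls, comps, q3_fun, class_hint = cls) {
  q1 <- vapply(comps, function(cd) {
    sp <- lipid_species(cls, acyl_chain(cd[1], cd[2], 0))
    precursor_mz(sp, if (cls == "CE") "[M+NH4]+" else "[M+H]+")$mz
  }, numeric(1))
  q1 <- round(q1, 1)
  transition_table(q1, q3_fun(q1), "+", class_hint)
}

cd <- function(...) {
  m <- matrix(c(...), nrow = 2)
  lapply(seq_len(ncol(m)), function(i) m[, i])
}

#' Synthetic reconstruction of the two screening methods
#'
#' Rebuilds the positive- and negative-mode flow-injection screening methods
#' at their published sizes (217 and 83 transitions). The transitions of the
#' significant-feature table are included verbatim; the remainder are
#' synthetic fillers enumerated deterministically from the species grids so
#' that the per-class feature counts match the discovery-phase report
#' (68 phospholipid, 32 cholesteryl-ester, 21 acylcarnitine, 33 ceramide and
#' 63 acyl-residue neutral-loss features in positive mode; 83 free fatty
#' acids in negative mode). This is a stand-in for the instrument method
#' tables, not a copy of them.
#'
#' @return List with `positive` and `negative` `screening_method` objects.
#' @export
reference_screening_methods <- function() {
  tab <- significant_features()
  scan_class <- c("Ceramide" = "Cer", "PC" = "PC", "Acylcarnitine" = "AC",
                  "NL AA" = "NL-arachidonate", "FFA" = "FFA")
  verbatim <- transition_table(tab$parent_mz, tab$fragment_mz, tab$polarity,
                               unname(scan_class[tab$scan]))
  ## ceramide class hints need the base resolved from the fragment setpoint
  cer <- verbatim$class_hint == "Cer"
  verbatim$class_hint[cer] <- c("264.1" = "Cer[S]", "266.1" = "Cer[DS]",
                                "282.1" = "Cer[P]")[
                                  as.character(verbatim$q3[cer])]

  fillers <- rbind(
    ## ceramides: 21 fillers -> 33 with the 12 verbatim rows
    cer_filler("d18:1", cd(18, 0, 20, 0, 26, 0, 28, 0, 30, 0, 18, 1, 20, 1,
                           26, 1), 0, 264.1, "Cer[S]"),
    cer_filler("d18:1", cd(18, 0, 20, 0, 22, 0), 1, 264.1, "Cer[S]"),
    cer_filler("t18:0", cd(18, 0, 20, 0, 22, 0, 24, 0), 0, 282.1, "Cer[P]"),
    cer_filler("t18:0", cd(18, 0, 20, 0, 24, 0), 1, 282.1, "Cer[P]"),
    cer_filler("d18:0", cd(12, 0, 14, 0, 16, 0), 0, 266.1, "Cer[DS]"),
    ## acylcarnitines: 15 fillers -> 21 with the 6 verbatim rows
    sum_class_filler("AC", cd(2, 0, 4, 0, 6, 0, 8, 0, 10, 0, 12, 0, 14, 0,
                              18, 0, 20, 0, 22, 0, 24, 0, 26, 0, 14, 1,
                              16, 1, 18, 1), function(q1) 85.1),
    ## cholesteryl esters: 32 features, none in the significant table
    sum_class_filler("CE", c(cd(12, 0, 12, 1, 12, 2, 12, 3,
                                14, 0, 14, 1, 14, 2, 14, 3,
                                16, 0, 16, 1, 16, 2, 16, 3,
                                18, 0, 18, 1, 18, 2, 18, 3,
                                20, 0, 20, 1, 20, 2, 20, 3,
                                22, 0, 22, 1, 22, 2, 22, 3,
                                24, 0, 24, 1, 24, 2, 24, 3),
                              cd(20, 4, 20, 5, 22, 4, 22, 6)),
                     function(q1) 369.1),
    ## phospholipids: 59 fillers -> 68 with the 9 verbatim PC-scan rows
    sum_class_filler("PC", cd(30, 0, 30, 1, 32, 0, 32, 1, 32, 2, 34, 0,
                              34, 1, 34, 2, 34, 3, 36, 0, 36, 1, 36, 2,
                              36, 3, 36, 4, 38, 4, 38, 6),
                     function(q1) 184.1),
    sum_class_filler("SM", cd(34, 1, 36, 1, 38, 1, 40, 1, 42, 1, 42, 2),
                     function(q1) 184.1, class_hint = "SM"),
    sum_class_filler("ePC", cd(36, 1), function(q1) 184.1,
                     class_hint = "PC"),
    sum_class_filler("PE", cd(32, 0, 32, 1, 34, 0, 34, 1, 34, 2, 36, 0,
                              36, 1, 36, 2, 36, 4, 38, 4, 38, 5, 38, 6,
                              40, 4, 40, 6),
                     function(q1) round(q1 - 141, 1)),
    sum_class_filler("PS", cd(32, 0, 34, 0, 34, 1, 36, 0, 36, 1, 36, 2,
                              38, 3, 38, 4, 40, 4, 40, 6),
                     function(q1) round(q1 - 185, 1)),
    sum_class_filler("PI", cd(32, 0, 32, 1, 34, 0, 34, 1, 34, 2, 36, 1,
                              36, 2, 36, 4, 38, 3, 38, 4, 38, 5, 40, 6),
                     function(q1) round(q1 - 277, 1)),
    ## acyl-residue neutral-loss features: 61 fillers -> 63 with 2 verbatim
    transition_table(seq(576.5, by = 2, length.out = 31),
                     round(seq(576.5, by = 2, length.out = 31) - 299, 1),
                     "+", "NL-oleate"),
    transition_table(seq(598.5, by = 2, length.out = 30),
                     round(seq(598.5, by = 2, length.out = 30) - 321, 1),
                     "+", "NL-arachidonate")
  )

  ## negative mode: 80 FFA fillers -> 83 with the 3 verbatim SIM rows.
  ## Species already present verbatim (within 0.15 Da) are skipped.
  ffa_grid <- c(lapply(12:34, function(n) c(n, 0, 0)),
                lapply(14:30, function(n) c(n, 1, 0)),
                lapply(16:30, function(n) c(n, 2, 0)),
                lapply(18:24, function(n) c(n, 3, 0)),
                lapply(c(20, 22, 24), function(n) c(n, 4, 0)),
                lapply(c(20, 22), function(n) c(n, 5, 0)),
                list(c(22, 6, 0)),
                lapply(setdiff(12:26, 20), function(n) c(n, 0, 1)))
  ffa_mz <- vapply(ffa_grid, function(x) {
    precursor_mz(lipid_species("FFA", acyl_chain(x[1], x[2], x[3])),
                 "[M-H]-")$mz
  }, numeric(1))
  verb_neg <- verbatim$q1[verbatim$polarity == "-"]
  keep <- vapply(ffa_mz, function(m) all(abs(m - verb_neg) > 0.15),
                 logical(1))
  ffa_mz <- round(ffa_mz[keep], 1)
  ffa <- transition_table(ffa_mz, ffa_mz, "-", "FFA")

  assemble_screening_methods(rbind(verbatim, fillers, ffa))
}
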