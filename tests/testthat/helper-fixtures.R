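# Shared fixtures: a compact screening-method pair (5 positive + 3 negative
# transitions drawn from the assay's headline features) and cohort configs
# built on it, so generator/ingest round-trip tests stay fast.

small_methods <- function() {
  tr <- rbind(
    transition_table(c(666.35, 554.2, 538.3, 760.8, 400.3),
                     c(264.1, 264.1, 264.1, 184.1, 85.1),
                     "+", c("Cer[S]", "Cer[S]", "Cer[S]", "PC", "AC")),
    transition_table(c(271.3, 395.4, 327.2), c(271.3, 395.4, 327.2),
                     "-", "FFA"))
  assemble_screening_methods(tr)
}

small_config <- function(methods = small_methods(), ...) {
  cohort_config(methods = methods,
                effects = c("666.35/264.1+" = 18.73, "538.3/264.1+" = 4.89,
                            "271.3/271.3-" = 2.31, "395.4/395.4-" = 0.23),
                baseline = c("666.35/264.1+" = 0.01, "554.2/264.1+" = 0.05,
                             "538.3/264.1+" = 0.02, "760.8/184.1+" = 0.72,
                             "400.3/85.1+" = 0.20,
                             "271.3/271.3-" = 0.05, "395.4/395.4-" = 0.20,
                             "327.2/327.2-" = 0.75),
                ...)
}

# wrap a plain matrix as a feature_matrix for unit tests
make_fm <- function(values, group, split = "testing", polarity = "+") {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("s%02d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("f%02d", seq_len(ncol(values)))
  }
  structure(list(
    values = values,
    samples = data.frame(sample_id = rownames(values), group = group,
                         split = rep_len(split, nrow(values)),
                         stringsAsFactors = FALSE),
    transitions = NULL, polarity = polarity),
    class = "feature_matrix")
}

# curated attribution strings, one row per printed name
curated_names <- function() {
  tab <- significant_features()
  tab <- tab[tab$attribution != "Not attributed", ]
  unlist(strsplit(tab$attribution, ";", fixed = TRUE))
}
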