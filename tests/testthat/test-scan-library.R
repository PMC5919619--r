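# Discovery scan panel, feature detection and screening-method assembly.

test_that("the discovery panel covers every class-supervised scan", {
  panel <- build_discovery_scans()
  has <- function(mode, key, pol, cls) {
    any(vapply(panel, function(s) {
      s$mode == mode && identical(s$polarity, pol) &&
        s$target_class == cls && (is.na(key) || isTRUE(s$key_mz == key))
    }, logical(1)))
  }
  expect_true(has("precursor_ion", 184, "+", "PC"))
  expect_true(has("neutral_loss", 141, "+", "PE"))
  expect_true(has("neutral_loss", 185, "+", "PS"))
  expect_true(has("neutral_loss", 277, "+", "PI"))
  expect_true(has("precursor_ion", 264.3, "+", "Cer[S]"))
  expect_true(has("precursor_ion", 266.4, "+", "Cer[DS]"))
  expect_true(has("precursor_ion", 282.4, "+", "Cer[P]"))
  expect_true(has("precursor_ion", 85, "+", "AC"))
  expect_true(has("precursor_ion", 369.1, "+", "CE"))
  expect_true(has("neutral_loss", 299, "+", "NL-oleate"))
  expect_true(has("neutral_loss", 321, "+", "NL-arachidonate"))
  expect_true(has("single_ion", NA, "-", "FFA"))
  # Q1 windows: 200-1000 positive, 199-600 negative
  expect_equal(panel$prec_184$q1_range, c(200, 1000))
  expect_equal(panel$sim_ffa$q1_range, c(199, 600))
})

test_that("feature detection maps peaks to transitions per scan mode", {
  prec <- scan_definition("precursor_ion", 264.3, "+", "Cer[S]")
  tr <- detect_features(data.frame(mz = 538.3, intensity = 100), prec)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$q1, 538.3)
  expect_equal(tr$q3, 264.3)

  nl <- scan_definition("neutral_loss", 141, "+", "PE")
  tr <- detect_features(data.frame(mz = 716.5, intensity = 50), nl)
  expect_equal(tr$q3, 716.5 - 141)

  sim <- scan_definition("single_ion", polarity = "-", target_class = "FFA")
  tr <- detect_features(data.frame(mz = c(255.2, 395.4),
                                   intensity = c(10, 5)), sim)
  expect_equal(tr$q1, tr$q3)

  expect_error(detect_features(data.frame(mz = c(300, 400),
                                          intensity = c(0, 0)), prec),
               "no signal")
  expect_error(detect_features(data.frame(mz = numeric(0),
                                          intensity = numeric(0)), prec),
               "non-empty")
})

test_that("feature detection keeps local maxima above the threshold only", {
  spec <- data.frame(mz = c(500, 520, 538.3, 560, 600.2, 620),
                     intensity = c(5, 1, 100, 2, 8, 0.5))
  scan <- scan_definition("precursor_ion", 264.3, "+", "Cer[S]")
  tr <- detect_features(spec, scan, min_rel_intensity = 0.03)
  expect_equal(tr$q1, c(500, 538.3, 600.2))  # shoulders at 520/560/620 drop
  tr <- detect_features(spec, scan, min_rel_intensity = 0.07)
  expect_equal(tr$q1, c(538.3, 600.2))       # 500 is below 7% of base
})

test_that("collision energies follow the class map", {
  expect_equal(collision_energy_for("Cer[S]", "+"), 22)
  expect_equal(collision_energy_for("PE", "+"), 22)
  expect_equal(collision_energy_for("PC", "+"), 20)
  expect_equal(collision_energy_for("SM", "+"), 20)
  expect_equal(collision_energy_for("PS", "+"), 16)
  expect_equal(collision_energy_for("CE", "+"), 17)
  expect_equal(collision_energy_for("AC", "+"), 30)
  expect_equal(collision_energy_for("FFA", "-"), 2)
  expect_equal(collision_energy_for("anything", "-"), 2)
  expect_error(collision_energy_for("mystery", "+"), "mystery")
})

test_that("assembly deduplicates, splits polarity and is idempotent", {
  tr <- rbind(
    transition_table(c(538.3, 538.3, 666.35), 264.1, "+", "Cer[S]"),
    transition_table(271.3, 271.3, "-", "FFA"))
  m <- assemble_screening_methods(tr)
  expect_equal(nrow(m$positive$transitions), 2)  # duplicate collapsed
  expect_equal(nrow(m$negative$transitions), 1)
  expect_true(all(m$positive$transitions$polarity == "+"))
  expect_true(all(m$negative$transitions$polarity == "-"))
  expect_equal(m$positive$acquisition_time, 2)
  expect_equal(unique(m$positive$transitions$fragmentor), 100)
  expect_equal(m$positive$transitions$collision_energy, c(22, 22))
  expect_equal(m$negative$transitions$collision_energy, 2)

  m2 <- assemble_screening_methods(rbind(m$positive$transitions,
                                         m$negative$transitions))
  expect_identical(m$positive$transitions, m2$positive$transitions)
  expect_identical(m$negative$transitions, m2$negative$transitions)
})

test_that("negative SIM transitions must monitor the same ion in Q1 and Q3", {
  expect_error(transition_table(271.3, 270.0, "-", "FFA"), "q1 == q3")
})

test_that("every positive transition of the packaged methods has a known Q3", {
  m <- reference_screening_methods()
  tr <- m$positive$transitions
  keys <- fragment_key_table()$key_mz
  ok <- vapply(seq_len(nrow(tr)), function(i) {
    any(abs(tr$q3[i] - keys) <= 0.5) ||
      any(abs((tr$q1[i] - tr$q3[i]) - c(141, 185, 277, 299, 321)) <= 0.5)
  }, logical(1))
  expect_true(all(ok))
})

test_that("method TSV files round-trip", {
  m <- small_methods()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_method_tsv(m$positive, path)
  back <- read_method_tsv(path)
  expect_equal(back$transitions, m$positive$transitions)
  expect_error(read_method_tsv("no/such/file.tsv"), "not found")
})
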