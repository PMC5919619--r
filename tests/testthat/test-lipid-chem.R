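# Shorthand parsing/formatting and monoisotopic mass arithmetic.

# Independent mass oracle: its own atomic-mass table and a plain formula-string
# parser, so species masses are cross-checked by atom counting alone.
oracle_mass <- function(formula) {
  masses <- c(C = 12, H = 1.0078250319, N = 14.0030740052,
              O = 15.9949146221, P = 30.97376151)
  m <- gregexpr("([CHNOP])([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, gregexpr("([CHNOP])([0-9]*)", formula))[[1]]
  sum(vapply(parts, function(p) {
    el <- substr(p, 1, 1)
    n <- sub("^[CHNOP]", "", p)
    masses[[el]] * if (nzchar(n)) as.numeric(n) else 1
  }, numeric(1)))
}

test_that("shorthand round-trip is stable for every curated attribution name", {
  for (nm in curated_names()) {
    sp <- parse_lipid(nm)
    sp2 <- parse_lipid(format(sp))
    expect_true(same_species(sp, sp2), info = nm)
    expect_identical(format(sp), format(sp2), info = nm)
  }
})

test_that("parsing populates ceramide sub-fields from the shorthand", {
  sp <- parse_lipid("CerAS(d18:1/16:0)2OH")
  expect_identical(sp$lipid_class, "Cer")
  expect_identical(sp$base$kind, "sphingosine")
  expect_identical(sp$chain$carbons, 16L)
  expect_identical(sp$chain$hydroxyls, 1L)
  pc <- parse_lipid("PC(34:1)")
  expect_identical(pc$lipid_class, "PC")
  expect_identical(pc$chain$carbons, 34L)
  expect_identical(pc$chain$double_bonds, 1L)
})

test_that("unparseable shorthand raises a parse error naming the token", {
  expect_error(parse_lipid("XX(9:9)"), "XX")
  expect_error(parse_lipid(""), "non-empty")
  expect_error(parse_lipid("Cer(18:1/16:0"), "parse")
})

test_that("free fatty acid masses match the printed values and the oracle", {
  expect_equal(acyl_mass(acyl_chain(16, 0)), 256.2402, tolerance = 1e-6)
  expect_equal(acyl_mass(acyl_chain(24, 0, 1)), 384.3603, tolerance = 1e-6)
  expect_equal(acyl_mass(acyl_chain(2, 0)), 60.0211, tolerance = 1e-6)
  expect_equal(acyl_mass(acyl_chain(16, 0)), oracle_mass("C16H32O2"),
               tolerance = 1e-9)
  expect_equal(acyl_mass(acyl_chain(24, 0, 1)), oracle_mass("C24H48O3"),
               tolerance = 1e-9)
  # the printed low-resolution values sit inside the 0.5 Da window
  expect_lt(abs(acyl_mass(acyl_chain(24, 0, 1)) - 384.2), 0.5)
  expect_lt(abs(acyl_mass(acyl_chain(16, 0)) - 256.1), 0.5)
})

test_that("sphingoid diagnostic fragments hit the scan set-points", {
  frag <- vapply(c("d18:1", "d18:0", "t18:0"), function(b) {
    base_fragment_mz(sphingoid_base(b))$mz
  }, numeric(1))
  expect_equal(unname(frag), c(264.2686, 266.2842, 282.2791),
               tolerance = 1e-6)
  expect_true(all(abs(frag - c(264.3, 266.4, 282.4)) <= 0.5))
})

test_that("precursor m/z matches the worked examples", {
  cer <- lipid_species("Cer", acyl_chain(16, 0), sphingoid_base("d18:1"))
  expect_equal(precursor_mz(cer, "[M+H]+")$mz, 538.519, tolerance = 1e-3)
  expect_lt(abs(precursor_mz(cer, "[M+H]+")$mz - 538.3), 0.5)
  ffa26 <- lipid_species("FFA", acyl_chain(26, 0))
  expect_equal(precursor_mz(ffa26, "[M-H]-")$mz, 395.389, tolerance = 1e-3)
  dha <- lipid_species("FFA", acyl_chain(22, 6))
  expect_equal(precursor_mz(dha, "[M-H]-")$mz, 327.233, tolerance = 1e-3)
})

test_that("unsupported class/adduct combinations raise capability errors", {
  ffa <- lipid_species("FFA", acyl_chain(16, 0))
  expect_error(precursor_mz(ffa, "[M+H]+"), "not supported")
  ce <- lipid_species("CE", acyl_chain(18, 1))
  expect_error(precursor_mz(ce, "[M+H]+"), "not supported")
  cer <- lipid_species("Cer", acyl_chain(16, 0), sphingoid_base("d18:1"))
  expect_error(precursor_mz(cer, "[M-H]-"), "not supported")
})

test_that("species masses agree with atom-count summation for 20 species", {
  table20 <- list(
    c("CerNS(d18:1/16:0)",     "C34H67NO3"),
    c("CerAS(d18:1/16:0)2OH",  "C34H67NO4"),
    c("CerAS(d18:1/24:0)2OH",  "C42H83NO4"),
    c("CerNS(d18:1/24:0)",     "C42H83NO3"),
    c("CerNS(d18:1/24:1)",     "C42H81NO3"),
    c("CerNP(t18:0/16:0)",     "C34H69NO4"),
    c("CerAP(t18:0/16:0)2OH",  "C34H69NO5"),
    c("CerDS(18:0/10:0)",      "C28H57NO3"),
    c("FFA(26:0)",             "C26H52O2"),
    c("FFA(22:6)",             "C22H32O2"),
    c("16-hydroxy(16:0)",      "C16H32O3"),
    c("AC(16:0)",              "C23H45NO4"),
    c("AC(12:1)OH",            "C19H35NO5"),
    c("PC(34:1)",              "C42H82NO8P"),
    c("SM(d34:1)",             "C39H79N2O6P"),
    c("ePC(34:1)",             "C42H84NO7P"),
    c("PE(34:1)",              "C39H76NO8P"),
    c("PS(36:2)",              "C42H78NO10P"),
    c("PI(38:4)",              "C47H83O13P"),
    c("CE(18:1)",              "C45H78O2"))
  for (row in table20) {
    expect_equal(species_mass(parse_lipid(row[1])), oracle_mass(row[2]),
                 tolerance = 1e-9, info = row[1])
  }
})

test_that("acyl mass is monotone in carbons/double bonds and additive in OH", {
  for (d in 0:2) for (h in 0:1) {
    masses <- vapply(seq(4, 30, 2), function(n) acyl_mass(acyl_chain(n, d, h)),
                     numeric(1))
    expect_true(all(diff(masses) > 0))
  }
  for (n in c(18, 22)) {
    by_db <- vapply(0:4, function(d) acyl_mass(acyl_chain(n, d)), numeric(1))
    expect_true(all(diff(by_db) < 0))
    expect_equal(acyl_mass(acyl_chain(n, 0, 1)) - acyl_mass(acyl_chain(n, 0)),
                 15.9949146221, tolerance = 1e-9)
  }
})

test_that("invalid chains and bases are rejected", {
  expect_error(acyl_chain(1, 0), "carbons")
  expect_error(acyl_chain(16, 16), "double bond")
  expect_error(acyl_chain(16, 0, 3), "hydroxyls")
  expect_error(sphingoid_base("t18:1"), "saturated")
  expect_error(mz_value(-5), "positive")
})

test_that("the species table reports names, formulas and masses", {
  tab <- species_table(list(
    lipid_species("Cer", acyl_chain(16, 0), sphingoid_base("d18:1")),
    lipid_species("FFA", acyl_chain(26, 0))))
  expect_identical(tab$formula, c("C34H67NO3", "C26H52O2"))
  expect_equal(tab$mass, c(537.5121, 396.3967), tolerance = 1e-4)
})
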