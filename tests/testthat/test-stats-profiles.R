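# Holm-Sidak t-tests, volcano selection, PCA, clustering and aggregate
# profiles.

# literal step-down definition, applied pairwise (independent oracle)
holm_sidak_oracle <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  out <- rep(FALSE, m)
  for (k in seq_len(m)) {
    ok <- TRUE
    for (j in seq_len(k)) {
      if (!(p[ord[j]] <= 1 - (1 - alpha)^(1 / (m - j + 1)))) ok <- FALSE
    }
    out[ord[k]] <- ok
  }
  out
}

test_that("mirrored groups give t = 0, p = 1 and no significance", {
  set.seed(31)
  base <- matrix(stats::rexp(30 * 4), 30, 4)
  vals <- rbind(base, base)          # cpdm samples duplicate the WT samples
  vals <- vals / rowSums(vals)
  fm <- make_fm(vals, rep(c("WT", "cpdm"), each = 30))
  st <- holm_sidak_ttests(fm)
  expect_equal(st$p, rep(1, 4), tolerance = 1e-12)
  expect_false(any(st$significant))
})

test_that("the m = 3 step-down thresholds follow the closed form", {
  flags <- holm_sidak_flags(c(0.001, 0.2, 0.9), alpha = 0.05)
  expect_identical(flags, c(TRUE, FALSE, FALSE))
  # boundary: threshold for the smallest of three is 1 - 0.95^(1/3)
  thr1 <- 1 - 0.95^(1 / 3)
  expect_identical(holm_sidak_flags(c(thr1 - 1e-9, 0.9, 0.9))[1], TRUE)
  expect_identical(holm_sidak_flags(c(thr1 + 1e-6, 0.9, 0.9))[1], FALSE)
  # step-down: a failure blocks everything below it
  expect_identical(holm_sidak_flags(c(0.04, 0.9, 0.001)),
                   c(FALSE, FALSE, TRUE))
})

test_that("Holm-Sidak flags equal the literal definition on random inputs", {
  set.seed(42)
  for (i in 1:1000) {
    m <- sample(1:20, 1)
    p <- stats::runif(m)^sample(1:3, 1)
    expect_identical(holm_sidak_flags(p, 0.05), holm_sidak_oracle(p, 0.05))
  }
})

test_that("significance is monotone in the raw p-value", {
  set.seed(7)
  for (i in 1:50) {
    p <- stats::runif(15)
    fl <- holm_sidak_flags(p, 0.05)
    if (any(fl)) expect_true(all(p[fl] <= max(p[fl])))
    expect_true(all(fl[order(p)] == cummin(fl[order(p)])))
  }
})

test_that("volcano selection applies both p and fold criteria", {
  st <- data.frame(transition = c("a", "b", "c", "d"),
                   fold_change = c(2.31, 0.42, 1.5, 2.5),
                   p = c(7.67e-12, 7.40e-06, 1e-9, 0.2))
  sel <- volcano_select(st)
  expect_setequal(sel$transition, c("a", "b"))  # c fails fold, d fails p
})

test_that("autoscaled PCA has unit-variance columns and valid spectra", {
  cfg <- small_config()
  fm <- ingest_cohort(generate_cohort(cfg, seed = 13),
                      small_methods()$positive)
  pc <- pca_autoscaled(fm)
  expect_true(all(pc$explained >= -1e-12))
  expect_true(all(diff(pc$explained) <= 1e-12))
  expect_equal(sum(pc$explained), 1, tolerance = 1e-9)
  xs <- scale(fm$values)
  expect_equal(unname(colMeans(xs)), rep(0, ncol(xs)), tolerance = 1e-12)
  expect_equal(unname(apply(xs, 2, stats::sd)), rep(1, ncol(xs)),
               tolerance = 1e-12)
  # sign convention: the largest-magnitude loading is positive
  for (k in 1:3) {
    v <- pc$loadings[, k]
    expect_gt(v[which.max(abs(v))], 0)
  }
})

test_that("constant features are dropped with a warning before scaling", {
  vals <- cbind(matrix(stats::runif(40), 10, 4), const = 0.5)
  vals <- vals / rowSums(vals)
  vals[, 5] <- 0.2                  # exactly constant after normalization
  fm <- make_fm(vals, rep(c("WT", "cpdm"), each = 5))
  expect_warning(pc <- pca_autoscaled(fm), "constant")
  expect_equal(nrow(pc$loadings), 4)
})

test_that("phenotypes separate on PC1 for seeded synthetic cohorts", {
  for (seed in 1:5) {
    cfg <- cohort_config()
    fm <- ingest_cohort(generate_cohort(cfg, seed = seed),
                        reference_screening_methods()$positive)
    pc <- pca_autoscaled(fm)
    s1 <- pc$scores[, 1]
    g <- fm$samples$group
    gap <- min(s1[g == "cpdm"]) > max(s1[g == "WT"]) ||
           min(s1[g == "WT"]) > max(s1[g == "cpdm"])
    expect_true(gap, info = paste("seed", seed))
  }
})

test_that("identical samples merge first in the dendrogram", {
  vals <- matrix(stats::runif(40), 8, 5)
  vals[2, ] <- vals[1, ]
  fm <- make_fm(vals / rowSums(vals), rep(c("WT", "cpdm"), each = 4))
  cl <- cluster_heatmap(fm)
  expect_equal(sort(cl$sample_clust$merge[1, ]), c(-2, -1))
})

test_that("the two-cluster cut recovers the phenotypes and ignores row order", {
  cfg <- cohort_config()
  fm <- ingest_cohort(generate_cohort(cfg, seed = 6),
                      reference_screening_methods()$positive)
  cl <- cluster_heatmap(fm)
  cut2 <- stats::cutree(cl$sample_clust, 2)
  agree <- table(cut2, fm$samples$group)
  expect_true(all(rowSums(agree > 0) == 1))  # each cluster is phenotype-pure

  perm <- sample(nrow(fm$values))
  fm2 <- fm
  fm2$values <- fm$values[perm, , drop = FALSE]
  fm2$samples <- fm$samples[perm, , drop = FALSE]
  cl2 <- cluster_heatmap(fm2)
  d1 <- as.matrix(stats::cophenetic(cl$sample_clust))
  d2 <- as.matrix(stats::cophenetic(cl2$sample_clust))
  expect_equal(d1, d2[rownames(d1), colnames(d1)], tolerance = 1e-9)
})

test_that("aggregate profile shares sum to 1 within a scheme and phenotype", {
  m <- reference_screening_methods()
  fm <- ingest_cohort(generate_cohort(cohort_config(), seed = 9),
                      m$positive)
  att <- attribute_method(m$positive)
  prof <- aggregate_profiles(subset_samples(fm, split = "testing"), att)
  base <- prof[prof$scheme == "cer_base", ]
  for (ph in c("WT", "cpdm")) {
    sub <- base[base$phenotype == ph, ]
    shares <- sub$mean / sum(sub$mean)
    expect_equal(sum(shares), 1, tolerance = 1e-12)
  }
})

test_that("profile directions match the dermatitis phenotype", {
  m <- reference_screening_methods()
  cfg <- cohort_config()
  tab <- generate_cohort(cfg, seed = 14)
  fm_pos <- subset_samples(ingest_cohort(tab, m$positive), split = "testing")
  fm_neg <- subset_samples(ingest_cohort(tab, m$negative), split = "testing")
  att <- rbind(attribute_method(m$positive), attribute_method(m$negative))

  prof <- aggregate_profiles(fm_pos, att)
  base <- prof[prof$scheme == "cer_base", ]
  share <- function(categ, ph) {
    sub <- base[base$phenotype == ph, ]
    sub$mean[sub$category == categ] / sum(sub$mean)
  }
  expect_gt(share("Cer[S]", "cpdm"), share("Cer[S]", "WT"))

  profn <- aggregate_profiles(fm_neg, att)
  bins <- profn[profn$scheme == "ffa_chain_bin", ]
  bshare <- function(categ, ph) {
    sub <- bins[bins$phenotype == ph, ]
    sub$mean[sub$category == categ] / sum(sub$mean)
  }
  expect_lt(bshare(">=26", "cpdm"), bshare(">=26", "WT"))
})

test_that("a matrix with only Cer[S] signal puts the whole base share there", {
  m <- small_methods()$positive
  tab <- generate_cohort(small_config(), seed = 1)
  tab <- tab[tab$polarity == "+", ]
  tab$intensity[!(tab$q3 == 264.1)] <- 1e-12
  fm <- ingest_cohort(tab, m)
  att <- attribute_method(m)
  prof <- aggregate_profiles(fm, att)
  base <- prof[prof$scheme == "cer_base", ]
  expect_true(all(base$category == "Cer[S]"))
  expect_equal(base$mean, rep(1, nrow(base)), tolerance = 1e-6)
})

test_that("sample order never changes any statistic", {
  cfg <- small_config()
  tab <- generate_cohort(cfg, seed = 23)
  fm1 <- ingest_cohort(tab, small_methods()$positive)
  set.seed(3)
  fm2 <- ingest_cohort(tab[sample(nrow(tab)), ], small_methods()$positive)
  expect_equal(holm_sidak_ttests(fm1), holm_sidak_ttests(fm2))
})
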