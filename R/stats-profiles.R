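## Univariate and multivariate statistics on the feature matrix: unpaired
## t-tests with Holm-Sidak step-down correction, volcano selection,
## autoscaled PCA, Ward hierarchical clustering, and the ceramide / free
## fatty acid aggregate profiles.

group_split_values <- function(fm, transition = NULL) {
  g <- fm$samples$group
  if (!all(c("WT", "cpdm") %in% g)) {
    stop("feature matrix must carry both WT and cpdm samples")
  }
  g
}

#' Holm-Sidak corrected unpaired t-tests per transition
#'
#' Two-sided unpaired t-tests (equal variance by default; Welch behind
#' `var_equal = FALSE`) of cpdm vs WT relative intensities, with the
#' Holm-Sidak step-down multiple-comparison procedure at family level
#' `alpha`: with p-values ordered ascending over m features, feature k is
#' significant iff `p_(j) <= 1 - (1 - alpha)^(1/(m - j + 1))` for every
#' j <= k.
#'
#' @param fm A `feature_matrix` with both groups present.
#' @param alpha Family-wise error level (default 0.05).
#' @param var_equal Pooled-variance t-test when `TRUE` (default).
#' @return `data.frame` with one row per transition: group means, cpdm/WT
#'   `fold_change`, `t`, `p` (raw), `significant` (Holm-Sidak flag) and
#'   `tested` (`FALSE` for zero-variance features, whose p is `NA`).
#' @export
holm_sidak_ttests <- function(fm, alpha = 0.05, var_equal = TRUE) {
  stopifnot(inherits(fm, "feature_matrix"))
  g <- group_split_values(fm)
  if (sum(g == "WT") < 2 || sum(g == "cpdm") < 2) {
    stop("need >= 2 samples per group")
  }
  x <- fm$values
  res <- data.frame(transition = colnames(x),
                    mean_wt = colMeans(x[g == "WT", , drop = FALSE]),
                    mean_cpdm = colMeans(x[g == "cpdm", , drop = FALSE]),
                    stringsAsFactors = FALSE)
  res$fold_change <- res$mean_cpdm / res$mean_wt
  stats_1 <- apply(x, 2, function(v) {
    if (stats::sd(v[g == "WT"]) == 0 && stats::sd(v[g == "cpdm"]) == 0) {
      return(c(NA_real_, NA_real_))
    }
    tt <- stats::t.test(v[g == "cpdm"], v[g == "WT"],
                        var.equal = var_equal)
    c(tt$statistic, tt$p.value)
  })
  res$t <- stats_1[1, ]
  res$p <- stats_1[2, ]
  res$tested <- !is.na(res$p)
  res$significant <- holm_sidak_flags(res$p, alpha)
  rownames(res) <- NULL
  res
}

#' Holm-Sidak step-down significance flags
#'
#' @param p Numeric vector of raw p-values (`NA` allowed; never significant).
#' @param alpha Family-wise error level.
#' @return Logical vector, `TRUE` where the step-down procedure rejects.
#' @export
holm_sidak_flags <- function(p, alpha = 0.05) {
  m <- sum(!is.na(p))
  out <- rep(FALSE, length(p))
  if (m == 0) return(out)
  ord <- order(p, na.last = NA)
  thresholds <- 1 - (1 - alpha)^(1 / (m - seq_len(m) + 1))
  pass <- p[ord] <= thresholds
  ## step-down: reject until the first failure
  k <- if (all(pass)) m else which(!pass)[1] - 1
  if (k > 0) out[ord[seq_len(k)]] <- TRUE
  out
}

#' Volcano selection of discriminant features
#'
#' Keeps features with raw p at most `p_max` and at least `min_fold`-fold
#' change in either direction.
#'
#' @param stats Output of [holm_sidak_ttests()].
#' @param p_max Raw p-value ceiling (default 0.05).
#' @param min_fold Fold-change floor (default 2): keep if
#'   `fold_change >= min_fold` or `<= 1/min_fold`.
#' @return The selected subset of `stats`.
#' @export
volcano_select <- function(stats, p_max = 0.05, min_fold = 2) {
  stopifnot(is.data.frame(stats), nrow(stats) > 0,
            all(c("p", "fold_change") %in% names(stats)))
  keep <- !is.na(stats$p) & stats$p <= p_max &
    (stats$fold_change >= min_fold | stats$fold_change <= 1 / min_fold)
  stats[keep, , drop = FALSE]
}

## per-feature mean-center and unit-variance scaling; constant features
## dropped with a warning
autoscale <- function(x) {
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping ", sum(sds == 0), " constant feature(s) before scaling")
    x <- x[, sds > 0, drop = FALSE]
  }
  scale(x)
}

#' Autoscaled principal component analysis
#'
#' PCA of the feature matrix after autoscaling (per-feature mean 0, SD 1).
#' Signs are fixed so the largest-magnitude loading of each component is
#' positive.
#'
#' @param fm A `feature_matrix` (>= 3 samples).
#' @return List with `scores`, `loadings` and `explained` (variance
#'   fractions, non-increasing, summing to 1).
#' @export
pca_autoscaled <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (nrow(fm$values) < 3) stop("PCA needs >= 3 samples")
  xs <- autoscale(fm$values)
  pc <- stats::prcomp(xs, center = FALSE, scale. = FALSE)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x, 2, flip, `*`)
  loadings <- sweep(pc$rotation, 2, flip, `*`)
  list(scores = scores, loadings = loadings,
       explained = pc$sdev^2 / sum(pc$sdev^2))
}

#' Hierarchical clustering for the heat map
#'
#' Agglomerative clustering (Euclidean distance, Ward linkage) of samples
#' and features on autoscaled values. Leaf order is deterministic for a
#' given input.
#'
#' @param fm A `feature_matrix` (>= 2 samples).
#' @return List with `sample_clust` and `feature_clust` (`hclust` objects),
#'   `sample_order`/`feature_order` (leaf orders as labels) and `scaled`
#'   (the autoscaled matrix).
#' @export
cluster_heatmap <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (nrow(fm$values) < 2) stop("clustering needs >= 2 samples")
  xs <- autoscale(fm$values)
  sc <- stats::hclust(stats::dist(xs), method = "ward.D2")
  fc <- stats::hclust(stats::dist(t(xs)), method = "ward.D2")
  list(sample_clust = sc, feature_clust = fc,
       sample_order = sc$labels[sc$order],
       feature_order = fc$labels[fc$order],
       scaled = xs)
}

ffa_chain_bin <- function(carbons) {
  ifelse(carbons >= 26, ">=26",
         ifelse(carbons >= 20, "20-24",
                ifelse(carbons >= 12, "12-18", "<12")))
}

## per-phenotype mean +- SE of per-sample sums over a feature subset
scheme_rows <- function(fm, scheme, members) {
  g <- fm$samples$group
  rows <- list()
  for (categ in names(members)) {
    cols <- members[[categ]]
    if (length(cols) == 0) next
    per_sample <- rowSums(fm$values[, cols, drop = FALSE])
    for (ph in c("WT", "cpdm")) {
      v <- per_sample[g == ph]
      rows[[length(rows) + 1]] <- data.frame(
        scheme = scheme, category = categ, phenotype = ph,
        mean = mean(v), se = stats::sd(v) / sqrt(length(v)),
        n_features = length(cols), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Aggregate ceramide and free fatty acid profiles
#'
#' Sums attributed-transition relative intensities into the profile schemes
#' used to compare phenotypes: ceramides by sphingoid base
#' (Cer[S]/Cer[DS]/Cer[P]), by N-acyl hydroxylation (A vs N, within base),
#' and by N-acyl chain length; free fatty acids by saturation class
#' (saturated / monounsaturated / polyunsaturated) and by chain-length bins
#' (12-18, 20-24, >= 26 carbons). Reported per phenotype as mean +- SE of
#' the per-sample summed relative amounts.
#'
#' @param fm A `feature_matrix`.
#' @param attributions Output of [attribute_method()] for the same method.
#' @return `data.frame` with columns `scheme`, `category`, `phenotype`,
#'   `mean`, `se`, `n_features`.
#' @export
aggregate_profiles <- function(fm, attributions) {
  stopifnot(inherits(fm, "feature_matrix"), is.data.frame(attributions))
  att <- attributions[attributions$status != "not_attributed" &
                      attributions$transition %in% colnames(fm$values), ,
                      drop = FALSE]
  out <- list()
  cer <- att[att$class_call %in% names(FRAGMENT_CLASS_BASES), , drop = FALSE]
  if (nrow(cer) > 0) {
    species <- lapply(cer$attribution, parse_lipid)
    base <- cer$class_call
    hydrox <- vapply(species, function(s) {
      if (s$chain$hydroxyls > 0) "A" else "N"
    }, "")
    chain_c <- vapply(species, function(s) s$chain$carbons, numeric(1))
    out$base <- scheme_rows(fm, "cer_base",
                            split(cer$transition, base))
    out$hydrox <- scheme_rows(fm, "cer_hydroxylation",
                              split(cer$transition, paste0(base, ":", hydrox)))
    out$chain <- scheme_rows(fm, "cer_chain_length",
                             split(cer$transition, chain_c))
  }
  ffa <- att[att$class_call == "FFA", , drop = FALSE]
  if (nrow(ffa) > 0) {
    species <- lapply(ffa$attribution, parse_lipid)
    db <- vapply(species, function(s) s$chain$double_bonds, numeric(1))
    sat <- ifelse(db == 0, "saturated",
                  ifelse(db == 1, "monounsaturated", "polyunsaturated"))
    carbons <- vapply(species, function(s) s$chain$carbons, numeric(1))
    out$sat <- scheme_rows(fm, "ffa_saturation",
                           split(ffa$transition, sat))
    out$bins <- scheme_rows(fm, "ffa_chain_bin",
                            split(ffa$transition, ffa_chain_bin(carbons)))
  }
  if (length(out) == 0) {
    warning("no attributed ceramide or FFA transitions; nothing to aggregate")
    return(data.frame())
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
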