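## Internal-standard LC-MS quantification (nmol per mg dry tissue),
## calibration-series linearity, and qPCR 2^-ddCt fold changes.

#' Internal-standard quantification of one measurement
#'
#' `concentration = (analyte area / IS area) * IS nmol / dry weight`, in
#' nmol per mg of dry tissue. Homogeneous of degree +1 in the analyte area
#' and degree -1 in the internal-standard area and the weight.
#'
#' @param area Analyte peak area (>= 0).
#' @param is_area Internal-standard peak area (> 0).
#' @param weight_mg Dry tissue weight in mg (> 0).
#' @param is_nmol Spiked internal-standard amount in nmol (default 0.5).
#' @return Concentration in nmol/mg.
#' @examples
#' quantify_sample(1e5, 1e5, 10) # 0.05
#' @export
quantify_sample <- function(area, is_area, weight_mg, is_nmol = 0.5) {
  if (any(area < 0)) stop("peak areas must be non-negative")
  if (any(is_area <= 0)) stop("internal-standard area must be positive")
  if (any(weight_mg <= 0)) stop("dry weight must be positive")
  (area / is_area) * is_nmol / weight_mg
}

#' Quantify a table of measurements
#'
#' @param quant `data.frame` with columns `sample_id`, `group`, `analyte`,
#'   `area`, `is_area`, `weight_mg` (e.g. from [generate_quant_table()]).
#' @inheritParams quantify_sample
#' @return The input with a `concentration` column (nmol/mg).
#' @export
quantify_table <- function(quant, is_nmol = 0.5) {
  need <- c("sample_id", "analyte", "area", "is_area", "weight_mg")
  stopifnot(is.data.frame(quant), all(need %in% names(quant)))
  quant$concentration <- quantify_sample(quant$area, quant$is_area,
                                         quant$weight_mg, is_nmol)
  quant
}

#' Fit a calibration series and judge linearity
#'
#' Ordinary least squares of intensity on concentration across the spiked
#' levels; the dynamic range is called `"linear"` when R^2 >= `r2_min`
#' over the full level span.
#'
#' @param series `data.frame` with columns `level_ppm` and `intensity`
#'   (e.g. from [generate_calibration()]).
#' @param r2_min Linearity cut-off on R^2 (default 0.99).
#' @return An object of class `calibration_fit`: list with `slope`,
#'   `intercept`, `r_squared`, `verdict`, `levels`, `span_orders`
#'   (log10 of the level span).
#' @export
fit_calibration <- function(series, r2_min = 0.99) {
  stopifnot(is.data.frame(series),
            all(c("level_ppm", "intensity") %in% names(series)))
  levels_ <- sort(unique(series$level_ppm))
  if (length(levels_) < 3) stop("calibration needs >= 3 distinct levels")
  fit <- stats::lm(intensity ~ level_ppm, data = series)
  ## direct R^2 (summary.lm warns on numerically perfect fits)
  r2 <- 1 - sum(stats::residuals(fit)^2) /
    sum((series$intensity - mean(series$intensity))^2)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 verdict = if (r2 >= r2_min) "linear" else "non-linear",
                 levels = levels_,
                 span_orders = log10(max(levels_) / min(levels_))),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat("<calibration ", x$verdict, ": R^2 ", format(x$r_squared, digits = 5),
      " over ", format(x$span_orders, digits = 3), " orders>\n", sep = "")
  invisible(x)
}

#' qPCR relative expression by 2^-ddCt
#'
#' Per gene: `dCt = Ct_gene - Ct_housekeeping` per sample,
#' `ddCt = mean dCt(cpdm) - mean dCt(WT)`, fold change `2^-ddCt`, with an
#' unpaired t-test on the per-sample dCt values.
#'
#' @param ct_table Long `data.frame` with columns `sample_id`, `group`,
#'   `gene`, `ct`, including the housekeeping gene rows.
#' @param housekeeping Housekeeping gene name (default `"Actb"`).
#' @return `data.frame` with one row per gene: `gene`, `ddct`,
#'   `fold_change`, `p`, and per-group mean dCt.
#' @examples
#' tab <- generate_qpcr_table(seed = 1)
#' ddct_fold_change(tab)
#' @export
ddct_fold_change <- function(ct_table, housekeeping = "Actb") {
  need <- c("sample_id", "group", "gene", "ct")
  stopifnot(is.data.frame(ct_table), all(need %in% names(ct_table)))
  hk <- ct_table[ct_table$gene == housekeeping, , drop = FALSE]
  if (nrow(hk) == 0) stop("housekeeping gene '", housekeeping, "' not found")
  hk_ct <- stats::setNames(hk$ct, hk$sample_id)
  genes <- setdiff(unique(ct_table$gene), housekeeping)
  rows <- lapply(genes, function(g) {
    sub <- ct_table[ct_table$gene == g, , drop = FALSE]
    if (!all(sub$sample_id %in% names(hk_ct))) {
      stop("housekeeping Ct missing for sample(s) of gene ", g)
    }
    dct <- sub$ct - hk_ct[sub$sample_id]
    wt <- dct[sub$group == "WT"]; cp <- dct[sub$group == "cpdm"]
    if (length(wt) == 0 || length(cp) == 0) {
      stop("both groups needed for gene ", g)
    }
    ddct <- mean(cp) - mean(wt)
    p <- if (length(wt) > 1 && length(cp) > 1 &&
             (stats::sd(wt) > 0 || stats::sd(cp) > 0)) {
      stats::t.test(cp, wt, var.equal = TRUE)$p.value
    } else NA_real_
    data.frame(gene = g, ddct = ddct, fold_change = 2^-ddct, p = p,
               mean_dct_wt = mean(wt), mean_dct_cpdm = mean(cp),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
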