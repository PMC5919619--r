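## Seeded synthetic inputs: two-group transition-intensity cohorts,
## flow-injection chronograms, calibration series, quantification and qPCR
## tables. The generator emulates the study design of the cpdm-vs-WT mouse
## epidermis screen: a testing set of 7 cpdm + 8 WT and a validation set of
## 10 cpdm + 11 WT, screened on the positive and negative methods.

## Evaluate `code` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  force(code)
}

## log-normal multiplicative noise with mean 1 and the given coefficient of
## variation
rlnorm_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Default wild-type baseline profile
#'
#' A deterministic relative-abundance profile over the transitions of a
#' method pair, emulating an epidermis-like lipid composition:
#' phosphatidylcholines and sphingomyelins dominate the positive method,
#' free fatty acids peak around palmitate/oleate with a secondary
#' ultra-long-chain bump at cerotic acid in the negative method. Each
#' method's baselines sum to 1.
#'
#' @param methods List with `positive` / `negative` `screening_method`s.
#' @return Named numeric vector keyed by transition id.
#' @export
default_baselines <- function(methods) {
  class_w <- c("PC" = 3, "SM" = 2.5, "CE" = 2, "Cer[S]" = 1.5,
               "Cer[P]" = 1.2, "Cer[DS]" = 0.15, "PE" = 1.2, "PS" = 0.7,
               "PI" = 0.7, "NL-oleate" = 0.5, "NL-arachidonate" = 0.5,
               "AC" = 0.5, "FFA" = 1, "unknown" = 0.5)
  out <- numeric(0)
  for (m in methods[!vapply(methods, is.null, logical(1))]) {
    tr <- m$transitions
    w <- class_w[tr$class_hint]
    w[is.na(w)] <- 0.5
    if (m$polarity == "-") {
      ## FFA SIM: bulk fatty acids around m/z 255 (16:0) / 281 (18:1), a
      ## cerotic-acid bump at m/z 395, and a low floor elsewhere
      w <- w * (3 * exp(-((tr$q1 - 255) / 40)^2) +
                1.5 * exp(-((tr$q1 - 395) / 18)^2) + 0.08)
    } else {
      ## mild decline with parent mass within each class
      w <- w * exp(-(tr$q1 - min(tr$q1)) / 1500)
    }
    out <- c(out, stats::setNames(w / sum(w), transition_id(tr)))
  }
  out
}

#' Cohort configuration
#'
#' Collects the study-design parameters of the synthetic two-group cohort.
#' The defaults are the conditions of the mouse epidermis study: a testing
#' set of 7 cpdm + 8 WT, a validation set of 10 cpdm + 11 WT, per-transition
#' cpdm/WT fold changes from the significant-feature table, within-group
#' coefficient of variation 0.2 and per-sample total-ion-current scale
#' factors with log-scale SD 0.3.
#'
#' Effects are expressed on the TIC-normalized (relative-abundance) scale:
#' the cpdm mean profile sets `baseline * effect` on the affected
#' transitions, then rescales the unaffected transitions by a common factor
#' so the profile still sums to 1. Fold changes of affected transitions are
#' therefore recoverable by construction.
#'
#' @param methods Screening-method pair (default the packaged
#'   reconstruction).
#' @param n_wt,n_cpdm Named vectors with `testing` and `validation` counts.
#' @param effects Named fold-change vector keyed by transition id.
#' @param baseline Named relative-abundance vector (default
#'   [default_baselines()]); each method must sum to 1.
#' @param cv Within-group coefficient of variation of per-transition
#'   intensities (fraction).
#' @param tic_scale_sd Log-scale SD of the per-sample, per-injection total
#'   intensity factor.
#' @param intensity_scale Arbitrary counts scale of the simulated detector.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(methods = reference_screening_methods(),
                          n_wt = c(testing = 8, validation = 11),
                          n_cpdm = c(testing = 7, validation = 10),
                          effects = reference_effects(),
                          baseline = NULL,
                          cv = 0.2, tic_scale_sd = 0.3,
                          intensity_scale = 1e6) {
  if (is.null(baseline)) baseline <- default_baselines(methods)
  stopifnot(all(c("testing", "validation") %in% names(n_wt)),
            all(c("testing", "validation") %in% names(n_cpdm)))
  if (any(c(n_wt, n_cpdm) < 2)) stop("need >= 2 samples per group and split")
  if (cv <= 0) stop("cv must be positive")
  if (any(baseline <= 0)) stop("baselines must be positive")
  if (any(effects <= 0)) stop("effects must be positive fold changes")
  all_ids <- unlist(lapply(methods[!vapply(methods, is.null, logical(1))],
                           function(m) transition_id(m$transitions)))
  orphan <- setdiff(names(effects), all_ids)
  if (length(orphan) > 0) {
    stop("effects reference unknown transitions: ",
         paste(utils::head(orphan, 5), collapse = ", "))
  }
  missing_b <- setdiff(all_ids, names(baseline))
  if (length(missing_b) > 0) {
    stop("baseline lacks transitions: ",
         paste(utils::head(missing_b, 5), collapse = ", "))
  }
  structure(list(methods = methods, n_wt = n_wt, n_cpdm = n_cpdm,
                 effects = effects, baseline = baseline, cv = cv,
                 tic_scale_sd = tic_scale_sd,
                 intensity_scale = intensity_scale),
            class = "cohort_config")
}

## expected relative-abundance profiles per group for one method
expected_profiles <- function(config, method) {
  ids <- transition_id(method$transitions)
  b <- config$baseline[ids]
  b <- b / sum(b)
  fc <- rep(1, length(ids))
  names(fc) <- ids
  known <- intersect(names(config$effects), ids)
  fc[known] <- config$effects[known]
  aff <- fc != 1
  p_c <- b
  if (any(aff)) {
    mass_aff <- sum(b[aff] * fc[aff])
    if (mass_aff >= 1) {
      stop("affected transitions exceed the total relative abundance; ",
           "reduce baselines or fold changes")
    }
    comp <- (1 - mass_aff) / (1 - sum(b[aff]))
    p_c[aff] <- b[aff] * fc[aff]
    p_c[!aff] <- b[!aff] * comp
  }
  list(WT = b, cpdm = p_c)
}

#' Generate a synthetic two-group cohort
#'
#' Draws per-sample, per-transition raw intensities
#' `raw = TIC * profile * epsilon * scale`, with `profile` the group's
#' expected relative-abundance vector, `epsilon` log-normal noise of mean 1
#' and CV `config$cv`, and `TIC` a per-sample, per-method log-normal factor.
#' Seeded runs are bit-reproducible.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return A long `data.frame` (the tabular acquisition dialect) with columns
#'   `sample_id`, `group`, `split`, `q1`, `q3`, `polarity`, `intensity`.
#' @examples
#' cfg <- cohort_config()
#' tab <- generate_cohort(cfg, seed = 1)
#' @export
generate_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  samples <- do.call(rbind, lapply(c("testing", "validation"), function(sp) {
    rbind(
      data.frame(group = "WT", split = sp,
                 idx = seq_len(config$n_wt[[sp]])),
      data.frame(group = "cpdm", split = sp,
                 idx = seq_len(config$n_cpdm[[sp]])))
  }))
  samples$sample_id <- sprintf("%s_%s_%02d",
                               ifelse(samples$split == "testing", "T", "V"),
                               samples$group, samples$idx)
  with_seed(seed, {
    out <- list()
    for (m in config$methods[!vapply(config$methods, is.null, logical(1))]) {
      prof <- expected_profiles(config, m)
      tr <- m$transitions
      p <- nrow(tr)
      for (i in seq_len(nrow(samples))) {
        tic <- rlnorm_cv(1, sqrt(exp(config$tic_scale_sd^2) - 1))
        eps <- rlnorm_cv(p, config$cv)
        raw <- config$intensity_scale * tic *
          prof[[samples$group[i]]] * eps
        out[[length(out) + 1]] <- data.frame(
          sample_id = samples$sample_id[i], group = samples$group[i],
          split = samples$split[i], q1 = tr$q1, q3 = tr$q3,
          polarity = tr$polarity, intensity = unname(raw),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  })
}

#' Render flow-injection chronograms
#'
#' Expands a raw intensity table into per-transition chronograms over the
#' 2-min acquisition window: one Gaussian injection peak per transition whose
#' trapezoidal integral equals the tabulated intensity (quadrature error
#' below 0.1%).
#'
#' @param table Raw intensity table from [generate_cohort()].
#' @param method The `screening_method` whose transitions to render.
#' @param peak_center,peak_sd Injection peak position and width in minutes.
#' @param time_step Sampling interval in minutes.
#' @return Long `data.frame` with columns `sample_id`, `group`, `split`,
#'   `q1`, `q3`, `polarity`, `time`, `intensity`.
#' @export
render_chronograms <- function(table, method, peak_center = 0.6,
                               peak_sd = 0.12, time_step = 0.01) {
  stopifnot(inherits(method, "screening_method"))
  tab <- table[table$polarity == method$polarity, , drop = FALSE]
  ids <- transition_id(tab)
  mids <- transition_id(method$transitions)
  if (!all(ids %in% mids)) {
    stop("table carries transitions outside the method: ",
         paste(utils::head(setdiff(ids, mids), 5), collapse = ", "))
  }
  times <- seq(0, method$acquisition_time, by = time_step)
  shape <- stats::dnorm(times, peak_center, peak_sd)
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    data.frame(sample_id = tab$sample_id[i], group = tab$group[i],
               split = tab$split[i], q1 = tab$q1[i], q3 = tab$q3[i],
               polarity = tab$polarity[i], time = times,
               intensity = tab$intensity[i] * shape,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Generate a spiked calibration series
#'
#' Emulates the lipid-standard dilution series used to establish assay
#' linearity: five concentration levels spanning 1 to 10,000 ppm with three
#' replicate injections each (15 points).
#'
#' @param levels Concentration levels in ppm.
#' @param replicates Replicate injections per level.
#' @param response_slope Counts per ppm.
#' @param noise_cv Multiplicative noise CV (fraction).
#' @param seed Integer seed.
#' @return `data.frame` with columns `level_ppm`, `replicate`, `intensity`.
#' @export
generate_calibration <- function(levels = c(1, 10, 100, 1000, 10000),
                                 replicates = 3, response_slope = 1000,
                                 noise_cv = 0.05, seed = NULL) {
  if (any(levels <= 0)) stop("calibration levels must be positive")
  with_seed(seed, {
    df <- expand.grid(replicate = seq_len(replicates), level_ppm = levels)
    df <- df[, c("level_ppm", "replicate")]
    noise <- if (noise_cv > 0) rlnorm_cv(nrow(df), noise_cv) else 1
    df$intensity <- response_slope * df$level_ppm * noise
    rownames(df) <- NULL
    df
  })
}

#' Generate synthetic quantification and qPCR tables
#'
#' @param n_wt,n_cpdm Samples per group.
#' @param analytes Named list: per analyte, a length-2 numeric
#'   `c(WT = , cpdm = )` of true concentrations in nmol/mg.
#' @param is_nmol Spiked internal-standard amount (nmol).
#' @param weight_mg Mean dry tissue weight (mg).
#' @param noise_cv Multiplicative CV on peak areas.
#' @param seed Integer seed.
#' @return `data.frame` with columns `sample_id`, `group`, `analyte`,
#'   `area`, `is_area`, `weight_mg`.
#' @export
generate_quant_table <- function(n_wt = 11, n_cpdm = 10,
                                 analytes = list(
                                   "666.3/264.1" = c(WT = 0.02, cpdm = 0.37),
                                   "554.3/264.1" = c(WT = 0.05, cpdm = 0.26),
                                   "538.3/264.1" = c(WT = 0.08, cpdm = 0.39)),
                                 is_nmol = 0.5, weight_mg = 10,
                                 noise_cv = 0.2, seed = NULL) {
  with_seed(seed, {
    samples <- data.frame(
      sample_id = c(sprintf("WT_%02d", seq_len(n_wt)),
                    sprintf("cpdm_%02d", seq_len(n_cpdm))),
      group = rep(c("WT", "cpdm"), c(n_wt, n_cpdm)),
      stringsAsFactors = FALSE)
    rows <- lapply(names(analytes), function(a) {
      conc <- analytes[[a]][samples$group] *
        rlnorm_cv(nrow(samples), noise_cv)
      w <- rep(weight_mg, nrow(samples))
      is_area <- 1e5 * rlnorm_cv(nrow(samples), noise_cv / 2)
      ## areas consistent with conc = (area / is_area) * is_nmol / weight
      data.frame(sample_id = samples$sample_id, group = samples$group,
                 analyte = a, area = conc * w * is_area / is_nmol,
                 is_area = is_area, weight_mg = w,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' @rdname generate_quant_table
#' @param genes Genes assayed against the *Actb* housekeeping gene.
#' @param expression_ratio Named true cpdm/WT expression ratios (genes absent
#'   from the map default to 1).
#' @param mean_ct Baseline target-gene Ct in WT.
#' @param actb_ct Housekeeping Ct.
#' @param sd_ct Per-well Ct standard deviation.
#' @return For `generate_qpcr_table()`: long `data.frame` with columns
#'   `sample_id`, `group`, `gene`, `ct` (housekeeping rows included).
#' @export
generate_qpcr_table <- function(n_wt = 8, n_cpdm = 8,
                                genes = c("Gba", "Pde12", "Fasn", "Elovl1"),
                                expression_ratio = c(Fasn = 0.5),
                                mean_ct = 24, actb_ct = 17, sd_ct = 0.3,
                                seed = NULL) {
  with_seed(seed, {
    samples <- data.frame(
      sample_id = c(sprintf("WT_%02d", seq_len(n_wt)),
                    sprintf("cpdm_%02d", seq_len(n_cpdm))),
      group = rep(c("WT", "cpdm"), c(n_wt, n_cpdm)),
      stringsAsFactors = FALSE)
    rows <- list(data.frame(sample_id = samples$sample_id,
                            group = samples$group, gene = "Actb",
                            ct = stats::rnorm(nrow(samples), actb_ct, sd_ct),
                            stringsAsFactors = FALSE))
    for (g in genes) {
      ratio <- if (g %in% names(expression_ratio)) expression_ratio[[g]]
               else 1
      ## halving expression raises Ct by one cycle
      shift <- ifelse(samples$group == "cpdm", -log2(ratio), 0)
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = samples$sample_id, group = samples$group, gene = g,
        ct = stats::rnorm(nrow(samples), mean_ct + shift, sd_ct),
        stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
}
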