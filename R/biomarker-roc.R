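## Univariate ROC/AUC and multivariate panel models (PLS-DA, optional random
## forest) trained on the testing split with blind prediction of the
## validation split.

POSITIVE_CLASS <- "cpdm"

#' Univariate ROC analysis of one feature
#'
#' AUC by the Mann-Whitney rank statistic (midranks for ties), oriented so
#' AUC >= 0.5; the optimal threshold maximizes the Youden index, placed at
#' the midpoint between the adjacent observed values.
#'
#' @param values Numeric feature vector.
#' @param labels Class labels (must contain both classes).
#' @param positive Label of the positive class (default `"cpdm"`).
#' @return An object of class `roc_result`: list with `auc`, `direction`
#'   (`">"` when the positive class has larger values), `threshold`,
#'   `sensitivity` and `specificity` at the threshold.
#' @export
univariate_roc <- function(values, labels, positive = POSITIVE_CLASS) {
  stopifnot(length(values) == length(labels))
  is_pos <- labels == positive
  n1 <- sum(is_pos); n2 <- sum(!is_pos)
  if (n1 == 0 || n2 == 0) stop("both classes must be present")
  r <- rank(values)
  auc <- (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n2)
  direction <- if (auc >= 0.5) ">" else "<"
  score <- if (direction == ">") values else -values
  auc <- max(auc, 1 - auc)
  ## Youden-optimal cut over midpoints between adjacent distinct scores
  s <- sort(unique(score))
  cuts <- if (length(s) > 1) (utils::head(s, -1) + utils::tail(s, -1)) / 2
          else s
  youden <- vapply(cuts, function(ct) {
    sens <- mean(score[is_pos] > ct)
    spec <- mean(score[!is_pos] <= ct)
    sens + spec - 1
  }, numeric(1))
  best <- cuts[which.max(youden)]
  thr <- if (direction == ">") best else -best
  structure(list(auc = auc, direction = direction, threshold = thr,
                 sensitivity = mean(score[is_pos] > best),
                 specificity = mean(score[!is_pos] <= best),
                 n_positive = n1, n_negative = n2),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("<ROC auc ", format(x$auc, digits = 4), ", threshold ",
      format(x$threshold, digits = 4), " (", x$direction, ")>\n", sep = "")
  invisible(x)
}

#' Trapezoidal ROC AUC
#'
#' The area under the empirical ROC curve by the trapezoidal rule; equals
#' the rank-statistic AUC of [univariate_roc()] on every input (internal
#' cross-check, both exported).
#'
#' @inheritParams univariate_roc
#' @return AUC in `[0, 1]` (oriented so that it is >= 0.5).
#' @export
trapezoid_auc <- function(values, labels, positive = POSITIVE_CLASS) {
  is_pos <- labels == positive
  n1 <- sum(is_pos); n2 <- sum(!is_pos)
  if (n1 == 0 || n2 == 0) stop("both classes must be present")
  cuts <- c(Inf, sort(unique(values), decreasing = TRUE), -Inf)
  sens <- vapply(cuts, function(ct) mean(values[is_pos] >= ct), numeric(1))
  fpr <- vapply(cuts, function(ct) mean(values[!is_pos] >= ct), numeric(1))
  auc <- sum(diff(fpr) * (utils::head(sens, -1) + utils::tail(sens, -1)) / 2)
  max(auc, 1 - auc)
}

plsda_probability <- function(model, newdata, ncomp) {
  pr <- stats::predict(model, newdata)$predict
  ## predicted dummy response for the positive class, truncated to [0, 1]
  p <- pr[, POSITIVE_CLASS, min(ncomp, dim(pr)[3])]
  pmin(pmax(p, 0), 1)
}

fit_panel_model <- function(x, y, algorithm, ncomp, n_tree) {
  if (algorithm == "plsda") {
    mixOmics::plsda(x, factor(y, levels = c("WT", POSITIVE_CLASS)),
                    ncomp = min(ncomp, ncol(x)))
  } else {
    if (!requireNamespace("randomForest", quietly = TRUE)) {
      stop("algorithm 'rf' needs the randomForest package")
    }
    randomForest::randomForest(
      x, factor(y, levels = c("WT", POSITIVE_CLASS)), ntree = n_tree)
  }
}

panel_probability <- function(fit, x, algorithm, ncomp) {
  if (algorithm == "plsda") {
    plsda_probability(fit, x, ncomp)
  } else {
    stats::predict(fit, x, type = "prob")[, POSITIVE_CLASS]
  }
}

#' Fit a multivariate biomarker panel on the testing split
#'
#' Trains a PLS-DA (default) or random-forest classifier on the
#' testing-split samples of the feature matrix, restricted to the panel
#' features, and estimates out-of-sample performance by repeated stratified
#' Monte-Carlo cross-validation (default 2/3 train fraction, 100 repeats).
#'
#' @param fm A `feature_matrix` containing a labeled testing split.
#' @param panel Character vector of transition ids (must all be present).
#' @param algorithm `"plsda"` or `"rf"`.
#' @param ncomp Latent components for PLS-DA (default 2).
#' @param cv_repeats,cv_train_fraction Monte-Carlo CV scheme.
#' @param n_tree Trees for the random forest (default 500).
#' @param seed Integer seed for the CV folds (and forest).
#' @return An object of class `panel_model`: list with the fitted model,
#'   `panel`, `algorithm`, `cv_auc` and `cv_accuracy` (means over repeats),
#'   `training_ids` and `cv_config`.
#' @export
fit_panel <- function(fm, panel, algorithm = c("plsda", "rf"), ncomp = 2,
                      cv_repeats = 100, cv_train_fraction = 2 / 3,
                      n_tree = 500, seed = 1) {
  algorithm <- match.arg(algorithm)
  stopifnot(inherits(fm, "feature_matrix"))
  missing_f <- setdiff(panel, colnames(fm$values))
  if (length(missing_f) > 0) {
    stop("panel features absent from the matrix: ",
         paste(missing_f, collapse = ", "))
  }
  train <- subset_samples(fm, split = "testing")
  y <- train$samples$group
  if (length(unique(y)) < 2) stop("testing split must carry both classes")
  x <- train$values[, panel, drop = FALSE]
  cv_auc <- cv_acc <- numeric(cv_repeats)
  with_seed(seed, {
    for (r in seq_len(cv_repeats)) {
      tr_idx <- unlist(lapply(split(seq_along(y), y), function(idx) {
        sample(idx, max(2, round(cv_train_fraction * length(idx))))
      }))
      te_idx <- setdiff(seq_along(y), tr_idx)
      if (length(te_idx) == 0 || length(unique(y[te_idx])) < 2) {
        cv_auc[r] <- NA; cv_acc[r] <- NA
        next
      }
      fit_r <- fit_panel_model(x[tr_idx, , drop = FALSE], y[tr_idx],
                               algorithm, ncomp, n_tree)
      p <- panel_probability(fit_r, x[te_idx, , drop = FALSE], algorithm,
                             ncomp)
      cv_auc[r] <- univariate_roc(p, y[te_idx])$auc
      cv_acc[r] <- mean((p > 0.5) == (y[te_idx] == POSITIVE_CLASS))
    }
    fit <- fit_panel_model(x, y, algorithm, ncomp, n_tree)
    structure(list(fit = fit, panel = panel, algorithm = algorithm,
                   ncomp = ncomp,
                   cv_auc = mean(cv_auc, na.rm = TRUE),
                   cv_accuracy = mean(cv_acc, na.rm = TRUE),
                   training_ids = train$samples$sample_id,
                   cv_config = list(scheme = "stratified MCCV",
                                    repeats = cv_repeats,
                                    train_fraction = cv_train_fraction,
                                    seed = seed)),
              class = "panel_model")
  })
}

#' @export
print.panel_model <- function(x, ...) {
  cat("<", x$algorithm, " panel of ", length(x$panel), " features; CV AUC ",
      format(x$cv_auc, digits = 4), ", CV accuracy ",
      format(x$cv_accuracy, digits = 4), ">\n", sep = "")
  invisible(x)
}

#' Predict the validation split with a fitted panel
#'
#' Scores unseen samples with a [fit_panel()] model: per-sample class
#' probability, hard call at probability 0.5, and accuracy when true labels
#' are available. Refuses to score samples that were part of training (split
#' leakage) or matrices lacking a panel feature.
#'
#' @param model A `panel_model`.
#' @param fm A `feature_matrix`; by default its validation split is scored.
#' @param split Split label to score (default `"validation"`).
#' @return `data.frame` with `sample_id`, `probability` (of cpdm),
#'   `predicted`, `truth` and attribute `accuracy` (also returned in the
#'   `"accuracy"` attribute; `NA` without labels).
#' @export
predict_validation <- function(model, fm, split = "validation") {
  stopifnot(inherits(model, "panel_model"), inherits(fm, "feature_matrix"))
  missing_f <- setdiff(model$panel, colnames(fm$values))
  if (length(missing_f) > 0) {
    stop("matrix lacks panel feature(s): ",
         paste(missing_f, collapse = ", "))
  }
  new <- subset_samples(fm, split = split)
  leaked <- intersect(new$samples$sample_id, model$training_ids)
  if (length(leaked) > 0) {
    stop("validation samples were seen in training: ",
         paste(leaked, collapse = ", "))
  }
  if (nrow(new$values) == 0) {
    out <- data.frame(sample_id = character(0), probability = numeric(0),
                      predicted = character(0), truth = character(0),
                      stringsAsFactors = FALSE)
    attr(out, "accuracy") <- NA_real_
    return(out)
  }
  p <- panel_probability(model$fit, new$values[, model$panel, drop = FALSE],
                         model$algorithm, model$ncomp)
  out <- data.frame(sample_id = new$samples$sample_id,
                    probability = unname(p),
                    predicted = ifelse(p > 0.5, POSITIVE_CLASS, "WT"),
                    truth = new$samples$group, stringsAsFactors = FALSE)
  known <- out$truth %in% c("WT", POSITIVE_CLASS)
  attr(out, "accuracy") <- if (any(known)) {
    mean(out$predicted[known] == out$truth[known])
  } else NA_real_
  out
}

#' The three-ceramide and three-FFA biomarker panels
#'
#' Transition ids of the two headline panels: the sphingosine ceramides
#' CerAS(d18:1/24:0)2OH, CerAS(d18:1/16:0)2OH and CerNS(d18:1/16:0)
#' (666.35/554.2/538.3 -> 264.1), and the free fatty acids
#' 16-hydroxy-palmitate, cerotic acid and docosahexaenoic acid.
#'
#' @param which `"ceramide"` or `"ffa"`.
#' @return Character vector of transition ids.
#' @export
biomarker_panel <- function(which = c("ceramide", "ffa")) {
  which <- match.arg(which)
  if (which == "ceramide") {
    c("666.35/264.1+", "554.2/264.1+", "538.3/264.1+")
  } else {
    dha <- round(precursor_mz(lipid_species("FFA", acyl_chain(22, 6)),
                              "[M-H]-")$mz, 1)
    c("271.3/271.3-", "395.4/395.4-", paste0(dha, "/", dha, "-"))
  }
}
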