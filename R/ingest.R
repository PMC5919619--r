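## Acquisition reading, per-transition integration, TIC normalization and
## feature-matrix assembly. Two tabular dialects are supported: per-transition
## scalar intensities (columns sample_id, group, split, q1, q3, polarity,
## intensity) and chronograms (same keys plus time), which are integrated by
## the trapezoidal rule over the acquisition window.

trapezoid <- function(x, y) {
  if (length(x) < 2) return(0)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

## Match acquired (q1, q3) pairs to method transitions within +-0.5 on both.
match_transitions <- function(acquired, method, tolerance = 0.5) {
  tr <- method$transitions
  mids <- transition_id(tr)
  idx <- vapply(seq_len(nrow(acquired)), function(i) {
    hit <- which(abs(tr$q1 - acquired$q1[i]) <= tolerance &
                 abs(tr$q3 - acquired$q3[i]) <= tolerance)
    if (length(hit) == 0) return(NA_integer_)
    hit[which.min(abs(tr$q1[hit] - acquired$q1[i]) +
                  abs(tr$q3[hit] - acquired$q3[i]))]
  }, integer(1))
  if (anyNA(idx)) {
    orphans <- unique(transition_id(acquired[is.na(idx), , drop = FALSE]))
    stop("acquired transitions not in the method: ",
         paste(utils::head(orphans, 10), collapse = ", "))
  }
  mids[idx]
}

#' Read an acquisition into per-transition intensities
#'
#' @param x A file path or `data.frame` in one of the tabular dialects.
#' @param method The `screening_method` the acquisition was run with;
#'   acquired transitions must match a method transition within 0.5 m/z on
#'   both Q1 and Q3.
#' @param format `"csv"` (scalar intensities) or `"chronogram"`
#'   (time-resolved traces, integrated by the trapezoidal rule).
#' @param tolerance m/z matching window (Da).
#' @return `data.frame` with columns `sample_id`, `group`, `split`,
#'   `transition` (method transition id), `intensity`.
#' @export
read_acquisition <- function(x, method, format = c("csv", "chronogram"),
                             tolerance = 0.5) {
  format <- match.arg(format)
  stopifnot(inherits(method, "screening_method"))
  if (is.character(x)) {
    if (!file.exists(x)) stop("acquisition file not found: ", x)
    x <- utils::read.csv(x, stringsAsFactors = FALSE)
  }
  need <- c("sample_id", "q1", "q3", "polarity", "intensity",
            if (format == "chronogram") "time")
  if (!is.data.frame(x) || !all(need %in% names(x))) {
    stop("malformed acquisition: need columns ",
         paste(need, collapse = ", "))
  }
  if (!"group" %in% names(x)) x$group <- "unknown"
  if (!"split" %in% names(x)) x$split <- "unknown"
  x <- x[x$polarity == method$polarity, , drop = FALSE]
  if (nrow(x) == 0) stop("acquisition has no rows in method polarity")
  if (format == "chronogram") {
    key <- paste(x$sample_id, x$q1, x$q3)
    parts <- split(x, key)
    x <- do.call(rbind, lapply(parts, function(d) {
      d <- d[order(d$time), , drop = FALSE]
      out <- d[1, c("sample_id", "group", "split", "q1", "q3", "polarity")]
      out$intensity <- trapezoid(d$time, d$intensity)
      out
    }))
    rownames(x) <- NULL
  }
  x$transition <- match_transitions(x, method, tolerance)
  x[, c("sample_id", "group", "split", "transition", "intensity")]
}

#' Total-ion-current normalization
#'
#' Divides each transition's intensity by the summed intensity of all
#' monitored transitions of the method for that sample, yielding relative
#' amounts that sum to 1.
#'
#' @param raw Numeric vector of non-negative per-transition intensities.
#' @return Numeric vector summing to 1.
#' @examples
#' tic_normalize(c(2, 3, 5)) # 0.2 0.3 0.5
#' @export
tic_normalize <- function(raw) {
  if (!is.numeric(raw) || length(raw) == 0) stop("raw must be numeric")
  if (any(raw < 0)) stop("negative intensities")
  total <- sum(raw)
  if (total <= 0) stop("all-zero sample cannot be TIC-normalized")
  raw / total
}

#' Assemble the labeled feature matrix
#'
#' Pivots per-transition intensities to a dense samples-by-transitions matrix
#' and TIC-normalizes each row. Screening is targeted, so a transition
#' missing for any sample is an error, as are duplicate sample/transition
#' pairs. Row order is the deterministic sample-id sort.
#'
#' @param acq Output of [read_acquisition()].
#' @param method The `screening_method` the acquisition belongs to.
#' @return An object of class `feature_matrix`: list with `values` (matrix of
#'   relative intensities), `samples` (`data.frame` with `sample_id`,
#'   `group`, `split`), `transitions` (the method transition table) and
#'   `polarity`.
#' @export
assemble_matrix <- function(acq, method) {
  stopifnot(is.data.frame(acq),
            all(c("sample_id", "transition", "intensity") %in% names(acq)))
  mids <- transition_id(method$transitions)
  key <- paste(acq$sample_id, acq$transition)
  if (anyDuplicated(key)) {
    stop("duplicate sample/transition pairs: ",
         paste(utils::head(unique(key[duplicated(key)]), 3), collapse = "; "))
  }
  sample_ids <- sort(unique(acq$sample_id))
  values <- matrix(NA_real_, length(sample_ids), length(mids),
                   dimnames = list(sample_ids, mids))
  values[cbind(match(acq$sample_id, sample_ids),
               match(acq$transition, mids))] <- acq$intensity
  if (anyNA(values)) {
    holes <- which(is.na(values), arr.ind = TRUE)
    stop("missing transitions for sample(s): ",
         paste(utils::head(unique(sample_ids[holes[, 1]]), 5),
               collapse = ", "))
  }
  values <- t(apply(values, 1, tic_normalize))
  meta <- acq[!duplicated(acq$sample_id),
              c("sample_id", "group", "split"), drop = FALSE]
  meta <- meta[match(sample_ids, meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(values = values, samples = meta,
                 transitions = method$transitions,
                 polarity = method$polarity),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature matrix [", x$polarity, "] ", nrow(x$values), " samples x ",
      ncol(x$values), " transitions>\n", sep = "")
  invisible(x)
}

#' @rdname assemble_matrix
#' @param x A raw table (e.g. from [generate_cohort()]), file path, or
#'   chronogram table.
#' @param format Acquisition dialect, as in [read_acquisition()].
#' @export
ingest_cohort <- function(x, method, format = c("csv", "chronogram")) {
  assemble_matrix(read_acquisition(x, method, format), method)
}

#' Subset a feature matrix by split or group
#'
#' @param fm A `feature_matrix`.
#' @param split,group Values to keep (default: keep all).
#' @return A `feature_matrix`.
#' @export
subset_samples <- function(fm, split = NULL, group = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  keep <- rep(TRUE, nrow(fm$samples))
  if (!is.null(split)) keep <- keep & fm$samples$split %in% split
  if (!is.null(group)) keep <- keep & fm$samples$group %in% group
  fm$values <- fm$values[keep, , drop = FALSE]
  fm$samples <- fm$samples[keep, , drop = FALSE]
  rownames(fm$samples) <- NULL
  fm
}
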