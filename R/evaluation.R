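#' Trimmed mean of per-field counts
#'
#' Removes exactly one occurrence of the maximum and one of the minimum and
#' averages the remaining fields — the standard guard against an outlier
#' field dominating a 10-field manual count.
#'
#' @param counts numeric vector of field counts, length >= 3.
#' @return mean count per field after trimming.
#' @export
trimmed_field_mean <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) < 3L) stop("need at least 3 field counts to trim")
  if (anyNA(counts)) stop("field counts contain NA")
  drop_min <- which.min(counts)
  rest <- counts[-drop_min]
  drop_max <- which.max(rest)
  mean(rest[-drop_max])
}

#' Convert a mean field count to a cell density
#'
#' @param mean_count mean positive cells per high-power field (>= 0).
#' @param hpf_area_mm2 field area in mm^2; 0.2595 is the conventional 400x
#'   high-power field.
#' @return density in cells/mm^2.
#' @export
density_per_mm2 <- function(mean_count, hpf_area_mm2 = 0.2595) {
  if (hpf_area_mm2 <= 0) stop("hpf_area_mm2 must be positive")
  if (any(mean_count < 0)) stop("mean_count must be non-negative")
  mean_count / hpf_area_mm2
}

#' Composite IHC immune score and median dichotomization
#'
#' For each case and marker: trimmed mean field count, converted to a
#' density (cells/mm^2), Z-scored across the cohort (sample SD, n-1);
#' the composite score is the mean of the four marker Z-scores and cases
#' are labelled `high` iff their composite strictly exceeds the cohort
#' median (ties go to `low`). A marker with zero SD across the cohort
#' carries no information; its Z is set to 0 with a warning.
#'
#' @param panels long data.frame with columns `case_id`, `marker`,
#'   `field_index`, `count` (extra columns such as `group` pass through);
#'   every case must have all four markers CD3, CD8, CD20, CD68.
#' @param hpf_area_mm2 high-power-field area, mm^2.
#' @param markers required marker set.
#' @return data.frame with one row per case: `case_id`, per-marker densities
#'   (`density_<marker>`), per-marker Z-scores (`z_<marker>`), `composite`,
#'   and `ihc_label` (`"high"`/`"low"`); pass-through columns retained.
#' @export
composite_ihc_scores <- function(panels, hpf_area_mm2 = 0.2595,
                                 markers = c("CD3", "CD8", "CD20", "CD68")) {
  stopifnot(all(c("case_id", "marker", "count") %in% names(panels)))
  cases <- unique(panels$case_id)
  if (length(cases) < 2L) stop("need at least 2 cases for cohort Z-scores")
  dens <- matrix(NA_real_, length(cases), length(markers),
                 dimnames = list(cases, markers))
  for (ci in seq_along(cases)) {
    for (mk in markers) {
      counts <- panels$count[panels$case_id == cases[ci] & panels$marker == mk]
      if (length(counts) == 0L) {
        stop("case ", cases[ci], " is missing marker ", mk)
      }
      dens[ci, mk] <- density_per_mm2(trimmed_field_mean(counts), hpf_area_mm2)
    }
  }
  z <- dens
  for (mk in markers) {
    s <- stats::sd(dens[, mk])
    if (is.na(s) || s == 0) {
      warning("marker ", mk, " has zero SD across the cohort; Z set to 0")
      z[, mk] <- 0
    } else {
      z[, mk] <- (dens[, mk] - mean(dens[, mk])) / s
    }
  }
  composite <- rowMeans(z)
  med <- stats::median(composite)
  out <- data.frame(case_id = cases, row.names = NULL)
  for (mk in markers) out[[paste0("density_", mk)]] <- dens[, mk]
  for (mk in markers) out[[paste0("z_", mk)]] <- z[, mk]
  out$composite <- composite
  out$ihc_label <- ifelse(composite > med, "high", "low")
  extra <- setdiff(names(panels), c("marker", "field_index", "count"))
  extra <- setdiff(extra, "case_id")
  for (col in extra) {
    out[[col]] <- panels[[col]][match(out$case_id, panels$case_id)]
  }
  out
}

#' Confusion matrix with high-immunity as the positive class
#'
#' @param predicted,reference label vectors of equal length and matching
#'   case order; the positive class is the `positive` label (default
#'   `"Immunity_H"`), everything else must equal `negative`.
#' @param positive,negative the two admissible labels.
#' @return object of class `confusion_matrix` with fields `tp`, `fp`, `fn`,
#'   `tn`.
#' @export
confusion_matrix <- function(predicted, reference,
                             positive = "Immunity_H",
                             negative = "Immunity_L") {
  if (length(predicted) != length(reference)) {
    stop("predicted and reference have different lengths")
  }
  vocab <- c(positive, negative)
  bad <- unique(c(predicted, reference)[!c(predicted, reference) %in% vocab])
  if (length(bad) > 0L) {
    stop("labels outside {", positive, ", ", negative, "}: ",
         paste(bad, collapse = ", "))
  }
  p <- predicted == positive; r <- reference == positive
  new_confusion_matrix(sum(p & r), sum(p & !r), sum(!p & r), sum(!p & !r))
}

#' Construct a confusion matrix from its four cells
#'
#' @param tp,fp,fn,tn non-negative integer cell counts.
#' @return object of class `confusion_matrix`.
#' @export
new_confusion_matrix <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("confusion-matrix cells must be non-negative integers")
  }
  structure(as.list(cells), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(c("pred High", "pred Low"),
                              c("ref High", "ref Low")))
  print(m)
  invisible(x)
}

#' Wilson score interval for a binomial proportion
#'
#' @param successes,n counts with `0 <= successes <= n`, `n > 0`.
#' @param conf confidence level (default 0.95, z = 1.959964).
#' @return named numeric `c(lower, upper)`, both in \[0, 1\].
#' @export
wilson_ci <- function(successes, n, conf = 0.95) {
  if (n <= 0 || successes < 0 || successes > n) {
    stop("need 0 <= successes <= n and n > 0")
  }
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- successes / n
  den <- 1 + z^2 / n
  ctr <- p + z^2 / (2 * n)
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  c(lower = max(0, (ctr - hw) / den), upper = min(1, (ctr + hw) / den))
}

#' Diagnostic-accuracy metrics with Wilson 95% intervals
#'
#' Accuracy, sensitivity, specificity, PPV and NPV as binomial proportions of
#' the corresponding confusion-matrix margins, each with a Wilson score
#' interval. A metric whose denominator is zero is undefined and reported as
#' `NULL` rather than NaN.
#'
#' @param cm a [confusion_matrix()] / [new_confusion_matrix()].
#' @param conf confidence level for the intervals.
#' @return object of class `metrics_report`: a named list of
#'   `list(estimate, lower, upper, successes, n)` entries for `accuracy`,
#'   `sensitivity`, `specificity`, `ppv`, `npv`.
#' @export
classification_metrics <- function(cm, conf = 0.95) {
  stopifnot(inherits(cm, "confusion_matrix"))
  n <- cm$tp + cm$fp + cm$fn + cm$tn
  if (n == 0L) stop("empty confusion matrix")
  one <- function(successes, denom) {
    if (denom == 0L) return(NULL)
    ci <- wilson_ci(successes, denom, conf)
    list(estimate = successes / denom,
         lower = unname(ci["lower"]), upper = unname(ci["upper"]),
         successes = successes, n = denom)
  }
  out <- list(
    accuracy = one(cm$tp + cm$tn, n),
    sensitivity = one(cm$tp, cm$tp + cm$fn),
    specificity = one(cm$tn, cm$tn + cm$fp),
    ppv = one(cm$tp, cm$tp + cm$fp),
    npv = one(cm$tn, cm$tn + cm$fn)
  )
  structure(out[!vapply(out, is.null, logical(1))], class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  for (nm in names(x)) {
    m <- x[[nm]]
    cat(sprintf("%-12s %5.1f%%  (95%% CI %.1f%% - %.1f%%)  [%d/%d]\n",
                nm, 100 * m$estimate, 100 * m$lower, 100 * m$upper,
                m$successes, m$n))
  }
  invisible(x)
}

#' ROC curve and AUC (Mann-Whitney formulation)
#'
#' AUC is computed from the rank-sum of the positive-class scores, which
#' equals the probability that a random positive outranks a random negative,
#' ties counting one half. ROC points are emitted at every unique score
#' threshold (rule: `score > threshold` is called positive).
#'
#' @param scores numeric per-case scores (higher = more positive-like).
#' @param references labels; `positive` marks the positive class.
#' @param positive positive-class label (default `"Immunity_H"`).
#' @return list with `auc` and `roc`, a data.frame of `threshold`, `tpr`,
#'   `fpr` sorted from the most permissive to the strictest cut.
#' @export
roc_auc <- function(scores, references, positive = "Immunity_H") {
  stopifnot(length(scores) == length(references))
  pos <- references == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) {
    stop("both classes must be present to compute AUC")
  }
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(-Inf, sort(unique(scores)))
  roc <- do.call(rbind, lapply(thr, function(t) {
    called <- scores > t
    data.frame(threshold = t,
               tpr = sum(called & pos) / n1,
               fpr = sum(called & !pos) / n0)
  }))
  list(auc = auc, roc = roc)
}
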