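#' Model configuration: attention and score thresholds
#'
#' Both rules use strict inequalities: a patch is high-attention when its
#' normalized density satisfies `a > attention_threshold`, and a slide is
#' called high-immunity when `Score > score_threshold`. The defaults (0.2 and
#' 0.05) are the published operating points of the rule.
#'
#' @param attention_threshold cutoff on the normalized density a, in (0, 1).
#' @param score_threshold cutoff on the slide score, in (0, 1).
#' @return object of class `model_config`.
#' @export
model_config <- function(attention_threshold = 0.2, score_threshold = 0.05) {
  check_unit_open(attention_threshold, "attention_threshold")
  check_unit_open(score_threshold, "score_threshold")
  structure(
    list(attention_threshold = attention_threshold,
         score_threshold = score_threshold),
    class = "model_config"
  )
}

check_unit_open <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0 || x >= 1) {
    stop(name, " must be a single number in (0, 1)")
  }
  invisible(x)
}

#' Flag high-attention patches
#'
#' Marks `is_high_attention = (a > attention_threshold) & is_valid` with a
#' strict inequality, so `a` exactly at the threshold is not flagged.
#'
#' @param grid a normalized `slide_grid` (densities set).
#' @param attention_threshold cutoff in (0, 1); default 0.2.
#' @return the grid with attention flags set.
#' @export
flag_high_attention <- function(grid, attention_threshold = 0.2) {
  stopifnot(inherits(grid, "slide_grid"))
  check_unit_open(attention_threshold, "attention_threshold")
  if (anyNA(grid$patches$a)) stop("densities not set; run normalize_density() first")
  grid$patches$is_high_attention <-
    (grid$patches$a > attention_threshold) & grid$patches$is_valid
  grid$attention_threshold <- attention_threshold
  grid
}

#' Compute the high-aggregation TILs patch ratio score for a slide
#'
#' `Score = N_high / N_valid`, where `N_high` counts high-attention patches
#' and `N_valid` counts valid patches (patches holding at least one counted
#' stromal TIL). Degenerate slides (no counted TILs anywhere) get score 0.
#'
#' @param grid a flagged `slide_grid`.
#' @return object of class `slide_score` with fields `slide_id`, `n_high`,
#'   `n_valid`, `score`, `degenerate`, and `label` (NA until
#'   [classify_slide()] is applied).
#' @export
compute_slide_score <- function(grid) {
  stopifnot(inherits(grid, "slide_grid"))
  if (anyNA(grid$patches$is_high_attention)) {
    stop("attention flags not set; run flag_high_attention() first")
  }
  n_high <- sum(grid$patches$is_high_attention)
  n_valid <- sum(grid$patches$is_valid)
  degenerate <- isTRUE(grid$degenerate) || n_valid == 0L
  score <- if (degenerate) 0 else n_high / n_valid
  structure(
    list(slide_id = grid$slide_id, n_high = n_high, n_valid = n_valid,
         score = score, label = NA_character_, degenerate = degenerate),
    class = "slide_score"
  )
}

#' Classify a slide score into an immune subtype label
#'
#' `Immunity_H` iff `score > score_threshold` (strict), else `Immunity_L`; a
#' score exactly at the threshold is low-immunity.
#'
#' @param score a `slide_score`, or a bare numeric vector of scores.
#' @param score_threshold cutoff in (0, 1); default 0.05.
#' @return for a `slide_score`, the object with `label` set; for a numeric
#'   vector, a character vector of labels.
#' @export
classify_slide <- function(score, score_threshold = 0.05) {
  check_unit_open(score_threshold, "score_threshold")
  if (is.numeric(score)) {
    return(ifelse(score > score_threshold, "Immunity_H", "Immunity_L"))
  }
  stopifnot(inherits(score, "slide_score"))
  score$label <- if (score$score > score_threshold) "Immunity_H" else "Immunity_L"
  score
}

#' @export
print.slide_score <- function(x, ...) {
  cat("<slide_score> ", x$slide_id, ": N_high=", x$n_high,
      " N_valid=", x$n_valid,
      " Score=", format(x$score, digits = 5), sep = "")
  if (!is.na(x$label)) cat(" -> ", x$label, sep = "")
  if (isTRUE(x$degenerate)) cat(" [degenerate]")
  cat("\n")
  invisible(x)
}

#' Score one annotated slide end to end
#'
#' Convenience wrapper: grid, stromal counting, normalization, attention
#' flagging, scoring and classification in one call.
#'
#' @param annotation a [slide_annotation()].
#' @param grid_cfg a [grid_config()].
#' @param model_cfg a [model_config()].
#' @return a classified `slide_score`; the underlying grid is attached as
#'   attribute `"grid"`.
#' @export
score_slide <- function(annotation, grid_cfg = grid_config(),
                        model_cfg = model_config()) {
  grid <- build_patch_grid(annotation, grid_cfg)
  grid <- count_tils(grid, annotation)
  grid <- normalize_density(grid)
  grid <- flag_high_attention(grid, model_cfg$attention_threshold)
  sc <- compute_slide_score(grid)
  sc <- classify_slide(sc, model_cfg$score_threshold)
  attr(sc, "grid") <- grid
  sc
}

#' Calibrate the attention threshold from patch densities
#'
#' The pooled normalized densities of training slides show a bimodal
#' structure: a dense cluster of low-density patches and a sparse cluster of
#' high-density ones. Agglomerative hierarchical clustering (Ward linkage,
#' Euclidean distance, 1-D) is cut at k = 2 and the threshold is placed at
#' the midpoint between the maximum of the lower cluster and the minimum of
#' the upper cluster. If the gap between clusters is below `min_gap` the
#' distribution is treated as unimodal and the published default 0.2 is
#' returned with a warning.
#'
#' @param a_values numeric vector of patch densities in \[0, 1\], length
#'   >= 10.
#' @param min_gap minimum inter-cluster gap for a trustworthy cut
#'   (default 0.02).
#' @param max_values subsampling cap for very large inputs (default 50000).
#' @param seed seed for the subsampling draw.
#' @return list with `threshold`, `gap`, `cluster_sizes`, and `fallback`
#'   (TRUE when the default was returned).
#' @export
calibrate_attention_threshold <- function(a_values, min_gap = 0.02,
                                          max_values = 50000L, seed = 1L) {
  a_values <- a_values[!is.na(a_values)]
  if (length(a_values) < 10L) {
    stop("need at least 10 density values to calibrate")
  }
  if (any(a_values < 0 | a_values > 1)) stop("densities must lie in [0, 1]")
  if (length(a_values) > max_values) {
    a_values <- local_seed(seed, sample(a_values, max_values))
  }
  hc <- stats::hclust(stats::dist(a_values), method = "ward.D2")
  cl <- stats::cutree(hc, k = 2L)
  m1 <- mean(a_values[cl == 1L]); m2 <- mean(a_values[cl == 2L])
  lower <- a_values[cl == (if (m1 <= m2) 1L else 2L)]
  upper <- a_values[cl == (if (m1 <= m2) 2L else 1L)]
  gap <- min(upper) - max(lower)
  sizes <- c(lower = length(lower), upper = length(upper))
  if (!is.finite(gap) || gap < min_gap) {
    warning("density distribution looks unimodal (gap = ",
            format(gap, digits = 3), "); returning default threshold 0.2")
    return(list(threshold = 0.2, gap = gap, cluster_sizes = sizes,
                fallback = TRUE))
  }
  list(threshold = (max(lower) + min(upper)) / 2, gap = gap,
       cluster_sizes = sizes, fallback = FALSE)
}

#' Calibrate the score threshold against reference labels
#'
#' Sweeps candidate thresholds at the midpoints between consecutive sorted
#' unique scores and picks the one maximizing training accuracy of the rule
#' `score > t -> Immunity_H`; ties are broken by maximizing Youden's J
#' (sensitivity + specificity - 1) and then by the smallest threshold.
#'
#' @param scores numeric per-slide scores.
#' @param labels reference labels, `"Immunity_H"` / `"Immunity_L"`.
#' @return list with `threshold`, `accuracy`, and the full `sweep`
#'   data.frame (threshold, accuracy, sensitivity, specificity, youden).
#' @export
calibrate_score_threshold <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- check_labels(labels)
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present to calibrate the score threshold")
  }
  u <- sort(unique(scores))
  cand <- if (length(u) > 1L) (u[-1] + u[-length(u)]) / 2 else u / 2
  cand <- unique(c(min(u) / 2, cand))
  pos <- labels == "Immunity_H"
  sweep <- do.call(rbind, lapply(cand, function(t) {
    pred <- scores > t
    tp <- sum(pred & pos); tn <- sum(!pred & !pos)
    fp <- sum(pred & !pos); fn <- sum(!pred & pos)
    sens <- tp / (tp + fn); spec <- tn / (tn + fp)
    data.frame(threshold = t, accuracy = (tp + tn) / length(pos),
               sensitivity = sens, specificity = spec,
               youden = sens + spec - 1)
  }))
  ord <- order(-sweep$accuracy, -sweep$youden, sweep$threshold)
  best <- sweep[ord[1L], ]
  list(threshold = best$threshold, accuracy = best$accuracy, sweep = sweep)
}

check_labels <- function(labels) {
  labels <- as.character(labels)
  ok <- labels %in% c("Immunity_H", "Immunity_L")
  if (!all(ok)) {
    stop("labels must be 'Immunity_H' or 'Immunity_L'; got: ",
         paste(unique(labels[!ok]), collapse = ", "))
  }
  labels
}
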