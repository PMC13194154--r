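#' Run the scoring pipeline over a cohort of annotated slides
#'
#' For each slide: read (if a path), build the patch grid, count stromal
#' TILs, normalize densities, flag high-attention patches, score and
#' classify. Optionally writes per-slide patch tables, a cohort score CSV
#' and heatmap PNGs, and — when reference labels are supplied — a
#' diagnostic-accuracy report. The output is a pure function of the inputs
#' and configuration; every threshold used is echoed in the returned table's
#' attributes and in the log messages.
#'
#' @param slides character vector of annotation file paths, or a list of
#'   [slide_annotation()] objects.
#' @param grid_cfg a [grid_config()].
#' @param model_cfg a [model_config()].
#' @param reference_labels optional named or positional vector of reference
#'   subtypes (`"Immunity_H"`/`"Immunity_L"`), same order as `slides`.
#' @param output_dir optional directory for CSV/PNG/JSON outputs.
#' @param heatmaps when TRUE and `output_dir` is set, writes one heatmap PNG
#'   per slide.
#' @param heatmap_cfg a [heatmap_config()].
#' @param on_error `"abort"` (default) or `"skip"`: a slide that fails to
#'   read or score is either fatal or dropped with a message (its reference
#'   label, if any, is dropped with it).
#' @param mpp_override forwarded to [read_annotations()] for files lacking
#'   scale metadata.
#' @param verbose emit per-slide progress messages.
#' @return list with `scores` (data.frame: slide_id, n_high, n_valid, score,
#'   label, degenerate), `metrics` (a `metrics_report`, or NULL), `auc`
#'   (numeric or NULL), and `skipped` (character vector of failed inputs).
#' @export
run_pipeline <- function(slides,
                         grid_cfg = grid_config(),
                         model_cfg = model_config(),
                         reference_labels = NULL,
                         output_dir = NULL,
                         heatmaps = FALSE,
                         heatmap_cfg = heatmap_config(),
                         on_error = c("abort", "skip"),
                         mpp_override = NULL,
                         verbose = FALSE) {
  on_error <- match.arg(on_error)
  if (is.character(slides)) slides <- as.list(slides)
  if (length(slides) == 0L) stop("empty cohort: no slides supplied")
  if (!is.null(reference_labels) && length(reference_labels) != length(slides)) {
    stop("reference_labels must match slides in length and order")
  }
  if (!is.null(output_dir) && !dir.exists(output_dir)) {
    dir.create(output_dir, recursive = TRUE)
  }

  rows <- list(); skipped <- character(0); kept_ref <- character(0)
  for (i in seq_along(slides)) {
    item <- slides[[i]]
    res <- tryCatch({
      ann <- if (inherits(item, "slide_annotation")) item
             else read_annotations(item, mpp_override = mpp_override)
      sc <- score_slide(ann, grid_cfg, model_cfg)
      list(ann = ann, sc = sc)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      lbl <- if (is.character(item)) item else sprintf("slide %d", i)
      if (on_error == "abort") {
        stop("failed on ", lbl, ": ", conditionMessage(res))
      }
      message("skipping ", lbl, ": ", conditionMessage(res))
      skipped <- c(skipped, lbl)
      next
    }
    sc <- res$sc
    if (verbose) {
      message(sprintf(
        "%s: N_high=%d N_valid=%d Score=%.6f -> %s (a>%.2f, Score>%.2f)",
        sc$slide_id, sc$n_high, sc$n_valid, sc$score, sc$label,
        model_cfg$attention_threshold, model_cfg$score_threshold))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      slide_id = sc$slide_id, n_high = sc$n_high, n_valid = sc$n_valid,
      score = sc$score, label = sc$label, degenerate = sc$degenerate
    )
    if (!is.null(reference_labels)) kept_ref <- c(kept_ref, reference_labels[i])
    if (!is.null(output_dir)) {
      grid <- attr(sc, "grid")
      patch_table(grid, file.path(output_dir,
                                  paste0(sc$slide_id, "_patches.csv")))
      if (isTRUE(heatmaps)) {
        surf <- interpolate_density_surface(grid, heatmap_cfg, res$ann)
        render_heatmap(surf, file.path(output_dir,
                                       paste0(sc$slide_id, "_heatmap.png")),
                       heatmap_cfg)
      }
    }
  }
  if (length(rows) == 0L) stop("no slide could be processed")
  scores <- do.call(rbind, rows)
  attr(scores, "attention_threshold") <- model_cfg$attention_threshold
  attr(scores, "score_threshold") <- model_cfg$score_threshold

  metrics <- NULL; auc <- NULL
  if (!is.null(reference_labels)) {
    cm <- confusion_matrix(scores$label, kept_ref)
    metrics <- classification_metrics(cm)
    auc <- roc_auc(scores$score, kept_ref)$auc
  }
  if (!is.null(output_dir)) {
    utils::write.csv(scores, file.path(output_dir, "cohort_scores.csv"),
                     row.names = FALSE)
    if (!is.null(metrics)) {
      jsonlite::write_json(
        list(metrics = unclass(metrics), auc = auc,
             attention_threshold = model_cfg$attention_threshold,
             score_threshold = model_cfg$score_threshold),
        file.path(output_dir, "metrics.json"),
        auto_unbox = TRUE, digits = NA)
    }
  }
  list(scores = scores, metrics = metrics, auc = auc, skipped = skipped)
}

#' Apply the score rule to published per-slide scores
#'
#' Classifies each score with the strict `score > threshold` rule and
#' reports agreement with supplied reference labels — the worked example the
#' package ships for the published ten-case TCGA-LUAD test set (see
#' [tcga_test_scores()]).
#'
#' @param scores numeric scores in \[0, 1\].
#' @param reference_labels reference subtype labels, same length.
#' @param score_threshold the rule cutoff (default 0.05).
#' @return list with `predictions` (data.frame: score, predicted, reference,
#'   concordant), `accuracy`, and `discordant` (rows where rule and
#'   reference disagree).
#' @export
apply_score_rule <- function(scores, reference_labels, score_threshold = 0.05) {
  if (length(scores) != length(reference_labels)) {
    stop("scores and reference_labels differ in length")
  }
  if (any(scores < 0 | scores > 1)) stop("scores must lie in [0, 1]")
  reference_labels <- check_labels(reference_labels)
  predicted <- classify_slide(scores, score_threshold)
  predictions <- data.frame(
    score = scores, predicted = predicted, reference = reference_labels,
    concordant = predicted == reference_labels
  )
  list(
    predictions = predictions,
    accuracy = mean(predictions$concordant),
    discordant = predictions[!predictions$concordant, , drop = FALSE]
  )
}

#' Published ten-case TCGA-LUAD validation scores
#'
#' The high-aggregation TILs patch ratio scores reported for ten TCGA-LUAD
#' slides of the internal validation cohort, with their transcriptomic
#' reference subtypes (4 high-immunity, 6 low-immunity). One case
#' (TCGA-44-2661, score 0.082299) exceeds the 0.05 cutoff but is
#' transcriptomically low-immunity, so the rule misclassifies exactly that
#' case: 90% accuracy. (The tabulated source prints that case's two label
#' columns transposed relative to its running text; this fixture follows the
#' text.)
#'
#' @return data.frame with columns `tcga_id`, `score`, `reference_label`.
#' @export
tcga_test_scores <- function() {
  path <- system.file("extdata", "tcga_test_scores.csv", package = "TILscore",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
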