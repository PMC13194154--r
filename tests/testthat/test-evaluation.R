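test_that("trimmed field mean drops exactly one max and one min occurrence", {
  expect_equal(trimmed_field_mean(1:10), 5.5)
  expect_equal(trimmed_field_mean(rep(7, 10)), 7)
  expect_equal(trimmed_field_mean(c(0, 0, 100, rep(10, 7))), 70 / 8)
  expect_error(trimmed_field_mean(c(1, 2)), "at least 3")
})

test_that("density conversion uses the 0.2595 mm^2 high-power field", {
  expect_equal(density_per_mm2(0), 0)
  expect_equal(density_per_mm2(0.2595), 1)
  expect_equal(density_per_mm2(112.84), 112.84 / 0.2595)
  expect_error(density_per_mm2(1, 0), "positive")
})

test_that("composite IHC scores: Z columns standardized, mirrored cases split", {
  # two cases with mirrored densities: composites +c and -c
  markers <- c("CD3", "CD8", "CD20", "CD68")
  mk_panel <- function(case, vals) {
    do.call(rbind, lapply(seq_along(markers), function(i) {
      data.frame(case_id = case, marker = markers[i],
                 field_index = 1:10, count = rep(vals[i], 10))
    }))
  }
  panels <- rbind(mk_panel("a", c(100, 20, 80, 60)),
                  mk_panel("b", c(40, 8, 30, 40)))
  out <- composite_ihc_scores(panels)
  expect_equal(out$composite[out$case_id == "a"],
               -out$composite[out$case_id == "b"])
  expect_identical(sort(out$ihc_label), c("high", "low"))

  # a larger cohort: each Z column has mean 0, sample SD 1
  tab <- simulate_ihc_cohort(ihc_sim_spec(seed = 11), 15)
  sc <- composite_ihc_scores(tab)
  for (mk in markers) {
    z <- sc[[paste0("z_", mk)]]
    expect_lt(abs(mean(z)), 1e-10)
    expect_equal(stats::sd(z), 1, tolerance = 1e-10)
  }
  expect_lt(abs(mean(sc$composite)), 1e-10)
  # median dichotomization is strict and balanced for even n
  expect_equal(sum(sc$ihc_label == "high"), 15)
})

test_that("zero-SD markers are flagged and contribute Z = 0", {
  panels <- rbind(
    data.frame(case_id = "a", marker = rep(c("CD3", "CD8", "CD20", "CD68"), each = 3),
               field_index = rep(1:3, 4), count = rep(c(10, 5, 5, 5), each = 3)),
    data.frame(case_id = "b", marker = rep(c("CD3", "CD8", "CD20", "CD68"), each = 3),
               field_index = rep(1:3, 4), count = rep(c(20, 5, 8, 9), each = 3))
  )
  expect_warning(out <- composite_ihc_scores(panels), "CD8")
  expect_true(all(out$z_CD8 == 0))
})

test_that("confusion matrix counts with high-immunity as the positive class", {
  ref <- c(rep("Immunity_H", 4), rep("Immunity_L", 6))
  cm <- confusion_matrix(ref, ref)
  expect_equal(unlist(cm[c("tp", "fp", "fn", "tn")]),
               c(tp = 4, fp = 0, fn = 0, tn = 6))

  inv <- ifelse(ref == "Immunity_H", "Immunity_L", "Immunity_H")
  cm2 <- confusion_matrix(inv, ref)
  expect_equal(cm2$tp + cm2$tn, 0)

  expect_error(confusion_matrix(c("yes"), c("Immunity_H")), "labels outside")
  expect_error(confusion_matrix(ref, ref[-1]), "length")
  expect_error(new_confusion_matrix(-1, 0, 0, 1), "non-negative")
})

test_that("published external-validation example: all five metrics at 1 dp", {
  cm <- new_confusion_matrix(tp = 26, fp = 2, fn = 4, tn = 28)
  m <- classification_metrics(cm)
  pct <- function(x) round(100 * x, 1)
  expect_equal(pct(m$accuracy$estimate), 90.0)
  expect_equal(pct(m$sensitivity$estimate), 86.7)
  expect_equal(pct(m$specificity$estimate), 93.3)
  expect_equal(pct(m$ppv$estimate), 92.9)
  expect_equal(pct(m$npv$estimate), 87.5)
})

test_that("degenerate confusion matrices omit undefined metrics", {
  perfect <- classification_metrics(new_confusion_matrix(1, 0, 0, 1))
  expect_equal(perfect$accuracy$estimate, 1)
  expect_equal(perfect$sensitivity$estimate, 1)

  nopos_pred <- classification_metrics(new_confusion_matrix(0, 0, 5, 5))
  expect_equal(nopos_pred$sensitivity$estimate, 0)
  expect_null(nopos_pred$ppv)  # no positive predictions: PPV undefined
})

test_that("Wilson intervals reproduce closed-form checks and boundary behavior", {
  ci <- wilson_ci(54, 60)
  expect_equal(round(100 * unname(ci), 1), c(79.9, 95.3))
  ci2 <- wilson_ci(26, 30)
  expect_equal(round(100 * unname(ci2), 1), c(70.3, 94.7))
  ci0 <- wilson_ci(0, 20)
  expect_equal(unname(ci0["lower"]), 0)
  cin <- wilson_ci(20, 20)
  expect_equal(unname(cin["upper"]), 1)
  expect_error(wilson_ci(5, 0), "n > 0")
  expect_error(wilson_ci(7, 5), "successes")
})

test_that("Wilson interval contains the estimate and shrinks with n", {
  for (p in c(0.1, 0.5, 0.9)) {
    widths <- vapply(c(10, 40, 160, 640), function(n) {
      ci <- wilson_ci(round(p * n), n)
      expect_lte(ci["lower"], p + 1e-9)
      expect_gte(ci["upper"], p - 1e-9)
      unname(ci["upper"] - ci["lower"])
    }, numeric(1))
    expect_true(all(diff(widths) < 0))
  }
})

test_that("AUC: closed-form cases and the brute-force pair-counting oracle", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12),
                       rep(c("Immunity_L", "Immunity_H"), each = 3))$auc, 1)
  expect_equal(roc_auc(rep(0.4, 6),
                       rep(c("Immunity_L", "Immunity_H"), each = 3))$auc, 0.5)
  expect_equal(roc_auc(c(0.1, 0.2, 0.3, 0.4),
                       c("Immunity_L", "Immunity_H", "Immunity_L", "Immunity_H"))$auc,
               0.75)

  pair_count_auc <- function(scores, labels) {
    pos <- which(labels == "Immunity_H"); neg <- which(labels == "Immunity_L")
    tot <- 0
    for (i in pos) for (j in neg) {
      tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
    }
    tot / (length(pos) * length(neg))
  }
  set.seed(14)
  for (rep in 1:10) {
    n <- sample(10:50, 1)
    scores <- round(runif(n), 2)  # rounded so ties occur
    labels <- sample(c("Immunity_H", "Immunity_L"), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    expect_equal(roc_auc(scores, labels)$auc, pair_count_auc(scores, labels))
  }
  expect_error(roc_auc(1:3, rep("Immunity_H", 3)), "both classes")
})

test_that("AUC complement identity and agreement with an independent package", {
  set.seed(15)
  scores <- runif(40)  # continuous: ties almost surely absent
  labels <- sample(c("Immunity_H", "Immunity_L"), 40, replace = TRUE,
                   prob = c(0.4, 0.6))
  a1 <- roc_auc(scores, labels)$auc
  a2 <- roc_auc(-scores, labels)$auc
  expect_equal(a1 + a2, 1)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = scores,
    levels = c("Immunity_L", "Immunity_H"), direction = "<", quiet = TRUE)))
  expect_equal(a1, ref)
})

test_that("ROC points trace the empirical operating characteristics", {
  scores <- c(0.1, 0.4, 0.35, 0.8)
  labels <- c("Immunity_L", "Immunity_H", "Immunity_L", "Immunity_H")
  roc <- roc_auc(scores, labels)$roc
  expect_equal(roc$tpr[roc$threshold == -Inf], 1)
  expect_equal(roc$fpr[roc$threshold == -Inf], 1)
  expect_equal(roc$tpr[roc$threshold == 0.8], 0)
  expect_true(all(diff(roc$tpr) <= 0) && all(diff(roc$fpr) <= 0))
})
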