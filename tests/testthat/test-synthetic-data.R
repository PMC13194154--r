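test_that("zero-rate processes yield zero detections", {
  cfg <- simulation_config(background_intensity = 0,
                           cluster_parent_intensity = 0, seed = 3)
  ann <- simulate_slide(cfg)
  expect_equal(nrow(ann$detections), 0)
})

test_that("slide simulation is deterministic given the seed and leaves the RNG alone", {
  cfg <- high_immunity_config(seed = 99)
  set.seed(123); before <- runif(1)
  set.seed(123)
  a1 <- simulate_slide(cfg)
  mid <- runif(1)
  a2 <- simulate_slide(cfg)
  expect_identical(a1$detections, a2$detections)
  expect_identical(a1$tumor_polygons, a2$tumor_polygons)
  expect_identical(before, mid)  # caller's RNG stream undisturbed
})

test_that("every simulated TIL lies in stroma: inside tissue, outside all tumors", {
  for (seed in c(2, 31)) {
    cfg <- high_immunity_config(seed = seed)
    ann <- simulate_slide(cfg)
    ctr <- detection_centers(ann, "um")
    tis <- lapply(ann$tissue_polygons, function(p) p * ann$mpp)
    tum <- lapply(ann$tumor_polygons, function(p) p * ann$mpp)
    expect_true(all(points_in_polygons(ctr[, 1], ctr[, 2], tis)))
    if (length(tum) > 0) {
      expect_false(any(points_in_polygons(ctr[, 1], ctr[, 2], tum)))
    }
  }
})

test_that("pure Poisson detection count matches intensity x stroma area", {
  # exact-area condition: rectangular tissue = the whole 2.5 x 4 mm frame,
  # no tumor, no clusters; lambda = 100 cells/mm^2 over 10 mm^2 -> mean 1000
  n_rep <- 500
  counts <- vapply(seq_len(n_rep), function(i) {
    cfg <- simulation_config(
      slide_width_um = 2500, slide_height_um = 4000,
      tissue_shape = "rect", tissue_inset_frac = 0, tumor_fraction = 0,
      background_intensity = 100, cluster_parent_intensity = 0,
      seed = 10000 + i
    )
    nrow(simulate_slide(cfg)$detections)
  }, numeric(1))
  se <- sd(counts) / sqrt(n_rep)
  expect_lt(abs(mean(counts) - 1000), 3 * se)
})

test_that("cohort simulation labels, sizes and reproducibility are exact", {
  spec <- cohort_spec(0, 3, seed = 5)
  co <- simulate_cohort(spec)
  expect_length(co$annotations, 3)
  expect_identical(co$labels, rep("Immunity_L", 3))

  spec2 <- cohort_spec(2, 2, seed = 17)
  c1 <- simulate_cohort(spec2)
  c2 <- simulate_cohort(spec2)
  expect_identical(c1$labels, c("Immunity_H", "Immunity_H",
                                "Immunity_L", "Immunity_L"))
  for (i in 1:4) {
    expect_identical(c1$annotations[[i]]$detections,
                     c2$annotations[[i]]$detections)
  }
  # distinct per-slide seeds: slides are not clones of each other
  expect_false(identical(c1$annotations[[3]]$detections,
                         c1$annotations[[4]]$detections))
})

test_that("IHC simulation honors SD=0, seeding, and the configured family", {
  p0 <- data.frame(marker = rep(c("CD3", "CD8", "CD20", "CD68"), each = 2),
                   group = rep(c("high", "low"), 4),
                   mean = c(100, 40, 20, 8, 80, 35, 60, 40), sd = 0)
  tab <- simulate_ihc_cohort(ihc_sim_spec(params = p0, seed = 2), 2)
  expect_true(all(tab$count[tab$marker == "CD3" & tab$group == "high"] == 100))
  expect_true(all(tab$count[tab$marker == "CD8" & tab$group == "low"] == 8))

  s1 <- simulate_ihc_cohort(ihc_sim_spec(seed = 7), 5)
  s2 <- simulate_ihc_cohort(ihc_sim_spec(seed = 7), 5)
  expect_identical(s1, s2)
  expect_true(all(s1$count >= 0))
  expect_true(all(s1$count == round(s1$count)))
  expect_equal(nrow(s1), 2 * 5 * 4 * 10)  # groups x cases x markers x fields

  nb <- simulate_ihc_cohort(ihc_sim_spec(family = "nbinom", seed = 7), 5)
  expect_true(all(nb$count >= 0))
})

test_that("rendered synthetic image has the promised mask structure", {
  # tissue covering the whole frame -> all-foreground mask
  full <- slide_annotation("full", mpp = 1,
                           tissue_polygons = list(square_ring(0, 0, 400)))
  ri <- render_synthetic_image(full, mpp_out = 8, noise_sd = 0)
  # foreground everywhere except the small border pad around the frame
  expect_true(all(ri$mask[2:(nrow(ri$mask) - 2), 2:(ncol(ri$mask) - 2)]))
  expect_gt(mean(ri$mask), 0.9)

  # two disjoint tissue blobs, no noise -> exactly 2 connected components
  two <- slide_annotation("two", mpp = 1,
                          tissue_polygons = list(
                            circle_ring(300, 300, 150, n = 48),
                            circle_ring(900, 900, 150, n = 48)))
  ri2 <- render_synthetic_image(two, mpp_out = 8, noise_sd = 0)
  lab <- EBImage::bwlabel(ri2$mask * 1)
  expect_equal(max(lab), 2)
  # image is tinted inside tissue, near-white outside
  gray <- apply(ri2$image, c(1, 2), mean)
  expect_lt(max(gray[ri2$mask]), 0.9)
  expect_gt(min(gray[!ri2$mask]), 0.9)
})

test_that("config validation rejects impossible geometry and rates", {
  expect_error(simulation_config(slide_width_um = 0), "positive")
  expect_error(simulation_config(tumor_fraction = 1), "tumor_fraction")
  expect_error(simulation_config(background_intensity = -1), "non-negative")
  expect_error(ihc_sim_spec(n_fields = 2), "n_fields")
})
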