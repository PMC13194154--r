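test_that("patch grid dimensions follow ceiling arithmetic on the tissue bbox", {
  # 1000 x 1000 um at 100 um -> 10 x 10 = 100 patches
  g <- build_patch_grid(square_annotation(NULL, side = 1000))
  expect_equal(nrow(g$patches), 100)
  expect_equal(c(g$n_row, g$n_col), c(10, 10))

  # 250 x 250 um -> 3 x 3 with partial edge patches
  g2 <- build_patch_grid(square_annotation(NULL, side = 250))
  expect_equal(nrow(g2$patches), 9)

  # 999 x 1 um strip -> ceil(999/100) x 1 = 10 patches
  strip <- slide_annotation("strip", mpp = 1,
                            tissue_polygons = list(rbind(
                              c(0, 0), c(999, 0), c(999, 1), c(0, 1))))
  g3 <- build_patch_grid(strip)
  expect_equal(c(g3$n_row, g3$n_col), c(1, 10))
  expect_equal(nrow(g3$patches), 10)
})

test_that("grid respects pixel/micron conversion through mpp", {
  # same 1000 um square expressed at mpp 0.25 (4000 px): still 10 x 10
  ann <- square_annotation(NULL, side = 1000, mpp = 0.25)
  g <- build_patch_grid(ann)
  expect_equal(nrow(g$patches), 100)
})

test_that("counting is exact on a hand-placed configuration", {
  # 7 detections in 3 patches (4, 2, 1)
  ctr <- rbind(
    c(10, 10), c(20, 20), c(30, 30), c(40, 40),   # patch (0,0)
    c(150, 50), c(160, 60),                       # patch (0,1)
    c(550, 750)                                   # patch (7,5)
  )
  ann <- square_annotation(ctr)
  g <- normalize_density(count_tils(build_patch_grid(ann), ann))
  expect_equal(sum(g$patches$num_tils), 7)
  expect_equal(g$num_max, 4)
  expect_equal(sum(g$patches$is_valid), 3)
  p <- g$patches
  expect_equal(p$num_tils[p$row == 0 & p$col == 0], 4)
  expect_equal(p$num_tils[p$row == 0 & p$col == 1], 2)
  expect_equal(p$a[p$row == 7 & p$col == 5], 0.25)
})

test_that("detections inside tumor or outside tissue are never counted", {
  tum <- circle_ring(500, 500, 100)
  ctr <- rbind(c(500, 500), c(450, 480),  # inside tumor
               c(1500, 500),              # outside tissue
               c(50, 50))                 # stromal
  ann <- square_annotation(ctr, tumor_polygons = list(tum))
  g <- count_tils(build_patch_grid(ann), ann)
  expect_equal(sum(g$patches$num_tils), 1)
})

test_that("half-open patches assign boundary centers to the next patch", {
  # center exactly on the shared edge x = 100 goes to column 1, not 0
  ann <- square_annotation(rbind(c(100, 50)))
  g <- count_tils(build_patch_grid(ann), ann)
  p <- g$patches
  expect_equal(p$num_tils[p$row == 0 & p$col == 1], 1)
  expect_equal(p$num_tils[p$row == 0 & p$col == 0], 0)
})

test_that("count conservation holds against the brute-force oracle", {
  for (seed in c(11, 21, 31, 41, 51)) {
    ann <- random_annotation(seed)
    g <- count_tils(build_patch_grid(ann), ann)
    oracle <- brute_force_score(ann)
    expect_equal(sum(g$patches$num_tils), sum(oracle$counts))
    expect_equal(g$num_max, oracle$num_max)
    got <- matrix(0L, g$n_row, g$n_col)
    got[cbind(g$patches$row + 1L, g$patches$col + 1L)] <- g$patches$num_tils
    expect_identical(got, oracle$counts)
  }
})

test_that("translating by whole patches permutes indices but not the count multiset", {
  set.seed(8)
  ctr <- cbind(runif(120, 0, 1000), runif(120, 0, 1000))
  ann <- square_annotation(ctr)
  g <- count_tils(build_patch_grid(ann), ann)

  shift <- 300  # 3 whole patches
  ann2 <- slide_annotation("fix", mpp = 1,
                           tissue_polygons = list(square_ring(shift, shift, 1000)),
                           detections = det_at(ctr[, 1] + shift, ctr[, 2] + shift))
  g2 <- count_tils(build_patch_grid(ann2), ann2)
  expect_equal(sort(g$patches$num_tils), sort(g2$patches$num_tils))
  expect_equal(g$num_max, g2$num_max)
})

test_that("normalization: formula, scale invariance, and the degenerate slide", {
  ann <- square_annotation(rbind(c(50, 50), c(55, 55), c(150, 50),
                                 c(155, 55), c(160, 60), c(165, 65),
                                 c(163, 62), c(157, 57), c(250, 50)))
  g <- normalize_density(count_tils(build_patch_grid(ann), ann))
  p <- g$patches
  # counts (2, 6, 1) -> a = (1/3, 1, 1/6)
  expect_equal(p$a[p$row == 0 & p$col == 0], 2 / 6)
  expect_equal(p$a[p$row == 0 & p$col == 1], 1)
  expect_equal(p$a[p$row == 0 & p$col == 2], 1 / 6)
  expect_equal(max(p$a), 1)

  # uniform count multiplication leaves a unchanged (each point tripled)
  ctr <- rbind(c(50, 50), c(55, 55), c(150, 50), c(155, 55), c(160, 60),
               c(165, 65), c(163, 62), c(157, 57), c(250, 50))
  ctr3 <- ctr[rep(seq_len(nrow(ctr)), each = 3), ]
  ann3 <- square_annotation(ctr3)
  g3 <- normalize_density(count_tils(build_patch_grid(ann3), ann3))
  expect_equal(sort(unique(g3$patches$a)), sort(unique(p$a)))

  # no TILs at all: degenerate flag, zero densities, warning
  empty <- square_annotation(NULL)
  ge <- count_tils(build_patch_grid(empty), empty)
  expect_warning(ge <- normalize_density(ge), "degenerate")
  expect_true(ge$degenerate)
  expect_true(all(ge$patches$a == 0))
})

test_that("optional tissue-fraction QC drops low-coverage edge patches", {
  # circle of radius 300: corner patches of its bbox hold little tissue
  ann <- slide_annotation("disc", mpp = 1,
                          tissue_polygons = list(circle_ring(300, 300, 300, n = 90)))
  g_off <- build_patch_grid(ann, grid_config())
  g_on <- build_patch_grid(ann, grid_config(min_tissue_fraction = 0.6))
  expect_lt(nrow(g_on$patches), nrow(g_off$patches))
  expect_true(all(g_on$patches$tissue_fraction >= 0.6))
})
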