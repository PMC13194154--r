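# Fixtures are built in code: geometry in microns with mpp = 1 unless a test
# exercises the pixel/micron conversion explicitly.

square_ring <- function(x0 = 0, y0 = 0, side = 1000) {
  rbind(c(x0, y0), c(x0 + side, y0), c(x0 + side, y0 + side), c(x0, y0 + side))
}

# detections as fixed-size boxes centered on the given micron coordinates
det_at <- function(x, y, size = 8, mpp = 1, confidence = NA_real_) {
  data.frame(
    x_min = (x - size / 2) / mpp, y_min = (y - size / 2) / mpp,
    width = size / mpp, height = size / mpp, confidence = confidence
  )
}

# square tissue slide with optional tumor polygons and detections at centers
square_annotation <- function(centers = NULL, side = 1000, mpp = 1,
                              tumor_polygons = list(), slide_id = "fix") {
  det <- if (is.null(centers)) {
    data.frame(x_min = numeric(0), y_min = numeric(0),
               width = numeric(0), height = numeric(0),
               confidence = numeric(0))
  } else {
    det_at(centers[, 1], centers[, 2], mpp = mpp)
  }
  slide_annotation(
    slide_id = slide_id, mpp = mpp,
    tissue_polygons = list(square_ring(side = side) / mpp),
    tumor_polygons = lapply(tumor_polygons, function(p) p / mpp),
    detections = det
  )
}

# Independent brute-force oracle: recount patch TILs straight from detection
# centers with nested loops and explicit point-in-rectangle tests, and rebuild
# the slide score from first principles. Shares no code with the grid path.
brute_force_score <- function(annotation, patch_size_um = 100,
                              attention_threshold = 0.2) {
  ctr <- cbind(
    (annotation$detections$x_min + annotation$detections$width / 2),
    (annotation$detections$y_min + annotation$detections$height / 2)
  ) * annotation$mpp
  tis <- lapply(annotation$tissue_polygons,
                function(p) if (is.list(p)) lapply(p, function(r) r * annotation$mpp)
                            else p * annotation$mpp)
  tum <- lapply(annotation$tumor_polygons,
                function(p) if (is.list(p)) lapply(p, function(r) r * annotation$mpp)
                            else p * annotation$mpp)
  keep <- logical(nrow(ctr))
  for (i in seq_len(nrow(ctr))) {
    in_t <- points_in_polygons(ctr[i, 1], ctr[i, 2], tis)
    in_u <- length(tum) > 0 && points_in_polygons(ctr[i, 1], ctr[i, 2], tum)
    keep[i] <- in_t && !in_u
  }
  ctr <- ctr[keep, , drop = FALSE]

  bb_rings <- lapply(tis, function(p) if (is.list(p)) p[[1]] else p)
  xs <- unlist(lapply(bb_rings, function(r) r[, 1]))
  ys <- unlist(lapply(bb_rings, function(r) r[, 2]))
  x0 <- min(xs); y0 <- min(ys)
  n_col <- max(1, ceiling((max(xs) - x0) / patch_size_um))
  n_row <- max(1, ceiling((max(ys) - y0) / patch_size_um))
  counts <- matrix(0L, n_row, n_col)
  for (i in seq_len(nrow(ctr))) {
    hit <- FALSE
    for (r in seq_len(n_row)) {
      for (cc in seq_len(n_col)) {
        px0 <- x0 + (cc - 1) * patch_size_um
        py0 <- y0 + (r - 1) * patch_size_um
        inx <- ctr[i, 1] >= px0 & ctr[i, 1] < px0 + patch_size_um
        iny <- ctr[i, 2] >= py0 & ctr[i, 2] < py0 + patch_size_um
        # far-edge centers belong to the last (partial) patch
        if (cc == n_col) inx <- inx || ctr[i, 1] == x0 + n_col * patch_size_um
        if (r == n_row) iny <- iny || ctr[i, 2] == y0 + n_row * patch_size_um
        if (inx && iny) { counts[r, cc] <- counts[r, cc] + 1L; hit <- TRUE }
      }
    }
    stopifnot(hit)
  }
  num_max <- max(counts)
  a <- if (num_max > 0) counts / num_max else counts * 0
  valid <- counts >= 1L
  high <- (a > attention_threshold) & valid
  list(
    counts = counts, num_max = num_max,
    n_valid = sum(valid), n_high = sum(high),
    score = if (sum(valid) > 0) sum(high) / sum(valid) else 0
  )
}

# random annotation with scattered detections for property tests
random_annotation <- function(seed, n_det_max = 500, side = 1000,
                              with_tumor = TRUE) {
  set.seed(seed)
  n <- sample.int(n_det_max, 1)
  tum <- if (with_tumor) list(circle_ring(side * 0.6, side * 0.6, side * 0.15))
         else list()
  ctr <- cbind(runif(n, -50, side + 50), runif(n, -50, side + 50))
  square_annotation(ctr, side = side, tumor_polygons = tum,
                    slide_id = paste0("rand", seed))
}
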