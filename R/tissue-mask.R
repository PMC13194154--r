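#' Tissue-mask configuration
#'
#' Parameters of the classical (non-learned) tissue-contour segmentation
#' stage. Defaults follow the published operating point: denoising with a
#' Gaussian (sigma 1.5) and a 3x3 median filter, edge extraction with the
#' Roberts operator binarized by Otsu plus a Canny detector with thresholds
#' (30, 120) on the 0-255 gradient scale, then two morphological closings
#' with a 3x3 elliptical structuring element and hole filling.
#'
#' @param target_mpp micron-per-pixel scale to which the image is
#'   downsampled before edge extraction; 4 um/px corresponds to a 2.5x
#'   objective. When the source scale is unknown a fixed 1/16 downsample is
#'   used instead.
#' @param gaussian_sigma Gaussian blur sigma (pixels).
#' @param median_radius median filter half-size (1 = 3x3 window).
#' @param canny_low,canny_high Canny hysteresis thresholds on the 0-255
#'   gradient scale; low < high required.
#' @param closing_size diameter of the elliptical closing brush (odd).
#' @param closing_iterations number of closing passes (>= 1).
#' @param min_component_frac connected components smaller than this fraction
#'   of the frame are discarded as speckle.
#' @return object of class `tissue_mask_config`.
#' @export
tissue_mask_config <- function(target_mpp = 4, gaussian_sigma = 1.5,
                               median_radius = 1L,
                               canny_low = 30, canny_high = 120,
                               closing_size = 3L, closing_iterations = 2L,
                               min_component_frac = 0.001) {
  if (canny_low >= canny_high) stop("canny_low must be < canny_high")
  if (closing_size %% 2L != 1L) stop("closing_size must be odd")
  if (closing_iterations < 1L) stop("closing_iterations must be >= 1")
  structure(
    list(target_mpp = target_mpp, gaussian_sigma = gaussian_sigma,
         median_radius = as.integer(median_radius),
         canny_low = canny_low, canny_high = canny_high,
         closing_size = as.integer(closing_size),
         closing_iterations = as.integer(closing_iterations),
         min_component_frac = min_component_frac),
    class = "tissue_mask_config"
  )
}

# collapse an RGB array to a grayscale matrix (rows x cols in [0, 1])
to_gray <- function(image) {
  if (is.matrix(image)) return(image)
  if (length(dim(image)) == 3L) return(apply(image, c(1, 2), mean))
  stop("image must be a matrix or an array with 3 dimensions")
}

# fill NA pixels by bilinear interpolation: linear interpolation along rows
# and along columns from the flanking valid pixels, averaged where both exist
fill_missing_bilinear <- function(m) {
  if (!anyNA(m)) return(m)
  if (all(is.na(m))) stop("image has no valid pixels to interpolate from")
  interp_lines <- function(mm) {
    t(apply(mm, 1, function(v) {
      if (!anyNA(v)) return(v)
      ok <- which(!is.na(v))
      if (length(ok) == 0L) return(v)
      if (length(ok) == 1L) return(rep(v[ok], length(v)))
      stats::approx(ok, v[ok], xout = seq_along(v), rule = 2)$y
    }))
  }
  by_row <- interp_lines(m)
  by_col <- t(interp_lines(t(m)))
  filled <- (by_row + by_col) / 2
  filled[is.na(by_row)] <- by_col[is.na(by_row)]
  filled[is.na(by_col)] <- by_row[is.na(by_col)]
  out <- m
  out[is.na(m)] <- filled[is.na(m)]
  out
}

#' Preprocess an image for tissue segmentation
#'
#' Missing pixels (NA, or flagged by `missing_mask`) are reconstructed by
#' bilinear interpolation from valid neighbors, then Gaussian and 3x3 median
#' filtering denoise the result. Dimensions are unchanged and constant images
#' pass through (numerically) unchanged.
#'
#' @param image matrix or RGB array with values in \[0, 1\].
#' @param missing_mask optional logical matrix flagging missing pixels.
#' @param config a [tissue_mask_config()].
#' @return denoised image of the same dimensions and kind.
#' @export
preprocess_image <- function(image, missing_mask = NULL,
                             config = tissue_mask_config()) {
  if (length(image) == 0L) stop("empty image")
  apply_plane <- function(m) {
    if (!is.null(missing_mask)) m[missing_mask] <- NA_real_
    m <- fill_missing_bilinear(m)
    # median first so impulse noise never spreads through the blur
    m <- EBImage::medianFilter(pmin(pmax(m, 0), 1), config$median_radius)
    m <- EBImage::gblur(m, sigma = config$gaussian_sigma)
    as.matrix(m)
  }
  if (is.matrix(image)) return(apply_plane(image))
  out <- image
  for (ch in seq_len(dim(image)[3])) out[, , ch] <- apply_plane(image[, , ch])
  out
}

# Roberts cross gradient magnitude (2x2 diagonal differences)
roberts_magnitude <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  gx <- matrix(0, nr, nc); gy <- matrix(0, nr, nc)
  gx[-nr, -nc] <- m[-nr, -nc] - m[-1, -1]
  gy[-nr, -nc] <- m[-1, -nc] - m[-nr, -1]
  sqrt(gx^2 + gy^2)
}

# Canny edge detector: Sobel gradient, 4-direction non-maximum suppression,
# hysteresis linking weak edges to strong via connected components
canny_edges <- function(m, low, high) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- function(mm) rbind(mm[1, , drop = FALSE], mm, mm[nr, , drop = FALSE])
  padc <- function(mm) cbind(mm[, 1, drop = FALSE], mm, mm[, nc, drop = FALSE])
  p <- padc(pad(m))  # replicate borders
  sh <- function(dr, dc) p[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  gx <- (sh(-1, 1) + 2 * sh(0, 1) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(0, -1) + sh(1, -1))
  gy <- (sh(1, -1) + 2 * sh(1, 0) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(-1, 0) + sh(-1, 1))
  mag <- sqrt(gx^2 + gy^2) * 255  # thresholds quoted on the 0-255 scale
  ang <- atan2(gy, gx)
  sector <- (round(ang / (pi / 4)) %% 4)  # 0:E-W, 1:NE-SW, 2:N-S, 3:NW-SE
  magp <- padc(pad(mag / 255)) * 255
  shm <- function(dr, dc) magp[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  n1 <- matrix(0, nr, nc); n2 <- matrix(0, nr, nc)
  pick <- function(sec, dr, dc) {
    idx <- sector == sec
    n1[idx] <<- shm(dr, dc)[idx]
    n2[idx] <<- shm(-dr, -dc)[idx]
  }
  pick(0, 0, 1); pick(1, 1, 1); pick(2, 1, 0); pick(3, 1, -1)
  nms <- mag >= n1 & mag >= n2
  strong <- nms & mag >= high
  weak <- nms & mag >= low
  if (!any(strong)) return(matrix(FALSE, nr, nc))
  lab <- EBImage::bwlabel(weak * 1)
  keep <- sort(unique(lab[strong]))
  keep <- keep[keep > 0]
  matrix(lab %in% keep, nr, nc)
}

#' Segment tissue from a raster image
#'
#' Classical pipeline: downsample to the 2.5x-equivalent scale, convert to
#' grayscale, extract boundaries with the Roberts gradient binarized by Otsu
#' unioned with Canny edges, close twice with a 3x3 elliptical brush, fill
#' interior holes, label connected components, discard speckle, and trace
#' contour polygons scaled back to input pixel coordinates. Deterministic
#' (no RNG anywhere in the pipeline).
#'
#' @param image matrix or RGB array in \[0, 1\] (ideally from
#'   [preprocess_image()]).
#' @param config a [tissue_mask_config()].
#' @param mpp source scale in microns per pixel; `NULL` triggers the fixed
#'   1/16 fallback downsample.
#' @return list with `mask` (logical matrix at input resolution),
#'   `polygons` (list of contour rings, input pixel coordinates, (x, y) =
#'   (col, row)), and `downsample` (the factor used).
#' @export
segment_tissue <- function(image, config = tissue_mask_config(), mpp = NULL) {
  gray <- to_gray(image)
  if (nrow(gray) < 8L || ncol(gray) < 8L) {
    stop("image too small for the segmentation kernels")
  }
  factor <- if (is.null(mpp)) 16 else config$target_mpp / mpp
  factor <- max(1, factor)
  nr <- max(8L, round(nrow(gray) / factor))
  nc <- max(8L, round(ncol(gray) / factor))
  small <- as.matrix(EBImage::resize(gray, w = nr, h = nc))
  factor_r <- nrow(gray) / nr
  factor_c <- ncol(gray) / nc

  rob <- roberts_magnitude(small)
  edges <- if (max(rob) > 0) {
    th <- EBImage::otsu(rob / max(rob), range = c(0, 1))
    rob / max(rob) > th
  } else {
    matrix(FALSE, nrow(small), ncol(small))
  }
  edges <- edges | canny_edges(small, config$canny_low, config$canny_high)
  if (!any(edges)) {
    return(list(mask = matrix(FALSE, nrow(gray), ncol(gray)),
                polygons = list(), downsample = factor))
  }

  brush <- EBImage::makeBrush(config$closing_size, shape = "disc")
  closed <- edges * 1
  for (i in seq_len(config$closing_iterations)) {
    closed <- EBImage::closing(closed, brush)
  }
  filled <- EBImage::fillHull(closed)
  lab <- EBImage::bwlabel(filled)
  sizes <- tabulate(lab[lab > 0])
  min_px <- config$min_component_frac * length(small)
  keep <- which(sizes >= min_px)
  if (length(keep) == 0L) {
    return(list(mask = matrix(FALSE, nrow(gray), ncol(gray)),
                polygons = list(), downsample = factor))
  }
  lab[!(lab %in% keep)] <- 0L
  lab <- EBImage::bwlabel(lab > 0)

  contours <- EBImage::ocontour(lab)
  polygons <- lapply(contours, function(ct) {
    # ocontour is 0-based (dim1, dim2) = (row, col); emit (x, y) = (col, row)
    ring <- cbind((ct[, 2] + 0.5) * factor_c, (ct[, 1] + 0.5) * factor_r)
    if (nrow(ring) >= 3L) close_ring(ring) else NULL
  })
  polygons <- Filter(Negate(is.null), polygons)

  mask_small <- lab > 0
  mask <- as.matrix(EBImage::resize(mask_small * 1, w = nrow(gray),
                                    h = ncol(gray))) >= 0.5
  list(mask = mask, polygons = polygons, downsample = factor)
}

#' Mask overlap metrics (Dice, precision, recall)
#'
#' `dice = 2|A^B| / (|A| + |B|)`, `precision = |A^B| / |A|`,
#' `recall = |A^B| / |B|`, with A the prediction and B the reference. Two
#' empty masks are in perfect agreement, so all metrics are defined as 1.0
#' in that case.
#'
#' @param mask_pred,mask_true logical (or 0/1) matrices of equal shape.
#' @return named list `dice`, `precision`, `recall`.
#' @export
mask_overlap_metrics <- function(mask_pred, mask_true) {
  if (!all(dim(mask_pred) == dim(mask_true))) {
    stop("mask shapes differ: ", paste(dim(mask_pred), collapse = "x"),
         " vs ", paste(dim(mask_true), collapse = "x"))
  }
  a <- as.logical(mask_pred); b <- as.logical(mask_true)
  na <- sum(a); nb <- sum(b); nab <- sum(a & b)
  if (na == 0L && nb == 0L) {
    return(list(dice = 1, precision = 1, recall = 1))
  }
  list(
    dice = 2 * nab / (na + nb),
    precision = if (na > 0L) nab / na else 0,
    recall = if (nb > 0L) nab / nb else 0
  )
}
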