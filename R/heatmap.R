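#' Heatmap configuration
#'
#' @param upsample_factor fine-grid cells per patch edge (>= 1, default 8).
#' @param mask_outside_tissue when TRUE (default), fine cells whose centers
#'   fall outside the tissue polygons are flagged and rendered transparent.
#' @param overlay_alpha opacity of the heatmap when composited over a
#'   background thumbnail, in \[0, 1\].
#' @param include_colorbar append a vertical 0-1 colorbar strip to rendered
#'   images.
#' @return object of class `heatmap_config`.
#' @export
heatmap_config <- function(upsample_factor = 8L, mask_outside_tissue = TRUE,
                           overlay_alpha = 0.5, include_colorbar = TRUE) {
  stopifnot(upsample_factor >= 1, overlay_alpha >= 0, overlay_alpha <= 1)
  structure(
    list(upsample_factor = as.integer(upsample_factor),
         mask_outside_tissue = mask_outside_tissue,
         overlay_alpha = overlay_alpha,
         include_colorbar = include_colorbar),
    class = "heatmap_config"
  )
}

#' Interpolate the per-patch density field to a fine surface
#'
#' Bilinear interpolation between patch-center nodes: the surface passes
#' exactly through the node values and, by convexity of bilinear weights,
#' never leaves the range of the input densities. Fine cells beyond the
#' outermost patch centers take the nearest node value along the clamped
#' axis. When masking is on, cells whose centers fall outside the tissue are
#' set to NA (rendered transparent).
#'
#' @param grid a normalized `slide_grid` (densities set).
#' @param config a [heatmap_config()].
#' @param annotation optional matching [slide_annotation()], needed only for
#'   tissue masking.
#' @return numeric matrix (`(n_row-1)*upsample + 1` x
#'   `(n_col-1)*upsample + 1`) of interpolated densities in \[0, 1\], with
#'   patch-center node `(i, j)` at fine index `(i*upsample + 1,
#'   j*upsample + 1)`; NA outside tissue when masked; micron geometry
#'   attached as attributes `origin_um` and `cell_um`.
#' @export
interpolate_density_surface <- function(grid, config = heatmap_config(),
                                        annotation = NULL) {
  stopifnot(inherits(grid, "slide_grid"))
  if (anyNA(grid$patches$a)) stop("densities not set; run normalize_density() first")
  if (nrow(grid$patches) < 1L) stop("grid has no patches")
  # node matrix indexed [row, col]; QC-filtered grids may be sparse: missing
  # cells carry 0 density (they hold no counted TILs)
  a_mat <- matrix(0, grid$n_row, grid$n_col)
  a_mat[cbind(grid$patches$row + 1L, grid$patches$col + 1L)] <- grid$patches$a

  up <- config$upsample_factor
  s <- grid$config$patch_size_um
  # fine grid samples the node lattice inclusively: node (i, j) sits exactly
  # at fine index (i*up + 1, j*up + 1), so the surface passes through the
  # input densities by construction
  fr <- if (grid$n_row > 1L) (grid$n_row - 1L) * up + 1L else 1L
  fc <- if (grid$n_col > 1L) (grid$n_col - 1L) * up + 1L else 1L
  u <- (seq_len(fc) - 1) / up  # position in node units along columns
  v <- (seq_len(fr) - 1) / up
  ui <- pmax(pmin(floor(u), grid$n_col - 2L), 0L)
  vi <- pmax(pmin(floor(v), grid$n_row - 2L), 0L)
  tu <- u - ui; tv <- v - vi
  if (grid$n_col == 1L) { ui <- rep(0L, fc); tu <- rep(0, fc) }
  if (grid$n_row == 1L) { vi <- rep(0L, fr); tv <- rep(0, fr) }
  ui1 <- pmin(ui + 1L, grid$n_col - 1L)
  vi1 <- pmin(vi + 1L, grid$n_row - 1L)
  TU <- matrix(tu, fr, fc, byrow = TRUE)
  TV <- matrix(tv, fr, fc)
  A00 <- a_mat[cbind(rep(vi + 1L, times = fc), rep(ui + 1L, each = fr))]
  A01 <- a_mat[cbind(rep(vi + 1L, times = fc), rep(ui1 + 1L, each = fr))]
  A10 <- a_mat[cbind(rep(vi1 + 1L, times = fc), rep(ui + 1L, each = fr))]
  A11 <- a_mat[cbind(rep(vi1 + 1L, times = fc), rep(ui1 + 1L, each = fr))]
  dim(A00) <- dim(A01) <- dim(A10) <- dim(A11) <- c(fr, fc)
  surface <- (1 - TV) * ((1 - TU) * A00 + TU * A01) +
    TV * ((1 - TU) * A10 + TU * A11)
  surface <- pmin(pmax(surface, 0), 1)

  if (config$mask_outside_tissue && !is.null(annotation)) {
    polys_um <- lapply(annotation$tissue_polygons, function(p) {
      scale_polygon(p, annotation$mpp)
    })
    cellsz <- s / up
    # fine sample (r, k) sits at the patch-center lattice position
    cx <- grid$origin_um["x"] + 0.5 * s + (rep(seq_len(fc), times = fr) - 1) * cellsz
    cy <- grid$origin_um["y"] + 0.5 * s + (rep(seq_len(fr), each = fc) - 1) * cellsz
    inside <- points_in_polygons(cx, cy, polys_um)
    surface[!matrix(inside, fr, fc, byrow = TRUE)] <- NA_real_
  }
  attr(surface, "origin_um") <- grid$origin_um
  attr(surface, "cell_um") <- s / up
  surface
}

# fixed diverging blue -> red palette over [0, 1]; endpoints anchored so color
# is comparable across slides
density_palette <- function(n = 256L) {
  grDevices::colorRampPalette(
    c("#2166AC", "#67A9CF", "#F7F7F7", "#EF8A62", "#B2182B")
  )(n)
}

#' Render a density surface to a PNG heatmap
#'
#' Blue at density 0, red at density 1 with fixed colormap anchors; NA cells
#' are transparent (or show the background when one is supplied). Rendering
#' is a pure function of its inputs: the same surface and config produce
#' byte-identical files.
#'
#' @param surface matrix from [interpolate_density_surface()].
#' @param path output PNG path.
#' @param config a [heatmap_config()].
#' @param background optional background image (matrix or RGB array) of the
#'   same shape as `surface`, alpha-composited under the heatmap.
#' @return `path`, invisibly.
#' @export
render_heatmap <- function(surface, path, config = heatmap_config(),
                           background = NULL) {
  stopifnot(is.matrix(surface))
  pal <- density_palette()
  rgb_pal <- grDevices::col2rgb(pal) / 255
  idx <- pmin(pmax(round(surface * 255) + 1L, 1L), 256L)
  nr <- nrow(surface); nc <- ncol(surface)
  img <- array(0, dim = c(nr, nc, 4L))
  nav <- is.na(surface)
  for (ch in 1:3) {
    plane <- matrix(0, nr, nc)
    plane[!nav] <- rgb_pal[ch, idx[!nav]]
    img[, , ch] <- plane
  }
  img[, , 4][!nav] <- 1

  if (!is.null(background)) {
    if (is.matrix(background)) {
      background <- array(rep(background, 3), dim = c(dim(background), 3L))
    }
    if (!all(dim(background)[1:2] == c(nr, nc))) {
      stop("background shape ", paste(dim(background)[1:2], collapse = "x"),
           " does not match surface ", nr, "x", nc)
    }
    al <- config$overlay_alpha
    for (ch in 1:3) {
      fg <- img[, , ch]; bg <- background[, , ch]
      out <- bg
      out[!nav] <- al * fg[!nav] + (1 - al) * bg[!nav]
      img[, , ch] <- out
    }
    img[, , 4] <- 1
  }

  if (isTRUE(config$include_colorbar)) {
    bar_w <- max(4L, round(nc * 0.04))
    bar_vals <- seq(1, 0, length.out = nr)
    bar_idx <- pmin(pmax(round(bar_vals * 255) + 1L, 1L), 256L)
    bar <- array(1, dim = c(nr, bar_w + 2L, 4L))
    for (ch in 1:3) {
      bar[, 3:(bar_w + 2L), ch] <- matrix(rgb_pal[ch, bar_idx], nr, bar_w)
    }
    bar[, 1:2, 1:3] <- 1  # white separator
    ext <- array(0, dim = c(nr, nc + bar_w + 2L, 4L))
    ext[, seq_len(nc), ] <- img
    ext[, nc + seq_len(bar_w + 2L), ] <- bar
    img <- ext
  }
  png::writePNG(img, target = path)
  invisible(path)
}
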