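#' Patch-grid configuration
#'
#' @param patch_size_um sliding-window step and patch side, microns
#'   (default 100, the scale at which focal lymphoid aggregates span one to a
#'   few patches).
#' @param min_tissue_fraction optional QC fraction: when not `NULL`, patches
#'   whose tissue coverage is below this fraction are dropped from the grid
#'   (0.60 is the conventional choice). Off by default because this filter
#'   belongs to training-time image QC, not to scoring.
#' @return object of class `grid_config`.
#' @export
grid_config <- function(patch_size_um = 100, min_tissue_fraction = NULL) {
  stopifnot(patch_size_um > 0)
  if (!is.null(min_tissue_fraction)) {
    stopifnot(min_tissue_fraction >= 0, min_tissue_fraction <= 1)
  }
  structure(
    list(patch_size_um = patch_size_um,
         min_tissue_fraction = min_tissue_fraction),
    class = "grid_config"
  )
}

#' Build the patch grid over a slide
#'
#' Tiles the bounding box of the tissue polygons (in micron space) with
#' axis-aligned, non-overlapping squares of side `patch_size_um`: the sliding
#' window's step equals its size, so the grid is a partition and the score
#' denominator counts disjoint patches. Each patch is the half-open square
#' `[x0, x0 + s) x [y0, y0 + s)`; partial patches at the right/top edges are
#' retained. The grid is anchored at the bounding-box minimum corner, which
#' makes it deterministic.
#'
#' @param annotation a [slide_annotation()] with >= 1 tissue polygon.
#' @param config a [grid_config()].
#' @return object of class `slide_grid` whose `patches` data.frame has one
#'   row per grid cell (`row`, `col` 0-based, `x0_um`, `y0_um`) with counts
#'   unset.
#' @export
build_patch_grid <- function(annotation, config = grid_config()) {
  stopifnot(inherits(annotation, "slide_annotation"),
            inherits(config, "grid_config"))
  if (length(annotation$tissue_polygons) == 0L) {
    stop("annotation has no tissue polygons")
  }
  polys_um <- lapply(annotation$tissue_polygons, function(p) {
    scale_polygon(p, annotation$mpp)
  })
  bb <- polygons_bbox(polys_um)
  s <- config$patch_size_um
  n_col <- max(1L, ceiling((bb["xmax"] - bb["xmin"]) / s))
  n_row <- max(1L, ceiling((bb["ymax"] - bb["ymin"]) / s))
  patches <- data.frame(
    row = rep(seq_len(n_row) - 1L, each = n_col),
    col = rep(seq_len(n_col) - 1L, times = n_row)
  )
  patches$x0_um <- bb["xmin"] + patches$col * s
  patches$y0_um <- bb["ymin"] + patches$row * s
  patches$num_tils <- NA_integer_
  patches$a <- NA_real_
  patches$is_valid <- NA
  patches$is_high_attention <- NA
  rownames(patches) <- NULL

  if (!is.null(config$min_tissue_fraction)) {
    frac <- patch_tissue_fraction(patches, s, polys_um)
    patches$tissue_fraction <- frac
    patches <- patches[frac >= config$min_tissue_fraction, , drop = FALSE]
    rownames(patches) <- NULL
  }

  structure(
    list(
      slide_id = annotation$slide_id, config = config,
      origin_um = c(x = unname(bb["xmin"]), y = unname(bb["ymin"])),
      n_row = n_row, n_col = n_col,
      patches = patches, num_max = NA_integer_, degenerate = NA
    ),
    class = "slide_grid"
  )
}

# tissue coverage fraction per patch, estimated on a 5x5 subsample of points
patch_tissue_fraction <- function(patches, s, polys_um) {
  offs <- (seq_len(5L) - 0.5) / 5 * s
  grid_off <- expand.grid(dx = offs, dy = offs)
  frac <- numeric(nrow(patches))
  px <- rep(patches$x0_um, each = nrow(grid_off)) + rep(grid_off$dx, nrow(patches))
  py <- rep(patches$y0_um, each = nrow(grid_off)) + rep(grid_off$dy, nrow(patches))
  inside <- points_in_polygons(px, py, polys_um)
  colMeans(matrix(inside, nrow = nrow(grid_off)))
}

#' Count stromal TILs per patch
#'
#' A detection is counted iff its box center, converted to microns, lies
#' inside a tissue polygon AND outside every tumor polygon (the stromal
#' filter); each counted detection increments exactly one patch, the
#' half-open square containing its center (centers exactly on a shared
#' boundary go to the right/upper patch). `num_max` is set to the maximum
#' patch count and `is_valid` becomes TRUE exactly for patches holding at
#' least one counted TIL.
#'
#' @param grid a [build_patch_grid()] result for the same slide.
#' @param annotation the matching [slide_annotation()].
#' @return the `slide_grid` with `num_tils`, `is_valid` and `num_max` set.
#' @export
count_tils <- function(grid, annotation) {
  stopifnot(inherits(grid, "slide_grid"), inherits(annotation, "slide_annotation"))
  if (!identical(grid$slide_id, annotation$slide_id)) {
    stop("grid and annotation refer to different slides: ",
         grid$slide_id, " vs ", annotation$slide_id)
  }
  ctr <- detection_centers(annotation, unit = "um")
  keep <- stromal_filter(ctr, annotation)
  ctr <- ctr[keep, , drop = FALSE]

  s <- grid$config$patch_size_um
  col <- floor((ctr[, 1] - grid$origin_um["x"]) / s)
  row <- floor((ctr[, 2] - grid$origin_um["y"]) / s)
  # centers on the far bounding-box edge fall in the last (partial) patch
  col <- pmin(pmax(col, 0L), grid$n_col - 1L)
  row <- pmin(pmax(row, 0L), grid$n_row - 1L)

  key <- paste(grid$patches$row, grid$patches$col)
  tab <- table(factor(paste(row, col), levels = key))
  grid$patches$num_tils <- as.integer(tab)
  grid$num_max <- if (nrow(grid$patches) > 0L) max(grid$patches$num_tils) else 0L
  grid$patches$is_valid <- grid$patches$num_tils >= 1L
  grid
}

#' Stromal filter for detection centers
#'
#' @param centers_um two-column matrix of centers in microns.
#' @param annotation a [slide_annotation()].
#' @return logical: inside a tissue polygon and outside all tumor polygons.
#' @keywords internal
stromal_filter <- function(centers_um, annotation) {
  if (nrow(centers_um) == 0L) return(logical(0))
  tis <- lapply(annotation$tissue_polygons, function(p) {
    scale_polygon(p, annotation$mpp)
  })
  tum <- lapply(annotation$tumor_polygons, function(p) {
    scale_polygon(p, annotation$mpp)
  })
  ok <- points_in_polygons(centers_um[, 1], centers_um[, 2], tis)
  if (length(tum) > 0L && any(ok)) {
    ok[ok] <- !points_in_polygons(centers_um[ok, 1], centers_um[ok, 2], tum)
  }
  ok
}

#' Normalize per-patch densities
#'
#' Sets the relative lymphocyte density `a = num_tils / num_max` for every
#' patch, so densities are comparable within a slide on a 0-1 scale and the
#' densest patch always has `a = 1`. A slide with no counted TILs at all is
#' degenerate: every `a` is set to 0, the grid's `degenerate` flag is raised
#' and a warning emitted (its score downstream is 0 and its label
#' `Immunity_L`).
#'
#' @param grid a counted `slide_grid`.
#' @return the grid with `a` set and `degenerate` resolved.
#' @export
normalize_density <- function(grid) {
  stopifnot(inherits(grid, "slide_grid"))
  if (anyNA(grid$patches$num_tils)) {
    stop("counts not set; run count_tils() first")
  }
  if (is.na(grid$num_max) || grid$num_max == 0L) {
    grid$patches$a <- 0
    grid$degenerate <- TRUE
    warning("slide ", grid$slide_id,
            " has no counted TILs; all densities set to 0 (degenerate slide)")
  } else {
    grid$patches$a <- grid$patches$num_tils / grid$num_max
    grid$degenerate <- FALSE
  }
  grid
}

#' @export
print.slide_grid <- function(x, ...) {
  cat("<slide_grid> ", x$slide_id, ": ", x$n_row, " x ", x$n_col,
      " patches of ", x$config$patch_size_um, " um\n", sep = "")
  if (!anyNA(x$patches$num_tils)) {
    cat("  counted TILs: ", sum(x$patches$num_tils),
        " | num_max: ", x$num_max,
        " | valid patches: ", sum(x$patches$is_valid), "\n", sep = "")
  }
  invisible(x)
}

#' Export the per-patch table
#'
#' @param grid a `slide_grid`.
#' @param path optional CSV path; when given the table is also written.
#' @return the patch data.frame (row, col, x0_um, y0_um, num_tils, a,
#'   is_valid, is_high_attention).
#' @export
patch_table <- function(grid, path = NULL) {
  stopifnot(inherits(grid, "slide_grid"))
  out <- grid$patches
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
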