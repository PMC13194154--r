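#' Slide annotation container
#'
#' Holds everything the scoring pipeline needs to know about one whole-slide
#' image: the tissue contour polygon(s), tumor-parenchyma polygon(s), and TIL
#' detections, all in level-0 pixel coordinates, plus the microns-per-pixel
#' scale that links them to physical space. This mirrors what an automated
#' annotation pipeline (e.g. QuPath plus a cell detector) exports: geometry in
#' pixels, scale as metadata. All micron-space computation downstream converts
#' at the point of use via `um = px * mpp`.
#'
#' @param slide_id character scalar identifying the slide.
#' @param mpp microns per pixel, > 0.
#' @param tissue_polygons list of tissue-contour polygons (ring matrix, or
#'   list of rings with holes after the outer ring), level-0 pixel coords.
#' @param tumor_polygons list of tumor-parenchyma polygons, same format.
#' @param detections data.frame of TIL detections with columns `x_min`,
#'   `y_min`, `width`, `height` (pixels, width/height > 0) and optionally
#'   `confidence` in \[0, 1\]. Detection centers are
#'   `(x_min + width/2, y_min + height/2)`.
#' @return object of class `slide_annotation`.
#' @export
slide_annotation <- function(slide_id, mpp,
                             tissue_polygons = list(),
                             tumor_polygons = list(),
                             detections = empty_detections()) {
  stopifnot(is.character(slide_id), length(slide_id) == 1L)
  if (!is.numeric(mpp) || length(mpp) != 1L || !is.finite(mpp) || mpp <= 0) {
    stop("mpp must be a single positive number (microns per pixel)")
  }
  tissue_polygons <- lapply(tissue_polygons, validate_polygon)
  tumor_polygons <- lapply(tumor_polygons, validate_polygon)
  detections <- validate_detections(detections)
  structure(
    list(
      slide_id = slide_id, mpp = mpp,
      tissue_polygons = tissue_polygons,
      tumor_polygons = tumor_polygons,
      detections = detections
    ),
    class = "slide_annotation"
  )
}

# a polygon is a ring matrix or a list of rings (outer first)
validate_polygon <- function(poly) {
  if (is.list(poly)) lapply(poly, validate_ring) else validate_ring(poly)
}

empty_detections <- function() {
  data.frame(
    x_min = numeric(0), y_min = numeric(0),
    width = numeric(0), height = numeric(0),
    confidence = numeric(0)
  )
}

validate_detections <- function(det) {
  det <- as.data.frame(det)
  if (nrow(det) == 0L) return(empty_detections())
  req <- c("x_min", "y_min", "width", "height")
  if (!all(req %in% names(det))) {
    stop("detections need columns x_min, y_min, width, height")
  }
  if (any(det$width <= 0) || any(det$height <= 0)) {
    stop("detection width and height must be positive")
  }
  if (!"confidence" %in% names(det)) det$confidence <- NA_real_
  bad <- !is.na(det$confidence) & (det$confidence < 0 | det$confidence > 1)
  if (any(bad)) stop("detection confidence must lie in [0, 1]")
  det[, c(req, "confidence")]
}

#' Detection box centers
#'
#' @param annotation a [slide_annotation()].
#' @param unit `"px"` (level-0 pixels) or `"um"` (microns, via mpp).
#' @return two-column matrix of center coordinates.
#' @export
detection_centers <- function(annotation, unit = c("px", "um")) {
  unit <- match.arg(unit)
  det <- annotation$detections
  ctr <- cbind(
    x = det$x_min + det$width / 2,
    y = det$y_min + det$height / 2
  )
  if (unit == "um") ctr <- ctr * annotation$mpp
  ctr
}

#' @export
print.slide_annotation <- function(x, ...) {
  cat("<slide_annotation> ", x$slide_id, "\n", sep = "")
  cat("  mpp: ", x$mpp, " um/px\n", sep = "")
  cat("  tissue polygons: ", length(x$tissue_polygons),
      " | tumor polygons: ", length(x$tumor_polygons),
      " | TIL detections: ", nrow(x$detections), "\n", sep = "")
  invisible(x)
}

# ---- GeoJSON dialect -------------------------------------------------------
# QuPath-style FeatureCollection: each feature carries
# properties$classification$name in {"Tissue", "Tumor", "TIL"}; mpp and
# slide_id live in a top-level "metadata" block. Detections are written as
# rectangle Polygon features; Point features read back as boxes of a nominal
# size (lymphocyte-nucleus scale) centered on the point.

ring_to_coords <- function(ring) {
  ring <- close_ring(ring)
  lapply(seq_len(nrow(ring)), function(i) c(ring[i, 1], ring[i, 2]))
}

polygon_to_geometry <- function(poly) {
  rings <- if (is.list(poly)) poly else list(poly)
  list(
    type = "Polygon",
    coordinates = lapply(rings, ring_to_coords)
  )
}

coords_to_ring <- function(coords) {
  close_ring(do.call(rbind, lapply(coords, function(p) as.numeric(p[1:2]))))
}

#' Write a slide annotation as QuPath-compatible GeoJSON
#'
#' Produces an RFC 7946 FeatureCollection whose features carry
#' `properties.classification.name` set to `"Tissue"`, `"Tumor"` or `"TIL"`,
#' with `mpp` and `slide_id` in a top-level `metadata` block. The output
#' round-trips through [read_annotations()] exactly (up to floating-point
#' text representation).
#'
#' @param annotation a [slide_annotation()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotation, path) {
  stopifnot(inherits(annotation, "slide_annotation"))
  feat <- list()
  add <- function(geometry, class_name) {
    list(
      type = "Feature",
      geometry = geometry,
      properties = list(classification = list(name = class_name))
    )
  }
  for (p in annotation$tissue_polygons) {
    feat[[length(feat) + 1L]] <- add(polygon_to_geometry(p), "Tissue")
  }
  for (p in annotation$tumor_polygons) {
    feat[[length(feat) + 1L]] <- add(polygon_to_geometry(p), "Tumor")
  }
  det <- annotation$detections
  for (i in seq_len(nrow(det))) {
    ring <- rbind(
      c(det$x_min[i], det$y_min[i]),
      c(det$x_min[i] + det$width[i], det$y_min[i]),
      c(det$x_min[i] + det$width[i], det$y_min[i] + det$height[i]),
      c(det$x_min[i], det$y_min[i] + det$height[i])
    )
    f <- add(polygon_to_geometry(ring), "TIL")
    if (!is.na(det$confidence[i])) {
      f$properties$confidence <- det$confidence[i]
    }
    feat[[length(feat) + 1L]] <- f
  }
  doc <- list(
    type = "FeatureCollection",
    metadata = list(slide_id = annotation$slide_id, mpp = annotation$mpp),
    features = feat
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}

#' Read a slide annotation from QuPath-compatible GeoJSON/JSON
#'
#' Features are mapped by `properties.classification.name`: `"Tissue"` to
#' tissue polygons, `"Tumor"` to tumor polygons, `"TIL"` to detections.
#' Point-geometry TILs become boxes of nominal physical size
#' `point_box_um` centered on the point; Polygon-geometry TILs take their
#' bounding box. Features with any other class are counted and reported via a
#' warning, never silently dropped: accepted + unknown always equals the input
#' feature count.
#'
#' @param path file to read.
#' @param mpp_override microns per pixel to use when the file lacks metadata
#'   (or to force; a file value takes precedence unless `force_mpp = TRUE`).
#' @param force_mpp logical; when TRUE, `mpp_override` wins over file metadata.
#' @param point_box_um nominal box side, microns, for Point-geometry TILs
#'   (default 8, the scale of a lymphocyte nucleus).
#' @param slide_id optional slide id override; default from metadata or the
#'   file name.
#' @return a [slide_annotation()].
#' @export
read_annotations <- function(path, mpp_override = NULL, force_mpp = FALSE,
                             point_box_um = 8, slide_id = NULL) {
  if (!file.exists(path)) stop("annotation file does not exist: ", path)
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$type) || !identical(doc$type, "FeatureCollection")) {
    stop("not a GeoJSON FeatureCollection: ", path)
  }
  mpp <- doc$metadata$mpp
  if (isTRUE(force_mpp) || is.null(mpp)) mpp <- mpp_override
  if (is.null(mpp)) {
    stop("no mpp in file metadata and no mpp_override supplied: ", path)
  }
  mpp <- as.numeric(mpp)
  if (is.null(slide_id)) {
    slide_id <- doc$metadata$slide_id
    if (is.null(slide_id)) {
      slide_id <- sub("\\.(geo)?json$", "", basename(path), ignore.case = TRUE)
    }
  }

  tissue <- list(); tumor <- list()
  det <- list()
  unknown <- character(0)
  half <- (point_box_um / mpp) / 2  # nominal half-side in pixels

  for (f in doc$features) {
    cls <- f$properties$classification$name
    if (is.null(cls)) cls <- "<unclassified>"
    geom <- f$geometry
    if (identical(cls, "Tissue") || identical(cls, "Tumor")) {
      rings <- lapply(geom$coordinates, coords_to_ring)
      poly <- if (length(rings) == 1L) rings[[1]] else rings
      if (identical(cls, "Tissue")) tissue[[length(tissue) + 1L]] <- poly
      else tumor[[length(tumor) + 1L]] <- poly
    } else if (identical(cls, "TIL")) {
      conf <- f$properties$confidence
      conf <- if (is.null(conf)) NA_real_ else as.numeric(conf)
      if (identical(geom$type, "Point")) {
        xy <- as.numeric(geom$coordinates[1:2])
        det[[length(det) + 1L]] <- data.frame(
          x_min = xy[1] - half, y_min = xy[2] - half,
          width = 2 * half, height = 2 * half, confidence = conf
        )
      } else if (identical(geom$type, "Polygon")) {
        ring <- coords_to_ring(geom$coordinates[[1]])
        det[[length(det) + 1L]] <- data.frame(
          x_min = min(ring[, 1]), y_min = min(ring[, 2]),
          width = max(ring[, 1]) - min(ring[, 1]),
          height = max(ring[, 2]) - min(ring[, 2]),
          confidence = conf
        )
      } else {
        unknown <- c(unknown, paste0("TIL/", geom$type))
      }
    } else {
      unknown <- c(unknown, cls)
    }
  }
  if (length(unknown) > 0L) {
    tab <- table(unknown)
    warning(
      length(unknown), " feature(s) with unrecognized class ignored: ",
      paste(sprintf("%s (%d)", names(tab), as.integer(tab)), collapse = ", ")
    )
  }
  slide_annotation(
    slide_id = slide_id, mpp = mpp,
    tissue_polygons = tissue, tumor_polygons = tumor,
    detections = if (length(det)) do.call(rbind, det) else empty_detections()
  )
}
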