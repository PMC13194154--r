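#' Simulation configuration for one synthetic slide
#'
#' Describes the geometry and the spatial point process used to place TILs on
#' a synthetic slide. Stromal TILs are the superposition of a homogeneous
#' Poisson background (rate `background_intensity`, cells per mm^2 of stroma)
#' and a Thomas-type cluster process: cluster parents follow a Poisson process
#' with rate `cluster_parent_intensity` (parents per mm^2), each parent
#' spawns a Poisson(`cluster_mean_size`) number of offspring displaced by an
#' isotropic Gaussian with standard deviation `cluster_sd_um` microns.
#' Offspring falling outside the stroma (outside tissue or inside tumor
#' parenchyma) are rejected, so realized detections always respect the
#' stromal compartment.
#'
#' @param slide_width_um,slide_height_um slide frame, microns.
#' @param mpp microns per pixel of the emitted annotation coordinates.
#' @param tissue_shape `"rounded_rect"` (default; inset rounded rectangle),
#'   `"rect"` (inset rectangle), or a ring matrix in micron coordinates.
#' @param tissue_inset_frac fractional inset of the tissue contour from the
#'   slide bounds on each side (ignored for an explicit ring).
#' @param tumor_fraction target fraction of tissue area covered by tumor
#'   polygons, in \[0, 1).
#' @param background_intensity TIL background rate, cells/mm^2 of stroma.
#' @param cluster_parent_intensity hotspot parent rate, parents/mm^2.
#' @param cluster_mean_size mean offspring per parent (>= 0).
#' @param cluster_sd_um offspring dispersion, microns.
#' @param det_box_um side of the emitted square detection boxes, microns
#'   (approximate lymphocyte nucleus; downstream rules consume box centers).
#' @param seed integer RNG seed; the realization is a pure function of the
#'   config including this seed.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(slide_width_um = 3000, slide_height_um = 3000,
                              mpp = 0.5,
                              tissue_shape = "rounded_rect",
                              tissue_inset_frac = 0.08,
                              tumor_fraction = 0.2,
                              background_intensity = 120,
                              cluster_parent_intensity = 0,
                              cluster_mean_size = 0,
                              cluster_sd_um = 30,
                              det_box_um = 8,
                              seed = 1L) {
  if (slide_width_um <= 0 || slide_height_um <= 0) {
    stop("slide dimensions must be positive")
  }
  if (mpp <= 0) stop("mpp must be positive")
  if (tumor_fraction < 0 || tumor_fraction >= 1) {
    stop("tumor_fraction must lie in [0, 1)")
  }
  if (background_intensity < 0 || cluster_parent_intensity < 0 ||
      cluster_mean_size < 0 || cluster_sd_um < 0) {
    stop("intensities, cluster size and dispersion must be non-negative")
  }
  structure(
    list(
      slide_width_um = slide_width_um, slide_height_um = slide_height_um,
      mpp = mpp, tissue_shape = tissue_shape,
      tissue_inset_frac = tissue_inset_frac,
      tumor_fraction = tumor_fraction,
      background_intensity = background_intensity,
      cluster_parent_intensity = cluster_parent_intensity,
      cluster_mean_size = cluster_mean_size,
      cluster_sd_um = cluster_sd_um,
      det_box_um = det_box_um,
      seed = seed
    ),
    class = "simulation_config"
  )
}

#' Preset: high-immunity slide
#'
#' Study condition for an immunologically "hot" slide: the same sparse
#' stromal background as the low preset, plus abundant dense lymphoid foci
#' (many cluster parents, large clusters). Under the patch-grid scoring rule
#' these slides carry a clear majority of their high-attention patches in the
#' foci and score well above the 0.05 cutoff.
#'
#' @param seed integer RNG seed.
#' @param ... overrides passed to [simulation_config()].
#' @return a `simulation_config`.
#' @export
high_immunity_config <- function(seed = 1L, ...) {
  simulation_config(
    background_intensity = 80,
    cluster_parent_intensity = 4,
    cluster_mean_size = 80,
    cluster_sd_um = 40,
    seed = seed, ...
  )
}

#' Preset: low-immunity slide
#'
#' Study condition for an immunologically "cold" slide: sparse homogeneous
#' stromal background with only rare, small lymphoid foci. The few foci pin
#' the per-slide maximum patch count high enough that ordinary background
#' patches normalize well below the 0.2 attention threshold, which is the
#' regime real low-immunity slides occupy (slide scores a few percent). A
#' strictly focus-free homogeneous field would instead have a small maximum
#' count and degenerate under max-normalization; see the methods vignette.
#'
#' @param seed integer RNG seed.
#' @param ... overrides passed to [simulation_config()].
#' @return a `simulation_config`.
#' @export
low_immunity_config <- function(seed = 1L, ...) {
  simulation_config(
    background_intensity = 80,
    cluster_parent_intensity = 0.8,
    cluster_mean_size = 60,
    cluster_sd_um = 15,
    seed = seed, ...
  )
}

# tissue ring in micron coordinates for a config
tissue_ring_um <- function(config) {
  if (is.matrix(config$tissue_shape)) return(close_ring(config$tissue_shape))
  w <- config$slide_width_um; h <- config$slide_height_um
  ix <- w * config$tissue_inset_frac; iy <- h * config$tissue_inset_frac
  switch(config$tissue_shape,
    rounded_rect = rounded_rect(ix, iy, w - 2 * ix, h - 2 * iy,
                                radius = min(w, h) / 10),
    rect = close_ring(rbind(
      c(ix, iy), c(w - ix, iy), c(w - ix, h - iy), c(ix, h - iy)
    )),
    stop("unknown tissue_shape: ", config$tissue_shape)
  )
}

# place tumor discs inside the tissue until the target area fraction is met;
# disc centers are rejection-sampled so every vertex stays inside the tissue
place_tumor_polygons <- function(tissue, target_area, slide_w, slide_h) {
  if (target_area <= 0) return(list())
  polys <- list()
  area <- 0
  r0 <- min(slide_w, slide_h) / 14
  attempts <- 0L
  while (area < target_area && attempts < 2000L) {
    attempts <- attempts + 1L
    r <- r0 * stats::runif(1, 0.7, 1.3)
    cx <- stats::runif(1, 0, slide_w)
    cy <- stats::runif(1, 0, slide_h)
    ring <- circle_ring(cx, cy, r, n = 32L)
    if (all(points_in_ring(ring[, 1], ring[, 2], tissue))) {
      polys[[length(polys) + 1L]] <- ring
      area <- area + polygon_area(ring)
    }
  }
  polys
}

#' Simulate one annotated synthetic slide
#'
#' Generates a tissue contour, tumor-parenchyma polygons inside it, and TIL
#' detections placed only in the stroma (inside tissue, outside every tumor
#' polygon) by a homogeneous Poisson background superposed with a Thomas-type
#' cluster process (see [simulation_config()]). Points are simulated over the
#' slide frame and restricted to stroma by rejection, so under pure Poisson
#' settings the expected detection count equals
#' `background_intensity * stroma area (mm^2)`. The realization is
#' deterministic given the config (including its seed).
#'
#' @param config a [simulation_config()].
#' @param slide_id identifier for the emitted annotation.
#' @return a [slide_annotation()] in level-0 pixel coordinates with the
#'   config's `mpp`.
#' @export
simulate_slide <- function(config, slide_id = "synthetic") {
  stopifnot(inherits(config, "simulation_config"))
  local_seed(config$seed, {
    tissue <- tissue_ring_um(config)
    tissue_area <- polygon_area(tissue)
    tumors <- place_tumor_polygons(
      tissue, config$tumor_fraction * tissue_area,
      config$slide_width_um, config$slide_height_um
    )

    in_stroma <- function(x, y) {
      ok <- points_in_ring(x, y, tissue)
      if (length(tumors) > 0L && any(ok)) {
        ok[ok] <- !points_in_polygons(x[ok], y[ok], tumors)
      }
      ok
    }

    bbox_mm2 <- (config$slide_width_um * config$slide_height_um) / 1e6
    # background: homogeneous Poisson over the frame, thinned to stroma
    n_bg <- stats::rpois(1L, config$background_intensity * bbox_mm2)
    bx <- stats::runif(n_bg, 0, config$slide_width_um)
    by <- stats::runif(n_bg, 0, config$slide_height_um)
    keep <- in_stroma(bx, by)
    px <- bx[keep]; py <- by[keep]

    # Thomas clusters: Poisson parents over the frame retained inside tissue,
    # Poisson(cluster_mean_size) Gaussian-displaced offspring thinned to stroma
    n_par <- stats::rpois(1L, config$cluster_parent_intensity * bbox_mm2)
    if (n_par > 0L && config$cluster_mean_size > 0) {
      pxp <- stats::runif(n_par, 0, config$slide_width_um)
      pyp <- stats::runif(n_par, 0, config$slide_height_um)
      in_tis <- points_in_ring(pxp, pyp, tissue)
      for (i in which(in_tis)) {
        n_off <- stats::rpois(1L, config$cluster_mean_size)
        if (n_off == 0L) next
        ox <- stats::rnorm(n_off, pxp[i], config$cluster_sd_um)
        oy <- stats::rnorm(n_off, pyp[i], config$cluster_sd_um)
        keep <- in_stroma(ox, oy)
        px <- c(px, ox[keep]); py <- c(py, oy[keep])
      }
    }

    s <- config$det_box_um
    det <- if (length(px) > 0L) {
      data.frame(
        x_min = (px - s / 2) / config$mpp,
        y_min = (py - s / 2) / config$mpp,
        width = s / config$mpp, height = s / config$mpp,
        confidence = NA_real_
      )
    } else {
      empty_detections()
    }
    to_px <- function(ring) ring / config$mpp
    slide_annotation(
      slide_id = slide_id, mpp = config$mpp,
      tissue_polygons = list(to_px(tissue)),
      tumor_polygons = lapply(tumors, to_px),
      detections = det
    )
  })
}

#' Cohort specification for synthetic slides
#'
#' @param n_high,n_low numbers of high-/low-immunity slides (>= 0).
#' @param high_config,low_config [simulation_config()] presets used for each
#'   group; their own `seed` fields are ignored in favor of per-slide seeds
#'   derived from `seed`.
#' @param seed integer base seed; slide `i` of the cohort runs under a seed
#'   derived deterministically from `seed` and `i`.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_high, n_low,
                        high_config = high_immunity_config(),
                        low_config = low_immunity_config(),
                        seed = 1L) {
  stopifnot(n_high >= 0, n_low >= 0)
  structure(
    list(
      n_high = as.integer(n_high), n_low = as.integer(n_low),
      high_config = high_config, low_config = low_config,
      seed = seed
    ),
    class = "cohort_spec"
  )
}

#' Simulate a labelled cohort of synthetic slides
#'
#' @param spec a [cohort_spec()].
#' @return list with `annotations` (list of [slide_annotation()]) and
#'   `labels` (character, `"Immunity_H"` / `"Immunity_L"`, one per slide).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_high + spec$n_low
  annotations <- vector("list", n)
  labels <- character(n)
  for (i in seq_len(n)) {
    is_high <- i <= spec$n_high
    config <- if (is_high) spec$high_config else spec$low_config
    config$seed <- derive_seed(spec$seed, i)
    labels[i] <- if (is_high) "Immunity_H" else "Immunity_L"
    annotations[[i]] <- simulate_slide(
      config,
      slide_id = sprintf("synthetic_%s_%02d",
                         if (is_high) "H" else "L", i)
    )
  }
  list(annotations = annotations, labels = labels)
}

#' IHC field-count simulation specification
#'
#' Per-group, per-marker means and SDs of positive-cell counts per 400x
#' high-power field. The defaults are set to the magnitudes reported for the
#' four-marker panel (CD3, CD8, CD20, CD68) in high- vs low-immunity lung
#' adenocarcinoma; CD20 was reported as median (IQR) and its SD default is
#' IQR/1.349 under a normal approximation.
#'
#' @param params data.frame with columns `marker`, `group` (`"high"`/`"low"`),
#'   `mean`, `sd`; defaults as above.
#' @param n_fields fields counted per case (>= 3 so trimming is defined).
#' @param family `"truncnorm"` (normal, truncated at 0, rounded to integers)
#'   or `"nbinom"` (negative binomial moment-matched to mean/SD).
#' @param seed integer RNG seed.
#' @return object of class `ihc_sim_spec`.
#' @export
ihc_sim_spec <- function(params = NULL, n_fields = 10L,
                         family = c("truncnorm", "nbinom"), seed = 1L) {
  family <- match.arg(family)
  if (is.null(params)) {
    params <- data.frame(
      marker = rep(c("CD3", "CD8", "CD20", "CD68"), each = 2L),
      group = rep(c("high", "low"), times = 4L),
      mean = c(112.84, 44.98, 22.98, 8.56, 83.25, 37.00, 61.28, 40.89),
      sd = c(28.76, 23.45, 12.67, 7.89, 33.26, 26.50, 24.56, 22.13)
    )
  }
  stopifnot(all(c("marker", "group", "mean", "sd") %in% names(params)))
  if (any(params$mean < 0) || any(params$sd < 0)) {
    stop("means and SDs must be non-negative")
  }
  if (n_fields < 3L) stop("n_fields must be >= 3 (trimming needs >= 3)")
  structure(
    list(params = params, n_fields = as.integer(n_fields),
         family = family, seed = seed),
    class = "ihc_sim_spec"
  )
}

#' Simulate an IHC field-count cohort
#'
#' Draws `n_fields` non-negative integer field counts per case and marker
#' from the configured family, for `n_cases_per_group` cases in each of the
#' high and low groups. Deterministic given the specification's seed field.
#'
#' @param spec an [ihc_sim_spec()].
#' @param n_cases_per_group cases per group.
#' @return long data.frame with columns `case_id`, `group`, `marker`,
#'   `field_index`, `count`.
#' @export
simulate_ihc_cohort <- function(spec, n_cases_per_group = 30L) {
  stopifnot(inherits(spec, "ihc_sim_spec"), n_cases_per_group >= 1L)
  local_seed(spec$seed, {
    rows <- list()
    case_no <- 0L
    for (grp in c("high", "low")) {
      for (ci in seq_len(n_cases_per_group)) {
        case_no <- case_no + 1L
        case_id <- sprintf("case_%s_%02d", grp, ci)
        for (mk in unique(spec$params$marker)) {
          p <- spec$params[spec$params$marker == mk & spec$params$group == grp, ]
          if (nrow(p) != 1L) stop("missing parameters for ", mk, "/", grp)
          counts <- draw_field_counts(spec$family, spec$n_fields, p$mean, p$sd)
          rows[[length(rows) + 1L]] <- data.frame(
            case_id = case_id, group = grp, marker = mk,
            field_index = seq_len(spec$n_fields), count = counts
          )
        }
      }
    }
    do.call(rbind, rows)
  })
}

draw_field_counts <- function(family, n, mean, sd) {
  if (sd == 0) return(rep(round(mean), n))
  if (family == "truncnorm") {
    pmax(0L, as.integer(round(stats::rnorm(n, mean, sd))))
  } else {
    if (sd^2 > mean && mean > 0) {
      size <- mean^2 / (sd^2 - mean)
      stats::rnbinom(n, size = size, mu = mean)
    } else {
      stats::rpois(n, mean)
    }
  }
}

#' Render a synthetic raster image for a slide annotation
#'
#' Rasterizes the tissue compartment as a tinted, noise-textured region on a
#' near-white background, as a fixture for the classical tissue-mask stage.
#' The ground-truth tissue mask is returned alongside.
#'
#' @param annotation a [slide_annotation()] with >= 1 tissue polygon.
#' @param mpp_out pixel size of the output raster, microns per pixel.
#' @param noise_sd SD of the additive Gaussian texture (0 disables it).
#' @param seed RNG seed for the texture.
#' @return list with `image` (height x width x 3 array in \[0, 1\]) and
#'   `mask` (logical height x width ground-truth tissue matrix), plus
#'   `mpp_out`.
#' @export
render_synthetic_image <- function(annotation, mpp_out = 8, noise_sd = 0.02,
                                   seed = 1L) {
  stopifnot(inherits(annotation, "slide_annotation"))
  if (length(annotation$tissue_polygons) == 0L) {
    stop("annotation has no tissue polygons")
  }
  polys_um <- lapply(annotation$tissue_polygons, function(p) {
    scale_polygon(p, annotation$mpp)
  })
  bb <- polygons_bbox(polys_um)
  width <- max(1L, ceiling(bb["xmax"] / mpp_out + 2))
  height <- max(1L, ceiling(bb["ymax"] / mpp_out + 2))
  cx <- (rep(seq_len(width), times = height) - 0.5) * mpp_out
  cy <- (rep(seq_len(height), each = width) - 0.5) * mpp_out
  inside <- points_in_polygons(cx, cy, polys_um)
  mask <- matrix(inside, nrow = height, ncol = width, byrow = TRUE)
  tint <- c(0.82, 0.70, 0.78)  # eosin-like
  img <- array(0.97, dim = c(height, width, 3L))
  local_seed(seed, {
    for (ch in 1:3) {
      plane <- matrix(0.97, height, width)
      val <- tint[ch]
      if (noise_sd > 0) {
        plane[mask] <- pmin(1, pmax(0, stats::rnorm(sum(mask), val, noise_sd)))
      } else {
        plane[mask] <- val
      }
      img[, , ch] <- plane
    }
  })
  list(image = img, mask = mask, mpp_out = mpp_out)
}

# polygon (ring or ring-list) scaled by a factor
scale_polygon <- function(poly, f) {
  if (is.list(poly)) lapply(poly, function(r) close_ring(r) * f)
  else close_ring(poly) * f
}
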