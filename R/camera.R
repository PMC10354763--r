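# Camera model and renderer: turns a platform state into a camera-like
# H x W x 3 frame plus exact ground-truth bounding boxes, emulating the
# training-image conditions of the real rig (transparent low-contrast
# droplets, dark particle mounds, colored reagent droplets, 25-1000 lux).

#' Camera model
#'
#' @param pixels_per_mm image scale; the default 10 px/mm turns the
#'   40 x 40 mm field of view into 400 x 400 px frames. All pixel thresholds
#'   in the control layer (10 px tolerance, 20 px overshoot, 3 px merge
#'   growth) live in this pixel space: 0-based, origin top-left, y downward.
#' @param image_width,image_height frame size in px.
#' @param illumination scene illumination in lux, `[25, 1000]`.
#' @param background_rgb background color; `NULL` derives a neutral gray from
#'   the illumination via `40 + 180 * (lux - 25) / 975` (an arbitrary but
#'   monotone map).
#' @param noise_sd optional Gaussian pixel noise SD (default 0 = off).
#' @return a `camera_model` object.
#' @export
camera_model <- function(pixels_per_mm = 10, image_width = 400,
                         image_height = 400, illumination = 400,
                         background_rgb = NULL, noise_sd = 0) {
  stopifnot(pixels_per_mm > 0, image_width > 0, image_height > 0)
  if (illumination < 25 || illumination > 1000)
    stop("illumination must lie in [25, 1000] lux")
  if (is.null(background_rgb)) {
    g <- illumination_gray(illumination)
    background_rgb <- c(g, g, g)
  }
  structure(list(pixels_per_mm = pixels_per_mm, image_width = image_width,
                 image_height = image_height, illumination = illumination,
                 background_rgb = as.numeric(background_rgb),
                 noise_sd = noise_sd),
            class = "camera_model")
}

#' Background gray level for a given illumination
#' @param lux illumination in lux.
#' @return gray level in `[0, 255]`.
#' @export
illumination_gray <- function(lux) {
  pmin(255, pmax(0, 40 + 180 * (lux - 25) / (1000 - 25)))
}

mm_to_px <- function(camera, point_mm) point_mm * camera$pixels_per_mm
px_to_mm <- function(camera, point_px) point_px / camera$pixels_per_mm

RIM_BOOST <- 25       # transparent droplet rim intensity over background
RIM_THICKNESS_MM <- 0.25
CLUSTER_GRAY <- 15    # particle mounds are nearly black

# geometric semi-axes (mm) of a droplet as drawn; `aspect` squashes the
# footprint area-preservingly to emulate oblique camera angles
droplet_axes <- function(d, aspect = 1) {
  r <- footprint_radius(d$volume)
  c(rx = r * aspect, ry = r / aspect)
}

#' Exact ground-truth boxes for a platform state
#'
#' Re-derives, from geometry alone, the bounding boxes the renderer draws;
#' the renderer's annotations always equal this (the annotation-geometry
#' consistency contract).
#'
#' @param state a [platform_state()].
#' @param camera a [camera_model()].
#' @param aspect droplet aspect-ratio distortion used at render time.
#' @return list of `list(class_label, box, id)`; objects whose box falls
#'   entirely outside the frame are dropped.
#' @export
ground_truth_boxes <- function(state, camera, aspect = 1) {
  out <- list()
  for (d in state$droplets) {
    ax <- droplet_axes(d, aspect)
    out <- c(out, gt_box_entry("droplet", d$id, d$center, ax["rx"], ax["ry"], camera))
  }
  for (cl in state$clusters) {
    r <- cluster_radius(cl$volume)
    out <- c(out, gt_box_entry("particle", cl$id, cl$center, r, r, camera))
  }
  out
}

gt_box_entry <- function(class_label, id, center_mm, rx_mm, ry_mm, camera) {
  c_px <- mm_to_px(camera, center_mm)
  r_px <- c(rx_mm, ry_mm) * camera$pixels_per_mm
  raw <- c(c_px[1] - r_px[1], c_px[2] - r_px[2],
           c_px[1] + r_px[1], c_px[2] + r_px[2])
  b <- tryCatch(clip_bbox(bbox(max(0, raw[1]), max(0, raw[2]),
                               max(raw[1] + 0.1, raw[3]), max(raw[2] + 0.1, raw[4])),
                          camera$image_width, camera$image_height),
                error = function(e) NULL)
  if (is.null(b)) return(list())
  list(list(class_label = class_label, box = b, id = id))
}

#' Render a platform state into an annotated frame
#'
#' Transparent droplets are drawn as a faint bright rim over an unchanged
#' background (deliberately low contrast, the hard case for detection);
#' reagent-colored droplets are filled with their RGB color; particle
#' clusters are dark filled mounds drawn on top. Background brightness
#' scales monotonically with illumination. Annotations are the exact
#' geometric boxes of the drawn objects.
#'
#' @param state a [platform_state()].
#' @param camera a [camera_model()].
#' @param aspect droplet aspect-ratio distortion (1 = circular).
#' @param frame_id token recorded on the frame.
#' @return an `annotated_frame`: list with `frame_id`, `image`
#'   (`H x W x 3` array in `[0, 255]`), `annotations` (as
#'   [ground_truth_boxes()]), `camera`, `provenance`.
#' @export
render <- function(state, camera, aspect = 1, frame_id = "frame") {
  H <- camera$image_height; W <- camera$image_width
  img <- array(0, dim = c(H, W, 3))
  for (ch in 1:3) img[, , ch] <- camera$background_rgb[ch]

  for (d in state$droplets) {
    ax <- droplet_axes(d, aspect)
    c_px <- mm_to_px(camera, d$center)
    rx <- ax["rx"] * camera$pixels_per_mm
    ry <- ax["ry"] * camera$pixels_per_mm
    if (is.null(d$color)) {
      # transparent: bright rim annulus only
      rim_px <- RIM_THICKNESS_MM * camera$pixels_per_mm
      rim_col <- pmin(255, camera$background_rgb + RIM_BOOST)
      img <- paint_ellipse(img, c_px, rx, ry, rim_col,
                           inner_scale = 1 - rim_px / max(rx, ry))
    } else {
      img <- paint_ellipse(img, c_px, rx, ry, d$color)
    }
  }
  for (cl in state$clusters) {
    r_px <- cluster_radius(cl$volume) * camera$pixels_per_mm
    c_px <- mm_to_px(camera, cl$center)
    img <- paint_ellipse(img, c_px, r_px, r_px, rep(CLUSTER_GRAY, 3))
  }
  if (camera$noise_sd > 0) {
    img <- img + array(stats::rnorm(length(img), sd = camera$noise_sd), dim = dim(img))
    img <- pmin(255, pmax(0, img))
  }
  structure(list(frame_id = frame_id, image = img,
                 annotations = ground_truth_boxes(state, camera, aspect),
                 camera = camera,
                 provenance = list(time = state$time, aspect = aspect)),
            class = "annotated_frame")
}

# fill an ellipse (or an annulus when inner_scale in (0,1)) with `col`
paint_ellipse <- function(img, center_px, rx, ry, col, inner_scale = NULL) {
  H <- dim(img)[1]; W <- dim(img)[2]
  # pixel (row i, col j) has center (j - 0.5, i - 0.5) in 0-based px coords
  j0 <- max(1L, floor(center_px[1] - rx) + 1L)
  j1 <- min(W, ceiling(center_px[1] + rx) + 1L)
  i0 <- max(1L, floor(center_px[2] - ry) + 1L)
  i1 <- min(H, ceiling(center_px[2] + ry) + 1L)
  if (j0 > j1 || i0 > i1) return(img)
  xs <- (j0:j1) - 0.5; ys <- (i0:i1) - 0.5
  dx2 <- ((xs - center_px[1]) / rx)^2
  dy2 <- ((ys - center_px[2]) / ry)^2
  q <- outer(dy2, dx2, `+`)
  mask <- q <= 1
  if (!is.null(inner_scale) && inner_scale > 0)
    mask <- mask & (q > inner_scale^2)
  if (!any(mask)) return(img)
  for (ch in 1:3) {
    sl <- img[i0:i1, j0:j1, ch]
    sl[mask] <- col[ch]
    img[i0:i1, j0:j1, ch] <- sl
  }
  img
}

#' @export
print.annotated_frame <- function(x, ...) {
  cat(sprintf("<annotated_frame> %s: %dx%d px, %d annotation(s)\n",
              x$frame_id, dim(x$image)[2], dim(x$image)[1],
              length(x$annotations)))
  invisible(x)
}
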