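# Classical two-class detector standing in for the trained neural detector.
# Particles are dark, unsaturated compact blobs; colored droplets are
# saturated regions; transparent droplets are faint bright rims. The
# detector sees only the pixel array — never the simulator state — so the
# control loop above it is genuinely image-fed.

#' Detector parameters
#'
#' @param particle_min_area,particle_max_area component area limits (px^2)
#'   for the dark-blob particle channel.
#' @param particle_chroma_max max channel spread for a pixel to count as
#'   unsaturated (particles are gray-black).
#' @param droplet_chroma_min min channel spread for the colored-droplet
#'   channel.
#' @param droplet_min_area min component area for droplet channels.
#' @param rim_delta intensity above the background median for rim pixels.
#' @param min_box_px reject droplet components narrower than this.
#' @return parameter list.
#' @export
detect_params <- function(particle_min_area = 12, particle_max_area = 4000,
                          particle_chroma_max = 30, droplet_chroma_min = 40,
                          droplet_min_area = 40, rim_delta = 12,
                          min_box_px = 6) {
  as.list(environment())
}

#' Detect droplets and particles in a frame
#'
#' @param image `H x W x 3` array in `[0, 255]` (or an `annotated_frame`).
#' @param params a [detect_params()] list.
#' @return list of [detection()] objects (empty when nothing is found).
#' @export
detect <- function(image, params = detect_params()) {
  if (inherits(image, "annotated_frame")) image <- image$image
  if (length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("detect expects an H x W x 3 image array")
  H <- dim(image)[1]; W <- dim(image)[2]
  gray <- (image[, , 1] + image[, , 2] + image[, , 3]) / 3
  mx <- pmax(image[, , 1], image[, , 2], image[, , 3])
  mn <- pmin(image[, , 1], image[, , 2], image[, , 3])
  chroma <- mx - mn
  bg <- stats::median(gray)

  out <- list()

  # particles: dark and unsaturated
  pm <- (gray < pmin(0.55 * bg + 5, bg - 8)) & (chroma < params$particle_chroma_max)
  for (comp in label_components(pm, gray)) {
    if (comp$area < params$particle_min_area ||
        comp$area > params$particle_max_area) next
    conf <- min(1, max(0.05, (bg - comp$vmin) / 120))
    out[[length(out) + 1L]] <- detection("particle", comp$box, conf)
  }

  # colored reagent droplets: saturated regions
  cm <- chroma >= params$droplet_chroma_min
  for (comp in label_components(cm, chroma)) {
    if (comp$area < params$droplet_min_area) next
    b <- comp$box
    if (bbox_width(b) < params$min_box_px || bbox_height(b) < params$min_box_px) next
    conf <- min(1, comp$vmax / 160)
    out[[length(out) + 1L]] <- detection("droplet", b, conf)
  }

  # transparent droplets: faint bright rims over the background
  rm_ <- (gray > bg + params$rim_delta) & (chroma < params$droplet_chroma_min)
  for (comp in label_components(rm_, gray)) {
    if (comp$area < params$droplet_min_area / 2) next
    b <- comp$box
    if (bbox_width(b) < params$min_box_px || bbox_height(b) < params$min_box_px) next
    conf <- min(1, max(0.05, (comp$vmax - bg) / 64))
    out[[length(out) + 1L]] <- detection("droplet", b, conf)
  }
  out
}

# Run-length connected-component labeling (8-connectivity) with per-component
# value aggregates. Returns a list of components, each
# list(box = bbox (0-based half-open px), area = n pixels, vmin, vmax).
label_components <- function(mask, values = NULL) {
  H <- nrow(mask); W <- ncol(mask)
  runs_row <- integer(0); runs_c0 <- integer(0); runs_c1 <- integer(0)
  for (i in seq_len(H)) {
    r <- mask[i, ]
    if (!any(r)) next
    d <- diff(c(FALSE, r, FALSE))
    c0 <- which(d == 1L); c1 <- which(d == -1L) - 1L
    runs_row <- c(runs_row, rep.int(i, length(c0)))
    runs_c0 <- c(runs_c0, c0); runs_c1 <- c(runs_c1, c1)
  }
  n <- length(runs_row)
  if (n == 0L) return(list())
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  union_ <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[ra] <<- rb }

  idx_by_row <- split(seq_len(n), runs_row)
  rows_present <- as.integer(names(idx_by_row))
  for (k in seq_along(rows_present)[-1]) {
    if (rows_present[k] - rows_present[k - 1L] != 1L) next
    above <- idx_by_row[[k - 1L]]; here <- idx_by_row[[k]]
    for (a in above) for (b in here) {
      if (runs_c0[a] <= runs_c1[b] + 1L && runs_c1[a] >= runs_c0[b] - 1L)
        union_(a, b)
    }
  }
  root <- vapply(seq_len(n), find, 0L)
  comps <- split(seq_len(n), root)
  lapply(unname(comps), function(ix) {
    rmin <- min(runs_row[ix]); rmax <- max(runs_row[ix])
    cmin <- min(runs_c0[ix]); cmax <- max(runs_c1[ix])
    area <- sum(runs_c1[ix] - runs_c0[ix] + 1L)
    vmin <- Inf; vmax <- -Inf
    if (!is.null(values)) {
      for (j in ix) {
        seg <- values[runs_row[j], runs_c0[j]:runs_c1[j]]
        vmin <- min(vmin, seg); vmax <- max(vmax, seg)
      }
    }
    list(box = bbox(cmin - 1L, rmin - 1L, cmax, rmax),
         area = area, vmin = vmin, vmax = vmax)
  })
}

#' Associate detections across frames
#'
#' Greedy nearest-centroid matching within each class: previous detections
#' are scanned in index order and matched to the nearest unmatched current
#' detection of the same class within `gate` pixels; equidistant candidates
#' resolve to the lower current index. Unmatched previous detections are
#' `lost`, unmatched current ones are `new`.
#'
#' @param previous,current lists of [detection()] objects.
#' @param gate matching gate in pixels (> 0).
#' @return list with a `matches` data frame (`prev`, `curr`, `dist`) and
#'   integer vectors `lost` and `new`.
#' @export
associate <- function(previous, current, gate = 40) {
  if (gate <= 0) stop("gate must be positive")
  cur_used <- rep(FALSE, length(current))
  matches <- data.frame(prev = integer(), curr = integer(), dist = numeric())
  for (i in seq_along(previous)) {
    p <- previous[[i]]
    best_j <- NA_integer_; best_d <- Inf
    for (j in seq_along(current)) {
      if (cur_used[j] || current[[j]]$class_label != p$class_label) next
      d <- dist2d(bbox_center(p$box), bbox_center(current[[j]]$box))
      if (d <= gate && d < best_d) { best_d <- d; best_j <- j }
    }
    if (!is.na(best_j)) {
      cur_used[best_j] <- TRUE
      matches <- rbind(matches,
                       data.frame(prev = i, curr = best_j, dist = best_d))
    }
  }
  list(matches = matches,
       lost = setdiff(seq_along(previous), matches$prev),
       new = which(!cur_used))
}
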