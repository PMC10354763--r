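# Synthetic annotated-frame generator. Emulates the six categories of
# training images used for the real detector: (i) varying particle/droplet
# (P/D) ratios, (ii) varying aspect ratios, (iii) particles moving in/out of
# droplets, (iv) varying illumination (25-1000 lux), (v) Carba NP colored
# droplets (red through yellow/orange), (vi) BCA colored droplets.

DATASET_CATEGORIES <- c("pd_ratio", "aspect_ratio", "in_out",
                        "illumination", "carba_colored", "bca_colored")

# run `code` under a fixed RNG state without disturbing the caller's stream
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a deterministic synthetic annotated dataset
#'
#' Frames are sampled round-robin across the requested categories with
#' randomized droplet positions, volumes, colors, particle loads and
#' illumination (uniform over the rig's 25-1000 lux working range).
#' Bit-identical output for identical `seed`.
#'
#' @param n_frames number of frames (> 0).
#' @param seed integer seed governing all sampling.
#' @param categories subset of
#'   `c("pd_ratio","aspect_ratio","in_out","illumination","carba_colored","bca_colored")`.
#' @param camera a [camera_model()] template (illumination is overridden per
#'   frame).
#' @return list of `annotated_frame` objects; each records its category and
#'   seed in `provenance`.
#' @export
generate_dataset <- function(n_frames, seed = 1L,
                             categories = DATASET_CATEGORIES,
                             camera = camera_model()) {
  stopifnot(n_frames > 0)
  unknown <- setdiff(categories, DATASET_CATEGORIES)
  if (length(unknown))
    stop("unknown dataset category: ", paste(unknown, collapse = ", "))
  with_seed(seed, {
    lapply(seq_len(n_frames), function(i) {
      cat_i <- categories[((i - 1L) %% length(categories)) + 1L]
      f <- sample_frame(cat_i, camera)
      f$frame_id <- sprintf("f%05d", i)
      f$provenance$category <- cat_i
      f$provenance$seed <- seed
      f
    })
  })
}

runif1 <- function(lo, hi) stats::runif(1, lo, hi)

sample_frame <- function(category, camera_tpl) {
  lux <- runif1(25, 1000)
  cam <- camera_model(pixels_per_mm = camera_tpl$pixels_per_mm,
                      image_width = camera_tpl$image_width,
                      image_height = camera_tpl$image_height,
                      illumination = lux, noise_sd = camera_tpl$noise_sd)
  bounds <- c(cam$image_width, cam$image_height) / cam$pixels_per_mm
  aspect <- if (category == "aspect_ratio") runif1(1.05, 1.4) else 1

  n_drop <- sample(1:3, 1)
  droplets <- list(); clusters <- list(); centers <- list(); radii <- c()
  for (k in seq_len(n_drop)) {
    vol <- runif1(4, 20)
    r <- footprint_radius(vol) * max(aspect, 1 / aspect)
    ctr <- place_disjoint(centers, radii, r, bounds)
    if (is.null(ctr)) next
    centers[[length(centers) + 1L]] <- ctr; radii <- c(radii, r)
    color <- switch(category,
      carba_colored = sample_carba_color(),
      bca_colored   = sample_bca_color(),
      NULL)
    id <- sprintf("d%d", k)
    d <- droplet_state(id, ctr, vol, color = color)
    droplets[[length(droplets) + 1L]] <- d

    want_particles <- switch(category,
      pd_ratio = TRUE, in_out = k == 1L,
      stats::runif(1) < 0.6)
    if (want_particles) {
      pd <- runif1(0.02, 0.12)   # P/D ratios seen on the rig
      pvol <- max(0.2, min(1.5, pd * vol))
      offset <- if (category == "in_out")
        runif1(0.5, 1.3) * footprint_radius(vol)
      else runif1(0, 0.4) * footprint_radius(vol)
      ang <- runif1(0, 2 * pi)
      pctr <- ctr + offset * c(cos(ang), sin(ang))
      pctr <- pmin(pmax(pctr, 0.5), bounds - 0.5)
      inside <- dist2d(pctr, ctr) <= footprint_radius(vol)
      clusters[[length(clusters) + 1L]] <- particle_cluster_state(
        sprintf("p%d", k), pctr, pvol,
        host_droplet_id = if (inside) id)
    }
  }
  st <- platform_state(droplets, clusters,
                       magnet_state(position = c(1, 1)),
                       bounds = bounds)
  render(st, cam, aspect = aspect)
}

place_disjoint <- function(centers, radii, r, bounds, tries = 40L) {
  for (t in seq_len(tries)) {
    ctr <- c(runif1(r + 0.3, bounds[1] - r - 0.3),
             runif1(r + 0.3, bounds[2] - r - 0.3))
    ok <- TRUE
    for (i in seq_along(centers))
      if (dist2d(ctr, centers[[i]]) < r + radii[i] + 0.5) { ok <- FALSE; break }
    if (ok) return(ctr)
  }
  NULL
}

# reagent palettes sampled along hue arcs (saturation preserved, as real
# indicator chemistry does — colors never pass through gray)

# phenol red: red (unreacted, ~355 deg) through orange to yellow (~50 deg)
sample_carba_color <- function() {
  hue_arc_color(from_deg = 355, to_deg = 50, s = 0.8, v = 0.85)
}

# BCA working reagent: apple-green toward violet with increasing protein
sample_bca_color <- function() {
  hue_arc_color(from_deg = 100, to_deg = 280, s = 0.6, v = 0.7)
}

hue_arc_color <- function(from_deg, to_deg, s, v) {
  span <- (to_deg - from_deg) %% 360
  h <- ((from_deg + stats::runif(1) * span) %% 360) / 360
  as.numeric(grDevices::col2rgb(grDevices::hsv(h, s, v)))
}

#' Deterministic train/test split
#'
#' Shuffles by seed and takes the first `floor(n * train_fraction)` frames
#' as the training partition; the split is disjoint and exhaustive.
#'
#' @param frames list (e.g. of `annotated_frame` objects).
#' @param train_fraction scalar in (0, 1); the rig's datasets use 0.7.
#' @param seed integer seed.
#' @return list with `train` and `test` sublists.
#' @export
#' @examples
#' s <- split_dataset(as.list(1:769), 0.7, seed = 1)
#' lengths(s)  # 538 / 231
split_dataset <- function(frames, train_fraction = 0.7, seed = 1L) {
  n <- length(frames)
  if (n == 0L) stop("cannot split an empty collection")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie strictly between 0 and 1")
  perm <- with_seed(seed, sample.int(n))
  n_train <- floor(n * train_fraction)
  list(train = frames[perm[seq_len(n_train)]],
       test  = frames[perm[setdiff(seq_len(n), seq_len(n_train))]])
}

## ---- interchange formats -------------------------------------------------

#' Write frames' annotations as COCO JSON
#'
#' Standard COCO layout: `images` / `annotations` / `categories` arrays,
#' `bbox` as `[x, y, width, height]` in pixels, category ids 1 = droplet,
#' 2 = particle.
#'
#' @param frames list of `annotated_frame` objects.
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
write_coco <- function(frames, path) {
  images <- list(); annotations <- list(); ann_id <- 0L
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    images[[i]] <- list(id = i, file_name = paste0(f$frame_id, ".ppm"),
                        width = dim(f$image)[2], height = dim(f$image)[1])
    for (a in f$annotations) {
      ann_id <- ann_id + 1L
      b <- a$box
      annotations[[ann_id]] <- list(
        id = ann_id, image_id = i,
        category_id = if (a$class_label == "droplet") 1L else 2L,
        bbox = unname(c(b["x_min"], b["y_min"], bbox_width(b), bbox_height(b))),
        area = bbox_area(b), iscrowd = 0L)
    }
  }
  obj <- list(images = images, annotations = annotations,
              categories = list(list(id = 1L, name = "droplet"),
                                list(id = 2L, name = "particle")))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read COCO JSON annotations
#'
#' @param path COCO JSON file.
#' @return data frame with columns `frame_id`, `class`, `x_min`, `y_min`,
#'   `x_max`, `y_max` (half-open pixel boxes).
#' @export
read_coco <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$images) || is.null(obj$categories))
    stop("not a COCO annotation file: ", path)
  imgs <- obj$images
  img_name <- stats::setNames(sub("\\.[a-z]+$", "", imgs$file_name), imgs$id)
  cats <- stats::setNames(obj$categories$name, obj$categories$id)
  ann <- obj$annotations
  if (length(ann) == 0L || (is.data.frame(ann) && nrow(ann) == 0L))
    return(detections_to_df(list())[, 1:6])
  bb <- do.call(rbind, ann$bbox)
  data.frame(frame_id = unname(img_name[as.character(ann$image_id)]),
             class = unname(cats[as.character(ann$category_id)]),
             x_min = bb[, 1], y_min = bb[, 2],
             x_max = bb[, 1] + bb[, 3], y_max = bb[, 2] + bb[, 4],
             stringsAsFactors = FALSE)
}

#' Write an image as binary PPM (P6)
#'
#' PPM keeps the toolchain dependency-free; any image viewer or converter
#' reads it.
#'
#' @param image `H x W x 3` array in `[0, 255]`.
#' @param path output path, conventionally `.ppm`.
#' @return the path, invisibly.
#' @export
write_ppm <- function(image, path) {
  H <- dim(image)[1]; W <- dim(image)[2]
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P6\n%d %d\n255\n", W, H), con, eos = NULL)
  px <- aperm(round(image), c(3, 2, 1))  # channel-major, row by row
  writeBin(as.raw(pmin(255, pmax(0, px))), con)
  invisible(path)
}

#' Write / read per-frame detection records as TSV
#'
#' Line-delimited interchange for detector output: one record per detection
#' with `frame_id`, `class`, box corners and `confidence`.
#'
#' @param df data frame as produced by [detections_to_df()].
#' @param path file path.
#' @return the path (write) or the data frame (read).
#' @export
write_detections <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_detections
#' @export
read_detections <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Ground-truth annotations of a frame list as a data frame
#' @param frames list of `annotated_frame` objects.
#' @return data frame in the same layout as [read_coco()].
#' @export
frames_truth_df <- function(frames) {
  rows <- lapply(frames, function(f) {
    df <- detections_to_df(lapply(f$annotations, function(a)
      detection(a$class_label, a$box, 1)), frame_id = f$frame_id)
    df
  })
  out <- do.call(rbind, rows)
  out[, setdiff(names(out), "confidence")]
}
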