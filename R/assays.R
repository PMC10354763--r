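# Scripted end-to-end choreographies of the two demonstrated IVD assays on
# the simulated platform: BCA protein quantification (triplicate) and the
# Carba NP carbapenemase test (test + control reaction pair), plus the
# colorimetric readout. The choreography layer drives only control-module
# operations through the actuation/detection contracts — it never touches
# simulator state.

#' Assay protocol description
#'
#' @param name `"BCA"` or `"CarbaNP"`.
#' @param areas list of reaction-area layouts; each a list with `reagent`
#'   (center mm, volume ul, color, particle volume, optional props),
#'   `sample` (center mm, volume ul, optional props) and `set` (center mm,
#'   radius mm).
#' @param power_level magnet power for the whole assay.
#' @param incubation_s incubation after mixing, s.
#' @param mix_loops cross-path loops per reaction.
#' @param arm_px cross arm length, px.
#' @param extract_travel_px extraction travel, px.
#' @param extract_direction compass token for extraction.
#' @param config an [operation_config()] used for every operation.
#' @return an `assay_protocol` object.
#' @export
assay_protocol <- function(name, areas, power_level = "default",
                           incubation_s = 600, mix_loops = 5, arm_px = 30,
                           extract_travel_px = 60,
                           extract_direction = "EAST",
                           config = operation_config()) {
  name <- match.arg(name, c("BCA", "CarbaNP"))
  stopifnot(length(areas) >= 1, incubation_s > 0, mix_loops >= 1)
  structure(list(name = name, areas = areas, power_level = power_level,
                 incubation_s = incubation_s, mix_loops = mix_loops,
                 arm_px = arm_px, extract_travel_px = extract_travel_px,
                 extract_direction = extract_direction, config = config),
            class = "assay_protocol")
}

BCA_REAGENT_COLOR <- c(120, 185, 90)   # apple-green working reagent
CARBA_RED <- c(220, 40, 50)            # phenol red at neutral pH

#' Default BCA protein-quantification protocol
#'
#' Three reaction areas, each primed with a 20 ul droplet of BCA working
#' reagent carrying 1.5 ul of magnetic particles, a 2 ul protein-sample
#' droplet, and one SET for the final particle extraction. The assay runs
#' at high power (36 V/1.2 A: protein solutions adhere strongly to the
#' substrate) with 10 min incubation after mixing.
#'
#' @return an `assay_protocol`.
#' @export
bca_protocol <- function() {
  ys <- c(8, 20, 32)
  areas <- lapply(seq_along(ys), function(i) list(
    reagent = list(center = c(8, ys[i]), volume = 20,
                   color = BCA_REAGENT_COLOR, particles = 1.5),
    sample = list(center = c(18, ys[i]), volume = 2),
    set = list(center = c(30, ys[i]), radius = 1)))
  assay_protocol("BCA", areas, power_level = "high", incubation_s = 600,
                 mix_loops = 5)
}

#' Default Carba NP protocol
#'
#' Two reaction pairs: the control pair (solution A without imipenem) and
#' the test pair (solution A with imipenem), each a 10 ul red solution A
#' droplet carrying 1.5 ul of particles plus a 10 ul bacterial lysate
#' droplet, with one SET per pair. One hour incubation after mixing, during
#' which a carbapenemase-producing lysate turns the test reaction from red
#' toward yellow.
#'
#' @return an `assay_protocol`.
#' @export
carba_np_protocol <- function() {
  areas <- list(
    control = list(
      reagent = list(center = c(8, 12), volume = 10, color = CARBA_RED,
                     particles = 1.5),
      sample = list(center = c(18, 12), volume = 10),
      set = list(center = c(30, 12), radius = 1)),
    test = list(
      reagent = list(center = c(8, 28), volume = 10, color = CARBA_RED,
                     particles = 1.5, props = list(imipenem = TRUE)),
      sample = list(center = c(18, 28), volume = 10),
      set = list(center = c(30, 28), radius = 1)))
  assay_protocol("CarbaNP", areas, power_level = "default",
                 incubation_s = 3600, mix_loops = 5)
}

#' Prime a platform for an assay protocol
#'
#' Builds the initial [platform_state()] with all reagent and sample
#' droplets, particle clusters and SETs declared by the protocol. For the
#' Carba NP protocol, `strain_profile$cpe` marks the bacterial lysate
#' droplets as carbapenemase-producing.
#'
#' @param protocol an [assay_protocol()].
#' @param strain_profile list with logical `cpe` (Carba NP only).
#' @return a [platform_state()].
#' @export
prime_platform <- function(protocol, strain_profile = list(cpe = FALSE)) {
  droplets <- list(); clusters <- list(); sets <- list()
  for (i in seq_along(protocol$areas)) {
    a <- protocol$areas[[i]]
    rid <- sprintf("reagent%d", i); sid <- sprintf("sample%d", i)
    rprops <- a$reagent$props %||% list()
    sprops <- a$sample$props %||% list()
    if (protocol$name == "CarbaNP")
      sprops$cpe <- isTRUE(strain_profile$cpe)
    droplets[[length(droplets) + 1L]] <-
      droplet_state(rid, a$reagent$center, a$reagent$volume,
                    color = a$reagent$color, props = rprops)
    droplets[[length(droplets) + 1L]] <-
      droplet_state(sid, a$sample$center, a$sample$volume,
                    color = a$sample$color %||% NULL, props = sprops)
    if (!is.null(a$reagent$particles))
      clusters[[length(clusters) + 1L]] <- particle_cluster_state(
        sprintf("particles%d", i), c(NA_real_, NA_real_),
        a$reagent$particles, host_droplet_id = rid)
    sets[[length(sets) + 1L]] <- surface_energy_trap(
      sprintf("set%d", i), a$set$center, a$set$radius)
  }
  platform_state(droplets, clusters,
                 magnet_state(position = c(1, 1),
                              power_level = protocol$power_level),
                 sets)
}

assay_report <- function(name, areas, incubation, readout = NULL,
                         valid = NA) {
  structure(list(name = name, areas = areas, incubation = incubation,
                 readout = readout, valid = valid),
            class = "assay_report")
}

#' @export
print.assay_report <- function(x, ...) {
  ok <- vapply(x$areas, function(a) identical(a$status, "complete"), TRUE)
  cat(sprintf("<assay_report> %s: %d/%d area(s) complete\n",
              x$name, sum(ok), length(ok)))
  if (!is.null(x$readout)) {
    for (i in seq_len(nrow(x$readout)))
      cat(sprintf("  %s: rgb(%.0f,%.0f,%.0f) -> %s\n", x$readout$area[i],
                  x$readout$r[i], x$readout$g[i], x$readout$b[i],
                  x$readout$classification[i]))
    cat(sprintf("  valid: %s\n", x$valid))
  }
  invisible(x)
}

# one reaction area: merge reagent onto sample, then mix. Coordinates are
# protocol mm turned into camera px through the world's camera.
merge_and_mix_area <- function(area, protocol, world, eyes) {
  ppmm <- world$camera$pixels_per_mm
  mover_px <- area$reagent$center * ppmm
  still_px <- area$sample$center * ppmm
  cfg <- protocol$config
  res <- list()
  res$merge <- merge_droplets(mover_px, still_px, cfg, world, eyes)
  if (res$merge$status != "success") { res$status <- "failed"; return(res) }
  res$mix <- mix_droplet(protocol$mix_loops, protocol$arm_px, cfg, world, eyes,
                         from = still_px)
  if (res$mix$status != "success") { res$status <- "failed"; return(res) }
  res$status <- "mixed"
  res
}

# park the droplet on the SET and pull the particles out
extract_area <- function(area, protocol, world, eyes) {
  ppmm <- world$camera$pixels_per_mm
  set_px <- area$set$center * ppmm
  cfg <- protocol$config
  res <- list()
  # particles sit at the mix center (the sample droplet's position)
  res$transport <- transport(list(set_px), cfg, world, eyes,
                             from = area$sample$center * ppmm)
  if (res$transport$status != "success") { res$status <- "failed"; return(res) }
  res$extract <- extract_particles(protocol$extract_direction,
                                   protocol$extract_travel_px,
                                   cfg, world, eyes, from = set_px)
  res$status <- if (res$extract$status == "success") "complete" else "failed"
  res
}

#' Run the BCA protein-quantification choreography
#'
#' Per area: merge the particle-bearing working-reagent droplet with the
#' protein droplet, mix along the cross path, and (after the 10 min
#' incubation) transport the reaction droplet onto its SET and extract the
#' particles so the solution can be retrieved. The areas are interleaved as
#' on the real platform: merges and mixes for areas 2-3 run while area 1
#' incubates, with the magnet parked at HOME and off during pure waiting;
#' extractions then run in area order, each gated on its own incubation
#' clock. A failed area is recorded and the remaining areas still run. The
#' assay's contract ends at successful particle extraction — absorbance
#' readout is a wet-lab measurement.
#'
#' @param protocol an [assay_protocol()] (default [bca_protocol()]).
#' @param world,eyes actuation and detection interfaces; built automatically
#'   from a freshly primed platform when `NULL`.
#' @return an `assay_report`.
#' @export
run_bca <- function(protocol = bca_protocol(), world = NULL, eyes = NULL) {
  if (is.null(world)) {
    world <- sim_world(prime_platform(protocol), engagement_model())
    eyes <- perfect_eyes(world)
  }
  world$set_power(protocol$power_level)
  n <- length(protocol$areas)
  areas <- vector("list", n)
  mix_end <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    areas[[i]] <- tryCatch(
      merge_and_mix_area(protocol$areas[[i]], protocol, world, eyes),
      error = function(e) list(status = "failed", error = conditionMessage(e)))
    mix_end[i] <- world$elapsed()
  }
  # magnet to HOME and off while the reactions incubate
  world$set_magnet(FALSE)
  world$home()
  extraction_start <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (!identical(areas[[i]]$status, "mixed")) next
    remaining <- protocol$incubation_s - (world$elapsed() - mix_end[i])
    if (remaining > 0) world$wait(remaining)
    extraction_start[i] <- world$elapsed()
    ex <- tryCatch(extract_area(protocol$areas[[i]], protocol, world, eyes),
                   error = function(e) list(status = "failed",
                                            error = conditionMessage(e)))
    areas[[i]] <- c(areas[[i]][setdiff(names(areas[[i]]), "status")], ex)
    world$set_magnet(FALSE)
    world$home()
  }
  incubation <- data.frame(area = seq_len(n), mix_end = mix_end,
                           extraction_start = extraction_start)
  assay_report(protocol$name, areas, incubation)
}

#' Run the Carba NP choreography and call the result
#'
#' Merges and mixes the control pair (no imipenem) and the test pair
#' (imipenem), incubates both for an hour — during which the simulated
#' chemistry turns the test droplet from red toward yellow iff the strain
#' produces carbapenemase — then parks each reaction droplet on its SET,
#' extracts the particles, and reads the droplet colors from a captured
#' frame. The test reaction is called positive on a yellow/orange hue and
#' negative on red; the assay is valid only while the control stays red.
#'
#' @param protocol an [assay_protocol()] (default [carba_np_protocol()]).
#' @param strain_profile list with logical `cpe`.
#' @param world,eyes interfaces; built from a platform primed with
#'   `strain_profile` when `NULL`.
#' @return an `assay_report` with a `readout` table and `valid` flag.
#' @export
run_carba_np <- function(protocol = carba_np_protocol(),
                         strain_profile = list(cpe = FALSE),
                         world = NULL, eyes = NULL) {
  if (is.null(world)) {
    world <- sim_world(prime_platform(protocol, strain_profile),
                       engagement_model())
    eyes <- perfect_eyes(world)
  }
  world$set_power(protocol$power_level)
  n <- length(protocol$areas)
  areas <- vector("list", n)
  mix_end <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    areas[[i]] <- tryCatch(
      merge_and_mix_area(protocol$areas[[i]], protocol, world, eyes),
      error = function(e) list(status = "failed", error = conditionMessage(e)))
    mix_end[i] <- world$elapsed()
  }
  world$set_magnet(FALSE)
  world$home()
  extraction_start <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (!identical(areas[[i]]$status, "mixed")) next
    remaining <- protocol$incubation_s - (world$elapsed() - mix_end[i])
    if (remaining > 0) world$wait(remaining)
    extraction_start[i] <- world$elapsed()
    ex <- tryCatch(extract_area(protocol$areas[[i]], protocol, world, eyes),
                   error = function(e) list(status = "failed",
                                            error = conditionMessage(e)))
    areas[[i]] <- c(areas[[i]][setdiff(names(areas[[i]]), "status")], ex)
    world$set_magnet(FALSE)
    world$home()
  }
  incubation <- data.frame(area = names(protocol$areas), mix_end = mix_end,
                           extraction_start = extraction_start)

  # colorimetric readout only where every operation succeeded
  frame <- eyes$frame()
  dets <- eyes$capture()
  readout <- NULL
  for (i in seq_len(n)) {
    nm <- names(protocol$areas)[i]
    if (!identical(areas[[i]]$status, "complete")) {
      row <- data.frame(area = nm, r = NA_real_, g = NA_real_, b = NA_real_,
                        classification = "invalid")
    } else {
      set_px <- protocol$areas[[i]]$set$center * world$camera$pixels_per_mm
      d <- nearest_detection(droplet_detections(dets), set_px)
      rgb <- read_droplet_color(frame, d$box)
      row <- data.frame(area = nm, r = rgb[1], g = rgb[2], b = rgb[3],
                        classification = classify_color(rgb))
    }
    readout <- rbind(readout, row)
  }
  valid <- identical(readout$classification[readout$area == "control"],
                     "negative")
  assay_report(protocol$name, areas, incubation, readout, valid)
}

#' Classify a droplet color as a Carba NP call
#'
#' RGB is mapped to hue-saturation-value; a yellow/orange hue (20-90
#' degrees) with adequate saturation reads positive (carbapenem
#' hydrolysis), a red hue (within 20 degrees of 0, wrap-around) reads
#' negative, anything else — including near-gray colors with no meaningful
#' hue — is indeterminate. Thresholds are configurable quantifications of
#' the qualitative red versus yellow/orange rule.
#'
#' @param rgb RGB triple in `[0, 255]`.
#' @param sat_floor minimum HSV saturation for a confident call.
#' @param positive_hue,negative_halfwidth hue windows in degrees.
#' @return `"positive"`, `"negative"` or `"indeterminate"`.
#' @export
#' @examples
#' classify_color(c(220, 40, 50))   # red -> negative
#' classify_color(c(230, 200, 40))  # yellow -> positive
classify_color <- function(rgb, sat_floor = 0.2, positive_hue = c(20, 90),
                           negative_halfwidth = 20) {
  rgb <- as.numeric(rgb)
  if (length(rgb) != 3L || any(!is.finite(rgb)) || any(rgb < 0) || any(rgb > 255))
    stop("rgb must be a triple in [0, 255]")
  hsv <- grDevices::rgb2hsv(rgb[1], rgb[2], rgb[3], maxColorValue = 255)
  hue <- hsv[1] * 360; sat <- hsv[2]
  if (sat < sat_floor) return("indeterminate")
  if (hue >= positive_hue[1] && hue <= positive_hue[2]) return("positive")
  if (hue >= 360 - negative_halfwidth || hue < negative_halfwidth)
    return("negative")
  "indeterminate"
}

#' Mean droplet color from a frame
#'
#' Averages RGB over the central sub-box holding 50% of the box area
#' (side scaled by 1/sqrt(2)), which excludes rim highlights.
#'
#' @param frame an `annotated_frame` or `H x W x 3` image array.
#' @param droplet_box a [bbox()] within the frame.
#' @return RGB triple.
#' @export
read_droplet_color <- function(frame, droplet_box) {
  img <- if (inherits(frame, "annotated_frame")) frame$image else frame
  H <- dim(img)[1]; W <- dim(img)[2]
  b <- as_bbox(droplet_box)
  if (b["x_max"] > W || b["y_max"] > H)
    stop("droplet_box extends outside the frame")
  ctr <- bbox_center(b)
  hw <- bbox_width(b) / 2 / sqrt(2); hh <- bbox_height(b) / 2 / sqrt(2)
  j0 <- max(1L, floor(ctr["x"] - hw) + 1L); j1 <- min(W, ceiling(ctr["x"] + hw))
  i0 <- max(1L, floor(ctr["y"] - hh) + 1L); i1 <- min(H, ceiling(ctr["y"] + hh))
  c(r = mean(img[i0:i1, j0:j1, 1]),
    g = mean(img[i0:i1, j0:j1, 2]),
    b = mean(img[i0:i1, j0:j1, 3]))
}

#' Reference panel of Carba NP strains
#'
#' The eight-strain panel used to exercise the assay end to end: six
#' carbapenemase producers (IMP, KPC and NDM beta-lactamase types) and two
#' non-producers.
#'
#' @return data frame with `sample_id`, `beta_lactamase`, `species`, `cpe`.
#' @export
carba_np_strains <- function() {
  data.frame(
    sample_id = c(2L, 7L, 8L, 9L, 11L, 14L, 26L, 27L),
    beta_lactamase = c("IMP", "KPC", "KPC", "IMP", "NDM", "NDM",
                       "None", "None"),
    species = c("Escherichia coli NCTC 13476", "E. coli 6013499989",
                "Klebsiella pneumoniae 6033440078",
                "Serratia marcescens 6013550755",
                "K. pneumoniae 2073318014", "E. coli MBRL 235",
                "K. pneumoniae C13 (6123-145679)",
                "E. coli C18 (7013-614848)"),
    cpe = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}
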