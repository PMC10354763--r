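# The four closed-loop droplet operations as explicit state machines. The
# controller acts on detector output only (never simulator ground truth),
# judges success against pixel-space criteria, and rectifies failures by
# returning the control point (CP) to the detected particles and retrying
# at an adjusted speed: lower for transport (magnet disengagement means the
# commanded speed was too high for the particle load), higher for particle
# extraction (surface tension held the cluster back).

#' Closed-loop operation parameters
#'
#' Pixel thresholds follow the platform's success criteria: a droplet has
#' arrived when its detected box center is within 10 px of the destination
#' (inclusive); overshoot carries the particles 20 px beyond the destination
#' along +y and back, to center the droplet on the target; merging is
#' confirmed by at least 3 px bounding-box growth in both dimensions. The
#' retry schedule (x0.6 down / x1.5 up, at most 5 retries) is a geometric
#' policy guaranteed to cross the feasibility threshold of the engagement
#' model; the platform itself only prescribes the direction.
#'
#' @param destination_tolerance px, inclusive arrival radius. Default 10.
#' @param overshoot px of +y overshoot during transport/merge. Default 20.
#' @param merge_growth px of required box growth in both dimensions. Default 3.
#' @param default_speed mm/s commanded on a first transport attempt. Default 8.33.
#' @param retry_slowdown multiplicative speed factor per transport retry, in
#'   (0,1). Default 0.6.
#' @param retry_speedup multiplicative speed factor per extraction retry,
#'   > 1. Default 1.5.
#' @param max_retries retry budget per operation. Default 5.
#' @param settle seconds to let the scene settle before a success check.
#'   Default 0.5.
#' @return an `operation_config` list.
#' @export
operation_config <- function(destination_tolerance = 10, overshoot = 20,
                             merge_growth = 3, default_speed = 8.33,
                             retry_slowdown = 0.6, retry_speedup = 1.5,
                             max_retries = 5, settle = 0.5) {
  stopifnot(destination_tolerance > 0, overshoot >= 0, merge_growth > 0,
            default_speed > 0, retry_slowdown > 0, retry_slowdown < 1,
            retry_speedup > 1, max_retries >= 0, settle >= 0)
  structure(as.list(environment()), class = "operation_config")
}

#' Arrival check
#'
#' Euclidean distance between the detected object center and the
#' destination, compared inclusively against the tolerance ("within 10 px"
#' includes exactly 10 px).
#'
#' @param center detected center `(x, y)` px.
#' @param destination target `(x, y)` px.
#' @param tolerance px (> 0).
#' @return logical.
#' @export
at_destination <- function(center, destination, tolerance = 10) {
  stopifnot(tolerance > 0)
  dist2d(as.numeric(center), as.numeric(destination)) <= tolerance
}

#' Extraction success check
#'
#' True iff the particle and droplet boxes are disjoint (zero intersection
#' area); boxes that merely touch along an edge have zero overlap and count
#' as separated.
#'
#' @param particle_box,droplet_box boxes from [bbox()].
#' @return logical.
#' @export
extraction_succeeded <- function(particle_box, droplet_box) {
  intersection_area(as_bbox(particle_box), as_bbox(droplet_box)) == 0
}

#' Merge success check
#'
#' True iff the detected droplet box after the move grew by at least
#' `growth` px in *both* width and height relative to the stationary
#' droplet's box before the move.
#'
#' @param before,after boxes from [bbox()].
#' @param growth required growth in px (> 0), inclusive.
#' @return logical.
#' @export
merge_succeeded <- function(before, after, growth = 3) {
  stopifnot(growth > 0)
  before <- as_bbox(before); after <- as_bbox(after)
  (bbox_width(after) - bbox_width(before) >= growth) &&
    (bbox_height(after) - bbox_height(before) >= growth)
}

operation_result <- function(op, status, retries, attempts,
                             final_state_summary = "") {
  structure(list(op = op, status = status, retries = retries,
                 attempts = attempts,
                 final_state_summary = final_state_summary),
            class = "operation_result")
}

#' @export
print.operation_result <- function(x, ...) {
  cat(sprintf("<operation_result> %s: %s after %d retr%s\n", x$op, x$status,
              x$retries, if (x$retries == 1) "y" else "ies"))
  if (nzchar(x$final_state_summary)) cat(" ", x$final_state_summary, "\n")
  invisible(x)
}

attempt_record <- function(speed, outcome, snapshot = NULL) {
  list(speed = speed, outcome = outcome, snapshot = snapshot)
}

## ---- detection bookkeeping ----------------------------------------------

particle_detections <- function(dets) detections_of_class(dets, "particle")
droplet_detections <- function(dets) detections_of_class(dets, "droplet")

nearest_detection <- function(dets, point) {
  if (length(dets) == 0L) return(NULL)
  d <- vapply(dets, function(x) dist2d(bbox_center(x$box), point), 0)
  dets[[which.min(d)]]
}

# the droplet detection hosting a particle box: largest overlap, falling
# back to the droplet nearest the particle center
host_droplet_detection <- function(dets, particle_box) {
  drs <- droplet_detections(dets)
  if (length(drs) == 0L) return(NULL)
  ov <- vapply(drs, function(d) intersection_area(d$box, particle_box), 0)
  if (max(ov) > 0) return(drs[[which.max(ov)]])
  nearest_detection(drs, bbox_center(particle_box))
}

clamp_px <- function(point, frame_size, margin = 2) {
  pmin(pmax(point, margin), frame_size - margin)
}

# locate the tracked particle cluster: nearest particle detection to `near`
locate_particles <- function(eyes, near = NULL) {
  dets <- eyes$capture()
  parts <- particle_detections(dets)
  if (length(parts) == 0L)
    stop("precondition failed: no particle cluster detected")
  p <- if (is.null(near)) parts[[which.max(vapply(parts, `[[`, 0, "confidence"))]]
       else nearest_detection(parts, near)
  list(dets = dets, particle = p, center = bbox_center(p$box))
}

## ---- transport -----------------------------------------------------------

#' Closed-loop droplet transport
#'
#' For each destination in order: the CP moves (field off) to the detected
#' particles, the magnet engages and drags toward the destination with a
#' +y overshoot of `config$overshoot` px which is then reversed; after a
#' settle interval the scene is re-detected and arrival is judged by
#' [at_destination()] on the detected droplet box center. Magnet
#' disengagement shows up solely as a failed arrival check, upon which the
#' CP returns to wherever the particles now are and the attempt repeats at
#' `retry_slowdown` times the previous speed. The magnet is released at the
#' end.
#'
#' @param destinations list of `(x, y)` px points (or a single point).
#' @param config an [operation_config()].
#' @param world an actuation interface (see [sim_world()]).
#' @param eyes a detection interface (see [perfect_eyes()]).
#' @param from optional `(x, y)` px hint selecting which particle cluster to
#'   drive when several are detected.
#' @return an `operation_result`.
#' @export
transport <- function(destinations, config, world, eyes, from = NULL) {
  if (is.numeric(destinations)) destinations <- list(destinations)
  if (length(destinations) == 0L) stop("destinations must be non-empty")
  fs <- world$frame_size()
  loc <- locate_particles(eyes, from)
  attempts <- list(); retries <- 0L

  for (dest in destinations) {
    dest <- clamp_px(as.numeric(dest), fs)
    speed <- config$default_speed
    repeat {
      host <- host_droplet_detection(loc$dets, loc$particle$box)
      ref_center <- if (is.null(host)) loc$center else bbox_center(host$box)
      if (at_destination(ref_center, dest, config$destination_tolerance)) {
        attempts[[length(attempts) + 1L]] <-
          attempt_record(speed, "already-at-destination")
        break
      }
      # return CP to the particles, engage, drive with overshoot
      world$set_magnet(FALSE)
      world$move_to(loc$center, config$default_speed)
      world$set_magnet(TRUE)
      over <- clamp_px(dest + c(0, config$overshoot), fs)
      world$move_to(over, speed)
      world$move_to(dest, speed)
      world$wait(config$settle)

      loc <- locate_particles(eyes, dest)
      host <- host_droplet_detection(loc$dets, loc$particle$box)
      ref_center <- if (is.null(host)) loc$center else bbox_center(host$box)
      ok <- at_destination(ref_center, dest, config$destination_tolerance)
      attempts[[length(attempts) + 1L]] <-
        attempt_record(speed, if (ok) "arrived" else "disengaged")
      if (ok) break
      retries <- retries + 1L
      if (retries > config$max_retries) {
        world$set_magnet(FALSE)
        return(operation_result("transport", "failed", retries - 1L, attempts,
                                "retry budget exhausted before arrival"))
      }
      speed <- speed * config$retry_slowdown
      loc <- locate_particles(eyes, loc$center)
    }
  }
  world$set_magnet(FALSE)
  operation_result("transport", "success", retries, attempts,
                   sprintf("droplet delivered to %d destination(s)",
                           length(destinations)))
}

## ---- particle extraction --------------------------------------------------

DIRECTION_VECTORS <- list(EAST = c(1, 0), WEST = c(-1, 0),
                          NORTH = c(0, -1), SOUTH = c(0, 1))

#' Closed-loop particle extraction
#'
#' The CP moves to the detected particles, engages, and drives `travel` px
#' in the compass `direction` at high speed (the first attempt commands
#' `retry_speedup * default_speed`). Success requires the re-detected
#' particle and droplet boxes to be disjoint ([extraction_succeeded()]); on
#' failure the CP returns to the particles and the attempt repeats at
#' `retry_speedup` times the previous speed. No overshoot is applied. The
#' magnet is released at the end.
#'
#' @param direction `"EAST"`, `"WEST"`, `"NORTH"` or `"SOUTH"`.
#' @param travel px to drive along the direction.
#' @param config an [operation_config()].
#' @param world,eyes actuation and detection interfaces.
#' @param from optional px hint selecting the particle cluster.
#' @return an `operation_result`.
#' @export
extract_particles <- function(direction, travel, config, world, eyes,
                              from = NULL) {
  dirv <- DIRECTION_VECTORS[[match.arg(direction, names(DIRECTION_VECTORS))]]
  fs <- world$frame_size()
  loc <- locate_particles(eyes, from)
  host <- host_droplet_detection(loc$dets, loc$particle$box)
  if (is.null(host) || intersection_area(host$box, loc$particle$box) == 0) {
    if (!is.null(host) && extraction_succeeded(loc$particle$box, host$box))
      return(operation_result("extract", "success", 0L,
                              list(attempt_record(0, "already-separated")),
                              "particles already outside the droplet"))
    stop("precondition failed: no overlapping droplet/particle pair detected")
  }
  droplet_ref <- bbox_center(host$box)

  speed <- config$retry_speedup * config$default_speed
  attempts <- list(); retries <- 0L
  repeat {
    world$set_magnet(FALSE)
    world$move_to(loc$center, config$default_speed)
    world$set_magnet(TRUE)
    target <- clamp_px(loc$center + travel * dirv, fs)
    world$move_to(target, speed)
    world$wait(config$settle)

    dets <- eyes$capture()
    parts <- particle_detections(dets)
    drs <- droplet_detections(dets)
    p <- nearest_detection(parts, target)
    d <- nearest_detection(drs, droplet_ref)
    ok <- !is.null(p) && !is.null(d) && extraction_succeeded(p$box, d$box)
    attempts[[length(attempts) + 1L]] <-
      attempt_record(speed, if (ok) "separated" else "retained")
    if (ok) {
      world$set_magnet(FALSE)
      return(operation_result("extract", "success", retries, attempts,
                              "particle and droplet boxes disjoint"))
    }
    retries <- retries + 1L
    if (retries > config$max_retries) {
      world$set_magnet(FALSE)
      return(operation_result("extract", "failed", retries - 1L, attempts,
                              "retry budget exhausted, boxes still overlap"))
    }
    speed <- speed * config$retry_speedup
    loc <- locate_particles(eyes, if (is.null(p)) loc$center else bbox_center(p$box))
  }
}

## ---- droplet merging -------------------------------------------------------

#' Closed-loop droplet merging
#'
#' Of the two droplets, the one containing the detected particles moves
#' (Droplet 2 in the platform's nomenclature); the other stays. The mover is
#' transported — overshoot and nested transport rectification included —
#' onto the stationary droplet's detected center; success requires the
#' detected particle-bearing droplet box after the move to exceed the
#' stationary droplet's pre-move box by at least `merge_growth` px in both
#' dimensions ([merge_succeeded()]). On failure the CP returns to the
#' particles and the merge is retried.
#'
#' @param moving_hint,still_hint `(x, y)` px points identifying the two
#'   droplets (nearest detected droplet to each hint).
#' @param config an [operation_config()].
#' @param world,eyes actuation and detection interfaces.
#' @return an `operation_result`.
#' @export
merge_droplets <- function(moving_hint, still_hint, config, world, eyes) {
  dets <- eyes$capture()
  drs <- droplet_detections(dets)
  if (length(drs) < 2L)
    stop("precondition failed: need two detected droplets to merge")
  mover <- nearest_detection(drs, as.numeric(moving_hint))
  still <- nearest_detection(drs, as.numeric(still_hint))
  if (identical(mover$box, still$box))
    stop("precondition failed: hints resolve to the same droplet")
  parts <- particle_detections(dets)
  if (length(parts) == 0L)
    stop("precondition failed: no particle cluster detected")
  in_mover <- any(vapply(parts, function(p)
    intersection_area(p$box, mover$box) > 0, TRUE))
  in_still <- any(vapply(parts, function(p)
    intersection_area(p$box, still$box) > 0, TRUE))
  if (in_mover == in_still)
    stop("precondition failed: exactly one droplet must contain the particles")
  if (in_still) { tmp <- mover; mover <- still; still <- tmp }

  before_box <- still$box
  dest <- bbox_center(before_box)
  attempts <- list(); retries <- 0L
  repeat {
    tr <- transport(list(dest), config, world, eyes,
                    from = bbox_center(mover$box))
    attempts <- c(attempts, tr$attempts)
    retries <- retries + tr$retries
    if (tr$status != "success") {
      return(operation_result("merge", "failed", retries, attempts,
                              "inner transport exhausted retries"))
    }
    dets <- eyes$capture()
    parts <- particle_detections(dets)
    after <- if (length(parts) > 0)
      host_droplet_detection(dets, parts[[1L]]$box)
    else nearest_detection(droplet_detections(dets), dest)
    ok <- !is.null(after) && merge_succeeded(before_box, after$box,
                                             config$merge_growth)
    attempts[[length(attempts) + 1L]] <-
      attempt_record(config$default_speed, if (ok) "merged" else "not-merged")
    if (ok)
      return(operation_result("merge", "success", retries, attempts,
                              sprintf("%d droplet(s) detected after merge",
                                      length(droplet_detections(dets)))))
    retries <- retries + 1L
    if (retries > config$max_retries)
      return(operation_result("merge", "failed", retries - 1L, attempts,
                              "box growth below threshold after retries"))
  }
}

## ---- passive mixing --------------------------------------------------------

#' Closed-loop passive mixing
#'
#' Drives the particle-bearing droplet along a cross-shaped path centered on
#' the particles' current location: per loop, out to each of the four arm
#' endpoints (+x, -x, +y, -y) and back to the center, each leg a full
#' [transport()] with rectification. A custom `path` (list of px waypoints,
#' visited in order each loop) overrides the cross.
#'
#' @param loops number of loops (>= 1).
#' @param arm_length cross arm length in px.
#' @param config an [operation_config()].
#' @param world,eyes actuation and detection interfaces.
#' @param path optional list of waypoints replacing the cross pattern.
#' @param from optional px hint selecting the particle cluster.
#' @return an `operation_result`.
#' @export
mix_droplet <- function(loops, arm_length, config, world, eyes, path = NULL,
                        from = NULL) {
  if (!is.numeric(loops) || loops < 1) stop("loops must be >= 1")
  loops <- as.integer(loops)
  fs <- world$frame_size()
  loc <- locate_particles(eyes, from)
  center <- loc$center
  waypoints <- if (!is.null(path)) path else {
    arms <- list(c(arm_length, 0), c(-arm_length, 0),
                 c(0, arm_length), c(0, -arm_length))
    out <- list()
    for (a in arms) {
      out[[length(out) + 1L]] <- clamp_px(center + a, fs)
      out[[length(out) + 1L]] <- center
    }
    out
  }
  attempts <- list(); retries <- 0L
  remaining <- loops
  last_at <- center
  while (remaining > 0L) {
    for (wp in waypoints) {
      tr <- transport(list(wp), config, world, eyes, from = last_at)
      last_at <- wp
      attempts <- c(attempts, tr$attempts)
      retries <- retries + tr$retries
      if (tr$status != "success")
        return(operation_result("mix", "failed", retries, attempts,
                                sprintf("leg failed with %d loop(s) remaining",
                                        remaining)))
    }
    remaining <- remaining - 1L
  }
  operation_result("mix", "success", retries, attempts,
                   sprintf("%d loop(s) completed", loops))
}
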