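# Actuation and detection interface implementations backed by the simulator.
# The control layer talks only to these contracts:
#   actuation: move_to(point_px, speed), set_magnet(on), set_power(level),
#              wait(seconds), home()
#   detection: capture() -> list of detection
# A hardware adapter could implement the same contracts; here the simulator
# does, which makes every closed-loop operation testable offline.

#' Create a simulator-backed world (actuation interface)
#'
#' Wraps a [platform_state()] in a mutable handle implementing the actuation
#' contract in image pixel coordinates. Each `move_to` integrates
#' [step_platform()] at fixed `dt`, then applies [contact_merge()] and
#' [anchor_check()] so droplets coalesce on contact and pin to SETs as they
#' arrive. All commands are appended to an event log for replay.
#'
#' @param state initial [platform_state()].
#' @param model an [engagement_model()].
#' @param camera a [camera_model()] fixing the mm-to-pixel mapping.
#' @param dt integration step, s.
#' @param home_px HOME position of the magnet in px (top-left by default).
#' @return an environment of class `sim_world` with functions `move_to`,
#'   `set_magnet`, `set_power`, `wait`, `home`, `capture_state`,
#'   `frame_size`, `events`, `elapsed`.
#' @export
sim_world <- function(state, model, camera = camera_model(), dt = 0.1,
                      home_px = c(10, 10)) {
  w <- new.env(parent = emptyenv())
  w$state <- state
  w$model <- model
  w$camera <- camera
  w$dt <- dt
  w$home_px <- home_px
  w$log <- list()

  log_event <- function(event, detail = "") {
    w$log[[length(w$log) + 1L]] <- data.frame(
      time = w$state$time, event = event, detail = detail,
      stringsAsFactors = FALSE)
  }

  w$move_to <- function(point_px, speed) {
    stopifnot(speed > 0)
    target_mm <- px_to_mm(w$camera, as.numeric(point_px))
    if (!in_bounds(w$state, target_mm))
      stop("move_to target outside substrate bounds")
    log_event("move_to", sprintf("px=(%.1f,%.1f) v=%.3f",
                                 point_px[1], point_px[2], speed))
    max_steps <- ceiling(dist2d(w$state$magnet$cp, target_mm) /
                           (speed * w$dt)) + 5L
    for (i in seq_len(max_steps)) {
      w$state <- step_platform(w$state, target_mm, speed, w$dt, w$model)
      w$state <- anchor_check(contact_merge(w$state))
      if (dist2d(w$state$magnet$cp, target_mm) < 1e-9) break
    }
    invisible(NULL)
  }
  w$set_magnet <- function(on) {
    w$state$magnet$engaged <- isTRUE(on)
    log_event("set_magnet", if (isTRUE(on)) "on" else "off")
    invisible(NULL)
  }
  w$set_power <- function(level) {
    level <- match.arg(level, c("default", "high"))
    w$state$magnet$power_level <- level
    log_event("set_power", level)
    invisible(NULL)
  }
  w$wait <- function(seconds) {
    if (seconds <= 0) return(invisible(NULL))
    log_event("wait", sprintf("%.1fs", seconds))
    w$state <- wait_platform(w$state, seconds)
    invisible(NULL)
  }
  w$home <- function(speed = 8.33) {
    log_event("home", "")
    w$move_to(w$home_px, speed)
    invisible(NULL)
  }
  w$capture_state <- function() w$state
  w$frame_size <- function() c(w$camera$image_width, w$camera$image_height)
  w$elapsed <- function() w$state$time
  w$events <- function() {
    if (length(w$log) == 0L)
      return(data.frame(time = numeric(), event = character(),
                        detail = character()))
    do.call(rbind, w$log)
  }
  class(w) <- c("sim_world", "environment")
  w
}

#' Faithful detection interface reading simulator geometry
#'
#' Emits exactly the ground-truth boxes (confidence 1). Useful for testing
#' the control logic in isolation from detector noise; the controller still
#' consumes only [detection()] objects.
#'
#' @param world a [sim_world()].
#' @return a detection interface: list with `capture()`.
#' @export
perfect_eyes <- function(world) {
  list(capture = function() {
    gts <- ground_truth_boxes(world$capture_state(), world$camera)
    lapply(gts, function(a) detection(a$class_label, a$box, 1))
  },
  frame = function() render(world$capture_state(), world$camera))
}

#' Pixel-route detection interface: render then detect
#'
#' The full image-feedback path: the current state is rendered through the
#' camera model and the classical detector runs on the pixels.
#'
#' @param world a [sim_world()].
#' @param params a [detect_params()] list.
#' @return a detection interface: list with `capture()`.
#' @export
pixel_eyes <- function(world, params = detect_params()) {
  list(capture = function() {
    detect(render(world$capture_state(), world$camera), params)
  },
  frame = function() render(world$capture_state(), world$camera))
}

#' Corrupt a detection interface (test harness)
#'
#' Wraps another interface with random detection dropout and centroid
#' jitter, to exercise how the closed loop degrades under a misbehaving
#' detector.
#'
#' @param eyes a detection interface.
#' @param dropout probability of dropping each detection.
#' @param jitter_px SD of Gaussian jitter added to box corners.
#' @return a detection interface.
#' @export
corrupt_eyes <- function(eyes, dropout = 0, jitter_px = 0) {
  list(capture = function() {
    dets <- eyes$capture()
    kept <- list()
    for (d in dets) {
      if (dropout > 0 && stats::runif(1) < dropout) next
      if (jitter_px > 0) {
        sh <- stats::rnorm(2, sd = jitter_px)
        b <- d$box
        d <- detection(d$class_label,
                       bbox(max(0, b["x_min"] + sh[1]), max(0, b["y_min"] + sh[2]),
                            max(0, b["x_min"] + sh[1]) + bbox_width(b),
                            max(0, b["y_min"] + sh[2]) + bbox_height(b)),
                       d$confidence)
      }
      kept[[length(kept) + 1L]] <- d
    }
    kept
  })
}
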