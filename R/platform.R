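# Deterministic physics-lite simulator of droplets and magnetic particle
# clusters on an open hydrophobic substrate. World coordinates are mm, origin
# at the field-of-view top-left corner, x rightward, y downward (matching the
# image convention); the default substrate is the 40 x 40 mm field of view.

CONTACT_ANGLE_DEG <- 120  # Teflon-coated glass; fixes the cap geometry

#' Footprint radius of a sessile droplet
#'
#' Droplets are modeled as spherical caps with a fixed 120 degree contact
#' angle (hydrophobic Teflon surface). Only the circular 2-D footprint
#' matters for overlap, anchoring and rendering.
#'
#' @param volume droplet volume in ul (= mm^3). May be vectorized.
#' @return footprint radius in mm.
#' @export
#' @examples
#' footprint_radius(10)  # about 1.22 mm
footprint_radius <- function(volume) {
  stopifnot(all(volume > 0))
  th <- CONTACT_ANGLE_DEG * pi / 180
  # cap volume: V = (pi R^3 / 3) (1 - cos th)^2 (2 + cos th); footprint a = R sin th
  R <- (3 * volume / (pi * (1 - cos(th))^2 * (2 + cos(th))))^(1 / 3)
  R * sin(th)
}

#' Footprint radius of a particle cluster
#'
#' Particle clusters pile up as roughly hemispherical dark mounds; the
#' footprint radius of a hemisphere of the same volume is used for rendering
#' and containment checks.
#'
#' @param volume cluster volume in ul.
#' @return radius in mm.
#' @export
cluster_radius <- function(volume) {
  stopifnot(all(volume > 0))
  (3 * volume / (2 * pi))^(1 / 3)
}

#' Droplet state
#'
#' @param id unique token.
#' @param center numeric `(x, y)` in mm.
#' @param volume liquid volume, ul (> 0).
#' @param color RGB triple in `[0, 255]` for reagent-colored droplets, or
#'   `NULL` for transparent water droplets.
#' @param particle_volume_inside total particle volume carried, ul.
#' @param anchored_set_id id of the surface energy trap pinning the droplet,
#'   or `NULL`.
#' @param props named list of reagent flags (e.g. `cpe`, `imipenem`) used by
#'   the colorimetric reaction rule; merged by logical OR on droplet merging.
#' @return a `droplet_state` object.
#' @export
droplet_state <- function(id, center, volume, color = NULL,
                          particle_volume_inside = 0,
                          anchored_set_id = NULL, props = list()) {
  stopifnot(is.character(id), length(center) == 2L, volume > 0,
            particle_volume_inside >= 0)
  if (!is.null(color)) {
    color <- as.numeric(color)
    if (length(color) != 3L || any(color < 0) || any(color > 255))
      stop("color must be an RGB triple in [0, 255]")
  }
  structure(list(id = id, center = as.numeric(center),
                 volume = as.numeric(volume), color = color,
                 particle_volume_inside = particle_volume_inside,
                 anchored_set_id = anchored_set_id, props = props,
                 residual_volume = 0,
                 reaction_start = NA_real_, reaction_base = NULL),
            class = "droplet_state")
}

#' Particle cluster state
#'
#' @param id unique token.
#' @param center numeric `(x, y)` mm; defaults to the host droplet's center
#'   when assembled into a platform.
#' @param volume particle volume, ul (> 0).
#' @param host_droplet_id id of the droplet containing the cluster, or `NULL`
#'   for an extracted (free) cluster.
#' @return a `particle_cluster_state` object.
#' @export
particle_cluster_state <- function(id, center, volume, host_droplet_id = NULL) {
  stopifnot(is.character(id), length(center) == 2L, volume > 0)
  structure(list(id = id, center = as.numeric(center),
                 volume = as.numeric(volume),
                 host_droplet_id = host_droplet_id),
            class = "particle_cluster_state")
}

#' Electromagnet state
#'
#' The control point (CP) is the software cursor the physical magnet tracks;
#' with a non-zero actuator `lag` the magnet position follows the CP as a
#' first-order delay (the hardware shows about a 1 s response time; tests
#' default to 0 for exact determinism at coarse time steps).
#'
#' @param position `(x, y)` mm within the stage stroke.
#' @param engaged is the field on?
#' @param speed commanded speed, mm/s.
#' @param power_level `"default"` (24 V/0.8 A) or `"high"` (36 V/1.2 A).
#' @param lag actuator first-order time constant, s.
#' @param capture_radius radius (mm) within which a cluster couples to the
#'   magnet (the pole piece is a 3 mm hemisphere cap).
#' @return a `magnet_state` object.
#' @export
magnet_state <- function(position = c(0, 0), engaged = FALSE, speed = 8.33,
                         power_level = "default", lag = 0,
                         capture_radius = 3) {
  power_level <- match.arg(power_level, c("default", "high"))
  stopifnot(length(position) == 2L, speed >= 0, lag >= 0, capture_radius > 0)
  if (any(position < 0) || any(position > 50))
    stop("magnet position outside stage stroke (0-50 mm per axis)")
  structure(list(position = as.numeric(position), cp = as.numeric(position),
                 engaged = isTRUE(engaged), speed = speed,
                 power_level = power_level, lag = lag,
                 capture_radius = capture_radius),
            class = "magnet_state")
}

#' Surface energy trap (SET)
#'
#' A locally hydrophilic patch that pins a droplet whose center comes within
#' `radius` of the trap center, easing particle extraction.
#'
#' @param id unique token.
#' @param center `(x, y)` mm.
#' @param radius trap radius, mm.
#' @return a `surface_energy_trap` object.
#' @export
surface_energy_trap <- function(id, center, radius = 1) {
  stopifnot(is.character(id), length(center) == 2L, radius > 0)
  structure(list(id = id, center = as.numeric(center),
                 radius = as.numeric(radius)),
            class = "surface_energy_trap")
}

#' Full simulated platform state
#'
#' @param droplets list of [droplet_state()] objects.
#' @param clusters list of [particle_cluster_state()] objects. A cluster with
#'   a `host_droplet_id` and an `NA`/missing center is placed at its host's
#'   center.
#' @param magnet a [magnet_state()].
#' @param sets list of [surface_energy_trap()] objects.
#' @param time simulation clock, s.
#' @param bounds substrate `(width, height)` in mm.
#' @return a `platform_state` object.
#' @export
platform_state <- function(droplets = list(), clusters = list(),
                           magnet = magnet_state(), sets = list(),
                           time = 0, bounds = c(40, 40)) {
  names(droplets) <- vapply(droplets, `[[`, "", "id")
  names(clusters) <- vapply(clusters, `[[`, "", "id")
  names(sets) <- vapply(sets, `[[`, "", "id")
  ids <- c(names(droplets), names(clusters), names(sets))
  if (anyDuplicated(ids)) stop("object ids must be unique")
  for (i in seq_along(clusters)) {
    cl <- clusters[[i]]
    if (!is.null(cl$host_droplet_id)) {
      host <- droplets[[cl$host_droplet_id]]
      if (is.null(host)) stop("unknown host droplet: ", cl$host_droplet_id)
      if (any(is.na(cl$center))) clusters[[i]]$center <- host$center
    }
  }
  st <- structure(list(droplets = droplets, clusters = clusters,
                       magnet = magnet, sets = sets, time = as.numeric(time),
                       bounds = as.numeric(bounds)),
                  class = "platform_state")
  refresh_particle_volumes(validate_platform(st))
}

validate_platform <- function(state) {
  for (d in state$droplets) {
    if (any(d$center < 0) || any(d$center > state$bounds))
      stop("droplet ", d$id, " outside substrate bounds")
  }
  state
}

in_bounds <- function(state, point) {
  all(point >= 0) && all(point <= state$bounds)
}

#' Total liquid volume on the platform
#' @param state a [platform_state()].
#' @return total droplet volume in ul.
#' @export
total_liquid_volume <- function(state) {
  sum(vapply(state$droplets, `[[`, 0, "volume"))
}

# particle_volume_inside = hosted cluster volumes + residual left-overs
refresh_particle_volumes <- function(state) {
  for (id in names(state$droplets)) {
    hosted <- Filter(function(cl) identical(cl$host_droplet_id, id),
                     state$clusters)
    state$droplets[[id]]$particle_volume_inside <-
      state$droplets[[id]]$residual_volume +
      sum(vapply(hosted, `[[`, 0, "volume"))
  }
  state
}

dist2d <- function(a, b) sqrt(sum((a - b)^2))

# Colorimetric reaction rule: a droplet holding both a CPE lysate and
# imipenem drifts linearly from its base (red) color to yellow over
# `CARBA_REACTION_S` seconds of incubation. This is the simulator's whole
# stand-in for carbapenem hydrolysis chemistry.
CARBA_REACTION_S <- 3600
CARBA_YELLOW <- c(235, 190, 40)

advance_clock <- function(state, dt) {
  state$time <- state$time + dt
  for (id in names(state$droplets)) {
    d <- state$droplets[[id]]
    if (isTRUE(d$props$cpe) && isTRUE(d$props$imipenem) && !is.null(d$color)) {
      if (is.na(d$reaction_start)) {
        d$reaction_start <- state$time - dt
        d$reaction_base <- d$color
      }
      frac <- min(1, (state$time - d$reaction_start) / CARBA_REACTION_S)
      d$color <- d$reaction_base + frac * (CARBA_YELLOW - d$reaction_base)
      state$droplets[[id]] <- d
    }
  }
  state
}

#' Advance the simulation clock without motion
#'
#' Used for incubation: time passes, reacting droplets change color, nothing
#' moves.
#'
#' @param state a [platform_state()].
#' @param duration seconds (> 0).
#' @return updated state.
#' @export
wait_platform <- function(state, duration) {
  stopifnot(duration > 0)
  advance_clock(state, duration)
}

#' One simulator time step
#'
#' Advances the magnet control point toward `target` by
#' `min(speed * dt, remaining distance)` (subject to the first-order actuator
#' lag), then resolves particle-cluster and droplet motion in the three
#' engagement regimes:
#'
#' * `speed > disengagement_speed`: the magnet outruns the particles; neither
#'   cluster nor droplet moves (disengagement — failed transport).
#' * escape threshold `<= speed <=` disengagement threshold: the cluster
#'   tracks the magnet and crosses the host droplet boundary; once its
#'   center leaves the droplet footprint the host link is cut, a small
#'   residual particle fraction stays behind, and the droplet does not move
#'   (extraction). The escape threshold is [extraction_speed()] for an
#'   anchored droplet and `k_drag + k_exit * Vp / g` for a free one.
#' * `speed` below the escape threshold: surface tension traps the cluster;
#'   the host droplet is dragged along with it (transport) — unless the
#'   droplet is anchored on a SET, in which case nothing moves.
#'
#' Volumes are unchanged; only explicit priming changes total liquid volume.
#'
#' @param state a [platform_state()].
#' @param target magnet target `(x, y)` in mm (must lie within bounds).
#' @param speed commanded speed, mm/s (>= 0).
#' @param dt time step, s (> 0).
#' @param model an [engagement_model()].
#' @return the updated state.
#' @export
step_platform <- function(state, target, speed, dt, model) {
  stopifnot(inherits(state, "platform_state"), inherits(model, "engagement_model"))
  if (dt <= 0) stop("dt must be positive")
  if (speed < 0) stop("speed must be non-negative")
  if (!in_bounds(state, target)) stop("target outside substrate bounds")

  mag <- state$magnet
  old_pos <- mag$position
  # CP kinematics
  to_go <- dist2d(mag$cp, target)
  if (to_go > 0) {
    adv <- min(speed * dt, to_go)
    mag$cp <- mag$cp + (target - mag$cp) / to_go * adv
  }
  # magnet follows CP with first-order lag
  if (mag$lag > 0) {
    mag$position <- mag$position + (mag$cp - mag$position) * (1 - exp(-dt / mag$lag))
  } else {
    mag$position <- mag$cp
  }
  state$magnet <- mag

  if (mag$engaged) {
    for (cid in names(state$clusters)) {
      cl <- state$clusters[[cid]]
      if (dist2d(cl$center, old_pos) > mag$capture_radius) next
      v_mag <- disengagement_speed(model, cl$volume, mag$power_level)
      if (speed > v_mag) next  # disengaged: nothing moves
      new_center <- mag$position
      host_id <- cl$host_droplet_id
      if (is.null(host_id)) {
        cl$center <- new_center
        state$clusters[[cid]] <- cl
        state <- maybe_rehost(state, cid, speed, model)
      } else {
        d <- state$droplets[[host_id]]
        anchored <- !is.null(d$anchored_set_id)
        v_esc <- escape_speed(model, cl$volume, anchored, mag$power_level)
        if (speed >= v_esc) {
          # extraction regime: cluster crosses the droplet boundary
          cl$center <- new_center
          if (dist2d(new_center, d$center) > footprint_radius(d$volume)) {
            cl$host_droplet_id <- NULL
            left <- model$residual_fraction * cl$volume
            d$residual_volume <- d$residual_volume + left
            cl$volume <- cl$volume - left
            state$droplets[[host_id]] <- d
          }
          state$clusters[[cid]] <- cl
        } else if (anchored) {
          # droplet pinned, cluster retained: nothing moves
        } else {
          # transport regime: droplet rides along with its particles
          cl$center <- new_center
          d$center <- new_center
          state$clusters[[cid]] <- cl
          state$droplets[[host_id]] <- d
        }
      }
    }
  }
  refresh_particle_volumes(advance_clock(state, dt))
}

# a free cluster dragged into a droplet footprint below the exit threshold
# is recaptured by surface tension
maybe_rehost <- function(state, cid, speed, model) {
  cl <- state$clusters[[cid]]
  for (d in state$droplets) {
    if (dist2d(cl$center, d$center) <= footprint_radius(d$volume)) {
      v_esc <- escape_speed(model, cl$volume,
                            !is.null(d$anchored_set_id),
                            state$magnet$power_level)
      if (speed < v_esc) {
        state$clusters[[cid]]$host_droplet_id <- d$id
        return(refresh_particle_volumes(state))
      }
    }
  }
  state
}

#' Merge droplets brought into contact
#'
#' Any two droplets whose circular footprints overlap are replaced by a
#' single droplet carrying the summed volume, the summed particle content,
#' the volume-weighted centroid and the volume-weighted RGB average of the
#' colored parents (transparent parents dilute nothing visually). Reagent
#' flags combine by logical OR, which is what arms the Carba NP reaction
#' when a lysate droplet meets an imipenem-bearing droplet. Applied to a
#' fixed point, so chain contacts collapse in one call; idempotent once no
#' overlaps remain.
#'
#' @param state a [platform_state()].
#' @return updated state.
#' @export
contact_merge <- function(state) {
  repeat {
    pair <- find_overlapping_pair(state$droplets)
    if (is.null(pair)) break
    state <- merge_pair(state, pair[1], pair[2])
  }
  refresh_particle_volumes(state)
}

find_overlapping_pair <- function(droplets) {
  ids <- names(droplets)
  n <- length(ids)
  if (n < 2L) return(NULL)
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    a <- droplets[[i]]; b <- droplets[[j]]
    if (dist2d(a$center, b$center) <
        footprint_radius(a$volume) + footprint_radius(b$volume))
      return(c(ids[i], ids[j]))
  }
  NULL
}

merge_pair <- function(state, id_a, id_b) {
  a <- state$droplets[[id_a]]; b <- state$droplets[[id_b]]
  if (b$volume > a$volume) { tmp <- a; a <- b; b <- tmp }  # keep larger id
  vol <- a$volume + b$volume
  center <- (a$center * a$volume + b$center * b$volume) / vol
  color <- merged_color(a, b)
  props <- a$props
  for (nm in names(b$props)) {
    props[[nm]] <- isTRUE(props[[nm]]) || isTRUE(b$props[[nm]])
  }
  m <- droplet_state(a$id, center, vol, color = color, props = props)
  m$residual_volume <- a$residual_volume + b$residual_volume
  # anchoring re-derived from trap geometry at the new centroid
  for (s in state$sets) {
    if (dist2d(center, s$center) <= s$radius) { m$anchored_set_id <- s$id; break }
  }
  state$droplets[[a$id]] <- m
  state$droplets[[b$id]] <- NULL
  for (cid in names(state$clusters)) {
    if (identical(state$clusters[[cid]]$host_droplet_id, b$id))
      state$clusters[[cid]]$host_droplet_id <- a$id
  }
  state
}

merged_color <- function(a, b) {
  if (is.null(a$color) && is.null(b$color)) return(NULL)
  if (is.null(a$color)) return(b$color)
  if (is.null(b$color)) return(a$color)
  (a$color * a$volume + b$color * b$volume) / (a$volume + b$volume)
}

#' Anchor droplets sitting on surface energy traps
#'
#' A droplet whose center lies within a trap radius becomes anchored (and
#' then refuses to translate during [step_platform()]). Anchoring is sticky:
#' no closed-loop operation releases it — droplets stay parked at their SETs.
#'
#' @param state a [platform_state()].
#' @return updated state.
#' @export
anchor_check <- function(state) {
  for (id in names(state$droplets)) {
    d <- state$droplets[[id]]
    if (!is.null(d$anchored_set_id)) next
    for (s in state$sets) {
      if (dist2d(d$center, s$center) <= s$radius) {
        state$droplets[[id]]$anchored_set_id <- s$id
        break
      }
    }
  }
  state
}

#' One trace row per simulated object
#'
#' @param state a [platform_state()].
#' @return data frame with columns `time`, `id`, `class`, `x`, `y`, `volume`.
#' @export
platform_trace <- function(state) {
  rows <- list()
  for (d in state$droplets)
    rows[[length(rows) + 1L]] <- data.frame(
      time = state$time, id = d$id, class = "droplet",
      x = d$center[1], y = d$center[2], volume = d$volume)
  for (cl in state$clusters)
    rows[[length(rows) + 1L]] <- data.frame(
      time = state$time, id = cl$id, class = "particle",
      x = cl$center[1], y = cl$center[2], volume = cl$volume)
  rows[[length(rows) + 1L]] <- data.frame(
    time = state$time, id = "magnet", class = "magnet",
    x = state$magnet$position[1], y = state$magnet$position[2],
    volume = NA_real_)
  do.call(rbind, rows)
}

#' @export
print.platform_state <- function(x, ...) {
  cat(sprintf("<platform_state> t=%.1fs, %d droplet(s), %d cluster(s), %d SET(s)\n",
              x$time, length(x$droplets), length(x$clusters), length(x$sets)))
  invisible(x)
}
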