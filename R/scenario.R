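# Scenario files: human-editable JSON declaring droplets, clusters, SETs,
# engagement-model constants and magnet defaults. All geometry in mm, all
# volumes in ul.

#' Read a scenario file
#'
#' @param path JSON file, or a list already parsed from one.
#' @return list with elements `state` ([platform_state()]),
#'   `model` ([engagement_model()]) and `camera` ([camera_model()]).
#' @export
read_scenario <- function(path) {
  cfg <- if (is.list(path)) path else jsonlite::read_json(path, simplifyVector = TRUE)
  scenario_from_config(cfg)
}

scenario_from_config <- function(cfg) {
  model <- do.call(engagement_model, as.list(cfg$model %||% list()))
  mg <- as.list(cfg$magnet %||% list())
  magnet <- magnet_state(position = mg$position %||% c(1, 1),
                         speed = mg$speed %||% 8.33,
                         power_level = mg$power_level %||% "default",
                         lag = mg$lag %||% 0,
                         capture_radius = mg$capture_radius %||% 3)
  droplets <- lapply(rows_of(cfg$droplets), function(d)
    droplet_state(id = d$id, center = unlist(d$center), volume = d$volume,
                  color = if (!is.null(d$color)) unlist(d$color),
                  props = as.list(d$props %||% list())))
  clusters <- lapply(rows_of(cfg$clusters), function(cl)
    particle_cluster_state(id = cl$id,
                           center = if (is.null(cl$center)) c(NA_real_, NA_real_)
                                    else unlist(cl$center),
                           volume = cl$volume,
                           host_droplet_id = cl$host %||% cl$host_droplet_id))
  sets <- lapply(rows_of(cfg$sets), function(s)
    surface_energy_trap(id = s$id, center = unlist(s$center),
                        radius = s$radius %||% 1))
  bounds <- unlist(cfg$bounds %||% c(40, 40))
  state <- platform_state(droplets, clusters, magnet, sets, bounds = bounds)
  camera <- do.call(camera_model, as.list(cfg$camera %||% list()))
  list(state = state, model = model, camera = camera)
}

# jsonlite may hand a data.frame (homogeneous records) or a list of lists
rows_of <- function(x) {
  if (is.null(x)) return(list())
  if (is.data.frame(x)) return(lapply(seq_len(nrow(x)), function(i) {
    row <- lapply(x, function(col) {
      v <- if (is.data.frame(col)) {
        # nested record (e.g. per-droplet props): one row -> named list
        sub <- as.list(col[i, , drop = FALSE])
        sub <- Filter(function(z) !(is.atomic(z) && length(z) == 1L && is.na(z)),
                      sub)
        if (length(sub) == 0L) NULL else sub
      } else if (is.list(col)) col[[i]] else col[i]
      if (is.null(v) || (is.atomic(v) && length(v) == 1L && is.na(v))) NULL else v
    })
    Filter(Negate(is.null), row)
  }))
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
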