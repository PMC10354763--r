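#' Parametric magnet-particle engagement model
#'
#' The physics of magnetic droplet actuation admits three regimes, ordered by
#' the commanded magnet speed for a given particle load: below the extraction
#' threshold the particle cluster drags its host droplet along (transport);
#' between the extraction and disengagement thresholds the cluster can be
#' pulled across the droplet boundary (solid/liquid separation); above the
#' disengagement threshold the magnet outruns the particles and nothing moves.
#' The model captures those thresholds with two linear coefficients:
#' `v_disengage = k_mag * Vp * g` and `v_extract = k_exit * Vp * s / g`,
#' where `Vp` is the particle volume (ul), `g` the power gain (1 at default
#' power, `power_gain` at high power) and `s` the surface-energy-trap (SET)
#' reduction factor applied when the host droplet is anchored.
#'
#' `k_mag > k_exit > 0` guarantees a non-empty feasible extraction window at
#' every particle load and power level.
#'
#' An unanchored droplet is free to follow its cluster, so pulling the
#' cluster out of it additionally requires outpacing the droplet's own drag:
#' the free-droplet escape threshold is `k_drag + k_exit * Vp / g`, strictly
#' above the retention threshold [extraction_speed()] reports. Anchoring on
#' a SET removes that freedom and the plain (set_factor-reduced) retention
#' threshold applies — which is why SETs facilitate extraction.
#'
#' @param k_mag magnet-particle coupling, mm/(s*ul). Default 20.
#' @param k_exit surface-tension retention, mm/(s*ul). Default 8.
#' @param k_drag free-droplet drag baseline, mm/s: the speed offset a
#'   cluster must exceed to escape an unanchored droplet. Default 6.
#' @param set_factor multiplier in (0,1) applied to the extraction threshold
#'   when the host droplet is anchored on a SET. Default 0.5.
#' @param power_gain multiplier (>= 1) applied at high power (36 V/1.2 A
#'   versus the default 24 V/0.8 A). Default 1.5.
#' @param residual_fraction fraction of the cluster volume left behind in the
#'   droplet after a successful extraction. Default 0.02.
#' @return an object of class `engagement_model`.
#' @export
#' @examples
#' m <- engagement_model()
#' disengagement_speed(m, 0.5)  # 10 mm/s
#' extraction_speed(m, 1.0, anchored = FALSE)  # 8 mm/s
engagement_model <- function(k_mag = 20, k_exit = 8, k_drag = 6,
                             set_factor = 0.5, power_gain = 1.5,
                             residual_fraction = 0.02) {
  stopifnot(is.numeric(k_mag), is.numeric(k_exit), length(k_mag) == 1L,
            length(k_exit) == 1L)
  if (!(k_mag > k_exit) || k_exit <= 0)
    stop("engagement model requires k_mag > k_exit > 0")
  if (set_factor <= 0 || set_factor >= 1)
    stop("set_factor must lie in (0, 1)")
  if (power_gain < 1)
    stop("power_gain must be >= 1")
  if (residual_fraction < 0 || residual_fraction >= 1)
    stop("residual_fraction must lie in [0, 1)")
  structure(list(k_mag = k_mag, k_exit = k_exit, k_drag = k_drag,
                 set_factor = set_factor, power_gain = power_gain,
                 residual_fraction = residual_fraction),
            class = "engagement_model")
}

power_gain_of <- function(model, power_level) {
  power_level <- match.arg(power_level, c("default", "high"))
  if (power_level == "high") model$power_gain else 1
}

#' Magnet disengagement speed threshold
#'
#' Highest commanded speed at which the magnet still carries a particle
#' cluster of the given volume. Above this speed the magnet disengages: the
#' particles (and any host droplet) stay behind. Linear in particle volume
#' and monotone non-decreasing in power.
#'
#' @param model an [engagement_model()].
#' @param particle_volume particle cluster volume, ul (>= 0).
#' @param power_level `"default"` (24 V/0.8 A) or `"high"` (36 V/1.2 A).
#' @return threshold speed in mm/s.
#' @export
disengagement_speed <- function(model, particle_volume,
                                power_level = "default") {
  stopifnot(inherits(model, "engagement_model"))
  if (!is.numeric(particle_volume) || any(particle_volume < 0))
    stop("particle_volume must be non-negative")
  model$k_mag * particle_volume * power_gain_of(model, power_level)
}

#' Particle extraction speed threshold
#'
#' Lowest commanded speed at which a particle cluster can be pulled across
#' its host droplet's boundary. Anchoring the droplet on a SET lowers the
#' threshold by `set_factor`; a stronger field lowers it by `1/power_gain`.
#' Always strictly below [disengagement_speed()] for the same inputs, so an
#' extraction-feasible speed window exists for every load.
#'
#' @inheritParams disengagement_speed
#' @param anchored is the host droplet anchored on a surface energy trap?
#' @return threshold speed in mm/s.
#' @export
extraction_speed <- function(model, particle_volume, anchored = FALSE,
                             power_level = "default") {
  stopifnot(inherits(model, "engagement_model"))
  if (!is.numeric(particle_volume) || any(particle_volume <= 0))
    stop("particle_volume must be positive")
  g <- power_gain_of(model, power_level)
  v <- model$k_exit * particle_volume / g
  if (isTRUE(anchored)) v <- v * model$set_factor
  v
}

# speed at which a hosted cluster actually crosses the droplet boundary:
# anchored droplets hold still, so the retention threshold applies; a free
# droplet rides along, so the cluster must additionally beat droplet drag
escape_speed <- function(model, particle_volume, anchored, power_level) {
  if (isTRUE(anchored))
    return(extraction_speed(model, particle_volume, TRUE, power_level))
  model$k_drag +
    model$k_exit * particle_volume / power_gain_of(model, power_level)
}
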