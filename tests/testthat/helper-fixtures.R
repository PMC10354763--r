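# Scenario builders used across the suite. Everything is generated in code;
# no stored fixtures.

dist_between <- function(a, b) sqrt(sum((a - b)^2))

# one droplet with a hosted cluster, default-model world + faithful eyes
make_transport_world <- function(particle_ul = 0.5, droplet_ul = 10,
                                 model = engagement_model(),
                                 start_mm = c(10, 20), sets = list()) {
  st <- platform_state(
    droplets = list(droplet_state("d1", start_mm, droplet_ul)),
    clusters = list(particle_cluster_state("p1", c(NA, NA), particle_ul,
                                           host_droplet_id = "d1")),
    magnet = magnet_state(position = c(1, 1)),
    sets = sets)
  w <- sim_world(st, model)
  list(world = w, eyes = perfect_eyes(w))
}

# two droplets, particles in the first
make_merge_world <- function(model = engagement_model()) {
  st <- platform_state(
    droplets = list(droplet_state("a", c(8, 20), 10),
                    droplet_state("b", c(20, 20), 10)),
    clusters = list(particle_cluster_state("p1", c(NA, NA), 0.5,
                                           host_droplet_id = "a")))
  w <- sim_world(st, model)
  list(world = w, eyes = perfect_eyes(w))
}

# a single colored droplet with a cluster inside, rendered
make_colored_frame <- function(lux = 400, color = c(220, 40, 50)) {
  st <- platform_state(
    droplets = list(droplet_state("d1", c(20, 20), 12, color = color)),
    clusters = list(particle_cluster_state("p1", c(20, 20), 0.8,
                                           host_droplet_id = "d1")))
  render(st, camera_model(illumination = lux))
}

# integer-coordinate random boxes for evaluation oracle tests
random_box_df <- function(n, frame_id, cls, with_conf = TRUE) {
  if (n == 0L) {
    df <- data.frame(frame_id = character(), class = character(),
                     x_min = numeric(), y_min = numeric(),
                     x_max = numeric(), y_max = numeric())
    if (with_conf) df$confidence <- numeric()
    return(df)
  }
  x0 <- sample(0:80, n, replace = TRUE)
  y0 <- sample(0:80, n, replace = TRUE)
  df <- data.frame(frame_id = frame_id, class = cls,
                   x_min = x0, y_min = y0,
                   x_max = x0 + sample(5:30, n, replace = TRUE),
                   y_max = y0 + sample(5:30, n, replace = TRUE),
                   stringsAsFactors = FALSE)
  # coarse confidences create deliberate ties
  if (with_conf) df$confidence <- sample(seq(0.1, 1, by = 0.1), n,
                                         replace = TRUE)
  df
}
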