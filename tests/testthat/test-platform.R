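test_that("step moves droplet and cluster together in the transport regime", {
  m <- engagement_model()
  st <- platform_state(
    droplets = list(droplet_state("d1", c(10, 20), 10)),
    clusters = list(particle_cluster_state("p1", c(NA, NA), 0.5, "d1")),
    magnet = magnet_state(position = c(10, 20), engaged = TRUE))
  # 5 mm/s is below both the disengagement (10) and escape (10) thresholds
  st2 <- step_platform(st, c(30, 20), 5, 1, m)
  expect_equal(st2$droplets$d1$center, c(15, 20))
  expect_equal(st2$clusters$p1$center, c(15, 20))
  expect_equal(st2$time, 1)
})

test_that("step disengages above the disengagement threshold", {
  m <- engagement_model()
  st <- platform_state(
    droplets = list(droplet_state("d1", c(10, 20), 10)),
    clusters = list(particle_cluster_state("p1", c(NA, NA), 0.5, "d1")),
    magnet = magnet_state(position = c(10, 20), engaged = TRUE))
  st2 <- step_platform(st, c(30, 20), 12, 0.5, m)  # > 10 mm/s
  expect_equal(st2$droplets$d1$center, c(10, 20))
  expect_equal(st2$clusters$p1$center, c(10, 20))
  expect_equal(st2$magnet$position, c(16, 20))  # magnet alone advanced
})

test_that("a disengaged (off) magnet moves nothing at any speed", {
  m <- engagement_model()
  st <- platform_state(
    droplets = list(droplet_state("d1", c(10, 20), 10)),
    clusters = list(particle_cluster_state("p1", c(NA, NA), 0.5, "d1")),
    magnet = magnet_state(position = c(10, 20), engaged = FALSE))
  for (v in c(1, 8.33, 30)) {
    st2 <- step_platform(st, c(30, 20), v, 0.5, m)
    expect_equal(st2$droplets$d1$center, c(10, 20))
    expect_equal(st2$clusters$p1$center, c(10, 20))
  }
})

test_that("fast motion pulls the cluster across the boundary of a free droplet", {
  m <- engagement_model()
  st <- platform_state(
    droplets = list(droplet_state("d1", c(10, 20), 10)),
    clusters = list(particle_cluster_state("p1", c(NA, NA), 1.0, "d1")),
    magnet = magnet_state(position = c(10, 20), engaged = TRUE))
  # free-droplet escape threshold = 6 + 8*1 = 14 <= 15 <= disengagement 20
  st2 <- st
  for (i in 1:10) st2 <- step_platform(st2, c(30, 20), 15, 0.2, m)
  expect_null(st2$clusters$p1$host_droplet_id)
  expect_equal(st2$droplets$d1$center, c(10, 20))          # droplet stayed
  expect_gt(dist_between(st2$clusters$p1$center, c(10, 20)), 5)
  # residual particles remain behind
  expect_equal(st2$droplets$d1$particle_volume_inside, 0.02 * 1.0)
  expect_equal(st2$clusters$p1$volume, 0.98)
})

test_that("step validates its arguments", {
  m <- engagement_model()
  st <- platform_state(droplets = list(droplet_state("d1", c(10, 20), 10)))
  expect_error(step_platform(st, c(60, 20), 5, 1, m), "outside")
  expect_error(step_platform(st, c(30, 20), 5, 0, m), "dt")
  expect_error(step_platform(st, c(30, 20), -1, 1, m), "speed")
})

test_that("contact_merge pools volume, centroid, color and particles", {
  st <- platform_state(
    droplets = list(droplet_state("a", c(10, 20), 10, color = c(200, 0, 0)),
                    droplet_state("b", c(11, 20), 10, color = c(0, 0, 200))))
  st2 <- contact_merge(st)
  expect_length(st2$droplets, 1)
  d <- st2$droplets[[1]]
  expect_equal(d$volume, 20)
  expect_equal(d$center, c(10.5, 20))
  expect_equal(d$color, c(100, 0, 100))
  expect_equal(total_liquid_volume(st2), total_liquid_volume(st))
  # merged footprint grows beyond each parent
  expect_gt(footprint_radius(20), footprint_radius(10))
  # idempotent once no overlaps remain
  expect_identical(contact_merge(st2)$droplets, st2$droplets)
})

test_that("contact_merge leaves disjoint droplets untouched", {
  st <- platform_state(
    droplets = list(droplet_state("a", c(5, 5), 10),
                    droplet_state("b", c(30, 30), 10)))
  expect_identical(contact_merge(st)$droplets, st$droplets)
})

test_that("merging ORs reagent flags and remaps cluster hosts", {
  st <- platform_state(
    droplets = list(
      droplet_state("a", c(10, 20), 10, color = c(220, 40, 50),
                    props = list(imipenem = TRUE)),
      droplet_state("b", c(11, 20), 5, props = list(cpe = TRUE))),
    clusters = list(particle_cluster_state("p1", c(11, 20), 0.5, "b")))
  st2 <- contact_merge(st)
  d <- st2$droplets[[1]]
  expect_true(d$props$imipenem)
  expect_true(d$props$cpe)
  expect_equal(d$color, c(220, 40, 50))  # transparent parent dilutes nothing
  expect_identical(st2$clusters$p1$host_droplet_id, d$id)
})

test_that("anchor_check pins droplets on SETs and step respects anchoring", {
  m <- engagement_model()
  st <- platform_state(
    droplets = list(droplet_state("d1", c(20, 20), 10),
                    droplet_state("d2", c(5, 5), 10)),
    clusters = list(particle_cluster_state("p1", c(NA, NA), 0.5, "d1")),
    magnet = magnet_state(position = c(20, 20), engaged = TRUE),
    sets = list(surface_energy_trap("s1", c(20.5, 20), radius = 1)))
  st <- anchor_check(st)
  expect_identical(st$droplets$d1$anchored_set_id, "s1")
  expect_null(st$droplets$d2$anchored_set_id)
  # anchored droplet does not translate at transport speeds (below the
  # anchored escape threshold of 2 mm/s for a 0.5 ul load)
  st3 <- step_platform(st, c(30, 20), 1.9, 1, m)
  expect_equal(st3$droplets$d1$center, c(20, 20))
  expect_equal(st3$clusters$p1$center, c(20, 20))
})

test_that("volume is conserved across arbitrary operation sequences", {
  m <- engagement_model()
  set.seed(42)
  for (rep in 1:5) {
    st <- platform_state(
      droplets = list(droplet_state("a", c(10, 10), runif(1, 5, 15)),
                      droplet_state("b", c(30, 30), runif(1, 5, 15)),
                      droplet_state("c", c(10, 30), runif(1, 2, 8))),
      clusters = list(particle_cluster_state("p1", c(NA, NA), 0.5, "a")),
      magnet = magnet_state(position = c(10, 10), engaged = TRUE),
      sets = list(surface_energy_trap("s1", c(35, 35), 1)))
    v0 <- total_liquid_volume(st)
    for (k in 1:30) {
      st <- step_platform(st, c(runif(1, 2, 38), runif(1, 2, 38)),
                          runif(1, 0, 15), 0.3, m)
      if (k %% 5 == 0) st <- anchor_check(contact_merge(st))
    }
    expect_equal(total_liquid_volume(st), v0, tolerance = 1e-12)
  }
})

test_that("the simulator is deterministic", {
  m <- engagement_model()
  run <- function() {
    st <- platform_state(
      droplets = list(droplet_state("d1", c(10, 20), 10)),
      clusters = list(particle_cluster_state("p1", c(NA, NA), 0.5, "d1")),
      magnet = magnet_state(position = c(10, 20), engaged = TRUE))
    for (k in 1:20) st <- step_platform(st, c(35, 25), 5, 0.25, m)
    st
  }
  expect_identical(run(), run())
})

test_that("actuator lag delays the magnet behind the control point", {
  m <- engagement_model()
  st <- platform_state(
    droplets = list(droplet_state("d1", c(30, 30), 10)),
    magnet = magnet_state(position = c(10, 20), lag = 1))
  st2 <- step_platform(st, c(20, 20), 5, 0.5, m)
  expect_equal(st2$magnet$cp, c(12.5, 20))
  expect_lt(st2$magnet$position[1], st2$magnet$cp[1])
  expect_gt(st2$magnet$position[1], 10)
})

test_that("platform trace and scenario round-trip work", {
  sc <- list(
    bounds = c(40, 40),
    model = list(k_mag = 15, k_exit = 5),
    magnet = list(position = c(2, 2), power_level = "high"),
    droplets = list(list(id = "d1", center = c(10, 20), volume = 10,
                         color = c(220, 40, 50))),
    clusters = list(list(id = "p1", host = "d1", volume = 0.5)),
    sets = list(list(id = "s1", center = c(30, 20), radius = 1)))
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(sc, path, auto_unbox = TRUE, digits = NA)
  loaded <- read_scenario(path)
  expect_equal(loaded$model$k_mag, 15)
  expect_equal(loaded$state$droplets$d1$color, c(220, 40, 50))
  expect_equal(loaded$state$clusters$p1$center, c(10, 20))  # placed at host
  expect_equal(loaded$state$magnet$power_level, "high")
  tr <- platform_trace(loaded$state)
  expect_setequal(tr$id, c("d1", "p1", "s1"[0], "magnet"))
  expect_true(all(c("time", "class", "x", "y", "volume") %in% names(tr)))
})
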