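test_that("success criteria use the stated inclusive thresholds", {
  # arrival: "within 10 px" includes exactly 10 px
  expect_true(at_destination(c(0, 0), c(0, 0), 10))
  expect_true(at_destination(c(10, 0), c(0, 0), 10))
  expect_false(at_destination(c(10.5, 0), c(0, 0), 10))
  expect_false(at_destination(c(8, 8), c(0, 0), 10))  # sqrt(128) > 10

  # merge: >= 3 px growth in BOTH dimensions
  before <- bbox(0, 0, 40, 40)
  expect_true(merge_succeeded(before, bbox(0, 0, 43, 43), 3))
  expect_false(merge_succeeded(before, bbox(0, 0, 44, 42), 3))
  expect_false(merge_succeeded(before, before, 3))

  # extraction: disjoint boxes, touching edges count as separated
  expect_false(extraction_succeeded(bbox(10, 10, 20, 20), bbox(0, 0, 40, 40)))
  expect_true(extraction_succeeded(bbox(40, 0, 50, 10), bbox(0, 0, 40, 40)))
  expect_true(extraction_succeeded(bbox(90, 0, 100, 10), bbox(0, 0, 40, 40)))
})

test_that("transport succeeds without retries when the load allows it", {
  fx <- make_transport_world(particle_ul = 0.5)
  res <- transport(list(c(300, 200)), operation_config(), fx$world, fx$eyes)
  expect_equal(res$status, "success")
  expect_equal(res$retries, 0)
  st <- fx$world$capture_state()
  expect_equal(st$droplets$d1$center, c(30, 20), tolerance = 1e-6)
  expect_false(st$magnet$engaged)  # released at the end
})

test_that("transport rectifies disengagement by slowing down", {
  # 0.3 ul: disengagement at 6 mm/s < default 8.33 -> one retry at 5.0
  fx <- make_transport_world(particle_ul = 0.3)
  res <- transport(list(c(300, 200)), operation_config(), fx$world, fx$eyes)
  expect_equal(res$status, "success")
  expect_equal(res$retries, 1)
  speeds <- vapply(res$attempts, `[[`, 0, "speed")
  expect_equal(speeds, c(8.33, 8.33 * 0.6))
  expect_true(all(diff(speeds) < 0))
  d <- fx$world$capture_state()$droplets$d1
  expect_true(at_destination(d$center * 10, c(300, 200), 10))
})

test_that("transport is a no-op when already at the destination", {
  fx <- make_transport_world()
  before <- fx$world$capture_state()
  res <- transport(list(c(101, 200)), operation_config(), fx$world, fx$eyes)
  expect_equal(res$status, "success")
  expect_equal(res$retries, 0)
  expect_equal(res$attempts[[1]]$outcome, "already-at-destination")
  expect_equal(fx$world$capture_state()$droplets$d1$center, before$droplets$d1$center)
})

test_that("transport fails cleanly when no speed works", {
  # magnet cannot carry 0.02 ul at any speed the schedule reaches
  fx <- make_transport_world(particle_ul = 0.02)
  res <- transport(list(c(300, 200)), operation_config(), fx$world, fx$eyes)
  expect_equal(res$status, "failed")
  expect_equal(res$retries, operation_config()$max_retries)
  expect_error(transport(list(), operation_config(), fx$world, fx$eyes),
               "non-empty")
})

test_that("transport requires detected particles", {
  st <- platform_state(droplets = list(droplet_state("d1", c(10, 20), 10)))
  w <- sim_world(st, engagement_model())
  expect_error(transport(list(c(300, 200)), operation_config(), w,
                         perfect_eyes(w)),
               "no particle cluster")
})

test_that("extraction retries upward and separates a heavy load", {
  # 1 ul unanchored: escape at 14 mm/s; attempts 12.5 (fail), 18.75 (ok)
  fx <- make_transport_world(particle_ul = 1.0, start_mm = c(20, 20))
  res <- extract_particles("EAST", 60, operation_config(), fx$world, fx$eyes)
  expect_equal(res$status, "success")
  expect_equal(res$retries, 1)
  speeds <- vapply(res$attempts, `[[`, 0, "speed")
  expect_equal(speeds, 8.33 * 1.5 * c(1, 1.5))
  expect_true(all(diff(speeds) > 0))
  st <- fx$world$capture_state()
  expect_null(st$clusters$p1$host_droplet_id)
  # the failed attempt dragged droplet and particles together (they still
  # overlapped — the stated failure signature); the retry left the droplet
  # behind, west of the escaped cluster
  expect_lt(st$droplets$d1$center[1], st$clusters$p1$center[1])
  dets <- fx$eyes$capture()
  labs <- vapply(dets, `[[`, "", "class_label")
  expect_true(extraction_succeeded(dets[[which(labs == "particle")]]$box,
                                   dets[[which(labs == "droplet")]]$box))
})

test_that("a SET anchor lowers the speed needed for extraction", {
  cfg <- operation_config()
  run_first_success_speed <- function(sets) {
    fx <- make_transport_world(particle_ul = 1.0, start_mm = c(20, 20),
                               sets = sets)
    fx$world$state <- anchor_check(fx$world$state)
    res <- extract_particles("EAST", 60, cfg, fx$world, fx$eyes)
    expect_equal(res$status, "success")
    vapply(res$attempts, `[[`, 0, "speed")[res$retries + 1]
  }
  v_anchored <- run_first_success_speed(
    list(surface_energy_trap("s1", c(20, 20), 1)))
  v_free <- run_first_success_speed(list())
  expect_lt(v_anchored, v_free)
})

test_that("extraction with already-separated boxes is an immediate success", {
  st <- platform_state(
    droplets = list(droplet_state("d1", c(10, 20), 10)),
    clusters = list(particle_cluster_state("p1", c(25, 20), 1.0)))
  w <- sim_world(st, engagement_model())
  res <- extract_particles("EAST", 60, operation_config(), w, perfect_eyes(w))
  expect_equal(res$status, "success")
  expect_equal(res$retries, 0)
})

test_that("merge transports the particle-bearing droplet and checks growth", {
  fx <- make_merge_world()
  res <- merge_droplets(c(80, 200), c(200, 200), operation_config(),
                        fx$world, fx$eyes)
  expect_equal(res$status, "success")
  st <- fx$world$capture_state()
  expect_length(st$droplets, 1)          # detection count drops by one
  expect_equal(total_liquid_volume(st), 20)
  dets <- fx$eyes$capture()
  expect_length(Filter(function(d) d$class_label == "droplet", dets), 1)
})

test_that("merge enforces its particle precondition", {
  # no particles at all
  st <- platform_state(
    droplets = list(droplet_state("a", c(8, 20), 10),
                    droplet_state("b", c(20, 20), 10)))
  w <- sim_world(st, engagement_model())
  expect_error(merge_droplets(c(80, 200), c(200, 200), operation_config(),
                              w, perfect_eyes(w)),
               "no particle")
  # particles in both droplets
  st2 <- platform_state(
    droplets = list(droplet_state("a", c(8, 20), 10),
                    droplet_state("b", c(20, 20), 10)),
    clusters = list(particle_cluster_state("p1", c(NA, NA), 0.5, "a"),
                    particle_cluster_state("p2", c(NA, NA), 0.5, "b")))
  w2 <- sim_world(st2, engagement_model())
  expect_error(merge_droplets(c(80, 200), c(200, 200), operation_config(),
                              w2, perfect_eyes(w2)),
               "exactly one")
})

test_that("mixing completes its loops and returns to the center", {
  fx <- make_transport_world(particle_ul = 0.5, start_mm = c(20, 20))
  res <- mix_droplet(2, 30, operation_config(), fx$world, fx$eyes)
  expect_equal(res$status, "success")
  d <- fx$world$capture_state()$droplets$d1
  expect_true(at_destination(d$center * 10, c(200, 200), 10))
  expect_error(mix_droplet(0, 30, operation_config(), fx$world, fx$eyes),
               "loops")
})

test_that("mixing honors a custom waypoint path", {
  fx <- make_transport_world(particle_ul = 0.5, start_mm = c(10, 10))
  path <- list(c(250, 100), c(250, 250), c(100, 250))
  res <- mix_droplet(1, 0, operation_config(), fx$world, fx$eyes, path = path)
  expect_equal(res$status, "success")
  d <- fx$world$capture_state()$droplets$d1
  expect_true(at_destination(d$center * 10, c(100, 250), 10))
})

test_that("the controller degrades to failure under a blind detector", {
  fx <- make_transport_world(particle_ul = 0.5)
  # a detector that always reports the particles where they started
  frozen <- local({
    snap <- fx$eyes$capture()
    list(capture = function() snap)
  })
  res <- transport(list(c(300, 200)), operation_config(), fx$world, frozen)
  expect_equal(res$status, "failed")
  expect_equal(res$retries, operation_config()$max_retries)
  # jittered-but-honest detector still converges
  fx2 <- make_transport_world(particle_ul = 0.5)
  set.seed(1)
  noisy <- corrupt_eyes(fx2$eyes, dropout = 0, jitter_px = 1.5)
  res2 <- transport(list(c(300, 200)), operation_config(), fx2$world, noisy)
  expect_equal(res2$status, "success")
})

test_that("identical commands replay to identical end states and logs", {
  run <- function() {
    fx <- make_transport_world(particle_ul = 0.3)
    transport(list(c(300, 200), c(150, 300)), operation_config(),
              fx$world, fx$eyes)
    list(state = fx$world$capture_state(), events = fx$world$events())
  }
  a <- run(); b <- run()
  expect_identical(a$state, b$state)
  expect_identical(a$events, b$events)
})

test_that("rectification converges within the predicted retry bound", {
  cfg <- operation_config()
  set.seed(2024)
  for (k in 1:20) {
    vp <- runif(1, 0.1, 0.4)   # v_mag in (2, 8) < default 8.33
    fx <- make_transport_world(particle_ul = vp)
    res <- transport(list(c(300, 200)), cfg, fx$world, fx$eyes)
    v_mag <- disengagement_speed(engagement_model(), vp)
    bound <- ceiling(log(cfg$default_speed / v_mag) / log(1 / cfg$retry_slowdown))
    expect_equal(res$status, "success")
    expect_lte(res$retries, bound)
  }
})
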