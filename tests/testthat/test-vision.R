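# overlap area recovered from the public iou + box areas
intersection_area_test <- function(a, b) {
  u <- (bbox_width(a) * bbox_height(a)) + (bbox_width(b) * bbox_height(b))
  v <- iou(a, b)
  v * u / (1 + v)
}

test_that("detect finds a colored droplet and its particle cluster", {
  f <- make_colored_frame()
  dets <- detect(f)
  drs <- Filter(function(d) d$class_label == "droplet", dets)
  prs <- Filter(function(d) d$class_label == "particle", dets)
  expect_gte(length(drs), 1)
  expect_gte(length(prs), 1)
  gt_d <- f$annotations[[1]]$box
  gt_p <- f$annotations[[2]]$box
  expect_gte(max(vapply(drs, function(d) iou(d$box, gt_d), 0)), 0.5)
  expect_gte(max(vapply(prs, function(p) iou(p$box, gt_p), 0)), 0.5)
  # nested boxes, as in the labeled training data
  best_d <- drs[[which.max(vapply(drs, function(d) iou(d$box, gt_d), 0))]]
  best_p <- prs[[which.max(vapply(prs, function(p) iou(p$box, gt_p), 0))]]
  expect_gt(intersection_area_test(best_d$box, best_p$box), 0)
})

test_that("detect returns an empty list on a blank frame", {
  f <- render(platform_state(), camera_model())
  expect_length(detect(f), 0)
})

test_that("detect handles transparent droplets across the lux range", {
  for (lux in c(25, 400, 1000)) {
    st <- platform_state(droplets = list(droplet_state("d", c(20, 20), 12)))
    f <- render(st, camera_model(illumination = lux))
    dets <- detect(f)
    drs <- Filter(function(d) d$class_label == "droplet", dets)
    expect_gte(length(drs), 1)
    expect_gte(max(vapply(drs, function(d)
      iou(d$box, f$annotations[[1]]$box), 0)), 0.5)
  }
})

test_that("associate matches greedily with the documented tie-break", {
  d <- function(x, cls = "droplet")
    detection(cls, bbox(x, 10, x + 10, 20), 1)
  # identity
  prev <- list(d(0), d(50))
  res <- associate(prev, prev, gate = 5)
  expect_equal(res$matches$prev, res$matches$curr)
  expect_length(res$lost, 0); expect_length(res$new, 0)
  # small displacement within gate
  res2 <- associate(list(d(0)), list(d(3)), gate = 10)
  expect_equal(nrow(res2$matches), 1)
  # beyond gate: lost + new
  res3 <- associate(list(d(0)), list(d(30)), gate = 10)
  expect_equal(nrow(res3$matches), 0)
  expect_equal(res3$lost, 1); expect_equal(res3$new, 1)
  # two equidistant candidates: lower index wins
  res4 <- associate(list(d(10)), list(d(5), d(15)), gate = 20)
  expect_equal(res4$matches$curr, 1)
  res5 <- associate(list(d(10)), list(d(15), d(5)), gate = 20)
  expect_equal(res5$matches$curr, 1)
  # class separation
  res6 <- associate(list(d(0, "particle")), list(d(0, "droplet")), gate = 5)
  expect_equal(nrow(res6$matches), 0)
  expect_error(associate(list(), list(), gate = 0), "gate")
})

test_that("evaluate reproduces the exact worked cases", {
  tru <- data.frame(frame_id = "f1", class = "droplet",
                    x_min = 0, y_min = 0, x_max = 10, y_max = 10)
  # truth-as-detections
  det_perfect <- cbind(tru, confidence = 1)
  expect_equal(evaluate(det_perfect, tru)$map_coco, 1)
  # no detections
  expect_equal(evaluate(det_perfect[0, ], tru)$map_coco, 0)
  # single detection at IoU exactly 0.60: AP 1 at {0.50, 0.55, 0.60},
  # 0 at the other seven thresholds
  det_060 <- data.frame(frame_id = "f1", class = "droplet",
                        x_min = 0, y_min = 2.5, x_max = 10, y_max = 12.5,
                        confidence = 0.9)
  expect_equal(iou(bbox(0, 0, 10, 10), bbox(0, 2.5, 10, 12.5)), 0.6)
  rep <- evaluate(det_060, tru)
  expect_equal(rep$map_coco, 0.30)
  expect_equal(unname(rep$per_class_ap["droplet", c("0.50", "0.60", "0.65")]),
               c(1, 1, 0))
  # alignment error
  bad <- det_perfect; bad$frame_id <- "f2"
  expect_error(evaluate(bad, tru), "frame ids")
})

test_that("evaluate equals the brute-force oracle on small fixtures", {
  set.seed(99)
  for (rep_i in 1:8) {
    tru <- do.call(rbind, lapply(c("f1", "f2", "f3"), function(fid)
      rbind(random_box_df(sample(0:5, 1), fid, "droplet", with_conf = FALSE),
            random_box_df(sample(0:3, 1), fid, "particle", with_conf = FALSE))))
    det <- do.call(rbind, lapply(c("f1", "f2", "f3"), function(fid)
      rbind(random_box_df(sample(0:5, 1), fid, "droplet"),
            random_box_df(sample(0:3, 1), fid, "particle"))))
    if (nrow(tru) == 0) next
    got <- evaluate(det, tru)$map_coco
    want <- oracle_map(det, tru)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("mAP is monotone non-increasing in the IoU threshold", {
  set.seed(7)
  tru <- rbind(random_box_df(4, "f1", "droplet", with_conf = FALSE),
               random_box_df(3, "f2", "droplet", with_conf = FALSE))
  det <- tru
  det$x_min <- det$x_min + sample(0:4, nrow(det), replace = TRUE)
  det$confidence <- runif(nrow(det))
  aps <- vapply(seq(0.5, 0.95, 0.05), function(t)
    evaluate(det, tru, iou_thresholds = t)$map_coco, 0)
  expect_true(all(diff(aps) <= 1e-12))
})

test_that("AP ignores permutation of equal-confidence detections up to tie-break", {
  tru <- data.frame(frame_id = "f1", class = "droplet",
                    x_min = c(0, 50), y_min = 0, x_max = c(10, 60), y_max = 10)
  det <- data.frame(frame_id = "f1", class = "droplet",
                    x_min = c(0, 50), y_min = 0, x_max = c(10, 60), y_max = 10,
                    confidence = 0.5)
  a <- evaluate(det, tru)$map_coco
  b <- evaluate(det[2:1, ], tru)$map_coco
  expect_equal(a, 1); expect_equal(b, 1)
})
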