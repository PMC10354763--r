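# Independent brute-force oracles. These deliberately avoid the package's
# own arithmetic: IoU by counting unit pixels of integer boxes, matching by
# naive scans, AP straight from its 101-point definition.

# pixel-set IoU for integer-coordinate boxes
oracle_iou <- function(a, b) {
  cells <- function(v) {
    xs <- seq(v[1], v[3] - 1); ys <- seq(v[2], v[4] - 1)
    as.vector(outer(xs, ys, function(x, y) paste(x, y)))
  }
  A <- cells(a); B <- cells(b)
  length(intersect(A, B)) / length(union(A, B))
}

# greedy confidence-ordered matching, written as plain nested loops
oracle_match <- function(det, tru, thr) {
  ord <- order(-det$confidence)
  used <- rep(FALSE, nrow(tru))
  tp <- logical(nrow(det))
  for (r in ord) {
    best <- NA; best_iou <- 0
    for (i in seq_len(nrow(tru))) {
      if (used[i] || tru$frame_id[i] != det$frame_id[r]) next
      v <- oracle_iou(as.numeric(det[r, c("x_min", "y_min", "x_max", "y_max")]),
                      as.numeric(tru[i, c("x_min", "y_min", "x_max", "y_max")]))
      if (v > best_iou) { best_iou <- v; best <- i }
    }
    if (!is.na(best) && best_iou >= thr) { tp[r] <- TRUE; used[best] <- TRUE }
  }
  tp[ord]
}

oracle_ap <- function(tp, n_pos) {
  if (n_pos == 0) return(NA_real_)
  if (length(tp) == 0) return(0)
  prec <- cumsum(tp) / seq_along(tp)
  rec <- cumsum(tp) / n_pos
  total <- 0
  for (r in seq(0, 1, by = 0.01)) {
    p <- 0
    for (i in seq_along(rec)) if (rec[i] >= r && prec_max_from(prec, i) > p)
      p <- prec_max_from(prec, i)
    total <- total + p
  }
  total / 101
}

prec_max_from <- function(prec, i) max(prec[i:length(prec)])

oracle_map <- function(det, tru, thresholds = seq(0.5, 0.95, by = 0.05)) {
  classes <- sort(unique(tru$class))
  vals <- c()
  for (cl in classes) {
    dc <- det[det$class == cl, , drop = FALSE]
    tc <- tru[tru$class == cl, , drop = FALSE]
    for (thr in thresholds)
      vals <- c(vals, oracle_ap(oracle_match(dc, tc, thr), nrow(tc)))
  }
  mean(vals)
}

# standard RGB -> hue (degrees) conversion, independent of grDevices
oracle_hue <- function(rgb) {
  r <- rgb[1] / 255; g <- rgb[2] / 255; b <- rgb[3] / 255
  mx <- max(r, g, b); mn <- min(r, g, b); d <- mx - mn
  if (d == 0) return(NA_real_)
  h <- if (mx == r) ((g - b) / d) %% 6
       else if (mx == g) (b - r) / d + 2
       else (r - g) / d + 4
  (h * 60) %% 360
}
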