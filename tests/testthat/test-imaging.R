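# lambda-1 route: egg edge circle, hot-region segmentation, ellipse fit

test_that("component labeling matches a flood-fill oracle", {
  withr::with_seed(21, {
    for (rep in 1:8) {
      mask <- matrix(runif(144) < 0.45, 12, 12)
      lab <- label_components(mask, 8)
      ref <- oracle_components(mask, 8)
      expect_equal(max(lab), max(ref))
      # same partition: component ids may differ, sizes must match
      expect_equal(sort(tabulate(lab[lab > 0])), sort(tabulate(ref[ref > 0])))
      # pixels sharing an implementation label share the oracle label
      for (l in seq_len(max(lab))) {
        expect_equal(length(unique(ref[lab == l])), 1L)
      }
    }
  })
})

test_that("egg outer edge is recovered on a noise-free frame", {
  sp <- small_scene(noise = 0)
  res <- render_thermal_video(sp)
  edge <- egg_outer_edge(res$video$frames[[1]])
  truth <- res$truth$egg_circle
  expect_lt(abs(edge$x_egg - truth$x), 0.5)
  expect_lt(abs(edge$y_egg - truth$y), 0.5)
  expect_lt(abs(edge$r - truth$r) / truth$r, 0.01)
})

test_that("degenerate frames raise an egg-detection error", {
  flat <- array(120L, c(40, 60, 3))
  expect_error(egg_outer_edge(flat), "no egg detected")
})

test_that("egg center survives sensor noise within 2 px", {
  sp <- small_scene(noise = 5, seed = 33)
  res <- render_thermal_video(sp)
  edge <- egg_outer_edge(res$video$frames[[1]])
  truth <- res$truth$egg_circle
  expect_lt(abs(edge$x_egg - truth$x), 2)
  expect_lt(abs(edge$y_egg - truth$y), 2)
})

test_that("hot-region segmentation overlaps the ground truth", {
  sp <- small_scene(noise = 0)
  res <- render_thermal_video(sp)
  edge <- egg_outer_edge(res$video$frames[[1]])
  peak <- res$truth$peak_frame
  seg <- segment_air_cell(res$video$frames[[peak]], edge)
  truth_mask <- res$truth$mask == 2L
  jacc <- sum(seg & truth_mask) / sum(seg | truth_mask)
  expect_gte(jacc, 0.95)

  # an unheated frame yields the empty sentinel, not an error
  empty <- segment_air_cell(res$video$frames[[1]], edge)
  expect_false(any(empty))
  expect_true(attr(empty, "empty"))
})

test_that("only the largest of two hot blobs survives", {
  fr <- array(0L, c(60, 80, 3))
  fr[, , 3] <- 40L
  fr[10:30, 10:30, 1] <- 255L   # large blob
  fr[45:50, 60:66, 1] <- 255L   # small blob
  egg_mask <- matrix(TRUE, 60, 80)
  seg <- segment_air_cell(fr, egg_mask, dilate_px = 0)
  expect_true(all(seg[10:30, 10:30]))
  expect_false(any(seg[45:50, 60:66]))
})

test_that("direct ellipse fit recovers rasterized parameters", {
  # rasterize an ellipse with full axes 90 x 60 at 25 degrees
  H <- 160; W <- 200
  cx <- 100; cy <- 80; asemi <- 45; bsemi <- 30; th <- 25 * pi / 180
  px <- outer(rep(1, H), seq_len(W)); py <- outer(seq_len(H), rep(1, W))
  u <- (px - cx) * cos(th) + (py - cy) * sin(th)
  v <- -(px - cx) * sin(th) + (py - cy) * cos(th)
  mask <- (u / asemi)^2 + (v / bsemi)^2 <= 1
  fit <- fit_air_cell_ellipse(mask)
  expect_lt(abs(fit$x_cell - cx), 0.5)
  expect_lt(abs(fit$y_cell - cy), 0.5)
  expect_lt(abs(fit$Lm - 90) / 90, 0.01)
  expect_lt(abs(fit$Ls - 60) / 60, 0.01)
  expect_lt(abs(fit$theta_c - 25), 1)

  # near-circular mask: axes agree, orientation is unstable but reported
  circ <- (px - cx)^2 + (py - cy)^2 <= 40^2
  cfit <- fit_air_cell_ellipse(circ)
  expect_lt(abs(cfit$Lm - cfit$Ls) / cfit$Lm, 0.01)
  expect_true(is.finite(cfit$theta_c))

  tiny <- matrix(FALSE, 10, 10); tiny[5, 5:6] <- TRUE; tiny[6, 5:6] <- TRUE
  expect_error(fit_air_cell_ellipse(tiny), "fewer than 5|not elliptical")
})

test_that("peak-frame selection follows the heating schedule", {
  sp <- small_scene(noise = 0)
  res <- render_thermal_video(sp)
  expect_equal(select_peak_frame(res$video), res$truth$peak_frame)

  # constant video: earliest index wins the tie
  const <- thermal_video(rep(res$video$frames[res$truth$peak_frame], 3))
  edge <- egg_outer_edge(res$video$frames[[1]])
  expect_equal(select_peak_frame(const, egg = edge), 1L)

  cold <- thermal_video(rep(res$video$frames[1], 3))
  expect_error(select_peak_frame(cold), "no air cell")
})

test_that("lambda-1 extraction recovers every feature end to end", {
  sp <- small_scene(h = 6, alpha = 20, theta_c = 25, noise = 0)
  res <- render_thermal_video(sp)
  l1 <- extract_lambda1(res$video)
  truth_c <- res$truth$egg_circle
  truth_e <- res$truth$air_cell_ellipse
  expect_lt(abs(l1$x_egg - truth_c$x), 2)
  expect_lt(abs(l1$y_egg - truth_c$y), 2)
  expect_lt(abs(l1$r - truth_c$r) / truth_c$r, 0.02)
  expect_lt(abs(l1$x_cell - truth_e$x), 2)
  expect_lt(abs(l1$y_cell - truth_e$y), 2)
  expect_lt(abs(l1$Lm - truth_e$Lm) / truth_e$Lm, 0.02)
  expect_lt(abs(l1$Ls - truth_e$Ls) / truth_e$Ls, 0.02)
  expect_lt(abs(l1$theta_c - truth_e$theta_c_deg), 2)

  expect_identical(extract_lambda1(res$video), l1)   # deterministic

  cold <- thermal_video(rep(res$video$frames[1], 4))
  expect_error(extract_lambda1(cold), "no air cell")
})

test_that("horizontal flip transforms the features predictably", {
  sp <- small_scene(h = 6, alpha = 20, theta_c = 25, noise = 0)
  res <- render_thermal_video(sp)
  W <- sp$width
  flipped <- thermal_video(lapply(res$video$frames, function(fr) {
    fr[, rev(seq_len(dim(fr)[2])), , drop = FALSE]
  }), res$video$frame_period_s, res$video$heat_stop_index)
  l1 <- extract_lambda1(res$video)
  l1f <- extract_lambda1(flipped)
  expect_equal(l1f$x_egg, W + 1 - l1$x_egg, tolerance = 0.02)
  expect_equal(l1f$x_cell, W + 1 - l1$x_cell, tolerance = 0.02)
  expect_equal(l1f$y_egg, l1$y_egg, tolerance = 0.02)
  expect_equal(l1f$r, l1$r, tolerance = 0.005)
  expect_equal(l1f$Lm, l1$Lm, tolerance = 0.01)
  expect_equal(l1f$Ls, l1$Ls, tolerance = 0.01)
  expect_equal(l1f$theta_c, -l1$theta_c, tolerance = 0.05)
})
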