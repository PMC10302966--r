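# ---- low-level image primitives -------------------------------------------
# Images are numeric/integer matrices [row = y, col = x], 1-based pixel
# centers; frames are H x W x 3 arrays with 8-bit channel values.

#' Label connected components of a logical mask
#'
#' Breadth-first labeling with 8- (default) or 4-connectivity.
#'
#' @param mask Logical matrix.
#' @param connectivity 8 or 4.
#' @return Integer matrix; 0 outside, components numbered from 1 in
#'   first-encounter (column-major) order.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  n <- nrow(mask); m <- ncol(mask)
  lab <- matrix(0L, n, m)
  todo <- which(mask)
  if (length(todo) == 0) return(lab)
  # neighbor offsets as (drow, dcol) pairs; linear offset = drow + n * dcol
  deltas <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  if (connectivity == 8) {
    deltas <- c(deltas, list(c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L)))
  }
  row_of <- function(idx) ((idx - 1L) %% n) + 1L
  visited <- matrix(FALSE, n, m)
  cur <- 0L
  for (seed in todo) {
    if (visited[seed]) next
    cur <- cur + 1L
    frontier <- seed
    visited[seed] <- TRUE
    lab[seed] <- cur
    while (length(frontier)) {
      nbrs <- integer(0)
      fr_row <- row_of(frontier)
      for (d in deltas) {
        new_row <- fr_row + d[1]
        cand <- frontier + d[1] + n * d[2]
        ok <- new_row >= 1L & new_row <= n & cand >= 1L & cand <= n * m
        cand <- cand[ok]
        cand <- cand[mask[cand] & !visited[cand]]
        if (length(cand)) {
          visited[cand] <- TRUE
          nbrs <- c(nbrs, cand)
        }
      }
      if (length(nbrs)) {
        nbrs <- unique(nbrs)
        lab[nbrs] <- cur
      }
      frontier <- nbrs
    }
  }
  lab
}

# largest connected component of a logical mask (ties: lowest label)
largest_component <- function(mask, connectivity = 8) {
  lab <- label_components(mask, connectivity)
  if (max(lab) == 0L) return(mask & FALSE)
  counts <- tabulate(lab[lab > 0L])
  lab == which.max(counts)
}

# binary dilation by a disk of given pixel radius
dilate_disk <- function(mask, radius) {
  if (radius <= 0) return(mask)
  n <- nrow(mask); m <- ncol(mask)
  r <- ceiling(radius)
  out <- mask
  for (di in -r:r) for (dj in -r:r) {
    if (di == 0 && dj == 0) next
    if (sqrt(di^2 + dj^2) > radius + 1e-9) next
    src_i <- max(1, 1 + di):min(n, n + di)
    dst_i <- src_i - di
    src_j <- max(1, 1 + dj):min(m, m + dj)
    dst_j <- src_j - dj
    out[dst_i, dst_j] <- out[dst_i, dst_j] | mask[src_i, src_j]
  }
  out
}

# boundary pixels of a logical mask (foreground with a 4-neighbor background
# or image border)
mask_boundary <- function(mask) {
  n <- nrow(mask); m <- ncol(mask)
  pad <- matrix(FALSE, n + 2, m + 2)
  pad[2:(n + 1), 2:(m + 1)] <- mask
  inner <- pad[2:(n + 1), 2:(m + 1)] &
    !(pad[1:n, 2:(m + 1)] & pad[3:(n + 2), 2:(m + 1)] &
        pad[2:(n + 1), 1:m] & pad[2:(n + 1), 3:(m + 2)])
  inner
}

#' Canny edge points of a grayscale image
#'
#' Gaussian smoothing, central-difference gradients, non-maximum
#' suppression quantized to four directions, and two-threshold hysteresis
#' (weak edges kept only when 8-connected to a strong edge).
#'
#' @param gray Numeric matrix.
#' @param sigma Gaussian blur sd in px.
#' @param low,high Hysteresis thresholds as fractions of the maximum
#'   gradient magnitude.
#' @return A tibble of edge pixel coordinates `x` (column), `y` (row).
#' @export
canny_edge_points <- function(gray, sigma = 1.4, low = 0.1, high = 0.3) {
  stopifnot(is.matrix(gray))
  n <- nrow(gray); m <- ncol(gray)
  g <- EBImage::gblur(EBImage::Image(gray / max(1, max(gray))), sigma = sigma)
  g <- EBImage::imageData(g)
  gx <- matrix(0, n, m); gy <- matrix(0, n, m)
  gx[, 2:(m - 1)] <- (g[, 3:m] - g[, 1:(m - 2)]) / 2
  gy[2:(n - 1), ] <- (g[3:n, ] - g[1:(n - 2), ]) / 2
  mag <- sqrt(gx^2 + gy^2)
  if (max(mag) == 0) return(tibble(x = integer(0), y = integer(0)))
  ang <- atan2(gy, gx)                     # y = row axis
  sector <- (round(ang / (pi / 4)) %% 4)   # 0:E-W 1:NE-SW 2:N-S 3:NW-SE
  shift <- function(M, di, dj) {
    out <- matrix(0, n, m)
    src_i <- max(1, 1 + di):min(n, n + di)
    src_j <- max(1, 1 + dj):min(m, m + dj)
    out[src_i - di, src_j - dj] <- M[src_i, src_j]
    out
  }
  nms <- matrix(FALSE, n, m)
  dirs <- list(c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  for (s in 0:3) {
    d <- dirs[[s + 1]]
    sel <- sector == s
    nms[sel] <- mag[sel] >= shift(mag, d[1], d[2])[sel] &
      mag[sel] >= shift(mag, -d[1], -d[2])[sel]
  }
  strong <- nms & mag >= high * max(mag)
  weak <- nms & mag >= low * max(mag)
  lab <- label_components(weak, 8)
  keep_labels <- unique(lab[strong])
  edges <- weak & lab %in% keep_labels[keep_labels > 0]
  idx <- which(edges, arr.ind = TRUE)
  tibble(x = idx[, 2], y = idx[, 1])
}

# algebraic (Kasa) least-squares circle fit
fit_circle_kasa <- function(x, y) {
  if (length(x) < 3) abort("circle fit requires at least 3 points")
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  sol <- qr.solve(A, b)
  r <- sqrt(sol[3] + sol[1]^2 + sol[2]^2)
  resid <- sqrt(mean((sqrt((x - sol[1])^2 + (y - sol[2])^2) - r)^2))
  list(x = sol[[1]], y = sol[[2]], r = r, residual = resid)
}

# direct least-squares ellipse fit (Halir & Flusser formulation); returns
# geometric parameters or NULL when the best conic is not an ellipse
fit_ellipse_direct <- function(x, y) {
  if (length(x) < 5) return(NULL)
  mx <- mean(x); my <- mean(y)
  xs <- x - mx; ys <- y - my
  D1 <- cbind(xs^2, xs * ys, ys^2)
  D2 <- cbind(xs, ys, rep(1, length(xs)))
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  Tm <- tryCatch(-solve(S3, t(S2)), error = function(e) NULL)
  if (is.null(Tm)) return(NULL)
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  cond <- 4 * Re(ev$vectors[1, ]) * Re(ev$vectors[3, ]) - Re(ev$vectors[2, ])^2
  ok <- which(cond > 0)
  if (length(ok) == 0) return(NULL)
  a1 <- Re(ev$vectors[, ok[1]])
  coef <- c(a1, as.numeric(Tm %*% a1))     # a, b, c, d, e, f in centered frame
  a <- coef[1]; b <- coef[2]; c3 <- coef[3]; d <- coef[4]; e <- coef[5]; f <- coef[6]
  den <- 4 * a * c3 - b^2
  if (den <= 0) return(NULL)
  xc <- (b * e - 2 * c3 * d) / den
  yc <- (b * d - 2 * a * e) / den
  fc <- f + a * xc^2 + b * xc * yc + c3 * yc^2 + d * xc + e * yc
  Q <- matrix(c(a, b / 2, b / 2, c3), 2)
  eg <- eigen(Q, symmetric = TRUE)
  sq <- -fc / eg$values
  if (any(sq <= 0)) return(NULL)
  semi <- sqrt(sq)                          # per eigenvalue
  major_i <- which.max(semi)
  vec <- eg$vectors[, major_i]
  theta <- atan2(vec[2], vec[1]) * 180 / pi
  if (theta <= -90) theta <- theta + 180
  if (theta > 90) theta <- theta - 180
  list(x = xc + mx, y = yc + my,
       semi_major = max(semi), semi_minor = min(semi),
       theta_deg = theta)
}

# ---- lambda-1 extraction route ---------------------------------------------

#' Fit the egg outer edge circle on an unheated frame
#'
#' The B channel of the RGB frame is binarized with Otsu's threshold (the
#' cool egg body is the most blue region in the scene), the largest
#' connected foreground component is kept, Canny edge points are extracted
#' from it, and an algebraic least-squares circle is fitted.
#'
#' @param frame `H x W x 3` array, 8-bit channels.
#' @return A one-row tibble of class `circle_edge` with `x_egg`, `y_egg`,
#'   `r` (px) and `residual`.
#' @export
egg_outer_edge <- function(frame) {
  stopifnot(length(dim(frame)) == 3, dim(frame)[3] == 3)
  B <- frame[, , 3] / 255
  if (diff(range(B)) < 1e-6) abort("no egg detected: uniform frame")
  thr <- EBImage::otsu(EBImage::Image(B), range = c(0, 1), levels = 256)
  fg <- B > thr
  if (!any(fg)) abort("no egg detected: empty foreground")
  comp <- largest_component(fg)
  pts <- canny_edge_points(comp * 255, sigma = 1.4)
  if (nrow(pts) < 3) abort("egg edge fit failed: fewer than 3 edge points")
  fit <- fit_circle_kasa(pts$x, pts$y)
  d <- dim(frame)
  if (fit$x < 1 || fit$x > d[2] || fit$y < 1 || fit$y > d[1] || fit$r <= 0) {
    abort("no egg detected: implausible circle fit")
  }
  out <- tibble(x_egg = fit$x, y_egg = fit$y, r = fit$r, residual = fit$residual)
  class(out) <- c("circle_edge", class(out))
  out
}

#' Default RGB thresholds for the hot (red) air-cell region
#'
#' On the canonical palette the heated air cell satisfies `R >= r_min` and
#' `R - max(G, B) >= dominance`. Real-camera palettes differ; both values
#' are configuration-exposed.
#'
#' @return Named list with `r_min` and `dominance`.
#' @export
hot_rgb_thresholds <- function() list(r_min = 180, dominance = 40)

#' Segment the hot air-cell region of a heated frame
#'
#' Removes the background with the (dilated) egg disk mask, applies the RGB
#' hot thresholds and keeps the largest connected component.
#'
#' @param frame `H x W x 3` array.
#' @param egg Either a `circle_edge` (from [egg_outer_edge()]) or a logical
#'   egg mask matrix.
#' @param thresholds See [hot_rgb_thresholds()].
#' @param dilate_px Dilation of the egg disk used for background removal.
#' @return Logical mask; when no hot pixel survives, an all-`FALSE` mask
#'   with attribute `empty = TRUE` (not an error).
#' @export
segment_air_cell <- function(frame, egg, thresholds = hot_rgb_thresholds(),
                             dilate_px = 3) {
  stopifnot(length(dim(frame)) == 3, dim(frame)[3] == 3)
  d <- dim(frame)
  if (is.data.frame(egg)) {
    px <- outer(rep(1, d[1]), seq_len(d[2]))
    py <- outer(seq_len(d[1]), rep(1, d[2]))
    egg_mask <- sqrt((px - egg$x_egg)^2 + (py - egg$y_egg)^2) <= egg$r + dilate_px
  } else {
    stopifnot(is.matrix(egg))
    egg_mask <- if (dilate_px > 0) dilate_disk(egg, dilate_px) else egg
  }
  R <- frame[, , 1]; G <- frame[, , 2]; B <- frame[, , 3]
  hot <- egg_mask & R >= thresholds$r_min &
    (R - pmax(G, B)) >= thresholds$dominance
  if (!any(hot)) {
    out <- hot
    attr(out, "empty") <- TRUE
    return(out)
  }
  out <- largest_component(hot)
  attr(out, "empty") <- FALSE
  out
}

#' Fit an ellipse to a segmented air-cell mask
#'
#' Boundary points of the mask are fitted with the direct least-squares
#' conic method constrained to ellipses. Axes are reported as full lengths
#' with `Lm >= Ls`; `theta_c` is the major-axis angle to the image
#' horizontal in (-90, 90] degrees (unstable when `Lm` is close to `Ls`).
#'
#' @param mask Logical matrix.
#' @return One-row tibble of class `ellipse_fit`: `x_cell`, `y_cell`, `Lm`,
#'   `Ls` (px), `theta_c` (deg).
#' @export
fit_air_cell_ellipse <- function(mask) {
  stopifnot(is.matrix(mask))
  bnd <- which(mask_boundary(mask), arr.ind = TRUE)
  if (nrow(bnd) < 5) abort("ellipse fit failed: fewer than 5 boundary points")
  fit <- fit_ellipse_direct(bnd[, 2], bnd[, 1])
  if (is.null(fit)) abort("ellipse fit failed: boundary is not elliptical")
  # boundary pixel centers sit about half a pixel inside the true contour
  out <- tibble(x_cell = fit$x, y_cell = fit$y,
                Lm = 2 * fit$semi_major + 1, Ls = 2 * fit$semi_minor + 1,
                theta_c = fit$theta_deg)
  class(out) <- c("ellipse_fit", class(out))
  out
}

#' Select the frame with the largest segmented air-cell area
#'
#' Runs [segment_air_cell()] on every frame and returns the (1-based) index
#' of the largest hot area; ties resolve to the earliest frame.
#'
#' @param video A [thermal_video()].
#' @param egg Optional precomputed egg reference (see [segment_air_cell()]);
#'   defaults to [egg_outer_edge()] on `reference_frame`.
#' @param reference_frame Index of the unheated reference frame.
#' @param thresholds See [hot_rgb_thresholds()].
#' @return Integer frame index.
#' @export
select_peak_frame <- function(video, egg = NULL, reference_frame = 1,
                              thresholds = hot_rgb_thresholds()) {
  stopifnot(inherits(video, "thermal_video"))
  if (is.null(egg)) egg <- egg_outer_edge(video$frames[[reference_frame]])
  areas <- vapply(video$frames, function(fr) {
    sum(segment_air_cell(fr, egg, thresholds))
  }, numeric(1))
  if (all(areas == 0)) abort("no air cell found in any frame")
  which.max(areas)
}

#' Extract the 8-value edge-route feature vector from a thermal video
#'
#' Composes the unheated-frame circle fit, peak-frame selection, hot-region
#' segmentation and ellipse fit into the feature vector
#' `[x_egg, y_egg, r, x_cell, y_cell, Lm, Ls, theta_c]` (px / deg).
#'
#' @param video A [thermal_video()].
#' @param reference_frame Unheated reference frame index (default 1, or the
#'   frame before heating when `heat_stop_index` metadata is present).
#' @param thresholds See [hot_rgb_thresholds()].
#' @return One-row tibble with the eight features plus `peak_frame`.
#' @export
extract_lambda1 <- function(video, reference_frame = 1,
                            thresholds = hot_rgb_thresholds()) {
  stopifnot(inherits(video, "thermal_video"))
  egg <- egg_outer_edge(video$frames[[reference_frame]])
  peak <- select_peak_frame(video, egg = egg, thresholds = thresholds)
  mask <- segment_air_cell(video$frames[[peak]], egg, thresholds)
  if (isTRUE(attr(mask, "empty"))) abort("no air cell found in any frame")
  ell <- fit_air_cell_ellipse(mask)
  tibble(x_egg = egg$x_egg, y_egg = egg$y_egg, r = egg$r,
         x_cell = ell$x_cell, y_cell = ell$y_cell,
         Lm = ell$Lm, Ls = ell$Ls, theta_c = ell$theta_c,
         peak_frame = peak)
}
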