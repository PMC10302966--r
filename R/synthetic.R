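#' Canonical thermal pseudo-color palette
#'
#' Fixed piecewise-linear RGB palette from cold blue through green and
#' yellow to hot red, applied over a fixed display range (no auto-scaling).
#' The numeric stops are part of the package contract so that the
#' "hot/red" RGB segmentation thresholds of the imaging route are
#' well-posed on synthetic frames.
#'
#' @param range_C Display temperature range, degC, mapped to palette
#'   position 0..1. Default `c(0, 50)`.
#' @return A function mapping a numeric vector/matrix of temperatures to a
#'   list of R, G, B matrices in 0..255.
#' @export
thermal_colormap <- function(range_C = c(0, 50)) {
  stops_t <- c(0.00, 0.20, 0.40, 0.55, 0.70, 0.85, 1.00)
  stops_rgb <- rbind(
    c(0,   0,   140),
    c(0,   60,  255),
    c(0,   200, 200),
    c(80,  255, 120),
    c(255, 255, 0),
    c(255, 90,  0),
    c(255, 0,   0)
  )
  force(range_C)
  function(T_C) {
    t01 <- pmin(1, pmax(0, (T_C - range_C[1]) / diff(range_C)))
    ch <- lapply(1:3, function(c3) {
      v <- stats::approx(stops_t, stops_rgb[, c3], xout = as.numeric(t01))$y
      if (is.matrix(T_C)) matrix(v, nrow(T_C), ncol(T_C)) else v
    })
    names(ch) <- c("R", "G", "B")
    ch
  }
}

#' Scene parameters for synthetic thermal video rendering
#'
#' Describes a blunt-end-on view of one egg: the silhouette is a circle of
#' radius `max halfwidth * scale`, the heated air cell is the projected
#' membrane ellipse of [forward_project()] at the same scale.
#'
#' @param profile An [egg_profile()].
#' @param cell An [air_cell_state()] (its `R` should be the profile's
#'   [blunt_crown_radius()]).
#' @param width,height Frame size in px.
#' @param scale_px_mm Pixels per mm.
#' @param center_px Egg center `(x, y)` in px (1-based pixel centers).
#' @param theta_c_deg Orientation of the projected ellipse major axis to
#'   the image horizontal, degrees in (-90, 90].
#' @param noise_sigma Gaussian sensor noise sd in 8-bit counts.
#' @param halo_px Width of the warm halo band outside the egg boundary, px.
#' @param n_pre,n_heat,n_cool Frame counts of the unheated, heating and
#'   cooling phases.
#' @param frame_period_s Seconds per frame.
#' @param temps Named list of scene temperatures (degC): `body`, `bg`,
#'   `halo`, `hot_edge`, `hot_peak`.
#' @param seed Integer seed; rendering is deterministic given the seed.
#' @return A list of class `scene_params`.
#' @export
scene_params <- function(profile = egg_profile(28.435, 21.89, 10),
                         cell = air_cell_state(R = blunt_crown_radius(profile), h = 6),
                         width = 320, height = 240, scale_px_mm = 3,
                         center_px = c(width / 2, height / 2),
                         theta_c_deg = 0, noise_sigma = 0, halo_px = 6,
                         n_pre = 5, n_heat = 20, n_cool = 15,
                         frame_period_s = 0.1,
                         temps = list(body = 10, bg = 28, halo = 33,
                                      hot_edge = 40, hot_peak = 46),
                         seed = 1L) {
  stopifnot(scale_px_mm > 0, noise_sigma >= 0, n_pre >= 1, n_heat >= 1)
  r_px <- max(profile_halfwidth(profile, seq(-profile$a, profile$a,
                                             length.out = 1024))) * scale_px_mm
  if (center_px[1] - r_px < 1 || center_px[1] + r_px > width ||
      center_px[2] - r_px < 1 || center_px[2] + r_px > height) {
    abort("rendered egg does not fit in the frame")
  }
  structure(list(profile = profile, cell = cell, width = width, height = height,
                 scale_px_mm = scale_px_mm, center_px = center_px,
                 theta_c_deg = theta_c_deg, noise_sigma = noise_sigma,
                 halo_px = halo_px, n_pre = n_pre, n_heat = n_heat,
                 n_cool = n_cool, frame_period_s = frame_period_s,
                 temps = temps, seed = as.integer(seed), egg_r_px = r_px),
            class = "scene_params")
}

#' Thermal video container
#'
#' @param frames List of `height x width x 3` integer arrays (0..255).
#' @param frame_period_s Seconds per frame.
#' @param heat_stop_index Index of the last heated frame, or `NULL`.
#' @return An object of class `thermal_video`.
#' @export
thermal_video <- function(frames, frame_period_s = 0.1, heat_stop_index = NULL) {
  stopifnot(is.list(frames), length(frames) >= 1)
  dims <- unique(lapply(frames, dim))
  if (length(dims) != 1) abort("all frames must share dimensions")
  structure(list(frames = frames, frame_period_s = frame_period_s,
                 heat_stop_index = heat_stop_index), class = "thermal_video")
}

#' @method print thermal_video
#' @export
print.thermal_video <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<thermal_video> %d frames of %dx%d px, %.3g s/frame\n",
              length(x$frames), d[2], d[1], x$frame_period_s))
  invisible(x)
}

#' @export
length.thermal_video <- function(x) length(x$frames)

# heating amplitude schedule in [0, 1] per frame
.heat_amplitude <- function(params) {
  n <- params$n_pre + params$n_heat + params$n_cool
  f <- seq_len(n)
  amp <- numeric(n)
  heat <- f > params$n_pre & f <= params$n_pre + params$n_heat
  amp[heat] <- (f[heat] - params$n_pre) / params$n_heat
  cool <- f > params$n_pre + params$n_heat
  tau <- max(1, params$n_cool / 3)
  amp[cool] <- exp(-(f[cool] - params$n_pre - params$n_heat) / tau)
  amp
}

#' Render a synthetic pseudo-colored thermal video with ground truth
#'
#' Emulates the three-phase appearance of blunt-end thermography: unheated
#' frames show the cool (blue) egg against a warmer background with a warm
#' halo ring at the silhouette; during heating a hot elliptical air-cell
#' region grows to the projected-membrane ellipse; during cooling it decays.
#' Rendering is deterministic given the scene seed.
#'
#' @param params A [scene_params()].
#' @param temperature_source Optional function `(frame_index)` returning a
#'   `height x width` temperature matrix, overriding the built-in
#'   parametric model (e.g. resampled simulator output).
#' @return A list with `video` (a [thermal_video()]) and `truth`, a list
#'   holding the label mask (`0` background, `1` eggshell, `2` egg air
#'   cell), the true egg circle (`x`, `y`, `r`, px), the true air-cell
#'   ellipse (`x`, `y`, full axes `Lm`, `Ls`, `theta_c_deg`), the mm-scale
#'   projection observation, the peak (heating-stop) frame index and the
#'   scene scale.
#' @export
render_thermal_video <- function(params, temperature_source = NULL) {
  stopifnot(inherits(params, "scene_params"))
  W <- params$width; H <- params$height
  cmap <- thermal_colormap()
  tp <- params$temps

  px <- outer(rep(1, H), seq_len(W))        # x (column) coordinate per pixel
  py <- outer(seq_len(H), rep(1, W))        # y (row) coordinate per pixel
  dxp <- px - params$center_px[1]
  dyp <- py - params$center_px[2]
  rho_egg <- sqrt(dxp^2 + dyp^2)
  egg_disk <- rho_egg <= params$egg_r_px

  obs <- forward_project(params$cell)
  a_px <- obs$Ra * params$scale_px_mm       # semi-major, px
  b_px <- obs$Rb * params$scale_px_mm       # semi-minor, px
  th <- params$theta_c_deg * pi / 180
  e1 <- c(cos(th), sin(th))                 # major-axis direction (image frame)
  e2 <- c(-sin(th), cos(th))                # minor-axis = tilt direction
  cx <- params$center_px[1] + obs$center_x * params$scale_px_mm * e2[1]
  cy <- params$center_px[2] + obs$center_x * params$scale_px_mm * e2[2]
  u <- (px - cx) * e1[1] + (py - cy) * e1[2]
  v <- (px - cx) * e2[1] + (py - cy) * e2[2]
  rho_ell <- sqrt((u / a_px)^2 + (v / b_px)^2)
  in_ell <- rho_ell <= 1 & egg_disk

  mask <- matrix(0L, H, W)
  mask[egg_disk] <- 1L
  mask[in_ell] <- 2L

  # static background/halo/body temperature field
  base_T <- matrix(tp$bg, H, W)
  d_out <- rho_egg - params$egg_r_px
  halo <- d_out > 0 & d_out <= 3 * params$halo_px
  base_T[halo] <- tp$bg + (tp$halo - tp$bg) * exp(-d_out[halo] / params$halo_px)
  base_T[egg_disk] <- tp$body

  # hot-region excess temperature at full amplitude
  hot_full <- matrix(0, H, W)
  hot_full[in_ell] <- (tp$hot_edge - tp$body) +
    (tp$hot_peak - tp$hot_edge) * (1 - rho_ell[in_ell]^2)
  skirt <- !in_ell & egg_disk & rho_ell <= 2
  hot_full[skirt] <- (tp$hot_edge - tp$body) *
    exp(-pmax(0, (rho_ell[skirt] - 1)) * b_px / 1.2)

  amp <- .heat_amplitude(params)
  frames <- withr::with_seed(params$seed, {
    lapply(seq_along(amp), function(f) {
      Tm <- if (is.null(temperature_source)) {
        base_T + amp[f] * hot_full
      } else {
        temperature_source(f)
      }
      ch <- cmap(Tm)
      fr <- array(0, dim = c(H, W, 3))
      for (c3 in 1:3) {
        v <- ch[[c3]]
        if (params$noise_sigma > 0) {
          v <- v + matrix(rnorm(H * W, 0, params$noise_sigma), H, W)
        }
        fr[, , c3] <- pmin(255, pmax(0, round(v)))
      }
      storage.mode(fr) <- "integer"
      fr
    })
  })

  video <- thermal_video(frames, params$frame_period_s,
                         heat_stop_index = params$n_pre + params$n_heat)
  truth <- list(
    mask = mask,
    egg_circle = tibble(x = params$center_px[1], y = params$center_px[2],
                        r = params$egg_r_px),
    air_cell_ellipse = tibble(x = cx, y = cy, Lm = 2 * a_px, Ls = 2 * b_px,
                              theta_c_deg = params$theta_c_deg),
    projection = obs,
    peak_frame = params$n_pre + params$n_heat,
    scale_px_mm = params$scale_px_mm
  )
  list(video = video, truth = truth)
}

#' Sample a labeled synthetic feature table for classifier tests
#'
#' Draws per-grade Gaussian clusters in an 8-dimensional feature space
#' shaped like the edge-route or mask-route feature vector. `separation`
#' scales the distance between class means (0 means indistinguishable
#' classes); `structure = "radial"` instead places the four grades on
#' concentric rings in the first two feature dimensions, a geometry that a
#' radial-kernel classifier separates but a linear one cannot.
#'
#' @param n_per_grade Rows per freshness grade (AA, A, B, C).
#' @param separation Non-negative class separation scale.
#' @param seed Integer seed.
#' @param route `"l1"` or `"l2"` feature naming.
#' @param structure `"clustered"` (default) or `"radial"`.
#' @return A tibble with 8 feature columns, `hu` and `grade`.
#' @export
sample_feature_table <- function(n_per_grade = 50, separation = 6, seed = 1L,
                                 route = c("l1", "l2"),
                                 structure = c("clustered", "radial")) {
  route <- match.arg(route)
  structure <- match.arg(structure)
  stopifnot(n_per_grade >= 1, separation >= 0)
  grades <- c("AA", "A", "B", "C")
  feat_names <- if (route == "l1") {
    c("x_egg", "y_egg", "r", "x_cell", "y_cell", "Lm", "Ls", "theta_c")
  } else {
    c("d", "theta", "PS", "PC", "CON", "COR", "ENT", "ASM")
  }
  hu_range <- list(AA = c(75, 95), A = c(62, 71), B = c(35, 59), C = c(10, 30))
  withr::with_seed(as.integer(seed), {
    rows <- lapply(seq_along(grades), function(g) {
      X <- matrix(rnorm(n_per_grade * 8), n_per_grade, 8)
      if (structure == "clustered") {
        mu <- numeric(8)
        mu[2 * g - c(1, 0)] <- separation / sqrt(2)
        X <- sweep(X, 2, mu, "+")
      } else {
        radius <- separation * (g - 0.5)
        ang <- runif(n_per_grade, 0, 2 * pi)
        r_i <- radius + rnorm(n_per_grade, 0, max(separation / 8, 1e-3))
        X[, 1] <- r_i * cos(ang)
        X[, 2] <- r_i * sin(ang)
      }
      hu <- runif(n_per_grade, hu_range[[g]][1], hu_range[[g]][2])
      df <- as_tibble(setNames(as.data.frame(X), feat_names))
      df$hu <- hu
      df$grade <- grades[g]
      df
    })
    out <- bind_rows(rows)
    out$grade <- factor(out$grade, levels = grades)
    out
  })
}

#' Geometric augmentation of images and masks
#'
#' Expands an image set with horizontal flip, vertical flip and integer
#' translation; masks are transformed identically. The output holds the
#' originals followed by each transform of each input, so the multiplicity
#' is `1 + number of transforms`.
#'
#' @param images List of matrices or `H x W x 3` arrays.
#' @param masks Optional list of label matrices, same length.
#' @param transforms Character vector drawn from `"hflip"`, `"vflip"`,
#'   `"translate"`.
#' @param translate_px Integer `(dx, dy)` shift used by `"translate"`;
#'   vacated pixels are filled with 0.
#' @return A list with `images` (and `masks` when given).
#' @export
augment_images <- function(images, masks = NULL,
                           transforms = c("hflip", "vflip", "translate"),
                           translate_px = c(5, 3)) {
  if (length(images) == 0) abort("no images to augment")
  transforms <- match.arg(transforms, several.ok = TRUE)
  apply_one <- function(img, tr) {
    flip_idx <- function(arr, rows, cols) {
      if (length(dim(arr)) == 3) arr[rows, cols, , drop = FALSE] else arr[rows, cols, drop = FALSE]
    }
    d <- dim(img)
    switch(tr,
      hflip = flip_idx(img, seq_len(d[1]), rev(seq_len(d[2]))),
      vflip = flip_idx(img, rev(seq_len(d[1])), seq_len(d[2])),
      translate = {
        out <- img
        out[] <- 0L
        dx <- as.integer(translate_px[1]); dy <- as.integer(translate_px[2])
        lo_r <- max(1, 1 - dy); hi_r <- min(d[1], d[1] - dy)
        lo_c <- max(1, 1 - dx); hi_c <- min(d[2], d[2] - dx)
        if (lo_r <= hi_r && lo_c <= hi_c) {
          src_r <- lo_r:hi_r
          src_c <- lo_c:hi_c
          if (length(dim(img)) == 3) {
            out[src_r + dy, src_c + dx, ] <- img[src_r, src_c, , drop = FALSE]
          } else {
            out[src_r + dy, src_c + dx] <- img[src_r, src_c, drop = FALSE]
          }
        }
        out
      }
    )
  }
  expand <- function(lst) {
    c(lst, unlist(lapply(transforms, function(tr) {
      lapply(lst, apply_one, tr = tr)
    }), recursive = FALSE))
  }
  out <- list(images = expand(images))
  if (!is.null(masks)) {
    stopifnot(length(masks) == length(images))
    out$masks <- expand(masks)
  }
  out
}
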