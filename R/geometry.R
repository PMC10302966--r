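#' Egg profile geometry
#'
#' Constructs the rotationally symmetric egg profile used throughout the
#' package. The profile curve in the axial plane is
#' \deqn{x^2/a^2 + y^2/(b + x\tan\theta)^2 = 1,}
#' where `a` is the long-axis radius (mm), `b` the short-axis radius (mm) and
#' `theta_deg` the egg shape angle (degrees). Rotating the curve about the
#' x-axis gives the egg solid; the blunt (wider) end sits at `x = +a`.
#'
#' @param a Long-axis radius in mm.
#' @param b Short-axis radius in mm. Must satisfy `a > b > 0`.
#' @param theta_deg Egg shape angle in degrees, `0 <= theta_deg < 45`.
#' @return An object of class `egg_profile`.
#' @examples
#' prof <- egg_profile(28.435, 21.89, 10)
#' profile_halfwidth(prof, 0) # == b
#' @export
egg_profile <- function(a, b, theta_deg = 0) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(theta_deg))
  if (!(a > b && b > 0)) {
    abort("egg profile requires a > b > 0")
  }
  if (theta_deg < 0 || theta_deg >= 45) {
    abort("egg shape angle must lie in [0, 45) degrees")
  }
  if (b - a * tan(theta_deg * pi / 180) <= 0) {
    abort("shape angle too large: profile halfwidth would vanish before x = -a")
  }
  structure(list(a = a, b = b, theta_deg = theta_deg), class = "egg_profile")
}

#' @method print egg_profile
#' @export
print.egg_profile <- function(x, ...) {
  cat(sprintf("<egg_profile> a = %.3f mm, b = %.3f mm, theta = %.1f deg\n",
              x$a, x$b, x$theta_deg))
  invisible(x)
}

#' Halfwidth of the egg profile at an axial position
#'
#' Solves the profile equation for the (non-negative) radial halfwidth
#' `y(x) = (b + x tan(theta)) * sqrt(1 - x^2/a^2)`.
#'
#' @param profile An [egg_profile()].
#' @param x Axial coordinate(s) in mm; must lie in `[-a, a]`.
#' @return Numeric vector of halfwidths in mm.
#' @export
profile_halfwidth <- function(profile, x) {
  stopifnot(inherits(profile, "egg_profile"))
  if (any(!is.finite(x)) || any(x < -profile$a - 1e-12) || any(x > profile$a + 1e-12)) {
    abort("axial coordinate outside [-a, a]")
  }
  x <- pmin(pmax(x, -profile$a), profile$a)
  (profile$b + x * tan(profile$theta_deg * pi / 180)) *
    sqrt(pmax(0, 1 - x^2 / profile$a^2))
}

#' Air-cell state at the egg blunt end
#'
#' The air cell is the spherical cap cut from the blunt-end crown sphere
#' (radius `R`) by the membrane plane. The membrane is a chord circle of
#' radius `Ra` tilted by `alpha_deg` against the egg equatorial plane;
#' the air-cell height `h` (ACH) is measured perpendicular to the membrane:
#' `h = R - sqrt(R^2 - Ra^2)`. Supply either `h` or `Ra`; the other is
#' derived.
#'
#' @param R Crown sphere radius, mm.
#' @param h Air-cell height, mm (`0 < h < R`).
#' @param alpha_deg Membrane tilt angle versus the equatorial plane, degrees,
#'   `0 <= alpha_deg < 90`.
#' @param Ra Membrane circle radius, mm (`0 < Ra < R`).
#' @return An object of class `air_cell_state` with fields `R`, `h`,
#'   `alpha_deg`, `Ra`.
#' @examples
#' air_cell_state(R = 30, h = 6)          # Ra = sqrt(2*30*6 - 36) = 18
#' air_cell_state(R = 30, Ra = 15, alpha_deg = 20)
#' @export
air_cell_state <- function(R, h = NULL, alpha_deg = 0, Ra = NULL) {
  stopifnot(is.numeric(R), R > 0)
  if (alpha_deg < 0 || alpha_deg >= 90) {
    abort("membrane tilt must lie in [0, 90) degrees")
  }
  if (is.null(h) && is.null(Ra)) abort("supply at least one of h, Ra")
  if (is.null(Ra)) {
    if (!(h > 0 && h < R)) abort("air-cell height must satisfy 0 < h < R")
    Ra <- sqrt(2 * R * h - h^2)
  } else if (is.null(h)) {
    if (!(Ra > 0 && Ra < R)) abort("membrane radius must satisfy 0 < Ra < R")
    h <- R - sqrt(R^2 - Ra^2)
  } else {
    if (abs(Ra - sqrt(2 * R * h - h^2)) > 1e-6 * R) {
      abort("inconsistent (R, h, Ra): expected Ra = sqrt(2Rh - h^2)")
    }
  }
  if (!(h > 0 && h < R) || !(Ra > 0 && Ra < R)) {
    abort("invalid air-cell state: need 0 < h < R and 0 < Ra < R")
  }
  structure(list(R = R, h = h, alpha_deg = alpha_deg, Ra = Ra),
            class = "air_cell_state")
}

#' @method print air_cell_state
#' @export
print.air_cell_state <- function(x, ...) {
  cat(sprintf("<air_cell_state> R = %.3f mm, h = %.3f mm, alpha = %.1f deg, Ra = %.3f mm\n",
              x$R, x$h, x$alpha_deg, x$Ra))
  invisible(x)
}

#' Project the air-cell membrane onto the equatorial plane
#'
#' The tilted membrane circle projects orthogonally onto the egg equatorial
#' plane as an ellipse with long semi-axis `Ra` (the direction perpendicular
#' to the tilt is preserved) and short semi-axis `Rb = Ra cos(alpha)`.
#' The ellipse center sits at horizontal offset
#' `center_x = sqrt(R^2 - Ra^2) * sin(alpha)` from the egg axis, and the
#' projected membrane endpoint B (the end of the tilt-plane diameter) at
#' `xB = center_x + Ra cos(alpha)`. All coordinates are expressed in the
#' equatorial-plane frame with origin on the egg symmetry axis, mm.
#'
#' @param cell An [air_cell_state()].
#' @return One-row tibble of class `projection_observation` with columns
#'   `Ra`, `Rb`, `xB`, `center_x` (mm).
#' @export
forward_project <- function(cell) {
  stopifnot(inherits(cell, "air_cell_state"))
  alpha <- cell$alpha_deg * pi / 180
  d_axis <- sqrt(cell$R^2 - cell$Ra^2)      # distance sphere center -> membrane plane
  obs <- tibble(
    Ra = cell$Ra,
    Rb = cell$Ra * cos(alpha),
    xB = d_axis * sin(alpha) + cell$Ra * cos(alpha),
    center_x = d_axis * sin(alpha)
  )
  class(obs) <- c("projection_observation", class(obs))
  obs
}

#' Estimate air-cell height from a projection observation
#'
#' Inverts the projection model. From the observed ellipse semi-axes
#' `(Ra, Rb)` and the horizontal coordinate `xB` of the projected membrane
#' endpoint, the distance from the sphere center to the membrane plane is
#' \deqn{D = R_a (x_B - R_b) / \sqrt{R_a^2 - R_b^2},}
#' and the air-cell height follows without knowledge of the crown radius:
#' \deqn{h = \sqrt{D^2 + R_a^2} - D.}
#' When the membrane is (near-)horizontal (`Ra - Rb < eps * Ra`) the tilted
#' formula is degenerate and the spherical-cap relation
#' `h = R - sqrt(R^2 - Ra^2)` is used instead, which requires an externally
#' supplied crown radius `R`.
#'
#' @param obs A `projection_observation` (or data frame with columns `Ra`,
#'   `Rb`, `xB`); rows are processed independently.
#' @param R Optional crown sphere radius (mm) for the horizontal-membrane
#'   fallback.
#' @param eps Relative degeneracy threshold on `Ra - Rb` (default `1e-6`).
#' @return Numeric vector of air-cell heights, mm.
#' @export
estimate_ach <- function(obs, R = NULL, eps = 1e-6) {
  stopifnot(is.data.frame(obs), all(c("Ra", "Rb", "xB") %in% names(obs)))
  Ra <- obs$Ra
  Rb <- obs$Rb
  xB <- obs$xB
  if (any(!is.finite(Ra)) || any(!is.finite(Rb)) || any(!is.finite(xB))) {
    abort("non-finite projection observation")
  }
  if (any(Rb > Ra)) abort("invalid observation: Rb > Ra")
  if (any(Rb <= 0)) abort("invalid observation: Rb must be positive")
  degen <- (Ra - Rb) < eps * Ra
  h <- numeric(length(Ra))
  if (any(degen)) {
    if (is.null(R)) {
      abort(paste("underdetermined: horizontal membrane requires the crown",
                  "sphere radius R to recover the cap height"))
    }
    if (any(R < Ra[degen])) abort("supplied R smaller than observed Ra")
    h[degen] <- R - sqrt(R^2 - Ra[degen]^2)
  }
  if (any(!degen)) {
    D <- Ra[!degen] * (xB[!degen] - Rb[!degen]) / sqrt(Ra[!degen]^2 - Rb[!degen]^2)
    h[!degen] <- sqrt(D^2 + Ra[!degen]^2) - D
  }
  h
}

#' Brute-force 3D construction of the membrane circle and its projection
#'
#' Test oracle for the projection model: samples the membrane chord circle
#' explicitly in 3D on the crown sphere and projects it onto the equatorial
#' plane by dropping the axial coordinate. The sphere center is the origin;
#' the egg axis is the z axis; the tilt lies in the xz plane.
#'
#' @param cell An [air_cell_state()].
#' @param n_points Number of sampled points on the circle (>= 3).
#' @return A list with `points3d` (tibble `x`, `y`, `z`) and `projection`
#'   (tibble `x`, `y`), plus the projected semi-axes `semi_major`,
#'   `semi_minor` and `xB` measured from the point set.
#' @export
aircell_oracle_construct <- function(cell, n_points = 360) {
  stopifnot(inherits(cell, "air_cell_state"), n_points >= 3)
  alpha <- cell$alpha_deg * pi / 180
  d_axis <- sqrt(cell$R^2 - cell$Ra^2)
  normal <- c(sin(alpha), 0, cos(alpha))
  center <- d_axis * normal
  u <- c(cos(alpha), 0, -sin(alpha))   # in-plane direction within tilt plane
  v <- c(0, 1, 0)                      # in-plane direction perpendicular to tilt
  t <- seq(0, 2 * pi, length.out = n_points + 1)[-(n_points + 1)]
  pts <- t(vapply(t, function(tt) {
    center + cell$Ra * (cos(tt) * u + sin(tt) * v)
  }, numeric(3)))
  points3d <- tibble(x = pts[, 1], y = pts[, 2], z = pts[, 3])
  projection <- tibble(x = pts[, 1], y = pts[, 2])
  list(
    points3d = points3d,
    projection = projection,
    semi_major = max(abs(projection$y)),
    semi_minor = max(abs(projection$x - center[1])),
    xB = center[1] + cell$Ra * cos(alpha)
  )
}
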