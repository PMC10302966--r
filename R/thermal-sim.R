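#' Thermo-physical properties of the egg model
#'
#' Default material properties for the three simulated regions: thermal
#' conductivity `k` (W/(m K)), specific heat `c` (J/(kg K)) and density
#' `rho` (kg/m^3).
#'
#' @return A tibble with columns `label`, `k`, `c`, `rho`.
#' @export
egg_material_properties <- function() {
  tibble(
    label = c("shell", "air_cell", "albumen"),
    k   = c(0.4560, 0.0239, 0.5900),
    c   = c(888.0, 1008.5, 3560.0),
    rho = c(2300.000, 1.265, 1035.000)
  )
}

#' Crown sphere radius of the blunt end
#'
#' Radius of the sphere through the blunt tip (`x = +a`) and the egg
#' equatorial circle (radius `b` at `x = 0`), centered on the symmetry
#' axis: `R = (a^2 + b^2) / (2 a)`. This sphere models the blunt-end
#' spherical crown that the air cell is cut from; it lies inside the egg
#' solid between equator and tip.
#'
#' @param profile An [egg_profile()].
#' @return Crown sphere radius in mm.
#' @export
blunt_crown_radius <- function(profile) {
  stopifnot(inherits(profile, "egg_profile"))
  (profile$a^2 + profile$b^2) / (2 * profile$a)
}

# pointwise material classification of the egg cross-section.
# Returns integer codes 0 outside, 1 shell, 2 air cell, 3 albumen for
# vectors of (x, z) positions in mm. The shell is the band within
# `shell_mm` of the egg surface (analytic normal distance, with the exact
# pole distances as upper bounds near the tips); the air cell is the
# crown-sphere cap above the (possibly tilted) membrane plane.
.classify_egg_points <- function(profile, cell, X, Z, shell_mm) {
  a <- profile$a
  out <- integer(length(X))
  okz <- abs(Z) < a
  hw <- rep(0, length(Z))
  hw[okz] <- profile_halfwidth(profile, Z[okz])
  inside <- okz & abs(X) < hw
  out[inside] <- 3L
  if (any(inside)) {
    eps <- 1e-4
    zi <- Z[inside]
    zp <- pmin(zi + eps, a); zm <- pmax(zi - eps, -a)
    slope <- (profile_halfwidth(profile, zp) - profile_halfwidth(profile, zm)) /
      (zp - zm)
    d_lin <- (hw[inside] - abs(X[inside])) / sqrt(1 + slope^2)
    d_surf <- pmin(d_lin,
                   sqrt(X[inside]^2 + (a - Z[inside])^2),
                   sqrt(X[inside]^2 + (a + Z[inside])^2))
    sh <- d_surf <= shell_mm
    out[inside][sh] <- 1L
    if (!is.null(cell)) {
      # the air cap lives under the shell: cut it from the crown sphere of
      # the shell's inner surface (profile shrunk by the shell thickness)
      ai <- a - shell_mm
      bi <- profile$b - shell_mm
      Ri <- (ai^2 + bi^2) / (2 * ai)
      z0i <- ai - Ri
      alpha <- cell$alpha_deg * pi / 180
      d_axis <- Ri - cell$h
      px <- X[inside]; pz <- Z[inside] - z0i
      in_cap <- (px * sin(alpha) + pz * cos(alpha)) > d_axis &
        (px^2 + pz^2) < Ri^2
      out[inside][in_cap & !sh] <- 2L
    }
  }
  out
}

#' Rasterize the egg cross-section into a labeled material map
#'
#' Builds a structured grid over the egg's axial cross-section (signed
#' transverse coordinate `x`, axial coordinate `z`, blunt end at
#' `z = +a`) and labels every cell as `outside`, `shell`, `air_cell` or
#' `albumen`. The shell is the band within `shell_mm` of the egg surface;
#' the air cell is the spherical cap of the blunt crown sphere above the
#' (optionally tilted) membrane plane. Each cell is additionally
#' subsampled on a `subsample x subsample` grid: the per-cell heat
#' capacity is the exact sub-cell material mix (partial surface cells
#' hand their mass to the nearest solid cell), and the convective
#' boundary carries the true revolved surface area per boundary cell
#' rather than staircase face areas. Both choices keep the thin shell
#' band's thermal response accurate well below the grid resolution.
#' The axisymmetric solver interprets `|x|` as the cylindrical radius, so
#' a tilted air cell (cross-section of the tilt plane) is an
#' approximation.
#'
#' @param profile An [egg_profile()].
#' @param cell An [air_cell_state()] or `NULL` for no air cell. Its `R`
#'   must equal [blunt_crown_radius()] of the profile (it is rebuilt from
#'   `h` and `alpha_deg` if it does not).
#' @param resolution Grid spacing in mm (isotropic). Default 0.5.
#' @param shell_mm Nominal shell thickness, mm. Default 0.35.
#' @param subsample Subsampling factor per cell edge for the effective
#'   properties (default 4; 1 disables mixing).
#' @param props Material property table, see [egg_material_properties()].
#' @return An object of class `material_map`.
#' @export
build_material_map <- function(profile, cell = NULL, resolution = 0.5,
                               shell_mm = 0.35, subsample = 4,
                               props = egg_material_properties()) {
  stopifnot(inherits(profile, "egg_profile"), resolution > 0, subsample >= 1)
  a <- profile$a
  R <- blunt_crown_radius(profile)
  if (!is.null(cell)) {
    stopifnot(inherits(cell, "air_cell_state"))
    if (abs(cell$R - R) > 1e-9) {
      cell <- air_cell_state(R = R, h = cell$h, alpha_deg = cell$alpha_deg)
    }
    if (cell$h >= R) abort("air cell larger than the blunt crown")
    # lowest point of the membrane ring must stay above the equator
    alpha <- cell$alpha_deg * pi / 180
    ring_low <- (a - R) + (R - cell$h) * cos(alpha) - cell$Ra * sin(alpha)
    if (ring_low < 0) {
      abort("air cell extends past the equator: too large for the crown")
    }
  }
  dx <- resolution
  xs <- seq(0, max(profile_halfwidth(profile, seq(-a, a, length.out = 2048))) + dx,
            by = dx)
  x_centers <- c(rev(-(xs + dx / 2)), xs + dx / 2)  # symmetric about the axis
  z_centers <- seq(-a - dx / 2, a + dx / 2, by = dx)
  nx <- length(x_centers)
  nz <- length(z_centers)

  code_names <- c("outside", "shell", "air_cell", "albumen")
  kv <- setNames(props$k, props$label)
  rcv <- setNames(props$rho * props$c, props$label)
  k_of <- c(NA, kv[["shell"]], kv[["air_cell"]], kv[["albumen"]])
  rc_of <- c(NA, rcv[["shell"]], rcv[["air_cell"]], rcv[["albumen"]])

  S <- as.integer(subsample)
  sub_off <- (seq_len(S) - (S + 1) / 2) / S * dx
  Xc <- rep(x_centers, times = nz)
  Zc <- rep(z_centers, each = nx)
  n_cells <- nx * nz
  mm3 <- 1e-9                            # mm^3 -> m^3
  cnt <- matrix(0L, n_cells, 4)          # per-cell subpoint counts by code
  cap_acc <- numeric(n_cells)            # per-cell heat capacity, J/K
  invk_zcol <- array(0, c(n_cells, S))   # sum of 1/k along z per x-subcolumn
  nin_zcol <- array(0L, c(n_cells, S))
  invk_xrow <- array(0, c(n_cells, S))   # sum of 1/k along x per z-subrow
  nin_xrow <- array(0L, c(n_cells, S))
  for (sx in seq_len(S)) for (sz in seq_len(S)) {
    ox <- sub_off[sx]; oz <- sub_off[sz]
    cls <- .classify_egg_points(profile, cell, Xc + ox, Zc + oz, shell_mm)
    for (cd in 0:3) cnt[, cd + 1] <- cnt[, cd + 1] + (cls == cd)
    ins <- cls > 0L
    # sub-cell ring volume on the full revolution; both halves of the
    # signed cross-section carry it, matching the doubled face areas
    subvol <- 2 * pi * abs(Xc[ins] + ox) * (dx / S)^2 * mm3
    cap_acc[ins] <- cap_acc[ins] + rc_of[cls[ins] + 1L] * subvol
    invk <- 1 / k_of[cls[ins] + 1L]
    invk_zcol[ins, sx] <- invk_zcol[ins, sx] + invk
    nin_zcol[ins, sx] <- nin_zcol[ins, sx] + 1L
    invk_xrow[ins, sz] <- invk_xrow[ins, sz] + invk
    nin_xrow[ins, sz] <- nin_xrow[ins, sz] + 1L
  }
  n_in <- rowSums(cnt[, 2:4, drop = FALSE])
  solid <- n_in > S^2 / 2                # majority-solid cells form the domain
  # direction-specific effective conductivity: series (harmonic) along the
  # flux direction within each sub-column, parallel (arithmetic) across
  # sub-columns -- the right homogenization for a thin insulating layer
  dir_keff <- function(invk_acc, nin_acc) {
    kcol <- ifelse(nin_acc > 0, nin_acc / pmax(invk_acc, 1e-300), NA_real_)
    num <- rowSums(ifelse(is.na(kcol), 0, kcol))
    den <- rowSums(!is.na(kcol))
    ifelse(den > 0, num / den, NA_real_)
  }
  kz_vec <- dir_keff(invk_zcol, nin_zcol)
  kx_vec <- dir_keff(invk_xrow, nin_xrow)
  lab_code <- max.col(cnt[, 2:4, drop = FALSE], ties.method = "first")
  labels <- matrix("outside", nx, nz)
  labels[solid] <- code_names[lab_code[solid] + 1L]
  keff <- kx <- kz <- matrix(NA_real_, nx, nz)
  keff[solid] <- k_of[lab_code[solid] + 1L]
  kx[solid] <- kx_vec[solid]
  kz[solid] <- kz_vec[solid]
  solid_m <- matrix(solid, nx, nz)
  snap_to_solid <- function(i, j) {
    # nearest solid cell within a small neighborhood (staircase snapping)
    for (rad in 0:2) {
      cand <- expand.grid(ii = pmax(1, i - rad):pmin(nx, i + rad),
                          jj = pmax(1, j - rad):pmin(nz, j + rad))
      ok <- solid_m[cbind(cand$ii, cand$jj)]
      if (any(ok)) {
        cand <- cand[ok, , drop = FALSE]
        d2 <- (x_centers[cand$ii] - x_centers[i])^2 +
          (z_centers[cand$jj] - z_centers[j])^2
        best <- which.min(d2)
        return(c(cand$ii[best], cand$jj[best]))
      }
    }
    c(NA_integer_, NA_integer_)
  }
  # conserve thermal mass: partial cells excluded from the solid domain
  # hand their capacity to the nearest solid cell
  capvol <- matrix(0, nx, nz)
  capvol[solid_m] <- cap_acc[solid]
  partial <- which(!solid & n_in > 0)
  for (p in partial) {
    i <- ((p - 1L) %% nx) + 1L
    j <- ((p - 1L) %/% nx) + 1L
    ij <- snap_to_solid(i, j)
    if (!is.na(ij[1])) capvol[ij[1], ij[2]] <- capvol[ij[1], ij[2]] + cap_acc[p]
  }
  capvol[!solid_m] <- NA_real_
  if (!is.null(cell) && !any(labels == "air_cell")) {
    abort("air cell did not rasterize: resolution too coarse for this cap")
  }

  # fractional region volumes; each half of the signed cross-section
  # generates the full solid of revolution, hence pi (not 2 pi)
  ring_vol <- pi * abs(Xc) * dx * dx
  volumes <- tibble(label = c("shell", "air_cell", "albumen")) |>
    mutate(volume_mm3 = map_dbl(2:4, function(cd) {
      sum(ring_vol * cnt[, cd] / S^2)
    }))

  # embedded-boundary convective surface: distribute the true revolved
  # surface area (dA = 2 pi x ds along the profile curve) over the solid
  # boundary cells, so the Robin flux sees the smooth egg surface rather
  # than the staircase faces (whose total area does not converge)
  th <- seq(0, pi, length.out = 8192)
  zs <- a * cos(th)
  xsur <- profile_halfwidth(profile, zs)
  xm <- (xsur[-1] + xsur[-length(xsur)]) / 2
  zm <- (zs[-1] + zs[-length(zs)]) / 2
  ds <- sqrt(diff(xsur)^2 + diff(zs)^2)
  dA <- 2 * pi * xm * ds                       # mm^2 on the full revolution
  ang_seg <- acos(pmin(1, pmax(-1, zm / sqrt(xm^2 + zm^2))))
  ii_seg <- findInterval(xm, c(x_centers - dx / 2, x_centers[nx] + dx / 2),
                         all.inside = TRUE)
  jj_seg <- findInterval(zm, c(z_centers - dx / 2, z_centers[nz] + dx / 2),
                         all.inside = TRUE)
  bnd_area <- matrix(0, nx, nz)
  bnd_ang <- matrix(0, nx, nz)                 # area-weighted angle sum
  for (s in seq_along(dA)) {
    if (dA[s] <= 0) next
    ij <- c(ii_seg[s], jj_seg[s])
    if (!solid_m[ij[1], ij[2]]) ij <- snap_to_solid(ij[1], ij[2])
    if (is.na(ij[1])) next
    for (sgn in c(1, -1)) {                    # both halves carry the full area
      im <- if (sgn == 1) ij[1] else nx + 1 - ij[1]
      bnd_area[im, ij[2]] <- bnd_area[im, ij[2]] + dA[s]
      bnd_ang[im, ij[2]] <- bnd_ang[im, ij[2]] + dA[s] * ang_seg[s]
    }
  }
  bidx <- which(bnd_area > 0, arr.ind = TRUE)
  boundary <- tibble(i = bidx[, 1], j = bidx[, 2],
                     area_mm2 = bnd_area[bidx],
                     polar_deg = bnd_ang[bidx] / bnd_area[bidx] * 180 / pi)

  structure(list(
    kind = "egg", dx = dx, x_centers = x_centers, z_centers = z_centers,
    labels = labels, keff = keff, kx = kx, kz = kz,
    capvol = capvol, boundary = boundary,
    shell_mm = shell_mm, resolution = resolution, subsample = S,
    profile = profile, cell = cell, crown_R = R,
    crown_R_inner = ((a - shell_mm)^2 + (profile$b - shell_mm)^2) /
      (2 * (a - shell_mm)),
    volumes = volumes,
    props = props
  ), class = "material_map")
}

#' Homogeneous slab material map (verification geometry)
#'
#' A cylinder of a single material with the heated face at the top
#' (`z = depth_mm`); used to verify the conduction solver against the
#' one-dimensional semi-infinite convective-boundary solution.
#'
#' @param material Label present in `props` (default `"albumen"`).
#' @param depth_mm Slab depth along z, mm.
#' @param radius_mm Cylinder radius, mm.
#' @param resolution Grid spacing, mm.
#' @param props Material property table.
#' @return A `material_map` with `kind = "slab"`; only the top face
#'   receives the jet boundary, all other faces are insulated.
#' @export
slab_material_map <- function(material = "albumen", depth_mm = 20,
                              radius_mm = 2, resolution = 0.1,
                              props = egg_material_properties()) {
  dx <- resolution
  nxh <- ceiling(radius_mm / dx)
  x_centers <- (seq_len(2 * nxh + 2) - (nxh + 1.5)) * dx
  nzin <- ceiling(depth_mm / dx)
  z_centers <- (seq_len(nzin + 2) - 1.5) * dx
  nx <- length(x_centers)
  nz <- length(z_centers)
  labels <- matrix("outside", nx, nz)
  labels[2:(nx - 1), 2:(nz - 1)] <- material
  pr <- props[props$label == material, ]
  if (nrow(pr) != 1) abort(sprintf("unknown material '%s'", material))
  keff <- matrix(NA_real_, nx, nz)
  capvol <- matrix(NA_real_, nx, nz)
  keff[labels == material] <- pr$k
  sel <- which(labels == material, arr.ind = TRUE)
  capvol[sel] <- pr$rho * pr$c *
    2 * pi * abs(x_centers[sel[, 1]]) * dx^2 * 1e-9
  structure(list(
    kind = "slab", dx = dx, x_centers = x_centers, z_centers = z_centers,
    labels = labels, keff = keff, capvol = capvol,
    shell_mm = NA_real_, resolution = resolution,
    profile = NULL, cell = NULL, crown_R = NA_real_,
    volumes = tibble(label = material,
                     volume_mm3 = sum(pi * abs(
                       x_centers[row(labels)[labels == material]]) * dx * dx)),
    props = props
  ), class = "material_map")
}

#' @method print material_map
#' @export
print.material_map <- function(x, ...) {
  cat(sprintf("<material_map:%s> %d x %d cells at %.3g mm\n",
              x$kind, length(x$x_centers), length(x$z_centers), x$dx))
  print(x$volumes)
  invisible(x)
}

#' Simulation configuration
#'
#' @param T_init Initial uniform temperature, degC.
#' @param T_air Hot-air jet temperature, degC.
#' @param h_jet Convective coefficient of the jet, W/(m^2 K).
#' @param jet_cap_deg Polar half-angle (from the blunt tip, about the egg
#'   center) of the surface patch covered by the jet, degrees.
#' @param h_ambient Convective coefficient to ambient elsewhere, W/(m^2 K).
#' @param T_ambient Ambient temperature, degC.
#' @param dt Time step, s.
#' @param duration Simulated time, s.
#' @param snap_dt Snapshot interval, s (recorded times are multiples of it).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(T_init = 10, T_air = 40, h_jet = 60, jet_cap_deg = 60,
                       h_ambient = 5, T_ambient = 10, dt = 0.05,
                       duration = 10, snap_dt = 0.1) {
  if (dt <= 0) abort("dt must be positive")
  if (duration <= 0) abort("duration must be positive")
  structure(list(T_init = T_init, T_air = T_air, h_jet = h_jet,
                 jet_cap_deg = jet_cap_deg, h_ambient = h_ambient,
                 T_ambient = T_ambient, dt = dt, duration = duration,
                 snap_dt = snap_dt), class = "sim_config")
}

# face classification helper: TRUE if the face midpoint belongs to the jet patch
.face_is_jet <- function(map, cfg, xm, zm, normal_axis, normal_sign) {
  if (map$kind == "slab") {
    return(rep(normal_axis == "z" && normal_sign > 0, length(xm)))
  }
  ang <- acos(pmin(1, pmax(-1, zm / sqrt(xm^2 + zm^2))))
  ang <= cfg$jet_cap_deg * pi / 180
}

#' Simulate transient heat conduction on a material map
#'
#' Backward-Euler (unconditionally stable) finite-volume time stepping of
#' axisymmetric conduction `rho c dT/dt = div(k grad T)` with a convective
#' (Robin) boundary: the jet patch couples to `T_air` through `h_jet`, the
#' remaining surface to `T_ambient` through `h_ambient`. Interface
#' conductivities use the harmonic mean; boundary faces use the series
#' resistance `1/h + d/(2k)`. Radiation and internal flow are ignored.
#'
#' @param map A [build_material_map()] or [slab_material_map()] result.
#' @param cfg A [sim_config()].
#' @return An object of class `temperature_field` with `times` (s) and
#'   `data`, an array `[nx, nz, n_snap]` of cell temperatures (degC, `NA`
#'   outside the solid).
#' @export
simulate_conduction <- function(map, cfg) {
  stopifnot(inherits(map, "material_map"), inherits(cfg, "sim_config"))
  labels <- map$labels
  nx <- nrow(labels); nz <- ncol(labels)
  inside <- labels != "outside"
  N <- sum(inside)
  if (N == 0) abort("material map has no solid cells")
  idx <- matrix(0L, nx, nz)
  idx[inside] <- seq_len(N)

  kmat <- map$keff
  capmat <- map$capvol
  if (any(inside & (is.na(kmat) | is.na(capmat)))) {
    abort("material map lacks effective properties on solid cells")
  }
  kxmat <- map$kx %||% kmat                # directional effective k
  kzmat <- map$kz %||% kmat

  mm <- 1e-3                               # grid metrics in SI (m)
  dx <- map$dx * mm
  xc <- map$x_centers * mm
  zc <- map$z_centers * mm
  xf <- c(xc - dx / 2, xc[nx] + dx / 2)    # x face positions, length nx+1

  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  diag_acc <- numeric(N)
  rhs_const <- numeric(N)

  add_interior <- function(i1, i2, G) {
    keep <- G > 0
    i1 <- i1[keep]; i2 <- i2[keep]; G <- G[keep]
    ii <<- c(ii, i1, i2); jj <<- c(jj, i2, i1); xx <<- c(xx, -G, -G)
    diag_acc[i1] <<- diag_acc[i1] + G
    diag_acc[i2] <<- diag_acc[i2] + G
  }
  use_faces <- is.null(map$boundary)   # embedded-boundary maps skip face Robin
  add_boundary <- function(cells, A, kin, xm, zm, axis, sgn) {
    if (!use_faces || length(cells) == 0) return(invisible())
    jet <- .face_is_jet(map, cfg, xm, zm, axis, sgn)
    hco <- ifelse(jet, cfg$h_jet, cfg$h_ambient)
    Tenv <- ifelse(jet, cfg$T_air, cfg$T_ambient)
    ok <- hco > 0 & A > 0
    if (!any(ok)) return(invisible())
    G <- A[ok] / (1 / hco[ok] + dx / (2 * kin[ok]))
    diag_acc[cells[ok]] <<- diag_acc[cells[ok]] + G
    rhs_const[cells[ok]] <<- rhs_const[cells[ok]] + G * Tenv[ok]
  }

  # ---- x-direction faces (between i and i+1) -------------------------------
  Af_x <- 2 * pi * abs(xf[2:nx]) * dx      # vector over interior x faces
  L1 <- inside[1:(nx - 1), , drop = FALSE]
  L2 <- inside[2:nx, , drop = FALSE]
  both <- which(L1 & L2, arr.ind = TRUE)
  if (nrow(both)) {
    i <- both[, 1]; j <- both[, 2]
    k1 <- kxmat[cbind(i, j)]; k2 <- kxmat[cbind(i + 1, j)]
    G <- Af_x[i] / (dx / (2 * k1) + dx / (2 * k2))
    add_interior(idx[cbind(i, j)], idx[cbind(i + 1, j)], G)
  }
  b <- which(L1 & !L2, arr.ind = TRUE)     # inside cell i, outside neighbor i+1
  if (nrow(b)) {
    i <- b[, 1]; j <- b[, 2]
    add_boundary(idx[cbind(i, j)], Af_x[i], kmat[cbind(i, j)],
                 xf[i + 1] / mm, zc[j] / mm, "x", +1)
  }
  b <- which(!L1 & L2, arr.ind = TRUE)     # inside cell i+1, outside neighbor i
  if (nrow(b)) {
    i <- b[, 1]; j <- b[, 2]
    add_boundary(idx[cbind(i + 1, j)], Af_x[i], kmat[cbind(i + 1, j)],
                 xf[i + 1] / mm, zc[j] / mm, "x", -1)
  }

  # ---- z-direction faces (between j and j+1) -------------------------------
  Af_z <- 2 * pi * abs(xc) * dx            # vector over x for any z face
  L1 <- inside[, 1:(nz - 1), drop = FALSE]
  L2 <- inside[, 2:nz, drop = FALSE]
  both <- which(L1 & L2, arr.ind = TRUE)
  if (nrow(both)) {
    i <- both[, 1]; j <- both[, 2]
    k1 <- kzmat[cbind(i, j)]; k2 <- kzmat[cbind(i, j + 1)]
    G <- Af_z[i] / (dx / (2 * k1) + dx / (2 * k2))
    add_interior(idx[cbind(i, j)], idx[cbind(i, j + 1)], G)
  }
  b <- which(L1 & !L2, arr.ind = TRUE)
  if (nrow(b)) {
    i <- b[, 1]; j <- b[, 2]
    add_boundary(idx[cbind(i, j)], Af_z[i], kmat[cbind(i, j)],
                 xc[i] / mm, (zc[j] + dx / 2) / mm, "z", +1)
  }
  b <- which(!L1 & L2, arr.ind = TRUE)
  if (nrow(b)) {
    i <- b[, 1]; j <- b[, 2]
    add_boundary(idx[cbind(i, j + 1)], Af_z[i], kmat[cbind(i, j + 1)],
                 xc[i] / mm, (zc[j] + dx / 2) / mm, "z", -1)
  }

  # ---- embedded-boundary Robin terms (egg maps) ----------------------------
  if (!use_faces) {
    bd <- map$boundary
    cells <- idx[cbind(bd$i, bd$j)]
    ok <- cells > 0
    bd <- bd[ok, , drop = FALSE]; cells <- cells[ok]
    jet <- bd$polar_deg <= cfg$jet_cap_deg
    hco <- ifelse(jet, cfg$h_jet, cfg$h_ambient)
    Tenv <- ifelse(jet, cfg$T_air, cfg$T_ambient)
    keep <- hco > 0
    if (any(keep)) {                 # one row per boundary cell: direct add
      G <- (bd$area_mm2[keep] * mm^2) /
        (1 / hco[keep] + dx / (2 * kmat[cbind(bd$i, bd$j)][keep]))
      diag_acc[cells[keep]] <- diag_acc[cells[keep]] + G
      rhs_const[cells[keep]] <- rhs_const[cells[keep]] + G * Tenv[keep]
    }
  }

  cap <- capmat[inside] / cfg$dt                # rho c V / dt per unknown, W/K
  A <- Matrix::sparseMatrix(i = c(ii, seq_len(N)), j = c(jj, seq_len(N)),
                            x = c(xx, cap + diag_acc), dims = c(N, N))
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE)

  n_steps <- ceiling(cfg$duration / cfg$dt)
  snap_every <- max(1L, round(cfg$snap_dt / cfg$dt))
  Tvec <- rep(cfg$T_init, N)
  snaps <- list(Tvec)
  snap_times <- 0
  for (s in seq_len(n_steps)) {
    rhs <- cap * Tvec + rhs_const
    Tvec <- as.numeric(Matrix::solve(ch, rhs))
    if (any(!is.finite(Tvec))) {
      abort(sprintf("conduction solve diverged at step %d (t = %.3f s)", s, s * cfg$dt))
    }
    if (s %% snap_every == 0 || s == n_steps) {
      snaps[[length(snaps) + 1]] <- Tvec
      snap_times <- c(snap_times, s * cfg$dt)
    }
  }

  data <- array(NA_real_, dim = c(nx, nz, length(snaps)))
  for (s in seq_along(snaps)) {
    M <- matrix(NA_real_, nx, nz)
    M[inside] <- snaps[[s]]
    data[, , s] <- M
  }
  structure(list(map = map, cfg = cfg, times = snap_times, data = data),
            class = "temperature_field")
}

#' @method print temperature_field
#' @export
print.temperature_field <- function(x, ...) {
  cat(sprintf("<temperature_field> %d snapshots over %.2f s, T in [%.2f, %.2f] degC\n",
              length(x$times), max(x$times),
              min(x$data, na.rm = TRUE), max(x$data, na.rm = TRUE)))
  invisible(x)
}

#' Probe temperature traces from a simulated field
#'
#' Bilinear interpolation of the snapshot temperatures at fixed probe
#' positions; grid cells outside the solid are excluded from the
#' interpolation stencil (weights renormalized).
#'
#' @param field A [simulate_conduction()] result.
#' @param probes Data frame with columns `id`, `x_mm` (signed transverse
#'   coordinate) and `z_mm` (axial coordinate, blunt end positive).
#' @return A tibble of class `probe_series` with columns `probe_id`,
#'   `x_mm`, `z_mm`, `time_s`, `T_C`.
#' @export
probe_temperature <- function(field, probes) {
  stopifnot(inherits(field, "temperature_field"), is.data.frame(probes),
            all(c("id", "x_mm", "z_mm") %in% names(probes)))
  xc <- field$map$x_centers
  zc <- field$map$z_centers
  out <- purrr::pmap(probes, function(id, x_mm, z_mm, ...) {
    if (x_mm < min(xc) || x_mm > max(xc) || z_mm < min(zc) || z_mm > max(zc)) {
      abort(sprintf("probe '%s' outside the grid", id))
    }
    i <- findInterval(x_mm, xc, all.inside = TRUE)
    j <- findInterval(z_mm, zc, all.inside = TRUE)
    wx <- (x_mm - xc[i]) / (xc[i + 1] - xc[i])
    wz <- (z_mm - zc[j]) / (zc[j + 1] - zc[j])
    w <- c((1 - wx) * (1 - wz), wx * (1 - wz), (1 - wx) * wz, wx * wz)
    traces <- vapply(seq_along(field$times), function(s) {
      v <- c(field$data[i, j, s], field$data[i + 1, j, s],
             field$data[i, j + 1, s], field$data[i + 1, j + 1, s])
      ok <- !is.na(v)
      if (!any(ok)) abort(sprintf("probe '%s' lies outside the solid", id))
      sum(w[ok] * v[ok]) / sum(w[ok])
    }, numeric(1))
    tibble(probe_id = id, x_mm = x_mm, z_mm = z_mm,
           time_s = field$times, T_C = traces)
  })
  out <- bind_rows(out)
  class(out) <- c("probe_series", class(out))
  out
}

# classify shell-surface cells by what lies beneath them (air cell / albumen)
.surface_backing <- function(map, max_depth_mm = 6) {
  labels <- map$labels
  nx <- nrow(labels); nz <- ncol(labels)
  inside <- labels != "outside"
  surf <- which(inside & (
    rbind(!inside[-1, , drop = FALSE], TRUE) |
      rbind(TRUE, !inside[-nx, , drop = FALSE]) |
      cbind(!inside[, -1, drop = FALSE], TRUE) |
      cbind(TRUE, !inside[, -nz, drop = FALSE])), arr.ind = TRUE)
  n_steps <- ceiling(max_depth_mm / map$dx)
  backing <- character(nrow(surf))
  for (r in seq_len(nrow(surf))) {
    p <- c(map$x_centers[surf[r, 1]], map$z_centers[surf[r, 2]])
    dir <- -p / sqrt(sum(p^2))        # toward the egg center
    backing[r] <- "shell"
    for (s in seq_len(n_steps)) {
      q <- p + dir * s * map$dx
      i <- which.min(abs(map$x_centers - q[1]))
      j <- which.min(abs(map$z_centers - q[2]))
      l <- labels[i, j]
      if (l %in% c("air_cell", "albumen")) { backing[r] <- l; break }
    }
  }
  tibble(i = surf[, 1], j = surf[, 2],
         x_mm = map$x_centers[surf[, 1]], z_mm = map$z_centers[surf[, 2]],
         backing = backing)
}

#' Earliest time the air-cell boundary becomes visible at the surface
#'
#' Computes, per snapshot, the contrast between the mean shell-surface
#' temperature over air-cell-backed cells and over albumen-backed cells
#' (both restricted to the jet patch), and returns the earliest time this
#' contrast exceeds `delta`. Returns `Inf` if it never does.
#'
#' @param field A [simulate_conduction()] result on an egg map with an
#'   air cell.
#' @param delta Contrast threshold in degC (> 0, or 0 for the first
#'   snapshot).
#' @return Onset time in seconds (or `Inf`).
#' @export
boundary_onset_time <- function(field, delta) {
  stopifnot(inherits(field, "temperature_field"))
  if (delta < 0) abort("delta must be non-negative")
  map <- field$map
  if (map$kind != "egg" || is.null(map$cell)) {
    abort("onset time requires an egg map with an air cell")
  }
  surf <- .surface_backing(map)
  ang <- acos(pmin(1, pmax(-1, surf$z_mm / sqrt(surf$x_mm^2 + surf$z_mm^2))))
  in_jet <- ang <= field$cfg$jet_cap_deg * pi / 180
  air_i <- which(in_jet & surf$backing == "air_cell")
  alb_i <- which(in_jet & surf$backing == "albumen")
  if (length(air_i) == 0 || length(alb_i) == 0) {
    abort("jet patch does not cover both air-cell-backed and albumen-backed surface")
  }
  for (s in seq_along(field$times)) {
    M <- field$data[, , s]
    contrast <- mean(M[cbind(surf$i[air_i], surf$j[air_i])]) -
      mean(M[cbind(surf$i[alb_i], surf$j[alb_i])])
    if (contrast > delta) return(field$times[s])
  }
  Inf
}

#' Surface contrast between air-cell-backed and albumen-backed shell
#'
#' @param field A [simulate_conduction()] result on an egg map.
#' @return A tibble `time_s`, `contrast_C` (mean air-cell-backed surface
#'   temperature minus mean albumen-backed, within the jet patch).
#' @export
surface_contrast <- function(field) {
  stopifnot(inherits(field, "temperature_field"))
  map <- field$map
  surf <- .surface_backing(map)
  ang <- acos(pmin(1, pmax(-1, surf$z_mm / sqrt(surf$x_mm^2 + surf$z_mm^2))))
  in_jet <- ang <= field$cfg$jet_cap_deg * pi / 180
  air_i <- which(in_jet & surf$backing == "air_cell")
  alb_i <- which(in_jet & surf$backing == "albumen")
  contrast <- vapply(seq_along(field$times), function(s) {
    M <- field$data[, , s]
    mean(M[cbind(surf$i[air_i], surf$j[air_i])]) -
      mean(M[cbind(surf$i[alb_i], surf$j[alb_i])])
  }, numeric(1))
  tibble(time_s = field$times, contrast_C = contrast)
}
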