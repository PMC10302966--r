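# axisymmetric transient conduction of the egg blunt end

test_that("material map reproduces the analytic spherical-cap volume", {
  prof <- reference_egg()
  R <- blunt_crown_radius(prof)
  Ri <- build_material_map(prof, resolution = 2)$crown_R_inner
  vols <- vapply(c(3, 9), function(h) {
    map <- build_material_map(prof, air_cell_state(R = R, h = h),
                              resolution = 0.25)
    map$volumes$volume_mm3[map$volumes$label == "air_cell"]
  }, numeric(1))
  # the cap is cut from the crown sphere of the shell's inner surface
  caps <- pi * c(3, 9)^2 * (3 * Ri - c(3, 9)) / 3
  expect_lt(abs(vols[1] - caps[1]) / caps[1], 0.05)
  expect_lt(abs(vols[2] - caps[2]) / caps[2], 0.05)
  expect_gt(vols[2], vols[1])   # stale egg has the larger cell
})

test_that("a tilted air cell rasterizes and oversized cells are rejected", {
  prof <- reference_egg()
  R <- blunt_crown_radius(prof)
  map <- build_material_map(prof, air_cell_state(R = R, h = 3, alpha_deg = 20),
                            resolution = 0.5)
  expect_true(any(map$labels == "air_cell"))
  # tilted cell is asymmetric across the axis
  air <- map$labels == "air_cell"
  expect_false(isTRUE(all.equal(air, air[rev(seq_len(nrow(air))), ])))
  # steep tilt drags the membrane ring below the equator
  expect_error(build_material_map(prof,
                                  air_cell_state(R = R, h = 15,
                                                 alpha_deg = 60),
                                  resolution = 0.5),
               "too large|larger")
})

test_that("uniform boundary temperature is an equilibrium", {
  prof <- reference_egg()
  map <- build_material_map(prof, air_cell_state(R = blunt_crown_radius(prof),
                                                 h = 3), resolution = 0.5)
  f <- simulate_conduction(map, sim_config(T_init = 10, T_air = 10,
                                           T_ambient = 10, duration = 1))
  expect_equal(range(f$data, na.rm = TRUE), c(10, 10), tolerance = 1e-10)
})

test_that("the maximum principle bounds every snapshot", {
  prof <- reference_egg()
  map <- build_material_map(prof, air_cell_state(R = blunt_crown_radius(prof),
                                                 h = 3), resolution = 0.5)
  f <- simulate_conduction(map, sim_config())
  expect_gte(min(f$data, na.rm = TRUE), 10 - 1e-9)
  expect_lte(max(f$data, na.rm = TRUE), 40 + 1e-9)

  # blunt-tip surface heats monotonically
  tip <- probe_temperature(f, data.frame(id = "tip", x_mm = 0.3,
                                         z_mm = prof$a - 0.6))
  expect_true(all(diff(tip$T_C) > 0))
  expect_equal(tip$T_C[tip$time_s == 0], 10)
})

test_that("slab solution matches the semi-infinite convective analytic form", {
  map <- slab_material_map(depth_mm = 12, radius_mm = 0.6, resolution = 0.1)
  cfg <- sim_config(T_init = 10, T_air = 40, h_jet = 60, h_ambient = 0,
                    dt = 0.02, duration = 5, snap_dt = 0.5)
  f <- simulate_conduction(map, cfg)
  pr <- egg_material_properties()
  alb <- pr[pr$label == "albumen", ]
  kk <- alb$k
  al <- kk / (alb$rho * alb$c)
  hh <- cfg$h_jet
  erfc <- function(x) 2 * pnorm(-sqrt(2) * x)
  analytic <- function(x, t) {
    10 + 30 * (erfc(x / (2 * sqrt(al * t))) -
                 exp(hh * x / kk + hh^2 * al * t / kk^2) *
                 erfc(x / (2 * sqrt(al * t)) + hh * sqrt(al * t) / kk))
  }
  depths <- c(0.25, 0.5, 1, 2)
  probes <- data.frame(id = paste0("d", depths), x_mm = 0.05,
                       z_mm = 12 - depths)
  tr <- probe_temperature(f, probes)
  tr <- tr[tr$time_s > 0, ]
  exact <- analytic(rep(depths, each = length(unique(tr$time_s))) * 1e-3,
                    tr$time_s)
  expect_lt(max(abs(tr$T_C - exact)) / 30, 0.02)
})

test_that("probe interpolation respects the grid domain", {
  map <- slab_material_map(depth_mm = 5, radius_mm = 0.5, resolution = 0.25)
  f <- simulate_conduction(map, sim_config(duration = 0.5, dt = 0.1))
  expect_error(probe_temperature(f, data.frame(id = "out", x_mm = 50,
                                               z_mm = 1)), "outside")
})

test_that("surface temperature ranks by distance from the blunt tip", {
  prof <- reference_egg()
  R <- blunt_crown_radius(prof)
  cell <- air_cell_state(R = R, h = 3)
  map <- build_material_map(prof, cell, resolution = 0.25)
  f <- simulate_conduction(map, sim_config(duration = 4))
  z0 <- prof$a - R
  probe_at <- function(phi, depth = 0.15) {
    dirv <- c(sin(phi), cos(phi))
    g <- function(s) {
      profile_halfwidth(prof, min(z0 + s * dirv[2], prof$a)) - s * dirv[1]
    }
    s <- uniroot(g, c(R * 0.5, R * 1.6))$root
    c(s * dirv[1], z0 + s * dirv[2]) - depth * dirv
  }
  phi_ring <- acos((R - cell$h) / R)
  p1 <- probe_at(1e-3)              # blunt tip (air-cell backed)
  p2 <- probe_at(phi_ring * 0.9)    # membrane edge
  p4 <- probe_at(45 * pi / 180)     # albumen backed
  tr <- probe_temperature(f, data.frame(id = c("H1", "H2", "H4"),
                                        x_mm = c(p1[1], p2[1], p4[1]),
                                        z_mm = c(p1[2], p2[2], p4[2])))
  at2 <- tr$T_C[tr$time_s == 2]
  expect_true(at2[1] >= at2[2])
  expect_true(at2[2] >= at2[3])

  # surface contrast between air-cell- and albumen-backed shell grows
  sc <- surface_contrast(f)
  expect_gt(sc$contrast_C[sc$time_s == 2], sc$contrast_C[sc$time_s == 0.1])
})

test_that("boundary onset time behaves with threshold and jet strength", {
  prof <- reference_egg()
  map <- build_material_map(prof, air_cell_state(R = blunt_crown_radius(prof),
                                                 h = 3), resolution = 0.5)
  f <- simulate_conduction(map, sim_config(duration = 3))
  expect_lte(boundary_onset_time(f, 0), f$times[3])  # essentially immediate
  expect_identical(boundary_onset_time(f, 100), Inf)
  t1 <- boundary_onset_time(f, 0.5)
  expect_true(is.finite(t1))
  f2 <- simulate_conduction(map, sim_config(duration = 3, h_jet = 150))
  expect_lte(boundary_onset_time(f2, 0.5), t1)
})

test_that("uniform ambient drives the slab to steady state", {
  map <- slab_material_map(depth_mm = 3, radius_mm = 0.4, resolution = 0.15)
  cfg <- sim_config(T_init = 10, T_air = 30, T_ambient = 30, h_jet = 60,
                    h_ambient = 60, dt = 2, duration = 500, snap_dt = 100)
  f <- simulate_conduction(map, cfg)
  final <- f$data[, , dim(f$data)[3]]
  expect_equal(range(final, na.rm = TRUE), c(30, 30), tolerance = 0.01 / 30)
})
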