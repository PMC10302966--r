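# lambda-2 route: connected-domain geometry and GLCM texture

test_that("region properties are exact on simple shapes", {
  m <- matrix(0L, 20, 20)
  m[6:15, 4:13] <- 1L                      # 10x10 square
  rp <- region_props(m, "egg")
  expect_equal(rp$x, 8.5)
  expect_equal(rp$y, 10.5)
  expect_equal(rp$area, 100)

  one <- matrix(0L, 5, 5); one[3, 3] <- 1L
  rp1 <- region_props(one, 1)
  expect_equal(rp1$area, 1)
  expect_equal(rp1$perimeter, 4 * sqrt(2) / 2)   # documented convention

  expect_error(region_props(m, "air_cell"), "no region")
})

test_that("centroid, area and perimeter match pixel-enumeration oracles", {
  withr::with_seed(5, {
    for (rep in 1:6) {
      m <- matrix(0L, 14, 14)
      blob <- oracle_components(matrix(runif(196) < 0.5, 14, 14))
      m[blob == 1] <- 1L                   # one connected random blob
      comp <- m == 1L
      rp <- region_props(m, 1)
      ref <- oracle_centroid_area(comp)
      expect_equal(rp$x, ref$x)
      expect_equal(rp$y, ref$y)
      expect_equal(rp$area, ref$area)
      expect_equal(rp$perimeter, oracle_perimeter(comp), tolerance = 1e-9)
    }
  })
})

test_that("pair geometry reduces to exact arithmetic", {
  egg <- tibble::tibble(x = 0, y = 0, area = 400, perimeter = 80)
  cell <- tibble::tibble(x = 3, y = 4, area = 100, perimeter = 40)
  pg <- pair_geometry(egg, cell)
  expect_equal(pg$d, 5)
  expect_equal(pg$PS, 0.25)
  expect_equal(pg$PC, 0.5)

  same <- pair_geometry(egg, egg)
  expect_equal(same$d, 0)
  expect_equal(same$theta, 0)

  # angle reduced to (-90, 90]
  up <- pair_geometry(tibble::tibble(x = 0, y = 0, area = 1, perimeter = 1),
                      tibble::tibble(x = -1, y = -1, area = 1, perimeter = 1))
  expect_gt(up$theta, -90)
  expect_lte(up$theta, 90)
})

test_that("the co-occurrence matrix matches hand enumeration", {
  img <- matrix(c(0, 1, 0, 1), 2, 2)       # columns (0,1) and (0,1)
  G <- glcm(img, levels = 2, offsets = list(c(0L, 1L)), symmetric = TRUE)
  expect_equal(sum(G), 1)
  # pairs (0,0) and (1,1), symmetrized: diagonal halves
  expect_equal(unname(G), matrix(c(0.5, 0, 0, 0.5), 2, 2))

  expect_error(glcm(img, domain = matrix(FALSE, 2, 2)), "empty domain")
  single <- matrix(5, 1, 1)
  expect_error(glcm(single, levels = 2, offsets = list(c(0L, 1L))),
               "no valid pixel pair")
})

test_that("constant and uniform textures give closed-form features", {
  gf <- glcm_features(glcm(matrix(7, 5, 5), levels = 8))
  expect_equal(gf$CON, 0)
  expect_equal(gf$ASM, 1)
  expect_equal(gf$ENT, 0)
  expect_true(is.na(gf$COR))
  expect_false(attr(gf, "cor_defined"))

  # uniform 2x2 G: ASM = 1/4, ENT = 2 bits, CON = 1/2, COR = 0
  G <- matrix(0.25, 2, 2)
  gf2 <- glcm_features(G)
  expect_equal(gf2$ASM, 0.25)
  expect_equal(gf2$ENT, 2)
  expect_equal(gf2$CON, 0.5)
  expect_equal(gf2$COR, 0)
})

test_that("texture statistics equal exhaustive enumeration on small images", {
  offs <- list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))
  withr::with_seed(13, {
    for (rep in 1:5) {
      gray <- matrix(sample(0:255, 256, replace = TRUE), 16, 16)
      domain <- matrix(runif(256) < 0.8, 16, 16)
      G <- glcm(gray, domain = domain, levels = 8, offsets = offs)
      Gref <- oracle_glcm(gray, domain, 8, offs)
      expect_equal(unname(G), unname(Gref), tolerance = 1e-12)
      gf <- glcm_features(G)
      ref <- oracle_glcm_features(G)
      expect_equal(gf$CON, ref$CON)
      expect_equal(gf$COR, ref$COR)
      expect_equal(gf$ENT, ref$ENT)
      expect_equal(gf$ASM, ref$ASM)
    }
  })
})

test_that("lambda-2 extraction agrees with the generator geometry", {
  sp <- small_scene(h = 6, alpha = 20, theta_c = 0, noise = 0)
  res <- render_thermal_video(sp)
  frame <- res$video$frames[[res$truth$peak_frame]]
  l2 <- extract_lambda2(frame, res$truth$mask)

  # centroid distance: egg disk center vs ellipse center offset
  d_true <- abs(res$truth$projection$center_x) * sp$scale_px_mm
  expect_lt(abs(l2$d - d_true), 1.5)
  # area ratio close to the analytic ellipse/circle ratio
  ps_true <- (res$truth$air_cell_ellipse$Lm / 2) *
    (res$truth$air_cell_ellipse$Ls / 2) / res$truth$egg_circle$r^2
  expect_lt(abs(l2$PS - ps_true) / ps_true, 0.05)
  expect_true(all(is.finite(unlist(l2[c("d", "theta", "PS", "PC", "CON",
                                        "ENT", "ASM")]))))
  expect_identical(extract_lambda2(frame, res$truth$mask), l2)

  no_cell <- res$truth$mask
  no_cell[no_cell == 2L] <- 1L
  expect_error(extract_lambda2(frame, no_cell), "no air-cell region")
})

test_that("rotating frame and mask by 90 degrees preserves the statistics", {
  sp <- small_scene(h = 6, alpha = 20, theta_c = 30, noise = 0)
  res <- render_thermal_video(sp)
  frame <- res$video$frames[[res$truth$peak_frame]]
  mask <- res$truth$mask
  rot90 <- function(m) t(m[rev(seq_len(nrow(m))), , drop = FALSE])
  frame_r <- array(0L, dim = c(dim(frame)[2], dim(frame)[1], 3))
  for (c3 in 1:3) frame_r[, , c3] <- rot90(frame[, , c3])
  l2 <- extract_lambda2(frame, mask)
  l2r <- extract_lambda2(frame_r, rot90(mask))
  for (col in c("d", "PS", "PC", "CON", "ENT", "ASM")) {
    expect_equal(l2r[[col]], l2[[col]], tolerance = 1e-9)
  }
  # centroid-line angle rotates by 90 degrees modulo the (-90, 90] range
  diff_theta <- (l2r$theta - l2$theta) %% 180
  expect_true(min(abs(diff_theta - 90), abs(diff_theta - 90 + 180)) < 1e-6)
})

test_that("best mask frame maximizes air-cell pixels near heating stop", {
  masks <- lapply(c(0, 5, 20, 35, 12, 3), function(n) {
    m <- matrix(0L, 10, 10)
    if (n > 0) m[seq_len(n)] <- 2L
    m
  })
  expect_equal(select_best_mask_frame(masks, heat_stop_index = 4, window = 2),
               4L)
  # window excludes the global maximum
  expect_equal(select_best_mask_frame(masks, heat_stop_index = 6, window = 1),
               5L)
  const <- rep(masks[3], 3)
  expect_equal(select_best_mask_frame(const, 2, window = 2), 1L)
  empty <- rep(list(matrix(0L, 4, 4)), 3)
  expect_error(select_best_mask_frame(empty, 2), "no air cell")
  expect_error(select_best_mask_frame(masks, heat_stop_index = 40,
                                      window = 2), "empty frame window")
})
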