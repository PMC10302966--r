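# shared fixtures and independent brute-force oracles

reference_egg <- function() egg_profile(28.435, 21.89, 10)

# small, fast rendering scene used across imaging tests
small_scene <- function(h = 6, alpha = 20, theta_c = 25, noise = 0, seed = 1,
                        n_pre = 3, n_heat = 10, n_cool = 6) {
  prof <- reference_egg()
  scene_params(prof,
               air_cell_state(R = blunt_crown_radius(prof), h = h,
                              alpha_deg = alpha),
               width = 220, height = 180, scale_px_mm = 2.4,
               theta_c_deg = theta_c, noise_sigma = noise,
               n_pre = n_pre, n_heat = n_heat, n_cool = n_cool, seed = seed)
}

# ---- exhaustive pixel-loop oracles (independent of the implementation) ------

oracle_centroid_area <- function(mask) {
  sx <- 0; sy <- 0; n <- 0
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (mask[i, j]) { sx <- sx + j; sy <- sy + i; n <- n + 1 }
  }
  list(x = sx / n, y = sy / n, area = n)
}

# marching-squares perimeter via base R contourLines (independent path)
oracle_perimeter <- function(mask) {
  n <- nrow(mask); m <- ncol(mask)
  pad <- matrix(0, n + 2, m + 2)
  pad[2:(n + 1), 2:(m + 1)] <- mask * 1
  cl <- grDevices::contourLines(x = seq_len(n + 2), y = seq_len(m + 2),
                                z = pad, levels = 0.5)
  sum(vapply(cl, function(seg) {
    sum(sqrt(diff(seg$x)^2 + diff(seg$y)^2))
  }, numeric(1)))
}

# pairwise-enumeration GLCM oracle
oracle_glcm <- function(gray, domain, levels, offsets, symmetric = TRUE) {
  rng <- range(gray[domain])
  q <- if (diff(rng) == 0) {
    matrix(1L, nrow(gray), ncol(gray))
  } else {
    matrix(pmax(1L, pmin(levels, 1L + floor((gray - rng[1]) / diff(rng) * levels))),
           nrow(gray), ncol(gray))
  }
  G <- matrix(0, levels, levels)
  for (off in offsets) {
    for (i in seq_len(nrow(gray))) for (j in seq_len(ncol(gray))) {
      i2 <- i + off[1]; j2 <- j + off[2]
      if (i2 < 1 || i2 > nrow(gray) || j2 < 1 || j2 > ncol(gray)) next
      if (!domain[i, j] || !domain[i2, j2]) next
      G[q[i, j], q[i2, j2]] <- G[q[i, j], q[i2, j2]] + 1
      if (symmetric) G[q[i2, j2], q[i, j]] <- G[q[i2, j2], q[i, j]] + 1
    }
  }
  G / sum(G)
}

# direct double-loop texture statistics
oracle_glcm_features <- function(G, log_base = 2) {
  L <- nrow(G)
  CON <- 0; ENT <- 0; ASM <- 0; Sij <- 0
  mu_i <- 0; mu_j <- 0
  for (i in 1:L) for (j in 1:L) {
    mu_i <- mu_i + i * G[i, j]
    mu_j <- mu_j + j * G[i, j]
  }
  v_i <- 0; v_j <- 0
  for (i in 1:L) for (j in 1:L) {
    CON <- CON + (i - j)^2 * G[i, j]
    ASM <- ASM + G[i, j]^2
    if (G[i, j] > 0) ENT <- ENT - G[i, j] * log(G[i, j], base = log_base)
    Sij <- Sij + i * j * G[i, j]
    v_i <- v_i + G[i, j] * (i - mu_i)^2
    v_j <- v_j + G[i, j] * (j - mu_j)^2
  }
  COR <- if (v_i == 0 || v_j == 0) NA_real_ else
    (Sij - mu_i * mu_j) / sqrt(v_i * v_j)
  list(CON = CON, COR = COR, ENT = ENT, ASM = ASM)
}

# stack-based flood-fill component labeling oracle
oracle_components <- function(mask, connectivity = 8) {
  n <- nrow(mask); m <- ncol(mask)
  lab <- matrix(0L, n, m)
  cur <- 0L
  nbrs <- if (connectivity == 8) {
    rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
          c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  } else {
    rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  }
  for (i0 in seq_len(n)) for (j0 in seq_len(m)) {
    if (!mask[i0, j0] || lab[i0, j0] > 0L) next
    cur <- cur + 1L
    stack <- list(c(i0, j0))
    lab[i0, j0] <- cur
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (r in seq_len(nrow(nbrs))) {
        ii <- p[1] + nbrs[r, 1]; jj <- p[2] + nbrs[r, 2]
        if (ii >= 1 && ii <= n && jj >= 1 && jj <= m &&
              mask[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- cur
          stack[[length(stack) + 1]] <- c(ii, jj)
        }
      }
    }
  }
  lab
}

# random valid air-cell state for property tests
random_air_cell <- function() {
  R <- runif(1, 18, 35)
  h <- runif(1, 0.5, 0.4 * R)
  alpha <- runif(1, 1, 60)
  air_cell_state(R = R, h = h, alpha_deg = alpha)
}
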