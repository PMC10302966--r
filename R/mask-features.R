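# ---- lambda-2 route: connected-domain geometry + GLCM texture --------------
# Label masks are integer matrices with 0 = background, 1 = eggshell,
# 2 = egg air cell. The "egg domain" is the union of labels 1 and 2.

.mask_region <- function(mask, label) {
  if (identical(label, "egg")) {
    mask == 1L | mask == 2L
  } else if (identical(label, "air_cell")) {
    mask == 2L
  } else {
    mask == as.integer(label)
  }
}

#' Marching-squares perimeter of a logical mask
#'
#' Sums the iso-contour segment lengths of the 0.5-level marching-squares
#' cases over all 2x2 pixel blocks (mask padded with background). A single
#' isolated pixel has perimeter `4 * sqrt(2) / 2 = 2.8284`.
#'
#' @param mask Logical matrix.
#' @return Perimeter length in px.
#' @export
perimeter_marching_squares <- function(mask) {
  stopifnot(is.matrix(mask))
  n <- nrow(mask); m <- ncol(mask)
  pad <- matrix(FALSE, n + 2, m + 2)
  pad[2:(n + 1), 2:(m + 1)] <- mask
  tl <- pad[1:(n + 1), 1:(m + 1)]
  tr <- pad[1:(n + 1), 2:(m + 2)]
  bl <- pad[2:(n + 2), 1:(m + 1)]
  br <- pad[2:(n + 2), 2:(m + 2)]
  case <- tl + 2L * tr + 4L * bl + 8L * br
  half_diag <- sqrt(2) / 2
  # per-case contour length: corners cut one half-diagonal, edges pass
  # straight through (length 1), both diagonals for the saddle cases
  len <- c(0, half_diag, half_diag, 1, half_diag, 1, 2 * half_diag, half_diag,
           half_diag, 2 * half_diag, 1, half_diag, 1, half_diag, half_diag, 0)
  sum(len[case + 1L])
}

#' Geometry of a labeled connected domain
#'
#' Finds the largest 8-connected component carrying the requested label and
#' returns its centroid (mean pixel coordinate), pixel-count area and
#' marching-squares perimeter.
#'
#' @param mask Integer label mask (0 background, 1 eggshell, 2 air cell).
#' @param label `"egg"` (union of labels 1 and 2), `"air_cell"`, or an
#'   integer label value.
#' @return One-row tibble of class `region_props`: `x`, `y`, `area`,
#'   `perimeter`.
#' @export
region_props <- function(mask, label) {
  stopifnot(is.matrix(mask))
  sel <- .mask_region(mask, label)
  if (!any(sel)) abort(sprintf("no region with label '%s'", paste(label)))
  comp <- largest_component(sel, connectivity = 8)
  idx <- which(comp, arr.ind = TRUE)
  out <- tibble(
    x = mean(idx[, 2]), y = mean(idx[, 1]),
    area = nrow(idx),
    perimeter = perimeter_marching_squares(comp)
  )
  class(out) <- c("region_props", class(out))
  out
}

#' Relative geometry of the egg and air-cell domains
#'
#' Center-of-gravity distance `d`, the angle `theta` of the centroid line
#' to the image horizontal (two-argument arctangent reduced to
#' (-90, 90] degrees; 0 by convention for coincident centroids), the area
#' ratio `PS = S_cell / S_egg` and perimeter ratio `PC = C_cell / C_egg`.
#'
#' @param egg,cell [region_props()] rows for the egg and air-cell domains.
#' @return One-row tibble: `d`, `theta`, `PS`, `PC`.
#' @export
pair_geometry <- function(egg, cell) {
  stopifnot(is.data.frame(egg), is.data.frame(cell))
  dx <- egg$x - cell$x
  dy <- egg$y - cell$y
  d <- sqrt(dx^2 + dy^2)
  if (d == 0) {
    theta <- 0
  } else {
    theta <- atan2(dy, dx) * 180 / pi
    if (theta <= -90) theta <- theta + 180
    if (theta > 90) theta <- theta - 180
  }
  tibble(d = d, theta = theta,
         PS = cell$area / egg$area,
         PC = cell$perimeter / egg$perimeter)
}

#' Normalized gray-level co-occurrence matrix
#'
#' Counts gray-level pairs at the given pixel offsets over the domain
#' pixels (both pixels of a pair must lie in the domain), optionally
#' symmetrized and averaged over offsets, and normalizes the result to
#' sum 1. Intensities are quantized uniformly into `levels` bins over the
#' domain intensity range (a constant domain maps to level 1).
#'
#' @param gray Numeric matrix of intensities.
#' @param domain Logical matrix restricting the computation (default: all).
#' @param levels Number of gray levels (>= 2).
#' @param offsets List of `(drow, dcol)` integer offsets; the default is
#'   distance 1 at 0, 45, 90 and 135 degrees.
#' @param symmetric Count each pair in both directions.
#' @param average Average the per-offset matrices (otherwise they are
#'   summed before normalization, which yields the same matrix).
#' @return `levels x levels` matrix summing to 1.
#' @export
glcm <- function(gray, domain = NULL, levels = 8,
                 offsets = list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L)),
                 symmetric = TRUE, average = TRUE) {
  stopifnot(is.matrix(gray), levels >= 2)
  if (is.null(domain)) domain <- matrix(TRUE, nrow(gray), ncol(gray))
  stopifnot(identical(dim(domain), dim(gray)))
  if (!any(domain)) abort("empty domain")
  rng <- range(gray[domain])
  if (diff(rng) == 0) {
    q <- matrix(1L, nrow(gray), ncol(gray))
  } else {
    q <- matrix(pmin(levels, 1L + floor((gray - rng[1]) / diff(rng) * levels)),
                nrow(gray), ncol(gray))
    q[q < 1L] <- 1L
  }
  n <- nrow(gray); m <- ncol(gray)
  G <- matrix(0, levels, levels)
  n_pairs <- 0
  for (off in offsets) {
    di <- off[1]; dj <- off[2]
    if (di == 0 && dj == 0) abort("offset must be nonzero")
    lo_i <- max(1, 1 - di); hi_i <- min(n, n - di)
    lo_j <- max(1, 1 - dj); hi_j <- min(m, m - dj)
    if (lo_i > hi_i || lo_j > hi_j) next
    src_i <- lo_i:hi_i
    src_j <- lo_j:hi_j
    d1 <- domain[src_i, src_j, drop = FALSE] &
      domain[src_i + di, src_j + dj, drop = FALSE]
    if (!any(d1)) next
    g1 <- q[src_i, src_j, drop = FALSE][d1]
    g2 <- q[src_i + di, src_j + dj, drop = FALSE][d1]
    inc <- matrix(0, levels, levels)
    tb <- table(factor(g1, levels = 1:levels), factor(g2, levels = 1:levels))
    inc <- inc + as.matrix(tb)
    if (symmetric) inc <- inc + t(inc)
    G <- G + inc
    n_pairs <- n_pairs + sum(inc)
  }
  if (n_pairs == 0) abort("no valid pixel pair for the GLCM")
  G / sum(G)
}

#' Texture features of a normalized co-occurrence matrix
#'
#' Contrast `CON = sum (i-j)^2 G(i,j)`, correlation
#' `COR = (sum ij G(i,j) - mu_i mu_j) / (S_i S_j)`, entropy
#' `ENT = -sum G log G` (with `0 log 0 = 0`) and angular second moment
#' `ASM = sum G^2`, where `mu` and `S` are the marginal means and standard
#' deviations of `G`. `COR` is `NA` with attribute `cor_defined = FALSE`
#' when a marginal variance vanishes.
#'
#' @param G Normalized co-occurrence matrix (sums to 1).
#' @param log_base Base of the entropy logarithm (default 2).
#' @return One-row tibble of class `glcm_features`: `CON`, `COR`, `ENT`,
#'   `ASM`.
#' @export
glcm_features <- function(G, log_base = 2) {
  stopifnot(is.matrix(G), nrow(G) == ncol(G))
  if (abs(sum(G) - 1) > 1e-8) abort("G must be normalized to sum 1")
  L <- nrow(G)
  i <- matrix(1:L, L, L)
  j <- t(i)
  CON <- sum((i - j)^2 * G)
  mu_i <- sum(i * G)
  mu_j <- sum(j * G)
  S_i <- sqrt(sum(G * (i - mu_i)^2))
  S_j <- sqrt(sum(G * (j - mu_j)^2))
  if (S_i == 0 || S_j == 0) {
    COR <- NA_real_
    cor_defined <- FALSE
  } else {
    COR <- (sum(i * j * G) - mu_i * mu_j) / (S_i * S_j)
    cor_defined <- TRUE
  }
  lg <- ifelse(G > 0, log(G, base = log_base), 0)
  ENT <- -sum(G * lg)
  ASM <- sum(G^2)
  out <- tibble(CON = CON, COR = COR, ENT = ENT, ASM = ASM)
  attr(out, "cor_defined") <- cor_defined
  class(out) <- c("glcm_features", class(out))
  out
}

#' Extract the 8-value mask-route feature vector
#'
#' Composes [region_props()], [pair_geometry()] and [glcm_features()] on a
#' 3-class label mask and the luminance of the matching frame, producing
#' `[d, theta, PS, PC, CON, COR, ENT, ASM]`. The texture features are
#' computed over the egg domain only.
#'
#' @param frame `H x W x 3` array (8-bit RGB) or a grayscale matrix.
#' @param mask Integer label mask (0 background, 1 eggshell, 2 air cell).
#' @param levels GLCM gray levels.
#' @param log_base Entropy log base.
#' @return One-row tibble with the eight features.
#' @export
extract_lambda2 <- function(frame, mask, levels = 8, log_base = 2) {
  stopifnot(is.matrix(mask))
  if (length(dim(frame)) == 3) {
    gray <- 0.299 * frame[, , 1] + 0.587 * frame[, , 2] + 0.114 * frame[, , 3]
  } else {
    gray <- frame
  }
  stopifnot(identical(dim(gray), dim(mask)))
  if (!any(mask == 2L)) abort("mask has no air-cell region")
  if (!any(mask == 1L | mask == 2L)) abort("mask has no egg region")
  egg <- region_props(mask, "egg")
  cellp <- region_props(mask, "air_cell")
  geom <- pair_geometry(egg, cellp)
  egg_domain <- largest_component(.mask_region(mask, "egg"), 8)
  tex <- glcm_features(glcm(gray, domain = egg_domain, levels = levels),
                       log_base = log_base)
  tibble(d = geom$d, theta = geom$theta, PS = geom$PS, PC = geom$PC,
         CON = tex$CON, COR = tex$COR, ENT = tex$ENT, ASM = tex$ASM)
}

#' Select the best mask frame around the heating stop
#'
#' Within a window of `window` frames before and after the heating-stop
#' index, returns the index of the mask with the largest air-cell pixel
#' count (ties resolve to the earliest frame).
#'
#' @param masks List of label masks, one per frame.
#' @param heat_stop_index Index of the last heated frame.
#' @param window Half-width of the search window in frames (default 50).
#' @return Integer frame index (into `masks`).
#' @export
select_best_mask_frame <- function(masks, heat_stop_index, window = 50) {
  stopifnot(is.list(masks), length(masks) >= 1)
  lo <- max(1L, heat_stop_index - window)
  hi <- min(length(masks), heat_stop_index + window)
  if (lo > hi) abort("empty frame window")
  counts <- vapply(masks[lo:hi], function(m) sum(m == 2L), numeric(1))
  if (all(counts == 0)) abort("no air cell present in the frame window")
  lo + which.max(counts) - 1L
}
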