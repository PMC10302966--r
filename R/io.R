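# ---- file formats -----------------------------------------------------------
# Frames: 8-bit RGB PNG (frame_0001.png, ...). Masks: 8-bit grayscale PNG
# holding the literal label values 0/1/2. Features/probes: CSV with fixed
# headers; numeric values are written with 17 significant digits so a
# write -> read cycle reproduces the doubles bit-identically.

#' Write a thermal video as numbered PNG frames
#'
#' @param video A [thermal_video()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_thermal_video <- function(video, dir) {
  stopifnot(inherits(video, "thermal_video"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(seq_along(video$frames), function(f) {
    p <- file.path(dir, sprintf("frame_%04d.png", f))
    png::writePNG(video$frames[[f]] / 255, p)
    p
  }, character(1))
  meta <- list(frame_period_s = video$frame_period_s,
               heat_stop_index = video$heat_stop_index)
  yaml::write_yaml(meta, file.path(dir, "video.yaml"))
  invisible(paths)
}

#' Read a thermal video from a directory of PNG frames
#'
#' @param dir Directory with `frame_*.png` files (and optionally a
#'   `video.yaml` with `frame_period_s` / `heat_stop_index`).
#' @param frame_period_s,heat_stop_index Overrides for the metadata.
#' @return A [thermal_video()].
#' @export
read_thermal_video <- function(dir, frame_period_s = NULL,
                               heat_stop_index = NULL) {
  if (!dir.exists(dir)) abort(sprintf("no such directory: %s", dir))
  files <- sort(list.files(dir, pattern = "^frame_.*\\.png$", full.names = TRUE))
  if (length(files) == 0) abort(sprintf("no frame_*.png files in %s", dir))
  frames <- lapply(files, function(p) {
    a <- png::readPNG(p)
    if (length(dim(a)) == 2) a <- array(rep(a, 3), dim = c(dim(a), 3))
    a <- a[, , 1:3, drop = FALSE] * 255
    storage.mode(a) <- "integer"
    a
  })
  meta_path <- file.path(dir, "video.yaml")
  meta <- if (file.exists(meta_path)) yaml::read_yaml(meta_path) else list()
  thermal_video(
    frames,
    frame_period_s = frame_period_s %||% meta$frame_period_s %||% 0.1,
    heat_stop_index = heat_stop_index %||% meta$heat_stop_index
  )
}

#' Write / read a 3-class label mask as grayscale PNG
#'
#' The PNG stores the literal label values (0 background, 1 eggshell,
#' 2 egg air cell) in an 8-bit gray channel, so labels round-trip exactly.
#'
#' @param mask Integer matrix with values 0/1/2.
#' @param path PNG path.
#' @return `write_label_mask`: the path, invisibly. `read_label_mask`: the
#'   integer label matrix.
#' @export
write_label_mask <- function(mask, path) {
  stopifnot(is.matrix(mask), all(mask %in% 0:2))
  png::writePNG(mask / 255, path)
  invisible(path)
}

#' @rdname write_label_mask
#' @export
read_label_mask <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  m <- matrix(as.integer(round(a * 255)), nrow(a), ncol(a))
  if (!all(m %in% 0:2)) abort("mask PNG contains values other than 0/1/2")
  m
}

#' Write / read a feature table as CSV
#'
#' Numeric columns are serialized with 17 significant digits so that the
#' doubles round-trip bit-identically.
#'
#' @param data Data frame.
#' @param path CSV path.
#' @return `write_features`: the path, invisibly. `read_features`: a
#'   tibble.
#' @export
write_features <- function(data, path) {
  stopifnot(is.data.frame(data))
  out <- data
  for (cl in names(out)) {
    if (is.numeric(out[[cl]]) && !is.integer(out[[cl]])) {
      out[[cl]] <- sprintf("%.17g", out[[cl]])
    }
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (cl in names(df)) {
    if (is.character(df[[cl]]) && all(grepl("^[-+0-9.eE]+$", df[[cl]]))) {
      df[[cl]] <- as.numeric(df[[cl]])
    }
  }
  as_tibble(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- YAML run configuration -------------------------------------------------

.config_schema <- list(
  egg = c("a_mm", "b_mm", "theta_deg"),
  aircell = c("h_mm", "alpha_deg"),
  scene = c("width", "height", "scale_px_mm", "theta_c_deg", "noise_sigma",
            "halo_px", "n_pre", "n_heat", "n_cool", "frame_period_s", "seed"),
  sim = c("T_init", "T_air", "h_jet", "jet_cap_deg", "h_ambient", "T_ambient",
          "dt", "duration", "snap_dt", "resolution"),
  model = c("model", "knn_k", "rf_trees", "rf_min_leaf", "svm_cost",
            "svm_gamma", "svm_kernel", "seed")
)

#' Read and validate a YAML run configuration
#'
#' Accepts the blocks `egg`, `aircell`, `scene`, `sim` and `model`;
#' unknown blocks or keys are rejected before any computation.
#'
#' @param path YAML file path.
#' @return Validated named list with attribute `hash` (content hash used
#'   for provenance).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) abort("config must be a YAML mapping")
  bad_blocks <- setdiff(names(cfg), names(.config_schema))
  if (length(bad_blocks)) {
    abort(sprintf("unknown config block(s): %s", paste(bad_blocks, collapse = ", ")))
  }
  for (bl in names(cfg)) {
    bad <- setdiff(names(cfg[[bl]]), .config_schema[[bl]])
    if (length(bad)) {
      abort(sprintf("unknown key(s) in '%s': %s", bl, paste(bad, collapse = ", ")))
    }
  }
  attr(cfg, "hash") <- rlang::hash(cfg)
  cfg
}

# scene/sim objects from a validated config, with package defaults
.config_profile <- function(cfg) {
  e <- cfg$egg %||% list()
  egg_profile(e$a_mm %||% 28.435, e$b_mm %||% 21.89, e$theta_deg %||% 10)
}

.config_cell <- function(cfg, profile) {
  a <- cfg$aircell %||% list()
  air_cell_state(R = blunt_crown_radius(profile), h = a$h_mm %||% 6,
                 alpha_deg = a$alpha_deg %||% 0)
}

.config_scene <- function(cfg) {
  profile <- .config_profile(cfg)
  cell <- .config_cell(cfg, profile)
  s <- cfg$scene %||% list()
  args <- list(profile = profile, cell = cell)
  for (k in names(s)) args[[k]] <- s[[k]]
  do.call(scene_params, args)
}

.config_sim <- function(cfg) {
  s <- cfg$sim %||% list()
  args <- s[setdiff(names(s), "resolution")]
  list(cfg = do.call(sim_config, args), resolution = s$resolution %||% 0.5)
}

.config_model <- function(cfg) {
  do.call(model_config, cfg$model %||% list())
}
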