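#' Render tracks into a synthetic fluorescence movie
#'
#' Each frame is `background + sum of spots + Poisson shot noise`, where a
#' spot is a pixel-integrated 2-D Gaussian of width `psf_sigma` whose
#' integrated photon count equals the track's intensity in that frame.
#' Pixel centres sit at integer pixel coordinates, origin at the image
#' corner; positions convert as `um = px * pixel_size`.
#'
#' Track coordinates are taken relative to the cell centre and shifted to
#' the centre of the field of view; the shifted ground truth (in field-of-
#' view micrometres, directly comparable to [detect_spots()] output) is
#' stored in the returned stack. Spots approaching within one `psf_sigma`
#' of another spot in the same frame are allowed but flagged
#' (`overlap_flag`) in the ground truth.
#'
#' @param tracks Tidy multi-track data frame ([generate_tracks()] format);
#'   all tracks must cover the same frames.
#' @param config A [sim_config()] supplying `pixel_size`, `psf_sigma`,
#'   `background`, `frame_interval` and the cell geometry used for the
#'   default field of view.
#' @param fov_um Optional length-2 field of view (width, height) in um;
#'   default fits the cell plus a margin.
#' @param noise If `FALSE`, frames are the noiseless expectation (useful
#'   for localization-accuracy oracles).
#' @param seed Optional seed for the shot noise (default: current RNG).
#' @return An `image_stack` list: `frames` (list of matrices, rows = y),
#'   `pixel_size`, `frame_interval`, `fov_um`, `ground_truth`.
#' @export
render_movie <- function(tracks, config, fov_um = NULL, noise = TRUE, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  px <- config$pixel_size
  if (is.null(fov_um)) {
    margin <- 0.5 + 3 * config$psf_sigma
    fov_um <- c(config$cell_length + 2 * margin,
                2 * config$cell_radius + 2 * margin)
  }
  nx <- ceiling(fov_um[1] / px)
  ny <- ceiling(fov_um[2] / px)
  frames_idx <- sort(unique(tracks$frame))
  gt <- tracks
  gt$x_um <- gt$x_um + nx * px / 2
  gt$y_um <- gt$y_um + ny * px / 2
  live <- !gt$gap_flag & is.finite(gt$x_um) & is.finite(gt$y_um)
  if (any(live & (gt$x_um < 0 | gt$x_um > nx * px | gt$y_um < 0 | gt$y_um > ny * px))) {
    stop("track positions fall outside the field of view; enlarge `fov_um`",
         call. = FALSE)
  }
  s_px <- config$psf_sigma / px
  half <- ceiling(5 * s_px)
  gt$overlap_flag <- FALSE
  frames <- vector("list", length(frames_idx))
  for (fi in seq_along(frames_idx)) {
    f <- frames_idx[fi]
    img <- matrix(config$background, nrow = ny, ncol = nx)
    rows <- which(gt$frame == f & live)
    if (length(rows) > 1) {
      xy <- cbind(gt$x_um[rows], gt$y_um[rows])
      d <- as.matrix(stats::dist(xy))
      diag(d) <- Inf
      gt$overlap_flag[rows[apply(d, 1, min) < config$psf_sigma]] <- TRUE
    }
    for (r in rows) {
      x0 <- gt$x_um[r] / px
      y0 <- gt$y_um[r] / px
      jj <- max(1, floor(x0 - half)):min(nx, ceiling(x0 + half))
      ii <- max(1, floor(y0 - half)):min(ny, ceiling(y0 + half))
      gx <- stats::pnorm((jj + 0.5 - x0) / s_px) - stats::pnorm((jj - 0.5 - x0) / s_px)
      gy <- stats::pnorm((ii + 0.5 - y0) / s_px) - stats::pnorm((ii - 0.5 - y0) / s_px)
      img[ii, jj] <- img[ii, jj] + gt$intensity[r] * (gy %o% gx)
    }
    frames[[fi]] <- img
  }
  if (noise) {
    draw <- function() {
      lapply(frames, function(img) {
        matrix(stats::rpois(length(img), img), nrow = nrow(img))
      })
    }
    frames <- if (is.null(seed)) draw() else with_seed(seed, draw())
  }
  structure(list(frames = frames, pixel_size = px,
                 frame_interval = config$frame_interval,
                 fov_um = c(nx, ny) * px, ground_truth = gt),
            class = "image_stack")
}

#' Write an image stack as a 16-bit multi-page TIFF with sidecar metadata
#'
#' Produces `<prefix>.tif` (one page per frame), `<prefix>.json` (pixel
#' size, frame interval, provenance labels) and `<prefix>_truth.csv`
#' (ground-truth track table) alongside each other.
#'
#' @param stack An `image_stack` from [render_movie()].
#' @param prefix Output path prefix (no extension).
#' @param metadata Optional named list merged into the JSON sidecar
#'   (e.g. condition, replicate, treatment_time).
#' @return Invisibly, the paths written.
#' @export
write_image_stack <- function(stack, prefix, metadata = list()) {
  stopifnot(inherits(stack, "image_stack"))
  vmax <- 65535
  pages <- lapply(stack$frames, function(img) {
    pmin(pmax(round(img), 0), vmax) / vmax
  })
  tif <- paste0(prefix, ".tif")
  jsn <- paste0(prefix, ".json")
  csv <- paste0(prefix, "_truth.csv")
  tiff::writeTIFF(pages, tif, bits.per.sample = 16L, compression = "none")
  meta <- c(list(pixel_size_um = stack$pixel_size,
                 frame_interval_s = stack$frame_interval,
                 n_frames = length(stack$frames),
                 fov_um = stack$fov_um), metadata)
  jsonlite::write_json(meta, jsn, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  gt <- stack$ground_truth
  utils::write.csv(
    data.frame(track_id = gt$track_id, frame = gt$frame,
               x_um = gt$x_um, y_um = gt$y_um, intensity = gt$intensity),
    csv, row.names = FALSE)
  invisible(c(tif = tif, json = jsn, truth = csv))
}

#' Read an image stack written by [write_image_stack()]
#'
#' @param prefix Path prefix used when writing.
#' @return An `image_stack` (ground truth included when the truth CSV is
#'   present).
#' @export
read_image_stack <- function(prefix) {
  pages <- tiff::readTIFF(paste0(prefix, ".tif"), all = TRUE)
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  frames <- lapply(pages, function(p) round(p * 65535))
  truth_path <- paste0(prefix, "_truth.csv")
  gt <- if (file.exists(truth_path)) utils::read.csv(truth_path) else NULL
  structure(list(frames = frames, pixel_size = meta$pixel_size_um,
                 frame_interval = meta$frame_interval_s,
                 fov_um = meta$fov_um, ground_truth = gt, metadata = meta),
            class = "image_stack")
}
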