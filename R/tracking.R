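#' Detect point-like fluorescent spots in a single frame
#'
#' Candidate pixels come from a difference-of-Gaussians band-pass response
#' at the point-spread-function scale; a candidate is kept if it is a local
#' maximum whose signal-to-noise ratio (smoothed amplitude above the frame
#' median, over the robust noise scale of the smoothed frame) reaches
#' `snr_threshold`. Positions are then refined to subpixel precision by a
#' least-squares fit of a pixel-integrated 2-D Gaussian (free position,
#' integrated intensity, background and width) in a window of about
#' `3 * psf_sigma_px` around the peak. Windows containing saturated pixels
#' are flagged and fall back to an intensity-weighted centroid.
#'
#' Pixel centres are at integer coordinates with origin at the image
#' corner; reported positions are `um = px * pixel_size`.
#'
#' @param frame Numeric matrix of photon counts (rows = y).
#' @param psf_sigma_px Spot width in pixels (> 0.5).
#' @param snr_threshold Minimum SNR (default 5).
#' @param pixel_size um per pixel used to convert positions (default 1).
#' @param saturation_level Pixel value treated as saturated (default Inf).
#' @return Data frame of detections: `x_um`, `y_um`, `x_px`, `y_px`,
#'   `intensity` (integrated photons above background), `snr`, `saturated`.
#'   Zero rows when nothing passes.
#' @export
detect_spots <- function(frame, psf_sigma_px, snr_threshold = 5,
                         pixel_size = 1, saturation_level = Inf) {
  stopifnot(is.matrix(frame), nrow(frame) > 0, ncol(frame) > 0)
  assert_scalar_num(psf_sigma_px, "psf_sigma_px", 0.5, strict_lower = TRUE)
  empty <- data.frame(x_um = numeric(0), y_um = numeric(0),
                      x_px = numeric(0), y_px = numeric(0),
                      intensity = numeric(0), snr = numeric(0),
                      saturated = logical(0))
  if (nrow(frame) < 5 || ncol(frame) < 5) return(empty)
  bg <- stats::median(frame)
  sm <- EBImage::gblur(frame, sigma = psf_sigma_px)
  dog <- sm - EBImage::gblur(frame, sigma = 1.6 * psf_sigma_px)
  noise_sm <- stats::mad(sm)
  if (noise_sm <= 0) noise_sm <- stats::sd(sm)
  if (!is.finite(noise_sm) || noise_sm <= 0) noise_sm <- 1e-12
  cand <- local_maxima(dog)
  if (nrow(cand) == 0) return(empty)
  snr <- (sm[cand] - stats::median(sm)) / noise_sm
  keep <- snr >= snr_threshold
  cand <- cand[keep, , drop = FALSE]
  snr <- snr[keep]
  if (nrow(cand) == 0) return(empty)

  half <- max(3L, as.integer(ceiling(3 * psf_sigma_px)))
  dets <- vector("list", nrow(cand))
  for (k in seq_len(nrow(cand))) {
    pi_ <- cand[k, 1]; pj <- cand[k, 2]
    ii <- max(1, pi_ - half):min(nrow(frame), pi_ + half)
    jj <- max(1, pj - half):min(ncol(frame), pj + half)
    win <- frame[ii, jj, drop = FALSE]
    sat <- any(win >= saturation_level)
    if (sat) {
      ctr <- weighted_centroid(win, ii, jj, bg)
      dets[[k]] <- data.frame(x_px = ctr["x"], y_px = ctr["y"],
                              intensity = ctr["mass"], snr = snr[k],
                              saturated = TRUE)
    } else {
      fit <- fit_gaussian_spot(win, ii, jj, psf_sigma_px, bg)
      dets[[k]] <- data.frame(x_px = fit$x, y_px = fit$y,
                              intensity = fit$intensity, snr = snr[k],
                              saturated = FALSE)
    }
  }
  out <- do.call(rbind, dets)
  out <- out[is.finite(out$x_px) & is.finite(out$y_px) & out$intensity > 0, ,
             drop = FALSE]
  # collapse duplicate maxima of the same spot (within one PSF width)
  if (nrow(out) > 1) {
    ord <- order(-out$snr)
    out <- out[ord, , drop = FALSE]
    kept <- rep(TRUE, nrow(out))
    for (a in seq_len(nrow(out) - 1)) {
      if (!kept[a]) next
      later <- (a + 1):nrow(out)
      d <- sqrt((out$x_px[later] - out$x_px[a])^2 + (out$y_px[later] - out$y_px[a])^2)
      kept[later[d < psf_sigma_px]] <- FALSE
    }
    out <- out[kept, , drop = FALSE]
  }
  rownames(out) <- NULL
  data.frame(x_um = out$x_px * pixel_size, y_um = out$y_px * pixel_size,
             out, stringsAsFactors = FALSE)
}

# Strict-on-one-side 8-neighbour local maxima; deterministic on plateaus.
local_maxima <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  if (nr < 3 || nc < 3) return(cbind(integer(0), integer(0)))
  c0 <- m[2:(nr - 1), 2:(nc - 1)]
  ok <- c0 >= m[1:(nr - 2), 2:(nc - 1)] &  # N
    c0 >= m[1:(nr - 2), 1:(nc - 2)] &      # NW
    c0 >= m[2:(nr - 1), 1:(nc - 2)] &      # W
    c0 >= m[3:nr,       1:(nc - 2)] &      # SW
    c0 >  m[3:nr,       2:(nc - 1)] &      # S
    c0 >  m[3:nr,       3:nc] &            # SE
    c0 >  m[2:(nr - 1), 3:nc] &            # E
    c0 >  m[1:(nr - 2), 3:nc]              # NE
  idx <- which(ok, arr.ind = TRUE)
  cbind(idx[, 1] + 1L, idx[, 2] + 1L)
}

weighted_centroid <- function(win, ii, jj, bg) {
  w <- pmax(win - bg, 0)
  tot <- sum(w)
  if (tot <= 0) return(c(x = NA_real_, y = NA_real_, mass = 0))
  c(x = sum(t(w) * jj) / tot, y = sum(w * ii) / tot, mass = tot)
}

# Least-squares pixel-integrated Gaussian: value(i, j) =
#   b + I * [Phi((j+.5-x0)/s) - Phi((j-.5-x0)/s)] * [same in y].
fit_gaussian_spot <- function(win, ii, jj, psf_sigma_px, bg) {
  ctr <- weighted_centroid(win, ii, jj, bg)
  if (!is.finite(ctr["x"])) return(list(x = NA_real_, y = NA_real_, intensity = 0))
  par0 <- c(x = unname(ctr["x"]), y = unname(ctr["y"]),
            logI = log(max(ctr["mass"], 1e-6)), b = bg,
            logs = log(psf_sigma_px))
  sse <- function(p) {
    s <- exp(p[5])
    gx <- stats::pnorm((jj + 0.5 - p[1]) / s) - stats::pnorm((jj - 0.5 - p[1]) / s)
    gy <- stats::pnorm((ii + 0.5 - p[2]) / s) - stats::pnorm((ii - 0.5 - p[2]) / s)
    model <- p[4] + exp(p[3]) * (gy %o% gx)
    sum((win - model)^2)
  }
  opt <- stats::optim(par0, sse, method = "BFGS",
                      control = list(maxit = 300, reltol = 1e-12))
  # polish with Nelder-Mead in case BFGS stalled on a flat valley
  opt <- stats::optim(opt$par, sse, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-12))
  list(x = unname(opt$par[1]), y = unname(opt$par[2]),
       intensity = unname(exp(opt$par[3])))
}

#' Detect spots in every frame of an image stack
#'
#' @param stack An `image_stack`.
#' @param psf_sigma_px Spot scale in pixels; default derived from the
#'   stack's metadata when rendered by [render_movie()] is not available,
#'   so normally supply it.
#' @param ... Passed to [detect_spots()].
#' @return Data frame of detections with a `frame` column (frames indexed
#'   as in the stack's ground truth, starting at 0).
#' @export
detect_movie <- function(stack, psf_sigma_px, ...) {
  stopifnot(inherits(stack, "image_stack"))
  res <- lapply(seq_along(stack$frames), function(fi) {
    d <- detect_spots(stack$frames[[fi]], psf_sigma_px,
                      pixel_size = stack$pixel_size, ...)
    if (nrow(d) > 0) data.frame(frame = fi - 1L, d) else NULL
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(frame = integer(0), x_um = numeric(0), y_um = numeric(0),
                      x_px = numeric(0), y_px = numeric(0),
                      intensity = numeric(0), snr = numeric(0),
                      saturated = logical(0))
  }
  attr(out, "frame_interval") <- stack$frame_interval
  out
}

#' Link per-frame detections into trajectories
#'
#' Frame-to-frame greedy nearest-neighbour assignment: candidate pairs
#' between open tracks and current detections are sorted by distance
#' (ties broken deterministically by lower detection then track index) and
#' accepted in order, subject to a hard displacement gate `max_disp_um`;
#' each detection joins at most one track. A track left unmatched stays
#' open for up to `max_gap_frames` frames; bridged gap frames appear in the
#' output flagged as missing (`gap_flag = TRUE`, `NA` positions) and are
#' excluded from MSD pairs downstream. Unmatched detections seed new
#' tracks. Greedy matching is effectively optimal for the sparse spot
#' densities this package targets (a few markers per cell).
#'
#' @param detections Data frame with columns `frame`, `x_um`, `y_um`,
#'   `intensity` ([detect_movie()] output).
#' @param max_disp_um Maximum frame-to-frame displacement, um.
#' @param max_gap_frames Maximum bridgeable gap, frames (default 0).
#' @param frame_interval Seconds per frame; default taken from the
#'   `frame_interval` attribute of `detections`.
#' @return Tidy multi-track data frame (`track_id`, `frame`, `time_s`,
#'   `x_um`, `y_um`, `intensity`, `gap_flag`).
#' @export
link_detections <- function(detections, max_disp_um, max_gap_frames = 0L,
                            frame_interval = NULL) {
  assert_scalar_num(max_disp_um, "max_disp_um", 0, strict_lower = TRUE)
  max_gap_frames <- assert_count(max_gap_frames, "max_gap_frames", min = 0L)
  if (is.null(frame_interval)) frame_interval <- attr(detections, "frame_interval")
  if (is.null(frame_interval)) stop("`frame_interval` must be supplied", call. = FALSE)
  det <- detections[order(detections$frame), , drop = FALSE]
  tracks <- list()   # each: list(rows = data.frame, last_x, last_y, last_frame, open)
  frames <- sort(unique(det$frame))
  for (f in frames) {
    d <- det[det$frame == f, , drop = FALSE]
    nd <- nrow(d)
    open_idx <- which(vapply(tracks, function(tr) {
      tr$open && (f - tr$last_frame) <= (max_gap_frames + 1L) && tr$last_frame < f
    }, logical(1)))
    assigned_det <- rep(FALSE, nd)
    if (length(open_idx) > 0 && nd > 0) {
      pairs <- expand.grid(ti = seq_along(open_idx), di = seq_len(nd))
      pairs$dist <- sqrt(
        (vapply(open_idx[pairs$ti], function(i) tracks[[i]]$last_x, numeric(1)) - d$x_um[pairs$di])^2 +
        (vapply(open_idx[pairs$ti], function(i) tracks[[i]]$last_y, numeric(1)) - d$y_um[pairs$di])^2)
      pairs <- pairs[pairs$dist <= max_disp_um, , drop = FALSE]
      pairs <- pairs[order(pairs$dist, pairs$di, pairs$ti), , drop = FALSE]
      used_tr <- rep(FALSE, length(open_idx))
      for (r in seq_len(nrow(pairs))) {
        ti <- pairs$ti[r]; di <- pairs$di[r]
        if (used_tr[ti] || assigned_det[di]) next
        used_tr[ti] <- TRUE
        assigned_det[di] <- TRUE
        i <- open_idx[ti]
        gap <- tracks[[i]]$last_frame + 1L
        if (gap < f) {
          gaps <- gap:(f - 1L)
          tracks[[i]]$rows <- rbind(tracks[[i]]$rows, data.frame(
            frame = gaps, x_um = NA_real_, y_um = NA_real_,
            intensity = NA_real_, gap_flag = TRUE))
        }
        tracks[[i]]$rows <- rbind(tracks[[i]]$rows, data.frame(
          frame = f, x_um = d$x_um[di], y_um = d$y_um[di],
          intensity = d$intensity[di], gap_flag = FALSE))
        tracks[[i]]$last_x <- d$x_um[di]
        tracks[[i]]$last_y <- d$y_um[di]
        tracks[[i]]$last_frame <- f
      }
    }
    # close tracks that exhausted their gap allowance
    for (i in seq_along(tracks)) {
      if (tracks[[i]]$open && (f - tracks[[i]]$last_frame) > max_gap_frames) {
        tracks[[i]]$open <- FALSE
      }
    }
    for (di in which(!assigned_det)) {
      tracks[[length(tracks) + 1L]] <- list(
        rows = data.frame(frame = f, x_um = d$x_um[di], y_um = d$y_um[di],
                          intensity = d$intensity[di], gap_flag = FALSE),
        last_x = d$x_um[di], last_y = d$y_um[di], last_frame = f, open = TRUE)
    }
  }
  if (length(tracks) == 0) {
    out <- data.frame(track_id = integer(0), frame = integer(0),
                      time_s = numeric(0), x_um = numeric(0), y_um = numeric(0),
                      intensity = numeric(0), gap_flag = logical(0))
  } else {
    out <- do.call(rbind, lapply(seq_along(tracks), function(i) {
      rows <- tracks[[i]]$rows
      data.frame(track_id = i, frame = rows$frame,
                 time_s = rows$frame * frame_interval,
                 x_um = rows$x_um, y_um = rows$y_um,
                 intensity = rows$intensity, gap_flag = rows$gap_flag)
    }))
  }
  rownames(out) <- NULL
  attr(out, "frame_interval") <- frame_interval
  out
}

#' Filter linked tracks on length and brightness
#'
#' Keeps tracks with at least `min_length_frames` usable (non-gap) frames
#' and mean usable-frame intensity of at least `min_mean_intensity`.
#' Discard counts by reason are attached as the `filter_log` attribute.
#'
#' @param tracks Tidy multi-track data frame.
#' @param min_length_frames,min_mean_intensity Thresholds (>= 0).
#' @return The surviving tracks (same format), `filter_log` attached.
#' @export
filter_tracks <- function(tracks, min_length_frames = 0L, min_mean_intensity = 0) {
  stopifnot(min_length_frames >= 0, min_mean_intensity >= 0)
  ids <- unique(tracks$track_id)
  short <- 0L; dim_ <- 0L
  keep_ids <- c()
  for (id in ids) {
    d <- tracks[tracks$track_id == id, ]
    usable <- !d$gap_flag
    if (sum(usable) < min_length_frames) { short <- short + 1L; next }
    if (sum(usable) == 0 || mean(d$intensity[usable]) < min_mean_intensity) {
      dim_ <- dim_ + 1L; next
    }
    keep_ids <- c(keep_ids, id)
  }
  out <- tracks[tracks$track_id %in% keep_ids, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "frame_interval") <- attr(tracks, "frame_interval")
  attr(out, "filter_log") <- c(
    n_input = length(ids), n_kept = length(keep_ids),
    discarded_short = short, discarded_dim = dim_)
  out
}

#' Detect, link and filter a whole movie in one call
#'
#' @param stack An `image_stack`.
#' @param psf_sigma_px Spot scale in pixels.
#' @param snr_threshold Detection SNR threshold.
#' @param max_disp_um,max_gap_frames Linking parameters.
#' @param min_length_frames,min_mean_intensity Track filters.
#' @return Tidy multi-track data frame, deterministic for a fixed movie.
#' @export
track_movie <- function(stack, psf_sigma_px, snr_threshold = 5,
                        max_disp_um = 0.5, max_gap_frames = 1L,
                        min_length_frames = 10L, min_mean_intensity = 0) {
  det <- detect_movie(stack, psf_sigma_px, snr_threshold = snr_threshold)
  trk <- link_detections(det, max_disp_um = max_disp_um,
                         max_gap_frames = max_gap_frames,
                         frame_interval = stack$frame_interval)
  filter_tracks(trk, min_length_frames = min_length_frames,
                min_mean_intensity = min_mean_intensity)
}
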