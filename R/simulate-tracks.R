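#' Simulation configuration for synthetic trajectory and movie generation
#'
#' Bundles the physical parameters of a simulated tracking experiment:
#' fractional Brownian motion (fBm) of point markers confined to a
#' spherocylindrical cell, exponential photobleaching, photon-limited
#' localization noise, and rendering onto a pixel grid.
#'
#' The motion model is 2-D fBm with Hurst parameter `hurst`; the ensemble
#' 2-D mean square displacement (MSD) is `amplitude * tau^(2*hurst)`, so the
#' anomalous-diffusion exponent is `alpha = 2 * hurst`. `amplitude` is the
#' full 2-D MSD prefactor; each coordinate contributes `amplitude/2`.
#'
#' @param n_tracks Number of tracks to simulate.
#' @param n_frames Frames per track (>= 2).
#' @param frame_interval Time between frames, seconds.
#' @param hurst Hurst parameter, strictly inside (0, 1).
#' @param amplitude 2-D MSD prefactor, um^2 s^(-2*hurst).
#' @param loc_noise_sigma Static localization error per coordinate at the
#'   reference intensity, um.
#' @param initial_intensity Integrated spot intensity at time 0, photons.
#' @param bleach_tau Photobleaching time constant, seconds.
#' @param cell_length,cell_radius Spherocylinder geometry, um
#'   (`cell_length >= 2 * cell_radius`).
#' @param pixel_size Camera pixel size, um/px.
#' @param psf_sigma Gaussian point-spread-function width, um.
#' @param background Background level, photons per pixel per frame.
#' @param seed Master seed; per-track seeds are derived with [derive_seed()].
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_tracks = 5, n_frames = 50)
#' trk <- generate_fbm_track(cfg, track_id = 1)
#' head(trk)
#' @export
sim_config <- function(n_tracks = 50L,
                       n_frames = 150L,
                       frame_interval = 0.1,
                       hurst = 0.2,
                       amplitude = 1.6e-3,
                       loc_noise_sigma = 0.02,
                       initial_intensity = 2000,
                       bleach_tau = 50,
                       cell_length = 3,
                       cell_radius = 0.5,
                       pixel_size = 0.1,
                       psf_sigma = 0.13,
                       background = 100,
                       seed = 1L) {
  cfg <- list(
    n_tracks = assert_count(n_tracks, "n_tracks"),
    n_frames = assert_count(n_frames, "n_frames", min = 2L),
    frame_interval = assert_scalar_num(frame_interval, "frame_interval", 0, strict_lower = TRUE),
    hurst = assert_scalar_num(hurst, "hurst", 0, 1, strict_lower = TRUE, strict_upper = TRUE),
    amplitude = assert_scalar_num(amplitude, "amplitude", 0),
    loc_noise_sigma = assert_scalar_num(loc_noise_sigma, "loc_noise_sigma", 0),
    initial_intensity = assert_scalar_num(initial_intensity, "initial_intensity", 0, strict_lower = TRUE),
    bleach_tau = assert_scalar_num(bleach_tau, "bleach_tau", 0, strict_lower = TRUE),
    cell_length = assert_scalar_num(cell_length, "cell_length", 0, strict_lower = TRUE),
    cell_radius = assert_scalar_num(cell_radius, "cell_radius", 0, strict_lower = TRUE),
    pixel_size = assert_scalar_num(pixel_size, "pixel_size", 0, strict_lower = TRUE),
    psf_sigma = assert_scalar_num(psf_sigma, "psf_sigma", 0, strict_lower = TRUE),
    background = assert_scalar_num(background, "background", 0),
    seed = assert_count(seed, "seed", min = 0L)
  )
  if (cfg$cell_length < 2 * cfg$cell_radius) {
    stop("`cell_length` must be >= 2 * `cell_radius`", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Default motion parameters for the three marker types
#'
#' Chromosomal loci near the replication origin (Ori2) and terminus (Ter3)
#' subdiffuse with exponent alpha ~ 0.4 and MSD(10 s) around 4.0e-3 and
#' 2.5e-3 um^2 respectively; inert cytosolic muNS aggregates move an order
#' of magnitude faster (MSD(10 s) ~ 0.08 um^2). Amplitudes here are the 2-D
#' prefactors that place MSD(10 s) = amplitude * 10^0.4 at those values.
#'
#' @return Named list with `amplitude` and `hurst` per marker.
#' @export
marker_defaults <- function() {
  list(
    Ori2 = list(amplitude = 4.0e-3 / 10^0.4, hurst = 0.2),
    Ter3 = list(amplitude = 2.5e-3 / 10^0.4, hurst = 0.2),
    muNS = list(amplitude = 8.0e-2 / 10^0.4, hurst = 0.2)
  )
}

# Eigenvalues of the circulant embedding of the fractional-Gaussian-noise
# covariance. sigma2 is the per-axis increment variance at lag dt; the fGn
# autocovariance at integer lag k is
#   gamma(k) = sigma2/2 * (|k-1|^2H - 2|k|^2H + |k+1|^2H).
fgn_circulant_eigen <- function(n_incr, hurst, sigma2) {
  m <- n_incr
  k <- 0:m
  g <- sigma2 / 2 * (abs(k - 1)^(2 * hurst) - 2 * k^(2 * hurst) + (k + 1)^(2 * hurst))
  circ <- if (m > 1) c(g, g[m:2]) else c(g, g[2])
  ev <- Re(stats::fft(circ))
  # tiny negative values from floating point are clipped; fGn with H < 1 is
  # always embeddable so anything larger signals a real error
  bad <- ev < -1e-8 * max(sigma2, 1e-300)
  if (any(bad)) stop("circulant embedding failed: negative eigenvalues", call. = FALSE)
  pmax(ev, 0)
}

# Draw one pair of independent fGn sample paths (x and y increments) from
# precomputed circulant eigenvalues, using the current RNG stream.
fgn_sample_pair <- function(ev, n_incr) {
  n <- length(ev)
  # real and imaginary outputs each carry the target covariance and are
  # independent, yielding the x and y axes from a single transform
  z <- complex(real = stats::rnorm(n), imaginary = stats::rnorm(n))
  f <- stats::fft(sqrt(ev / n) * z)
  list(dx = Re(f)[seq_len(n_incr)], dy = Im(f)[seq_len(n_incr)])
}

new_track <- function(frame, time_s, x_um, y_um, intensity,
                      gap_flag = rep(FALSE, length(frame)),
                      track_id = 1L, marker = NA_character_,
                      condition = NA_character_, treatment_time = NA_real_,
                      replicate = NA_integer_, frame_interval = NA_real_) {
  structure(
    data.frame(frame = frame, time_s = time_s, x_um = x_um, y_um = y_um,
               intensity = intensity, gap_flag = gap_flag),
    track_id = track_id, marker = marker, condition = condition,
    treatment_time = treatment_time, replicate = replicate,
    frame_interval = frame_interval,
    class = c("spt_track", "data.frame")
  )
}

#' Simulate one unconfined, noiseless fractional Brownian motion track
#'
#' Positions are exact-covariance fBm sampled by circulant embedding of
#' fractional Gaussian noise, so the ensemble 2-D MSD equals
#' `amplitude * tau^(2*hurst)` at every lag. x and y are independent.
#' The track starts at the origin with constant intensity
#' `initial_intensity`; confinement, bleaching and localization noise are
#' separate, composable steps ([confine_track()], [apply_photobleaching()],
#' [apply_localization_noise()]).
#'
#' @param config A [sim_config()].
#' @param track_id Integer id; combined with `config$seed` to derive this
#'   track's own RNG seed, so tracks are reproducible in any order.
#' @return A `spt_track` data frame with columns `frame`, `time_s`, `x_um`,
#'   `y_um`, `intensity`, `gap_flag`.
#' @export
generate_fbm_track <- function(config, track_id = 1L) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_frames
  dt <- config$frame_interval
  sigma2 <- config$amplitude / 2 * dt^(2 * config$hurst)
  ev <- fgn_circulant_eigen(n - 1L, config$hurst, sigma2)
  incr <- with_seed(derive_seed(config$seed, "track", track_id),
                    fgn_sample_pair(ev, n - 1L))
  new_track(
    frame = 0:(n - 1L),
    time_s = (0:(n - 1L)) * dt,
    x_um = c(0, cumsum(incr$dx)),
    y_um = c(0, cumsum(incr$dy)),
    intensity = rep(config$initial_intensity, n),
    track_id = as.integer(track_id),
    frame_interval = dt
  )
}

# TRUE for points inside (or on) the 2-D spherocylinder centred at the
# origin with long axis along x.
inside_spherocylinder <- function(x, y, cell_length, cell_radius, tol = 0) {
  hl <- cell_length / 2 - cell_radius
  in_rect <- abs(x) <= hl & abs(y) <= cell_radius + tol
  dcap <- sqrt((abs(x) - hl)^2 + y^2)
  in_cap <- abs(x) > hl & dcap <= cell_radius + tol
  in_rect | in_cap
}

reflect_point <- function(x, y, cell_length, cell_radius) {
  hl <- cell_length / 2 - cell_radius
  for (i in 1:200) {
    if (inside_spherocylinder(x, y, cell_length, cell_radius, tol = 1e-12)) break
    if (abs(x) <= hl) {
      # flat side: mirror across y = +/- cell_radius
      y <- sign(y) * 2 * cell_radius - y
    } else {
      cx <- sign(x) * hl
      rho <- sqrt((x - cx)^2 + y^2)
      if (rho > cell_radius) {
        # cap: mirror radially across the circle of radius cell_radius;
        # a step longer than a diameter is clamped to the boundary
        rho_new <- 2 * cell_radius - rho
        if (rho_new < 0) rho_new <- cell_radius
        x <- cx + (x - cx) * rho_new / rho
        y <- y * rho_new / rho
      } else break
    }
  }
  c(x, y)
}

#' Confine a track inside a 2-D spherocylindrical cell
#'
#' The cell outline is a rectangle of length `cell_length - 2*cell_radius`
#' capped by semicircles of radius `cell_radius`, centred at the origin with
#' the long axis along x. Each successive increment is applied and, when it
#' would leave the cell, reflected at the boundary; a track that never
#' touches the boundary is returned unchanged.
#'
#' @param track A `spt_track` data frame.
#' @param cell_length,cell_radius Geometry in um.
#' @return The confined track; all positions satisfy the inside predicate.
#' @export
confine_track <- function(track, cell_length, cell_radius) {
  assert_scalar_num(cell_radius, "cell_radius", 0, strict_lower = TRUE)
  assert_scalar_num(cell_length, "cell_length", 2 * cell_radius)
  x <- track$x_um
  y <- track$y_um
  n <- length(x)
  if (n == 0) return(track)
  p <- reflect_point(x[1], y[1], cell_length, cell_radius)
  out_x <- numeric(n); out_y <- numeric(n)
  out_x[1] <- p[1]; out_y[1] <- p[2]
  if (n > 1) {
    dx <- diff(x); dy <- diff(y)
    for (i in 2:n) {
      p <- reflect_point(out_x[i - 1] + dx[i - 1], out_y[i - 1] + dy[i - 1],
                         cell_length, cell_radius)
      out_x[i] <- p[1]; out_y[i] <- p[2]
    }
  }
  track$x_um <- out_x
  track$y_um <- out_y
  track
}

#' Apply exponential photobleaching to a track's intensity trace
#'
#' Fluorophore emission decays as `intensity(t) = initial_intensity *
#' exp(-t / bleach_tau)`; positions are untouched. Dim, heavily bleached
#' spots localize poorly, which is why downstream MSD analysis needs the
#' intensity trace ([correct_marker_effects()]).
#'
#' @param track A `spt_track`.
#' @param initial_intensity Photons at `t = 0`.
#' @param bleach_tau Decay time constant, seconds (> 0).
#' @export
apply_photobleaching <- function(track, initial_intensity, bleach_tau) {
  assert_scalar_num(initial_intensity, "initial_intensity", 0)
  assert_scalar_num(bleach_tau, "bleach_tau", 0, strict_lower = TRUE)
  track$intensity <- initial_intensity * exp(-track$time_s / bleach_tau)
  track
}

#' Add photon-limited localization noise to a track
#'
#' Adds independent Gaussian noise to each coordinate with standard
#' deviation `loc_noise_sigma * sqrt(reference_intensity / intensity(t))`:
#' localization precision scales with the inverse square root of the photon
#' count, so bleached (dim) frames are noisier. The noise inflates the
#' measured 2-D MSD by a lag-independent additive offset `4 * sigma_eff^2`.
#' Frames with zero intensity have undefined noise and are flagged as gaps
#' (positions set to `NA`).
#'
#' Uses the current RNG stream; seed it (e.g. via [with_seed()] internally
#' in [generate_tracks()]) for reproducibility.
#'
#' @param track A `spt_track`.
#' @param loc_noise_sigma Noise SD per coordinate at the reference
#'   intensity, um (>= 0).
#' @param reference_intensity Intensity at which the noise SD equals
#'   `loc_noise_sigma`, photons.
#' @export
apply_localization_noise <- function(track, loc_noise_sigma, reference_intensity) {
  assert_scalar_num(loc_noise_sigma, "loc_noise_sigma", 0)
  assert_scalar_num(reference_intensity, "reference_intensity", 0, strict_lower = TRUE)
  if (loc_noise_sigma == 0) return(track)
  n <- nrow(track)
  dead <- !(track$intensity > 0)
  sd_t <- loc_noise_sigma * sqrt(reference_intensity / pmax(track$intensity, 1e-300))
  track$x_um <- track$x_um + stats::rnorm(n, 0, sd_t)
  track$y_um <- track$y_um + stats::rnorm(n, 0, sd_t)
  if (any(dead)) {
    track$x_um[dead] <- NA_real_
    track$y_um[dead] <- NA_real_
    track$gap_flag[dead] <- TRUE
  }
  track
}

#' Simulate a batch of tracks for one experimental unit
#'
#' Convenience wrapper generating `config$n_tracks` tracks and composing the
#' simulation stages: fBm motion, confinement in the cell, photobleaching
#' and localization noise (each optional). Initial intensities can be varied
#' across tracks to emulate marker-size / copy-number heterogeneity.
#'
#' @param config A [sim_config()].
#' @param marker,condition,treatment_time,replicate Provenance labels stored
#'   on each track (and folded into per-track seeds so distinct units get
#'   independent noise).
#' @param confine,bleach,noise Stage toggles.
#' @param start `"center"` starts every track at the cell centre;
#'   `"random"` draws uniform start positions inside the cell.
#' @param intensity_range Length-2 numeric; per-track initial intensities
#'   are drawn log-uniformly in this range. Default is the configured
#'   `initial_intensity` for every track.
#' @return A tidy data frame of all tracks (columns `track_id`, `marker`,
#'   `condition`, `treatment_time`, `replicate`, `frame`, `time_s`, `x_um`,
#'   `y_um`, `intensity`, `gap_flag`).
#' @export
generate_tracks <- function(config, marker = "Ori2", condition = "control",
                            treatment_time = 0, replicate = 1L,
                            confine = TRUE, bleach = TRUE, noise = TRUE,
                            start = c("center", "random"),
                            intensity_range = NULL) {
  stopifnot(inherits(config, "sim_config"))
  start <- match.arg(start)
  n <- config$n_frames
  dt <- config$frame_interval
  sigma2 <- config$amplitude / 2 * dt^(2 * config$hurst)
  ev <- fgn_circulant_eigen(n - 1L, config$hurst, sigma2)
  out <- vector("list", config$n_tracks)
  for (i in seq_len(config$n_tracks)) {
    seed_i <- derive_seed(config$seed, marker, condition, treatment_time,
                          replicate, "track", i)
    trk <- with_seed(seed_i, {
      incr <- fgn_sample_pair(ev, n - 1L)
      x <- c(0, cumsum(incr$dx))
      y <- c(0, cumsum(incr$dy))
      if (start == "random") {
        repeat {
          x0 <- stats::runif(1, -config$cell_length / 2, config$cell_length / 2)
          y0 <- stats::runif(1, -config$cell_radius, config$cell_radius)
          if (inside_spherocylinder(x0, y0, config$cell_length, config$cell_radius)) break
        }
        x <- x + x0
        y <- y + y0
      }
      I0 <- if (is.null(intensity_range)) config$initial_intensity else
        exp(stats::runif(1, log(intensity_range[1]), log(intensity_range[2])))
      t_i <- new_track(0:(n - 1L), (0:(n - 1L)) * dt, x, y,
                       rep(I0, n), track_id = i, marker = marker,
                       condition = condition, treatment_time = treatment_time,
                       replicate = as.integer(replicate), frame_interval = dt)
      if (confine) t_i <- confine_track(t_i, config$cell_length, config$cell_radius)
      if (bleach) t_i <- apply_photobleaching(t_i, I0, config$bleach_tau)
      if (noise && config$loc_noise_sigma > 0) {
        t_i <- apply_localization_noise(t_i, config$loc_noise_sigma,
                                        config$initial_intensity)
      }
      t_i
    })
    out[[i]] <- data.frame(
      track_id = i, marker = marker, condition = condition,
      treatment_time = treatment_time, replicate = as.integer(replicate),
      trk, stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "frame_interval") <- dt
  res
}

#' Split a tidy multi-track data frame into a list of `spt_track` objects
#'
#' @param tracks Tidy data frame as returned by [generate_tracks()] or
#'   [link_detections()].
#' @return Named list of `spt_track` data frames, one per `track_id`.
#' @export
split_tracks <- function(tracks) {
  dt <- attr(tracks, "frame_interval")
  if (is.null(dt) && nrow(tracks) > 1) {
    dt <- min(diff(sort(unique(tracks$time_s))))
  }
  lapply(split(tracks, tracks$track_id), function(d) {
    new_track(d$frame, d$time_s, d$x_um, d$y_um, d$intensity,
              gap_flag = if ("gap_flag" %in% names(d)) d$gap_flag else rep(FALSE, nrow(d)),
              track_id = d$track_id[1],
              marker = if ("marker" %in% names(d)) d$marker[1] else NA_character_,
              condition = if ("condition" %in% names(d)) d$condition[1] else NA_character_,
              treatment_time = if ("treatment_time" %in% names(d)) d$treatment_time[1] else NA_real_,
              replicate = if ("replicate" %in% names(d)) d$replicate[1] else NA_integer_,
              frame_interval = dt)
  })
}
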