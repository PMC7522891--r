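# Shared fixtures and independent oracles, built in code at test time.

# O(n^2) brute-force time-averaged MSD: the independent oracle for
# time_averaged_msd(). Enumerates every frame pair explicitly.
brute_force_msd <- function(track, min_pairs = 5L) {
  n <- nrow(track)
  usable <- !track$gap_flag & is.finite(track$x_um) & is.finite(track$y_um)
  dt <- min(diff(track$time_s))
  lags <- integer(0); msd <- numeric(0); np <- integer(0)
  for (k in 1:(n - 1)) {
    acc <- c()
    for (t in 1:(n - k)) {
      if (usable[t] && usable[t + k]) {
        acc <- c(acc, (track$x_um[t + k] - track$x_um[t])^2 +
                   (track$y_um[t + k] - track$y_um[t])^2)
      }
    }
    if (length(acc) >= min_pairs) {
      lags <- c(lags, k); msd <- c(msd, mean(acc)); np <- c(np, length(acc))
    }
  }
  data.frame(lag_s = c(0, lags * dt), msd_um2 = c(0, msd),
             n_pairs = c(sum(usable), np))
}

# A short random walk with optional gap frames, for property tests.
random_track <- function(n, gap_prob = 0) {
  x <- cumsum(stats::rnorm(n, 0, 0.05))
  y <- cumsum(stats::rnorm(n, 0, 0.05))
  gaps <- stats::runif(n) < gap_prob
  x[gaps] <- NA; y[gaps] <- NA
  structure(
    data.frame(frame = 0:(n - 1), time_s = (0:(n - 1)) * 0.1,
               x_um = x, y_um = y, intensity = rep(1000, n), gap_flag = gaps),
    frame_interval = 0.1, class = c("spt_track", "data.frame"))
}

# A stationary track at a fixed position.
stationary_track <- function(n, x = 0, y = 0, intensity = 1000, dt = 0.1) {
  structure(
    data.frame(frame = 0:(n - 1), time_s = (0:(n - 1)) * dt,
               x_um = rep(x, n), y_um = rep(y, n),
               intensity = rep(intensity, n), gap_flag = rep(FALSE, n)),
    frame_interval = dt, class = c("spt_track", "data.frame"))
}

# Closed-form fractional-Gaussian-noise autocovariance at integer lags.
fgn_acov <- function(k, hurst, sigma2) {
  sigma2 / 2 * (abs(k - 1)^(2 * hurst) - 2 * abs(k)^(2 * hurst) +
                  (abs(k) + 1)^(2 * hurst))
}

# Render a single-spot frame directly (independent of render_movie):
# pixel-integrated Gaussian on an ny x nx grid, pixel centres at integers.
reference_spot_frame <- function(nx, ny, x0_px, y0_px, intensity, sigma_px,
                                 background = 0) {
  jj <- seq_len(nx); ii <- seq_len(ny)
  gx <- stats::pnorm((jj + 0.5 - x0_px) / sigma_px) -
    stats::pnorm((jj - 0.5 - x0_px) / sigma_px)
  gy <- stats::pnorm((ii + 0.5 - y0_px) / sigma_px) -
    stats::pnorm((ii - 0.5 - y0_px) / sigma_px)
  background + intensity * (gy %o% gx)
}
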