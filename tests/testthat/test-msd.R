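test_that("stationary and ballistic tracks have closed-form MSDs", {
  st <- stationary_track(50)
  cv <- time_averaged_msd(st)
  expect_true(all(cv$msd_um2 == 0))
  expect_equal(cv$msd_um2[cv$lag_s == 0], 0)

  n <- 100
  ball <- stationary_track(n)
  ball$x_um <- 0.1 * ball$time_s  # v = 0.1 um/s along x
  cb <- time_averaged_msd(ball)
  expect_equal(cb$msd_um2[abs(cb$lag_s - 1) < 1e-9], 0.01, tolerance = 1e-12)
  sel <- cb$lag_s > 0
  expect_equal(cb$msd_um2[sel], (0.1 * cb$lag_s[sel])^2, tolerance = 1e-12)
})

test_that("time-averaged MSD equals the O(n^2) brute-force oracle", {
  set.seed(42)
  for (i in 1:30) {
    n <- sample(10:30, 1)
    trk <- random_track(n, gap_prob = if (i %% 3 == 0) 0.15 else 0)
    got <- time_averaged_msd(trk, min_pairs = 1L)
    oracle <- brute_force_msd(trk, min_pairs = 1L)
    expect_equal(got$lag_s, oracle$lag_s)
    expect_equal(got$msd_um2, oracle$msd_um2, tolerance = 1e-12)
    expect_equal(got$n_pairs, oracle$n_pairs)
  }
})

test_that("pair counts are non-increasing and short lags are dropped by min_pairs", {
  trk <- random_track(40)
  cv <- time_averaged_msd(trk, min_pairs = 5L)
  expect_true(all(diff(cv$n_pairs[cv$lag_s > 0]) <= 0))
  expect_true(all(cv$n_pairs[cv$lag_s > 0] >= 5))
  expect_lt(max(cv$lag_s), 40 * 0.1)
})

test_that("ensemble MSD equals the mean of per-track curves", {
  cfg <- sim_config(n_tracks = 10, n_frames = 30, seed = 4)
  trks <- generate_tracks(cfg, confine = FALSE, bleach = FALSE, noise = FALSE)
  ens <- ensemble_msd(trks, min_pairs = 1L)
  per <- lapply(split_tracks(trks), time_averaged_msd, min_pairs = 1L)
  man <- rowMeans(sapply(per, function(cv) cv$msd_um2))
  expect_equal(ens$msd_um2, man, tolerance = 1e-12)
})

test_that("power-law fits recover exact power laws to high precision", {
  lags <- seq(0.1, 14, by = 0.1)
  curve <- data.frame(lag_s = c(0, lags), msd_um2 = c(0, 0.004 * lags^0.4),
                      n_pairs = 100)
  class(curve) <- c("msd_curve", "data.frame")
  # lm warns that the fit is "essentially perfect" on exact data
  fit <- suppressWarnings(fit_power_law(curve, c(0.1, 14)))
  expect_equal(fit$alpha, 0.4, tolerance = 1e-9)
  expect_equal(fit$amplitude, 0.004, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  lin <- data.frame(lag_s = c(0, lags), msd_um2 = c(0, lags), n_pairs = 100)
  class(lin) <- c("msd_curve", "data.frame")
  fl <- suppressWarnings(fit_power_law(lin, c(0.1, 10)))
  expect_equal(fl$alpha, 1, tolerance = 1e-9)
  expect_equal(fl$amplitude, 1, tolerance = 1e-9)
})

test_that("power-law fit refuses windows with too few usable lags", {
  curve <- data.frame(lag_s = c(0, 0.1, 0.2, 0.3), msd_um2 = c(0, 1, 0, 2),
                      n_pairs = 10)
  class(curve) <- c("msd_curve", "data.frame")
  expect_error(fit_power_law(curve, c(0.1, 10)), "fewer than 4")
})

test_that("msd_at_lag interpolates exactly for power laws and refuses extrapolation", {
  lags <- c(0.1, 0.3, 1, 3, 9, 15)
  curve <- data.frame(lag_s = c(0, lags), msd_um2 = c(0, 0.004 * lags^0.4),
                      n_pairs = 50)
  class(curve) <- c("msd_curve", "data.frame")
  expect_equal(msd_at_lag(curve, 1), 0.004, tolerance = 1e-12)       # on grid
  expect_equal(msd_at_lag(curve, 10), 0.004 * 10^0.4, tolerance = 1e-12) # between
  expect_error(msd_at_lag(curve, 20), "outside")
  expect_error(msd_at_lag(curve, 0.05), "outside")
})

test_that("msd_at_lag is monotone in the curve", {
  lags <- seq(0.1, 5, by = 0.1)
  lo <- data.frame(lag_s = lags, msd_um2 = 0.01 * lags^0.5, n_pairs = 10)
  hi <- data.frame(lag_s = lags, msd_um2 = 0.02 * lags^0.5, n_pairs = 10)
  class(lo) <- class(hi) <- c("msd_curve", "data.frame")
  for (target in c(0.25, 1, 4.99)) {
    expect_lt(msd_at_lag(lo, target), msd_at_lag(hi, target))
  }
})

test_that("identical intensities leave the correction a pass-through with a warning", {
  cfg <- sim_config(n_tracks = 25, n_frames = 60, seed = 8)
  trks <- generate_tracks(cfg, confine = FALSE, bleach = FALSE, noise = FALSE)
  curves <- lapply(split_tracks(trks), time_averaged_msd)
  ints <- rep(2000, length(curves))
  expect_warning(out <- correct_marker_effects(curves, ints),
                 "insufficient calibration")
  for (i in seq_along(curves)) {
    expect_equal(out[[i]]$msd_um2, curves[[i]]$msd_um2)
  }
})

test_that("correction removes intensity-dependent noise offsets", {
  cfg <- sim_config(n_tracks = 60, n_frames = 100, amplitude = 0.03,
                    loc_noise_sigma = 0.02, initial_intensity = 1600, seed = 15)
  clean <- generate_tracks(cfg, confine = FALSE, bleach = FALSE, noise = FALSE,
                           intensity_range = c(400, 1600))
  noisy <- generate_tracks(cfg, confine = FALSE, bleach = FALSE, noise = TRUE,
                           intensity_range = c(400, 1600))
  curves <- lapply(split_tracks(noisy), time_averaged_msd)
  ints <- vapply(split(noisy$intensity, noisy$track_id), mean, numeric(1))
  corrected <- correct_marker_effects(curves, ints, reference_intensity = 1600)
  log <- attr(corrected, "correction_log")
  expect_true(any(grepl("static-error subtraction applied", log)))
  ens_clean <- ensemble_msd(clean)
  corr_mean <- rowMeans(sapply(corrected, function(cv) cv$msd_um2))
  lags <- corrected[[1]]$lag_s
  sel <- lags >= 2 * 0.1 & lags <= 5
  ref <- ens_clean$msd_um2[match(lags[sel], ens_clean$lag_s)]
  expect_lt(max(abs(corr_mean[sel] / ref - 1)), 0.10)
})

test_that("correction leaves no residual amplitude-intensity trend", {
  cfg <- sim_config(n_tracks = 60, n_frames = 100, amplitude = 0.03,
                    loc_noise_sigma = 0.02, initial_intensity = 1600, seed = 16)
  noisy <- generate_tracks(cfg, confine = FALSE, bleach = FALSE, noise = TRUE,
                           intensity_range = c(400, 1600))
  curves <- lapply(split_tracks(noisy), time_averaged_msd)
  ints <- vapply(split(noisy$intensity, noisy$track_id), mean, numeric(1))
  corrected <- correct_marker_effects(curves, ints, reference_intensity = 1600)
  amps <- vapply(corrected, function(cv) {
    f <- tryCatch(fit_power_law(cv), error = function(e) NULL)
    if (is.null(f)) NA_real_ else f$amplitude
  }, numeric(1))
  ok <- is.finite(amps) & amps > 0
  fit <- lm(log(amps[ok]) ~ log(ints[ok]))
  slope <- coef(fit)[2]
  se <- summary(fit)$coefficients[2, 2]
  expect_lt(abs(slope), 2 * se)
})
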