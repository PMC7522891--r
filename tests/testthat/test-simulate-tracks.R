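test_that("config validation rejects unphysical parameters", {
  expect_error(sim_config(hurst = 1.5), "hurst")
  expect_error(sim_config(hurst = 0), "hurst")
  expect_error(sim_config(frame_interval = -0.1), "frame_interval")
  expect_error(sim_config(n_frames = 1), "n_frames")
  expect_error(sim_config(cell_length = 0.5, cell_radius = 0.5), "cell_length")
})

test_that("zero amplitude gives a motionless track", {
  cfg <- sim_config(amplitude = 0, n_frames = 40)
  trk <- generate_fbm_track(cfg, 1)
  expect_equal(trk$x_um, rep(0, 40))
  expect_equal(trk$y_um, rep(0, 40))
})

test_that("fBm generation is deterministic for a fixed seed and track id", {
  cfg <- sim_config(n_frames = 60, seed = 42)
  expect_identical(generate_fbm_track(cfg, 3), generate_fbm_track(cfg, 3))
  expect_false(identical(generate_fbm_track(cfg, 3)$x_um,
                         generate_fbm_track(cfg, 4)$x_um))
  trks <- generate_tracks(cfg)
  expect_identical(trks, generate_tracks(cfg))
})

test_that("increment autocovariance matches the fGn closed form", {
  for (H in c(0.2, 0.35, 0.5)) {
    cfg <- sim_config(n_tracks = 400, n_frames = 80, hurst = H,
                      amplitude = 0.01, seed = 11)
    trks <- generate_tracks(cfg, confine = FALSE, bleach = FALSE, noise = FALSE)
    dt <- 0.1
    sigma2 <- cfg$amplitude / 2 * dt^(2 * H)
    dx <- do.call(cbind, lapply(split(trks$x_um, trks$track_id), diff))
    for (k in 0:3) {
      emp <- mean(dx[1:(nrow(dx) - k), ] * dx[(1 + k):nrow(dx), ])
      theo <- fgn_acov(k, H, sigma2)
      mc_se <- stats::sd(dx[1:(nrow(dx) - k), ] * dx[(1 + k):nrow(dx), ]) /
        sqrt(length(dx[1:(nrow(dx) - k), ]))
      expect_lt(abs(emp - theo), 4 * mc_se + 1e-12)
    }
  }
})

test_that("ensemble MSD matches amplitude * tau^(2H) within Monte-Carlo error", {
  cfg <- sim_config(n_tracks = 500, n_frames = 120, hurst = 0.2,
                    amplitude = 0.004, seed = 5)
  trks <- generate_tracks(cfg, confine = FALSE, bleach = FALSE, noise = FALSE)
  ens <- ensemble_msd(trks)
  n <- 120
  X <- matrix(trks$x_um, nrow = n)
  Y <- matrix(trks$y_um, nrow = n)
  for (k in c(5, 20, 100)) {
    theo <- 0.004 * (k * 0.1)^0.4
    got <- msd_at_lag(ens, k * 0.1)
    # Monte-Carlo SE from the spread of per-track time-averaged MSDs
    per_track <- colMeans((X[(k + 1):n, ] - X[1:(n - k), ])^2 +
                            (Y[(k + 1):n, ] - Y[1:(n - k), ])^2)
    mc_se <- stats::sd(per_track) / sqrt(ncol(X))
    expect_lt(abs(got - theo), 3 * mc_se)
  }
})

test_that("confinement keeps every point inside the spherocylinder", {
  cfg <- sim_config(n_tracks = 20, n_frames = 100, amplitude = 0.5,
                    hurst = 0.45, cell_length = 2, cell_radius = 0.4, seed = 9)
  trks <- generate_tracks(cfg, confine = TRUE, bleach = FALSE, noise = FALSE)
  ok <- crowdmsd:::inside_spherocylinder(trks$x_um, trks$y_um, 2, 0.4, tol = 1e-9)
  expect_true(all(ok))
})

test_that("a track far from the boundary is unchanged by confinement", {
  cfg <- sim_config(amplitude = 1e-6, n_frames = 50, seed = 2)
  trk <- generate_fbm_track(cfg, 1)
  conf <- confine_track(trk, cell_length = 4, cell_radius = 1)
  expect_equal(conf$x_um, trk$x_um)
  expect_equal(conf$y_um, trk$y_um)
})

test_that("strong confinement caps the long-lag MSD below the cell size", {
  # free MSD(tau_max) = 4 * 10^0.9 ~ 32 um^2 >> cell area
  cfg <- sim_config(n_tracks = 150, n_frames = 100, amplitude = 4,
                    hurst = 0.45, cell_length = 2.5, cell_radius = 0.5, seed = 3)
  trks <- generate_tracks(cfg, confine = TRUE, bleach = FALSE, noise = FALSE,
                          start = "random")
  ens <- ensemble_msd(trks)
  plateau <- msd_at_lag(ens, 9.9)
  expect_lt(plateau, 2.5^2)
  expect_gt(4 * 9.9^0.9, 2.5^2)  # the free MSD really would overflow the cell
})

test_that("photobleaching decays exponentially and leaves positions alone", {
  trk <- stationary_track(100, dt = 0.5)
  out <- apply_photobleaching(trk, initial_intensity = 2000, bleach_tau = 10)
  expect_equal(out$intensity[1], 2000)
  i_at_tau <- out$intensity[which.min(abs(out$time_s - 10))]
  expect_equal(i_at_tau, 2000 / exp(1), tolerance = 1e-12)
  expect_true(all(diff(out$intensity) < 0))
  expect_equal(out$x_um, trk$x_um)
})

test_that("localization noise has the stated intensity scaling", {
  set.seed(1)
  trk <- stationary_track(4000, intensity = 1000)
  noisy <- apply_localization_noise(trk, loc_noise_sigma = 0.02,
                                    reference_intensity = 1000)
  # at reference intensity the per-coordinate SD is loc_noise_sigma
  expect_equal(stats::sd(noisy$x_um), 0.02, tolerance = 0.05)
  half <- stationary_track(4000, intensity = 500)
  noisy_half <- apply_localization_noise(half, loc_noise_sigma = 0.02,
                                         reference_intensity = 1000)
  # halving the intensity doubles the variance
  expect_equal(stats::var(noisy_half$x_um) / stats::var(noisy$x_um), 2,
               tolerance = 0.15)
})

test_that("noise adds a lag-independent 4 sigma^2 offset to the MSD", {
  set.seed(2)
  trk <- stationary_track(3000, intensity = 1000)
  noisy <- apply_localization_noise(trk, 0.02, 1000)
  curve <- time_averaged_msd(noisy, max_lag_frames = 20)
  offs <- curve$msd_um2[curve$lag_s > 0]
  expect_equal(mean(offs), 4 * 0.02^2, tolerance = 0.1)
  expect_lt(stats::sd(offs) / mean(offs), 0.1)  # flat across lags
})

test_that("zero-intensity frames are flagged as gaps, zero noise is a no-op", {
  trk <- stationary_track(20)
  expect_identical(apply_localization_noise(trk, 0, 1000), trk)
  trk$intensity[5] <- 0
  set.seed(3)
  out <- apply_localization_noise(trk, 0.01, 1000)
  expect_true(out$gap_flag[5])
  expect_true(is.na(out$x_um[5]))
  expect_false(any(out$gap_flag[-5]))
})
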