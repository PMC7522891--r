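test_that("a flat frame yields no detections", {
  frame <- matrix(100, 40, 40)
  expect_equal(nrow(detect_spots(frame, psf_sigma_px = 1.3)), 0)
  set.seed(1)
  noisy <- matrix(rpois(1600, 100), 40, 40)
  expect_equal(nrow(detect_spots(noisy, psf_sigma_px = 1.3)), 0)
})

test_that("a noiseless rendered spot is localized within 0.05 px", {
  frame <- reference_spot_frame(60, 60, x0_px = 20.30, y0_px = 41.70,
                                intensity = 5000, sigma_px = 1.3,
                                background = 100)
  det <- detect_spots(frame, psf_sigma_px = 1.3)
  expect_equal(nrow(det), 1)
  expect_lt(abs(det$x_px - 20.30), 0.05)
  expect_lt(abs(det$y_px - 41.70), 0.05)
  # integrated intensity is a by-product of the Gaussian fit
  expect_equal(det$intensity, 5000, tolerance = 0.05)
})

test_that("two spots separated by 6 psf widths give exactly two detections", {
  frame <- reference_spot_frame(60, 30, 20, 15, 4000, 1.3, background = 100) +
    reference_spot_frame(60, 30, 20 + 6 * 1.3, 15, 4000, 1.3, background = 0)
  det <- detect_spots(frame, psf_sigma_px = 1.3)
  expect_equal(nrow(det), 2)
  expect_equal(sort(det$x_px), c(20, 20 + 6 * 1.3), tolerance = 0.01)
})

test_that("saturated windows fall back to a flagged centroid", {
  frame <- reference_spot_frame(40, 40, 20, 20, 50000, 1.3, background = 100)
  det <- detect_spots(frame, psf_sigma_px = 1.3,
                      saturation_level = max(frame) * 0.9)
  expect_equal(nrow(det), 1)
  expect_true(det$saturated)
  expect_lt(abs(det$x_px - 20), 0.2)
})

test_that("one detection per frame links into a single complete track", {
  det <- data.frame(frame = 0:19,
                    x_um = 1 + 0.01 * (0:19), y_um = 2 - 0.005 * (0:19),
                    intensity = 1000)
  trk <- link_detections(det, max_disp_um = 0.5, frame_interval = 0.1)
  expect_equal(length(unique(trk$track_id)), 1)
  expect_equal(nrow(trk), 20)
  expect_false(any(trk$gap_flag))
  expect_equal(trk$time_s, det$frame * 0.1)
})

test_that("a single missing frame is bridged as a flagged gap, not a split", {
  det <- data.frame(frame = c(0:8, 10:19), x_um = 1, y_um = 1, intensity = 500)
  trk <- link_detections(det, max_disp_um = 0.5, max_gap_frames = 1,
                         frame_interval = 0.1)
  expect_equal(length(unique(trk$track_id)), 1)
  expect_equal(sum(trk$gap_flag), 1)
  expect_true(trk$gap_flag[trk$frame == 9])
  # without gap bridging the same input splits in two
  trk0 <- link_detections(det, max_disp_um = 0.5, max_gap_frames = 0,
                          frame_interval = 0.1)
  expect_equal(length(unique(trk0$track_id)), 2)
})

test_that("well-separated simulated tracks are recovered without identity swaps", {
  cfg <- sim_config(n_tracks = 3, n_frames = 40, amplitude = 4e-3, seed = 21)
  sim <- generate_tracks(cfg, confine = FALSE, bleach = FALSE, noise = FALSE)
  # separate the tracks by 5 um >> 5 * max_disp
  sim$x_um <- sim$x_um + 5 * (sim$track_id - 1)
  det <- data.frame(frame = sim$frame, x_um = sim$x_um, y_um = sim$y_um,
                    intensity = sim$intensity)
  det <- det[order(det$frame, -det$x_um), ]  # scrambled input order
  trk <- link_detections(det, max_disp_um = 0.5, frame_interval = 0.1)
  expect_equal(length(unique(trk$track_id)), 3)
  for (id in unique(trk$track_id)) {
    d <- trk[trk$track_id == id, ]
    truth_id <- round(d$x_um[1] / 5) + 1
    truth <- sim[sim$track_id == truth_id, ]
    expect_equal(d$x_um[order(d$frame)], truth$x_um[order(truth$frame)],
                 tolerance = 1e-12)
  }
})

test_that("track filtering matches the brute-force predicate", {
  make <- function(id, n, intensity) {
    data.frame(track_id = id, frame = 0:(n - 1), time_s = 0.1 * (0:(n - 1)),
               x_um = 0, y_um = 0, intensity = intensity, gap_flag = FALSE)
  }
  trks <- rbind(make(1, 30, 100), make(2, 10, 100), make(3, 30, 5),
                make(4, 25, 60), make(5, 9, 500))
  attr(trks, "frame_interval") <- 0.1
  # thresholds 0,0: unchanged
  expect_equal(nrow(filter_tracks(trks, 0, 0)), nrow(trks))
  out <- filter_tracks(trks, min_length_frames = 20, min_mean_intensity = 50)
  pred <- vapply(split(trks, trks$track_id),
                 function(d) nrow(d) >= 20 && mean(d$intensity) >= 50, logical(1))
  expect_setequal(unique(out$track_id), as.integer(names(pred)[pred]))
  log <- attr(out, "filter_log")
  expect_equal(unname(log["n_input"] - log["n_kept"]), sum(!pred))
  # everything shorter than the threshold: empty output, all discarded
  all_gone <- filter_tracks(trks, min_length_frames = 100)
  expect_equal(nrow(all_gone), 0)
  expect_equal(unname(attr(all_gone, "filter_log")["discarded_short"]), 5)
})

test_that("localization error grows as photon-limited 1/sqrt(intensity)", {
  sigma_px <- 1.3
  err <- sapply(c(4000, 1000), function(I) {
    errs <- sapply(1:25, function(r) {
      set.seed(1000 + r + I)
      lam <- reference_spot_frame(24, 24, 12.3, 11.6, I, sigma_px,
                                  background = 20)
      frame <- matrix(rpois(length(lam), lam), nrow(lam))
      det <- detect_spots(frame, sigma_px, snr_threshold = 4)
      if (nrow(det) == 1) sqrt((det$x_px - 12.3)^2 + (det$y_px - 11.6)^2) else NA
    })
    sqrt(mean(errs^2, na.rm = TRUE))
  })
  # intensity ratio 4 -> RMS error ratio ~ 2 (allow generous MC slack)
  expect_gt(err[2] / err[1], 1.4)
  expect_lt(err[2] / err[1], 2.8)
})

test_that("detect-link-filter is deterministic on a fixed movie", {
  cfg <- sim_config(n_tracks = 2, n_frames = 15, amplitude = 4e-3,
                    initial_intensity = 3000, background = 50, seed = 13)
  sim <- generate_tracks(cfg, confine = TRUE, bleach = FALSE, noise = FALSE)
  sim$x_um <- sim$x_um + ifelse(sim$track_id == 2, 1.2, -1.2)
  stack <- render_movie(sim, cfg, seed = 99)
  t1 <- track_movie(stack, psf_sigma_px = 1.3, max_disp_um = 0.5,
                    min_length_frames = 5)
  t2 <- track_movie(stack, psf_sigma_px = 1.3, max_disp_um = 0.5,
                    min_length_frames = 5)
  expect_identical(t1, t2)
  expect_gt(nrow(t1), 0)
})
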