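make_track <- function(bend, fps = 30, worm_id = 1L) {
  structure(list(worm_id = worm_id, frames = seq_along(bend),
                 x = rep(10, length(bend)), y = rep(10, length(bend)),
                 bend = bend, fps = fps, n_frames = length(bend)),
            class = "worm_track")
}

test_that("a single stationary worm yields one full-length track", {
  tr <- swim_video_truth(0, fps = 30, duration_s = 10,
                         worm_length_px = 24, amplitude_px = 6, seed = 5)
  v <- generate_swim_video(tr, 1, width = 96, height = 96, noise_sd = 0,
                           orbit_radius = 0)
  # a worm that never moves would survive into a temporal background
  # estimate; the rolling (morphological) background handles it
  bin <- binarize_frames(v$frames, background = "rolling",
                         threshold = "fixed", level = 50)
  tracks <- track_worms(bin, fps = 30)
  expect_length(tracks, 1)
  expect_equal(tracks[[1]]$n_frames, 300)
  rec <- count_body_bends(tracks[[1]])
  expect_equal(rec$bbps, 0)   # constant shape -> immobile call
})

test_that("two separated worms give two tracks matching truth within 2 px RMS", {
  tr <- swim_video_truth(c(1.0, 1.5), fps = 30, duration_s = 8,
                         worm_length_px = 36, amplitude_px = 9, seed = 6)
  v <- generate_swim_video(tr, 2, width = 220, height = 220, noise_sd = 5)
  bin <- binarize_frames(v$frames)
  tracks <- track_worms(bin, fps = 30, min_area = 20)
  tracks <- Filter(function(t) t$n_frames > 100, tracks)
  expect_length(tracks, 2)
  for (t in tracks) {
    # match the track to the closer ground-truth worm
    rms <- vapply(1:2, function(w) {
      sqrt(mean((t$x - v$centroids[t$frames, w, 1])^2 +
                  (t$y - v$centroids[t$frames, w, 2])^2))
    }, numeric(1))
    expect_lt(min(rms), 2)
  }
})

test_that("a worm exiting the field ends its track at the exit frame", {
  tr <- swim_video_truth(0, fps = 30, duration_s = 6, worm_length_px = 24,
                         amplitude_px = 6, seed = 7)
  v <- generate_swim_video(tr, 1, width = 120, height = 120, noise_sd = 0,
                           orbit_radius = 0,
                           positions = matrix(c(90, 60), 1),
                           drift = matrix(c(30, 0), 1))
  bin <- binarize_frames(v$frames, threshold = "fixed", level = 50)
  tracks <- track_worms(bin, fps = 30, min_area = 10)
  # frames in which the worm still has rendered pixels
  k <- sum(!is.na(v$centroids[, 1, 1]))
  expect_lt(k, 180)
  expect_length(tracks, 1)
  expect_equal(tracks[[1]]$n_frames, k)
})

test_that("bend counting matches the signal frequency and its edge cases", {
  expect_equal(count_body_bends(make_track(rep(3, 90)))$bbps, 0)
  expect_error(count_body_bends(make_track(rep(3, 20))), "too short")
  # pure sinusoid at 1.5 Hz for 30 s at 30 fps -> 1.5 BBPS
  t <- seq(0, 30 - 1 / 30, by = 1 / 30)
  rec <- count_body_bends(make_track(5 + sin(2 * pi * 1.5 * t)))
  expect_equal(rec$bbps, 1.5, tolerance = 0.04)
  expect_equal(rec$duration_s, 30)
})

test_that("the full chain recovers ground-truth BBPS within 10%", {
  for (freq in c(1.0, 1.86)) {
    tr <- swim_video_truth(freq, fps = 30, duration_s = 30,
                           worm_length_px = 36, amplitude_px = 9,
                           seed = 8)
    v <- generate_swim_video(tr, 1, width = 128, height = 128,
                             noise_sd = 5)
    recs <- video_to_records(v$frames, fps = 30, min_track_s = 20)
    expect_equal(nrow(recs), 1)
    expect_lt(abs(recs$bbps - freq) / freq, 0.1)
  }
})

test_that("defect_fraction uses at-or-below semantics and is well-behaved", {
  expect_equal(defect_fraction(c(2, 2, 2)), 0)
  expect_equal(defect_fraction(c(0.5, 1.1, 2.0)), 2 / 3)
  expect_error(defect_fraction(numeric(0)), "no swimming records")
  v <- c(0.3, 1.09, 1.1, 1.11, 2, 2.5)
  expect_equal(defect_fraction(v), defect_fraction(rev(v)))
  # monotone nonincreasing as the threshold is reduced
  ths <- seq(2, 0.2, by = -0.2)
  fr <- vapply(ths, function(th) defect_fraction(v, th), numeric(1))
  expect_true(all(diff(fr) <= 0))
})

test_that("swim_defect_test matches the closed-form Pearson chi-squared", {
  # table [[10,30],[2,38]]: 10/40 defective vs 2/40 defective
  variant <- c(rep(0.5, 10), rep(2, 30))
  wt <- c(rep(0.5, 2), rep(2, 38))
  res <- swim_defect_test(variant, wt)
  expect_equal(res$statistic, pearson_2x2(10, 30, 2, 38),
               tolerance = 1e-10)
  expect_equal(res$p_raw,
               stats::pchisq(pearson_2x2(10, 30, 2, 38), 1,
                             lower.tail = FALSE), tolerance = 1e-10)
  # symmetry under swapping the groups
  res2 <- swim_defect_test(wt, variant)
  expect_equal(res2$statistic, res$statistic, tolerance = 1e-12)
  # identical defect fractions -> statistic 0, p 1
  same <- swim_defect_test(variant, variant)
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p_raw, 1)
  # empty margin -> degenerate convention
  none <- swim_defect_test(c(2, 2, 2), c(2, 2, 2))
  expect_equal(none$statistic, 0)
  expect_equal(none$p_raw, 1)
  expect_true(none$degenerate)
})

test_that("wt-vs-wt chi-squared calls are nominal or conservative", {
  # at the wild-type defect rate the expected cell counts are small and
  # the uncorrected test is conservative; the rejection rate must not
  # exceed the nominal level (plus Monte-Carlo slack)
  p <- make_profile("wild_type")
  rej <- vapply(1:300, function(seed) {
    a <- simulate_swimming(p, 40, seed)
    b <- simulate_swimming(make_profile("wild_type", list(name = "wt2")),
                           40, seed)
    swim_defect_test(a, b)$p_raw <= 0.05
  }, logical(1))
  expect_lte(mean(rej), 0.065)
})
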