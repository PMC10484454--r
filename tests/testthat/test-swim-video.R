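test_that("truth invariants are enforced", {
  expect_error(swim_video_truth(1, fps = 1, duration_s = 1), "2 frames")
  expect_error(swim_video_truth(10, fps = 30), "Nyquist")
  tr <- swim_video_truth(1.86, fps = 30, duration_s = 30)
  expect_equal(round(tr$fps * tr$duration_s), 900)
})

test_that("frame count equals fps x duration and stacks round-trip TIFF", {
  tr <- swim_video_truth(1, fps = 30, duration_s = 2,
                         worm_length_px = 24, amplitude_px = 6, seed = 2)
  v <- generate_swim_video(tr, 1, width = 96, height = 96, noise_sd = 0)
  expect_equal(dim(v$frames), c(96, 96, 60))
  f <- tempfile(fileext = ".tif")
  write_video_tiff(v$frames, f)
  back <- read_frame_stack(f)
  expect_equal(dim(back), dim(v$frames))
  # 8-bit quantization only
  expect_lt(max(abs(back - v$frames)), 1)
})

test_that("a non-bending worm has an identical shape in every frame", {
  tr <- swim_video_truth(0, fps = 30, duration_s = 2,
                         worm_length_px = 24, amplitude_px = 6, seed = 3)
  v <- generate_swim_video(tr, 1, width = 96, height = 96, noise_sd = 0,
                           orbit_radius = 0)
  for (i in 2:dim(v$frames)[3])
    expect_identical(v$frames[, , i], v$frames[, , 1])
})

test_that("worms cannot be placed beyond the packing density", {
  tr <- swim_video_truth(1, fps = 30, duration_s = 1, worm_length_px = 40,
                         amplitude_px = 10, seed = 1)
  expect_error(generate_swim_video(tr, 50, width = 128, height = 128),
               "cannot place")
})

test_that("binarization recovers the rendered worm mask", {
  tr <- swim_video_truth(1.0, fps = 30, duration_s = 8,
                         worm_length_px = 36, amplitude_px = 9, seed = 4)
  v <- generate_swim_video(tr, 2, width = 220, height = 220, noise_sd = 5,
                           return_masks = TRUE)
  bin <- binarize_frames(v$frames)
  # foreground overlaps >= 90% of rendered worm pixels, every frame
  overlaps <- vapply(seq_len(dim(bin)[3]), function(i) {
    sum(bin[, , i] & v$masks[, , i]) / sum(v$masks[, , i])
  }, numeric(1))
  expect_gte(min(overlaps), 0.9)
  # per frame exactly n_worms sizeable components
  ncomp <- vapply(seq_len(dim(bin)[3]), function(i) {
    lab <- EBImage::bwlabel(bin[, , i] * 1)
    sum(tabulate(lab[lab > 0]) >= 20)
  }, numeric(1))
  expect_true(all(ncomp == 2))
})

test_that("all-zero stacks binarize to background with a fixed threshold", {
  z <- array(0, dim = c(16, 16, 4))
  out <- binarize_frames(z, threshold = "fixed", level = 0.5)
  expect_false(any(out))
  expect_error(binarize_frames(z, threshold = "otsu"), "degenerate")
  expect_error(binarize_frames(array(0, c(4, 4, 1))), "2 frames")
})
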