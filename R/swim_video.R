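# Synthetic swim videos with ground truth.
#
# A worm is rendered as a thickened constant-curvature arc (a C-shape)
# whose curvature oscillates sinusoidally in time. BBPS counts side-bends
# (two per full left-right cycle), so the curvature oscillates at
# bend_freq_hz / 2: the body then passes through a bent configuration
# bend_freq_hz times per second, and shape-based bend signals (component
# elongation) oscillate at bend_freq_hz.

#' Ground-truth parameters for a synthetic swim video
#'
#' @param bend_freq_hz True body bends per second for each worm (bends/s);
#'   recycled to the number of worms when the video is generated.
#' @param fps Frames per second.
#' @param duration_s Video duration in seconds.
#' @param worm_length_px Worm body length in pixels.
#' @param amplitude_px Maximal lateral deflection of the bend in pixels.
#' @param seed Integer seed for placement, phases and pixel noise.
#' @return An object of class `swim_video_truth`.
#' @export
swim_video_truth <- function(bend_freq_hz, fps = 30, duration_s = 30,
                             worm_length_px = 60, amplitude_px = 15,
                             seed = 1) {
  stopifnot(all(is.finite(bend_freq_hz)), all(bend_freq_hz >= 0),
            fps > 0, duration_s > 0, worm_length_px >= 4, amplitude_px >= 0)
  if (fps * duration_s < 2)
    stop("video must contain at least 2 frames (fps x duration_s >= 2)",
         call. = FALSE)
  if (any(bend_freq_hz >= fps / 4))
    stop("bend_freq_hz must be below fps/4 (Nyquist margin)", call. = FALSE)
  structure(list(bend_freq_hz = bend_freq_hz, fps = fps,
                 duration_s = duration_s, worm_length_px = worm_length_px,
                 amplitude_px = amplitude_px, seed = seed),
            class = "swim_video_truth")
}

# backbone points of an arc of length L with signed curvature kappa,
# centred at (cx, cy) with heading theta; m points along the arc
worm_backbone <- function(cx, cy, theta, kappa, L, m = 64L) {
  s <- seq(-L / 2, L / 2, length.out = m)
  if (abs(kappa) < 1e-8) {
    x <- cx + s * cos(theta)
    y <- cy + s * sin(theta)
  } else {
    x <- cx + (sin(theta + kappa * s) - sin(theta)) / kappa
    y <- cy - (cos(theta + kappa * s) - cos(theta)) / kappa
  }
  cbind(x, y)
}

#' Generate a synthetic swim-video frame stack with ground truth
#'
#' Renders `n_worms` bright worms on a noisy dark background. Each worm is
#' a thickened arc whose curvature oscillates so that its shape passes
#' through a bent configuration `bend_freq_hz` times per second (the
#' ground-truth BBPS). By default each worm also translates slowly along a
#' small circular orbit around its placement point — thrashing worms are
#' not pixel-stationary, and the motion keeps the temporal-median
#' background estimate worm-free. Worms are placed without overlap on a
#' jittered grid; placement, headings, bend phases and pixel noise all
#' derive from `truth$seed`.
#'
#' @param truth A [swim_video_truth()].
#' @param n_worms Number of worms to place.
#' @param width,height Frame size in pixels.
#' @param noise_sd Gaussian background noise SD (grey levels, 8-bit scale).
#' @param bg_level Background grey level.
#' @param worm_intensity Worm grey level.
#' @param worm_radius Half-thickness of the rendered body in pixels.
#' @param orbit_radius Radius (px) of the slow translation orbit; 0 keeps
#'   worm centres fixed.
#' @param positions Optional `n_worms x 2` matrix of (x, y) centres; when
#'   supplied, placement checks are skipped (centres may even lie outside
#'   the frame, e.g. to make a worm exit the field).
#' @param drift Optional `n_worms x 2` matrix of linear centre drift in
#'   px/s, added on top of the orbit.
#' @param return_masks If `TRUE`, also return the noiseless binary stack.
#' @return A list with `frames` (height x width x n_frames array of grey
#'   levels, 8-bit scale), `truth` (per-worm data frame with `worm_id`,
#'   `bbps`, placement), `centroids` (n_frames x n_worms x 2 array of true
#'   rendered-pixel centroids, (x, y); `NA` when a worm has no pixels in
#'   frame), `fps`, and optionally `masks`.
#' @export
generate_swim_video <- function(truth, n_worms,
                                width = 512, height = 512,
                                noise_sd = 5, bg_level = 20,
                                worm_intensity = 220, worm_radius = 2,
                                orbit_radius = 7,
                                positions = NULL, drift = NULL,
                                return_masks = FALSE) {
  stopifnot(inherits(truth, "swim_video_truth"), n_worms >= 1)
  n_frames <- as.integer(round(truth$fps * truth$duration_s))
  L <- truth$worm_length_px
  # curvature giving lateral deflection ~ amplitude_px at full bend
  kappa_max <- if (truth$amplitude_px > 0) 8 * truth$amplitude_px / L^2 else 0
  freq <- rep_len(truth$bend_freq_hz, n_worms)

  with_seed(derive_seed(truth$seed, "swim_video"), {
    # worm bounding radius around its centre, orbit included
    extent <- L / 2 + truth$amplitude_px + worm_radius + orbit_radius
    if (is.null(positions)) {
      margin <- extent + 2
      min_sep <- 2 * extent + 2
      xs <- seq(margin, width - margin, by = min_sep)
      ys <- seq(margin, height - margin, by = min_sep)
      if (!length(xs) || !length(ys) || length(xs) * length(ys) < n_worms)
        stop("cannot place ", n_worms,
             " worms without overlap at this density", call. = FALSE)
      cells <- expand.grid(x = xs, y = ys)
      cells <- cells[sample.int(nrow(cells), n_worms), , drop = FALSE]
      positions <- as.matrix(cells) +
        matrix(stats::runif(2 * n_worms, -1, 1), n_worms, 2)
    } else {
      positions <- matrix(positions, ncol = 2)
    }
    if (is.null(drift)) drift <- matrix(0, n_worms, 2)
    theta <- stats::runif(n_worms, 0, 2 * pi)
    phase <- stats::runif(n_worms, 0, 2 * pi)
    orbit_period <- stats::runif(n_worms, 6, 10)   # seconds per revolution
    orbit_phase <- stats::runif(n_worms, 0, 2 * pi)

    # disk stamp offsets for the body thickness
    r <- ceiling(worm_radius)
    off <- expand.grid(dx = -r:r, dy = -r:r)
    off <- off[off$dx^2 + off$dy^2 <= worm_radius^2 + 0.5, ]
    m_pts <- max(24L, as.integer(ceiling(2 * L)))
    tt <- (seq_len(n_frames) - 1L) / truth$fps

    frames <- array(0, dim = c(height, width, n_frames))
    masks <- if (return_masks) array(FALSE, dim = c(height, width, n_frames))
    centroids <- array(NA_real_, dim = c(n_frames, n_worms, 2))

    for (f in seq_len(n_frames)) {
      fr <- if (noise_sd > 0)
        matrix(bg_level + stats::rnorm(height * width, 0, noise_sd),
               height, width)
      else matrix(bg_level, height, width)
      for (w in seq_len(n_worms)) {
        # curvature oscillates at freq/2 -> bends (|curvature| maxima)
        # occur freq times per second
        kappa <- kappa_max * sin(pi * freq[w] * tt[f] + phase[w])
        ang <- 2 * pi * tt[f] / orbit_period[w] + orbit_phase[w]
        cx <- positions[w, 1] + drift[w, 1] * tt[f] +
          orbit_radius * cos(ang)
        cy <- positions[w, 2] + drift[w, 2] * tt[f] +
          orbit_radius * sin(ang)
        bb <- worm_backbone(cx, cy, theta[w], kappa, L, m_pts)
        px <- rep(round(bb[, 1]), each = nrow(off)) + off$dx
        py <- rep(round(bb[, 2]), each = nrow(off)) + off$dy
        keep <- px >= 1 & px <= width & py >= 1 & py <= height
        if (!any(keep)) next
        idx <- unique((px[keep] - 1L) * height + py[keep])
        centroids[f, w, 1] <- mean((idx - 1L) %/% height + 1L)
        centroids[f, w, 2] <- mean((idx - 1L) %% height + 1L)
        fr[idx] <- worm_intensity
        if (return_masks) {
          mk <- masks[, , f]
          mk[idx] <- TRUE
          masks[, , f] <- mk
        }
      }
      frames[, , f] <- fr
    }

    out <- list(frames = frames,
                truth = data.frame(worm_id = seq_len(n_worms), bbps = freq,
                                   x = positions[, 1], y = positions[, 2],
                                   heading = theta, phase = phase,
                                   stringsAsFactors = FALSE),
                centroids = centroids, fps = truth$fps)
    if (return_masks) out$masks <- masks
    out
  })
}

#' Write a frame stack as a multi-page TIFF
#'
#' @param frames height x width x n_frames array of grey levels in
#'   `[0, 255]`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_video_tiff <- function(frames, path) {
  stopifnot(is.array(frames), length(dim(frames)) == 3)
  pages <- lapply(seq_len(dim(frames)[3]),
                  function(i) frames[, , i] / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read a frame stack from a multi-page TIFF or a directory of PNG frames
#'
#' @param path A `.tif`/`.tiff` file or a directory of `.png` frames
#'   (frames sorted by file name).
#' @return A height x width x n_frames array of grey levels in `[0, 255]`.
#' @export
read_frame_stack <- function(path) {
  grey <- function(m) {
    if (length(dim(m)) == 3) m <- m[, , 1]
    m * 255
  }
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    if (!length(files)) stop("no PNG frames found in ", path, call. = FALSE)
    if (!requireNamespace("png", quietly = TRUE))
      stop("reading PNG frames requires the 'png' package", call. = FALSE)
    pages <- lapply(files, function(f) grey(png::readPNG(f)))
  } else {
    pages <- lapply(tiff::readTIFF(path, all = TRUE), grey)
  }
  d <- dim(pages[[1]])
  array(unlist(pages), dim = c(d[1], d[2], length(pages)))
}
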