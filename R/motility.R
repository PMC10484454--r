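# Swim-video processing: background subtraction and binarization, worm
# tracking across frames, and body-bend counting from the tracked
# component's shape signal.

#' Background-subtract and binarize a swim-video frame stack
#'
#' The background is estimated either from a per-pixel temporal quantile
#' of the stack (`median_stack`; `bg_quantile = 0.5` is the median, and
#' the default 0.2 stays robust even where a slowly translating worm
#' covers a pixel in up to ~80% of frames) or by per-frame morphological
#' opening (`rolling`, the rolling-ball analogue; also the right choice
#' for a worm that never moves). The background-subtracted frames are
#' then thresholded globally, either by Otsu's method on the pooled
#' intensity histogram or at a fixed level.
#'
#' @param frames height x width x n_frames array (>= 2 frames).
#' @param background Background model, `"median_stack"` or `"rolling"`.
#' @param threshold `"otsu"` or `"fixed"`.
#' @param level Threshold level for `threshold = "fixed"`, in the grey
#'   units of the background-subtracted stack.
#' @param rolling_radius Structuring-element radius (px) for
#'   `background = "rolling"`.
#' @param median_subsample Maximal number of frames used for the temporal
#'   background estimate (evenly spaced subsample; the background is
#'   static so a subsample estimates it equally well).
#' @param bg_quantile Temporal quantile used as the per-pixel background
#'   for `background = "median_stack"` (0.5 = median).
#' @return A logical array of the same dimensions; `TRUE` = worm pixels.
#' @export
binarize_frames <- function(frames,
                            background = c("median_stack", "rolling"),
                            threshold = c("otsu", "fixed"),
                            level = NULL,
                            rolling_radius = 15,
                            median_subsample = 31L,
                            bg_quantile = 0.2) {
  background <- match.arg(background)
  threshold <- match.arg(threshold)
  if (!is.array(frames) || length(dim(frames)) != 3)
    stop("frames must be a height x width x n_frames array", call. = FALSE)
  n <- dim(frames)[3]
  if (n < 2) stop("need at least 2 frames", call. = FALSE)

  # background estimate and per-frame subtraction are streamed so that
  # peak memory stays near one input stack plus one logical output
  sub_idx <- unique(round(seq(1, n, length.out = min(n, median_subsample))))
  brush <- if (background == "rolling")
    EBImage::makeBrush(2L * as.integer(rolling_radius) + 1L, shape = "disc")
  bgm <- NULL
  if (background == "median_stack") {
    sub <- frames[, , sub_idx, drop = FALSE]
    bgm <- apply(sub, c(1, 2), stats::quantile, probs = bg_quantile,
                 names = FALSE, type = 1)
    rm(sub)
  }
  frame_diff <- function(i) {
    fr <- frames[, , i]
    bg <- if (background == "median_stack") bgm
          else EBImage::opening(fr / 255, brush) * 255
    d <- fr - bg
    d[d < 0] <- 0
    d
  }

  if (threshold == "otsu") {
    # global Otsu level from the pooled histogram of a frame subsample
    v <- as.vector(vapply(sub_idx, frame_diff,
                          matrix(0, dim(frames)[1], dim(frames)[2])))
    rng <- range(v)
    if (diff(rng) <= .Machine$double.eps)
      stop("degenerate histogram: frames are constant after background ",
           "subtraction; Otsu thresholding is undefined", call. = FALSE)
    if (length(v) > 2e6) v <- v[seq(1, length(v), length.out = 2e6)]
    v <- v[seq_len(1024 * (length(v) %/% 1024))]
    lev <- EBImage::otsu(matrix(v / rng[2], nrow = 1024),
                         range = c(0, 1)) * rng[2]
  } else {
    if (is.null(level))
      stop("threshold = 'fixed' requires a level", call. = FALSE)
    lev <- level
  }
  out <- array(FALSE, dim = dim(frames))
  for (i in seq_len(n)) out[, , i] <- frame_diff(i) > lev
  out
}

# centroid and principal-second-moment elongation of a pixel set
component_shape <- function(rows, cols) {
  n <- length(rows)
  cx <- mean(cols); cy <- mean(rows)
  # +1/12 per-pixel variance regularizes single-pixel-thin components
  mxx <- sum((cols - cx)^2) / n + 1 / 12
  myy <- sum((rows - cy)^2) / n + 1 / 12
  mxy <- sum((cols - cx) * (rows - cy)) / n
  tr <- mxx + myy
  det2 <- sqrt(max((mxx - myy)^2 + 4 * mxy^2, 0))
  l1 <- (tr + det2) / 2
  l2 <- max((tr - det2) / 2, 1e-9)
  c(x = cx, y = cy, elong = sqrt(l1 / l2), area = n)
}

#' Track worms across a binarized frame stack
#'
#' Connected components (8-connectivity) are detected per frame, filtered
#' by a minimal area, and linked across frames to the nearest open track
#' head. Tracks not extended for more than `max_gap` frames are closed.
#' Each track records the per-frame centroid and a bend signal: the
#' component's normalized elongation (square root of the ratio of its
#' principal second moments), which oscillates as the body bends.
#'
#' @param binary Logical (or 0/1) height x width x n_frames array.
#' @param fps Frames per second.
#' @param min_area Minimal component area in px^2.
#' @param max_gap Maximal number of frames a track may go undetected.
#' @param max_move Maximal centroid displacement per frame for linking (px).
#' @return A list of `worm_track` objects, each with `worm_id`, `frames`
#'   (frame indices), `x`, `y` (centroids), `bend` (elongation signal),
#'   `fps` and `n_frames`. Ties in linking distance resolve to the lower
#'   component label, then the older track.
#' @export
track_worms <- function(binary, fps, min_area = 20, max_gap = 5,
                        max_move = 25) {
  if (!is.array(binary) || length(dim(binary)) != 3)
    stop("binary must be a height x width x n_frames array", call. = FALSE)
  n <- dim(binary)[3]
  h <- dim(binary)[1]
  open_tracks <- list()   # each: list(id, last_frame, x, y, rows...)
  done_tracks <- list()
  next_id <- 1L

  for (f in seq_len(n)) {
    lab <- EBImage::bwlabel(binary[, , f] * 1)
    dets <- list()
    if (max(lab) > 0) {
      pix <- which(lab > 0)
      labv <- lab[pix]
      rows <- (pix - 1L) %% h + 1L
      cols <- (pix - 1L) %/% h + 1L
      for (k in sort(unique(labv))) {
        sel <- labv == k
        if (sum(sel) < min_area) next
        dets[[length(dets) + 1L]] <- component_shape(rows[sel], cols[sel])
      }
    }
    # close stale tracks
    if (length(open_tracks)) {
      stale <- vapply(open_tracks, function(tr) f - tr$last_frame > max_gap,
                      logical(1))
      done_tracks <- c(done_tracks, open_tracks[stale])
      open_tracks <- open_tracks[!stale]
    }
    if (!length(dets)) next
    nd <- length(dets)
    assigned_det <- rep(FALSE, nd)
    if (length(open_tracks)) {
      nt <- length(open_tracks)
      dmat <- matrix(Inf, nt, nd)
      for (i in seq_len(nt)) for (j in seq_len(nd)) {
        gap <- f - open_tracks[[i]]$last_frame
        d <- sqrt((open_tracks[[i]]$x_last - dets[[j]]["x"])^2 +
                    (open_tracks[[i]]$y_last - dets[[j]]["y"])^2)
        if (d <= max_move * gap) dmat[i, j] <- d
      }
      # greedy nearest assignment; ties -> lower component label, older track
      repeat {
        if (all(!is.finite(dmat))) break
        mn <- min(dmat)
        hit <- which(dmat == mn, arr.ind = TRUE)
        hit <- hit[order(hit[, 2], hit[, 1]), , drop = FALSE][1, ]
        i <- hit[1]; j <- hit[2]
        tr <- open_tracks[[i]]
        tr$frames <- c(tr$frames, f)
        tr$x <- c(tr$x, dets[[j]]["x"]); tr$y <- c(tr$y, dets[[j]]["y"])
        tr$bend <- c(tr$bend, dets[[j]]["elong"])
        tr$x_last <- dets[[j]]["x"]; tr$y_last <- dets[[j]]["y"]
        tr$last_frame <- f
        open_tracks[[i]] <- tr
        assigned_det[j] <- TRUE
        dmat[i, ] <- Inf
        dmat[, j] <- Inf
      }
    }
    for (j in which(!assigned_det)) {
      open_tracks[[length(open_tracks) + 1L]] <-
        list(id = next_id, frames = f,
             x = dets[[j]]["x"], y = dets[[j]]["y"],
             bend = dets[[j]]["elong"],
             x_last = dets[[j]]["x"], y_last = dets[[j]]["y"],
             last_frame = f)
      next_id <- next_id + 1L
    }
  }
  done_tracks <- c(done_tracks, open_tracks)
  out <- lapply(done_tracks, function(tr) {
    structure(list(worm_id = tr$id, frames = tr$frames,
                   x = unname(tr$x), y = unname(tr$y),
                   bend = unname(tr$bend), fps = fps,
                   n_frames = length(tr$frames)),
              class = "worm_track")
  })
  out[order(vapply(out, `[[`, integer(1), "worm_id"))]
}

#' @export
print.worm_track <- function(x, ...) {
  cat("<worm_track> id", x$worm_id, "|", x$n_frames, "frames @", x$fps,
      "fps\n")
  invisible(x)
}

#' Count body bends from a tracked worm's bend signal
#'
#' The elongation signal is lightly smoothed (moving average over ~0.1 s),
#' mean-centred, and bends are counted at crossings of zero with a
#' hysteresis band of `hysteresis_frac` times the signal SD. Two crossings
#' make one full bend cycle; BBPS counts side-bends, i.e.
#' `crossings / 2 / duration`. A signal SD below `sd_floor` yields 0 BBPS
#' (immobile worm).
#'
#' @param track A `worm_track` from [track_worms()] spanning at least 1 s.
#' @param genotype Optional genotype label for the record.
#' @param hysteresis_frac Hysteresis half-band as a fraction of signal SD.
#' @param sd_floor Minimal signal SD below which the worm is called
#'   immobile.
#' @param smooth_s Moving-average window in seconds.
#' @return A one-row data frame (class `swimming_record`) with `genotype`,
#'   `animal_id`, `bbps`, `duration_s`.
#' @export
count_body_bends <- function(track, genotype = NA_character_,
                             hysteresis_frac = 0.25, sd_floor = 0.05,
                             smooth_s = 0.1) {
  stopifnot(inherits(track, "worm_track"))
  duration_s <- (max(track$frames) - min(track$frames) + 1) / track$fps
  if (duration_s < 1)
    stop("track too short to count bends (< 1 s)", call. = FALSE)
  s <- track$bend
  w <- max(1L, as.integer(round(track$fps * smooth_s)))
  if (w > 1L && length(s) > w)
    s <- stats::filter(s, rep(1 / w, w), sides = 2)
  s <- s[!is.na(s)]
  s <- s - mean(s)
  sdev <- stats::sd(s)
  bbps <- 0
  if (is.finite(sdev) && sdev >= sd_floor) {
    h <- hysteresis_frac * sdev
    state <- 0L
    crossings <- 0L
    for (v in s) {
      if (v > h) {
        if (state == -1L) crossings <- crossings + 1L
        state <- 1L
      } else if (v < -h) {
        if (state == 1L) crossings <- crossings + 1L
        state <- -1L
      }
    }
    bbps <- (crossings / 2) / duration_s
  }
  structure(data.frame(genotype = genotype, animal_id = track$worm_id,
                       bbps = bbps, duration_s = duration_s,
                       stringsAsFactors = FALSE),
            class = c("swimming_record", "data.frame"))
}

#' Fraction of animals at or below the swimming-defect threshold
#'
#' The defect threshold (default 1.1 BBPS, the corroborated mean swimming
#' rate of lmn-1(Y59C) worms) is compared with "at or below" semantics:
#' ties at the threshold count as defective.
#'
#' @param records A data frame with a `bbps` column, or a numeric vector
#'   of BBPS values, for one genotype.
#' @param threshold Defect threshold in bends/s.
#' @return Fraction in `[0, 1]` of animals with `bbps <= threshold`.
#' @export
defect_fraction <- function(records, threshold = 1.1) {
  v <- if (is.data.frame(records)) records$bbps else records
  if (is.null(v) || !length(v))
    stop("no swimming records supplied", call. = FALSE)
  stopifnot(is.numeric(v), all(is.finite(v)))
  mean(v <= threshold)
}

#' Chi-squared test of swimming-defect fractions against wild type
#'
#' Builds the 2x2 table (defective / non-defective x variant / wild type)
#' at the given BBPS threshold and applies Pearson's chi-squared test
#' without continuity correction. A table with an empty margin (e.g. no
#' defective animal in either group) is degenerate: statistic 0, p = 1,
#' flagged.
#'
#' @param variant_records,wildtype_records Data frames with a `bbps`
#'   column (or numeric BBPS vectors) for the two groups.
#' @param threshold Defect threshold in bends/s.
#' @param alpha Significance level recorded in the result.
#' @param correct Apply Yates continuity correction (default `FALSE`).
#' @return A one-row `stat_result` data frame.
#' @export
swim_defect_test <- function(variant_records, wildtype_records,
                             threshold = 1.1, alpha = 0.05,
                             correct = FALSE) {
  gv <- if (is.data.frame(variant_records))
    unique(variant_records$genotype) else "variant"
  gw <- if (is.data.frame(wildtype_records))
    unique(wildtype_records$genotype) else "wild type"
  v <- if (is.data.frame(variant_records)) variant_records$bbps
       else variant_records
  w <- if (is.data.frame(wildtype_records)) wildtype_records$bbps
       else wildtype_records
  if (!length(v) || !length(w))
    stop("both groups must be non-empty", call. = FALSE)
  tab <- rbind(variant = c(defective = sum(v <= threshold),
                           ok = sum(v > threshold)),
               wildtype = c(defective = sum(w <= threshold),
                            ok = sum(w > threshold)))
  comparison <- paste(gv[1], "vs", gw[1])
  fv <- mean(v <= threshold)
  fw <- mean(w <= threshold)
  if (any(colSums(tab) == 0) || any(rowSums(tab) == 0)) {
    return(stat_result(comparison, estimate = fv - fw, statistic = 0,
                       p_raw = 1, p_adjusted = 1, method = "chi_squared",
                       alpha = alpha, degenerate = TRUE))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  stat_result(comparison, estimate = fv - fw,
              statistic = unname(ct$statistic), p_raw = ct$p.value,
              p_adjusted = ct$p.value, method = "chi_squared",
              alpha = alpha)
}

#' Process a swim-video frame stack into swimming records
#'
#' Convenience wrapper chaining [binarize_frames()], [track_worms()] and
#' [count_body_bends()], keeping only tracks spanning at least
#' `min_track_s` seconds.
#'
#' @param frames height x width x n_frames grey-level array.
#' @param fps Frames per second.
#' @param genotype Genotype label for the records.
#' @param min_track_s Minimal track span (s) to score a worm.
#' @param ... Passed to [binarize_frames()] and [track_worms()].
#' @return A data frame of swimming records, one row per tracked worm.
#' @export
video_to_records <- function(frames, fps, genotype = NA_character_,
                             min_track_s = 5, ...) {
  dots <- list(...)
  bin_args <- dots[names(dots) %in%
                     names(formals(binarize_frames))]
  trk_args <- dots[names(dots) %in% names(formals(track_worms))]
  binary <- do.call(binarize_frames, c(list(frames), bin_args))
  tracks <- do.call(track_worms, c(list(binary, fps = fps), trk_args))
  keep <- vapply(tracks, function(tr) {
    (max(tr$frames) - min(tr$frames) + 1) / fps >= min_track_s
  }, logical(1))
  recs <- lapply(tracks[keep], count_body_bends, genotype = genotype)
  if (!length(recs))
    return(data.frame(genotype = character(), animal_id = integer(),
                      bbps = numeric(), duration_s = numeric()))
  do.call(rbind, lapply(recs, as.data.frame))
}
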