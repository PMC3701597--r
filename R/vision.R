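#' Estimate the static background of a frame sequence
#'
#' Per-pixel temporal median over `window` frames sampled evenly across the
#' sequence. A fish transits the chamber quickly, so any given pixel is
#' foreground in a minority of frames and the median recovers the static
#' background exactly in noise-free input.
#'
#' @param frames list of numeric matrices (same shape).
#' @param window odd integer >= 3; number of frames entering the median.
#'   If fewer frames are available all are used, with a warning.
#' @return numeric matrix, the estimated background.
#' @export
estimate_background <- function(frames, window = 9L) {
  stopifnot(is.list(frames), length(frames) >= 1L)
  if (window < 3L || window %% 2L == 0L)
    stop("window must be an odd integer >= 3")
  n <- length(frames)
  if (n < window) {
    warning("fewer frames (", n, ") than window (", window, "); using all")
    idx <- seq_len(n)
  } else {
    idx <- unique(round(seq(1L, n, length.out = window)))
  }
  cols <- lapply(frames[idx], as.numeric)
  # odd-length vectorised median: full exchange sort over the few columns
  k <- length(cols)
  if (k == 1L) return(frames[[idx]])
  for (i in seq_len(k - 1L)) {
    for (j in seq_len(k - i)) {
      lo <- pmin(cols[[j]], cols[[j + 1L]])
      hi <- pmax(cols[[j]], cols[[j + 1L]])
      cols[[j]] <- lo; cols[[j + 1L]] <- hi
    }
  }
  mid <- if (k %% 2L == 1L) cols[[(k + 1L) %/% 2L]] else
    (cols[[k %/% 2L]] + cols[[k %/% 2L + 1L]]) / 2
  matrix(mid, nrow(frames[[1L]]), ncol(frames[[1L]]))
}

#' Default detector parameters
#'
#' @param gradient_threshold minimum mean boundary gradient magnitude (gray
#'   levels per pixel) for a foreground component to be confirmed as an
#'   object. The gradient across a clean step edge of contrast `C` is about
#'   `C / 2` under 3x3 central differences.
#' @param diff_threshold background-difference threshold (gray levels)
#'   defining candidate foreground support.
#' @param min_area_px,max_area_px admissible component area range.
#' @return named list of parameters.
#' @export
detect_params <- function(gradient_threshold = 20, diff_threshold = 25,
                          min_area_px = 60, max_area_px = 20000) {
  stopifnot(gradient_threshold >= 0, diff_threshold >= 0,
            min_area_px >= 1, max_area_px >= min_area_px)
  list(gradient_threshold = gradient_threshold,
       diff_threshold = diff_threshold,
       min_area_px = min_area_px, max_area_px = max_area_px)
}

#' Detect objects in one frame
#'
#' Segments moving objects by background subtraction: pixels whose absolute
#' difference from the background exceeds `diff_threshold` form the
#' candidate support, which is morphologically closed and hole-filled; each
#' 8-connected component is then confirmed by requiring the mean gradient
#' magnitude of the difference image on the component boundary to exceed
#' `gradient_threshold`, and its area to lie in
#' `[min_area_px, max_area_px]`. The gradient confirmation is what makes
#' detection fade as turbidity flattens silhouette contrast.
#'
#' @param frame,background numeric matrices of equal shape.
#' @param params see [detect_params()].
#' @param frame_index 0-based frame index stored in each detection.
#' @return list of detections sorted by (centroid row, centroid col); each
#'   has `frame_index`, `contour` (closed polygon, 0-based (row, col)),
#'   `bbox` (`c(row0, col0, row1, col1)`, half-open, 0-based), `centroid`,
#'   `area_px`, `mean_intensity`, and the component's pixel `mask` cropped
#'   to its bounding box (frame position in `mask_offset`, 0-based).
#' @export
detect_objects <- function(frame, background, params = detect_params(),
                           frame_index = 0L) {
  stopifnot(all(dim(frame) == dim(background)))
  d <- frame - background
  support <- abs(d) > params$diff_threshold
  if (!any(support)) return(list())
  support <- binary_close(support, 1L)
  lab <- label_components(support, 8L)
  n_comp <- max(lab)
  if (n_comp == 0L) return(list())
  g <- gradient_magnitude(d)
  nr <- nrow(frame); nc <- ncol(frame)
  comp_idx <- split(which(lab > 0L), lab[lab > 0L])
  out <- list()
  for (idx_lin in comp_idx) {
    # quick reject before the (per-component) hole fill
    if (length(idx_lin) > params$max_area_px) next
    rr <- ((idx_lin - 1L) %% nr) + 1L
    cc <- ((idx_lin - 1L) %/% nr) + 1L
    r0 <- max(1L, min(rr) - 1L); r1 <- min(nr, max(rr) + 1L)
    c0 <- max(1L, min(cc) - 1L); c1 <- min(nc, max(cc) + 1L)
    sub <- matrix(FALSE, r1 - r0 + 1L, c1 - c0 + 1L)
    sub[cbind(rr - r0 + 1L, cc - c0 + 1L)] <- TRUE
    sub <- fill_holes(sub)
    area <- sum(sub)
    if (area < params$min_area_px || area > params$max_area_px) next
    bnd <- boundary_mask(sub)
    gsub <- g[r0:r1, c0:c1, drop = FALSE]
    if (mean(gsub[bnd]) < params$gradient_threshold) next
    sidx <- which(sub, arr.ind = TRUE)
    r <- sidx[, 1L] + r0 - 2L   # 0-based frame coordinates
    c <- sidx[, 2L] + c0 - 2L
    centroid <- c(row = mean(r), col = mean(c))
    bbox <- c(row0 = min(r), col0 = min(c), row1 = max(r) + 1,
              col1 = max(c) + 1)
    cl <- contourLines(x = (r0:r1) - 1, y = (c0:c1) - 1,
                       z = sub * 1, levels = 0.5)
    contour <- if (length(cl)) {
      longest <- cl[[which.max(vapply(cl, function(l) length(l$x), 0))]]
      cbind(row = longest$x, col = longest$y)
    } else cbind(row = r, col = c)
    fsub <- frame[r0:r1, c0:c1, drop = FALSE]
    out[[length(out) + 1L]] <- structure(
      list(frame_index = as.integer(frame_index), contour = contour,
           bbox = bbox, centroid = centroid, area_px = as.integer(area),
           mean_intensity = mean(fsub[sub]),
           mask = sub, mask_offset = c(r0 - 1L, c0 - 1L)),
      class = "detection")
  }
  if (length(out) > 1L) {
    ord <- order(vapply(out, function(x) x$centroid[1L], 0),
                 vapply(out, function(x) x$centroid[2L], 0))
    out <- out[ord]
  }
  out
}

#' Detect objects in every frame of a sequence
#'
#' Convenience wrapper: estimates the background once with
#' [estimate_background()] and runs [detect_objects()] per frame.
#'
#' @inheritParams estimate_background
#' @inheritParams detect_objects
#' @return list (one element per frame) of detection lists.
#' @export
detect_sequence <- function(frames, params = detect_params(), window = 9L) {
  bg <- estimate_background(frames, window)
  lapply(seq_along(frames), function(i)
    detect_objects(frames[[i]], bg, params, frame_index = i - 1L))
}

#' Default tracker parameters
#'
#' @param gating_px maximum distance between a track's predicted centroid
#'   and a detection for association. The default allows a fish to transit
#'   the full-size chamber (1600 px) in about half a second at 60 fps.
#' @param max_gap_frames number of consecutive frames a track may go
#'   undetected before it is terminated.
#' @param min_track_length minimum number of detections for a track to be
#'   kept (suppresses transient noise blobs).
#' @return named list of parameters.
#' @export
track_params <- function(gating_px = 60, max_gap_frames = 2L,
                         min_track_length = 3L) {
  stopifnot(gating_px > 0, max_gap_frames >= 0, min_track_length >= 1)
  list(gating_px = gating_px, max_gap_frames = as.integer(max_gap_frames),
       min_track_length = as.integer(min_track_length))
}

#' Link per-frame detections into tracks
#'
#' Constant-velocity nearest-neighbour association: each open track
#' predicts its next centroid from its last position and velocity;
#' detections within `gating_px` of a prediction are assigned greedily by
#' smallest distance (ties broken by lowest track id). Unassigned
#' detections open new tracks; tracks unseen for more than
#' `max_gap_frames` are closed; tracks shorter than `min_track_length`
#' are discarded.
#'
#' @param detections list of per-frame detection lists (as returned by
#'   [detect_sequence()]), or a flat list of detections carrying
#'   `frame_index`.
#' @param params see [track_params()].
#' @return list of tracks; each has `track_id`, `detections` (strictly
#'   increasing `frame_index`), `first_frame`, `last_frame`.
#' @export
link_tracks <- function(detections, params = track_params()) {
  if (length(detections) && inherits(detections[[1L]], "detection")) {
    fidx <- vapply(detections, function(d) d$frame_index, 0L)
    frames_idx <- sort(unique(fidx))
    detections <- lapply(frames_idx, function(f) detections[fidx == f])
    frame_no <- frames_idx
  } else {
    frame_no <- vapply(seq_along(detections), function(i) {
      dl <- detections[[i]]
      if (length(dl)) dl[[1L]]$frame_index else i - 1L
    }, 0L)
  }
  active <- list()   # each: id, dets, last_pos, vel, last_frame
  done <- list()
  next_id <- 1L
  for (k in seq_along(detections)) {
    t <- frame_no[k]
    dets <- detections[[k]]
    # retire stale tracks
    if (length(active)) {
      stale <- vapply(active, function(tr) t - tr$last_frame >
                        params$max_gap_frames + 1L, TRUE)
      done <- c(done, active[stale])
      active <- active[!stale]
    }
    n_tr <- length(active); n_de <- length(dets)
    assigned_de <- rep(FALSE, n_de)
    if (n_tr > 0L && n_de > 0L) {
      pred <- t(vapply(active, function(tr)
        tr$last_pos + tr$vel * (t - tr$last_frame), numeric(2)))
      dpos <- t(vapply(dets, function(d) unname(d$centroid), numeric(2)))
      dist <- sqrt(outer(pred[, 1L], dpos[, 1L], "-")^2 +
                   outer(pred[, 2L], dpos[, 2L], "-")^2)
      ids <- vapply(active, function(tr) tr$id, 0L)
      assigned_tr <- rep(FALSE, n_tr)
      repeat {
        dist_ok <- dist
        dist_ok[assigned_tr, ] <- Inf
        dist_ok[, assigned_de] <- Inf
        m <- min(dist_ok)
        if (!is.finite(m) || m > params$gating_px) break
        cand <- which(dist_ok == m, arr.ind = TRUE)
        # ties: smallest distance already equal; break by lowest track id
        pick <- cand[order(ids[cand[, 1L]])[1L], , drop = TRUE]
        ti <- pick[1L]; di <- pick[2L]
        tr <- active[[ti]]
        new_pos <- unname(dets[[di]]$centroid)
        dt <- t - tr$last_frame
        tr$vel <- (new_pos - tr$last_pos) / dt
        tr$last_pos <- new_pos
        tr$last_frame <- t
        tr$dets[[length(tr$dets) + 1L]] <- dets[[di]]
        active[[ti]] <- tr
        assigned_tr[ti] <- TRUE
        assigned_de[di] <- TRUE
        if (all(assigned_tr) || all(assigned_de)) break
      }
    }
    for (di in which(!assigned_de)) {
      active[[length(active) + 1L]] <- list(
        id = next_id, dets = list(dets[[di]]),
        last_pos = unname(dets[[di]]$centroid), vel = c(0, 0),
        last_frame = t)
      next_id <- next_id + 1L
    }
  }
  done <- c(done, active)
  done <- Filter(function(tr) length(tr$dets) >= params$min_track_length, done)
  done <- done[order(vapply(done, function(tr) tr$id, 0L))]
  lapply(seq_along(done), function(i) {
    tr <- done[[i]]
    fidx <- vapply(tr$dets, function(d) d$frame_index, 0L)
    structure(list(track_id = tr$id, detections = tr$dets,
                   first_frame = min(fidx), last_frame = max(fidx)),
              class = "track")
  })
}

#' Count fish passages
#'
#' Each track is one physical passage through the chamber, so the count is
#' simply the number of tracks. If a passage is broken by a gap longer than
#' `max_gap_frames` it is counted twice; this over-count mode is inherent
#' to per-track counting.
#'
#' @param tracks list of tracks from [link_tracks()].
#' @return integer count.
#' @export
count_passages <- function(tracks) length(tracks)

#' @export
print.track <- function(x, ...) {
  cat(sprintf("Track %d: frames %d-%d, %d detections\n", x$track_id,
              x$first_frame, x$last_frame, length(x$detections)))
  invisible(x)
}

#' Serialize tracks to JSON
#'
#' Schema version 1: per track id, frame span and per-detection centroid,
#' bbox, area and mean intensity (contours and pixel masks are not
#' persisted).
#'
#' @param tracks list of tracks.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  obj <- list(schema = "fishpass/tracks/v1",
              tracks = lapply(tracks, function(tr) list(
                track_id = tr$track_id, first_frame = tr$first_frame,
                last_frame = tr$last_frame,
                detections = lapply(tr$detections, function(d) list(
                  frame_index = d$frame_index,
                  centroid = unname(d$centroid), bbox = unname(d$bbox),
                  area_px = d$area_px, mean_intensity = d$mean_intensity)))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read tracks written by [write_tracks()]
#' @param path JSON file.
#' @return list of tracks (without pixel masks or contours).
#' @export
read_tracks <- function(path) {
  obj <- jsonlite::read_json(path)
  if (!identical(obj$schema, "fishpass/tracks/v1"))
    stop("unrecognised tracks schema")
  lapply(obj$tracks, function(tr) {
    dets <- lapply(tr$detections, function(d) structure(list(
      frame_index = as.integer(d$frame_index),
      centroid = c(row = d$centroid[[1L]], col = d$centroid[[2L]]),
      bbox = unlist(d$bbox), area_px = as.integer(d$area_px),
      mean_intensity = d$mean_intensity), class = "detection"))
    structure(list(track_id = as.integer(tr$track_id), detections = dets,
                   first_frame = as.integer(tr$first_frame),
                   last_frame = as.integer(tr$last_frame)),
              class = "track")
  })
}
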