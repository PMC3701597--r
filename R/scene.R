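#' Specify a synthetic viewing-chamber scene
#'
#' Describes a grayscale video of fish-like silhouettes crossing a fixed
#' viewing chamber: frame geometry, the fish present with their entry
#' frames and straight-line trajectories, turbidity, sensor noise and the
#' RNG seed. The default geometry matches the field camera (1600 x 1200
#' pixels at 60 frames per second); test suites typically use a scaled-down
#' chamber.
#'
#' @param frame_shape integer vector `(rows, cols)`.
#' @param frame_rate_hz frames per second.
#' @param duration_s scene duration in seconds; the frame count is
#'   `round(duration_s * frame_rate_hz)`.
#' @param fish list of fish entries, each a list with fields `spec`
#'   (a [species_shape_spec()]), `entry_frame` (0-based frame index),
#'   `entry_point` (`c(row, col)` of the body centre at the entry frame),
#'   `velocity` (`c(drow, dcol)` pixels per frame) and `orientation_deg`.
#' @param turbidity_ntu turbidity in NTU (>= 0). Foreground/background
#'   contrast is attenuated by `exp(-0.02 * NTU)` and the noise standard
#'   deviation grows by 0.15 gray levels per NTU, calibrated so detection
#'   with default parameters collapses near 80 NTU.
#' @param noise_sd baseline Gaussian pixel noise SD (gray levels) at 0 NTU.
#' @param background_level background gray level.
#' @param seed integer; fully determines the rendered frames.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(frame_shape = c(1200L, 1600L), frame_rate_hz = 60,
                       duration_s = 1, fish = list(), turbidity_ntu = 0,
                       noise_sd = 0, background_level = 40, seed = 1L) {
  stopifnot(length(frame_shape) == 2L, all(frame_shape >= 16),
            frame_rate_hz > 0, duration_s > 0, turbidity_ntu >= 0,
            noise_sd >= 0, background_level >= 0, background_level <= 255)
  for (f in fish) {
    stopifnot(is.list(f), inherits(f$spec, "species_shape_spec"),
              length(f$entry_point) == 2L, length(f$velocity) == 2L)
    if (is.null(f$entry_frame)) stop("fish entry_frame missing")
    if (is.null(f$orientation_deg)) stop("fish orientation_deg missing")
  }
  structure(list(frame_shape = as.integer(frame_shape),
                 frame_rate_hz = frame_rate_hz, duration_s = duration_s,
                 fish = fish, turbidity_ntu = turbidity_ntu,
                 noise_sd = noise_sd, background_level = background_level,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# Turbidity model constants: contrast attenuation per NTU and noise growth
# (gray levels of additional SD per NTU).
TURBIDITY_ATTENUATION <- 0.02
TURBIDITY_NOISE_SLOPE <- 0.15

#' Render a scene to frames plus ground truth
#'
#' Rasterises every fish along its trajectory, attenuates the
#' foreground/background contrast by `exp(-0.02 * turbidity_ntu)`, adds
#' Gaussian pixel noise with SD `noise_sd + 0.15 * turbidity_ntu`, and
#' clips to `[0, 255]`. The returned ground truth carries one track per
#' fish (frames where any part of the silhouette is inside the chamber,
#' with per-frame centroids) and per-species scene totals.
#'
#' @param scene a [scene_spec()].
#' @param labels if `TRUE`, also return per-frame label masks (integer
#'   matrices; 0 background, fish numbered as in `scene$fish`).
#' @return list with elements `frames` (list of numeric matrices),
#'   `ground_truth` (class `ground_truth`: `fish` = per-fish list with
#'   `species`, `frames` (0-based), `centroids` (n x 2, 0-based row/col);
#'   `totals` = named per-species counts) and optionally `labels`.
#' @export
render_scene <- function(scene, labels = FALSE) {
  stopifnot(inherits(scene, "scene_spec"))
  nr <- scene$frame_shape[1L]; nc <- scene$frame_shape[2L]
  n_frames <- round(scene$duration_s * scene$frame_rate_hz)
  atten <- exp(-TURBIDITY_ATTENUATION * scene$turbidity_ntu)
  sd_tot <- scene$noise_sd +
    if (scene$noise_sd > 0) TURBIDITY_NOISE_SLOPE * scene$turbidity_ntu else 0
  bg <- scene$background_level

  sil <- lapply(scene$fish, function(f)
    species_silhouette(f$spec, f$orientation_deg, scale = 1))
  gt_fish <- lapply(scene$fish, function(f)
    list(species = f$spec$name, frames = integer(0),
         centroids = matrix(numeric(0), 0, 2,
                            dimnames = list(NULL, c("row", "col")))))

  frames <- vector("list", n_frames)
  lab_frames <- if (labels) vector("list", n_frames) else NULL

  with_seed(scene$seed, {
    for (t in seq_len(n_frames) - 1L) {
      fr <- matrix(bg, nr, nc)
      lab <- if (labels) matrix(0L, nr, nc) else NULL
      for (i in seq_along(scene$fish)) {
        f <- scene$fish[[i]]
        ctr <- f$entry_point + (t - f$entry_frame) * f$velocity
        m <- sil[[i]]
        mr <- nrow(m); mc <- ncol(m)
        top <- round(ctr[1L] - (mr - 1) / 2)   # 0-based top-left of mask
        left <- round(ctr[2L] - (mc - 1) / 2)
        rr <- max(0L, top):min(nr - 1L, top + mr - 1L)
        cc <- max(0L, left):min(nc - 1L, left + mc - 1L)
        if (length(rr) < 1L || length(cc) < 1L ||
            rr[1L] > rr[length(rr)] || cc[1L] > cc[length(cc)]) next
        sub <- m[rr - top + 1L, cc - left + 1L, drop = FALSE]
        if (!any(sub)) next
        fg_val <- bg + (f$spec$intensity - bg) * atten
        block <- fr[rr + 1L, cc + 1L, drop = FALSE]
        block[sub] <- fg_val
        fr[rr + 1L, cc + 1L] <- block
        if (labels) {
          lblock <- lab[rr + 1L, cc + 1L, drop = FALSE]
          lblock[sub] <- i
          lab[rr + 1L, cc + 1L] <- lblock
        }
        vis <- which(sub, arr.ind = TRUE)
        cen <- c(mean(vis[, 1L] - 1 + rr[1L]), mean(vis[, 2L] - 1 + cc[1L]))
        gt_fish[[i]]$frames <- c(gt_fish[[i]]$frames, t)
        gt_fish[[i]]$centroids <- rbind(gt_fish[[i]]$centroids, cen,
                                        deparse.level = 0)
      }
      if (sd_tot > 0) fr <- fr + matrix(rnorm(nr * nc, 0, sd_tot), nr, nc)
      frames[[t + 1L]] <- pmin(pmax(fr, 0), 255)
      if (labels) lab_frames[[t + 1L]] <- lab
    }
  })

  present <- vapply(gt_fish, function(g) length(g$frames) > 0L, TRUE)
  species <- vapply(gt_fish, function(g) g$species, "")
  totals <- if (length(species[present]))
    table(factor(species[present])) else table(factor(character(0)))
  gt <- structure(list(fish = gt_fish,
                       totals = setNames(as.integer(totals), names(totals))),
                  class = "ground_truth")
  out <- list(frames = frames, ground_truth = gt)
  if (labels) out$labels <- lab_frames
  out
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Ground truth:", length(x$fish), "fish\n")
  if (length(x$totals)) {
    for (s in names(x$totals)) cat(sprintf("  %s: %d\n", s, x$totals[[s]]))
  }
  invisible(x)
}

#' Write a rendered scene to a frame directory
#'
#' Frames are written as zero-padded grayscale PNG files
#' (`frame_000000.png`, ...), scene metadata as `scene.json`, ground truth
#' as `ground_truth.json` and, when present, label masks as
#' `label_000000.png` (component id stored in the gray value).
#'
#' @param rendered result of [render_scene()].
#' @param dir output directory (created if needed).
#' @param scene the [scene_spec()] used, for the metadata sidecar.
#' @return `dir`, invisibly.
#' @export
write_scene <- function(rendered, dir, scene = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(rendered$frames)) {
    png::writePNG(rendered$frames[[i]] / 255,
                  file.path(dir, sprintf("frame_%06d.png", i - 1L)))
  }
  if (!is.null(rendered$labels)) {
    for (i in seq_along(rendered$labels)) {
      png::writePNG(rendered$labels[[i]] / 255,
                    file.path(dir, sprintf("label_%06d.png", i - 1L)))
    }
  }
  meta <- list(n_frames = length(rendered$frames),
               shape = dim(rendered$frames[[1L]]))
  if (!is.null(scene)) {
    meta$frame_rate_hz <- scene$frame_rate_hz
    meta$seed <- scene$seed
    meta$turbidity_ntu <- scene$turbidity_ntu
    meta$background_level <- scene$background_level
  }
  jsonlite::write_json(meta, file.path(dir, "scene.json"), auto_unbox = TRUE)
  gt <- rendered$ground_truth
  gt_json <- list(
    totals = as.list(gt$totals),
    fish = lapply(gt$fish, function(g)
      list(species = g$species, frames = g$frames,
           centroids = unname(g$centroids))))
  jsonlite::write_json(gt_json, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a frame directory written by [write_scene()]
#'
#' @param dir directory containing `frame_*.png` and `scene.json`.
#' @return list with `frames` (numeric matrices on the 0-255 scale),
#'   `meta`, and `ground_truth` if `ground_truth.json` is present.
#' @export
read_scene <- function(dir) {
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.png$",
                           full.names = TRUE))
  if (!length(files)) stop("no frame_*.png files in ", dir)
  frames <- lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    img * 255
  })
  meta_path <- file.path(dir, "scene.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else NULL
  out <- list(frames = frames, meta = meta)
  gt_path <- file.path(dir, "ground_truth.json")
  if (file.exists(gt_path)) {
    gj <- jsonlite::read_json(gt_path, simplifyVector = TRUE)
    fish <- lapply(seq_len(nrow_or_len(gj$fish)), function(i) {
      g <- if (is.data.frame(gj$fish)) gj$fish[i, ] else gj$fish[[i]]
      cen <- g$centroids
      if (is.list(cen)) cen <- do.call(rbind, cen)
      # a fish that never entered the frame has no centroids at all
      cen <- if (is.null(cen) || !length(cen))
        matrix(numeric(0), 0L, 2L, dimnames = list(NULL, c("row", "col")))
      else matrix(unlist(cen), ncol = 2,
                  dimnames = list(NULL, c("row", "col")))
      list(species = as.character(g$species),
           frames = as.integer(unlist(g$frames)), centroids = cen)
    })
    totals <- unlist(gj$totals)
    out$ground_truth <- structure(
      list(fish = fish,
           totals = setNames(as.integer(totals), names(totals))),
      class = "ground_truth")
  }
  out
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
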