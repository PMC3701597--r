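# Silhouette shape descriptors: the feature set used by the species
# identifier. All descriptors operate on binary masks [row, col]; see the
# package help for the coordinate conventions.

#' Hu invariant moments of a silhouette
#'
#' The seven algebraic moment invariants computed from normalized central
#' moments; invariant to translation exactly, and to rotation and scale up
#' to rasterization. By default each invariant `h` is reported as
#' `sign(h) * log10(|h| + eps)` to tame the dynamic range for the
#' classifier.
#'
#' @param mask non-empty logical matrix.
#' @param transform `"signed_log"` (default) or `"none"` (raw invariants).
#' @param eps offset inside the log transform.
#' @return numeric vector of length 7 (`hu1` ... `hu7`).
#' @export
hu_moments <- function(mask, transform = c("signed_log", "none"),
                       eps = 1e-30) {
  transform <- match.arg(transform)
  if (!any(mask)) stop("mask is empty")
  mm <- mask_moments(mask)
  m00 <- mm$m00
  eta <- function(mu, p, q) mu / m00^(1 + (p + q) / 2)
  n20 <- eta(mm$mu20, 2, 0); n02 <- eta(mm$mu02, 0, 2)
  n11 <- eta(mm$mu11, 1, 1)
  n30 <- eta(mm$mu30, 3, 0); n03 <- eta(mm$mu03, 0, 3)
  n21 <- eta(mm$mu21, 2, 1); n12 <- eta(mm$mu12, 1, 2)
  a <- n30 + n12; b <- n21 + n03
  c1 <- n30 - 3 * n12; d1 <- 3 * n21 - n03
  h <- c(
    n20 + n02,
    (n20 - n02)^2 + 4 * n11^2,
    c1^2 + d1^2,
    a^2 + b^2,
    c1 * a * (a^2 - 3 * b^2) + d1 * b * (3 * a^2 - b^2),
    (n20 - n02) * (a^2 - b^2) + 4 * n11 * a * b,
    d1 * a * (a^2 - 3 * b^2) - c1 * b * (3 * a^2 - b^2))
  names(h) <- paste0("hu", 1:7)
  if (transform == "signed_log") sign(h) * log10(abs(h) + eps) else h
}

#' Aspect ratio of a silhouette
#'
#' Ratio of major to minor axis lengths of the inertia-equivalent ellipse
#' (from the second central moments); always >= 1 and invariant to
#' position, orientation and scale.
#'
#' @param mask non-empty logical matrix with at least 2 px extent on both
#'   principal axes.
#' @return scalar >= 1.
#' @export
aspect_ratio <- function(mask) {
  if (!any(mask)) stop("mask is empty")
  idx <- which(mask, arr.ind = TRUE)
  if (diff(range(idx[, 1L])) < 1L && diff(range(idx[, 2L])) < 1L)
    stop("degenerate mask: needs >= 2 px extent")
  ax <- mask_axes(mask_moments(mask))
  if (ax$lambda2 <= 0) stop("degenerate mask: zero minor-axis variance")
  sqrt(ax$lambda1 / ax$lambda2)
}

#' Defect from the best-fitting ellipse
#'
#' Area of the symmetric difference between the mask and its moment-fitted
#' ellipse (same centroid, orientation and axis ratio, equal area), divided
#' by the mask area. Zero for a perfect ellipse (up to rasterization);
#' bounded by 2.
#'
#' @param mask non-empty logical matrix.
#' @return scalar in `[0, 2]`.
#' @export
ellipse_defect <- function(mask) {
  if (!any(mask)) stop("mask is empty")
  mm <- mask_moments(mask)
  ax <- mask_axes(mm)
  ratio <- if (ax$lambda2 > 0) sqrt(ax$lambda1 / ax$lambda2) else 1
  # equal-area ellipse: pi * a * b = m00, a / b = ratio
  b <- sqrt(mm$m00 / (pi * ratio))
  a <- ratio * b
  th <- ax$angle_deg * pi / 180
  idx <- which(mask, arr.ind = TRUE)
  pad <- ceiling(a) + 2L
  r_rng <- (min(idx[, 1L]) - pad):(max(idx[, 1L]) + pad)
  c_rng <- (min(idx[, 2L]) - pad):(max(idx[, 2L]) + pad)
  co <- rep(c_rng, each = length(r_rng)) - 1   # 0-based
  ro <- rep(r_rng, times = length(c_rng)) - 1
  dx <- co - mm$xc
  dy <- -ro - mm$yc          # y axis points up
  u <- dx * cos(th) + dy * sin(th)
  w <- -dx * sin(th) + dy * cos(th)
  in_ell <- (u / a)^2 + (w / b)^2 <= 1
  in_mask <- ro >= 0 & ro <= (nrow(mask) - 1) & co >= 0 & co <= (ncol(mask) - 1)
  in_mask[in_mask] <- mask[cbind(ro[in_mask] + 1, co[in_mask] + 1)]
  sum(xor(in_ell, in_mask)) / mm$m00
}

#' Radial outline pattern of a silhouette
#'
#' Distance from the centroid to the silhouette boundary sampled at `B`
#' equally spaced angles starting from the major axis, divided by the mean
#' radius. Scale-invariant, and rotation-invariant up to the major-axis
#' alignment. This is a reconstruction of a rotation-normalized radial
#' signature; the original system's exact form is not public.
#'
#' @param mask non-empty logical matrix.
#' @param B number of angular samples (>= 8).
#' @return numeric vector of length `B`.
#' @export
radial_pattern <- function(mask, B = 32L) {
  if (!any(mask)) stop("mask is empty")
  if (B < 8L) stop("B must be >= 8")
  mm <- mask_moments(mask)
  ax <- mask_axes(mm)
  th0 <- ax$angle_deg * pi / 180
  # the principal axis is only defined up to a half-turn; orient it by the
  # sign of the third moment along the body, as the template normalizer does,
  # so the first ray always leaves from the same end of the fish
  idx <- which(mask, arr.ind = TRUE)
  u <- ((idx[, 2L] - 1) - mm$xc) * cos(th0) +
    (-(idx[, 1L] - 1) - mm$yc) * sin(th0)
  if (sum(u^3) > 0) th0 <- th0 + pi
  r0 <- mm$centroid[1L]; c0 <- mm$centroid[2L]
  rmax <- sqrt(nrow(mask)^2 + ncol(mask)^2)
  steps <- seq(0, rmax, by = 0.4)
  rad <- numeric(B)
  for (b in seq_len(B)) {
    th <- th0 + 2 * pi * (b - 1) / B
    rr <- r0 - steps * sin(th)          # up = decreasing row
    cc <- c0 + steps * cos(th)
    ri <- round(rr) + 1; ci <- round(cc) + 1
    ok <- ri >= 1 & ri <= nrow(mask) & ci >= 1 & ci <= ncol(mask)
    inside <- rep(FALSE, length(steps))
    inside[ok] <- mask[cbind(ri[ok], ci[ok])]
    hit <- which(inside)
    rad[b] <- if (length(hit)) steps[max(hit)] else 0
  }
  rad / mean(rad)
}

#' Build a normalized species template
#'
#' Renders (or accepts) a silhouette, rotates it so the major axis is
#' horizontal with the head at the left (disambiguated by the sign of the
#' third moment along the body axis), resamples its occupancy onto a fixed
#' grid, and standardizes to zero mean and unit variance. All templates
#' share the grid shape and normalization, so the RMS difference between
#' any two normalized images is directly comparable.
#'
#' @param spec a [species_shape_spec()], or `NULL` if `mask` is given.
#' @param mask optional silhouette mask to normalize instead of rendering
#'   `spec`.
#' @param shape template grid `(rows, cols)`, default 64 x 128.
#' @return object of class `species_template` with fields `species`,
#'   `image` (standardized matrix) and `shape`.
#' @export
species_template <- function(spec = NULL, mask = NULL,
                             shape = c(64L, 128L)) {
  if (is.null(mask)) {
    stopifnot(inherits(spec, "species_shape_spec"))
    mask <- species_silhouette(spec, 0, 1)
  }
  name <- if (!is.null(spec)) spec$name else "template"
  img <- normalize_silhouette(mask, shape = shape)
  structure(list(species = name, image = img, shape = as.integer(shape)),
            class = "species_template")
}

#' Default species templates
#' @param shape template grid shape.
#' @return named list of [species_template()] objects for
#'   [default_species()].
#' @export
default_templates <- function(shape = c(64L, 128L)) {
  lapply(default_species(), species_template, shape = shape)
}

# Rotate a silhouette so its major axis is horizontal (head left),
# resample occupancy (or a masked intensity image) to `shape`, and
# standardize. Returns the standardized matrix.
normalize_silhouette <- function(mask, image = NULL, shape = c(64L, 128L)) {
  mm <- mask_moments(mask)
  ax <- mask_axes(mm)
  th <- ax$angle_deg * pi / 180
  idx <- which(mask, arr.ind = TRUE)
  dx <- (idx[, 2L] - 1) - mm$xc
  dy <- -(idx[, 1L] - 1) - mm$yc
  u <- dx * cos(th) + dy * sin(th)
  w <- -dx * sin(th) + dy * cos(th)
  if (sum(u^3) > 0) { u <- -u; w <- -w; th <- th + pi }  # head left
  mu <- range(u); mw <- range(w)
  pad_u <- 0.03 * diff(mu); pad_w <- 0.03 * diff(mw)
  mu <- mu + c(-pad_u, pad_u); mw <- mw + c(-pad_w, pad_w)
  nr_t <- shape[1L]; nc_t <- shape[2L]
  uu <- mu[1L] + (rep(seq_len(nc_t), each = nr_t) - 0.5) / nc_t * diff(mu)
  ww <- mw[2L] - (rep(seq_len(nr_t), times = nc_t) - 0.5) / nr_t * diff(mw)
  # back to source (row, col): x = xc + u cos - w sin ; y = yc + u sin + w cos
  sx <- mm$xc + uu * cos(th) - ww * sin(th)
  sy <- mm$yc + uu * sin(th) + ww * cos(th)
  src <- if (is.null(image)) mask * 1 else image * (mask * 1)
  vals <- bilinear_sample(src, rows = -sy, cols = sx, fill = 0)
  out <- matrix(vals, nr_t, nc_t)
  s <- sd(as.numeric(out))
  if (!is.finite(s) || s < 1e-8)
    stop("degenerate normalization: zero variance over template grid")
  (out - mean(out)) / s
}

#' RMS deviation from a normalized species template
#'
#' Normalizes the object silhouette exactly as templates are built
#' ([species_template()]) and returns the root-mean-square pixel
#' difference over the template grid, minimized over the mirror
#' reflections that the orientation normalization cannot fix. Two
#' standardized images that differ only in sign give RMS 2; identical
#' images give 0.
#'
#' @param object either a `species_template` (compared directly) or an
#'   intensity image (may be `NULL` to use occupancy only).
#' @param mask silhouette mask (ignored when `object` is a template).
#' @param template a [species_template()].
#' @return scalar >= 0.
#' @export
template_rms <- function(object, mask = NULL, template) {
  stopifnot(inherits(template, "species_template"))
  if (inherits(object, "species_template")) {
    # already normalized: compare directly, no reflection search
    return(sqrt(mean((object$image - template$image)^2)))
  }
  if (is.null(mask)) stop("mask required")
  norm <- normalize_silhouette(mask, image = object,
                               shape = template$shape)
  cands <- list(norm,
                norm[nrow(norm):1, , drop = FALSE],
                norm[, ncol(norm):1, drop = FALSE],
                norm[nrow(norm):1, ncol(norm):1, drop = FALSE])
  min(vapply(cands, function(m)
    sqrt(mean((m - template$image)^2)), 0))
}

#' Assemble the full shape feature vector
#'
#' Combines object size (pixel area), the seven log-transformed Hu
#' moments, aspect ratio, ellipse defect, the RMS deviation from each
#' species template, and the radial outline pattern.
#'
#' @param image intensity image, or `NULL` to use occupancy only.
#' @param mask silhouette mask.
#' @param templates non-empty list of [species_template()] objects.
#' @param B radial pattern resolution.
#' @return object of class `fish_features`: a named numeric vector with
#'   components `area_px`, `hu1..hu7`, `aspect_ratio`, `ellipse_defect`,
#'   `rms_<species>` per template, `rad_1..rad_B`.
#' @export
feature_vector <- function(image = NULL, mask, templates, B = 32L) {
  if (!length(templates)) stop("at least one template required")
  hu <- hu_moments(mask)
  rms <- vapply(templates, function(tp) template_rms(image, mask, tp), 0)
  species <- vapply(templates, function(tp) tp$species, "")
  rad <- radial_pattern(mask, B)
  v <- c(area_px = sum(mask), hu,
         aspect_ratio = aspect_ratio(mask),
         ellipse_defect = ellipse_defect(mask),
         setNames(rms, paste0("rms_", species)),
         setNames(rad, paste0("rad_", seq_len(B))))
  structure(v, class = c("fish_features", "numeric"))
}

#' Feature matrix for a set of tracks
#'
#' For each track picks its best silhouette (the largest detection whose
#' bounding box does not touch the frame border, falling back to the
#' largest overall) and computes [feature_vector()] from the detection's
#' pixel mask.
#'
#' @param tracks list of tracks from [link_tracks()] whose detections
#'   retain pixel masks.
#' @param templates list of [species_template()] objects.
#' @param frame_shape `(rows, cols)` of the frames, used to detect
#'   border-clipped silhouettes; `NULL` disables the border check.
#' @param B radial pattern resolution.
#' @return matrix with one row per track (rownames = track ids).
#' @export
track_features <- function(tracks, templates, frame_shape = NULL, B = 32L) {
  rows <- lapply(tracks, function(tr) {
    dets <- tr$detections
    if (!is.null(frame_shape)) {
      interior <- vapply(dets, function(d)
        d$bbox[1L] > 0 && d$bbox[2L] > 0 &&
          d$bbox[3L] < frame_shape[1L] && d$bbox[4L] < frame_shape[2L], TRUE)
      if (any(interior)) dets <- dets[interior]
    }
    areas <- vapply(dets, function(d) d$area_px, 0L)
    d <- dets[[which.max(areas)]]
    if (is.null(d$mask)) stop("track detections carry no pixel masks")
    unclass(feature_vector(NULL, trim_mask(d$mask), templates, B))
  })
  m <- do.call(rbind, rows)
  rownames(m) <- vapply(tracks, function(tr) as.character(tr$track_id), "")
  m
}

#' Write a feature matrix to CSV
#' @param features matrix from [track_features()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(features, path) {
  df <- data.frame(track_id = rownames(features), features,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
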