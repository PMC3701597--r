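#' Describe a fish-like silhouette
#'
#' A `species_shape_spec` parameterises a 2-D fish silhouette: a tapered
#' body outline plus a set of fins attached along the body. The defaults in
#' [default_species()] are chosen so that look-alike estuarine species
#' (a slender smelt, two deeper-bodied shads) are separable by silhouette
#' detail alone — for example the small adipose fin of a smelt, or the
#' trailing dorsal-fin thread of a threadfin shad.
#'
#' @param name species label.
#' @param body_length_px body length in pixels (snout to caudal peduncle),
#'   must be positive.
#' @param body_aspect ratio of body length to maximum body depth; must
#'   exceed 1.
#' @param fin_profile list of fins, each a list with fields `anchor`
#'   (position along the body in `[0, 1]`, 0 = snout), `extent` (fin height
#'   as a fraction of body depth, in `[0, 0.5]`) and `kind` (one of
#'   `"dorsal"`, `"adipose"`, `"anal"`, `"caudal"`, `"thread"`). Anchors
#'   must be strictly increasing.
#' @param intensity mean foreground gray level in `[0, 255]`.
#' @return an object of class `species_shape_spec`.
#' @seealso [species_silhouette()], [default_species()]
#' @export
species_shape_spec <- function(name, body_length_px, body_aspect,
                               fin_profile = list(), intensity = 200) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("'name' must be a non-empty string")
  if (!is.numeric(body_length_px) || body_length_px <= 0)
    stop("degenerate spec: body_length_px must be > 0")
  if (!is.numeric(body_aspect) || body_aspect <= 1)
    stop("body_aspect must be > 1")
  if (!is.numeric(intensity) || intensity < 0 || intensity > 255)
    stop("intensity must lie in [0, 255]")
  kinds <- c("dorsal", "adipose", "anal", "caudal", "thread")
  anchors <- numeric(0)
  for (f in fin_profile) {
    stopifnot(is.list(f), all(c("anchor", "extent", "kind") %in% names(f)))
    if (f$anchor < 0 || f$anchor > 1) stop("fin anchor must lie in [0, 1]")
    if (f$extent < 0 || f$extent > 0.5) stop("fin extent must lie in [0, 0.5]")
    if (!f$kind %in% kinds)
      stop("fin kind must be one of: ", paste(kinds, collapse = ", "))
    anchors <- c(anchors, f$anchor)
  }
  if (length(anchors) > 1L && any(diff(anchors) <= 0))
    stop("fin anchors must be strictly increasing")
  structure(list(name = name, body_length_px = body_length_px,
                 body_aspect = body_aspect, fin_profile = fin_profile,
                 intensity = intensity),
            class = "species_shape_spec")
}

#' @export
print.species_shape_spec <- function(x, ...) {
  cat("Species shape spec:", x$name, "\n")
  cat(sprintf("  body %.0f px, aspect %.1f, intensity %.0f\n",
              x$body_length_px, x$body_aspect, x$intensity))
  for (f in x$fin_profile)
    cat(sprintf("  fin %-8s anchor %.2f extent %.2f\n",
                f$kind, f$anchor, f$extent))
  invisible(x)
}

#' Default species silhouette specifications
#'
#' Three look-alike species modelled after the juvenile fishes most often
#' seen together in upper San Francisco Estuary trawls: delta smelt
#' (slender, with a small adipose fin), threadfin shad (deep-bodied, with
#' a trailing dorsal thread) and American shad (deep-bodied, no thread).
#' Pixel sizes describe fish a few body-lengths from the camera in a fixed
#' viewing chamber; they are chosen for silhouette separability.
#'
#' @return named list of [species_shape_spec()] objects.
#' @export
default_species <- function() {
  list(
    delta_smelt = species_shape_spec(
      "delta_smelt", body_length_px = 120, body_aspect = 5.5, intensity = 200,
      fin_profile = list(
        list(anchor = 0.45, extent = 0.32, kind = "dorsal"),
        list(anchor = 0.62, extent = 0.28, kind = "anal"),
        list(anchor = 0.78, extent = 0.14, kind = "adipose"),
        list(anchor = 0.97, extent = 0.42, kind = "caudal"))),
    threadfin_shad = species_shape_spec(
      "threadfin_shad", body_length_px = 110, body_aspect = 2.9,
      intensity = 190,
      fin_profile = list(
        list(anchor = 0.42, extent = 0.30, kind = "dorsal"),
        list(anchor = 0.50, extent = 0.45, kind = "thread"),
        list(anchor = 0.68, extent = 0.26, kind = "anal"),
        list(anchor = 0.97, extent = 0.40, kind = "caudal"))),
    american_shad = species_shape_spec(
      "american_shad", body_length_px = 135, body_aspect = 2.5,
      intensity = 210,
      fin_profile = list(
        list(anchor = 0.44, extent = 0.24, kind = "dorsal"),
        list(anchor = 0.70, extent = 0.20, kind = "anal"),
        list(anchor = 0.97, extent = 0.38, kind = "caudal"))))
}

# Half-depth profile of the body at relative position s in [0, 1]:
# blunt head, deepest near s = 0.4, narrowing to a caudal peduncle that
# stays wide enough for the caudal fin to connect.
body_half_depth <- function(s, half_depth_max) {
  base <- (4 * s * (1 - s))^0.75
  peduncle <- 1 - 0.55 * pmax(0, (s - 0.65) / 0.35)
  half_depth_max * pmax(base * peduncle, ifelse(s > 0 & s < 1, 0.10, 0))
}

#' Render a species silhouette as a binary mask
#'
#' Rasterises the body outline and fins of a [species_shape_spec()] at a
#' given orientation and scale by evaluating the analytic outline on the
#' pixel grid (no resampling), then applies one morphological closing so
#' thin parts such as fin threads stay attached.
#'
#' @param spec a [species_shape_spec()].
#' @param orientation_deg orientation of the body axis, degrees
#'   counter-clockwise from the column axis (0 = head left, horizontal).
#' @param scale scale factor, must be positive.
#' @return logical matrix (a single 8-connected component), trimmed to the
#'   silhouette with a 1-pixel margin.
#' @examples
#' m <- species_silhouette(default_species()$delta_smelt)
#' sum(m)  # silhouette area in pixels
#' @export
species_silhouette <- function(spec, orientation_deg = 0, scale = 1) {
  stopifnot(inherits(spec, "species_shape_spec"))
  if (!is.numeric(scale) || scale <= 0) stop("scale must be > 0")
  L <- spec$body_length_px * scale
  if (L < 4) stop("degenerate spec: scaled body length below 4 px")
  D <- L / spec$body_aspect
  max_ext <- if (length(spec$fin_profile))
    max(vapply(spec$fin_profile, function(f) f$extent, 0)) else 0
  umax <- 0.64 * L                      # caudal fin overhangs the body
  vmax <- 0.5 * D + max_ext * D + 2
  half <- ceiling(sqrt(umax^2 + vmax^2)) + 2L
  n <- 2L * half + 1L
  cc <- half  # 0-based centre
  co <- rep(0:(n - 1L), each = n) - cc   # x (col) per pixel, column-major
  ro <- rep(0:(n - 1L), times = n) - cc
  x <- co
  y <- -ro
  th <- orientation_deg * pi / 180
  u <- x * cos(th) + y * sin(th)         # along-body (head at u = -L/2)
  v <- -x * sin(th) + y * cos(th)        # dorsal side v > 0
  s <- (u + L / 2) / L
  inside_body <- s >= 0 & s <= 1
  h <- numeric(length(s))
  h[inside_body] <- body_half_depth(s[inside_body], D / 2)
  mask_v <- inside_body & abs(v) <= h

  for (f in spec$fin_profile) {
    a <- f$anchor; e <- f$extent
    fm <- switch(f$kind,
      dorsal = {
        w <- 0.07
        rel <- (s - a) / w
        inside <- s >= a - w & s <= a + w
        # raked triangle: tall at the anchor, sloping down toward the tail
        height <- e * D * pmax(0, pmin(1, (1 + rel) / 1.2)) *
          pmax(0, 1 - pmax(0, rel))
        inside & v >= h - 0.5 & v <= h + height
      },
      anal = {
        w <- 0.06
        rel <- (s - a) / w
        inside <- s >= a - w & s <= a + w
        height <- e * D * pmax(0, pmin(1, (1 + rel) / 1.2)) *
          pmax(0, 1 - pmax(0, rel))
        inside & v <= -h + 0.5 & v >= -h - height
      },
      adipose = {
        w <- 0.045
        inside <- abs(s - a) <= w
        bump <- e * D * sqrt(pmax(0, 1 - ((s - a) / w)^2))
        inside & v >= h - 0.5 & v <= h + bump
      },
      caudal = {
        s_end <- 1.12
        inside <- s >= a & s <= s_end
        spread <- e * D * (s - a) / (s_end - a)
        inside & abs(v) <= pmax(spread, 0.6 * scale)
      },
      thread = {
        # trailing filament from the dorsal-fin apex across the peduncle
        inside <- s >= a - 0.02 & s <= a + 0.30
        v0 <- body_half_depth(a, D / 2) + e * D * 0.85
        inside & abs(v - v0) <= 1.1 * scale
      })
    mask_v <- mask_v | fm
  }

  mask <- matrix(mask_v, n, n)  # column-major fill matches (ro, co) layout
  mask <- binary_close(mask, 1L)
  lab <- label_components(mask, 8L)
  if (max(lab) == 0L) stop("degenerate spec: empty silhouette")
  if (max(lab) > 1L) {
    # keep the largest component (a detached thread tip, if any)
    sizes <- tabulate(lab[lab > 0L])
    mask <- lab == which.max(sizes)
  }
  trim_mask(mask)
}
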