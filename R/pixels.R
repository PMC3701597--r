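# Internal pixel-grid toolkit: connected components, binary morphology,
# hole filling, gradients, moments. Masks are logical matrices [row, col].

#' Label connected components of a binary mask
#'
#' Frontier-vectorised flood fill. Used both by the detector and, at
#' `connectivity = 4`, by the hole-filling routine.
#'
#' @param mask logical matrix.
#' @param connectivity 8 (default) or 4.
#' @return integer matrix of the same shape; 0 = background, components
#'   numbered from 1 in raster-scan order of their first pixel.
#' @keywords internal
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), connectivity %in% c(4L, 8L))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  fg <- which(mask)
  if (length(fg) == 0L) return(lab)
  if (connectivity == 8L) {
    dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
    dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  } else {
    dr <- c(-1L, 0L, 0L, 1L)
    dc <- c(0L, -1L, 1L, 0L)
  }
  off_lin <- dr + dc * nr
  inmask <- mask
  cur <- 0L
  for (seed in fg) {
    if (lab[seed] != 0L) next
    cur <- cur + 1L
    lab[seed] <- cur
    frontier <- seed
    while (length(frontier)) {
      r0 <- ((frontier - 1L) %% nr) + 1L
      c0 <- ((frontier - 1L) %/% nr) + 1L
      nb_r <- rep(r0, each = length(dr)) + dr
      nb_c <- rep(c0, each = length(dc)) + dc
      ok <- nb_r >= 1L & nb_r <= nr & nb_c >= 1L & nb_c <= nc
      nb <- nb_r[ok] + (nb_c[ok] - 1L) * nr
      nb <- unique(nb[inmask[nb] & lab[nb] == 0L])
      lab[nb] <- cur
      frontier <- nb
    }
  }
  lab
}

# One-step 8-neighbourhood (square structuring element) dilation.
dilate1 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  p <- matrix(FALSE, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- mask
  out <- matrix(FALSE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    out <- out | p[(2L + dr):(nr + 1L + dr), (2L + dc):(nc + 1L + dc)]
  }
  out
}

erode1 <- function(mask) !dilate1(!mask)

# Morphological closing with a square structuring element of radius `iter`.
binary_close <- function(mask, iter = 1L) {
  m <- mask
  for (i in seq_len(iter)) m <- dilate1(m)
  for (i in seq_len(iter)) m <- erode1(m)
  m
}

# Fill interior holes: background 4-components not touching the border.
fill_holes <- function(mask) {
  bg <- label_components(!mask, connectivity = 4L)
  border <- unique(c(bg[1L, ], bg[nrow(bg), ], bg[, 1L], bg[, ncol(bg)]))
  border <- border[border != 0L]
  mask | (bg != 0L & !(bg %in% border))
}

# Inner boundary: mask pixels with at least one 4-neighbour outside.
boundary_mask <- function(mask) mask & !erode4(mask)

erode4 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  p <- matrix(FALSE, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- mask
  p[2:(nr + 1L), 2:(nc + 1L)] &
    p[1:nr, 2:(nc + 1L)] & p[3:(nr + 2L), 2:(nc + 1L)] &
    p[2:(nr + 1L), 1:nc] & p[2:(nr + 1L), 3:(nc + 2L)]
}

# Gradient magnitude by 3x3 central differences (replicated borders).
gradient_magnitude <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  up <- img[c(1L, 1:(nr - 1L)), , drop = FALSE]
  dn <- img[c(2:nr, nr), , drop = FALSE]
  lf <- img[, c(1L, 1:(nc - 1L)), drop = FALSE]
  rt <- img[, c(2:nc, nc), drop = FALSE]
  sqrt(((dn - up) / 2)^2 + ((rt - lf) / 2)^2)
}

# Raw and central moments of a mask. Coordinates: x = col, y = -row, both
# 0-based, so angles come out counter-clockwise from the column axis.
mask_moments <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("mask is empty")
  x <- idx[, 2L] - 1
  y <- -(idx[, 1L] - 1)
  m00 <- nrow(idx)
  xc <- mean(x); yc <- mean(y)
  dx <- x - xc; dy <- y - yc
  mu <- function(p, q) sum(dx^p * dy^q)
  list(
    m00 = m00,
    centroid = c(row = -yc, col = xc),  # back to (row, col), 0-based
    xc = xc, yc = yc,
    mu20 = mu(2, 0), mu02 = mu(0, 2), mu11 = mu(1, 1),
    mu30 = mu(3, 0), mu03 = mu(0, 3), mu21 = mu(2, 1), mu12 = mu(1, 2)
  )
}

# Principal-axis decomposition of the second central moments.
# Returns angle (deg, CCW from column axis), eigenvalues of the
# covariance matrix (lambda1 >= lambda2), and equivalent-ellipse semi-axes.
mask_axes <- function(mm) {
  c20 <- mm$mu20 / mm$m00
  c02 <- mm$mu02 / mm$m00
  c11 <- mm$mu11 / mm$m00
  theta <- 0.5 * atan2(2 * c11, c20 - c02)
  tr <- c20 + c02
  det4 <- sqrt(pmax(0, (c20 - c02)^2 + 4 * c11^2))
  l1 <- (tr + det4) / 2
  l2 <- (tr - det4) / 2
  list(angle_deg = theta * 180 / pi, lambda1 = l1, lambda2 = l2,
       semi_major = 2 * sqrt(pmax(l1, 0)), semi_minor = 2 * sqrt(pmax(l2, 0)))
}

# Bilinear sampling of `img` at (row, col) positions (0-based, fractional).
# Out-of-range positions return `fill`.
bilinear_sample <- function(img, rows, cols, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- floor(rows); c0 <- floor(cols)
  fr <- rows - r0; fc <- cols - c0
  val <- numeric(length(rows))
  get_px <- function(r, c) {
    ok <- r >= 0 & r <= (nr - 1) & c >= 0 & c <= (nc - 1)
    v <- rep(fill, length(r))
    v[ok] <- img[cbind(r[ok] + 1, c[ok] + 1)]
    v
  }
  v00 <- get_px(r0, c0)
  v01 <- get_px(r0, c0 + 1)
  v10 <- get_px(r0 + 1, c0)
  v11 <- get_px(r0 + 1, c0 + 1)
  v00 * (1 - fr) * (1 - fc) + v01 * (1 - fr) * fc +
    v10 * fr * (1 - fc) + v11 * fr * fc
}

# Tight bounding box of a mask with a 1-px margin, clipped to the grid.
trim_mask <- function(mask, margin = 1L) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(mask)
  r <- range(idx[, 1L]); c <- range(idx[, 2L])
  r0 <- max(1L, r[1L] - margin); r1 <- min(nrow(mask), r[2L] + margin)
  c0 <- max(1L, c[1L] - margin); c1 <- min(ncol(mask), c[2L] + margin)
  mask[r0:r1, c0:c1, drop = FALSE]
}

# Evaluate an expression with the RNG seeded, restoring the caller's RNG
# state afterwards.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
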