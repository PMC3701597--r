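# Independent oracles and fixture builders used across the suite.
# These deliberately avoid the package's own internals: labeling is a
# plain stack-based flood fill, moments are explicit double sums, and
# rotation is a standalone nearest/bilinear resampler.

# Brute-force connected-component labeling by explicit flood fill.
flood_fill_label <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  if (connectivity == 8) {
    nb <- cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    nb <- cbind(c(-1, 0, 0, 1), c(0, -1, 1, 0))
  }
  cur <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!mask[r, c] || lab[r, c] != 0L) next
    cur <- cur + 1L
    stack <- list(c(r, c))
    lab[r, c] <- cur
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(nb))) {
        rr <- p[1] + nb[k, 1]; cc <- p[2] + nb[k, 2]
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
            mask[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- cur
          stack[[length(stack) + 1L]] <- c(rr, cc)
        }
      }
    }
  }
  lab
}

# Explicit double-sum central moments (x = col - 1, y = -(row - 1)).
brute_central_moment <- function(mask, p, q) {
  idx <- which(mask, arr.ind = TRUE)
  x <- idx[, 2] - 1
  y <- -(idx[, 1] - 1)
  xc <- mean(x); yc <- mean(y)
  s <- 0
  for (i in seq_along(x)) s <- s + (x[i] - xc)^p * (y[i] - yc)^q
  s
}

# Principal-axis aspect ratio by direct eigen-decomposition of the
# second-central-moment matrix from brute-force pixel sums.
brute_aspect <- function(mask) {
  n <- sum(mask)
  m <- matrix(c(brute_central_moment(mask, 2, 0),
                brute_central_moment(mask, 1, 1),
                brute_central_moment(mask, 1, 1),
                brute_central_moment(mask, 0, 2)) / n, 2, 2)
  ev <- eigen(m, symmetric = TRUE)$values
  sqrt(ev[1] / ev[2])
}

# Rotate a mask about its centroid by resampling (independent sampler).
rotate_mask <- function(mask, angle_deg, pad = 40) {
  idx <- which(mask, arr.ind = TRUE)
  rc <- mean(idx[, 1] - 1); cc <- mean(idx[, 2] - 1)
  n <- max(dim(mask)) + 2 * pad
  ctr <- (n - 1) / 2
  th <- angle_deg * pi / 180
  out <- matrix(FALSE, n, n)
  co <- rep(0:(n - 1), each = n) - ctr
  ro <- rep(0:(n - 1), times = n) - ctr
  # inverse map: rotate (x, y-up) by -th around the centroid
  u <- co * cos(th) + (-ro) * sin(th)
  v <- -co * sin(th) + (-ro) * cos(th)
  sr <- round(rc - v)   # source row (v is y-up offset)
  sc <- round(cc + u)
  ok <- sr >= 0 & sr <= nrow(mask) - 1 & sc >= 0 & sc <= ncol(mask) - 1
  vals <- rep(FALSE, n * n)
  vals[ok] <- mask[cbind(sr[ok] + 1, sc[ok] + 1)]
  matrix(vals, n, n)
}

# Filled shapes on a grid.
make_disc <- function(radius, size = 2 * radius + 11) {
  ctr <- (size + 1) / 2
  x <- rep(seq_len(size), each = size); y <- rep(seq_len(size), times = size)
  matrix((x - ctr)^2 + (y - ctr)^2 <= radius^2, size, size)
}

make_ellipse <- function(a, b, size_r = 2 * b + 11, size_c = 2 * a + 11) {
  cr <- (size_r + 1) / 2; cc <- (size_c + 1) / 2
  co <- rep(seq_len(size_c), each = size_r)
  ro <- rep(seq_len(size_r), times = size_c)
  matrix(((co - cc) / a)^2 + ((ro - cr) / b)^2 <= 1, size_r, size_c)
}

make_rect <- function(h, w, size_r = h + 20, size_c = w + 20) {
  m <- matrix(FALSE, size_r, size_c)
  r0 <- floor((size_r - h) / 2) + 1; c0 <- floor((size_c - w) / 2) + 1
  m[r0:(r0 + h - 1), c0:(c0 + w - 1)] <- TRUE
  m
}

# A standard scaled-down test scene: fish in separated horizontal lanes,
# crossing left to right.
lane_scene <- function(seed, turbidity_ntu = 10, species = NULL,
                       n_fish = NULL, frame_shape = c(300, 400),
                       duration_s = 0.8, noise_sd = 2) {
  sp <- default_species()
  if (is.null(species)) {
    set.seed(seed * 1000 + 17)
    if (is.null(n_fish)) n_fish <- sample(2:3, 1)
    species <- sample(names(sp)[1:2], n_fish, replace = TRUE)
  }
  n_fish <- length(species)
  set.seed(seed * 1000 + 18)
  fish <- lapply(seq_len(n_fish), function(i) list(
    spec = sp[[species[i]]],
    entry_frame = sample(0:5, 1),
    entry_point = c(60 + 90 * (i - 1), -80),
    velocity = c(0, sample(10:13, 1)),
    orientation_deg = 0))
  scene_spec(frame_shape = frame_shape, frame_rate_hz = 60,
             duration_s = duration_s, fish = fish,
             turbidity_ntu = turbidity_ntu, noise_sd = noise_sd,
             background_level = 40, seed = seed)
}

# Ground-truth-matched per-frame detection recall.
scene_recall <- function(rendered, detections, match_px = 30) {
  hit <- 0; tot <- 0
  for (g in rendered$ground_truth$fish) {
    for (k in seq_along(g$frames)) {
      tot <- tot + 1
      dl <- detections[[g$frames[k] + 1]]
      if (!length(dl)) next
      dd <- vapply(dl, function(d)
        sqrt(sum((d$centroid - g$centroids[k, ])^2)), 0)
      if (min(dd) < match_px) hit <- hit + 1
    }
  }
  if (tot == 0) NA_real_ else hit / tot
}

# Gaussian feature clouds for classifier tests: two (or more) classes with
# centers `sep` SDs apart along the first axis.
gaussian_library <- function(n_per_class, n_classes = 2, dim = 5, sep = 10,
                             seed = 1) {
  set.seed(seed)
  X <- NULL; labs <- character(0)
  for (k in seq_len(n_classes)) {
    ctr <- c((k - 1) * sep, rep(0, dim - 1))
    X <- rbind(X, sweep(matrix(rnorm(n_per_class * dim), n_per_class, dim),
                        2, ctr, "+"))
    labs <- c(labs, rep(paste0("class", k), n_per_class))
  }
  colnames(X) <- paste0("f", seq_len(dim))
  list(x = X, labels = labs)
}
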