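test_that("Hu moments are exactly translation invariant", {
  sq <- make_rect(30, 30, 64, 64)
  shifted <- matrix(FALSE, 80, 90)
  idx <- which(sq, arr.ind = TRUE)
  shifted[cbind(idx[, 1] + 5, idx[, 2] + 9)] <- TRUE
  expect_equal(hu_moments(sq), hu_moments(shifted), tolerance = 1e-12)
})

test_that("the first Hu invariant of a filled square is 1/6 by brute-force sums", {
  sq <- make_rect(40, 40)
  n <- sum(sq)
  phi1 <- (brute_central_moment(sq, 2, 0) + brute_central_moment(sq, 0, 2)) /
    n^2
  expect_equal(phi1, 1 / 6, tolerance = 1e-3)
  expect_equal(unname(hu_moments(sq, transform = "none")[1]), phi1,
               tolerance = 1e-12)
})

test_that("Hu moments are rotation invariant within tolerance", {
  blob <- make_ellipse(60, 28)
  blob[20:36, 70:95] <- TRUE   # asymmetric lump
  h0 <- hu_moments(blob)
  h30 <- hu_moments(rotate_mask(blob, 30))
  expect_true(all(abs(h30 - h0) < 1e-2))
})

test_that("Hu moments are scale invariant within tolerance", {
  raw0 <- hu_moments(make_ellipse(40, 18), transform = "none")
  raw2 <- hu_moments(make_ellipse(80, 36), transform = "none")
  # compare on the raw scale with a floor at rasterization noise
  expect_true(all(abs(raw2 - raw0) <= pmax(0.02 * abs(raw0), 1e-7)))
  expect_error(hu_moments(matrix(FALSE, 5, 5)), "empty")
})

test_that("aspect ratio matches axis-aligned, rotated and circular references", {
  expect_equal(aspect_ratio(make_rect(20, 40)), 2.0, tolerance = 0.05 / 2)
  rot45 <- rotate_mask(make_rect(20, 40), 45)
  expect_equal(aspect_ratio(rot45), 2.0, tolerance = 0.05 / 2)
  expect_equal(aspect_ratio(make_disc(20)), 1.0, tolerance = 0.02)
  single <- matrix(FALSE, 9, 9); single[5, 5] <- TRUE
  expect_error(aspect_ratio(single), "degenerate")
})

test_that("ellipse defect is near zero for ellipses and matches a pixel XOR oracle", {
  expect_lt(ellipse_defect(make_ellipse(30, 15)), 0.03)

  sq <- make_rect(36, 36)
  defect <- ellipse_defect(sq)
  expect_gt(defect, 0)
  # oracle: place the equal-area, equal-axes ellipse analytically and
  # count the symmetric difference pixel by pixel
  n <- sum(sq)
  a <- b <- sqrt(n / pi)   # square: lambda1 = lambda2
  idx <- which(sq, arr.ind = TRUE)
  rc <- mean(idx[, 1]); cc <- mean(idx[, 2])
  xor_count <- 0
  for (r in 1:nrow(sq)) for (c in 1:ncol(sq)) {
    in_e <- ((r - rc) / b)^2 + ((c - cc) / a)^2 <= 1
    if (xor(in_e, sq[r, c])) xor_count <- xor_count + 1
  }
  expect_equal(defect, xor_count / n, tolerance = 0.01)

  # a plus sign deviates more from its ellipse than a square of equal area
  plus <- matrix(FALSE, 70, 70)
  plus[28:43, 11:60] <- TRUE
  plus[11:60, 28:43] <- TRUE
  sq2 <- make_rect(round(sqrt(sum(plus))), round(sqrt(sum(plus))))
  expect_gt(ellipse_defect(plus), ellipse_defect(sq2))
})

test_that("radial pattern matches analytic circle and ellipse profiles", {
  rp_circle <- radial_pattern(make_disc(20), 32)
  expect_length(rp_circle, 32)
  expect_true(all(abs(rp_circle - 1) < 0.05))
  rp_ell <- radial_pattern(make_ellipse(60, 30), 32)
  expect_equal(max(rp_ell) / min(rp_ell), 2.0, tolerance = 0.1 / 2)
  # analytic polar radius of the ellipse, normalized the same way
  th <- 2 * pi * (0:31) / 32
  r_analytic <- (60 * 30) / sqrt((30 * cos(th))^2 + (60 * sin(th))^2)
  r_analytic <- r_analytic / mean(r_analytic)
  expect_equal(rp_ell, r_analytic, tolerance = 0.05)
  # scale invariance
  rp_big <- radial_pattern(make_ellipse(120, 60), 32)
  expect_true(all(abs(rp_big - rp_ell) < 0.05))
  expect_error(radial_pattern(make_disc(10), 4), "B")
})

test_that("template RMS separates species and honors the analytic anchors", {
  tpl <- default_templates()
  expect_identical(template_rms(tpl$delta_smelt,
                                template = tpl$delta_smelt), 0)
  neg <- tpl$delta_smelt
  neg$image <- -neg$image
  expect_equal(template_rms(neg, template = tpl$delta_smelt), 2.0,
               tolerance = 1e-3)
  m <- species_silhouette(default_species()$delta_smelt, 35, 1.1)
  rms_own <- template_rms(NULL, m, tpl$delta_smelt)
  expect_lt(rms_own, template_rms(NULL, m, tpl$threadfin_shad))
  expect_lt(rms_own, template_rms(NULL, m, tpl$american_shad))
  flat <- matrix(0, 50, 50)
  expect_error(species_template(mask = flat > 1), "empty")
})

test_that("feature vectors are deterministic, translation invariant and complete", {
  tpl <- default_templates()
  m <- species_silhouette(default_species()$threadfin_shad, 20)
  fv1 <- feature_vector(NULL, m, tpl, B = 32)
  fv2 <- feature_vector(NULL, m, tpl, B = 32)
  expect_identical(fv1, fv2)
  expect_length(fv1, 1 + 7 + 1 + 1 + 3 + 32)
  expect_true(all(is.finite(fv1)))
  # translation: embed the same mask elsewhere in a larger canvas
  big <- matrix(FALSE, nrow(m) + 40, ncol(m) + 60)
  idx <- which(m, arr.ind = TRUE)
  big[cbind(idx[, 1] + 17, idx[, 2] + 23)] <- TRUE
  fv3 <- feature_vector(NULL, big, tpl, B = 32)
  expect_equal(unclass(fv1), unclass(fv3), tolerance = 1e-9)
  rms <- fv1[grep("^rms_", names(fv1))]
  expect_identical(names(which.min(rms)), "rms_threadfin_shad")
})

test_that("rotation and scale leave the invariant features stable over random placements", {
  sp <- default_species()
  set.seed(202)
  for (i in 1:25) {
    spec <- sp[[sample(3, 1)]]
    scl <- runif(1, 1.0, 1.5)
    ang <- runif(1, 0, 360)
    m0 <- species_silhouette(spec, 0, scl)
    m1 <- species_silhouette(spec, ang, scl)
    expect_lt(abs(aspect_ratio(m1) - aspect_ratio(m0)) / aspect_ratio(m0),
              0.03)
    expect_lt(abs(ellipse_defect(m1) - ellipse_defect(m0)), 0.03)
    r0 <- radial_pattern(m0, 16); r1 <- radial_pattern(m1, 16)
    expect_lt(max(abs(r0 - r1)), 0.15)
  }
})
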