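test_that("depth stratum assignment follows the mid-depth rule", {
  expect_identical(assign_stratum(c(2.5, 2.6, 2.7), 10.5), "upper")
  expect_identical(assign_stratum(c(7.8, 7.9, 8.0), 10.1), "lower")
  expect_identical(assign_stratum(5.25, 10.5), "lower")  # tie -> lower
  expect_error(assign_stratum(numeric(0), 10), "no depth")
  expect_error(assign_stratum(3, NA), "water_depth")
})

test_that("windowed counts filter by first-detection time and confidence", {
  ids <- data.frame(
    track_id = as.character(1:8),
    species = c(rep("delta_smelt", 6), "threadfin_shad", "delta_smelt"),
    confidence = c(1.0, 1.0, 1.0, 1.0, 1.0, 0.9, 1.0, 1.0),
    first_time = c(10, 20, 30, 40, 50, 55, 70, 700),
    stringsAsFactors = FALSE)
  w <- c(0, 600)
  cnt <- windowed_counts(ids, w, min_confidence = 1.0)
  expect_identical(cnt[["delta_smelt"]], 5L)  # conf 0.9 and t=700 excluded
  expect_identical(cnt[["threadfin_shad"]], 1L)
  expect_identical(sum(windowed_counts(ids[0, ], w)), 0L)
})

test_that("a confidence-threshold sweep recovers the staircase of counts", {
  ids <- data.frame(track_id = as.character(1:3),
                    species = "delta_smelt",
                    confidence = c(1.0, 0.9, 0.04),
                    first_time = c(1, 2, 3), stringsAsFactors = FALSE)
  w <- c(0, 10)
  got <- vapply(c(1.0, 0.9, 0.04), function(th)
    windowed_counts(ids, w, th)[["delta_smelt"]], 0L)
  expect_identical(got, c(1L, 2L, 3L))
})

test_that("human-assigned override confidence takes precedence", {
  ids <- data.frame(track_id = "1", species = "delta_smelt",
                    confidence = 0.5, override_confidence = 1.0,
                    first_time = 5, stringsAsFactors = FALSE)
  expect_identical(windowed_counts(ids, c(0, 10), 1.0)[["delta_smelt"]], 1L)
})

test_that("density per 10,000 cubic metres is linear and matches the printed maxima", {
  expect_identical(catch_density(0, 5000), 0)
  expect_identical(catch_density(1, 10000), 1)
  # 22 fish in 5,946 m^3 is 37 per 10,000 m^3
  expect_equal(catch_density(22, 5946), 37.0, tolerance = 0.05 / 37)
  expect_equal(catch_density(44, 5946), 2 * catch_density(22, 5946))
  expect_error(catch_density(1, 0), "volume")
})

test_that("survival accounting reproduces the open-codend gain", {
  s <- survival_summary(142, 55)
  expect_identical(s$total, 197L)
  expect_identical(s$percent_survived, 72)
  expect_identical(survival_summary(10, 0)$percent_survived, 100)
  expect_identical(survival_summary(0, 10)$percent_survived, 0)
  # invariant to proportional scaling
  expect_identical(survival_summary(284, 110)$percent_survived, 72)
  expect_error(survival_summary(0, 0), "total")
  expect_error(survival_summary(-1, 5), "non-negative")
})

make_samples <- function(n = 52, n_positive = 16) {
  lv <- expand.grid(tide = c("flood", "ebb"), horizontal = c("center", "side"),
                    vertical = c("upper", "lower"),
                    stringsAsFactors = FALSE)
  lapply(seq_len(n), function(i) {
    row <- lv[(i - 1) %% 8 + 1, ]
    cnt <- if (i <= n_positive) c(delta_smelt = ((i - 1) %% 5) + 1L)
           else c(delta_smelt = 0L)
    trawl_sample(sprintf("s%02d", i), row$tide, row$horizontal,
                 row$vertical, volume_m3 = 4388 + 70 * i, counts = cnt)
  })
}

test_that("the count dataset reproduces the survey zero fraction", {
  d <- build_count_dataset(make_samples(), "delta_smelt")
  expect_identical(nrow(d), 52L)
  expect_identical(sum(d$y == 0), 36L)
  expect_identical(round(100 * mean(d$y == 0)), 69)
  expect_identical(levels(d$T), c("ebb", "flood"))
  expect_identical(rownames(d), sort(rownames(d)))
  # a species absent everywhere gives an all-zero response
  d2 <- build_count_dataset(make_samples(), "green_sturgeon")
  expect_true(all(d2$y == 0))
})

test_that("sample records validate factor levels and compute densities", {
  expect_error(trawl_sample("x", "slack", "center", "upper", 5000), "tide")
  expect_error(trawl_sample("x", "flood", "center", "upper", -1), "volume")
  s <- trawl_sample("x", "flood", "center", "upper", 5000,
                    counts = c(delta_smelt = 3L))
  expect_equal(s$densities[["delta_smelt"]],
               catch_density(3, 5000), tolerance = 1e-12)
})

test_that("count datasets round-trip through CSV with factor levels intact", {
  d <- build_count_dataset(make_samples(12, 5), "delta_smelt")
  path <- withr::local_tempfile(fileext = ".csv")
  write_count_dataset(d, path)
  back <- read_count_dataset(path)
  expect_identical(back$y, d$y)
  expect_identical(levels(back$T), levels(d$T))
  expect_identical(levels(back$H), levels(d$H))
  expect_identical(levels(back$V), levels(d$V))
  expect_identical(as.character(back$T), as.character(d$T))
  expect_equal(back$volume_m3, d$volume_m3, tolerance = 1e-9)
})

test_that("sensor CSV parsing enforces schema and monotone timestamps", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(timestamp = c("2012-11-27T10:00:00", "2012-11-27T10:00:01"),
                   latitude = c(38.04, 38.04), longitude = c(-121.8, -121.8),
                   depth_m = c(2.56, 2.64), tilt = c(1, 2), roll = c(0, 0),
                   pitch = c(3, 3))
  write.csv(df, path, row.names = FALSE)
  got <- read_sensor_csv(path)
  expect_s3_class(got$timestamp, "POSIXct")
  df_bad <- df; df_bad$timestamp <- rev(df_bad$timestamp)
  write.csv(df_bad, path, row.names = FALSE)
  expect_error(read_sensor_csv(path), "increasing")
  write.csv(df[, -4], path, row.names = FALSE)
  expect_error(read_sensor_csv(path), "missing columns")
})
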