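# Trawl-survey plumbing: depth-stratum assignment from the sensor record,
# confidence-filtered per-sample counts, densities per 10,000 m^3, the
# survival accounting, and assembly of the factorial count dataset.

#' Assign the vertical stratum of a deployment
#'
#' A tow targets either the upper or the lower half of the water column
#' (about one quarter or three quarters of the water depth). The stratum is
#' decided by the median deployment depth: strictly less than half the
#' water depth is `"upper"`, otherwise `"lower"` (a median exactly at
#' mid-depth is assigned to `"lower"`).
#'
#' @param depth_m numeric vector of depth readings (m) over the sample
#'   window; at least one reading.
#' @param water_depth_m total water depth (m).
#' @return `"upper"` or `"lower"`.
#' @export
assign_stratum <- function(depth_m, water_depth_m) {
  if (is.null(water_depth_m) || !is.finite(water_depth_m) ||
      water_depth_m <= 0)
    stop("water_depth_m missing or invalid")
  depth_m <- depth_m[is.finite(depth_m)]
  if (!length(depth_m)) stop("no depth readings in window")
  if (median(depth_m) < water_depth_m / 2) "upper" else "lower"
}

#' Count identified tracks inside a sample window
#'
#' Counts, per species, the tracks whose first detection time lies in
#' `[start, end)` and whose identification confidence is at least
#' `min_confidence`. Filtering at confidence 1.0 reproduces the
#' conservative analysis choice of keeping only identifications made with
#' 100% confidence; lowering the threshold sweeps in lower-confidence
#' identifications.
#'
#' @param identifications data.frame with columns `species`, `confidence`
#'   and `first_time` (numeric or POSIXct). An `override_confidence`
#'   column, where non-NA, replaces `confidence` (human-assigned
#'   confidence).
#' @param window length-2 vector `(start, end)`, same time scale as
#'   `first_time`.
#' @param min_confidence threshold in `[0, 1]`.
#' @return named integer vector of per-species counts (all species present
#'   in `identifications`, zero where none qualify).
#' @export
windowed_counts <- function(identifications, window, min_confidence = 1) {
  stopifnot(length(window) == 2L)
  if (as.numeric(window[2L]) <= as.numeric(window[1L]))
    stop("window end must exceed start")
  species_all <- sort(unique(as.character(identifications$species)))
  if (!nrow(identifications))
    return(setNames(integer(0), character(0)))
  conf <- identifications$confidence
  if (!is.null(identifications$override_confidence)) {
    ov <- identifications$override_confidence
    conf[!is.na(ov)] <- ov[!is.na(ov)]
  }
  t0 <- as.numeric(identifications$first_time)
  keep <- t0 >= as.numeric(window[1L]) & t0 < as.numeric(window[2L]) &
    conf >= min_confidence
  tab <- table(factor(as.character(identifications$species)[keep],
                      levels = species_all))
  setNames(as.integer(tab), species_all)
}

#' Catch density per 10,000 cubic metres
#'
#' @param count non-negative count.
#' @param volume_m3 volume filtered by the tow (m^3), must be positive.
#' @return `count / volume_m3 * 10000`.
#' @export
catch_density <- function(count, volume_m3) {
  if (any(volume_m3 <= 0)) stop("volume_m3 must be > 0")
  if (any(count < 0)) stop("count must be >= 0")
  count / volume_m3 * 10000
}

#' Survival accounting for an open-codend deployment
#'
#' Every fish that swims through the open chamber survives; fish entangled
#' in the net mesh are handled (and in practice lost). The percent
#' survived is therefore the survival gain over a closed codend, in which
#' all fish would have been handled.
#'
#' @param passed number of fish that passed through the chamber.
#' @param entangled number of fish entangled in the mesh.
#' @return object of class `survival_summary` with fields `passed`,
#'   `entangled`, `total` and `percent_survived`
#'   (`round(100 * passed / total)`).
#' @examples
#' survival_summary(142, 55)  # 72% of 197 fish survived
#' @export
survival_summary <- function(passed, entangled) {
  if (passed < 0 || entangled < 0 || passed != round(passed) ||
      entangled != round(entangled))
    stop("passed and entangled must be non-negative integers")
  total <- passed + entangled
  if (total == 0) stop("no fish: total must be > 0")
  structure(list(passed = as.integer(passed),
                 entangled = as.integer(entangled),
                 total = as.integer(total),
                 percent_survived = round(100 * passed / total)),
            class = "survival_summary")
}

#' @export
print.survival_summary <- function(x, ...) {
  cat(sprintf(
    "Survival: %d of %d fish passed through the open codend (%d%%); %d entangled\n",
    x$passed, x$total, x$percent_survived, x$entangled))
  invisible(x)
}

#' Construct a single trawl sample record
#'
#' @param sample_id unique sample identifier.
#' @param tide `"flood"` or `"ebb"`.
#' @param horizontal `"center"` or `"side"`.
#' @param vertical `"upper"` or `"lower"`.
#' @param volume_m3 flowmeter-derived volume filtered (m^3).
#' @param counts named integer vector, species -> count.
#' @param start,end sample window timestamps (nominally 10 minutes apart).
#' @return object of class `trawl_sample`; `densities` holds per-species
#'   density per 10,000 m^3.
#' @export
trawl_sample <- function(sample_id, tide, horizontal, vertical, volume_m3,
                         counts = integer(0), start = NA, end = NA) {
  check_level <- function(x, levels, what) {
    if (length(x) != 1L || is.na(x) || !x %in% levels)
      stop("sample ", sample_id, ": ", what, " must be one of ",
           paste(levels, collapse = "/"))
    x
  }
  tide <- check_level(tide, c("flood", "ebb"), "tide")
  horizontal <- check_level(horizontal, c("center", "side"), "horizontal")
  vertical <- check_level(vertical, c("upper", "lower"), "vertical")
  if (!is.numeric(volume_m3) || volume_m3 <= 0)
    stop("sample ", sample_id, ": volume_m3 must be > 0")
  if (length(counts) && any(counts < 0))
    stop("sample ", sample_id, ": counts must be >= 0")
  structure(list(sample_id = as.character(sample_id), tide = tide,
                 horizontal = horizontal, vertical = vertical,
                 start = start, end = end, volume_m3 = volume_m3,
                 counts = counts,
                 densities = if (length(counts))
                   catch_density(counts, volume_m3) else numeric(0)),
            class = "trawl_sample")
}

#' Assemble the factorial count dataset for one species
#'
#' One row per sample, ordered by `sample_id`, with the response count
#' `y`, the offset volume and the three design factors with the reference
#' levels ebb (tide), center (horizontal) and upper (vertical), so that
#' treatment-coded coefficients are the flood, side and lower effects.
#'
#' @param samples non-empty list of [trawl_sample()] objects.
#' @param species species label; samples without that species record a
#'   zero count.
#' @return a `count_dataset` (see [count_dataset()]).
#' @export
build_count_dataset <- function(samples, species) {
  if (!length(samples)) stop("samples must be non-empty")
  ids <- vapply(samples, function(s) s$sample_id, "")
  ord <- order(ids)
  samples <- samples[ord]
  y <- vapply(samples, function(s) {
    if (is.null(s$counts) || !species %in% names(s$counts)) 0L
    else as.integer(s$counts[[species]])
  }, 0L)
  count_dataset(
    y = y,
    volume_m3 = vapply(samples, function(s) s$volume_m3, 0),
    T = vapply(samples, function(s) s$tide, ""),
    H = vapply(samples, function(s) s$horizontal, ""),
    V = vapply(samples, function(s) s$vertical, ""),
    sample_id = ids[ord])
}

#' Read sensor records from CSV
#'
#' Expected columns: `timestamp` (ISO-8601 UTC), `latitude`, `longitude`,
#' `depth_m`, `tilt`, `roll`, `pitch`, and optionally `temperature_c`,
#' `humidity_pct`. Timestamps must be strictly increasing.
#'
#' @param path CSV file.
#' @return data.frame with `timestamp` parsed to POSIXct (UTC).
#' @export
read_sensor_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "latitude", "longitude", "depth_m",
            "tilt", "roll", "pitch")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("sensor CSV missing columns: ", paste(missing, collapse = ", "))
  df$timestamp <- as.POSIXct(df$timestamp, tz = "UTC",
                             tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                            "%Y-%m-%d %H:%M:%OS"))
  if (any(is.na(df$timestamp))) stop("unparseable timestamps in sensor CSV")
  if (any(diff(as.numeric(df$timestamp)) <= 0))
    stop("sensor timestamps must be strictly increasing")
  df
}

#' Write per-sample counts and densities to CSV
#'
#' @param samples list of [trawl_sample()] objects.
#' @param counts_path,densities_path output CSV paths (either may be
#'   `NULL` to skip).
#' @return data.frame of the written table, invisibly.
#' @export
write_sample_tables <- function(samples, counts_path = NULL,
                                densities_path = NULL) {
  species <- sort(unique(unlist(lapply(samples, function(s)
    names(s$counts)))))
  base <- data.frame(
    sample_id = vapply(samples, function(s) s$sample_id, ""),
    tide = vapply(samples, function(s) s$tide, ""),
    horizontal = vapply(samples, function(s) s$horizontal, ""),
    vertical = vapply(samples, function(s) s$vertical, ""),
    volume_m3 = vapply(samples, function(s) s$volume_m3, 0),
    stringsAsFactors = FALSE)
  cnt <- vapply(species, function(sp) vapply(samples, function(s) {
    if (is.null(s$counts) || !sp %in% names(s$counts)) 0L
    else as.integer(s$counts[[sp]])
  }, 0L), integer(length(samples)))
  cnt <- matrix(cnt, nrow = length(samples),
                dimnames = list(NULL, species))
  if (!is.null(counts_path))
    write.csv(cbind(base, cnt), counts_path, row.names = FALSE)
  if (!is.null(densities_path)) {
    dens <- sweep(cnt, 1L, base$volume_m3, function(c, v)
      catch_density(c, v))
    write.csv(cbind(base, dens), densities_path, row.names = FALSE)
  }
  invisible(cbind(base, cnt))
}
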