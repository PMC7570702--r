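# Session containers and plain-text I/O.
#
# A session is a directory with one CSV per sensor location (HD, C7, L5,
# LA, RA; columns t, ax..az, gx..gz, mx..my) plus a `session.json` sidecar
# declaring units, sample rate and the sensor-axis -> anatomical-axis
# mapping. Internally everything is stored in anatomical VT/AP/ML order,
# seconds, g, deg/s and Gauss.

#' Construct an IMU recording
#'
#' One location's synchronized tri-axial accelerometer, gyroscope and
#' magnetometer streams as a tibble with class `imu_recording`.
#'
#' @param t time in seconds, monotonically increasing
#' @param acc 3-column matrix or data frame (VT, AP, ML) in g
#' @param gyr 3-column matrix (VT, AP, ML) in deg/s
#' @param mag 3-column matrix (VT, AP, ML) in Gauss, or `NULL` if absent
#' @param location one of `"HD"`, `"C7"`, `"L5"`, `"LA"`, `"RA"`
#' @param fs nominal sample rate in Hz (default 128)
#'
#' @return a tibble with columns `t`, `acc_vt`, `acc_ap`, `acc_ml`,
#'   `gyr_vt`, `gyr_ap`, `gyr_ml`, `mag_vt`, `mag_ap`, `mag_ml` and
#'   attributes `location` and `fs`.
#' @export
imu_recording <- function(t, acc, gyr, mag = NULL, location, fs = 128) {
  location <- match.arg(location, .LOCATIONS)
  acc <- as.matrix(acc); gyr <- as.matrix(gyr)
  n <- length(t)
  if (n < 2) stopf("recording at %s needs at least 2 samples", location)
  if (nrow(acc) != n || nrow(gyr) != n)
    stopf("channel lengths differ at %s", location)
  if (any(diff(t) <= 0))
    stopf("non-monotonic time vector at %s", location)
  if (fs <= 0) stopf("fs must be positive")
  dt_med <- median(diff(t))
  if (abs(dt_med - 1 / fs) > 0.1 / fs)
    stopf("median sample interval %.6f s inconsistent with fs = %g Hz at %s",
          dt_med, fs, location)
  if (is.null(mag)) mag <- matrix(NA_real_, n, 3) else mag <- as.matrix(mag)
  if (nrow(mag) != n) stopf("magnetometer length differs at %s", location)
  rec <- tibble(
    t = as.numeric(t),
    acc_vt = acc[, 1], acc_ap = acc[, 2], acc_ml = acc[, 3],
    gyr_vt = gyr[, 1], gyr_ap = gyr[, 2], gyr_ml = gyr[, 3],
    mag_vt = mag[, 1], mag_ap = mag[, 2], mag_ml = mag[, 3]
  )
  structure(rec, location = location, fs = fs,
            class = c("imu_recording", class(rec)))
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording> %s, %d samples @ %g Hz, %.2f s\n",
              attr(x, "location"), nrow(x), attr(x, "fs"),
              x$t[nrow(x)] - x$t[1]))
  NextMethod()
}

rec_location <- function(rec) attr(rec, "location")
rec_fs <- function(rec) attr(rec, "fs")
has_mag <- function(rec) !anyNA(rec$mag_vt)

#' Construct a sensor-array session
#'
#' @param recordings named list of [imu_recording()] objects keyed by
#'   location; the lower-back (`L5`) recording is required because primary
#'   turn detection runs on it.
#' @param subject_id subject identifier string
#' @param group_label optional group label (`"PD"` or `"CL"`)
#' @return an object of class `imu_session`
#' @export
imu_session <- function(recordings, subject_id, group_label = NULL) {
  if (!("L5" %in% names(recordings)))
    stopf("session '%s' is missing the required L5 recording", subject_id)
  bad <- setdiff(names(recordings), .LOCATIONS)
  if (length(bad)) stopf("unknown location(s): %s", paste(bad, collapse = ", "))
  if (!is.null(group_label)) group_label <- match.arg(group_label, c("PD", "CL"))
  missing_loc <- setdiff(.LOCATIONS, names(recordings))
  if (length(missing_loc))
    warnf("session '%s' missing location(s) %s; dependent operations will refuse",
          subject_id, paste(missing_loc, collapse = ", "))
  structure(list(recordings = recordings,
                 subject_id = subject_id,
                 group_label = group_label),
            class = "imu_session")
}

#' @export
print.imu_session <- function(x, ...) {
  cat(sprintf("<imu_session> subject '%s'%s, locations: %s\n", x$subject_id,
              if (is.null(x$group_label)) "" else paste0(" [", x$group_label, "]"),
              paste(names(x$recordings), collapse = ", ")))
  invisible(x)
}

# Canonical units written by write_session and accepted by read_session
.UNIT_FACTORS <- list(
  t   = c(s = 1, ms = 1e-3),
  acc = c(g = 1, `m/s^2` = 1 / 9.80665),
  gyr = c(`deg/s` = 1, `rad/s` = 180 / pi),
  mag = c(gauss = 1, uT = 0.01)
)

unit_factor <- function(kind, unit) {
  f <- .UNIT_FACTORS[[kind]][unit]
  if (is.na(f)) stopf("unsupported %s unit '%s'", kind, unit)
  unname(f)
}

# Resolve one axis spec like "z" or "-x" to (column, sign)
axis_spec <- function(spec) {
  sgn <- if (startsWith(spec, "-")) -1 else 1
  col <- sub("^-", "", spec)
  if (!col %in% c("x", "y", "z")) stopf("bad axis spec '%s'", spec)
  list(col = col, sign = sgn)
}

#' Write a session to a directory
#'
#' Emits one CSV per location (`<LOC>.csv`, columns
#' `t,ax,ay,az,gx,gy,gz,mx,my,mz`) and a `session.json` sidecar declaring
#' units, sample rate and the axis mapping. The writer uses the canonical
#' mapping VT -> z, AP -> x, ML -> y and canonical units, so a write/read
#' round trip is the identity.
#'
#' @param session an [imu_session()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  axes <- list(vt = "z", ap = "x", ml = "y")
  for (loc in names(session$recordings)) {
    rec <- session$recordings[[loc]]
    out <- tibble(
      t = rec$t,
      ax = rec$acc_ap, ay = rec$acc_ml, az = rec$acc_vt,
      gx = rec$gyr_ap, gy = rec$gyr_ml, gz = rec$gyr_vt,
      mx = rec$mag_ap, my = rec$mag_ml, mz = rec$mag_vt
    )
    readr::write_csv(out, file.path(dir, paste0(loc, ".csv")), progress = FALSE)
  }
  sidecar <- list(
    subject_id = session$subject_id,
    group_label = session$group_label,
    fs = rec_fs(session$recordings[[1]]),
    units = list(t = "s", acc = "g", gyr = "deg/s", mag = "gauss"),
    axes = axes,
    locations = names(session$recordings)
  )
  jsonlite::write_json(sidecar, file.path(dir, "session.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(dir)
}

#' Read a session from a directory
#'
#' Inverse of [write_session()]. The sidecar must declare units explicitly;
#' there is no silent unit guessing. Declared units are converted to the
#' internal canon (seconds, g, deg/s, Gauss) and `fs` is recomputed when the
#' time unit is not seconds.
#'
#' @param path session directory containing per-location CSVs and
#'   `session.json`
#' @return an [imu_session()]
#' @export
read_session <- function(path) {
  sidecar_path <- file.path(path, "session.json")
  if (!file.exists(sidecar_path))
    stopf("unit sidecar '%s' is absent; units must be declared", sidecar_path)
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  for (k in c("units", "axes", "fs"))
    if (is.null(meta[[k]])) stopf("sidecar missing required key '%s'", k)
  locs <- intersect(.LOCATIONS,
                    sub("\\.csv$", "", basename(list.files(path, "\\.csv$"))))
  if (!("L5" %in% locs)) stopf("session at '%s' is missing the L5 file", path)
  f_t <- unit_factor("t", meta$units$t)
  recs <- lapply(locs, function(loc) {
    df <- readr::read_csv(file.path(path, paste0(loc, ".csv")),
                          show_col_types = FALSE, progress = FALSE)
    t <- df$t * f_t
    fs_loc <- if (f_t == 1) meta$fs else 1 / median(diff(t))
    pull_axes <- function(prefix, kind) {
      f <- unit_factor(kind, meta$units[[kind]])
      sapply(.AXES, function(a) {
        sp <- axis_spec(meta$axes[[a]])
        col <- paste0(prefix, sp$col)
        if (!col %in% names(df)) return(rep(NA_real_, nrow(df)))
        sp$sign * df[[col]] * f
      })
    }
    acc <- pull_axes("a", "acc")
    gyr <- pull_axes("g", "gyr")
    mag <- pull_axes("m", "mag")
    if (anyNA(mag)) mag <- NULL
    imu_recording(t, acc, gyr, mag, location = loc, fs = fs_loc)
  })
  names(recs) <- locs
  imu_session(recs, subject_id = meta$subject_id %||% basename(path),
              group_label = meta$group_label)
}

#' Write detected turn events to CSV
#'
#' @param events a `turn_events` tibble as returned by [detect_turns()]
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_events <- function(events, path) {
  out <- tibble(
    location = events$location %||% character(0),
    start_s = events$start_s, end_s = events$end_s,
    angle_deg = events$angle_deg, direction = events$direction,
    n_subturns = events$n_subturns %||% rep(1L, nrow(events))
  )
  if (nrow(out) > 1) {
    ord <- order(out$location, out$start_s)
    out <- out[ord, ]
    overlap <- out |>
      group_by(.data$location) |>
      summarise(bad = any(head(.data$end_s, -1) > tail(.data$start_s, -1)),
                .groups = "drop")
    if (any(overlap$bad))
      warnf("overlapping events at the same location; preserved as-is")
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read turn events from CSV
#'
#' @param path CSV written by [write_events()]
#' @return a `turn_events` tibble
#' @export
read_events <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          location = readr::col_character(),
                          start_s = readr::col_double(),
                          end_s = readr::col_double(),
                          angle_deg = readr::col_double(),
                          direction = readr::col_character(),
                          n_subturns = readr::col_integer()
                        ))
  as_turn_events(tibble(
    location = as.character(df$location), start_s = df$start_s,
    end_s = df$end_s, angle_deg = df$angle_deg,
    direction = as.character(df$direction),
    n_subturns = as.integer(df$n_subturns)
  ))
}

#' Write / read rater annotations
#'
#' Annotations are turn boundary times marked by a human rater:
#' columns `turn_index`, `start_s`, `end_s`, `rater_id`, `direction`.
#'
#' @param annotations tibble of annotations
#' @param path CSV path
#' @return `path` invisibly (writer); tibble (reader)
#' @export
write_annotations <- function(annotations, path) {
  stopifnot(all(annotations$end_s > annotations$start_s))
  readr::write_csv(annotations, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (any(df$end_s <= df$start_s)) stopf("annotation with end_s <= start_s")
  as_tibble(df)
}
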