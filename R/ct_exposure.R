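# CT acquisition arithmetic used around a CT-Expo style analysis:
# collimation, table feed, mAs estimation from CTDIvol, and the
# male-vs-female model "potential error".

#' CT scanner acquisition configuration
#'
#' Holds the acquisition settings of one multi-slice CT protocol: tube
#' voltage, slice collimation and number of simultaneously acquired
#' channels, pitch, scan range (signed cm in the anatomical coordinate used
#' for organ-dose modelling, vertex at +94 cm and caudal positions
#' negative), rotation time, and the scanner's normalized weighted CTDI
#' (mGy per 100 mAs) used to back-calculate mAs from CTDIvol.
#'
#' @param scanner_name Label.
#' @param tube_voltage kVp.
#' @param slice_collimation mm per data channel.
#' @param active_channels Number of simultaneously acquired slices.
#' @param pitch Dimensionless table travel per rotation over total
#'   collimation; must be positive.
#' @param scan_range Numeric length-2 `(start, end)` in cm, `end > start`.
#' @param rotation_time s.
#' @param normalized_ctdiw mGy per 100 mAs; a scanner-specific constant
#'   supplied by configuration.
#' @return An object of class `ct_scanner_config`.
#' @export
ct_scanner_config <- function(scanner_name, tube_voltage, slice_collimation,
                              active_channels, pitch, scan_range,
                              rotation_time, normalized_ctdiw) {
  stopifnot_number(slice_collimation, "slice_collimation", positive = TRUE)
  stopifnot_number(pitch, "pitch", positive = TRUE)
  if (active_channels < 1) abort_invalid("`active_channels` must be >= 1")
  if (length(scan_range) != 2 || scan_range[2] <= scan_range[1]) {
    abort_invalid("`scan_range` must be (start, end) with end > start")
  }
  stopifnot_number(normalized_ctdiw, "normalized_ctdiw", positive = TRUE)
  structure(list(scanner_name = scanner_name, tube_voltage = tube_voltage,
                 slice_collimation = slice_collimation,
                 active_channels = active_channels, pitch = pitch,
                 scan_range = scan_range, rotation_time = rotation_time,
                 normalized_ctdiw = normalized_ctdiw),
            class = "ct_scanner_config")
}

#' @export
print.ct_scanner_config <- function(x, ...) {
  cat(sprintf(
    "<ct_scanner_config> %s\n  %g kVp, %g mm x %d channels (total %g mm), pitch %g\n  scan range %g to %g cm (%g cm), rotation %g s, nCTDIw %g mGy/100 mAs\n",
    x$scanner_name, x$tube_voltage, x$slice_collimation, x$active_channels,
    total_collimation(x$slice_collimation, x$active_channels), x$pitch,
    x$scan_range[1], x$scan_range[2], scan_length(x), x$rotation_time,
    x$normalized_ctdiw))
  invisible(x)
}

#' Load CT scanner configurations from a YAML file
#'
#' The packaged default file carries the two audit scanners (the 128-slice
#' CT of the LAFOV system, and the 64-slice CT of the conventional system at
#' its two most common scan ranges). The `normalized_ctdiw` values in that
#' file are synthetic placeholders: the constant is scanner-specific and
#' must be supplied from the scanner's own documentation for real use.
#'
#' @param path YAML file; defaults to the packaged `scanners.yaml`.
#' @return Named list of `ct_scanner_config` objects.
#' @export
load_scanner_configs <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "scanners.yaml", package = "petctdose")
  }
  if (!file.exists(path)) abort_config(paste0("no such config file: ", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw$scanners)) abort_config("config file has no `scanners` section")
  out <- lapply(raw$scanners, function(s) {
    do.call(ct_scanner_config, s[c("scanner_name", "tube_voltage",
                                   "slice_collimation", "active_channels",
                                   "pitch", "scan_range", "rotation_time",
                                   "normalized_ctdiw")])
  })
  names(out) <- vapply(raw$scanners, function(s) s$config_id, character(1))
  out
}

#' Total collimation of a multi-slice CT acquisition
#'
#' Product of the slice collimation and the number of simultaneously
#' acquired data channels.
#'
#' @param slice_collimation mm, positive.
#' @param active_channels Count, positive.
#' @return Total collimation in mm.
#' @examples
#' total_collimation(0.6, 128)  # 76.8 mm
#' @export
total_collimation <- function(slice_collimation, active_channels) {
  stopifnot_number(slice_collimation, "slice_collimation", positive = TRUE)
  stopifnot_number(active_channels, "active_channels", positive = TRUE)
  slice_collimation * active_channels
}

#' Table feed per rotation
#'
#' Product of the total collimation and the pitch factor.
#'
#' @param total_collimation mm, positive.
#' @param pitch Dimensionless, positive.
#' @return Table feed in mm per rotation.
#' @examples
#' table_feed(76.8, 0.8)  # 61.44 mm
#' @export
table_feed <- function(total_collimation, pitch) {
  stopifnot_number(total_collimation, "total_collimation", positive = TRUE)
  stopifnot_number(pitch, "pitch", positive = TRUE)
  total_collimation * pitch
}

#' Scan length of a configured protocol
#'
#' @param config A [ct_scanner_config()].
#' @return Scan length in cm (`end - start`).
#' @export
scan_length <- function(config) {
  config$scan_range[2] - config$scan_range[1]
}

#' Estimate mAs from a recorded CTDIvol
#'
#' Scanners report CTDIvol rather than the average mAs actually delivered
#' under automatic exposure control. Using `CTDIvol = CTDIw / pitch` and
#' `CTDIw = normalized_ctdiw x mAs / 100`, the effective mAs is recovered
#' as `mAs = 100 x CTDIvol x pitch / normalized_ctdiw`.
#'
#' @param ctdivol mGy, non-negative.
#' @param pitch Dimensionless, positive.
#' @param normalized_ctdiw mGy per 100 mAs; a non-positive value is a
#'   configuration error.
#' @return Effective tube current-time product in mAs.
#' @examples
#' mas_from_ctdivol(4.0, 0.8, 10.0)  # 32 mAs
#' @export
mas_from_ctdivol <- function(ctdivol, pitch, normalized_ctdiw) {
  stopifnot_number(ctdivol, "ctdivol", nonneg = TRUE)
  stopifnot_number(pitch, "pitch", positive = TRUE)
  if (!is.numeric(normalized_ctdiw) || any(is.na(normalized_ctdiw)) ||
      any(normalized_ctdiw <= 0)) {
    abort_config("`normalized_ctdiw` must be a positive scanner constant")
  }
  100 * ctdivol * pitch / normalized_ctdiw
}

#' Potential error of assuming a male phantom
#'
#' When patient gender is unknown, organ-dose modelling may assume a male
#' phantom throughout. The potential error of that assumption is the
#' relative difference between the female- and male-model effective doses,
#' expressed as a percentage of the female-model value:
#' `100 x (ED_female - ED_male) / ED_female`.
#'
#' @param ed_male,ed_female Effective doses in mSv, positive.
#' @return Percent; full precision (round to 1 decimal for reporting).
#' @examples
#' round(potential_error_gender(4.9, 5.9), 1)  # 16.9
#' @export
potential_error_gender <- function(ed_male, ed_female) {
  stopifnot_number(ed_male, "ed_male", positive = TRUE)
  stopifnot_number(ed_female, "ed_female", positive = TRUE)
  100 * (ed_female - ed_male) / ed_female
}
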