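#' Hemoglobin concentration time series
#'
#' Container for channel-wise concentration changes of oxygenated
#' (`hbo`) and deoxygenated (`hbr`) hemoglobin, in micromol/L, sampled
#' uniformly at `fs` Hz. Channels flagged invalid by quality control stay in
#' the matrices but are excluded from every average and statistic downstream.
#'
#' @param hbo channels x time matrix of delta-HbO2 (micromol/L).
#' @param hbr channels x time matrix of delta-HbR, same shape as `hbo`
#'   (optional; defaults to a zero matrix).
#' @param fs sampling rate in Hz.
#' @param valid_channels logical mask per channel.
#' @param condition `"rest"` or `"walk"`.
#' @return an object of class `hb_series`.
#' @export
hb_series <- function(hbo, hbr = NULL, fs = 10,
                      valid_channels = rep(TRUE, nrow(hbo)),
                      condition = c("rest", "walk")) {
  condition <- match.arg(condition)
  hbo <- as.matrix(hbo)
  if (is.null(hbr)) hbr <- matrix(0, nrow(hbo), ncol(hbo))
  hbr <- as.matrix(hbr)
  if (!all(dim(hbo) == dim(hbr))) stop("hbo and hbr must have the same shape")
  if (length(valid_channels) != nrow(hbo))
    stop("valid_channels must have one entry per channel")
  if (fs <= 0) stop("fs must be > 0")
  structure(list(hbo = hbo, hbr = hbr, fs = fs,
                 valid_channels = as.logical(valid_channels),
                 condition = condition),
            class = "hb_series")
}

#' @export
print.hb_series <- function(x, ...) {
  cat(sprintf("hb_series: %d channels x %d samples @ %g Hz (%s), %d valid\n",
              nrow(x$hbo), ncol(x$hbo), x$fs, x$condition,
              sum(x$valid_channels)))
  invisible(x)
}

#' Raw dual-wavelength optical intensity
#'
#' @param data channels x wavelengths x time array of detected intensity
#'   (device units, > 0).
#' @param wavelengths wavelengths in nm (default 730 and 850).
#' @param fs sampling rate in Hz.
#' @return an object of class `raw_intensity`.
#' @export
raw_intensity <- function(data, wavelengths = c(730, 850), fs = 10) {
  if (length(dim(data)) != 3) stop("data must be channels x wavelengths x time")
  if (dim(data)[2] != length(wavelengths))
    stop("second dimension must match wavelengths")
  if (any(data <= 0)) stop("intensities must be > 0")
  structure(list(data = data, wavelengths = wavelengths, fs = fs),
            class = "raw_intensity")
}

#' Read a samples-x-channels CSV into a channels-x-time matrix
#'
#' The CSV holds one chromophore: rows are samples, columns are channels, the
#' header row carries channel ids. Columns are reordered to the layout's
#' channel order; ids that do not exactly match the layout are an error, as
#' are non-numeric cells.
#'
#' @param path CSV file path.
#' @param fs sampling rate in Hz (recorded on the result as an attribute).
#' @param layout a [probe_layout()].
#' @return channels x time numeric matrix, rows named by channel id.
#' @export
read_csv_matrix <- function(path, fs, layout) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  ids <- colnames(df)
  if (length(ids) != layout$n_channels)
    stop(sprintf("expected %d channel columns, found %d",
                 layout$n_channels, length(ids)))
  if (!setequal(ids, layout$channel_ids))
    stop("header channel ids do not match layout: missing ",
         paste(setdiff(layout$channel_ids, ids), collapse = ", "))
  m <- as.matrix(df[, layout$channel_ids, drop = FALSE])
  if (!is.numeric(m) || anyNA(m)) stop("non-numeric cell in ", path)
  out <- t(m)
  rownames(out) <- layout$channel_ids
  attr(out, "fs") <- fs
  out
}

#' Write a channels-x-time matrix as a samples-x-channels CSV
#'
#' @param x channels x time matrix.
#' @param path output CSV path.
#' @param layout a [probe_layout()] supplying the header ids.
#' @export
write_csv_matrix <- function(x, path, layout) {
  df <- as.data.frame(t(x))
  colnames(df) <- layout$channel_ids
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write / read an `hb_series` as a plain-text recording bundle
#'
#' The native on-disk container is plain text: `<prefix>_hbo.csv` and
#' `<prefix>_hbr.csv` (samples x channels) plus `<prefix>_meta.json` holding
#' sampling rate, condition and the validity mask. Round-trips preserve the
#' data to write/read precision.
#'
#' @param hb an [hb_series()].
#' @param prefix output path prefix.
#' @param layout a [probe_layout()].
#' @return `prefix`, invisibly (`write_hb`); an `hb_series` (`read_hb`).
#' @export
write_hb <- function(hb, prefix, layout) {
  write_csv_matrix(hb$hbo, paste0(prefix, "_hbo.csv"), layout)
  write_csv_matrix(hb$hbr, paste0(prefix, "_hbr.csv"), layout)
  meta <- list(fs = hb$fs, condition = hb$condition,
               valid_channels = hb$valid_channels)
  jsonlite::write_json(meta, paste0(prefix, "_meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_hb
#' @export
read_hb <- function(prefix, layout) {
  meta_path <- paste0(prefix, "_meta.json")
  if (!file.exists(meta_path)) stop("missing sidecar: ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  hbo <- read_csv_matrix(paste0(prefix, "_hbo.csv"), meta$fs, layout)
  hbr <- read_csv_matrix(paste0(prefix, "_hbr.csv"), meta$fs, layout)
  hb_series(hbo, hbr, fs = meta$fs, valid_channels = meta$valid_channels,
            condition = meta$condition)
}

#' Write / read a probe layout as JSON
#'
#' @param layout a [probe_layout()].
#' @param path JSON file path.
#' @export
write_layout_json <- function(layout, path) {
  jsonlite::write_json(unclass(layout), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_layout_json
#' @export
read_layout_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("n_channels", "channel_ids", "region_of_channel",
              "separation_cm"))
    if (is.null(x[[f]])) stop("layout JSON missing field: ", f)
  probe_layout(x$n_channels, x$region_of_channel,
               source_idx = x$source_idx, detector_idx = x$detector_idx,
               separation_cm = x$separation_cm, channel_ids = x$channel_ids)
}
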