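#' Probe layout: channels, optodes and cortical regions
#'
#' A `probe_layout` describes the measurement montage: which source/detector
#' pair forms each channel, the source-detector separation, and which cortical
#' region each channel samples. Regions use hemisphere-anatomical labels
#' (`PFC_left`, `PFC_right`, `MC_left`, `MC_right`); dominance-relative labels
#' (DPFC/NPFC/DMC/NMC) are derived per subject with [assign_dominance()].
#'
#' @param n_channels number of measurement channels.
#' @param region_of_channel character vector of length `n_channels`, each
#'   entry one of `"PFC_left"`, `"PFC_right"`, `"MC_left"`, `"MC_right"`.
#' @param source_idx,detector_idx integer optode indices per channel
#'   (defaults: a nominal 1:1 pairing).
#' @param separation_cm source-detector separation in cm (> 0).
#' @param channel_ids channel labels; defaults to `"CH1"..` (user-facing
#'   labels are 1-based).
#' @return an object of class `probe_layout`.
#' @seealso [default_layout()] for the packaged 34-channel montage.
#' @export
probe_layout <- function(n_channels,
                         region_of_channel,
                         source_idx = seq_len(n_channels),
                         detector_idx = seq_len(n_channels),
                         separation_cm = 3,
                         channel_ids = paste0("CH", seq_len(n_channels))) {
  regions <- c("PFC_left", "PFC_right", "MC_left", "MC_right")
  if (length(region_of_channel) != n_channels)
    stop("region_of_channel must have one entry per channel")
  if (!all(region_of_channel %in% regions))
    stop("unknown region label(s): ",
         paste(setdiff(unique(region_of_channel), regions), collapse = ", "))
  if (anyNA(region_of_channel))
    stop("every channel must map to exactly one region")
  if (!is.numeric(separation_cm) || separation_cm <= 0)
    stop("separation_cm must be > 0")
  if (anyDuplicated(channel_ids))
    stop("channel_ids must be unique")
  structure(
    list(n_channels = as.integer(n_channels),
         channel_ids = as.character(channel_ids),
         source_idx = as.integer(source_idx),
         detector_idx = as.integer(detector_idx),
         region_of_channel = as.character(region_of_channel),
         separation_cm = separation_cm),
    class = "probe_layout")
}

#' Default 34-channel montage (14 prefrontal + 20 motor channels)
#'
#' The packaged montage has 34 channels at 3 cm separation: channels 1-7 over
#' the left prefrontal cortex, 8-14 over the right prefrontal cortex, 15-24
#' over the left motor cortex and 25-34 over the right motor cortex. The
#' 20-channel motor set yields 190 upper-triangle channel pairs, the feature
#' dimensionality used by the dynamic-state analysis. The channel-to-region
#' assignment is a documented assumption of the packaged montage and can be
#' overridden by constructing a [probe_layout()] directly.
#'
#' @return a `probe_layout` with 34 channels.
#' @export
default_layout <- function() {
  regions <- c(rep("PFC_left", 7), rep("PFC_right", 7),
               rep("MC_left", 10), rep("MC_right", 10))
  probe_layout(34L, regions)
}

#' @export
print.probe_layout <- function(x, ...) {
  cat("probe_layout:", x$n_channels, "channels,",
      x$separation_cm, "cm separation\n")
  print(table(x$region_of_channel))
  invisible(x)
}

#' Subject metadata
#'
#' @param subject_id label.
#' @param group `"CP"` (cerebral palsy) or `"HC"` (healthy control).
#' @param age age in years (> 0); drives the differential pathlength factor.
#' @param dominant_side `"L"` or `"R"`: the dominant hemisphere (for CP, the
#'   hemisphere ipsilateral to the affected side). Taken from the metadata
#'   table, never inferred.
#' @return an object of class `subject_meta`.
#' @export
subject_meta <- function(subject_id, group = c("HC", "CP"), age,
                         dominant_side = c("R", "L")) {
  group <- match.arg(group)
  dominant_side <- match.arg(dominant_side)
  if (!is.numeric(age) || age <= 0) stop("age must be > 0")
  structure(list(subject_id = as.character(subject_id), group = group,
                 age = age, dominant_side = dominant_side),
            class = "subject_meta")
}

#' Relabel regions by hemispheric dominance
#'
#' Maps the anatomical region of each channel to dominance-relative labels:
#' regions on the dominant hemisphere become `DPFC`/`DMC`, the other
#' hemisphere `NPFC`/`NMC`. Applying the map with the opposite side swaps
#' D and N labels (the relabeling is an involution).
#'
#' @param layout a [probe_layout()].
#' @param meta a [subject_meta()] (or a side string `"L"`/`"R"`).
#' @return character vector per channel in `{DPFC, NPFC, DMC, NMC}`.
#' @export
assign_dominance <- function(layout, meta) {
  side <- if (inherits(meta, "subject_meta")) meta$dominant_side else meta
  if (!side %in% c("L", "R")) stop("dominant_side must be 'L' or 'R'")
  dom <- if (side == "L") "left" else "right"
  reg <- layout$region_of_channel
  hemi <- ifelse(grepl("_left$", reg), "left", "right")
  lobe <- ifelse(grepl("^PFC", reg), "PFC", "MC")
  paste0(ifelse(hemi == dom, "D", "N"), lobe)
}
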