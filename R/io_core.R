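# Data model and I/O: two-channel stacks, traces, ROIs, stimulus protocols.
#
# Conventions used throughout the package:
#   * pixel coordinates are 0-based (row, col), row-major, with pixel centers
#     at integer coordinates;
#   * within one channel, sample i is at time i * frame_interval_s from that
#     channel's first frame (the half-frame offset between the two excitation
#     wavelengths is ignored: it is far below every fitted time constant);
#   * stacks are stored as T x H x W numeric arrays.

#' Stimulus protocol
#'
#' Describes an electrical stimulus train: when it starts relative to the
#' first frame, how many stimuli are delivered, at what frequency, and at
#' what nominal intensity.
#'
#' @param onset_time_s Seconds from the first frame to the first stimulus.
#' @param n_stimuli Number of stimuli in the train (>= 0).
#' @param frequency_hz Stimulation frequency in Hz (required > 0 when
#'   `n_stimuli > 1`).
#' @param intensity_v Nominal stimulus intensity label, in volts.
#' @return An object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(onset_time_s, n_stimuli, frequency_hz = 20,
                              intensity_v = 20) {
  stopifnot(is.numeric(onset_time_s), length(onset_time_s) == 1,
            onset_time_s >= 0)
  stopifnot(is.numeric(n_stimuli), length(n_stimuli) == 1, n_stimuli >= 0)
  if (n_stimuli > 1 && (!is.numeric(frequency_hz) || frequency_hz <= 0)) {
    stop("frequency_hz must be > 0 when n_stimuli > 1")
  }
  structure(list(onset_time_s = as.numeric(onset_time_s),
                 n_stimuli = as.integer(n_stimuli),
                 frequency_hz = as.numeric(frequency_hz),
                 intensity_v = as.numeric(intensity_v)),
            class = "stimulus_protocol")
}

#' Stimulus times of a protocol
#'
#' @param stim A [stimulus_protocol()].
#' @return Numeric vector of stimulus times in seconds (empty when
#'   `n_stimuli == 0`).
#' @export
stimulus_times <- function(stim) {
  if (is.null(stim) || stim$n_stimuli == 0) return(numeric(0))
  stim$onset_time_s + (seq_len(stim$n_stimuli) - 1) / stim$frequency_hz
}

#' Two-channel fluorescence stack
#'
#' Bundles the deinterleaved green (calcium-dependent) and red
#' (calcium-independent reference) frame sequences with their shared timing
#' and stimulus metadata.
#'
#' @param green,red Numeric T x H x W arrays with identical dimensions and
#'   non-negative values.
#' @param frame_interval_s Seconds per frame within one channel (> 0).
#' @param stim A [stimulus_protocol()] or `NULL`.
#' @return An object of class `two_channel_stack`.
#' @export
two_channel_stack <- function(green, red, frame_interval_s, stim = NULL) {
  if (!is.array(green) || !is.array(red) || length(dim(green)) != 3 ||
      length(dim(red)) != 3 || !identical(dim(green), dim(red))) {
    stop("green and red must be T x H x W arrays with identical dimensions")
  }
  stopifnot(is.numeric(frame_interval_s), frame_interval_s > 0)
  if (any(green < 0) || any(red < 0)) stop("intensities must be >= 0")
  if (!is.null(stim) && !inherits(stim, "stimulus_protocol")) {
    stop("stim must be a stimulus_protocol or NULL")
  }
  structure(list(green = green, red = red,
                 frame_interval_s = as.numeric(frame_interval_s),
                 stim = stim, pixel_origin = "rc0"),
            class = "two_channel_stack")
}

#' @export
print.two_channel_stack <- function(x, ...) {
  d <- dim(x$green)
  cat(sprintf("<two_channel_stack> %d frames/channel, %d x %d px, dt = %g s\n",
              d[1], d[2], d[3], x$frame_interval_s))
  if (!is.null(x$stim)) {
    cat(sprintf("  stim: %d @ %g Hz, onset %g s, %g V\n", x$stim$n_stimuli,
                x$stim$frequency_hz, x$stim$onset_time_s, x$stim$intensity_v))
  }
  invisible(x)
}

#' Frame times of one channel of a stack
#' @param stack A [two_channel_stack()].
#' @return Numeric vector of frame times in seconds, starting at 0.
#' @export
frame_times <- function(stack) {
  (seq_len(dim(stack$green)[1]) - 1) * stack$frame_interval_s
}

#' Fluorescence trace
#'
#' One time series extracted from an ROI or region, tagged with the
#' processing stage it has reached.
#'
#' @param times_s Strictly increasing sample times, seconds.
#' @param values Fluorescence (or F/F0, or green/red ratio) per sample.
#' @param stage One of `"raw"`, `"bleach_corrected"`, `"normalized"`,
#'   `"ratio"`.
#' @param f0 Baseline used for normalization (required > 0 when
#'   `stage == "normalized"`).
#' @param id Optional ROI identifier carried through to CSV output.
#' @return An object of class `trace`.
#' @export
trace <- function(times_s, values, stage = "raw", f0 = NULL, id = NA_character_) {
  stopifnot(length(times_s) == length(values), length(times_s) >= 1)
  if (any(diff(times_s) <= 0)) stop("times_s must be strictly increasing")
  stage <- match.arg(stage, c("raw", "bleach_corrected", "normalized", "ratio"))
  if (stage == "normalized") {
    if (is.null(f0) || f0 <= 0) stop("normalized traces require f0 > 0")
  }
  structure(list(times_s = as.numeric(times_s), values = as.numeric(values),
                 stage = stage, f0 = if (is.null(f0)) NA_real_ else f0,
                 id = as.character(id)),
            class = "trace")
}

#' @export
print.trace <- function(x, ...) {
  cat(sprintf("<trace %s> %d samples, t = [%g, %g] s, stage = %s\n",
              x$id, length(x$values), x$times_s[1],
              x$times_s[length(x$times_s)], x$stage))
  invisible(x)
}

#' Region of interest
#'
#' A labeled pixel set with a designated center. Coordinates are 0-based
#' (row, col).
#'
#' @param id Identifier.
#' @param pixels Integer matrix with columns (row, col), one pixel per row.
#' @param center Length-2 integer (row, col); must be one of `pixels`.
#' @param kind One of `"punctum"`, `"fixed3x3"`, `"region"`, `"background"`.
#' @return An object of class `roi`.
#' @export
roi <- function(id, pixels, center, kind = "region") {
  kind <- match.arg(kind, c("punctum", "fixed3x3", "region", "background"))
  pixels <- matrix(as.integer(pixels), ncol = 2,
                   dimnames = list(NULL, c("row", "col")))
  if (nrow(pixels) == 0) stop("pixels must be non-empty")
  center <- as.integer(center)
  if (!any(pixels[, 1] == center[1] & pixels[, 2] == center[2])) {
    stop("center must be one of the ROI's pixels")
  }
  if (kind == "fixed3x3") {
    if (nrow(pixels) > 9 ||
        any(abs(pixels[, 1] - center[1]) > 1) ||
        any(abs(pixels[, 2] - center[2]) > 1)) {
      stop("fixed3x3 ROI pixels must fit in a 3x3 window around the center")
    }
  }
  structure(list(id = as.character(id), pixels = pixels, center = center,
                 kind = kind),
            class = "roi")
}

# --- deinterleaving ---------------------------------------------------------

#' Split an interleaved frame sequence into its two channels
#'
#' Acquisitions alternate the excitation wavelength frame by frame, so the
#' raw stack holds the two channels interleaved; this separates them.
#'
#' @param frames A T x H x W array (T even) of interleaved frames.
#' @param order `"GR"` (green excitation first, the default) or `"RG"`.
#' @return `list(green =, red =)` of (T/2) x H x W arrays.
#' @export
deinterleave <- function(frames, order = c("GR", "RG")) {
  order <- match.arg(order)
  stopifnot(is.array(frames), length(dim(frames)) == 3)
  n <- dim(frames)[1]
  if (n %% 2 != 0) {
    stop("malformed input: interleaved stack must have an even frame count")
  }
  odd <- frames[seq(1, n, by = 2), , , drop = FALSE]
  even <- frames[seq(2, n, by = 2), , , drop = FALSE]
  if (order == "GR") list(green = odd, red = even)
  else list(green = even, red = odd)
}

#' Re-interleave two channels into one frame sequence
#'
#' Inverse of [deinterleave()]: `interleave(deinterleave(x, o), o)` is `x`.
#'
#' @param green,red (T) x H x W arrays of equal dimensions.
#' @param order `"GR"` or `"RG"`.
#' @return A (2T) x H x W array.
#' @export
interleave <- function(green, red, order = c("GR", "RG")) {
  order <- match.arg(order)
  stopifnot(identical(dim(green), dim(red)))
  d <- dim(green)
  out <- array(0, c(2 * d[1], d[2], d[3]))
  if (order == "GR") {
    out[seq(1, 2 * d[1], by = 2), , ] <- green
    out[seq(2, 2 * d[1], by = 2), , ] <- red
  } else {
    out[seq(1, 2 * d[1], by = 2), , ] <- red
    out[seq(2, 2 * d[1], by = 2), , ] <- green
  }
  out
}

# --- stack reader / writer --------------------------------------------------

#' Read a two-channel stack from a multi-page TIFF plus metadata sidecar
#'
#' The TIFF holds the interleaved 16-bit frames; the YAML sidecar declares
#' the frame interval, the channel order of the interleave, and (optionally)
#' the stimulus protocol. Round-trips bit-exactly with [write_stack()] for
#' integer data.
#'
#' @param path Multi-page TIFF file.
#' @param meta_path YAML sidecar with keys `frame_interval_s`,
#'   `channel_order`, and optionally `stim` (with `onset_time_s`,
#'   `n_stimuli`, `frequency_hz`, `intensity_v`).
#' @return A [two_channel_stack()].
#' @export
read_stack <- function(path, meta_path) {
  if (!file.exists(path)) stop("I/O error: no such file: ", path)
  if (!file.exists(meta_path)) stop("I/O error: no such file: ", meta_path)
  meta <- yaml::read_yaml(meta_path)
  for (key in c("frame_interval_s", "channel_order")) {
    if (is.null(meta[[key]])) stop("metadata error: missing key '", key, "'")
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  n <- length(pages)
  if (n %% 2 != 0) {
    stop("malformed input: interleaved TIFF must have an even page count, got ", n)
  }
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  frames <- array(0, c(n, h, w))
  for (i in seq_len(n)) frames[i, , ] <- pages[[i]]
  frames[frames < 0] <- 0
  ch <- deinterleave(frames, order = meta$channel_order)
  stim <- NULL
  if (!is.null(meta$stim)) {
    stim <- stimulus_protocol(meta$stim$onset_time_s, meta$stim$n_stimuli,
                              meta$stim$frequency_hz, meta$stim$intensity_v)
  }
  two_channel_stack(ch$green, ch$red, meta$frame_interval_s, stim)
}

#' Write a two-channel stack as an interleaved 16-bit TIFF plus sidecar
#'
#' Values are rounded and clamped to the 16-bit range `[0, 65535]`.
#'
#' @param stack A [two_channel_stack()].
#' @param path Output TIFF path.
#' @param meta_path Output YAML sidecar path.
#' @param order Channel order of the interleave, `"GR"` or `"RG"`.
#' @return Invisibly, `path`.
#' @export
write_stack <- function(stack, path, meta_path, order = "GR") {
  frames <- interleave(stack$green, stack$red, order = order)
  frames <- pmin(pmax(round(frames), 0), 65535)
  pages <- lapply(seq_len(dim(frames)[1]),
                  function(i) frames[i, , ] / 65535)
  ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = 16L), silent = TRUE)
  if (inherits(ok, "try-error")) stop("I/O error writing TIFF: ", path)
  meta <- list(frame_interval_s = stack$frame_interval_s,
               channel_order = order)
  if (!is.null(stack$stim)) {
    meta$stim <- list(onset_time_s = stack$stim$onset_time_s,
                      n_stimuli = stack$stim$n_stimuli,
                      frequency_hz = stack$stim$frequency_hz,
                      intensity_v = stack$stim$intensity_v)
  }
  yaml::write_yaml(meta, meta_path)
  invisible(path)
}

# --- trace CSV --------------------------------------------------------------

#' Write traces to a long-format CSV
#'
#' Columns: `roi_id, time_s, value, stage`. An empty collection yields a
#' header-only file.
#'
#' @param traces List of [trace()] objects.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_traces <- function(traces, path) {
  rows <- lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    id <- if (is.na(tr$id)) as.character(i) else tr$id
    data.frame(roi_id = id, time_s = tr$times_s, value = tr$values,
               stage = tr$stage, stringsAsFactors = FALSE)
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(roi_id = character(), time_s = numeric(), value = numeric(),
               stage = character(), stringsAsFactors = FALSE)
  ok <- try(utils::write.csv(df, path, row.names = FALSE), silent = TRUE)
  if (inherits(ok, "try-error")) stop("I/O error writing CSV: ", path)
  invisible(path)
}

#' Read traces written by [write_traces()]
#'
#' @param path CSV path.
#' @return List of [trace()] objects, one per distinct `roi_id`, in first
#'   appearance order.
#' @export
read_traces <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(roi_id = "character"))
  ids <- unique(df$roi_id)
  lapply(ids, function(id) {
    sub <- df[df$roi_id == id, , drop = FALSE]
    trace(sub$time_s, sub$value, stage = sub$stage[1], id = id,
          f0 = if (sub$stage[1] == "normalized") 1 else NULL)
  })
}

#' Write ROIs to CSV (summary) plus a JSON pixel-list file
#'
#' @param rois List of [roi()] objects.
#' @param csv_path Summary CSV (`id, kind, center_row, center_col, n_pixels`).
#' @param json_path Optional JSON file with the full pixel lists.
#' @return Invisibly, `csv_path`.
#' @export
write_rois <- function(rois, csv_path, json_path = NULL) {
  df <- data.frame(
    id = vapply(rois, function(r) r$id, character(1)),
    kind = vapply(rois, function(r) r$kind, character(1)),
    center_row = vapply(rois, function(r) r$center[1], integer(1)),
    center_col = vapply(rois, function(r) r$center[2], integer(1)),
    n_pixels = vapply(rois, function(r) nrow(r$pixels), integer(1)),
    stringsAsFactors = FALSE)
  utils::write.csv(df, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    px <- lapply(rois, function(r) {
      list(id = r$id, kind = r$kind, center = as.integer(r$center),
           pixels = unname(apply(r$pixels, 1, as.integer, simplify = FALSE)))
    })
    jsonlite::write_json(px, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}
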