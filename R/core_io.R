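#' Electrode map
#'
#' Assigns each electrode an identity, a position on the chip (micrometers)
#' and a compartment: `LEFT` or `RIGHT` organoid, the connecting axon
#' `BUNDLE`, or `UNUSED`. Inter-compartment analyses (synchronized-burst
#' pairing, inter-organoid coupling) require at least one LEFT and one RIGHT
#' electrode.
#'
#' @param electrode_id integer vector, unique electrode identifiers.
#' @param x_um,y_um numeric electrode positions in micrometers.
#' @param compartment character vector, one of `"LEFT"`, `"RIGHT"`,
#'   `"BUNDLE"`, `"UNUSED"`.
#' @return A `data.frame` of class `electrode_map`.
#' @export
electrode_map <- function(electrode_id, x_um = 0, y_um = 0,
                          compartment = "LEFT") {
  em <- data.frame(electrode_id = as.integer(electrode_id),
                   x_um = as.numeric(x_um), y_um = as.numeric(y_um),
                   compartment = as.character(compartment),
                   stringsAsFactors = FALSE)
  validate_electrode_map(em)
  class(em) <- c("electrode_map", "data.frame")
  em
}

validate_electrode_map <- function(em) {
  stopifnot(is.data.frame(em),
            all(c("electrode_id", "x_um", "y_um", "compartment") %in%
                  names(em)))
  if (anyDuplicated(em$electrode_id))
    stop("electrode ids must be unique")
  if (!all(is.finite(em$x_um)) || !all(is.finite(em$y_um)))
    stop("electrode positions must be finite")
  ok <- em$compartment %in% c("LEFT", "RIGHT", "BUNDLE", "UNUSED")
  if (!all(ok))
    stop("unknown compartment label(s): ",
         paste(unique(em$compartment[!ok]), collapse = ", "))
  invisible(em)
}

#' Grid electrode map for a two-compartment chip
#'
#' Convenience constructor: `n` electrodes split into a LEFT and a RIGHT
#' block of equal size laid out on square grids separated by `gap_um`.
#'
#' @param n total electrode count (even).
#' @param pitch_um electrode pitch within a block.
#' @param gap_um separation between the two blocks.
#' @return An `electrode_map`.
#' @export
two_compartment_map <- function(n = 64, pitch_um = 150, gap_um = 1500) {
  stopifnot(n >= 2, n %% 2 == 0)
  half <- n / 2
  side <- ceiling(sqrt(half))
  idx <- seq_len(half) - 1L
  x <- (idx %% side) * pitch_um
  y <- (idx %/% side) * pitch_um
  electrode_map(electrode_id = seq_len(n),
                x_um = c(x, x + max(x) + gap_um),
                y_um = c(y, y),
                compartment = rep(c("LEFT", "RIGHT"), each = half))
}

#' Multichannel extracellular recording
#'
#' The universal input of the pipeline: a channels-by-time matrix of
#' extracellular voltage in microvolts, its sampling rate, an
#' [electrode_map()] whose rows correspond one-to-one to channel rows, the
#' acquisition band, an optional stimulus log and free-form annotations.
#'
#' @param samples numeric matrix, channels x time, microvolts.
#' @param sampling_rate_hz positive sampling rate (canonical 20000).
#' @param electrode_map an [electrode_map()] with one row per channel.
#' @param acquisition_band_hz length-2 band recorded by the amplifier.
#' @param stimlog optional [stimulus_log()].
#' @param annotations named list of free-form metadata.
#' @return An object of class `Recording`.
#' @export
recording <- function(samples, sampling_rate_hz, electrode_map,
                      acquisition_band_hz = c(0.1, 10000),
                      stimlog = NULL, annotations = list()) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1)
  stopifnot(is.matrix(samples), is.numeric(samples),
            sampling_rate_hz > 0, ncol(samples) >= 1)
  validate_electrode_map(electrode_map)
  if (nrow(samples) != nrow(electrode_map))
    stop("channel count (", nrow(samples),
         ") does not match electrode map size (", nrow(electrode_map), ")")
  if (!is.null(stimlog)) validate_stimlog(stimlog)
  rec <- structure(list(samples = samples,
                        sampling_rate_hz = sampling_rate_hz,
                        electrode_map = electrode_map,
                        acquisition_band_hz = as.numeric(acquisition_band_hz),
                        stimlog = stimlog,
                        annotations = annotations),
                   class = "Recording")
  rec
}

#' @export
print.Recording <- function(x, ...) {
  cat(sprintf("Recording: %d channels x %d samples @ %g Hz (%.2f s)\n",
              nrow(x$samples), ncol(x$samples), x$sampling_rate_hz,
              rec_duration(x)))
  cat("  compartments:",
      paste(sprintf("%s=%d", names(table(x$electrode_map$compartment)),
                    table(x$electrode_map$compartment)), collapse = " "), "\n")
  if (!is.null(x$stimlog))
    cat(sprintf("  stimulus log: %d pulses (%s)\n",
                length(x$stimlog$pulse_onsets_s), x$stimlog$label))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec a `Recording`.
#' @export
rec_duration <- function(rec) ncol(rec$samples) / rec$sampling_rate_hz

#' Channel indices belonging to a compartment
#' @param rec a `Recording`.
#' @param compartment `"LEFT"`, `"RIGHT"` or `"BUNDLE"`.
#' @export
compartment_channels <- function(rec, compartment) {
  which(rec$electrode_map$compartment == compartment)
}

#' Optogenetic stimulation log
#'
#' Event-time representation of TTL-driven light pulses: pulse onsets,
#' width, nominal train frequency and the actuator label (`EXCITE_470` for
#' ChR2 pacing pulses, `INHIBIT_565` for ArchT silencing illumination).
#' Optional epochs partition the session into labelled states.
#'
#' @param pulse_onsets_s strictly increasing onset times (s).
#' @param pulse_width_s pulse width (s).
#' @param train_frequency_hz nominal stimulation frequency (Hz).
#' @param label `"EXCITE_470"`, `"INHIBIT_565"` or `"NONE"`.
#' @param epochs optional `data.frame(start_s, end_s, state)` with
#'   non-overlapping spans.
#' @return An object of class `stimulus_log`.
#' @export
stimulus_log <- function(pulse_onsets_s = numeric(0), pulse_width_s = 0.2,
                         train_frequency_hz = 1, label = "NONE",
                         epochs = NULL) {
  sl <- structure(list(pulse_onsets_s = as.numeric(pulse_onsets_s),
                       pulse_width_s = pulse_width_s,
                       train_frequency_hz = train_frequency_hz,
                       label = label, epochs = epochs),
                  class = "stimulus_log")
  validate_stimlog(sl)
  sl
}

validate_stimlog <- function(sl) {
  stopifnot(inherits(sl, "stimulus_log"))
  if (length(sl$pulse_onsets_s) > 1 && any(diff(sl$pulse_onsets_s) <= 0))
    stop("pulse onsets must be strictly increasing")
  if (!sl$label %in% c("EXCITE_470", "INHIBIT_565", "NONE"))
    stop("unknown stimulus label: ", sl$label)
  if (!is.null(sl$epochs)) {
    ep <- sl$epochs
    stopifnot(all(c("start_s", "end_s", "state") %in% names(ep)))
    if (any(ep$end_s <= ep$start_s)) stop("epochs must have end > start")
    if (nrow(ep) > 1) {
      o <- order(ep$start_s)
      if (any(ep$start_s[o][-1] < ep$end_s[o][-nrow(ep)]))
        stop("epochs must not overlap")
    }
  }
  invisible(sl)
}

#' Import a sampled TTL channel as a stimulus log
#'
#' Thresholds a recorded TTL trace at half its logic level and keeps rising
#' edges only.
#'
#' @param ttl numeric vector, sampled TTL signal.
#' @param sampling_rate_hz sampling rate of `ttl`.
#' @param logic_level TTL high level in the trace's units.
#' @inheritParams stimulus_log
#' @return A `stimulus_log`.
#' @export
stimlog_from_ttl <- function(ttl, sampling_rate_hz, logic_level = max(ttl),
                             pulse_width_s = 0.2, train_frequency_hz = 1,
                             label = "EXCITE_470") {
  hi <- ttl > logic_level / 2
  rising <- which(hi & !c(FALSE, hi[-length(hi)]))
  stimulus_log(pulse_onsets_s = (rising - 1) / sampling_rate_hz,
               pulse_width_s = pulse_width_s,
               train_frequency_hz = train_frequency_hz, label = label)
}

#' Write a recording container
#'
#' Serializes the full `Recording` (signals, electrode map, stimulus log,
#' annotations) to a single container file. [load_recording()] reproduces
#' it field-by-field (floats to machine precision).
#'
#' @param rec a `Recording`.
#' @param path destination file path.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "Recording"))
  saveRDS(rec, path)
  invisible(path)
}

#' Load a recording container
#'
#' @param path file written by [write_recording()].
#' @return The validated `Recording`.
#' @export
load_recording <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  rec <- readRDS(path)
  if (!inherits(rec, "Recording") || is.null(rec$sampling_rate_hz))
    stop("file is not a recording container (missing sampling rate)")
  # re-validate: channel/map mismatch or corrupted fields must not pass
  recording(rec$samples, rec$sampling_rate_hz, rec$electrode_map,
            rec$acquisition_band_hz, rec$stimlog, rec$annotations)
}

#' Extract a time slice of a recording
#'
#' Returns the half-open slice `[start_s, end_s)`; sample `i` covers time
#' `[i/fs, (i+1)/fs)`. Stimulus events outside the slice are dropped and the
#' remaining ones re-zeroed to the new origin; the electrode map is
#' unchanged.
#'
#' @param rec a `Recording`.
#' @param start_s,end_s slice bounds in seconds, `0 <= start_s < end_s <=
#'   duration`.
#' @return A `Recording`.
#' @export
segment_recording <- function(rec, start_s, end_s) {
  dur <- rec_duration(rec)
  if (!(start_s >= 0 && start_s < end_s && end_s <= dur + 1e-9))
    stop("slice [", start_s, ", ", end_s, ") out of range [0, ", dur, "]")
  i0 <- floor(start_s * rec$sampling_rate_hz) + 1
  i1 <- floor(end_s * rec$sampling_rate_hz + 1e-9)
  sl <- rec$stimlog
  if (!is.null(sl)) {
    keep <- sl$pulse_onsets_s >= start_s & sl$pulse_onsets_s < end_s
    ep <- sl$epochs
    if (!is.null(ep)) {
      ep <- ep[ep$end_s > start_s & ep$start_s < end_s, , drop = FALSE]
      if (nrow(ep)) {
        ep$start_s <- pmax(ep$start_s, start_s) - start_s
        ep$end_s <- pmin(ep$end_s, end_s) - start_s
      } else ep <- NULL
    }
    sl <- stimulus_log(sl$pulse_onsets_s[keep] - start_s, sl$pulse_width_s,
                       sl$train_frequency_hz, sl$label, ep)
  }
  recording(rec$samples[, i0:i1, drop = FALSE], rec$sampling_rate_hz,
            rec$electrode_map, rec$acquisition_band_hz, sl, rec$annotations)
}

#' Export / import electrode maps and stimulus logs as CSV
#'
#' Plain-text side-car formats: electrode maps use columns
#' `electrode_id,x_um,y_um,compartment`; stimulus logs use one row per pulse
#' (`onset_s`) with width/frequency/label carried in a header comment.
#'
#' @param em an `electrode_map`.
#' @param path CSV file path.
#' @export
write_electrode_map_csv <- function(em, path) {
  validate_electrode_map(em)
  utils::write.csv(as.data.frame(em), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_electrode_map_csv
#' @export
read_electrode_map_csv <- function(path) {
  em <- utils::read.csv(path, stringsAsFactors = FALSE)
  electrode_map(em$electrode_id, em$x_um, em$y_um, em$compartment)
}

#' @rdname write_electrode_map_csv
#' @param sl a `stimulus_log`.
#' @export
write_stimlog_csv <- function(sl, path) {
  validate_stimlog(sl)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pulse_width_s=%g frequency_hz=%g label=%s",
                     sl$pulse_width_s, sl$train_frequency_hz, sl$label), con)
  utils::write.csv(data.frame(onset_s = sl$pulse_onsets_s), con,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_electrode_map_csv
#' @export
read_stimlog_csv <- function(path) {
  hdr <- readLines(path, n = 1)
  kv <- regmatches(hdr, gregexpr("[a-z_]+=[^ ]+", hdr))[[1]]
  kv <- strsplit(kv, "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  on <- utils::read.csv(path, comment.char = "#")
  stimulus_log(on$onset_s,
               pulse_width_s = as.numeric(vals[["pulse_width_s"]]),
               train_frequency_hz = as.numeric(vals[["frequency_hz"]]),
               label = vals[["label"]])
}
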