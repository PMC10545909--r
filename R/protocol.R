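#' Build a saturation-pulse light-protocol timeline
#'
#' A timeline describes, frame by frame, the light regime of an acquisition:
#' a dark-adapted reference block, an actinic-light block and a dark
#' relaxation block, acquired at uniform spacing. Frames concurrent with a
#' saturating pulse are flagged so that Y-mode analyses can locate Fm.
#'
#' @param n_dark Number of dark-reference frames (>= 1; the NPQ reference
#'   Fm is averaged over these).
#' @param n_light Number of frames under actinic light.
#' @param n_relax Number of dark relaxation frames after the light block.
#' @param interval Time between consecutive acquisitions, seconds.
#' @param actinic_intensity Actinic light intensity, umol photons m-2 s-1.
#' @param pulse_frames Integer indices (1-based) of frames acquired during a
#'   saturating pulse; empty when the measuring laser itself saturates.
#' @param pulse_intensity Saturating-pulse intensity, umol photons m-2 s-1.
#' @param pulse_duration Pulse duration in seconds; must be > 0 if any
#'   frame is pulse-flagged.
#' @return A `protocol_timeline`: list with `frames` (data.frame with
#'   columns `timestamp`, `phase`, `pulse`), `actinic_intensity`,
#'   `pulse_intensity`, `pulse_duration`.
#' @examples
#' tl <- build_timeline(3, 6, 6, 60, actinic_intensity = 500)
#' table(tl$frames$phase)
#' @export
build_timeline <- function(n_dark, n_light, n_relax, interval,
                           actinic_intensity = 0,
                           pulse_frames = integer(),
                           pulse_intensity = 2000,
                           pulse_duration = 1.1) {
  if (n_dark < 1)
    stop("invalid protocol: at least one dark_reference frame is required (no Fm reference possible)")
  if (n_light < 0 || n_relax < 0) stop("frame counts must be >= 0")
  if (interval <= 0) stop("interval must be > 0")
  n <- n_dark + n_light + n_relax
  pulse_frames <- as.integer(pulse_frames)
  if (length(pulse_frames) && (any(pulse_frames < 1) || any(pulse_frames > n)))
    stop("pulse_frames out of range")
  if (length(pulse_frames) && pulse_duration <= 0)
    stop("pulse_duration must be > 0 when pulse frames are set")
  frames <- data.frame(
    timestamp = (seq_len(n) - 1) * interval,
    phase = rep(c("dark_reference", "actinic", "relaxation"),
                c(n_dark, n_light, n_relax)),
    pulse = seq_len(n) %in% pulse_frames,
    stringsAsFactors = FALSE
  )
  tl <- structure(list(frames = frames,
                       actinic_intensity = actinic_intensity,
                       pulse_intensity = pulse_intensity,
                       pulse_duration = pulse_duration),
                  class = "protocol_timeline")
  validate_timeline(tl)
}

#' Validate a protocol timeline
#'
#' Checks the structural invariants: strictly increasing timestamps, at
#' least one dark_reference frame, phases in dark_reference / actinic /
#' relaxation block order, and a positive pulse duration whenever a pulse
#' flag is set.
#'
#' @param timeline A `protocol_timeline`.
#' @return The timeline, invisibly unchanged, or an error.
#' @export
validate_timeline <- function(timeline) {
  if (!inherits(timeline, "protocol_timeline")) stop("not a protocol_timeline")
  fr <- timeline$frames
  stopifnot(is.data.frame(fr),
            all(c("timestamp", "phase", "pulse") %in% names(fr)))
  if (nrow(fr) < 1) stop("timeline has no frames")
  if (any(diff(fr$timestamp) <= 0)) stop("timestamps must be strictly increasing")
  known <- c("dark_reference", "actinic", "relaxation")
  if (!all(fr$phase %in% known)) stop("unknown phase label")
  if (!any(fr$phase == "dark_reference"))
    stop("invalid protocol: at least one dark_reference frame is required")
  ord <- match(fr$phase, known)
  if (any(diff(ord) < 0))
    stop("phases must appear in dark_reference, actinic, relaxation order")
  if (any(fr$pulse) && timeline$pulse_duration <= 0)
    stop("pulse_duration must be > 0 when any pulse flag is set")
  invisible(timeline)
}

phase_frames <- function(timeline, phase) which(timeline$frames$phase == phase)

#' @export
print.protocol_timeline <- function(x, ...) {
  tab <- table(factor(x$frames$phase,
                      c("dark_reference", "actinic", "relaxation")))
  cat(sprintf("protocol_timeline: %d frames (%d dark, %d actinic, %d relax), %g-%g s\n",
              nrow(x$frames), tab[1], tab[2], tab[3],
              min(x$frames$timestamp), max(x$frames$timestamp)))
  cat(sprintf("  actinic %g umol m-2 s-1; pulse %g umol m-2 s-1 x %g s on %d frame(s)\n",
              x$actinic_intensity, x$pulse_intensity, x$pulse_duration,
              sum(x$frames$pulse)))
  invisible(x)
}

#' Write / read a protocol timeline as JSON
#'
#' @param timeline A `protocol_timeline`.
#' @param path File path for the JSON document.
#' @return `write_timeline` returns `path` invisibly; `read_timeline`
#'   returns the parsed, validated `protocol_timeline`. The pair is an
#'   exact round trip.
#' @export
write_timeline <- function(timeline, path) {
  validate_timeline(timeline)
  obj <- list(frames = timeline$frames,
              actinic_intensity = timeline$actinic_intensity,
              pulse_intensity = timeline$pulse_intensity,
              pulse_duration = timeline$pulse_duration)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_timeline
#' @export
read_timeline <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  fr <- as.data.frame(obj$frames, stringsAsFactors = FALSE)
  fr$timestamp <- as.numeric(fr$timestamp)
  fr$pulse <- as.logical(fr$pulse)
  tl <- structure(list(frames = fr,
                       actinic_intensity = as.numeric(obj$actinic_intensity),
                       pulse_intensity = as.numeric(obj$pulse_intensity),
                       pulse_duration = as.numeric(obj$pulse_duration)),
                  class = "protocol_timeline")
  validate_timeline(tl)
}

# First timestamp of a phase block, or NA if the block is empty.
phase_onset <- function(timeline, phase) {
  i <- phase_frames(timeline, phase)
  if (!length(i)) return(NA_real_)
  timeline$frames$timestamp[i[1]]
}
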