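#' PSII capacity Y from a pulsed acquisition
#'
#' Y = (Fm - F')/Fm, where F' is the mean fluorescence of the dark-adapted
#' frames acquired with the non-saturating measuring laser before the
#' saturating pulse, and Fm is the maximum fluorescence among the frames
#' concurrent with the pulse.
#'
#' @param trace Background-corrected `fluor_trace`.
#' @param pulse_frames 1-based indices of the frames acquired during the
#'   saturating pulse.
#' @param pre_frames Indices of the pre-pulse frames used for F'; defaults
#'   to every frame before the first pulse frame.
#' @return List with `F_prime`, `Fm`, `Y`. `Y < 0` (F' above Fm, i.e. the
#'   measuring light itself saturated) is returned with a warning.
#' @examples
#' tr <- fluor_trace("cell", c(100, 100, 100, 100, 400), 0:4,
#'                   background_corrected = TRUE)
#' compute_Y(tr, pulse_frames = 5)$Y  # 0.75
#' @export
compute_Y <- function(trace, pulse_frames,
                      pre_frames = seq_len(min(pulse_frames) - 1)) {
  stopifnot(inherits(trace, "fluor_trace"))
  pulse_frames <- as.integer(pulse_frames)
  n <- length(trace$values)
  if (!length(pulse_frames) || any(pulse_frames < 1 | pulse_frames > n))
    stop("pulse_frames must be a non-empty set of valid frame indices")
  if (!length(pre_frames) || any(pre_frames < 1 | pre_frames > n))
    stop("at least one pre-pulse frame is required for F'")
  F_prime <- mean(trace$values[pre_frames])
  Fm <- max(trace$values[pulse_frames])
  if (Fm <= 0) stop("undefined parameter: Fm <= 0")
  Y <- (Fm - F_prime) / Fm
  if (Fm < F_prime)
    warning("Fm < F': Y is negative (measuring light likely saturating)")
  list(F_prime = F_prime, Fm = Fm, Y = Y)
}

#' NPQ time course from a saturating-measuring-light acquisition
#'
#' When the measuring laser itself saturates PSII, every frame records a
#' maximal fluorescence: the dark-adapted frames give Fm (averaged), and
#' each later frame gives Fm'(t), so NPQ(t) = (Fm - Fm'(t)) / Fm'(t).
#' NPQ is reported for every frame after the dark-reference block.
#'
#' @param trace Background-corrected `fluor_trace`, frame-aligned with
#'   `timeline`.
#' @param timeline A `protocol_timeline` with >= 1 dark_reference frame.
#' @return List with `Fm_dark` and `npq`, a data.frame of `frame`,
#'   `timestamp`, `phase`, `F` (Fm' per frame) and `npq`. Frames with
#'   F <= 0 get `npq = NA` (undefined, not dropped).
#' @examples
#' tl <- build_timeline(3, 1, 0, 60)
#' tr <- fluor_trace("cell", c(400, 400, 400, 200), tl$frames$timestamp,
#'                   background_corrected = TRUE)
#' compute_npq_series(tr, tl)$npq$npq  # 1
#' @export
compute_npq_series <- function(trace, timeline) {
  stopifnot(inherits(trace, "fluor_trace"))
  validate_timeline(timeline)
  fr <- timeline$frames
  if (length(trace$values) != nrow(fr))
    stop("trace length does not match timeline")
  dark <- phase_frames(timeline, "dark_reference")
  Fm_dark <- mean(trace$values[dark])
  if (!is.finite(Fm_dark) || Fm_dark <= 0) stop("Fm_dark <= 0: NPQ undefined")
  post <- which(seq_len(nrow(fr)) > max(dark))
  f <- trace$values[post]
  npq <- ifelse(f > 0, (Fm_dark - f) / f, NA_real_)
  if (anyNA(npq))
    message(sum(is.na(npq)), " frame(s) with F <= 0: NPQ marked undefined")
  list(Fm_dark = Fm_dark,
       npq = data.frame(frame = post, timestamp = fr$timestamp[post],
                        phase = fr$phase[post], F = f, npq = npq,
                        stringsAsFactors = FALSE))
}

#' Effective PSII quantum yield
#'
#' Standard saturation-pulse definition (Fm' - Fs)/Fm', with Fs the
#' steady-state fluorescence under the non-saturating measuring light and
#' Fm' the maximum reached during the concurrent saturating pulse.
#'
#' @param Fs Steady-state fluorescence, a.u.
#' @param Fm_pulse Pulse-saturated fluorescence, a.u. (> 0).
#' @return Dimensionless yield; negative (Fs > Fm') with a warning.
#' @export
compute_phi_psii <- function(Fs, Fm_pulse) {
  if (any(Fm_pulse <= 0)) stop("Fm_pulse must be > 0")
  if (any(Fs > Fm_pulse)) warning("Fs > Fm': negative PSII yield")
  (Fm_pulse - Fs) / Fm_pulse
}

# OLS slope of y on t (seconds), returned per minute; NA with < 2 points.
slope_per_min <- function(t, y) {
  ok <- is.finite(t) & is.finite(y)
  t <- t[ok]; y <- y[ok]
  if (length(t) < 2L) return(NA_real_)
  60 * sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
}

#' Six-variable kinetic feature set of one cell
#'
#' From an NPQ time course: NPQav (mean NPQ under actinic light), NPQmax
#' (maximum under actinic light), Induction and Decay (least-squares NPQ
#' slopes, min^-1, over the frames within the first 2 minutes of the
#' dark-to-light and light-to-dark transitions, windows inclusive at the
#' boundary), Fmax (the dark-adapted Fm of the cell, a.u.) and AreaFrac
#' (percent of the cell section occupied by plastids, passed through).
#'
#' @param npq Result of [compute_npq_series()] (or its `npq` data.frame).
#' @param timeline The `protocol_timeline` of the acquisition.
#' @param Fm_dark Dark-adapted Fm; taken from `npq` when available.
#' @param area_frac Plastid area fraction, percent (see [area_fraction()]).
#' @param window_s Transition-window length, seconds.
#' @return One-row data.frame with columns NPQav, NPQmax, Induction, Decay,
#'   Fmax, AreaFrac. Undefined features are NA, never 0.
#' @export
extract_features <- function(npq, timeline, Fm_dark = NULL, area_frac = NA_real_,
                             window_s = 120) {
  validate_timeline(timeline)
  if (is.list(npq) && !is.data.frame(npq) && !is.null(npq$npq)) {
    if (is.null(Fm_dark)) Fm_dark <- npq$Fm_dark
    npq <- npq$npq
  }
  if (is.null(Fm_dark)) stop("Fm_dark is required")
  if (!is.na(area_frac) && (area_frac < 0 || area_frac > 100))
    stop("area_frac must be within [0, 100]")
  light <- npq[npq$phase == "actinic", , drop = FALSE]
  relax <- npq[npq$phase == "relaxation", , drop = FALSE]
  t_on <- phase_onset(timeline, "actinic")
  t_off <- phase_onset(timeline, "relaxation")

  NPQav <- if (nrow(light)) mean(light$npq, na.rm = TRUE) else NA_real_
  NPQmax <- if (nrow(light)) suppressWarnings(max(light$npq, na.rm = TRUE)) else NA_real_
  if (!is.finite(NPQmax)) NPQmax <- NA_real_

  ind_w <- light[light$timestamp - t_on <= window_s, , drop = FALSE]
  Induction <- if (nrow(light)) slope_per_min(ind_w$timestamp, ind_w$npq) else NA_real_
  dec_w <- relax[relax$timestamp - t_off <= window_s, , drop = FALSE]
  Decay <- if (nrow(relax)) slope_per_min(dec_w$timestamp, dec_w$npq) else NA_real_

  data.frame(NPQav = NPQav, NPQmax = NPQmax, Induction = Induction,
             Decay = Decay, Fmax = Fm_dark, AreaFrac = area_frac)
}
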