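#' Define a region of interest on the projected frame
#'
#' @param mask Logical matrix `(y, x)`, TRUE inside the ROI; must be
#'   non-empty and match the projected frame geometry when used.
#' @param label Identifier.
#' @param role `"object"` (chloroplast, cell, tissue) or `"background"`
#'   (empty region used for background estimation). Background ROIs cannot
#'   have a parent.
#' @param parent Optional label of a containing ROI (plastid -> cell).
#' @return An `roi` object.
#' @export
roi <- function(mask, label, role = c("object", "background"), parent = NULL) {
  role <- match.arg(role)
  if (!is.matrix(mask) || !is.logical(mask)) stop("mask must be a logical matrix")
  if (!any(mask)) stop("ROI mask is empty")
  if (role == "background" && !is.null(parent))
    stop("background ROIs have no parent")
  structure(list(mask = mask, label = as.character(label), role = role,
                 parent = parent),
            class = "roi")
}

#' Mean gray value of an ROI over time
#'
#' For each timepoint of a projected series, the arithmetic mean of the
#' projected pixel values inside the ROI mask — the per-ROI raw
#' fluorescence trace.
#'
#' @param series A `projected_series`.
#' @param roi An [roi()].
#' @return A `fluor_trace`: list with `roi_label`, `role`, `values`,
#'   `timestamps`, `background_corrected = FALSE`.
#' @export
mean_gray <- function(series, roi) {
  stopifnot(inherits(series, "projected_series"), inherits(roi, "roi"))
  d <- dim(series$intensities)
  if (!identical(dim(roi$mask), c(d[2], d[3])))
    stop("ROI mask geometry does not match the projected frame")
  vals <- vapply(seq_len(d[1]),
                 function(t) mean(series$intensities[t, , ][roi$mask]),
                 numeric(1))
  fluor_trace(roi$label, vals, series$timestamps, role = roi$role)
}

#' Construct a fluorescence trace
#'
#' @param roi_label Identifier of the source ROI.
#' @param values Mean gray value per timepoint (a.u.).
#' @param timestamps Seconds, same length as `values`.
#' @param background_corrected Logical.
#' @param role ROI role the trace came from.
#' @return A `fluor_trace` object.
#' @export
fluor_trace <- function(roi_label, values, timestamps,
                        background_corrected = FALSE, role = "object") {
  if (length(values) != length(timestamps))
    stop("values and timestamps must have the same length")
  if (!background_corrected && any(values < 0, na.rm = TRUE))
    stop("uncorrected trace values must be >= 0")
  structure(list(roi_label = as.character(roi_label),
                 values = as.numeric(values),
                 timestamps = as.numeric(timestamps),
                 background_corrected = isTRUE(background_corrected),
                 role = role),
            class = "fluor_trace")
}

#' Subtract an empty-ROI background trace from an object trace
#'
#' The background is the signal measured in an empty ROI near the object;
#' it is subtracted per timepoint, which removes both the detector offset
#' and the stray contribution of the external actinic light. Negative
#' corrected values are retained (clamping would bias NPQ) but reported.
#'
#' @param object_trace `fluor_trace` from an object ROI.
#' @param background_trace `fluor_trace` from a background ROI with
#'   identical timestamps.
#' @return Background-corrected `fluor_trace`.
#' @export
subtract_background <- function(object_trace, background_trace) {
  stopifnot(inherits(object_trace, "fluor_trace"),
            inherits(background_trace, "fluor_trace"))
  if (!isTRUE(all.equal(object_trace$timestamps, background_trace$timestamps)))
    stop("timestamp mismatch between object and background traces")
  if (background_trace$role != "background")
    stop("background_trace must come from a background ROI")
  v <- object_trace$values - background_trace$values
  if (any(v < 0, na.rm = TRUE))
    message(sum(v < 0, na.rm = TRUE),
            " corrected value(s) are negative (background exceeds object signal)")
  fluor_trace(object_trace$roi_label, v, object_trace$timestamps,
              background_corrected = TRUE, role = object_trace$role)
}

#' @export
as.data.frame.fluor_trace <- function(x, ...) {
  data.frame(roi_label = x$roi_label, timestamp_s = x$timestamps,
             value = x$values, background_corrected = x$background_corrected,
             stringsAsFactors = FALSE)
}

#' Tabulate and write raw / background / corrected traces as CSV
#'
#' One row per object ROI and timepoint, with columns `roi_label`,
#' `timestamp_s`, `raw`, `background`, `corrected`.
#'
#' @param object_traces List of raw object `fluor_trace`s.
#' @param background_trace The shared background `fluor_trace`.
#' @param path Optional CSV output path.
#' @return The assembled data.frame (invisibly when `path` is given).
#' @export
trace_table <- function(object_traces, background_trace, path = NULL) {
  rows <- lapply(object_traces, function(tr) {
    corr <- subtract_background(tr, background_trace)
    data.frame(roi_label = tr$roi_label, timestamp_s = tr$timestamps,
               raw = tr$values, background = background_trace$values,
               corrected = corr$values, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Read ROIs from an integer label mask and a role map
#'
#' @param labels Integer matrix (0 = outside all ROIs) or path to a
#'   label-mask TIFF.
#' @param roles Named list/character vector mapping label numbers to
#'   `"object"`/`"background"`, or path to such a JSON map. Labels absent
#'   from the map default to `"object"`.
#' @return List of [roi()] objects named by label.
#' @export
read_rois <- function(labels, roles = NULL) {
  if (is.character(labels)) {
    pg <- tiff::readTIFF(labels, as.is = TRUE)
    labels <- matrix(as.integer(pg), nrow(pg), ncol(pg))
  }
  if (is.character(roles))
    roles <- jsonlite::read_json(roles, simplifyVector = TRUE)
  labs <- sort(setdiff(unique(as.vector(labels)), 0L))
  out <- lapply(labs, function(l) {
    role <- if (!is.null(roles) && !is.null(roles[[as.character(l)]]))
      roles[[as.character(l)]] else "object"
    roi(labels == l, label = as.character(l), role = role)
  })
  names(out) <- as.character(labs)
  out
}
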