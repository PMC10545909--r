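#' Construct a 4D acquisition stack
#'
#' Container for raw confocal intensities indexed `(t, z, y, x)`, with the
#' physical voxel geometry and per-frame timestamps. All indices are
#' 1-based; physical sizes are in micrometres.
#'
#' @param intensities Numeric 4D array, dimensions `(t, z, y, x)`,
#'   non-negative counts.
#' @param voxel_size Length-2 numeric `(dy, dx)` pixel size, um.
#' @param z_step z spacing between slices, um.
#' @param timestamps Numeric vector of acquisition times (s), one per t.
#' @return An `acquisition_stack` object.
#' @export
acquisition_stack <- function(intensities, voxel_size = c(0.5, 0.5),
                              z_step = 2, timestamps = NULL) {
  if (!is.array(intensities) || length(dim(intensities)) != 4L)
    stop("intensities must be a 4D (t, z, y, x) array")
  if (any(intensities < 0)) stop("intensities must be non-negative")
  if (length(voxel_size) != 2L || any(voxel_size <= 0))
    stop("voxel_size must be positive (dy, dx)")
  if (z_step <= 0) stop("z_step must be > 0")
  nt <- dim(intensities)[1]
  if (is.null(timestamps)) timestamps <- as.numeric(seq_len(nt) - 1)
  if (length(timestamps) != nt)
    stop("length(timestamps) must equal the t extent")
  structure(list(intensities = intensities,
                 voxel_size = as.numeric(voxel_size),
                 z_step = as.numeric(z_step),
                 timestamps = as.numeric(timestamps)),
            class = "acquisition_stack")
}

#' @export
print.acquisition_stack <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("acquisition_stack: t=%d z=%d y=%d x=%d, voxel %g x %g um, z-step %g um\n",
              d[1], d[2], d[3], d[4], x$voxel_size[1], x$voxel_size[2], x$z_step))
  invisible(x)
}

#' Write an acquisition stack as multi-page TIFF plus JSON sidecar
#'
#' Pages are ordered t-major (all z of frame 1, then frame 2, ...).
#' Intensities are rounded to integer counts and stored at the requested
#' bit depth; geometry and timestamps go to `<path>.json` so that
#' [read_stack()] can restore the axes exactly.
#'
#' @param stack An `acquisition_stack`.
#' @param path Output TIFF path.
#' @param bits Bits per sample (8, 16 or 32).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, bits = 16L) {
  stopifnot(inherits(stack, "acquisition_stack"), bits %in% c(8L, 16L, 32L))
  maxval <- 2^bits - 1
  a <- round(stack$intensities)
  if (any(a > maxval)) stop("intensity exceeds bit depth")
  d <- dim(a)
  pages <- vector("list", d[1] * d[2])
  k <- 1L
  for (t in seq_len(d[1])) for (z in seq_len(d[2])) {
    pages[[k]] <- a[t, z, , ] / maxval
    k <- k + 1L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits))
  meta <- list(n_t = d[1], n_z = d[2],
               voxel_size = stack$voxel_size, z_step = stack$z_step,
               timestamps = stack$timestamps, page_order = "tz")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

# Best-effort parse of OME-XML axis metadata from a TIFF ImageDescription.
parse_ome_description <- function(desc) {
  if (is.null(desc) || !nzchar(desc) || !grepl("<OME", desc, fixed = TRUE))
    return(NULL)
  px <- tryCatch({
    doc <- xml2::read_xml(desc)
    xml2::xml_find_first(doc, "//*[local-name()='Pixels']")
  }, error = function(e) NULL)
  if (is.null(px) || inherits(px, "xml_missing")) return(NULL)
  att <- function(a) {
    v <- xml2::xml_attr(px, a)
    if (is.na(v)) NULL else as.numeric(v)
  }
  out <- list(n_t = att("SizeT"), n_z = att("SizeZ"),
              dim_order = xml2::xml_attr(px, "DimensionOrder"))
  psx <- att("PhysicalSizeX"); psy <- att("PhysicalSizeY"); psz <- att("PhysicalSizeZ")
  if (!is.null(psx) && !is.null(psy)) out$voxel_size <- c(psy, psx)
  if (!is.null(psz)) out$z_step <- psz
  out
}

#' Read a TIFF / OME-TIFF stack into an acquisition stack
#'
#' Pixel data are read page by page; the `(t, z)` factorisation of the page
#' list and the physical geometry come from, in order of precedence: the
#' `config` argument (a list or a YAML/JSON file path), a `<path>.json`
#' sidecar written by [write_stack()], or OME-XML in the first page's
#' ImageDescription. Config fields that contradict file metadata win, with
#' a warning. A single-page file with no metadata is read as t=1, z=1.
#'
#' @param path TIFF file.
#' @param config Optional list or path to a YAML/JSON sidecar with any of
#'   `n_t`, `n_z`, `voxel_size` (dy, dx), `z_step`, `timestamps`,
#'   `interval_s`.
#' @return An `acquisition_stack` with axes `(t, z, y, x)`.
#' @export
read_stack <- function(path, config = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  npages <- length(pages)
  if (!is.numeric(pages[[1]])) stop("non-numeric pixel data")

  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  sidecar <- NULL
  sp <- paste0(path, ".json")
  if (file.exists(sp)) sidecar <- jsonlite::read_json(sp, simplifyVector = TRUE)
  ome <- parse_ome_description(attr(pages[[1]], "description"))

  pick <- function(field) {
    for (src in list(config, sidecar, ome))
      if (!is.null(src[[field]])) return(src[[field]])
    NULL
  }
  n_t <- pick("n_t"); n_z <- pick("n_z")
  # config wins over file-derived metadata, but disagreement is flagged
  for (src in list(sidecar, ome)) {
    if (!is.null(config$n_t) && !is.null(src$n_t) && config$n_t != src$n_t)
      warning("config n_t (", config$n_t, ") overrides file metadata (", src$n_t, ")")
    if (!is.null(config$n_z) && !is.null(src$n_z) && config$n_z != src$n_z)
      warning("config n_z (", config$n_z, ") overrides file metadata (", src$n_z, ")")
  }
  if (is.null(n_t) && is.null(n_z)) {
    if (npages == 1L) { n_t <- 1L; n_z <- 1L }
    else stop("ambiguous axis order: multi-page TIFF without n_t/n_z metadata or sidecar")
  }
  if (is.null(n_t)) n_t <- npages / n_z
  if (is.null(n_z)) n_z <- npages / n_t
  if (n_t * n_z != npages || n_t != round(n_t) || n_z != round(n_z))
    stop(sprintf("page count %d does not factor as n_t=%s x n_z=%s", npages, n_t, n_z))
  n_t <- as.integer(n_t); n_z <- as.integer(n_z)

  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  a <- array(0, c(n_t, n_z, ny, nx))
  k <- 1L
  for (t in seq_len(n_t)) for (z in seq_len(n_z)) {
    a[t, z, , ] <- pages[[k]]
    k <- k + 1L
  }

  voxel_size <- pick("voxel_size"); z_step <- pick("z_step")
  timestamps <- pick("timestamps")
  if (!is.null(timestamps) && length(timestamps) != n_t) {
    message("metadata timestamps do not match the t extent; synthesizing uniform spacing")
    timestamps <- NULL
  }
  if (is.null(timestamps)) {
    iv <- pick("interval_s")
    if (!is.null(iv)) timestamps <- (seq_len(n_t) - 1) * iv
  }
  acquisition_stack(a,
                    voxel_size = if (is.null(voxel_size)) c(1, 1) else as.numeric(voxel_size),
                    z_step = if (is.null(z_step)) 1 else as.numeric(z_step),
                    timestamps = timestamps)
}

#' Intensity-preserving sum projection
#'
#' Collapses the z axis of a 4D stack by per-pixel summation, so that the
#' total fluorescence of every timepoint is conserved exactly (the Fiji
#' "sum slices" behaviour). Accumulation is in double precision, which is
#' exact for integer counts below 2^53.
#'
#' @param stack An `acquisition_stack`.
#' @return A `projected_series`: list with `intensities` `(t, y, x)`,
#'   `pixel_size` and `timestamps`.
#' @examples
#' a <- array(1L, c(2, 3, 4, 4))
#' p <- sum_project(acquisition_stack(a, timestamps = c(0, 60)))
#' p$intensities[1, 1, 1]  # 3 slices of 1 -> 3
#' @export
sum_project <- function(stack) {
  stopifnot(inherits(stack, "acquisition_stack"))
  d <- dim(stack$intensities)
  p <- array(0, c(d[1], d[3], d[4]))
  for (z in seq_len(d[2])) {
    slice <- stack$intensities[, z, , , drop = FALSE]
    dim(slice) <- c(d[1], d[3], d[4])
    p <- p + slice
  }
  projected_series(p, pixel_size = stack$voxel_size, timestamps = stack$timestamps)
}

#' Construct a projected (2D + t) series
#'
#' @param intensities Numeric 3D array `(t, y, x)`.
#' @param pixel_size `(dy, dx)` in um.
#' @param timestamps Seconds, one per t.
#' @return A `projected_series` object.
#' @export
projected_series <- function(intensities, pixel_size = c(0.5, 0.5),
                             timestamps = NULL) {
  if (!is.array(intensities) || length(dim(intensities)) != 3L)
    stop("intensities must be a 3D (t, y, x) array")
  nt <- dim(intensities)[1]
  if (is.null(timestamps)) timestamps <- as.numeric(seq_len(nt) - 1)
  if (length(timestamps) != nt) stop("length(timestamps) must equal t extent")
  structure(list(intensities = intensities,
                 pixel_size = as.numeric(pixel_size),
                 timestamps = as.numeric(timestamps)),
            class = "projected_series")
}

#' Write a projected series as a multi-page TIFF (one page per timepoint)
#'
#' @param series A `projected_series`.
#' @param path Output TIFF path.
#' @param bits Bits per sample; projected sums can exceed 16-bit range, in
#'   which case use 32.
#' @return `path`, invisibly.
#' @export
write_projected <- function(series, path, bits = 32L) {
  stopifnot(inherits(series, "projected_series"))
  maxval <- 2^bits - 1
  a <- round(series$intensities)
  if (any(a > maxval)) stop("intensity exceeds bit depth")
  pages <- lapply(seq_len(dim(a)[1]), function(t) a[t, , ] / maxval)
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits))
  meta <- list(n_t = dim(a)[1], n_z = 1L, voxel_size = series$pixel_size,
               z_step = 1, timestamps = series$timestamps, page_order = "tz")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
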