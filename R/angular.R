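#' Fit an equivalent-area circle to a cell section mask
#'
#' For cells whose plastids are too small and densely packed to segment
#' individually, fluorescence is analysed on a circular approximation of
#' the cell section: centre = mask centroid, radius = sqrt(area / pi).
#'
#' @param section_mask Non-empty logical matrix `(y, x)`.
#' @param z_index Optional slice index the section came from.
#' @return A `cell_disk`: list with `center` `(y, x)` in pixels, `radius`
#'   in pixels, `z_index`.
#' @export
fit_disk <- function(section_mask, z_index = NA_integer_) {
  if (!is.matrix(section_mask) || !is.logical(section_mask))
    stop("section_mask must be a logical matrix")
  px <- which(section_mask, arr.ind = TRUE)
  if (!nrow(px)) stop("empty section mask")
  structure(list(center = c(y = mean(px[, 1]), x = mean(px[, 2])),
                 radius = sqrt(nrow(px) / pi),
                 z_index = z_index),
            class = "cell_disk")
}

#' Interpolated intensity profile along one radius
#'
#' Samples the image by bilinear interpolation at `n_samples` points evenly
#' spaced from the disk centre to centre + radius * (cos(angle),
#' sin(angle)). Angle 0 points along +x (columns) and increases towards +y
#' (rows), i.e. counter-clockwise in the (x, y) plane.
#'
#' @param image Numeric matrix `(y, x)`.
#' @param disk A [fit_disk()] result (or list with `center`, `radius`).
#' @param angle Degrees.
#' @param n_samples Number of radial samples (>= 2); default about one per
#'   pixel of radius.
#' @return Numeric vector of interpolated intensities, centre first.
#' @export
radial_profile <- function(image, disk, angle,
                           n_samples = ceiling(disk$radius) + 1) {
  if (!is.matrix(image)) stop("image must be a matrix")
  if (n_samples < 2) stop("n_samples must be >= 2")
  th <- angle * pi / 180
  s <- seq(0, disk$radius, length.out = n_samples)
  yp <- disk$center[["y"]] + s * sin(th)
  xp <- disk$center[["x"]] + s * cos(th)
  if (any(yp < 1 | yp > nrow(image) | xp < 1 | xp > ncol(image)))
    stop("radial samples fall outside the image")
  pracma::interp2(x = seq_len(ncol(image)), y = seq_len(nrow(image)),
                  Z = image, xp = xp, yp = yp, method = "linear")
}

#' Angular NPQ profile of a cell section
#'
#' For every angle on a regular grid, reduces the radial intensity profile
#' of the dark-adapted image to Fm and of the light-exposed image to Fm',
#' and computes NPQ = (Fm - Fm')/Fm'. The quotient is invariant to the
#' choice of mean vs sum along the radius.
#'
#' @param dark_image Dark-adapted 2D frame (gives Fm).
#' @param light_image Light-exposed 2D frame, same geometry (gives Fm').
#' @param disk The circular cell approximation ([fit_disk()]).
#' @param angle_step Degrees; must divide 360 (default 5 gives 72 angles).
#' @param n_samples Radial samples per angle.
#' @param stat Reduction along the radius: mean (default), sum or median.
#' @return An `angular_npq_profile`: data.frame with `angle`, `Fm`,
#'   `Fm_prime`, `npq` (NA where Fm' <= 0), and attributes `angle_step`,
#'   `sections_used = 1`.
#' @export
angular_npq <- function(dark_image, light_image, disk, angle_step = 5,
                        n_samples = ceiling(disk$radius) + 1,
                        stat = c("mean", "sum", "median")) {
  stat <- match.arg(stat)
  if (!identical(dim(dark_image), dim(light_image)))
    stop("dark and light images must have identical geometry")
  if (360 %% angle_step != 0) stop("angle_step must divide 360")
  reduce <- switch(stat, mean = mean, sum = sum, median = stats::median)
  angles <- seq(0, 360 - angle_step, by = angle_step)
  Fm <- Fmp <- numeric(length(angles))
  for (i in seq_along(angles)) {
    Fm[i] <- reduce(radial_profile(dark_image, disk, angles[i], n_samples))
    Fmp[i] <- reduce(radial_profile(light_image, disk, angles[i], n_samples))
  }
  npq <- ifelse(Fmp > 0, (Fm - Fmp) / Fmp, NA_real_)
  out <- data.frame(angle = angles, Fm = Fm, Fm_prime = Fmp, npq = npq)
  attr(out, "angle_step") <- angle_step
  attr(out, "sections_used") <- 1L
  class(out) <- c("angular_npq_profile", "data.frame")
  out
}

#' Aggregate angular NPQ profiles across z sections
#'
#' Several sections of the same cell (typically >= 10, i.e. 10 um at 1 um
#' spacing) are scanned to assess reproducibility; this averages the
#' per-angle quantities and reports the per-angle sample SD of NPQ.
#'
#' @param profiles List of `angular_npq_profile`s on identical angle grids.
#' @return An `angular_npq_profile` with per-angle means, an `npq_sd`
#'   column (NA when fewer than 2 profiles) and `sections_used` set.
#' @export
aggregate_sections <- function(profiles) {
  if (!length(profiles)) stop("no profiles to aggregate")
  ang <- profiles[[1]]$angle
  for (p in profiles)
    if (!isTRUE(all.equal(p$angle, ang))) stop("mismatched angle grids")
  get <- function(col) sapply(profiles, function(p) p[[col]])
  Fm <- rowMeans(as.matrix(get("Fm")))
  Fmp <- rowMeans(as.matrix(get("Fm_prime")))
  npq_mat <- as.matrix(get("npq"))
  out <- data.frame(angle = ang, Fm = Fm, Fm_prime = Fmp,
                    npq = rowMeans(npq_mat),
                    npq_sd = if (length(profiles) >= 2)
                      apply(npq_mat, 1, stats::sd) else NA_real_)
  attr(out, "angle_step") <- attr(profiles[[1]], "angle_step")
  attr(out, "sections_used") <- length(profiles)
  class(out) <- c("angular_npq_profile", "data.frame")
  out
}
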