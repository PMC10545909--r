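#' Edge-preserving 3D median filter
#'
#' Each voxel is replaced by the median of the axis-aligned box
#' neighbourhood of side `2 * radius + 1`; borders are handled by edge
#' replication. Standard pre-processing before thresholding so that
#' shot-noise outliers do not seed spurious objects while object edges stay
#' in place.
#'
#' @param vol Numeric 3D array `(z, y, x)`.
#' @param radius Neighbourhood radius in voxels (>= 1, smaller than every
#'   volume extent).
#' @return Filtered array, same dimensions.
#' @export
median_filter3d <- function(vol, radius = 1L) {
  if (!is.array(vol) || length(dim(vol)) != 3L) stop("vol must be a 3D array")
  r <- as.integer(radius)
  d <- dim(vol)
  if (r < 1L) stop("radius must be >= 1")
  if (any(r >= d)) stop("radius exceeds a volume dimension")
  offs <- as.matrix(expand.grid(dz = -r:r, dy = -r:r, dx = -r:r))
  m <- matrix(0, prod(d), nrow(offs))
  clamp <- function(i, n) pmin(pmax(i, 1L), n)
  for (j in seq_len(nrow(offs))) {
    iz <- clamp(seq_len(d[1]) + offs[j, 1], d[1])
    iy <- clamp(seq_len(d[2]) + offs[j, 2], d[2])
    ix <- clamp(seq_len(d[3]) + offs[j, 3], d[3])
    m[, j] <- vol[iz, iy, ix]
  }
  array(apply(m, 1, stats::median), d)
}

#' Global Otsu threshold of a volume
#'
#' @param vol Numeric array.
#' @param levels Histogram bins.
#' @return Threshold on the intensity scale of `vol`.
#' @export
otsu_threshold <- function(vol, levels = 256L) {
  rng <- range(vol)
  if (rng[1] == rng[2]) stop("constant volume: Otsu threshold undefined")
  scaled <- (as.numeric(vol) - rng[1]) / (rng[2] - rng[1])
  # single 2D image so EBImage returns one global threshold
  th <- EBImage::otsu(EBImage::Image(matrix(scaled, ncol = 1)),
                      range = c(0, 1), levels = as.integer(levels))
  rng[1] + th * (rng[2] - rng[1])
}

#' Threshold + 26-connected-component 3D segmentation
#'
#' Voxels strictly above the threshold are grouped into 26-connected
#' components on the index grid (connectivity ignores voxel anisotropy);
#' components smaller than `min_voxels` are discarded and the survivors are
#' labelled 1..N by decreasing size (ties broken by first voxel position,
#' so the labelling is deterministic).
#'
#' @param filtered Numeric 3D array `(z, y, x)`, typically
#'   [median_filter3d()] output.
#' @param threshold Numeric cutoff or `"otsu"` (default) for a global Otsu
#'   threshold on `filtered`.
#' @param min_voxels Minimum component size kept.
#' @param voxel_dims `(dz, dy, dx)` physical voxel size, um, carried for
#'   volume computation.
#' @return A `labeled_volume`: list with integer `labels` array (0 =
#'   background) and `voxel_dims`. An empty labelling (nothing above
#'   threshold) is valid and reported with a message.
#' @export
segment_objects <- function(filtered, threshold = "otsu", min_voxels = 1L,
                            voxel_dims = c(1, 1, 1)) {
  if (!is.array(filtered) || length(dim(filtered)) != 3L)
    stop("filtered must be a 3D array")
  if (identical(threshold, "otsu")) threshold <- otsu_threshold(filtered)
  d <- dim(filtered)
  fg <- filtered > threshold
  labels <- array(0L, d)
  idx <- which(fg)
  if (!length(idx)) {
    message("no voxels above threshold: empty labeling")
    return(labeled_volume(labels, voxel_dims))
  }
  id <- integer(prod(d))
  id[idx] <- seq_along(idx)
  z <- (idx - 1L) %% d[1] + 1L
  y <- ((idx - 1L) %/% d[1]) %% d[2] + 1L
  x <- (idx - 1L) %/% (d[1] * d[2]) + 1L
  # half of the 26-neighbourhood; the other half follows by symmetry
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[offs[, 3] > 0 | (offs[, 3] == 0 & (offs[, 2] > 0 |
            (offs[, 2] == 0 & offs[, 1] > 0))), , drop = FALSE]
  ef <- integer(0); et <- integer(0)
  for (j in seq_len(nrow(offs))) {
    zz <- z + offs[j, 1]; yy <- y + offs[j, 2]; xx <- x + offs[j, 3]
    ok <- zz >= 1L & zz <= d[1] & yy >= 1L & yy <= d[2] & xx >= 1L & xx <= d[3]
    nb <- (xx[ok] - 1L) * d[1] * d[2] + (yy[ok] - 1L) * d[1] + zz[ok]
    hit <- id[nb] > 0L
    ef <- c(ef, id[idx[ok]][hit])
    et <- c(et, id[nb][hit])
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(ef))
    g <- igraph::add_edges(g, rbind(ef, et))
  memb <- igraph::components(g)$membership
  sizes <- tabulate(memb)
  keep <- which(sizes >= min_voxels)
  if (!length(keep)) {
    message("all components below min_voxels: empty labeling")
    return(labeled_volume(labels, voxel_dims))
  }
  first_voxel <- vapply(keep, function(k) min(idx[memb == k]), integer(1))
  keep <- keep[order(-sizes[keep], first_voxel)]
  relabel <- integer(max(memb))
  relabel[keep] <- seq_along(keep)
  lab <- relabel[memb]
  labels[idx[lab > 0L]] <- lab[lab > 0L]
  labeled_volume(labels, voxel_dims)
}

#' Construct a labeled volume
#'
#' @param labels Integer 3D array, 0 = background, objects labelled 1..N
#'   contiguously.
#' @param voxel_dims `(dz, dy, dx)` in um.
#' @return A `labeled_volume` object.
#' @export
labeled_volume <- function(labels, voxel_dims = c(1, 1, 1)) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("labels must be a 3D array")
  if (any(labels < 0)) stop("labels must be non-negative")
  u <- sort(unique(as.vector(labels[labels > 0])))
  if (length(u) && !identical(as.integer(u), seq_along(u)))
    stop("labels must be contiguous 1..N")
  if (length(voxel_dims) != 3L || any(voxel_dims <= 0))
    stop("voxel_dims must be positive (dz, dy, dx)")
  structure(list(labels = labels, voxel_dims = as.numeric(voxel_dims)),
            class = "labeled_volume")
}

#' Voxel counts and physical volumes per object
#'
#' Object volume is voxel count times the physical voxel size
#' (dz * dy * dx).
#'
#' @param labeled A `labeled_volume`.
#' @return data.frame with `label`, `voxel_count`, `volume_um3` (empty for
#'   an empty labelling).
#' @export
object_volume <- function(labeled) {
  stopifnot(inherits(labeled, "labeled_volume"))
  lab <- labeled$labels[labeled$labels > 0L]
  if (!length(lab))
    return(data.frame(label = integer(0), voxel_count = integer(0),
                      volume_um3 = numeric(0)))
  counts <- tabulate(lab)
  vox <- prod(labeled$voxel_dims)
  data.frame(label = seq_along(counts), voxel_count = counts,
             volume_um3 = counts * vox)
}

#' Per-object integrated and mean fluorescence
#'
#' Sums the raw intensities of each labelled object and derives the mean,
#' giving the total and mean fluorescence of a plastid or cell.
#'
#' @param labeled A `labeled_volume`.
#' @param stack_frame Numeric 3D array of raw intensities, same geometry.
#' @return data.frame with `label`, `voxel_count`, `volume_um3`,
#'   `integrated_fluorescence`, `mean_fluorescence`.
#' @export
integrate_fluorescence <- function(labeled, stack_frame) {
  stopifnot(inherits(labeled, "labeled_volume"))
  if (!identical(dim(labeled$labels), dim(stack_frame)))
    stop("geometry mismatch between labels and intensities")
  stats <- object_volume(labeled)
  if (!nrow(stats)) stop("labeled volume contains no objects")
  inside <- labeled$labels > 0L
  sums <- as.numeric(tapply(stack_frame[inside], labeled$labels[inside], sum))
  stats$integrated_fluorescence <- sums
  stats$mean_fluorescence <- sums / stats$voxel_count
  stats
}

#' Plastid area fraction of a cell section
#'
#' Percentage of the cell-section area occupied by plastids:
#' 100 * |plastid| / |cell|. Plastid pixels must lie inside the cell mask.
#'
#' @param cell_mask Logical matrix of the cell section.
#' @param plastid_mask Logical matrix of the plastid pixels, same geometry.
#' @return Percent in `[0, 100]`.
#' @export
area_fraction <- function(cell_mask, plastid_mask) {
  if (!identical(dim(cell_mask), dim(plastid_mask)))
    stop("mask geometry mismatch")
  n_cell <- sum(cell_mask)
  if (n_cell == 0) stop("empty cell mask")
  if (any(plastid_mask & !cell_mask))
    stop("plastid pixels outside the cell mask")
  100 * sum(plastid_mask) / n_cell
}
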