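#' Parameters of a synthetic saturation-pulse acquisition
#'
#' Describes a scene of fluorescent plastid-sized blobs moving inside cell
#' boundaries, whose emission is modulated by NPQ induction/relaxation
#' kinetics, on top of a nonzero background that steps up while the
#' external actinic light is on, with optional Poisson shot noise and
#' Gaussian read noise. The rendered stacks feed every pipeline stage with
#' known ground truth.
#'
#' The top `background$strip_rows` image rows are kept free of cells so
#' that an empty background ROI is always available.
#'
#' @param grid `(z, y, x)` extents in voxels.
#' @param voxel_size `(dy, dx)` um.
#' @param z_step um.
#' @param n_cells Cells, laid out side by side along x.
#' @param plastids_per_cell Blobs per cell.
#' @param plastid_radius Blob radius, um (intensity falls to half maximum
#'   at this distance; Gaussian profile truncated at 3.5 sigma).
#' @param motion_step Random-walk step SD per frame, um; the walk is
#'   reflected so each blob's full support stays inside its cell.
#' @param Fm_amplitude Dark-adapted peak blob intensity, counts.
#' @param kinetics List: `NPQmax`, `tau_ind` (s), `tau_rel` (s),
#'   `transient_amp`, `transient_tau` (s). See [npq_kinetics()].
#' @param noise List: `gaussian_sd` (counts), `poisson` (logical).
#' @param background List: `level` (counts), `actinic_step` (extra counts
#'   while the actinic light is on), `strip_rows` (cell-free rows).
#' @param seed Integer; fixes all randomness of [render_scene()].
#' @return A `scene_params` object.
#' @export
scene_params <- function(grid = c(z = 14, y = 64, x = 64),
                         voxel_size = c(0.5, 0.5), z_step = 2,
                         n_cells = 1, plastids_per_cell = 8,
                         plastid_radius = 2, motion_step = 0.2,
                         Fm_amplitude = 500,
                         kinetics = list(),
                         noise = list(),
                         background = list(),
                         seed = 1L) {
  kin <- utils::modifyList(list(NPQmax = 2, tau_ind = 90, tau_rel = 120,
                                transient_amp = 0, transient_tau = 60),
                           kinetics)
  noi <- utils::modifyList(list(gaussian_sd = 0, poisson = FALSE), noise)
  bgr <- utils::modifyList(list(level = 50, actinic_step = 10,
                                strip_rows = 16), background)
  if (any(grid < 1) || any(voxel_size <= 0) || z_step <= 0 ||
      plastid_radius <= 0 || Fm_amplitude <= 0 || motion_step < 0)
    stop("physical scene parameters must be positive")
  if (kin$NPQmax < 0) stop("NPQmax must be >= 0")
  structure(list(grid = grid, voxel_size = as.numeric(voxel_size),
                 z_step = z_step, n_cells = as.integer(n_cells),
                 plastids_per_cell = as.integer(plastids_per_cell),
                 plastid_radius = plastid_radius, motion_step = motion_step,
                 Fm_amplitude = Fm_amplitude, kinetics = kin, noise = noi,
                 background = bgr, seed = as.integer(seed)),
            class = "scene_params")
}

#' NPQ induction / relaxation kinetics
#'
#' The simulator's forward model of the NPQ time course:
#' under actinic light, exponential induction plus an optional gamma-shaped
#' transient (the overshoot seen when dark-adapted cells meet low light
#' before carbon fixation activates),
#' `NPQmax * (1 - exp(-t/tau_ind)) +
#'  transient_amp * (t/transient_tau) * exp(1 - t/transient_tau)`;
#' in the dark after light, exponential relaxation
#' `npq_at_light_off * exp(-t/tau_rel)`; in the dark-adapted reference
#' phase, 0.
#'
#' @param t_since_transition Seconds since the last phase transition
#'   (>= 0); vectorised.
#' @param phase `"dark_reference"`, `"actinic"` or `"relaxation"`.
#' @param kinetics Kinetics list as in [scene_params()].
#' @param npq_at_light_off NPQ value when the light went off (required for
#'   the relaxation phase).
#' @return True NPQ value(s).
#' @export
npq_kinetics <- function(t_since_transition, phase, kinetics,
                         npq_at_light_off = NULL) {
  t <- t_since_transition
  if (any(t < 0)) stop("t_since_transition must be >= 0")
  switch(phase,
    dark_reference = rep(0, length(t)),
    actinic = kinetics$NPQmax * (1 - exp(-t / kinetics$tau_ind)) +
      kinetics$transient_amp * (t / kinetics$transient_tau) *
        exp(1 - t / kinetics$transient_tau),
    relaxation = {
      if (is.null(npq_at_light_off))
        stop("npq_at_light_off is required for the relaxation phase")
      npq_at_light_off * exp(-t / kinetics$tau_rel)
    },
    stop("unknown phase: ", phase))
}

#' True NPQ at every frame of a protocol
#'
#' Applies [npq_kinetics()] at each frame timestamp. The actinic light is
#' taken to switch on at the first actinic frame and off at the first
#' relaxation frame, so the first frame of each block sits at t = 0 of its
#' kinetic segment (NPQ is continuous across the light-off transition).
#'
#' @param timeline A `protocol_timeline`.
#' @param kinetics Kinetics list.
#' @return Numeric vector, one true NPQ per frame.
#' @export
npq_true_series <- function(timeline, kinetics) {
  validate_timeline(timeline)
  fr <- timeline$frames
  t_on <- phase_onset(timeline, "actinic")
  t_off <- phase_onset(timeline, "relaxation")
  npq_off <- if (!is.na(t_off) && !is.na(t_on))
    npq_kinetics(t_off - t_on, "actinic", kinetics) else 0
  vapply(seq_len(nrow(fr)), function(i) {
    ph <- fr$phase[i]; ts <- fr$timestamp[i]
    switch(ph,
      dark_reference = 0,
      actinic = npq_kinetics(ts - t_on, "actinic", kinetics),
      relaxation = npq_kinetics(ts - t_off, "relaxation", kinetics,
                                npq_at_light_off = npq_off))
  }, numeric(1))
}

# run expr with a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

# support half-widths in voxels for a Gaussian truncated at 3.5 sigma
blob_margins <- function(params) {
  sigma <- params$plastid_radius / sqrt(2 * log(2))
  c(z = ceiling(3.5 * sigma / params$z_step) + 1L,
    y = ceiling(3.5 * sigma / params$voxel_size[1]) + 1L,
    x = ceiling(3.5 * sigma / params$voxel_size[2]) + 1L)
}

# cell bounding boxes (voxel indices), side by side along x below the
# background strip
cell_boxes <- function(params) {
  g <- params$grid
  y0 <- params$background$strip_rows + 2L
  if (y0 >= g[["y"]]) stop("background strip leaves no room for cells")
  xb <- round(seq(1, g[["x"]] + 1, length.out = params$n_cells + 1))
  data.frame(cell = seq_len(params$n_cells),
             z0 = 1L, z1 = g[["z"]],
             y0 = y0, y1 = g[["y"]] - 1L,
             x0 = xb[-length(xb)] + 1L, x1 = xb[-1] - 1L)
}

# place plastid centres (continuous voxel coords) on a jittered grid
# inside one cell box, pairwise physical separation >= 3.5 radius so
# blobs never merge at a half-maximum threshold
place_plastids <- function(params, box) {
  m <- blob_margins(params)
  lo <- c(box$z0 + m["z"], box$y0 + m["y"], box$x0 + m["x"])
  hi <- c(box$z1 - m["z"], box$y1 - m["y"], box$x1 - m["x"])
  if (any(hi < lo))
    stop("plastids cannot fit inside the cell (support margin exceeds cell size)")
  phys <- c(params$z_step, params$voxel_size)
  jit <- 0.5  # um of positional jitter around each grid slot
  spacing <- 3.5 * params$plastid_radius + 2 * jit
  span <- (hi - lo) * phys
  nslots <- pmax(floor(span / spacing) + 1, 1)
  n <- params$plastids_per_cell
  if (prod(nslots) < n)
    stop("plastids cannot fit inside the cell (separation constraint)")
  axis_pos <- lapply(1:3, function(k) {
    offs <- (span[k] - (nslots[k] - 1) * spacing) / 2
    offs + spacing * (seq_len(nslots[k]) - 1)
  })
  slots <- as.matrix(expand.grid(axis_pos[[1]], axis_pos[[2]], axis_pos[[3]]))
  pick <- sample(nrow(slots), n)
  um <- slots[pick, , drop = FALSE] +
    matrix(stats::runif(3 * n, -jit, jit), n, 3)
  um <- pmin(pmax(um, 0), matrix(span, n, 3, byrow = TRUE))
  sweep(sweep(um, 2, phys, "/"), 2, lo, "+")
}

#' Render a synthetic acquisition with ground truth
#'
#' Plastids are 3D Gaussian-profile blobs (half maximum at
#' `plastid_radius`, truncated at 3.5 sigma) on confined random-walk
#' trajectories; their peak intensity at frame t is
#' `Fm_amplitude / (1 + NPQ_true(t))`, the fluorescence law implied by the
#' NPQ definition. The background adds `level` counts everywhere plus
#' `actinic_step` during actinic frames. Optional Poisson noise is applied
#' first, then Gaussian read noise (clipped at zero). An identical seed
#' gives a bit-identical stack.
#'
#' @param params A [scene_params()].
#' @param timeline A `protocol_timeline`.
#' @return List with `stack` (an `acquisition_stack`) and `truth`, a
#'   `scene_truth` list: `cells` (bounding boxes), `plastids`,
#'   `trajectories` (t x plastid x (z, y, x) voxel coords), `npq`
#'   (per-frame true NPQ), `volumes` (digitised true voxel counts and um^3
#'   at frame 1), `area_frac` (true percent per cell), and the generating
#'   `params`.
#' @export
render_scene <- function(params, timeline) {
  stopifnot(inherits(params, "scene_params"))
  validate_timeline(timeline)
  with_seed(params$seed, {
    g <- params$grid
    fr <- timeline$frames
    nt <- nrow(fr)
    sigma <- params$plastid_radius / sqrt(2 * log(2))
    boxes <- cell_boxes(params)
    m <- blob_margins(params)
    phys <- c(params$z_step, params$voxel_size)

    centers0 <- lapply(seq_len(nrow(boxes)), function(i)
      place_plastids(params, boxes[i, ]))
    np_cell <- params$plastids_per_cell
    n_pl <- params$n_cells * np_cell
    cell_of <- rep(seq_len(params$n_cells), each = np_cell)

    # confined random walk, reflected at the margin-inset cell box
    traj <- array(NA_real_, c(nt, n_pl, 3),
                  dimnames = list(NULL, NULL, c("z", "y", "x")))
    step_vox <- params$motion_step / phys
    reflect <- function(v, lo, hi) {
      w <- hi - lo
      out <- lo
      pos <- w > 0
      vv <- (v[pos] - lo[pos]) %% (2 * w[pos])
      out[pos] <- lo[pos] + ifelse(vv > w[pos], 2 * w[pos] - vv, vv)
      out
    }
    for (p in seq_len(n_pl)) {
      b <- boxes[cell_of[p], ]
      lo <- c(b$z0 + m["z"], b$y0 + m["y"], b$x0 + m["x"])
      hi <- c(b$z1 - m["z"], b$y1 - m["y"], b$x1 - m["x"])
      pos <- centers0[[cell_of[p]]][(p - 1) %% np_cell + 1, ]
      for (t in seq_len(nt)) {
        traj[t, p, ] <- pos
        pos <- reflect(pos + stats::rnorm(3, 0, step_vox), lo, hi)
      }
    }

    npq_true <- npq_true_series(timeline, params$kinetics)
    a <- array(0, c(nt, g[["z"]], g[["y"]], g[["x"]]))
    for (t in seq_len(nt)) {
      vol <- array(params$background$level +
                     if (fr$phase[t] == "actinic") params$background$actinic_step else 0,
                   c(g[["z"]], g[["y"]], g[["x"]]))
      amp <- params$Fm_amplitude / (1 + npq_true[t])
      for (p in seq_len(n_pl)) {
        cz <- traj[t, p, 1]; cy <- traj[t, p, 2]; cx <- traj[t, p, 3]
        zr <- max(1, round(cz) - m["z"]):min(g[["z"]], round(cz) + m["z"])
        yr <- max(1, round(cy) - m["y"]):min(g[["y"]], round(cy) + m["y"])
        xr <- max(1, round(cx) - m["x"]):min(g[["x"]], round(cx) + m["x"])
        dz2 <- ((zr - cz) * phys[1])^2
        dy2 <- ((yr - cy) * phys[2])^2
        dx2 <- ((xr - cx) * phys[3])^2
        gaus <- exp(-outer(outer(dz2, dy2, "+"), dx2, "+") / (2 * sigma^2))
        vol[zr, yr, xr] <- vol[zr, yr, xr] + amp * gaus
      }
      if (params$noise$poisson)
        vol <- array(stats::rpois(length(vol), vol), dim(vol))
      if (params$noise$gaussian_sd > 0)
        vol <- vol + stats::rnorm(length(vol), 0, params$noise$gaussian_sd)
      a[t, , , ] <- pmax(vol, 0)
    }

    stack <- acquisition_stack(a, voxel_size = params$voxel_size,
                               z_step = params$z_step,
                               timestamps = fr$timestamp)
    plastids <- data.frame(cell = cell_of, plastid = seq_len(n_pl),
                           radius_um = params$plastid_radius,
                           sigma_um = sigma)
    truth <- structure(list(
      params = params, timeline = timeline,
      cells = boxes, plastids = plastids, trajectories = traj,
      npq = data.frame(frame = seq_len(nt), timestamp = fr$timestamp,
                       phase = fr$phase, npq_true = npq_true),
      volumes = truth_volumes(params, boxes, traj, plastids),
      area_frac = truth_area_frac(params, boxes, traj, cell_of)
    ), class = "scene_truth")
    list(stack = stack, truth = truth)
  })
}

# digitised sphere voxel counts (physical distance <= radius) at frame 1
truth_volumes <- function(params, boxes, traj, plastids) {
  g <- params$grid; phys <- c(params$z_step, params$voxel_size)
  counts <- vapply(seq_len(nrow(plastids)), function(p) {
    c0 <- traj[1, p, ]
    r <- params$plastid_radius
    zr <- max(1, floor(c0[1] - r / phys[1])):min(g[["z"]], ceiling(c0[1] + r / phys[1]))
    yr <- max(1, floor(c0[2] - r / phys[2])):min(g[["y"]], ceiling(c0[2] + r / phys[2]))
    xr <- max(1, floor(c0[3] - r / phys[3])):min(g[["x"]], ceiling(c0[3] + r / phys[3]))
    d2 <- outer(outer(((zr - c0[1]) * phys[1])^2, ((yr - c0[2]) * phys[2])^2, "+"),
                ((xr - c0[3]) * phys[3])^2, "+")
    sum(d2 <= r^2)
  }, numeric(1))
  data.frame(cell = plastids$cell, plastid = plastids$plastid,
             voxel_count = counts,
             volume_um3 = counts * params$z_step * prod(params$voxel_size))
}

# true plastid area fraction per cell from frame-1 projected disks
truth_area_frac <- function(params, boxes, traj, cell_of) {
  g <- params$grid; vs <- params$voxel_size
  vapply(seq_len(nrow(boxes)), function(ci) {
    b <- boxes[ci, ]
    mask <- matrix(FALSE, g[["y"]], g[["x"]])
    for (p in which(cell_of == ci)) {
      c0 <- traj[1, p, ]
      r <- params$plastid_radius
      yy <- matrix(seq_len(g[["y"]]), g[["y"]], g[["x"]])
      xx <- matrix(seq_len(g[["x"]]), g[["y"]], g[["x"]], byrow = TRUE)
      mask <- mask | (((yy - c0[2]) * vs[1])^2 + ((xx - c0[3]) * vs[2])^2 <= r^2)
    }
    cell_area <- (b$y1 - b$y0 + 1) * (b$x1 - b$x0 + 1)
    100 * sum(mask[b$y0:b$y1, b$x0:b$x1]) / cell_area
  }, numeric(1))
}

#' ROIs implied by a scene's ground truth
#'
#' `truth_cell_roi` returns the 2D bounding-box ROI of one cell;
#' `truth_background_roi` returns the guaranteed-empty background strip.
#'
#' @param truth A `scene_truth`.
#' @param cell Cell index.
#' @return An [roi()].
#' @export
truth_cell_roi <- function(truth, cell) {
  g <- truth$params$grid
  b <- truth$cells[truth$cells$cell == cell, ]
  if (!nrow(b)) stop("unknown cell: ", cell)
  mask <- matrix(FALSE, g[["y"]], g[["x"]])
  mask[b$y0:b$y1, b$x0:b$x1] <- TRUE
  roi(mask, label = paste0("cell", cell), role = "object")
}

#' @rdname truth_cell_roi
#' @export
truth_background_roi <- function(truth) {
  g <- truth$params$grid
  mask <- matrix(FALSE, g[["y"]], g[["x"]])
  mask[seq_len(truth$params$background$strip_rows), ] <- TRUE
  roi(mask, label = "background", role = "background")
}

#' True plastid label volume at one frame
#'
#' Digitises each plastid as a sphere (physical distance <= radius) at its
#' frame-`frame` position; labels follow plastid order.
#'
#' @param truth A `scene_truth`.
#' @param frame Frame index.
#' @return A `labeled_volume`.
#' @export
truth_plastid_labels <- function(truth, frame = 1L) {
  params <- truth$params
  g <- params$grid; phys <- c(params$z_step, params$voxel_size)
  labels <- array(0L, c(g[["z"]], g[["y"]], g[["x"]]))
  for (p in seq_len(dim(truth$trajectories)[2])) {
    c0 <- truth$trajectories[frame, p, ]
    r <- params$plastid_radius
    zr <- max(1, floor(c0[1] - r / phys[1])):min(g[["z"]], ceiling(c0[1] + r / phys[1]))
    yr <- max(1, floor(c0[2] - r / phys[2])):min(g[["y"]], ceiling(c0[2] + r / phys[2]))
    xr <- max(1, floor(c0[3] - r / phys[3])):min(g[["x"]], ceiling(c0[3] + r / phys[3]))
    d2 <- outer(outer(((zr - c0[1]) * phys[1])^2, ((yr - c0[2]) * phys[2])^2, "+"),
                ((xr - c0[3]) * phys[3])^2, "+")
    sub <- labels[zr, yr, xr]
    sub[d2 <= r^2] <- p
    labels[zr, yr, xr] <- sub
  }
  labeled_volume(labels, voxel_dims = c(params$z_step, params$voxel_size))
}

#' Compare estimated quantities against simulator ground truth
#'
#' @param estimated data.frame with an id column and a value column.
#' @param truth data.frame with the same id column and the true values.
#' @param id_col,value_col Column names (same in both tables).
#' @return A `recovery_report`: list with `table` (id, true, estimated,
#'   error, rel_error), `bias`, `rmse`, and `rel_bias`/`rel_rmse`
#'   normalised by the mean absolute true value.
#' @export
recovery_report <- function(estimated, truth, id_col = "id",
                            value_col = "value") {
  if (!setequal(estimated[[id_col]], truth[[id_col]]))
    stop("unmatched cells between estimates and ground truth")
  tr <- truth[, c(id_col, value_col)]; names(tr)[2] <- "true"
  es <- estimated[, c(id_col, value_col)]; names(es)[2] <- "estimated"
  tab <- merge(tr, es, by = id_col)
  tab$error <- tab$estimated - tab$true
  tab$rel_error <- ifelse(tab$true != 0, tab$error / abs(tab$true), NA_real_)
  denom <- mean(abs(tab$true))
  structure(list(table = tab,
                 bias = mean(tab$error),
                 rmse = sqrt(mean(tab$error^2)),
                 rel_bias = mean(tab$error) / denom,
                 rel_rmse = sqrt(mean(tab$error^2)) / denom),
            class = "recovery_report")
}

#' Synthetic four-group kinetic feature table
#'
#' Emulates a phenotyping experiment crossing genotype (wild type vs an
#' NPQ-deficient mutant: all NPQ-linked variables shifted down in the
#' mutant) with cell type (chloroplast-rich chloronema vs elongated
#' caulonema: Fmax and AreaFrac shifted). Group means are fixed, within-
#' group variation Gaussian; NPQav is drawn as a fraction of each cell's
#' own NPQmax so the two stay correlated.
#'
#' @param n Total number of cells (split as evenly as possible across the
#'   four groups).
#' @param seed Integer seed.
#' @return data.frame with `genotype`, `cell_type` and the six feature
#'   columns.
#' @export
simulate_feature_table <- function(n = 175, seed = 1L) {
  with_seed(seed, {
    groups <- expand.grid(genotype = c("WT", "npq_mutant"),
                          cell_type = c("chloronema", "caulonema"),
                          stringsAsFactors = FALSE)
    sizes <- rep(n %/% 4, 4) + c(rep(1, n %% 4), rep(0, 4 - n %% 4))
    rows <- lapply(seq_len(4), function(i) {
      k <- sizes[i]
      wt <- groups$genotype[i] == "WT"
      chl <- groups$cell_type[i] == "chloronema"
      NPQmax <- pmax(stats::rnorm(k, if (wt) 2.0 else 0.6,
                                  if (wt) 0.35 else 0.15), 0.05)
      data.frame(
        genotype = groups$genotype[i], cell_type = groups$cell_type[i],
        NPQav = NPQmax * stats::rnorm(k, 0.75, 0.04),
        NPQmax = NPQmax,
        Induction = pmax(stats::rnorm(k, if (wt) 0.9 else 0.3,
                                      if (wt) 0.2 else 0.1), 0.01),
        Decay = pmin(stats::rnorm(k, if (wt) -0.5 else -0.15,
                                  if (wt) 0.12 else 0.06), -0.01),
        Fmax = pmax(stats::rnorm(k, if (chl) 1500 else 700,
                                 if (chl) 250 else 180), 50),
        AreaFrac = pmin(pmax(stats::rnorm(k, if (chl) 55 else 20,
                                          if (chl) 8 else 6), 1), 95),
        stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
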