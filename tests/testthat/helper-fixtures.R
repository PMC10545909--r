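# shared fixtures and independent brute-force oracles

random_int_stack <- function(nt, nz, ny, nx, max_count = 1000L) {
  a <- array(sample.int(max_count, nt * nz * ny * nx, replace = TRUE),
             c(nt, nz, ny, nx))
  acquisition_stack(a, voxel_size = c(0.5, 0.5), z_step = 2,
                    timestamps = (seq_len(nt) - 1) * 60)
}

# naive triple-loop sum projection
oracle_sum_project <- function(a) {
  d <- dim(a)
  out <- array(0, c(d[1], d[3], d[4]))
  for (t in seq_len(d[1])) for (y in seq_len(d[3])) for (x in seq_len(d[4])) {
    s <- 0
    for (z in seq_len(d[2])) s <- s + a[t, z, y, x]
    out[t, y, x] <- s
  }
  out
}

# naive box-median filter with edge replication
oracle_median3d <- function(vol, r) {
  d <- dim(vol)
  out <- array(0, d)
  cl <- function(i, n) min(max(i, 1), n)
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    nb <- numeric(0)
    for (dz in -r:r) for (dy in -r:r) for (dx in -r:r)
      nb <- c(nb, vol[cl(z + dz, d[1]), cl(y + dy, d[2]), cl(x + dx, d[3])])
    out[z, y, x] <- median(nb)
  }
  out
}

# rasterized disk mask: pixel centres within radius of (cy, cx)
disk_mask <- function(ny, nx, cy, cx, radius) {
  yy <- matrix(seq_len(ny), ny, nx)
  xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  (yy - cy)^2 + (xx - cx)^2 <= radius^2
}

# standard 3/6/6-frame protocol at 1-min spacing
default_timeline <- function(interval = 60)
  build_timeline(3, 6, 6, interval, actinic_intensity = 500)

corrected_trace <- function(values, timestamps = seq_along(values) - 1,
                            label = "cell")
  fluor_trace(label, values, timestamps, background_corrected = TRUE)

# simulate -> project -> trace -> correct -> NPQ for one cell
run_npq_recovery <- function(params, timeline) {
  sc <- render_scene(params, timeline)
  pr <- sum_project(sc$stack)
  bg <- mean_gray(pr, truth_background_roi(sc$truth))
  obj <- mean_gray(pr, truth_cell_roi(sc$truth, 1))
  npq <- compute_npq_series(subtract_background(obj, bg), timeline)
  list(npq = npq, truth = sc$truth, stack = sc$stack)
}
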