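#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> sum-project -> ROI traces ->
#' background correction -> NPQ time courses -> kinetic features
#' (-> optional PCA), writing every stage output plus a machine-readable
#' manifest with MD5 checksums. Rerunning with the same config and seed
#' reproduces the checksums of all deterministic artifacts.
#'
#' @param config A list, or path to a YAML/JSON file, with:
#'   \describe{
#'     \item{timeline}{`n_dark`, `n_light`, `n_relax`, `interval_s`,
#'       optional `actinic_umol` (required unless `input$timeline` given).}
#'     \item{simulation}{Overrides for [scene_params()] (mutually exclusive
#'       with `input`). An empty list uses the defaults.}
#'     \item{input}{`stack` (TIFF path), optional `config` sidecar, `rois`
#'       (label-mask TIFF) and `roles` (JSON role map); exactly one ROI
#'       must have the background role.}
#'     \item{pca}{Logical; run correlation-matrix PCA on the feature table
#'       (needs >= 2 cells with non-degenerate features).}
#'   }
#' @param out_dir Output directory (created if needed).
#' @param seed Integer; overrides `config$seed` and fixes the simulation.
#' @return The manifest, invisibly: list with `package`, `version`,
#'   `seed`, `config`, and `files` (path + md5 per artifact).
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stage <- function(name, expr) {
    tryCatch(force(expr), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  has_sim <- !is.null(config$simulation)
  has_input <- !is.null(config$input)
  if (has_sim == has_input)
    stop("config must declare exactly one input source ('simulation' or 'input')")
  if (is.null(config$timeline))
    stop("config missing 'timeline'")
  if (is.null(seed)) seed <- if (!is.null(config$seed)) config$seed else 1L
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  emit <- function(p) { paths[[length(paths) + 1]] <<- p; p }

  tl <- stage("timeline", {
    tc <- config$timeline
    timeline <- build_timeline(tc$n_dark, tc$n_light, tc$n_relax,
                               tc$interval_s,
                               actinic_intensity = tc$actinic_umol %||% 0)
    write_timeline(timeline, emit(file.path(out_dir, "timeline.json")))
    timeline
  })

  sim_out <- stage("stack", {
    if (has_sim) {
      sim <- config$simulation
      sim$seed <- seed
      params <- do.call(scene_params, sim)
      message("simulating scene (seed ", seed, ")")
      sc <- render_scene(params, tl)
      write_stack(sc$stack, emit(file.path(out_dir, "stack.tif")))
      emit(file.path(out_dir, "stack.tif.json"))
      jsonlite::write_json(
        list(npq = sc$truth$npq, volumes = sc$truth$volumes,
             area_frac = sc$truth$area_frac, cells = sc$truth$cells),
        emit(file.path(out_dir, "truth.json")),
        auto_unbox = TRUE, digits = NA)
      sc
    } else {
      list(stack = read_stack(config$input$stack,
                              config = config$input$config),
           truth = NULL)
    }
  })
  stack <- sim_out$stack
  truth <- sim_out$truth

  projected <- stage("project", {
    p <- sum_project(stack)
    write_projected(p, emit(file.path(out_dir, "projected.tif")))
    emit(file.path(out_dir, "projected.tif.json"))
    p
  })

  rois <- stage("rois", {
    if (has_sim) {
      r <- lapply(seq_len(truth$params$n_cells),
                  function(i) truth_cell_roi(truth, i))
      names(r) <- vapply(r, `[[`, "", "label")
      c(r, list(background = truth_background_roi(truth)))
    } else {
      read_rois(config$input$rois, config$input$roles)
    }
  })

  traces <- stage("trace", {
    roles <- vapply(rois, `[[`, "", "role")
    if (sum(roles == "background") != 1)
      stop("exactly one background ROI is required")
    bg <- mean_gray(projected, rois[[which(roles == "background")]])
    objs <- lapply(rois[roles == "object"], function(r) mean_gray(projected, r))
    trace_table(objs, bg, emit(file.path(out_dir, "traces.csv")))
    lapply(objs, subtract_background, background_trace = bg)
  })

  npq_list <- stage("npq", {
    out <- lapply(traces, compute_npq_series, timeline = tl)
    tab <- do.call(rbind, lapply(names(out), function(nm)
      cbind(roi_label = nm, out[[nm]]$npq)))
    utils::write.csv(tab, emit(file.path(out_dir, "npq.csv")), row.names = FALSE)
    out
  })

  features <- stage("features", {
    af <- if (has_sim) truth$area_frac else rep(NA_real_, length(npq_list))
    tab <- do.call(rbind, lapply(seq_along(npq_list), function(i)
      cbind(roi_label = names(npq_list)[i],
            extract_features(npq_list[[i]], tl, area_frac = af[i]))))
    utils::write.csv(tab, emit(file.path(out_dir, "features.csv")),
                     row.names = FALSE)
    tab
  })

  if (isTRUE(config$pca)) {
    stage("pca", {
      sds <- vapply(FEATURE_COLS, function(cl)
        stats::sd(features[[cl]], na.rm = TRUE), numeric(1))
      if (nrow(features) < 3 || any(!is.finite(sds)) || any(sds == 0)) {
        message("skipping PCA: feature table is degenerate (",
                nrow(features), " cells)")
      } else {
        pca <- principal_components(standardize_features(features))
        for (p in write_pca(pca, out_dir)) emit(p)
      }
    })
  }

  manifest <- list(
    package = "pamscope",
    version = as.character(utils::packageVersion("pamscope")),
    seed = seed,
    config = config,
    files = data.frame(path = basename(unlist(paths)),
                       md5 = unname(tools::md5sum(unlist(paths))),
                       stringsAsFactors = FALSE))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
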