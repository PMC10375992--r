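#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end workflow: scene/acquisition
#' parameters, DOPU kernel, SSADA settings, segmentation parameters,
#' quantification thresholds, the TBI simulation block and the master seed.
#' Round-trips losslessly through JSON ([write_config()] / [read_config()]).
#'
#' @param scene a [scene_config()]
#' @param snr_db rendering SNR in dB (Inf = noise-free)
#' @param dopu_kernel c(kz, kx) DOPU window
#' @param dopu_weighted use intensity-weighted Stokes averaging for the DOPU
#'   volume fed to segmentation (robust against noise-dominated voxels)
#' @param ssada list(M =, overlap =): split-spectrum settings
#' @param seg a [segmentation_params()]
#' @param quantify list(bin_threshold = NULL for percentile auto-calibration,
#'   calib_prob =, min_area =, ret_threshold =, dilation_px =)
#' @param tbi NULL or list(fractions =, roi = NULL for a centred square,
#'   flow_threshold = NULL for auto)
#' @param seed master integer seed
#' @return list of class "PipelineConfig"
#' @export
pipeline_config <- function(scene = scene_config(),
                            snr_db = 25,
                            dopu_kernel = c(5L, 5L),
                            dopu_weighted = TRUE,
                            ssada = list(M = 4L, overlap = 0.5),
                            seg = segmentation_params(),
                            quantify = list(bin_threshold = NULL,
                                            calib_prob = 0.99,
                                            min_area = 4L,
                                            ret_threshold = 35,
                                            dilation_px = 2L),
                            tbi = list(fractions = c(0.05, 0.15, 0.30),
                                       roi = NULL, flow_threshold = NULL),
                            seed = 1L) {
  cfg <- list(scene = scene, snr_db = snr_db,
              dopu_kernel = as.integer(dopu_kernel),
              dopu_weighted = isTRUE(dopu_weighted), ssada = ssada,
              seg = seg, quantify = quantify, tbi = tbi,
              seed = as.integer(seed))
  class(cfg) <- "PipelineConfig"
  validate_config(cfg)
  cfg
}

#' @rdname pipeline_config
#' @param config object to validate
#' @export
validate_config <- function(config) {
  if (!inherits(config, "PipelineConfig")) err_config("not a PipelineConfig")
  if (!inherits(config$scene, "mfoct_scene_config"))
    err_config("field 'scene': not a scene_config")
  if (config$ssada$M < 1) err_config("field 'ssada$M': must be >= 1")
  if (length(config$dopu_kernel) != 2 || any(config$dopu_kernel %% 2 != 1))
    err_config("field 'dopu_kernel': must be two odd sizes")
  if (!is.numeric(config$seed)) err_config("field 'seed': must be numeric")
  invisible(config)
}

deep_unclass <- function(x) {
  if (is.list(x)) lapply(unclass(x), deep_unclass) else x
}

#' Serialize / deserialize a pipeline configuration
#'
#' @param config a PipelineConfig
#' @param path JSON path
#' @export
write_config <- function(config, path) {
  validate_config(config)
  jsonlite::write_json(deep_unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  sc <- j$scene
  named <- function(v, nms) {            # JSON arrays drop names; restore them
    v <- unlist(v)
    if (is.null(names(v)) && length(v) == length(nms)) names(v) <- nms
    v
  }
  scene <- scene_config(grid = unlist(sc$grid),
                        pitch_um = named(sc$pitch_um, c("z", "x", "y")),
                        offsets = unlist(sc$offsets),
                        undulation_amp = sc$undulation_amp,
                        undulation_waves = sc$undulation_waves,
                        lambda0_um = sc$lambda0_um,
                        target_retardation_deg =
                          named(sc$target_retardation_deg, c("skin", "skull")),
                        dn = if (!is.null(sc$dn)) named(sc$dn, c("skin", "skull")),
                        backscatter = named(sc$backscatter,
                                            c("skin", "skull", "suture",
                                              "pigment", "brain", "vessel")),
                        attenuation_per_um = named(sc$attenuation_per_um,
                                                   c("skin", "skull", "brain")),
                        pigment = lapply(sc$pigment, unlist),
                        sutures = lapply(sc$sutures, unlist),
                        vessels = lapply(sc$vessels, unlist),
                        n_repeats = sc$n_repeats,
                        line_rate_hz = sc$line_rate_hz)
  sg <- j$seg
  seg <- segmentation_params(thr_int_air_skin = sg$thr_int_air_skin,
                             thr_int_skull_brain = sg$thr_int_skull_brain,
                             thr_dopu = sg$thr_dopu,
                             opening_width = sg$opening_width,
                             spline_smoothing = sg$spline_smoothing,
                             min_component_area = sg$min_component_area,
                             min_column_count = sg$min_column_count %||% 5L,
                             thickness_tol = sg$thickness_tol %||% 8)
  pipeline_config(scene = scene, snr_db = j$snr_db,
                  dopu_kernel = unlist(j$dopu_kernel),
                  dopu_weighted = j$dopu_weighted %||% TRUE,
                  ssada = lapply(j$ssada, unlist), seg = seg,
                  quantify = j$quantify,
                  tbi = if (!is.null(j$tbi)) j$tbi, seed = j$seed)
}

#' Hash a pipeline configuration for provenance
#' @param config a PipelineConfig
#' @return 8-hex-digit hash string
#' @export
config_hash <- function(config) {
  fnv1a_hash(jsonlite::toJSON(deep_unclass(config), auto_unbox = TRUE,
                              digits = NA, null = "null"))
}

log_info <- function(...) {
  message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(...)))
}

#' Run the end-to-end analysis pipeline
#'
#' Orchestrates the workflow: simulate (or read) a tomogram series, compute
#' intensity / retardation / DOPU, run the organ segmentation, compute the
#' SSADA angiogram, render the en-face outputs, detect transcranial channels
#' and co-localize them with the suture map, and (in simulation mode)
#' quantify a TBI revascularization time series. All scalar artifacts are
#' written to `out_dir` with the config hash as provenance; the run is
#' deterministic given (config, seed).
#'
#' Stages may be run individually (`stages` argument); later stages load the
#' intermediates earlier stages wrote to `out_dir`, so a stage-by-stage run
#' reproduces an `all` run bit for bit.
#'
#' @param config a [pipeline_config()]
#' @param out_dir output directory (created if needed)
#' @param input optional tomogram prefix to read instead of simulating
#' @param stages character vector, subset of c("simulate", "signals",
#'   "segment", "angio", "project", "channels", "tbi"); default all
#' @return invisible list with the main in-memory artifacts and the manifest
#' @export
run_pipeline <- function(config, out_dir, input = NULL,
                         stages = c("simulate", "signals", "segment", "angio",
                                    "project", "channels", "tbi")) {
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  seed <- config$seed
  art <- new.env(parent = emptyenv())
  pfx <- function(name) file.path(out_dir, name)
  manifest <- character()
  add_manifest <- function(...) manifest <<- c(manifest, ...)

  need_tomo <- function() {
    if (!is.null(art$tomo)) return(art$tomo)
    art$tomo <- read_tomogram(pfx("tomogram"))
    art$tomo
  }
  need_vol <- function(name) {
    key <- paste0("vol_", name)
    if (!is.null(art[[key]])) return(art[[key]])
    art[[key]] <- read_derived_volume(pfx(name))
    art[[key]]
  }
  need_boundaries <- function() {
    if (!is.null(art$boundaries)) return(art$boundaries)
    art$boundaries <- read_boundaries(pfx("boundaries.csv"))
    art$boundaries
  }

  run_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    ok <- tryCatch({fun(); TRUE}, error = function(e) {
      write_json_sidecar(list(config_hash = hash, failed_stage = name,
                              error = conditionMessage(e),
                              manifest = manifest),
                         pfx("provenance.json"))
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    log_info("stage %-9s done in %.2fs", name, proc.time()[["elapsed"]] - t0)
    ok
  }

  if ("simulate" %in% stages) run_stage("simulate", function() {
    if (!is.null(input)) {
      art$tomo <- read_tomogram(input)
      write_tomogram(art$tomo, pfx("tomogram"), config_hash = hash)
    } else {
      scene <- build_scene(config$scene, seed)
      rs <- render_series(scene, snr_db = config$snr_db, seed = seed)
      art$tomo <- rs$tomo; art$truth <- rs$truth; art$scene <- scene
      write_tomogram(art$tomo, pfx("tomogram"), config_hash = hash)
      write_json_sidecar(list(config_hash = hash,
                              channel_truth = rs$truth$channel_truth,
                              seed = seed),
                         pfx("truth.json"))
      add_manifest("truth.json")
    }
    add_manifest("tomogram.json", "tomogram.bin")
  })

  if ("signals" %in% stages) run_stage("signals", function() {
    tomo <- need_tomo()
    art$vol_intensity <- compute_intensity(tomo)
    art$vol_retardation <- compute_retardation(tomo)
    art$vol_dopu <- compute_dopu(tomo, kernel = config$dopu_kernel,
                                 intensity_weighted = config$dopu_weighted %||% TRUE)
    write_derived_volume(art$vol_intensity, pfx("intensity"), hash)
    write_derived_volume(art$vol_retardation, pfx("retardation"), hash)
    write_derived_volume(art$vol_dopu, pfx("dopu"), hash)
    add_manifest("intensity.bin", "retardation.bin", "dopu.bin")
  })

  if ("segment" %in% stages) run_stage("segment", function() {
    seg <- segment_volume(need_vol("intensity"), need_vol("dopu"), config$seg)
    art$boundaries <- seg$boundaries
    art$layers <- seg$layers
    write_boundaries(seg$boundaries, pfx("boundaries.csv"), hash)
    add_manifest("boundaries.csv")
  })

  if ("angio" %in% stages) run_stage("angio", function() {
    tomo <- need_tomo()
    if (tomo$n_repeats < 2)
      stop("angiography requires N >= 2 repeats, got ", tomo$n_repeats)
    bands <- split_spectrum(tomo, M = config$ssada$M,
                            overlap = config$ssada$overlap)
    art$vol_decorr <- ssada_decorrelation(bands, need_vol("intensity"))
    write_derived_volume(art$vol_decorr, pfx("decorrelation"), hash)
    add_manifest("decorrelation.bin")
  })

  if ("project" %in% stages) run_stage("project", function() {
    b <- need_boundaries()
    int <- need_vol("intensity"); ret <- need_vol("retardation")
    dec <- need_vol("decorrelation")
    for (band in c("skin", "skull", "brain")) {
      pi_ <- layer_projection(int, band, b)
      pr <- layer_projection(ret, band, b)
      write_enface(pi_, pfx(paste0("proj_intensity_", band)), hash)
      write_enface(pr, pfx(paste0("proj_retardation_", band)), hash)
      write_enface(retardation_grayscale(pr),
                   pfx(paste0("proj_retgray_", band)), hash)
      art[[paste0("proj_int_", band)]] <- pi_
      art[[paste0("proj_ret_", band)]] <- pr
    }
    ei <- split_extra_intra(dec, b)
    art$proj_extra <- ei$extra; art$proj_intra <- ei$intra
    write_enface(ei$extra, pfx("octa_extracranial"), hash)
    write_enface(ei$intra, pfx("octa_intracranial"), hash)
    write_enface(merge_red_green(ei$extra, ei$intra), pfx("octa_merged"), hash)
    write_enface(depth_encode(dec, "extracranial", b),
                 pfx("octa_depth_extracranial"), hash)
    write_enface(depth_encode(dec, "intracranial", b),
                 pfx("octa_depth_intracranial"), hash)
    add_manifest("octa_extracranial.csv", "octa_intracranial.csv",
                 "octa_merged.ppm", "octa_depth_extracranial.ppm",
                 "octa_depth_intracranial.ppm", "proj_retgray_skull.csv")
  })

  if ("channels" %in% stages) run_stage("channels", function() {
    b <- need_boundaries()
    dec <- need_vol("decorrelation")
    halves <- skull_half_projections(dec, b)
    thr <- config$quantify$bin_threshold %||%
      calibrate_flow_threshold(halves$upper, halves$lower,
                               probs = config$quantify$calib_prob %||% 0.99)
    calls <- detect_channels(halves$upper, halves$lower, thr,
                             config$quantify$min_area %||% 4L)
    sm <- build_suture_map(
      layer_projection(need_vol("retardation"), "skull", b),
      layer_projection(need_vol("intensity"), "skull", b),
      ret_threshold = config$quantify$ret_threshold %||% 35)
    calls <- colocalize(calls, sm, config$quantify$dilation_px %||% 2L)
    art$channel_calls <- calls; art$suture_map <- sm
    write_channel_calls(calls, pfx("channels"), hash)
    write_enface(new_enface(sm$suture_mask * 1, "mean_intensity", "skull"),
                 pfx("suture_map"), hash)
    add_manifest("channels.csv", "channels.json", "suture_map.csv")
  })

  if ("tbi" %in% stages && !is.null(config$tbi) && is.null(input))
    run_stage("tbi", function() {
      fr <- config$tbi$fractions
      nx <- config$scene$grid[["nx"]]; ny <- config$scene$grid[["ny"]]
      roi <- config$tbi$roi %||% list(x0 = round(nx * 0.3), x1 = round(nx * 0.7),
                                      y0 = round(ny * 0.3), y1 = round(ny * 0.7))
      base <- build_scene(config$scene, seed)
      series <- list(); thr <- config$tbi$flow_threshold
      for (i in seq_along(fr)) {
        sc <- plant_roi_vessels(base, roi, fr[i], seed = seed + i)
        rs <- render_series(sc, snr_db = config$snr_db, seed = seed + i)
        int <- compute_intensity(rs$tomo)
        dop <- compute_dopu(rs$tomo, kernel = config$dopu_kernel,
                            intensity_weighted = config$dopu_weighted %||% TRUE)
        bnd <- segment_volume(int, dop, config$seg)$boundaries
        dec <- ssada_decorrelation(split_spectrum(rs$tomo, config$ssada$M,
                                                  config$ssada$overlap), int)
        series[[i]] <- list(timepoint = c(0.5, 24, 48, 72, 96)[i],
                            image = layer_projection(dec, "intracranial", bnd))
      }
      if (is.null(thr)) {
        rs0 <- render_series(base, snr_db = config$snr_db, seed = seed)
        int0 <- compute_intensity(rs0$tomo)
        dop0 <- compute_dopu(rs0$tomo, kernel = config$dopu_kernel,
                             intensity_weighted = config$dopu_weighted %||% TRUE)
        bnd0 <- segment_volume(int0, dop0, config$seg)$boundaries
        dec0 <- ssada_decorrelation(split_spectrum(rs0$tomo, config$ssada$M,
                                                   config$ssada$overlap), int0)
        p0 <- layer_projection(dec0, "intracranial", bnd0)
        thr <- calibrate_flow_threshold(p0, probs = 0.999)
      }
      metrics <- tbi_metrics(series, roi, thr)
      art$tbi_metrics <- metrics
      write_metrics(metrics, pfx("tbi_metrics.csv"), hash)
      add_manifest("tbi_metrics.csv")
    })

  write_json_sidecar(list(config_hash = hash, seed = seed,
                          package_version = as.character(utils::packageVersion("mfoct")),
                          stages = stages, manifest = manifest),
                     pfx("provenance.json"))
  invisible(list(artifacts = art, manifest = manifest, config_hash = hash,
                 out_dir = out_dir))
}
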