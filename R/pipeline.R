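# End-to-end pipeline: simulate -> calibrate -> fuse -> preprocess -> IK ->
# workspace / assessment, with one seed and a JSON report.

#' Pipeline configuration
#'
#' @param action Protocol action id (see [protocol_actions()]).
#' @param impairment An [impairment_spec()].
#' @param fps Frame rate (Hz).
#' @param seed Integer seed used by every stage.
#' @param cameras Two-camera rig as [default_cameras()].
#' @param median_window,cutoff Filter settings (see [filter_spec()]);
#'   `cutoff = NULL` uses the rate-dependent default.
#' @param swarm A [swarm_config()].
#' @param model An [arm_model()].
#' @param assess_model Optional trained [build_network()] model; when `NULL`
#'   an untrained network (seeded) is used, so the report's score column is
#'   a placeholder marked `trained = FALSE`.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(action = "RW-V90",
                            impairment = impairment_spec(),
                            fps = 30, seed = 1,
                            cameras = default_cameras(),
                            median_window = 5, cutoff = NULL,
                            swarm = swarm_config(max_iter = 100),
                            model = arm_model(),
                            assess_model = NULL) {
  structure(list(action = action, impairment = impairment, fps = fps,
                 seed = seed, cameras = cameras,
                 median_window = median_window, cutoff = cutoff,
                 swarm = swarm, model = model, assess_model = assess_model),
            class = "pipeline_config")
}

# deterministic 32-bit config digest for report sidecars
.config_hash <- function(config) {
  raw <- utf8ToInt(paste(deparse(config[setdiff(names(config),
                                                "assess_model")]),
                         collapse = ""))
  sprintf("%08x", sum(raw * (seq_along(raw) %% 97 + 1)) %% .Machine$integer.max)
}

#' Calibrate two cameras from synthetic checkerboard correspondences
#'
#' Renders a set of world points into both camera frames and estimates the
#' subordinate-to-master rigid transform from the correspondences.
#'
#' @param cameras List with `master` and `subordinate` `camera_spec`s.
#' @param n_points Number of correspondences.
#' @param seed Integer seed.
#' @return A `rigid_transform` (subordinate to master).
#' @export
calibrate_cameras <- function(cameras, n_points = 24, seed = 1) {
  set.seed(seed)
  pw <- matrix(stats::runif(n_points * 3, -0.8, 0.8), ncol = 3)
  pm <- apply_transform(cameras$master$transform, pw)
  ps <- apply_transform(cameras$subordinate$transform, pw)
  estimate_rigid_transform(ps, pm)
}

#' Transform every frame of a stream rigidly
#' @param stream A `skeleton_stream`.
#' @param transform A `rigid_transform`.
#' @return Transformed `skeleton_stream`.
#' @export
transform_stream <- function(stream, transform) {
  xyz <- stream$xyz
  for (i in seq_len(n_frames(stream)))
    xyz[i, , ] <- apply_transform(transform, matrix(stream$xyz[i, , ], ncol = 3))
  skeleton_stream(stream$timestamps, stream$joints, xyz, stream$conf)
}

#' Run the full assessment pipeline on simulated data
#'
#' Executes, under one seed: simulation of the configured action, extrinsic
#' calibration, stream fusion, world registration, denoising, SNR
#' computation, CBPSO inverse kinematics, reachable-workspace analysis and
#' score assessment.  A stage failure halts the run with the stage name.
#'
#' @param config A [pipeline_config()].
#' @param out_json Optional path for the JSON report.
#' @return Report list with elements `score`, `envelope`, `snr`,
#'   `importance` and `meta`.
#' @export
run_pipeline <- function(config, out_json = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  ses <- stage("simulate",
               simulate_session(config$action, config$impairment, config$fps,
                                config$seed, config$model, config$cameras))
  extr <- stage("calibrate",
                calibrate_cameras(config$cameras, seed = config$seed))
  fused <- stage("fuse",
                 fuse_streams(ses$views$master, ses$views$sub, extr))
  world <- stage("register",
                 transform_stream(fused,
                                  invert_transform(config$cameras$master$transform)))
  clean <- stage("preprocess", {
    fs <- config$fps
    spec <- if (is.null(config$cutoff))
      filter_spec(fs, config$median_window)
    else filter_spec(fs, config$median_window, cutoff = config$cutoff)
    preprocess_stream(world, spec)
  })
  snr <- stage("snr", snr_table(to_model_frame(world), to_model_frame(clean)))
  ik <- stage("ik", solve_sequence(clean, config$swarm, config$model))
  envelope <- stage("workspace", {
    tryCatch(reachable_workspace(ik$reconstructed, "right"),
             error = function(e) quadrant_areas(matrix(numeric(0), 0, 3)))
  })
  assessment <- stage("assess", {
    net <- config$assess_model
    trained <- !is.null(net)
    if (!trained) net <- build_network(net_config(), seed = config$seed)
    seq <- skeleton_sequence(ik$reconstructed)
    imp <- joint_importance(net, stats::setNames(list(list(seq)),
                                                 config$action))
    list(score = predict_score(net, seq), trained = trained,
         importance = imp)
  })
  report <- list(
    score = list(value = assessment$score, trained = assessment$trained,
                 truth = ses$score),
    envelope = list(quadrant_rsa = as.list(envelope$quadrant_rsa),
                    total_rsa = envelope$total_rsa),
    snr = snr,
    importance = as.data.frame(assessment$importance),
    meta = list(action = config$action, seed = config$seed, fps = config$fps,
                config_hash = .config_hash(config)))
  if (!is.null(out_json))
    jsonlite::write_json(report, out_json, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  report
}
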