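# Synthetic-data generator: ground-truth joint-angle trajectories for the
# 16-action exercise protocol, rendered to two noisy, occlusion-corrupted
# camera views, with ground-truth quality scores from an explicit impairment
# model.

#' The 16-action exercise protocol
#'
#' Eight reachable-workspace sweeps with the arm straight — four
#' vertical-plane sweeps at azimuths 0/45/90/135 deg with elevation
#' traversing 0-180 deg, and four horizontal sweeps at elevations
#' 45/90/135/180 deg with azimuth traversing 0-135 deg — plus eight proximal
#' reaches to body landmarks (side, lumbar spine, stomach, contralateral and
#' ipsilateral shoulder, nose, ear, head top).
#'
#' @return `data.frame` with one row per action: `id`, `type`
#'   (`sweep_v`/`sweep_h`/`proximal`), `azimuth_deg`, `elevation_deg`,
#'   `duration_s`.
#' @export
protocol_actions <- function() {
  rw_v <- data.frame(id = paste0("RW-V", c(0, 45, 90, 135)), type = "sweep_v",
                     azimuth_deg = c(0, 45, 90, 135), elevation_deg = 180,
                     duration_s = 4)
  rw_h <- data.frame(id = paste0("RW-H", c(45, 90, 135, 180)), type = "sweep_h",
                     azimuth_deg = 135, elevation_deg = c(45, 90, 135, 180),
                     duration_s = 4)
  px <- data.frame(id = paste0("P-", c("Side", "LumbarSpine", "Stomach",
                                       "ContralateralShoulder",
                                       "IpsilateralShoulder", "Nose", "Ear",
                                       "HeadTop")),
                   type = "proximal", azimuth_deg = NA, elevation_deg = NA,
                   duration_s = 3)
  rbind(rw_v, rw_h, px)
}

# target joint-angle configurations (degrees) for the proximal reaches
.proximal_targets <- function() {
  t0 <- stats::setNames(numeric(9), arm_angle_names())
  set <- function(...) { v <- t0; a <- c(...); v[names(a)] <- a; v }
  list(
    "P-Side" = set(sh_z = 25, elb_x = 15),
    "P-LumbarSpine" = set(sh_x = -40, sh_y = -50, elb_x = 95, wr_x = 25),
    "P-Stomach" = set(sh_x = 25, elb_x = 85),
    "P-ContralateralShoulder" = set(sh_x = 80, sh_y = 30, elb_x = 120),
    "P-IpsilateralShoulder" = set(sh_x = 40, elb_x = 145),
    "P-Nose" = set(sh_x = 50, elb_x = 130, wr_x = 10),
    "P-Ear" = set(sh_x = 60, sh_z = 30, elb_x = 140),
    "P-HeadTop" = set(sh_x = 110, elb_x = 110))
}

#' Impairment specification and its ground-truth quality score
#'
#' The score label is artifact-defined and documented:
#' `score = clamp(100 * rom_scale - c_t * tremor_amp, 0, 100)` — strictly
#' increasing in range of motion, strictly decreasing in tremor amplitude.
#'
#' @param rom_scale Fraction in (0, 1] multiplying joint-angle amplitude.
#' @param tremor_amp Tremor RMS amplitude (degrees) added in angle space.
#' @param tremor_band Tremor frequency band (Hz), default 4-8 Hz.
#' @param slowness Time-dilation factor >= 1.
#' @param c_t Score penalty per degree of tremor.
#' @return An `impairment_spec` with the computed `score` in `[0, 100]`.
#' @export
impairment_spec <- function(rom_scale = 1, tremor_amp = 0,
                            tremor_band = c(4, 8), slowness = 1, c_t = 4) {
  stopifnot(rom_scale > 0, rom_scale <= 1, tremor_amp >= 0, slowness >= 1)
  structure(list(rom_scale = rom_scale, tremor_amp = tremor_amp,
                 tremor_band = tremor_band, slowness = slowness, c_t = c_t,
                 score = impairment_score(rom_scale, tremor_amp, c_t)),
            class = "impairment_spec")
}

#' @rdname impairment_spec
#' @export
impairment_score <- function(rom_scale, tremor_amp, c_t = 4) {
  min(100, max(0, 100 * rom_scale - c_t * tremor_amp))
}

# band-limited tremor series (degrees), RMS-scaled
.tremor_series <- function(n, fs, amp, band, nchan) {
  if (amp == 0 || n < 12) return(matrix(0, n, nchan))
  hi <- min(band[2], 0.45 * fs)
  lo <- min(band[1], 0.5 * hi)
  bf <- signal::butter(2, c(lo, hi) / (fs / 2), type = "pass")
  out <- matrix(0, n, nchan)
  for (k in seq_len(nchan)) {
    w <- as.numeric(signal::filtfilt(bf, stats::rnorm(n)))
    r <- sqrt(mean(w^2))
    out[, k] <- if (r > 0) w / r * amp else w
  }
  out
}

# smooth out-and-back profiles on [0,1]
.sweep_profile <- function(tau) sin(pi * tau)^2
.minjerk <- function(u) 10 * u^3 - 15 * u^4 + 6 * u^5
.reach_profile <- function(tau) ifelse(tau < 0.5, .minjerk(2 * tau),
                                       .minjerk(2 * (1 - tau)))

#' Generate a ground-truth trajectory for one protocol action
#'
#' Builds the right-arm joint-angle sequence for the requested action (the
#' left arm rests), couples the shoulder girdle to the lift angle by the
#' scapulohumeral-rhythm regression, applies the impairment model (amplitude
#' scaling, band-limited tremor in angle space, time dilation) and renders
#' ground-truth model frames by forward kinematics.
#'
#' @param action Action id (row of [protocol_actions()]).
#' @param impairment An [impairment_spec()].
#' @param fps Frame rate (Hz).
#' @param seed Integer seed (tremor noise).
#' @param model An [arm_model()].
#' @return List: `angles` (T x 9 matrix, right arm, radians), `stream`
#'   (ground-truth model-marker `skeleton_stream`), `score`, `action`,
#'   `fps`.
#' @export
generate_trajectory <- function(action, impairment = impairment_spec(),
                                fps = 30, seed = 1, model = arm_model()) {
  acts <- protocol_actions()
  row <- acts[acts$id == action, ]
  if (nrow(row) != 1) stop(sprintf("generate_trajectory: unknown action '%s'", action))
  stopifnot(fps > 0)
  set.seed(seed)
  dur <- row$duration_s * impairment$slowness
  nT <- max(2L, as.integer(round(dur * fps)) + 1L)
  tau <- seq(0, 1, length.out = nT)
  ts <- tau * dur
  rom <- impairment$rom_scale

  A <- matrix(0, nT, 9, dimnames = list(NULL, arm_angle_names()))
  if (row$type == "sweep_v") {
    A[, "sh_z"] <- rom * row$elevation_deg * .sweep_profile(tau)
    A[, "sh_y"] <- row$azimuth_deg - 90
  } else if (row$type == "sweep_h") {
    A[, "sh_z"] <- rom * row$elevation_deg
    A[, "sh_y"] <- rom * row$azimuth_deg * .sweep_profile(tau) - 90
  } else {
    tgt <- .proximal_targets()[[row$id]]
    A <- outer(rom * .reach_profile(tau), tgt)
    colnames(A) <- arm_angle_names()
  }
  # girdle follows the rhythm regression of the lift angle
  rh <- scapulohumeral_rhythm(A[, "sh_z"])
  A[, "sc_fb"] <- rh$theta_fb
  A[, "sc_ud"] <- rh$theta_ud

  A <- A + .tremor_series(nT, fps, impairment$tremor_amp,
                          impairment$tremor_band, 9)
  # clamp to anatomical limits so ground truth stays solvable
  lim <- model$limits * 180 / pi
  for (k in seq_len(9))
    A[, k] <- pmin(pmax(A[, k], lim["lo", k]), lim["hi", k])
  A <- A * pi / 180

  xyz <- array(0, c(nT, 11, 3))
  ang <- zero_angles()
  for (i in seq_len(nT)) {
    ang$right <- stats::setNames(A[i, ], arm_angle_names())
    xyz[i, , ] <- forward_kinematics(ang, model)
  }
  stream <- skeleton_stream(ts, model_markers(), xyz)
  list(angles = A, stream = stream, score = impairment$score,
       action = row$id, fps = fps)
}

#' Camera specification
#'
#' @param position Camera position in world coordinates (m).
#' @param look_at Point the optical axis passes through.
#' @param noise_sd Additive Gaussian position noise (m).
#' @param dropout_prob Per joint-frame probability of a tracking dropout.
#' @param occlude If `TRUE`, markers behind the torso's frontal plane
#'   relative to the camera are reported with confidence 0.
#' @return A `camera_spec`; `$transform` maps world to camera coordinates.
#' @export
camera_spec <- function(position, look_at = c(0, 0, 0), noise_sd = 0.005,
                        dropout_prob = 0, occlude = TRUE) {
  stopifnot(noise_sd >= 0, dropout_prob >= 0, dropout_prob <= 1)
  zc <- look_at - position
  zc <- zc / sqrt(sum(zc^2))
  xc <- c(zc[3], 0, -zc[1])             # horizontal, perpendicular to view
  nx <- sqrt(sum(xc^2))
  if (nx < 1e-9) xc <- c(1, 0, 0) else xc <- xc / nx
  yc <- c(zc[2] * xc[3] - zc[3] * xc[2],
          zc[3] * xc[1] - zc[1] * xc[3],
          zc[1] * xc[2] - zc[2] * xc[1])   # cross(zc, xc) -> up
  R <- rbind(xc, yc, zc)                   # rows: camera axes in world
  dimnames(R) <- NULL
  structure(list(position = position,
                 transform = rigid_transform(R, drop(-R %*% position)),
                 noise_sd = noise_sd, dropout_prob = dropout_prob,
                 occlude = occlude),
            class = "camera_spec")
}

#' Default two-camera rig
#'
#' Two cameras 2 m apart subtending 90 degrees at the subject, both aimed at
#' the torso origin.
#'
#' @inheritParams camera_spec
#' @return List with `master` and `subordinate` `camera_spec`s.
#' @export
default_cameras <- function(noise_sd = 0.005, dropout_prob = 0.02,
                            occlude = TRUE) {
  list(master = camera_spec(c(1, 0, 1), noise_sd = noise_sd,
                            dropout_prob = dropout_prob, occlude = occlude),
       subordinate = camera_spec(c(-1, 0, 1), noise_sd = noise_sd,
                                 dropout_prob = dropout_prob,
                                 occlude = occlude))
}

#' True subordinate-to-master extrinsics of a camera pair
#' @param master,subordinate `camera_spec` objects.
#' @return `rigid_transform` mapping subordinate camera coordinates into the
#'   master camera frame.
#' @export
camera_extrinsics <- function(master, subordinate) {
  compose_transform(master$transform, invert_transform(subordinate$transform))
}

# static standing-pose template for the 21 non-upper-limb device joints (m,
# world frame, neck at origin); exists only so device frames are
# format-complete
.body_template <- function() {
  rbind(PELVIS = c(0, -0.60, 0), SPINE_NAVEL = c(0, -0.45, 0),
        SPINE_CHEST = c(0, -0.25, 0),
        CLAVICLE_LEFT = c(-0.06, -0.03, 0.02),
        THUMB_LEFT = c(-0.22, -0.68, 0.02),
        CLAVICLE_RIGHT = c(0.06, -0.03, 0.02),
        THUMB_RIGHT = c(0.22, -0.68, 0.02),
        HIP_LEFT = c(-0.10, -0.62, 0), KNEE_LEFT = c(-0.11, -1.05, 0),
        ANKLE_LEFT = c(-0.11, -1.45, 0), FOOT_LEFT = c(-0.11, -1.52, 0.12),
        HIP_RIGHT = c(0.10, -0.62, 0), KNEE_RIGHT = c(0.11, -1.05, 0),
        ANKLE_RIGHT = c(0.11, -1.45, 0), FOOT_RIGHT = c(0.11, -1.52, 0.12),
        HEAD = c(0, 0.15, 0.02), NOSE = c(0, 0.14, 0.12),
        EYE_LEFT = c(-0.04, 0.18, 0.10), EAR_LEFT = c(-0.08, 0.16, 0.01),
        EYE_RIGHT = c(0.04, 0.18, 0.10), EAR_RIGHT = c(0.08, 0.16, 0.01))
}

#' Render a ground-truth stream to two noisy camera views
#'
#' Expresses each frame in each camera's coordinate frame, fills the
#' non-upper-limb device joints from a static standing template, then applies
#' occlusion (markers behind the torso's frontal plane as seen from the
#' camera), i.i.d. tracking dropouts and additive Gaussian noise.  Occluded
#' or dropped joints carry confidence 0 and the sentinel position (0,0,0).
#'
#' @param stream Ground-truth model-marker `skeleton_stream` (world frame).
#' @param cam_master,cam_sub `camera_spec` objects.
#' @param seed Integer seed.
#' @return List of two 32-joint device `skeleton_stream`s (`master`, `sub`),
#'   each in its own camera frame.
#' @export
render_views <- function(stream, cam_master = default_cameras()$master,
                         cam_sub = default_cameras()$subordinate, seed = 1) {
  set.seed(seed)
  lapply(list(master = cam_master, sub = cam_sub), function(cam) {
    .render_one_view(stream, cam)
  })
}

.render_one_view <- function(stream, cam) {
  nT <- n_frames(stream)
  dj <- device_joints()
  map <- marker_device_map()
  tmpl <- .body_template()
  xyz <- array(0, c(nT, 32, 3))
  conf <- matrix(1, nT, 32)
  n_hat <- c(0, 0, 1)                     # torso anterior normal (world)
  for (i in seq_len(nT)) {
    world <- matrix(NA_real_, 32, 3, dimnames = list(dj, NULL))
    world[map, ] <- matrix(stream$xyz[i, match(names(map), stream$joints), ],
                           ncol = 3)
    world[rownames(tmpl), ] <- tmpl
    p_tor <- world["NECK", ]
    if (cam$occlude) {
      cam_front <- sum((cam$position - p_tor) * n_hat) > 0
      behind <- (world %*% n_hat - sum(p_tor * n_hat)) < -0.10
      occ <- if (cam_front) drop(behind) else !drop(behind)
      conf[i, occ] <- 0
    }
    pc <- apply_transform(cam$transform, world)
    if (cam$noise_sd > 0)
      pc <- pc + matrix(stats::rnorm(96, sd = cam$noise_sd), 32, 3)
    xyz[i, , ] <- pc
  }
  if (cam$dropout_prob > 0) {
    drop_mask <- matrix(stats::runif(nT * 32) < cam$dropout_prob, nT, 32)
    conf[drop_mask] <- 0
  }
  for (d in 1:3) {
    plane <- xyz[, , d]
    plane[conf == 0] <- 0               # sentinel position
    xyz[, , d] <- plane
  }
  skeleton_stream(stream$timestamps, dj, xyz, conf)
}

#' Simulate a full recording session for one action
#'
#' Convenience wrapper chaining [generate_trajectory()] and [render_views()];
#' optionally writes the two camera CSV streams, the ground-truth CSV and a
#' JSON sidecar with the impairment specification and score label.
#'
#' @inheritParams generate_trajectory
#' @param cameras List with `master`/`subordinate` `camera_spec`s.
#' @param out_dir Optional output directory for CSV/JSON artifacts.
#' @return List: `truth` (trajectory list), `views` (two device streams),
#'   `score`.
#' @export
simulate_session <- function(action, impairment = impairment_spec(),
                             fps = 30, seed = 1, model = arm_model(),
                             cameras = default_cameras(), out_dir = NULL) {
  truth <- generate_trajectory(action, impairment, fps, seed, model)
  views <- render_views(truth$stream, cameras$master, cameras$subordinate,
                        seed = seed + 1L)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_skeleton_csv(views$master, file.path(out_dir, "camera_master.csv"))
    write_skeleton_csv(views$sub, file.path(out_dir, "camera_sub.csv"))
    write_skeleton_csv(truth$stream, file.path(out_dir, "ground_truth.csv"))
    jsonlite::write_json(list(action = action, seed = seed, fps = fps,
                              impairment = unclass(impairment),
                              score = truth$score),
                         file.path(out_dir, "session.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(truth = truth, views = views, score = truth$score)
}
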