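# 9-DOF-per-arm rigid-body model of the upper limbs.
#
# Conventions (documented in the methods vignette):
#  * torso/world frame: x to the subject's right, y up, z anterior (toward
#    the camera); the base frame sits at the neck.
#  * rest pose: arms hanging at the sides, segment axes along -y; the
#    shoulder offset from the neck lies along +x (right) / -x (left).
#  * x-axis joint rotations (shoulder/elbow/wrist/hand flexion) are
#    flexion-positive: a positive angle moves the segment anteriorly.
#  * the left chain mirrors the right one: rotations about y and z act with
#    opposite sign, offsets are reflected through the sagittal plane.
#  * all angles are radians internally; the rhythm regression coefficients
#    are degree-based and converted at the boundary.

#' Elementary rotation matrix
#'
#' @param axis One of `"x"`, `"y"`, `"z"`.
#' @param angle Angle in radians.
#' @return Orthonormal 3x3 rotation matrix (det +1).
#' @export
rot <- function(axis = c("x", "y", "z"), angle) {
  axis <- match.arg(axis)
  c_ <- cos(angle); s_ <- sin(angle)
  switch(axis,
    x = matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3, 3),
    y = matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3),
    z = matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3))
}

#' Homogeneous transform from rotation and translation
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation Length-3 translation vector (m).
#' @return 4x4 homogeneous matrix with bottom row (0,0,0,1).
#' @export
hom <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rbind(cbind(rotation, matrix(translation, 3, 1)), c(0, 0, 0, 1))
}

#' Names of the 9 per-arm joint angles
#'
#' Order: sternoclavicular (2), shoulder (3), elbow (1), wrist (2), hand (1).
#' @return Character vector of length 9.
#' @export
arm_angle_names <- function() {
  c("sc_fb", "sc_ud", "sh_x", "sh_y", "sh_z",
    "elb_x", "wr_x", "wr_z", "hand_x")
}

#' Default anatomical joint limits (radians)
#'
#' Box limits on the 9 per-arm angles, chosen from standard range-of-motion
#' tables.  The shoulder-elevation slot absorbs the scapular contribution to
#' total elevation, so its upper bound reaches a full 180 degrees, and the
#' girdle elevation bound accommodates the rhythm regression at high lift
#' angles.
#'
#' @return Named 2 x 9 matrix (`lo`, `hi` rows).
#' @export
default_joint_limits <- function() {
  deg <- rbind(lo = c(sc_fb = -30, sc_ud = -15, sh_x = -60, sh_y = -90,
                      sh_z = -90, elb_x = 0, wr_x = -70, wr_z = -20,
                      hand_x = -45),
               hi = c(sc_fb = 30, sc_ud = 60, sh_x = 180, sh_y = 90,
                      sh_z = 180, elb_x = 150, wr_x = 80, wr_z = 35,
                      hand_x = 45))
  deg * pi / 180
}

#' Construct an arm model
#'
#' @param lengths Named list/vector with `LSCAP` (girdle), `LUA` (upper arm),
#'   `LLA` (forearm), `LH` (wrist-to-palm), `LT` (palm-to-tip), meters.
#' @param limits Joint-limit matrix as [default_joint_limits()].
#' @return An `arm_model` object holding both arms' geometry.
#' @export
arm_model <- function(lengths = c(LSCAP = 0.18, LUA = 0.30, LLA = 0.25,
                                  LH = 0.08, LT = 0.10),
                      limits = default_joint_limits()) {
  lengths <- unlist(lengths)[c("LSCAP", "LUA", "LLA", "LH", "LT")]
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("arm_model: all segment lengths must be positive")
  structure(list(lengths = lengths, limits = limits), class = "arm_model")
}

#' @export
print.arm_model <- function(x, ...) {
  cat("<arm_model> segment lengths (m):\n")
  print(round(x$lengths, 4))
  invisible(x)
}

#' Zero joint-angle set
#'
#' @return Named list with `right`, `left` (9 named angles each, radians),
#'   `torso_rot` (3 angles) and `torso_t` (3-vector, m), all zero.
#' @export
zero_angles <- function() {
  a <- stats::setNames(numeric(9), arm_angle_names())
  list(right = a, left = a, torso_rot = c(0, 0, 0), torso_t = c(0, 0, 0))
}

# Chain of per-segment frames for one arm, in the torso frame.
# Returns list(points = 5x3 marker positions SHO,ELB,WRI,HAN,TIP)
.arm_chain <- function(a, lengths, side) {
  s <- if (side == "right") 1 else -1
  L <- lengths
  # girdle: the up/down angle acts on the factor that elevates the shoulder
  # (Rz for a shoulder offset along x), the forward/backward angle on Ry
  R_sc <- rot("z", s * a[["sc_ud"]]) %*% rot("y", s * a[["sc_fb"]])
  p_sho <- drop(R_sc %*% c(s * L[["LSCAP"]], 0, 0))
  R_sh <- R_sc %*% rot("x", -a[["sh_x"]]) %*% rot("y", s * a[["sh_y"]]) %*%
    rot("z", s * a[["sh_z"]])
  p_elb <- p_sho + drop(R_sh %*% c(0, -L[["LUA"]], 0))
  R_el <- R_sh %*% rot("x", -a[["elb_x"]])
  p_wri <- p_elb + drop(R_el %*% c(0, -L[["LLA"]], 0))
  R_wr <- R_el %*% rot("x", -a[["wr_x"]]) %*% rot("z", s * a[["wr_z"]])
  p_han <- p_wri + drop(R_wr %*% c(0, -L[["LH"]], 0))
  R_ha <- R_wr %*% rot("x", -a[["hand_x"]])
  p_tip <- p_han + drop(R_ha %*% c(0, -L[["LT"]], 0))
  rbind(SHO = p_sho, ELB = p_elb, WRI = p_wri, HAN = p_han, TIP = p_tip)
}

#' Forward kinematics: joint angles to the 11 model markers
#'
#' Chains the torso pose and both arm chains (sternoclavicular, shoulder,
#' elbow, wrist, hand) by successive rigid transforms and returns the marker
#' map: TOR plus shoulder/elbow/wrist/hand/tip of each arm.
#'
#' @param angles Angle set as returned by [zero_angles()].
#' @param model An [arm_model()].
#' @param check_limits If `TRUE`, error when any angle violates its limit.
#' @return 11 x 3 matrix of marker positions (m), rows named as
#'   [model_markers()].
#' @export
forward_kinematics <- function(angles, model, check_limits = FALSE) {
  if (check_limits) {
    lim <- model$limits
    for (side in c("right", "left")) {
      a <- angles[[side]]
      bad <- names(a)[a < lim["lo", names(a)] - 1e-12 |
                      a > lim["hi", names(a)] + 1e-12]
      if (length(bad))
        stop(sprintf("forward_kinematics: %s-arm angle(s) outside limits: %s",
                     side, paste(bad, collapse = ", ")))
    }
  }
  Rt <- rot("x", angles$torso_rot[1]) %*% rot("y", angles$torso_rot[2]) %*%
    rot("z", angles$torso_rot[3])
  tt <- angles$torso_t
  right <- .arm_chain(angles$right, model$lengths, "right")
  left <- .arm_chain(angles$left, model$lengths, "left")
  local <- rbind(TOR = c(0, 0, 0), right, left)
  world <- t(Rt %*% t(local)) + matrix(tt, 11, 3, byrow = TRUE)
  rownames(world) <- model_markers()
  colnames(world) <- c("x", "y", "z")
  world
}

#' Scapulohumeral rhythm of the shoulder girdle
#'
#' Piecewise-linear regression of the sternoclavicular forward/backward
#' extension angle and up/down angle against the arm lift angle, from
#' healthy-subject experiments on four lifting planes:
#' \deqn{\theta_{fb} = -0.35\beta \ (\beta<0);\quad 0 \ (0\le\beta\le70);
#'   \quad -0.22\beta + 15.4 \ (\beta>70)}
#' \deqn{\theta_{ud} = -0.3\beta \ (\beta<0);\quad 0 \ (0\le\beta\le30);
#'   \quad 0.36\beta - 10.8 \ (\beta>30)}
#'
#' @param beta Lift angle in degrees (vectorized).
#' @return List with numeric vectors `theta_fb` and `theta_ud` (degrees).
#' @export
scapulohumeral_rhythm <- function(beta) {
  stopifnot(all(is.finite(beta)))
  theta_fb <- ifelse(beta < 0, -0.35 * beta,
               ifelse(beta <= 70, 0, -0.22 * beta + 15.4))
  theta_ud <- ifelse(beta < 0, -0.3 * beta,
               ifelse(beta <= 30, 0, 0.36 * beta - 10.8))
  list(theta_fb = theta_fb, theta_ud = theta_ud)
}

#' Estimate segment lengths from observed model frames
#'
#' Per segment, takes the median inter-marker distance over frames in which
#' both endpoint markers are confident; left/right estimates of the same
#' segment are pooled.
#'
#' @param stream Model-marker `skeleton_stream`.
#' @param min_frames Minimum number of fully confident frames required.
#' @return Named vector of the five segment lengths (m).
#' @export
estimate_segment_lengths <- function(stream, min_frames = 10) {
  stopifnot(inherits(stream, "skeleton_stream"))
  ok <- rowSums(stream$conf > 0) == length(stream$joints)
  if (sum(ok) < min_frames)
    stop(sprintf("estimate_segment_lengths: only %d fully confident frames (need >= %d)",
                 sum(ok), min_frames))
  seg_dist <- function(a, b) {
    ia <- match(a, stream$joints); ib <- match(b, stream$joints)
    d <- stream$xyz[ok, ia, , drop = FALSE] - stream$xyz[ok, ib, , drop = FALSE]
    sqrt(rowSums(matrix(d, ncol = 3)^2))
  }
  pooled <- function(pairs)
    stats::median(unlist(lapply(pairs, function(p) seg_dist(p[1], p[2]))))
  c(LSCAP = pooled(list(c("TOR", "RSHO"), c("TOR", "LSHO"))),
    LUA = pooled(list(c("RSHO", "RELB"), c("LSHO", "LELB"))),
    LLA = pooled(list(c("RELB", "RWRI"), c("LELB", "LWRI"))),
    LH = pooled(list(c("RWRI", "RHAN"), c("LWRI", "LHAN"))),
    LT = pooled(list(c("RHAN", "RTIP"), c("LHAN", "LTIP"))))
}

# Flatten/unflatten one arm's angles for the optimizer.
.angles_to_vec <- function(angles, side) unname(angles[[side]])
.vec_to_angles <- function(x) stats::setNames(x, arm_angle_names())

#' Read or write an arm-model configuration file
#'
#' JSON or YAML (by extension) with `lengths` (five segment lengths, m) and
#' optional `limits_deg` (named `lo`/`hi` lists, degrees).
#'
#' @param path Config file path (`.json`, `.yaml` or `.yml`).
#' @return `read_model_config` returns an [arm_model()].
#' @export
read_model_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  limits <- default_joint_limits()
  if (!is.null(cfg$limits_deg)) {
    for (side in c("lo", "hi")) {
      v <- unlist(cfg$limits_deg[[side]])
      limits[side, names(v)] <- v * pi / 180
    }
  }
  arm_model(unlist(cfg$lengths), limits)
}

#' @rdname read_model_config
#' @param model An [arm_model()].
#' @export
write_model_config <- function(model, path) {
  cfg <- list(lengths = as.list(model$lengths),
              limits_deg = list(lo = as.list(model$limits["lo", ] * 180 / pi),
                                hi = as.list(model$limits["hi", ] * 180 / pi)))
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(cfg, path)
  else jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
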