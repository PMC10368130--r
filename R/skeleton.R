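# Canonical joint naming, the 11-marker upper-limb graph, and conversions
# between full-body device frames and the model marker set.

#' Model marker catalogue
#'
#' The 11 upper-limb markers used by the rigid-body model: the torso reference
#' (neck) plus shoulder, elbow, wrist, hand (palm) and hand tip of both arms.
#'
#' @return Character vector of length 11.
#' @export
model_markers <- function() {
  c("TOR",
    "RSHO", "RELB", "RWRI", "RHAN", "RTIP",
    "LSHO", "LELB", "LWRI", "LHAN", "LTIP")
}

#' Device joint catalogue
#'
#' The 32-joint full-body catalogue of an Azure-Kinect-style body tracker.
#'
#' @return Character vector of length 32.
#' @export
device_joints <- function() {
  c("PELVIS", "SPINE_NAVEL", "SPINE_CHEST", "NECK",
    "CLAVICLE_LEFT", "SHOULDER_LEFT", "ELBOW_LEFT", "WRIST_LEFT",
    "HAND_LEFT", "HANDTIP_LEFT", "THUMB_LEFT",
    "CLAVICLE_RIGHT", "SHOULDER_RIGHT", "ELBOW_RIGHT", "WRIST_RIGHT",
    "HAND_RIGHT", "HANDTIP_RIGHT", "THUMB_RIGHT",
    "HIP_LEFT", "KNEE_LEFT", "ANKLE_LEFT", "FOOT_LEFT",
    "HIP_RIGHT", "KNEE_RIGHT", "ANKLE_RIGHT", "FOOT_RIGHT",
    "HEAD", "NOSE", "EYE_LEFT", "EAR_LEFT", "EYE_RIGHT", "EAR_RIGHT")
}

#' Mapping from model markers to device joints
#'
#' Frozen lookup table.  TOR maps to the neck joint because the model's base
#' frame is fixed at the neck; the tip markers map to the hand-tip joints.
#'
#' @return Named character vector: names are model markers, values device
#'   joints.
#' @export
marker_device_map <- function() {
  c(TOR  = "NECK",
    RSHO = "SHOULDER_RIGHT", RELB = "ELBOW_RIGHT", RWRI = "WRIST_RIGHT",
    RHAN = "HAND_RIGHT",     RTIP = "HANDTIP_RIGHT",
    LSHO = "SHOULDER_LEFT",  LELB = "ELBOW_LEFT",  LWRI = "WRIST_LEFT",
    LHAN = "HAND_LEFT",      LTIP = "HANDTIP_LEFT")
}

#' Skeleton stream container
#'
#' A time-ordered sequence of skeleton frames.  Positions are meters in a
#' right-handed frame (x to the subject's right, y up, z from the subject
#' toward the camera).  Confidence 0 marks an occluded/untracked joint.
#'
#' @param timestamps Numeric vector of frame times (seconds), non-decreasing.
#' @param joints Character vector of joint names (one per column).
#' @param xyz Numeric array `T x J x 3` of positions (m).
#' @param conf Numeric matrix `T x J` of confidences in `[0, 1]`.  Defaults
#'   to all 1.
#' @return An object of class `skeleton_stream`.
#' @export
skeleton_stream <- function(timestamps, joints, xyz, conf = NULL) {
  nT <- length(timestamps)
  nJ <- length(joints)
  xyz <- array(as.numeric(xyz), dim = c(nT, nJ, 3))
  if (is.null(conf)) conf <- matrix(1, nT, nJ)
  conf <- matrix(as.numeric(conf), nT, nJ)
  stopifnot(all(is.finite(timestamps)), !is.unsorted(timestamps))
  if (any(!is.finite(xyz)))
    stop("skeleton_stream: positions must be finite")
  if (any(conf < 0 | conf > 1))
    stop("skeleton_stream: confidences must lie in [0, 1]")
  structure(list(timestamps = as.numeric(timestamps),
                 joints = as.character(joints),
                 xyz = xyz, conf = conf),
            class = "skeleton_stream")
}

#' @export
print.skeleton_stream <- function(x, ...) {
  cat(sprintf("<skeleton_stream: %d frames x %d joints, %.2f-%.2f s, %.1f%% tracked>\n",
              n_frames(x), length(x$joints),
              min(x$timestamps), max(x$timestamps),
              100 * mean(x$conf > 0)))
  invisible(x)
}

#' Number of frames in a stream
#' @param stream A `skeleton_stream`.
#' @return Integer frame count.
#' @export
n_frames <- function(stream) length(stream$timestamps)

#' Extract one frame from a stream
#'
#' @param stream A `skeleton_stream`.
#' @param i Frame index.
#' @return A `skeleton_frame`: list with `timestamp`, `joints` (named
#'   `J x 3` matrix) and `confidence` (named vector).
#' @export
get_frame <- function(stream, i) {
  pos <- matrix(stream$xyz[i, , ], ncol = 3,
                dimnames = list(stream$joints, c("x", "y", "z")))
  structure(list(timestamp = stream$timestamps[i],
                 joints = pos,
                 confidence = stats::setNames(stream$conf[i, ], stream$joints)),
            class = "skeleton_frame")
}

#' Assemble a stream from a list of frames
#' @param frames List of `skeleton_frame` objects sharing one joint set.
#' @return A `skeleton_stream`.
#' @export
frames_to_stream <- function(frames) {
  stopifnot(length(frames) >= 1)
  joints <- rownames(frames[[1]]$joints)
  nT <- length(frames); nJ <- length(joints)
  xyz <- array(0, c(nT, nJ, 3)); conf <- matrix(1, nT, nJ)
  ts <- numeric(nT)
  for (i in seq_len(nT)) {
    f <- frames[[i]]
    if (!identical(rownames(f$joints), joints))
      stop("frames_to_stream: inconsistent joint sets across frames")
    xyz[i, , ] <- f$joints
    conf[i, ] <- f$confidence
    ts[i] <- f$timestamp
  }
  skeleton_stream(ts, joints, xyz, conf)
}

#' Restrict a device stream to the 11 model markers
#'
#' Selects the model-marker subset of a full-body device stream (or single
#' frame) and renames joints to the model catalogue; positions and
#' confidences are carried over unchanged.
#'
#' @param x A `skeleton_stream` or `skeleton_frame` containing all 32 device
#'   joints.
#' @return Object of the same class with exactly the 11 model markers.
#' @export
to_model_frame <- function(x) {
  map <- marker_device_map()
  if (inherits(x, "skeleton_frame")) {
    missing <- setdiff(map, rownames(x$joints))
    if (length(missing))
      stop(sprintf("to_model_frame: missing device joint(s): %s",
                   paste(missing, collapse = ", ")))
    pos <- x$joints[map, , drop = FALSE]
    rownames(pos) <- names(map)
    return(structure(list(timestamp = x$timestamp, joints = pos,
                          confidence = stats::setNames(x$confidence[map], names(map))),
                     class = "skeleton_frame"))
  }
  stopifnot(inherits(x, "skeleton_stream"))
  idx <- match(map, x$joints)
  if (anyNA(idx))
    stop(sprintf("to_model_frame: missing device joint(s): %s",
                 paste(map[is.na(idx)], collapse = ", ")))
  skeleton_stream(x$timestamps, names(map),
                  x$xyz[, idx, , drop = FALSE],
                  x$conf[, idx, drop = FALSE])
}

#' Build the 11-marker upper-limb graph
#'
#' Ten segments connect the 11 model markers as a tree rooted at the torso
#' marker: TOR-RSHO-RELB-RWRI-RHAN-RTIP and the mirrored left chain.
#'
#' @return A `limb_graph`: list with `nodes` (11 markers), `edges`
#'   (10 x 2 character matrix) and `adjacency` (symmetric 11 x 11 0/1 matrix).
#' @export
build_limb_graph <- function() {
  nodes <- model_markers()
  chain <- function(side) {
    m <- paste0(side, c("SHO", "ELB", "WRI", "HAN", "TIP"))
    cbind(c("TOR", m[-5]), m)
  }
  edges <- rbind(chain("R"), chain("L"))
  A <- matrix(0L, 11, 11, dimnames = list(nodes, nodes))
  for (k in seq_len(nrow(edges))) {
    A[edges[k, 1], edges[k, 2]] <- 1L
    A[edges[k, 2], edges[k, 1]] <- 1L
  }
  structure(list(nodes = nodes, edges = edges, adjacency = A),
            class = "limb_graph")
}
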