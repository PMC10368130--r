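# Extrinsic calibration between two cameras (rigid registration of 3-D point
# correspondences) and per-joint fusion of the two synchronized streams.

#' Rigid transform constructor
#'
#' @param rotation 3x3 orthonormal matrix with det +1.
#' @param translation Length-3 vector (m).
#' @return A `rigid_transform` object.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6 || det(rotation) < 0)
    stop("rigid_transform: rotation must be orthonormal with det +1")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\nR =\n"); print(round(x$rotation, 6))
  cat("t =", round(x$translation, 6), "\n")
  invisible(x)
}

#' Apply a rigid transform to points
#' @param transform A `rigid_transform`.
#' @param points `n x 3` matrix (or length-3 vector).
#' @return Transformed points, same shape.
#' @export
apply_transform <- function(transform, points) {
  v <- is.null(dim(points))
  p <- matrix(points, ncol = 3)
  out <- p %*% t(transform$rotation) +
    matrix(transform$translation, nrow(p), 3, byrow = TRUE)
  if (v) drop(out) else out
}

#' Compose two rigid transforms
#' @param a,b `rigid_transform` objects; the result applies `b` first, then `a`.
#' @return A `rigid_transform`.
#' @export
compose_transform <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  drop(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param transform A `rigid_transform`.
#' @return The inverse `rigid_transform`.
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(Rt, drop(-Rt %*% transform$translation))
}

#' Least-squares rigid registration of point correspondences
#'
#' Kabsch/SVD solution of the orthogonal Procrustes problem: the rotation and
#' translation minimizing the sum of squared residuals between transformed
#' `points_a` and `points_b`.  Reflections are excluded.  Used to calibrate
#' the subordinate camera against the master from checkerboard-derived 3-D
#' correspondences.
#'
#' @param points_a,points_b `n x 3` matrices of corresponding points (n >= 3,
#'   non-collinear).
#' @return A `rigid_transform` `T` with `T(points_a) ~ points_b`.
#' @export
estimate_rigid_transform <- function(points_a, points_b) {
  A <- matrix(as.numeric(points_a), ncol = 3)
  B <- matrix(as.numeric(points_b), ncol = 3)
  if (nrow(A) != nrow(B))
    stop("estimate_rigid_transform: point lists differ in length")
  if (nrow(A) < 3)
    stop("estimate_rigid_transform: degenerate geometry (need >= 3 correspondences)")
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  # collinear sets have rank-deficient cross-covariance
  sv <- svd(crossprod(Ac, Bc))
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1e-300))
    stop("estimate_rigid_transform: degenerate geometry (collinear points)")
  S <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  R <- sv$v %*% S %*% t(sv$u)
  rigid_transform(R, cb - drop(R %*% ca))
}

#' Read/write an extrinsics JSON file
#'
#' JSON layout: 9 row-major rotation entries and 3 translation entries.
#' @param transform A `rigid_transform`.
#' @param path File path.
#' @return `read_extrinsics` returns a `rigid_transform`.
#' @export
write_extrinsics <- function(transform, path) {
  jsonlite::write_json(list(rotation = as.vector(t(transform$rotation)),
                            translation = transform$translation),
                       path, digits = NA)
  invisible(path)
}

#' @rdname write_extrinsics
#' @export
read_extrinsics <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(matrix(x$rotation, 3, 3, byrow = TRUE), x$translation)
}

#' Fuse one master and one subordinate skeleton frame
#'
#' The subordinate frame is brought into the master frame by the calibration
#' transform; each joint is then the confidence-weighted average of the two
#' observations.  If one camera reports confidence 0 the other is taken
#' verbatim; if both are 0 the joint stays at the master's sentinel position
#' with confidence 0.  Fused confidence is the maximum of the two.
#'
#' @param master,subordinate `skeleton_frame` objects with a shared joint set.
#' @param t_sub_to_master `rigid_transform` mapping subordinate coordinates
#'   into the master frame.
#' @param sync_tol Maximum allowed timestamp mismatch (s).
#' @return A fused `skeleton_frame` in the master frame.
#' @export
fuse_frames <- function(master, subordinate, t_sub_to_master,
                        sync_tol = 0.005) {
  if (abs(master$timestamp - subordinate$timestamp) > sync_tol)
    stop(sprintf("fuse_frames: timestamps %.4f s apart (tolerance %.4f s)",
                 abs(master$timestamp - subordinate$timestamp), sync_tol))
  stopifnot(identical(rownames(master$joints), rownames(subordinate$joints)))
  ps <- apply_transform(t_sub_to_master, subordinate$joints)
  wm <- master$confidence; ws <- subordinate$confidence
  tot <- wm + ws
  w <- ifelse(tot > 0, wm / pmax(tot, .Machine$double.eps), 1)
  pos <- master$joints * w + ps * (1 - w)
  pos[tot == 0, ] <- master$joints[tot == 0, ]
  structure(list(timestamp = master$timestamp, joints = pos,
                 confidence = pmax(wm, ws)),
            class = "skeleton_frame")
}

#' Fuse two synchronized skeleton streams
#'
#' Pairs each master frame with the nearest-timestamp subordinate frame and
#' applies [fuse_frames()]; master frames with no subordinate frame within
#' the tolerance are passed through unchanged.
#'
#' @param master,subordinate `skeleton_stream` objects.
#' @inheritParams fuse_frames
#' @return A fused `skeleton_stream`.
#' @export
fuse_streams <- function(master, subordinate, t_sub_to_master,
                         sync_tol = 0.005) {
  out <- vector("list", n_frames(master))
  for (i in seq_len(n_frames(master))) {
    fm <- get_frame(master, i)
    j <- which.min(abs(subordinate$timestamps - fm$timestamp))
    if (abs(subordinate$timestamps[j] - fm$timestamp) <= sync_tol)
      out[[i]] <- fuse_frames(fm, get_frame(subordinate, j), t_sub_to_master,
                              sync_tol)
    else out[[i]] <- fm
  }
  frames_to_stream(out)
}
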