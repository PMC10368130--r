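# Reachable-workspace quantification: shoulder-centered normalization,
# alpha-shape boundary extraction in an azimuth-elevation chart,
# Catmull-Rom smoothing, quadrant decomposition and relative surface areas.

# chart: azimuth = atan2(x, z) (0 = anterior, +90 = subject's right, seam
# behind the back), elevation = asin(y); both degrees.
.sphere_to_chart <- function(p) {
  p <- p / sqrt(rowSums(p^2))
  cbind(az = atan2(p[, 1], p[, 3]) * 180 / pi,
        el = asin(pmin(1, pmax(-1, p[, 2]))) * 180 / pi)
}

.chart_to_sphere <- function(ch) {
  az <- ch[, 1] * pi / 180; el <- ch[, 2] * pi / 180
  cbind(cos(el) * sin(az), sin(el), cos(el) * cos(az))
}

#' Project a hand trajectory onto the shoulder-centered unit sphere
#'
#' Per frame, `(hand - shoulder) / arm_length` is projected radially onto
#' the unit sphere; frames in which the hand is not extended (radius below
#' `min_extension` of arm length) are dropped.
#'
#' @param hand_traj,shoulder_traj `n x 3` position matrices (m).
#' @param arm_length Arm length (m).
#' @param min_extension Extension threshold as a fraction of arm length.
#' @return Matrix of unit-sphere points (possibly fewer rows than input).
#' @export
to_shoulder_sphere <- function(hand_traj, shoulder_traj, arm_length,
                               min_extension = 0.2) {
  hand_traj <- matrix(hand_traj, ncol = 3)
  shoulder_traj <- matrix(shoulder_traj, ncol = 3)
  stopifnot(nrow(hand_traj) == nrow(shoulder_traj), arm_length > 0)
  if (nrow(hand_traj) == 0) stop("to_shoulder_sphere: empty input")
  v <- (hand_traj - shoulder_traj) / arm_length
  r <- sqrt(rowSums(v^2))
  keep <- r >= min_extension
  if (!any(keep)) {
    warning("to_shoulder_sphere: no extended frames; returning empty set")
    return(matrix(numeric(0), 0, 3))
  }
  v[keep, , drop = FALSE] / r[keep]
}

#' Alpha-shape boundary of a spherical point set
#'
#' Classical empty-disk criterion in the azimuth-elevation chart: a pair of
#' points at most `2*alpha` apart is a boundary edge if one of the two disks
#' of radius `alpha` through both points contains no other point.  Candidate
#' endpoints are prefiltered to points that are not locally surrounded by
#' neighbors (interior points cannot carry boundary edges), which keeps the
#' quadratic pair scan tractable.  Edges are chained into a closed polyline
#' (falling back to an angular sort around the centroid when the chain does
#' not close).
#'
#' @param points `n x 3` unit-sphere points (n >= 3, non-degenerate).
#' @param alpha Disk radius in chart degrees; default
#'   `max(1.5 * median nearest-neighbor distance, 0.15 * chart diagonal)`,
#'   which adapts both to uniform covers and to sparse trajectory traces.
#' @param max_points Deterministic thinning bound applied before boundary
#'   extraction (every k-th point); the emptiness test still uses all points.
#' @return List: `vertices` (`m x 3` unit vectors, closed implicitly),
#'   `chart` (`m x 2` az/el), `alpha`.
#' @export
boundary_alpha_shape <- function(points, alpha = NULL, max_points = 1000) {
  points <- matrix(points, ncol = 3)
  if (nrow(points) < 3) stop("boundary_alpha_shape: need >= 3 points")
  ch0 <- .sphere_to_chart(points)
  dup <- duplicated(round(ch0, 9))
  ch <- ch0[!dup, , drop = FALSE]
  pts <- points[!dup, , drop = FALSE]
  n <- nrow(ch)
  if (n < 3) stop("boundary_alpha_shape: degenerate geometry (fewer than 3 distinct points)")
  if (n > max_points) {
    keep <- unique(round(seq(1, n, length.out = max_points)))
    ch <- ch[keep, , drop = FALSE]
    pts <- pts[keep, , drop = FALSE]
    n <- nrow(ch)
  }
  # collinearity check in the chart
  v1 <- ch[2, ] - ch[1, ]
  cr <- abs((ch[, 1] - ch[1, 1]) * v1[2] - (ch[, 2] - ch[1, 2]) * v1[1])
  if (max(cr) < 1e-9)
    stop("boundary_alpha_shape: degenerate geometry (collinear points)")
  nn <- vapply(seq_len(n), function(i) {
    d2 <- (ch[, 1] - ch[i, 1])^2 + (ch[, 2] - ch[i, 2])^2
    sqrt(min(d2[-i]))
  }, numeric(1))
  if (is.null(alpha)) {
    diag_ <- sqrt(diff(range(ch[, 1]))^2 + diff(range(ch[, 2]))^2)
    alpha <- max(1.5 * stats::median(nn), 0.15 * diag_)
  }
  if (n == 3) {
    ord <- order(atan2(ch[, 2] - mean(ch[, 2]), ch[, 1] - mean(ch[, 1])))
    return(list(vertices = pts[ord, , drop = FALSE],
                chart = ch[ord, , drop = FALSE], alpha = alpha))
  }
  r <- alpha
  # prefilter: a point surrounded by neighbors on all sides is interior
  rad_p <- 4 * stats::median(nn)
  open_dir <- vapply(seq_len(n), function(i) {
    d2 <- (ch[, 1] - ch[i, 1])^2 + (ch[, 2] - ch[i, 2])^2
    nb <- which(d2 > 0 & d2 <= rad_p^2)
    if (length(nb) < 3) return(TRUE)
    a <- sort(atan2(ch[nb, 2] - ch[i, 2], ch[nb, 1] - ch[i, 1]))
    gaps <- diff(c(a, a[1] + 2 * pi))
    max(gaps) > 110 * pi / 180
  }, logical(1))
  cand_idx <- which(open_dir)
  if (length(cand_idx) < 3) cand_idx <- seq_len(n)
  edges <- list(); ne <- 0L
  az <- ch[, 1]; el <- ch[, 2]
  for (ii in seq_along(cand_idx)) {
    i <- cand_idx[ii]
    rest <- cand_idx[-seq_len(ii)]
    if (!length(rest)) next
    d2 <- (az[rest] - az[i])^2 + (el[rest] - el[i])^2
    rest <- rest[d2 <= (2 * r)^2 & d2 > 0]
    for (j in rest) {
      mid <- c((az[i] + az[j]) / 2, (el[i] + el[j]) / 2)
      dv <- c(az[j] - az[i], el[j] - el[i])
      d <- sqrt(sum(dv^2))
      h <- sqrt(max(0, r^2 - (d / 2)^2))
      per <- c(-dv[2], dv[1]) / d
      for (sgn in c(1, -1)) {
        cen <- mid + sgn * h * per
        d2c <- (az - cen[1])^2 + (el - cen[2])^2
        inside <- which(d2c < r^2 * (1 - 1e-12))
        if (!length(setdiff(inside, c(i, j)))) {
          ne <- ne + 1L; edges[[ne]] <- c(i, j)
          break
        }
      }
    }
  }
  if (ne < 3) stop("boundary_alpha_shape: alpha too small to form a boundary")
  E <- do.call(rbind, edges)
  verts <- sort(unique(as.vector(E)))
  # chain edges into a closed walk
  adj <- lapply(verts, function(v) setdiff(unique(as.vector(E[E[, 1] == v | E[, 2] == v, ])), v))
  names(adj) <- as.character(verts)
  path <- verts[1]; prev <- NA_integer_
  repeat {
    cur <- path[length(path)]
    nxt <- setdiff(adj[[as.character(cur)]], prev)
    nxt <- nxt[!(nxt %in% path[-1])]
    if (!length(nxt)) break
    prev <- cur
    path <- c(path, nxt[1])
    if (nxt[1] == path[1]) break
    if (length(path) > length(verts) + 1) break
  }
  if (length(path) < max(4, 0.8 * length(verts))) {
    # fallback: angular order around the centroid
    cc <- colMeans(ch[verts, , drop = FALSE])
    path <- verts[order(atan2(ch[verts, 2] - cc[2], ch[verts, 1] - cc[1]))]
  }
  path <- path[path != path[c(length(path), seq_len(length(path) - 1))]]
  list(vertices = pts[path, , drop = FALSE],
       chart = ch[path, , drop = FALSE], alpha = alpha)
}

# Barry-Goldman centripetal Catmull-Rom between P1 and P2
.cr_segment <- function(P0, P1, P2, P3, n_samples) {
  tj <- function(ti, a, b) ti + sqrt(sqrt(sum((b - a)^2)))
  t0 <- 0; t1 <- tj(t0, P0, P1); t2 <- tj(t1, P1, P2); t3 <- tj(t2, P2, P3)
  if (t1 == t0 || t2 == t1 || t3 == t2) {
    return(matrix(P1, n_samples, length(P1), byrow = TRUE))
  }
  ts <- seq(t1, t2, length.out = n_samples + 1)[-(n_samples + 1)]
  t(vapply(ts, function(t) {
    A1 <- (t1 - t) / (t1 - t0) * P0 + (t - t0) / (t1 - t0) * P1
    A2 <- (t2 - t) / (t2 - t1) * P1 + (t - t1) / (t2 - t1) * P2
    A3 <- (t3 - t) / (t3 - t2) * P2 + (t - t2) / (t3 - t2) * P3
    B1 <- (t2 - t) / (t2 - t0) * A1 + (t - t0) / (t2 - t0) * A2
    B2 <- (t3 - t) / (t3 - t1) * A2 + (t - t1) / (t3 - t1) * A3
    (t2 - t) / (t2 - t1) * B1 + (t - t1) / (t2 - t1) * B2
  }, numeric(length(P1))))
}

#' Smooth a closed boundary with a centripetal Catmull-Rom spline
#'
#' Interpolates through every boundary vertex and re-projects the dense
#' curve onto the unit sphere.  With fewer than 4 vertices the polyline is
#' returned unchanged.
#'
#' @param boundary Output of [boundary_alpha_shape()], or an `m x 3` matrix
#'   of closed-boundary vertices.
#' @param samples_per_edge Interpolated samples per boundary edge.
#' @return `m * samples_per_edge x 3` matrix of unit-sphere points.
#' @export
smooth_boundary <- function(boundary, samples_per_edge = 8) {
  V <- if (is.list(boundary)) boundary$vertices else matrix(boundary, ncol = 3)
  m <- nrow(V)
  if (m < 4) {
    message("smooth_boundary: fewer than 4 vertices; returning polyline unchanged")
    return(V)
  }
  out <- vector("list", m)
  for (i in seq_len(m)) {
    idx <- ((i + c(-2, -1, 0, 1)) %% m) + 1
    out[[i]] <- .cr_segment(V[idx[1], ], V[idx[2], ], V[idx[3], ], V[idx[4], ],
                            samples_per_edge)
  }
  dense <- do.call(rbind, out)
  dense / sqrt(rowSums(dense^2))
}

# Sutherland-Hodgman clip of a closed chart polygon against a half plane
# keep_fn(p) >= 0
.clip_halfplane <- function(poly, value_fn) {
  n <- nrow(poly)
  if (n == 0) return(poly)
  vals <- value_fn(poly)
  out <- list(); k <- 0L
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ci <- vals[i] >= 0; cj <- vals[j] >= 0
    if (ci) { k <- k + 1L; out[[k]] <- poly[i, ] }
    if (xor(ci, cj)) {
      t <- vals[i] / (vals[i] - vals[j])
      k <- k + 1L; out[[k]] <- poly[i, ] + t * (poly[j, ] - poly[i, ])
    }
  }
  if (k == 0) return(poly[0, , drop = FALSE])
  do.call(rbind, out)
}

.spherical_polygon_area <- function(chart_poly) {
  if (nrow(chart_poly) < 3) return(0)
  abs(geosphere::areaPolygon(chart_poly[, c(1, 2)], a = 1, f = 0))
}

# naive self-intersection test for a moderately sized closed chart polygon
.self_intersects <- function(ch) {
  n <- nrow(ch)
  if (n > 1200 || n < 4) return(FALSE)
  seg <- cbind(ch, ch[c(2:n, 1), ])
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    js <- js[!(i == 1 & js == n)]
    if (!length(js)) next
    p <- seg[i, 1:2]; r <- seg[i, 3:4] - p
    q <- seg[js, 1:2, drop = FALSE]; s <- seg[js, 3:4, drop = FALSE] - q
    denom <- r[1] * s[, 2] - r[2] * s[, 1]
    qp <- sweep(q, 2, p)
    t <- (qp[, 1] * s[, 2] - qp[, 2] * s[, 1]) / denom
    u <- (qp[, 1] * r[2] - qp[, 2] * r[1]) / denom
    hit <- is.finite(t) & is.finite(u) & t > 1e-9 & t < 1 - 1e-9 &
      u > 1e-9 & u < 1 - 1e-9
    if (any(hit)) return(TRUE)
  }
  FALSE
}

#' Quadrant decomposition and relative surface areas
#'
#' Splits the spherical region enclosed by a closed boundary curve by the
#' horizontal plane through the shoulder and the sagittal (inner/outer)
#' plane, and reports each piece's spherical surface area normalized by the
#' full sphere (`4*pi`).  Quadrant order: Q1 inner-above, Q2 inner-below,
#' Q3 outer-above, Q4 outer-below; for a right arm "inner" is the side of
#' the body midline.
#'
#' @param curve Closed curve on the unit sphere (`n x 3` matrix, ordered).
#' @param side `"right"` or `"left"` (fixes which azimuth half-space is
#'   inner).
#' @param frontal_axis,vertical_axis Unit vectors defining the anterior
#'   direction and the up direction used for the quadrant planes (defaults:
#'   world +z and +y).
#' @return A `workspace_envelope`: list with `boundary`, `quadrant_rsa`
#'   (named length-4), `total_rsa`.
#' @export
quadrant_areas <- function(curve, side = "right",
                           frontal_axis = c(0, 0, 1),
                           vertical_axis = c(0, 1, 0)) {
  curve <- matrix(curve, ncol = 3)
  f <- frontal_axis / sqrt(sum(frontal_axis^2))
  v <- vertical_axis - sum(vertical_axis * f) * f
  v <- v / sqrt(sum(v^2))
  lat <- c(v[2] * f[3] - v[3] * f[2],
           v[3] * f[1] - v[1] * f[3],
           v[1] * f[2] - v[2] * f[1])   # cross(v, f): lateral (+x-like)
  curve <- curve %*% cbind(lat, v, f)   # express in the analysis frame
  if (nrow(curve) == 0) {
    return(structure(list(boundary = curve,
                          quadrant_rsa = stats::setNames(numeric(4),
                            c("Q1_inner_above", "Q2_inner_below",
                              "Q3_outer_above", "Q4_outer_below")),
                          total_rsa = 0), class = "workspace_envelope"))
  }
  ch <- .sphere_to_chart(curve)
  if (.self_intersects(ch))
    stop("quadrant_areas: self-intersecting boundary curve")
  inner_sign <- if (side == "right") -1 else 1   # inner: az < 0 for right arm
  quads <- list(
    Q1_inner_above = list(az = inner_sign, el = 1),
    Q2_inner_below = list(az = inner_sign, el = -1),
    Q3_outer_above = list(az = -inner_sign, el = 1),
    Q4_outer_below = list(az = -inner_sign, el = -1))
  rsa <- vapply(quads, function(q) {
    p <- .clip_halfplane(ch, function(m) q$az * m[, 1, drop = TRUE])
    p <- .clip_halfplane(p, function(m) q$el * m[, 2, drop = TRUE])
    .spherical_polygon_area(p) / (4 * pi)
  }, numeric(1))
  structure(list(boundary = curve, quadrant_rsa = rsa,
                 total_rsa = sum(rsa)),
            class = "workspace_envelope")
}

#' @export
print.workspace_envelope <- function(x, ...) {
  cat("<workspace_envelope> relative surface areas (fraction of full sphere):\n")
  print(round(c(x$quadrant_rsa, total = x$total_rsa), 4))
  invisible(x)
}

#' Full reachable-workspace analysis of a model stream
#'
#' Chains [to_shoulder_sphere()], [boundary_alpha_shape()],
#' [smooth_boundary()] and [quadrant_areas()] for one arm of a model-marker
#' stream, using the hand-tip marker as end effector.
#'
#' @param stream Model-marker `skeleton_stream`.
#' @param side `"right"` or `"left"`.
#' @param arm_length Arm length (m); `NULL` to estimate as the 95th
#'   percentile of observed shoulder-tip distance.
#' @param alpha Alpha-shape radius (chart degrees); `NULL` for the default.
#' @param samples_per_edge Catmull-Rom density.
#' @return A `workspace_envelope`.
#' @export
reachable_workspace <- function(stream, side = "right", arm_length = NULL,
                                alpha = NULL, samples_per_edge = 8) {
  pre <- toupper(substr(side, 1, 1))
  hand <- matrix(stream$xyz[, match(paste0(pre, "TIP"), stream$joints), ],
                 ncol = 3)
  sho <- matrix(stream$xyz[, match(paste0(pre, "SHO"), stream$joints), ],
                ncol = 3)
  if (is.null(arm_length)) {
    d <- sqrt(rowSums((hand - sho)^2))
    arm_length <- stats::quantile(d, 0.95, names = FALSE)
  }
  pts <- to_shoulder_sphere(hand, sho, arm_length)
  bnd <- boundary_alpha_shape(pts, alpha)
  dense <- smooth_boundary(bnd, samples_per_edge)
  # spline overshoot on very thin envelopes can self-intersect; fall back
  # to the raw boundary polyline in that case
  tryCatch(quadrant_areas(dense, side), error = function(e) {
    message("reachable_workspace: smoothed boundary rejected (",
            conditionMessage(e), "); using the polyline boundary")
    quadrant_areas(bnd$vertices, side)
  })
}
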