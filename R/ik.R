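# Inverse kinematics as optimization: classical particle swarm updates
# extended with the crossbreed (hybridization) operator, minimizing a
# confidence-weighted marker-distance fitness per frame, with warm starts
# along the sequence.

#' Swarm configuration for the crossbreed PSO solver
#'
#' @param n_particles Swarm size N.
#' @param omega Inertia weight.
#' @param c1,c2 Cognitive and social learning factors.
#' @param pc Crossbreed blend weight in `[0, 1]` (child position is the
#'   `pc`-blend of its two parents).
#' @param pool_frac Fraction of the swarm entering the hybridization pool
#'   each time the crossbreed operator fires.
#' @param hybrid_prob Per-iteration probability that the crossbreed operator
#'   fires.
#' @param max_iter Iteration budget per frame.
#' @param tol Stop when the global-best fitness (m^2) falls below this.
#' @param rhythm_weight Weight of the soft scapulohumeral-rhythm prior.
#' @param warm_weight Weight of the temporal-continuity prior pulling the
#'   solution toward the warm start; it resolves degrees of freedom that the
#'   currently visible markers leave unconstrained (e.g. wrist angles while
#'   the hand is occluded) without noticeably biasing observed markers.
#' @param seed Integer seed used by [solve_sequence()].
#' @return A `swarm_config` object.
#' @export
swarm_config <- function(n_particles = 60, omega = 0.72, c1 = 1.49,
                         c2 = 1.49, pc = 0.6, pool_frac = 0.2,
                         hybrid_prob = 1, max_iter = 300, tol = 1e-8,
                         rhythm_weight = 1e-4, warm_weight = 1e-6, seed = 1) {
  stopifnot(n_particles >= 2, pc >= 0, pc <= 1, c1 >= 0, c2 >= 0,
            max_iter >= 1)
  structure(list(n_particles = n_particles, omega = omega, c1 = c1, c2 = c2,
                 pc = pc, pool_frac = pool_frac, hybrid_prob = hybrid_prob,
                 max_iter = max_iter, tol = tol,
                 rhythm_weight = rhythm_weight, warm_weight = warm_weight,
                 seed = seed),
            class = "swarm_config")
}

#' Build a fitness target from one observed model frame
#'
#' Extracts one arm's five markers (shoulder, elbow, wrist, hand, tip) from a
#' model `skeleton_frame`, expresses them in the torso frame and records the
#' per-marker confidence weights.  Markers with confidence 0 are excluded
#' from the fitness sum.
#'
#' @param frame Model-marker `skeleton_frame` (world coordinates).
#' @param side `"right"` or `"left"`.
#' @param torso List with `rotation` (3x3) and `translation` (torso pose in
#'   the world); see [estimate_torso_pose()].
#' @return A `fitness_target` with `y` (5x3 matrix), `weights` (length 5)
#'   and `side`.
#' @export
fitness_target <- function(frame, side = c("right", "left"),
                           torso = list(rotation = diag(3),
                                        translation = c(0, 0, 0))) {
  side <- match.arg(side)
  mk <- paste0(toupper(substr(side, 1, 1)), c("SHO", "ELB", "WRI", "HAN", "TIP"))
  w <- unname(frame$confidence[mk])
  if (sum(w > 0) < 3)
    stop(sprintf("fitness_target: underdetermined %s arm (%d confident markers, need >= 3)",
                 side, sum(w > 0)))
  y_world <- frame$joints[mk, , drop = FALSE]
  y <- sweep(y_world, 2, torso$translation) %*% torso$rotation
  structure(list(y = unname(y), weights = w, side = side), class = "fitness_target")
}

#' Marker-distance fitness of a candidate angle vector
#'
#' Confidence-weighted sum of squared distances between observed markers and
#' the forward-kinematics prediction, plus a soft prior pulling the
#' sternoclavicular angles toward the scapulohumeral-rhythm regression of
#' the candidate lift angle.
#'
#' @param x Angle vector (9, radians) or `N x 9` matrix of candidates.
#' @param target A [fitness_target()].
#' @param model An [arm_model()].
#' @param rhythm_weight Prior weight (`0` disables the prior).
#' @return Numeric fitness value(s), `>= 0`.
#' @export
ik_fitness <- function(x, target, model, rhythm_weight = 1e-4) {
  X <- if (is.null(dim(x))) matrix(x, 1) else x
  f <- .fitness_batch_cpp(X, target$y, target$weights, unname(model$lengths),
                          target$side == "right", rhythm_weight)
  if (is.null(dim(x))) f[1] else f
}

#' Estimate the torso pose of a frame
#'
#' Translation is the neck (TOR) position.  For full-body device frames the
#' rotation is estimated from the pelvis line (left to right hip) and the
#' spine axis; for 11-marker model frames the rotation is taken as
#' world-aligned, matching the capture protocol in which the subject faces
#' the camera rig and does not rotate the trunk.
#'
#' @param frame A `skeleton_frame` (device or model joint set).
#' @return List with `rotation` (3x3, torso axes as columns) and
#'   `translation` (3-vector).
#' @export
estimate_torso_pose <- function(frame) {
  jn <- rownames(frame$joints)
  tor_name <- if ("TOR" %in% jn) "TOR" else "NECK"
  tt <- if (frame$confidence[tor_name] > 0) unname(frame$joints[tor_name, ])
        else c(0, 0, 0)
  R <- diag(3)
  if (all(c("HIP_LEFT", "HIP_RIGHT", "SPINE_CHEST", "NECK") %in% jn) &&
      all(frame$confidence[c("HIP_LEFT", "HIP_RIGHT", "SPINE_CHEST", "NECK")] > 0)) {
    xh <- frame$joints["HIP_RIGHT", ] - frame$joints["HIP_LEFT", ]
    yh <- frame$joints["NECK", ] - frame$joints["SPINE_CHEST", ]
    xh <- xh / sqrt(sum(xh^2))
    zh <- c(xh[2] * yh[3] - xh[3] * yh[2],
            xh[3] * yh[1] - xh[1] * yh[3],
            xh[1] * yh[2] - xh[2] * yh[1])
    zh <- zh / sqrt(sum(zh^2))
    yh <- c(zh[2] * xh[3] - zh[3] * xh[2],
            zh[3] * xh[1] - zh[1] * xh[3],
            zh[1] * xh[2] - zh[2] * xh[1])
    R <- cbind(xh, yh, zh, deparse.level = 0)
  }
  list(rotation = R, translation = tt)
}

# geometric angle estimates from the observed markers: a small bank of
# deterministic seeds that put swarm particles into the right basins of
# attraction.  Two shoulder parametrization families (twist+elevation and
# flexion+elevation) are derived from the shoulder->elbow direction after
# compensating the rhythm-predicted girdle rotation; elbow and wrist
# flexion come from marker angles.
.analytic_seed <- function(target) {
  y <- target$y; w <- target$weights
  base <- numeric(9)
  s <- if (target$side == "right") 1 else -1
  elb <- wri <- 0
  if (all(w[2:3] > 0)) {
    v1 <- y[1, ] - y[2, ]; v2 <- y[3, ] - y[2, ]
    cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
    elb <- pi - acos(min(1, max(-1, cosang)))
  }
  if (all(w[3:4] > 0)) {
    v1 <- y[2, ] - y[3, ]; v2 <- y[4, ] - y[3, ]
    cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
    wri <- pi - acos(min(1, max(-1, cosang)))
  }
  seeds <- list()
  if (all(w[1:2] > 0)) {
    u0 <- y[2, ] - y[1, ]
    u0 <- u0 / sqrt(sum(u0^2))
    u0[1] <- s * u0[1]                   # mirror the left arm
    # iterate once so the girdle's rhythm rotation is compensated
    elev <- acos(min(1, max(-1, -u0[2])))
    for (it in 1:2) {
      rh <- scapulohumeral_rhythm(elev * 180 / pi)
      R_sc <- rot("z", rh$theta_ud * pi / 180) %*%
        rot("y", rh$theta_fb * pi / 180)
      u <- drop(t(R_sc) %*% u0)
      elev <- acos(min(1, max(-1, -u[2])))
    }
    fb <- rh$theta_fb * pi / 180; ud <- rh$theta_ud * pi / 180
    # family 1: twist + elevation (sh_y, sh_z), sh_x = 0
    b <- if (abs(u[2]) > 1 - 1e-9) 0 else atan2(-u[3], u[1])
    s1 <- base; s1[1] <- fb; s1[2] <- ud
    s1[4] <- b; s1[5] <- elev; s1[6] <- elb
    # family 2: flexion + abduction (sh_x, sh_z), sh_y = 0
    cc <- asin(min(1, max(-1, u[1])))
    aa <- atan2(u[3], -u[2])
    s2 <- base; s2[1] <- fb; s2[2] <- ud
    s2[3] <- aa; s2[5] <- cc; s2[6] <- elb
    s1w <- s1; s1w[7] <- wri
    s2w <- s2; s2w[7] <- wri
    s1q <- s1; s1q[4] <- b + pi / 2
    s1m <- s1; s1m[4] <- b - pi / 2
    seeds <- list(s1, s2, s1w, s2w, s1q, s1m)
  }
  if (!length(seeds)) return(matrix(base, 1))
  do.call(rbind, seeds)
}

# uniform swarm initialization within bounds; `seeds` rows are deterministic
# starting positions (warm start, analytic estimate) placed with velocity 0
.init_swarm <- function(config, lo, hi, warm_start = NULL, seeds = NULL) {
  N <- config$n_particles; D <- length(lo)
  X <- matrix(stats::runif(N * D), N, D)
  X <- sweep(sweep(X, 2, hi - lo, "*"), 2, lo, "+")
  V <- matrix(stats::runif(N * D, -0.5, 0.5), N, D) *
    matrix(hi - lo, N, D, byrow = TRUE) * 0.2
  if (!is.null(warm_start)) seeds <- rbind(warm_start, seeds)
  if (!is.null(seeds)) {
    k <- min(nrow(seeds), N - 1)
    for (i in seq_len(k)) {
      X[i, ] <- pmin(pmax(seeds[i, ], lo), hi)
      V[i, ] <- 0
    }
  }
  list(X = X, V = V, pbest_x = X, pbest_f = rep(Inf, N),
       gbest_x = X[1, ], gbest_f = Inf, lo = lo, hi = hi, evaluated = FALSE)
}

.eval_swarm <- function(swarm, fitness_fn) {
  f <- fitness_fn(swarm$X)
  improved <- f < swarm$pbest_f
  swarm$pbest_f[improved] <- f[improved]
  swarm$pbest_x[improved, ] <- swarm$X[improved, , drop = FALSE]
  b <- which.min(swarm$pbest_f)
  if (swarm$pbest_f[b] < swarm$gbest_f) {
    swarm$gbest_f <- swarm$pbest_f[b]
    swarm$gbest_x <- swarm$pbest_x[b, ]
  }
  swarm$evaluated <- TRUE
  swarm
}

#' One particle-swarm iteration
#'
#' Velocity and position updates of classical PSO with fresh uniform random
#' factors per particle and per dimension; positions are clamped to the
#' bounds with the velocity zeroed on clamped dimensions; personal and
#' global bests are refreshed (the global-best fitness is non-increasing).
#'
#' @param swarm Swarm state (see [solve_frame()]).
#' @param config A [swarm_config()].
#' @param fitness_fn Function mapping an `N x D` matrix to `N` fitness values.
#' @return Updated swarm state.
#' @export
pso_step <- function(swarm, config, fitness_fn) {
  if (!swarm$evaluated) swarm <- .eval_swarm(swarm, fitness_fn)
  N <- nrow(swarm$X); D <- ncol(swarm$X)
  r1 <- matrix(stats::runif(N * D), N, D)
  r2 <- matrix(stats::runif(N * D), N, D)
  G <- matrix(swarm$gbest_x, N, D, byrow = TRUE)
  V <- config$omega * swarm$V +
    config$c1 * r1 * (swarm$pbest_x - swarm$X) +
    config$c2 * r2 * (G - swarm$X)
  X <- swarm$X + V
  LO <- matrix(swarm$lo, N, D, byrow = TRUE)
  HI <- matrix(swarm$hi, N, D, byrow = TRUE)
  clamped <- X < LO | X > HI
  X <- pmin(pmax(X, LO), HI)
  V[clamped] <- 0
  swarm$X <- X; swarm$V <- V
  .eval_swarm(swarm, fitness_fn)
}

#' Crossbreed (hybridization) operator
#'
#' A random pool of particles is paired; each pair is replaced by two
#' children whose positions are the `pc`-blend of the parents and whose
#' velocity is the parents' velocity sum rescaled to the first parent's
#' speed (falling back to the first parent's velocity when the sum
#' vanishes).  Children inherit the personal-best memory of the parent they
#' replace; the global best is untouched.
#'
#' @inheritParams pso_step
#' @return Updated swarm state (fitness of children not yet evaluated).
#' @export
crossbreed <- function(swarm, config) {
  N <- nrow(swarm$X)
  n_pool <- floor(config$pool_frac * N / 2) * 2
  if (n_pool < 2) return(swarm)
  pool <- sample.int(N, n_pool)
  p1 <- pool[seq(1, n_pool, by = 2)]
  p2 <- pool[seq(2, n_pool, by = 2)]
  x1 <- swarm$X[p1, , drop = FALSE]; x2 <- swarm$X[p2, , drop = FALSE]
  v1 <- swarm$V[p1, , drop = FALSE]; v2 <- swarm$V[p2, , drop = FALSE]
  child_v <- function(va, vb) {
    vs <- va + vb
    ns <- sqrt(rowSums(vs^2))
    na <- sqrt(rowSums(va^2))
    out <- vs * ifelse(ns > 0, na / pmax(ns, .Machine$double.eps), 0)
    out[ns == 0, ] <- va[ns == 0, , drop = FALSE]
    out
  }
  swarm$X[p1, ] <- config$pc * x1 + (1 - config$pc) * x2
  swarm$X[p2, ] <- config$pc * x2 + (1 - config$pc) * x1
  swarm$V[p1, ] <- child_v(v1, v2)
  swarm$V[p2, ] <- child_v(v2, v1)
  swarm$evaluated <- FALSE
  swarm
}

#' Solve one frame's inverse kinematics for one arm
#'
#' Initializes a swarm within the joint limits (one particle at the warm
#' start when provided), then iterates [pso_step()], firing [crossbreed()]
#' with the configured per-iteration probability, until the fitness
#' tolerance or the iteration budget is reached.
#'
#' @param target A [fitness_target()].
#' @param config A [swarm_config()].
#' @param model An [arm_model()].
#' @param warm_start Optional angle vector (9, radians) to seed the swarm.
#' @return List: `angles` (named 9-vector, radians), `fitness`,
#'   `iterations`.
#' @export
solve_frame <- function(target, config = swarm_config(), model = arm_model(),
                        warm_start = NULL) {
  lim <- model$limits
  lo <- unname(lim["lo", ]); hi <- unname(lim["hi", ])
  fitness_fn <- function(X) {
    f <- ik_fitness(X, target, model, config$rhythm_weight)
    if (!is.null(warm_start) && config$warm_weight > 0)
      f <- f + config$warm_weight *
        rowSums(sweep(X, 2, warm_start)^2)
    f
  }
  swarm <- .init_swarm(config, lo, hi, warm_start,
                       seeds = .analytic_seed(target))
  swarm <- .eval_swarm(swarm, fitness_fn)
  iter <- 0L
  while (iter < config$max_iter && swarm$gbest_f > config$tol) {
    swarm <- pso_step(swarm, config, fitness_fn)
    if (config$hybrid_prob > 0 && stats::runif(1) < config$hybrid_prob) {
      swarm <- crossbreed(swarm, config)
      swarm <- .eval_swarm(swarm, fitness_fn)
    }
    iter <- iter + 1L
  }
  list(angles = .vec_to_angles(swarm$gbest_x), fitness = swarm$gbest_f,
       iterations = iter)
}

#' Solve a whole sequence and reconstruct biologically feasible markers
#'
#' Per frame: the torso pose is estimated, each requested arm is solved by
#' [solve_frame()] warm-started from the previous frame's solution, and the
#' reconstructed marker set is the forward-kinematics image of the solved
#' angles (bone lengths therefore hold exactly).  Frames whose arm target is
#' underdetermined (fewer than 3 confident markers) carry the previous
#' solution forward.
#'
#' @param stream Model-marker `skeleton_stream` (world frame); a 32-joint
#'   device stream is reduced with [to_model_frame()] after its torso pose
#'   information is used.
#' @param config A [swarm_config()].
#' @param model An [arm_model()].
#' @param sides Arms to solve.
#' @return List: `angles` (list with per-side `T x 9` matrices), `fitness`
#'   (`T x sides`), `reconstructed` (model `skeleton_stream`), `failed`
#'   (logical `T x sides`).
#' @export
solve_sequence <- function(stream, config = swarm_config(),
                           model = arm_model(),
                           sides = c("right", "left")) {
  if (n_frames(stream) < 1) stop("solve_sequence: empty sequence")
  set.seed(config$seed)
  nT <- n_frames(stream)
  device <- !("TOR" %in% stream$joints)
  model_stream <- if (device) to_model_frame(stream) else stream
  ang <- lapply(sides, function(s)
    matrix(NA_real_, nT, 9, dimnames = list(NULL, arm_angle_names())))
  names(ang) <- sides
  fit <- matrix(NA_real_, nT, length(sides), dimnames = list(NULL, sides))
  failed <- matrix(FALSE, nT, length(sides), dimnames = list(NULL, sides))
  xyz <- array(0, c(nT, 11, 3))
  warm <- stats::setNames(vector("list", length(sides)), sides)
  full <- zero_angles()
  for (i in seq_len(nT)) {
    torso <- estimate_torso_pose(
      if (device) get_frame(stream, i) else get_frame(model_stream, i))
    fr <- get_frame(model_stream, i)
    for (s in sides) {
      res <- tryCatch({
        tg <- fitness_target(fr, s, torso)
        solve_frame(tg, config, model, warm[[s]])
      }, error = function(e) NULL)
      if (is.null(res)) {
        failed[i, s] <- TRUE
        prev <- if (!is.null(warm[[s]])) warm[[s]] else numeric(9)
        ang[[s]][i, ] <- prev
      } else {
        ang[[s]][i, ] <- res$angles
        fit[i, s] <- res$fitness
      }
      warm[[s]] <- ang[[s]][i, ]
    }
    full$torso_rot <- .rotmat_to_xyz(torso$rotation)
    full$torso_t <- torso$translation
    for (s in sides) full[[s]] <- stats::setNames(ang[[s]][i, ], arm_angle_names())
    xyz[i, , ] <- forward_kinematics(full, model)
  }
  list(angles = ang, fitness = fit,
       reconstructed = skeleton_stream(model_stream$timestamps,
                                       model_markers(), xyz),
       failed = failed)
}

# Euler angles (x, y, z, intrinsic, matching rot("x")%*%rot("y")%*%rot("z"))
# of a rotation matrix.
.rotmat_to_xyz <- function(R) {
  sy <- min(1, max(-1, R[1, 3]))
  y <- asin(sy)
  if (abs(sy) < 1 - 1e-9) {
    x <- atan2(-R[2, 3], R[3, 3])
    z <- atan2(-R[1, 2], R[1, 1])
  } else {
    x <- atan2(R[3, 2], R[2, 2])
    z <- 0
  }
  c(x, y, z)
}
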