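test_that("elementary rotations and homogeneous transforms behave canonically", {
  expect_equal(rot("z", 0), diag(3))
  expect_equal(drop(rot("z", pi / 2) %*% c(1, 0, 0)), c(0, 1, 0),
               tolerance = 1e-12)
  h1 <- hom(diag(3), c(1, 2, 3)); h2 <- hom(diag(3), c(-1, 0, 5))
  expect_equal(h1 %*% h2, hom(diag(3), c(0, 2, 8)))
  R <- rot("x", 0.3) %*% rot("y", -1.1)
  expect_equal(crossprod(R), diag(3), tolerance = 1e-12)
  expect_equal(det(R), 1, tolerance = 1e-12)
  expect_equal(hom(R)[4, ], c(0, 0, 0, 1))
})

test_that("rest pose lays the chain along -y with segment-length gaps", {
  m <- arm_model(c(LSCAP = 0.18, LUA = 0.30, LLA = 0.25, LH = 0.08, LT = 0.10))
  p <- forward_kinematics(zero_angles(), m)
  expect_equal(nrow(p), 11)
  # right chain collinear below the shoulder
  expect_equal(unname(p["RSHO", ]), c(0.18, 0, 0))
  expect_equal(unname(p["RELB", ]), c(0.18, -0.30, 0))
  expect_equal(unname(p["RTIP", ]), c(0.18, -0.73, 0))
  expect_equal(unname(p["LSHO", ]), c(-0.18, 0, 0))
})

test_that("elbow flexion by pi/2 gives the right-triangle wrist distance", {
  m <- arm_model(c(LSCAP = 0.18, LUA = 0.30, LLA = 0.25, LH = 0.08, LT = 0.10))
  a <- zero_angles()
  a$right["elb_x"] <- pi / 2
  p <- forward_kinematics(a, m)
  expect_equal(sqrt(sum((p["RWRI", ] - p["RSHO", ])^2)),
               sqrt(0.30^2 + 0.25^2), tolerance = 1e-12)
})

test_that("bone lengths are conserved for arbitrary poses (both chains)", {
  m <- arm_model()
  segs <- list(c("TOR", "RSHO"), c("RSHO", "RELB"), c("RELB", "RWRI"),
               c("RWRI", "RHAN"), c("RHAN", "RTIP"),
               c("TOR", "LSHO"), c("LSHO", "LELB"), c("LELB", "LWRI"),
               c("LWRI", "LHAN"), c("LHAN", "LTIP"))
  want <- rep(unname(m$lengths), 2)
  set.seed(42)
  for (rep_i in 1:25) {
    p <- forward_kinematics(random_angles(m), m)
    got <- vapply(segs, function(s) sqrt(sum((p[s[1], ] - p[s[2], ])^2)),
                  numeric(1))
    expect_lt(max(abs(got - want) / want), 1e-9)
  }
})

test_that("the per-arm optimization vector has exactly 9 named angles", {
  expect_length(arm_angle_names(), 9)
  expect_equal(ncol(default_joint_limits()), 9)
})

test_that("C++ and R forward kinematics agree", {
  m <- arm_model()
  set.seed(7)
  for (i in 1:20) {
    a <- random_angles(m)
    for (side in c("right", "left")) {
      rr <- armassess:::.arm_chain(a[[side]], m$lengths, side)
      cc <- armassess:::.fk_arm_cpp(unname(a[[side]]), unname(m$lengths),
                                    side == "right")
      expect_lt(max(abs(rr - cc)), 1e-12)
    }
  }
})

test_that("mirroring right-arm angles through the sagittal plane gives the left arm", {
  m <- arm_model()
  set.seed(8)
  lim <- m$limits
  a <- zero_angles()
  ang <- stats::setNames(runif(9, lim["lo", ], lim["hi", ]), arm_angle_names())
  a$right <- ang; a$left <- ang
  p <- forward_kinematics(a, m)
  right <- p[c("RSHO", "RELB", "RWRI", "RHAN", "RTIP"), ]
  left <- p[c("LSHO", "LELB", "LWRI", "LHAN", "LTIP"), ]
  mirrored <- right %*% diag(c(-1, 1, 1))
  expect_lt(max(abs(mirrored - left)), 1e-12)
})

test_that("limit checking names the offending angles", {
  m <- arm_model()
  a <- zero_angles()
  a$right["elb_x"] <- -0.5                 # below the 0 lower bound
  expect_error(forward_kinematics(a, m, check_limits = TRUE), "elb_x")
  expect_silent(forward_kinematics(a, m))  # limits disabled by default
})

test_that("the scapulohumeral rhythm matches its printed piecewise form", {
  r <- scapulohumeral_rhythm(70)
  expect_equal(r$theta_fb, 0)              # middle and upper branches agree
  expect_equal(-0.22 * 70 + 15.4, 0)
  r90 <- scapulohumeral_rhythm(90)
  expect_equal(r90$theta_fb, -4.4)
  expect_equal(r90$theta_ud, 21.6)
  rneg <- scapulohumeral_rhythm(-10)
  expect_equal(rneg$theta_fb, 3.5)
  expect_equal(rneg$theta_ud, 3.0)
})

test_that("the rhythm is continuous at its breakpoints", {
  for (b in c(0, 70)) {
    eps <- 10^-(3:7)
    lo <- scapulohumeral_rhythm(b - eps)$theta_fb
    hi <- scapulohumeral_rhythm(b + eps)$theta_fb
    mid <- scapulohumeral_rhythm(b)$theta_fb
    expect_lt(max(abs(c(lo, hi) - mid)), 1e-2)
  }
  for (b in c(0, 30)) {
    eps <- 10^-(3:7)
    lo <- scapulohumeral_rhythm(b - eps)$theta_ud
    hi <- scapulohumeral_rhythm(b + eps)$theta_ud
    mid <- scapulohumeral_rhythm(b)$theta_ud
    expect_lt(max(abs(c(lo, hi) - mid)), 1e-2)
  }
})

test_that("segment lengths are recovered from observed frames", {
  m <- arm_model()
  tj <- sim_stream("RW-V45", fps = 25, seed = 11)
  est <- estimate_segment_lengths(tj$stream)
  expect_equal(unname(est), unname(m$lengths), tolerance = 1e-9)

  # 5 mm noise, 300 frames: medians concentrate within 2 mm
  set.seed(12)
  s <- tj$stream
  reps <- ceiling(300 / n_frames(s))
  xyz <- array(0, c(n_frames(s) * reps, 11, 3))
  for (r in seq_len(reps))
    xyz[((r - 1) * n_frames(s) + 1):(r * n_frames(s)), , ] <-
      s$xyz + array(rnorm(length(s$xyz), sd = 0.005), dim(s$xyz))
  noisy <- skeleton_stream(seq_len(dim(xyz)[1]) / 25, s$joints, xyz)
  est2 <- estimate_segment_lengths(noisy)
  expect_lt(max(abs(est2 - m$lengths)), 0.002)

  short <- skeleton_stream(s$timestamps[1:5], s$joints,
                           s$xyz[1:5, , , drop = FALSE], s$conf[1:5, ])
  expect_error(estimate_segment_lengths(short), "confident frames")
})

test_that("model configuration files round-trip through JSON and YAML", {
  m <- arm_model(c(LSCAP = 0.2, LUA = 0.31, LLA = 0.24, LH = 0.07, LT = 0.09))
  for (ext in c(".json", ".yaml")) {
    path <- withr::local_tempfile(fileext = ext)
    write_model_config(m, path)
    back <- read_model_config(path)
    expect_equal(back$lengths, m$lengths, tolerance = 1e-9)
    expect_equal(back$limits, m$limits, tolerance = 1e-9)
  }
})
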