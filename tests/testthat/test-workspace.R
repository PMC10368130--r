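# deterministic quasi-uniform cover of the spherical cap around +z
fib_cap <- function(n, half_angle_deg) {
  i <- seq_len(n) - 0.5
  zc <- 1 - (1 - cos(half_angle_deg * pi / 180)) * i / n
  ph <- pi * (1 + sqrt(5)) * i
  cbind(sqrt(1 - zc^2) * cos(ph), sqrt(1 - zc^2) * sin(ph), zc)
}

test_that("shoulder-sphere projection normalizes and filters non-extended frames", {
  n <- 20
  sho <- matrix(0, n, 3)
  hand <- matrix(rep(c(0.7, 0, 0), each = n), n, 3)
  pts <- to_shoulder_sphere(hand, sho, arm_length = 0.7)
  expect_equal(pts, matrix(rep(c(1, 0, 0), each = n), n, 3))

  hand2 <- matrix(rep(c(0, 0.35, 0), each = n), n, 3)
  pts2 <- to_shoulder_sphere(hand2, sho, arm_length = 0.7)
  expect_equal(pts2[1, ], c(0, 1, 0))     # radial projection to the sphere

  hand3 <- matrix(rep(c(0, 0.05, 0), each = n), n, 3)
  expect_warning(out <- to_shoulder_sphere(hand3, sho, 0.7), "extended")
  expect_equal(nrow(out), 0)
  expect_error(to_shoulder_sphere(matrix(0, 0, 3), matrix(0, 0, 3), 0.7),
               "empty")
})

test_that("three points give their triangle; degenerate sets error", {
  tri <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  bd <- boundary_alpha_shape(tri)
  expect_equal(nrow(bd$vertices), 3)
  md <- apply(tri, 1, function(p) min(rowSums(sweep(bd$vertices, 2, p)^2)))
  expect_lt(max(md), 1e-18)
  expect_error(boundary_alpha_shape(tri[1:2, ]), "3 points")
  line <- armassess:::.chart_to_sphere(cbind(seq(0, 40, 10), seq(0, 20, 5)))
  expect_error(boundary_alpha_shape(line), "collinear")
})

test_that("the alpha boundary of a dense cap cover hugs the rim", {
  pts <- fib_cap(2000, 60)
  bd <- boundary_alpha_shape(pts, alpha = 10, max_points = 2000)
  polar <- acos(pmin(1, bd$vertices[, 3])) * 180 / pi
  expect_true(all(60 - polar < 2))        # every vertex within 2 deg of rim
  expect_true(all(polar <= 60 + 1e-6))    # vertices are input points
})

test_that("Catmull-Rom smoothing interpolates the vertices", {
  sq <- armassess:::.chart_to_sphere(cbind(c(-20, 20, 20, -20),
                                           c(-20, -20, 20, 20)))
  out <- smooth_boundary(sq, samples_per_edge = 1)
  expect_equal(nrow(out), 4)
  match_dist <- apply(sq, 1, function(p) min(rowSums(sweep(out, 2, p)^2)))
  expect_lt(max(match_dist), 1e-18)

  th <- seq(0, 2 * pi, length.out = 13)[-13]
  circ <- cbind(sin(pi / 4) * cos(th), sin(pi / 4) * sin(th),
                rep(cos(pi / 4), 12))
  dense <- smooth_boundary(circ, samples_per_edge = 20)
  polar <- acos(pmin(1, dense[, 3]))
  expect_lt(max(abs(polar - pi / 4)) / (pi / 4), 0.01)
  # interpolation property: all 12 original points on the dense curve
  d <- apply(circ, 1, function(p) min(sqrt(rowSums(sweep(dense, 2, p)^2))))
  expect_lt(max(d), 1e-9)

  expect_message(out3 <- smooth_boundary(circ[1:3, ]), "unchanged")
  expect_equal(out3, circ[1:3, ])
})

test_that("quadrant areas match closed forms for octants and caps", {
  # upper-inner octant for a right arm: x < 0, y > 0, z > 0
  oct_chart <- rbind(c(0, 0), c(0, 90), c(-90, 0))
  octant <- smooth_boundary(armassess:::.chart_to_sphere(
    rbind(c(0, 1e-6), c(-1e-6, 89.99), c(-89.99, 1e-6))), 40)
  env <- quadrant_areas(octant, side = "right")
  expect_equal(unname(env$quadrant_rsa["Q1_inner_above"]), 0.125,
               tolerance = 0.01)
  expect_lt(sum(env$quadrant_rsa[-1]), 0.005)

  # frontal cap of half-angle 60: total RSA = 2*pi*(1 - cos 60)/(4*pi)
  th <- seq(0, 2 * pi, length.out = 181)[-181]
  cap <- cbind(sin(pi / 3) * cos(th), sin(pi / 3) * sin(th),
               rep(cos(pi / 3), 180))
  env2 <- quadrant_areas(cap)
  expect_equal(env2$total_rsa, 0.25, tolerance = 0.25 * 0.01)

  env0 <- quadrant_areas(matrix(numeric(0), 0, 3))
  expect_equal(unname(env0$quadrant_rsa), rep(0, 4))
  expect_equal(env0$total_rsa, 0)
})

test_that("quadrant RSAs are additive and rotation-invariant", {
  pts <- fib_cap(600, 50)
  R <- rot("y", 0.4) %*% rot("x", -0.3)
  tilted <- pts %*% t(R)                      # off-axis region
  bd <- smooth_boundary(boundary_alpha_shape(tilted, alpha = 12), 6)
  env <- quadrant_areas(bd)
  expect_equal(sum(env$quadrant_rsa), env$total_rsa, tolerance = 1e-9)
  expect_gt(env$total_rsa, 0.05)

  # rotate the whole scene (points and axes): all RSAs unchanged
  Q <- rot("z", 0.7) %*% rot("y", -0.2)
  env_rot <- quadrant_areas(bd %*% t(Q),
                            frontal_axis = drop(Q %*% c(0, 0, 1)),
                            vertical_axis = drop(Q %*% c(0, 1, 0)))
  expect_equal(env_rot$quadrant_rsa, env$quadrant_rsa, tolerance = 1e-9)
})

test_that("self-intersecting boundary curves are rejected", {
  bow <- armassess:::.chart_to_sphere(cbind(c(-20, 20, -20, 20),
                                            c(-20, 20, 20, -20)))
  expect_error(quadrant_areas(bow), "self-intersecting")
})

test_that("workspace area grows strictly with range of motion", {
  env_for <- function(rom) {
    streams <- lapply(c("RW-V0", "RW-V45", "RW-V90", "RW-V135"), function(a)
      sim_stream(a, rom = rom, fps = 12, seed = 20)$stream)
    hand <- do.call(rbind, lapply(streams, function(s)
      matrix(s$xyz[, match("RTIP", s$joints), ], ncol = 3)))
    sho <- do.call(rbind, lapply(streams, function(s)
      matrix(s$xyz[, match("RSHO", s$joints), ], ncol = 3)))
    pts <- to_shoulder_sphere(hand, sho, arm_length = 0.73)
    quadrant_areas(smooth_boundary(boundary_alpha_shape(pts), 6))
  }
  e_half <- env_for(0.5)
  e_full <- env_for(1.0)
  expect_gt(e_full$total_rsa, e_half$total_rsa)
})
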