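noise_free_target <- function(action = "RW-V45", frame = 15, fps = 10,
                              seed = 3, side = "right") {
  tj <- sim_stream(action, fps = fps, seed = seed)
  fr <- get_frame(tj$stream, frame)
  list(target = fitness_target(fr, side, estimate_torso_pose(fr)),
       truth = tj$angles[frame, ], frame = fr, stream = tj$stream)
}

test_that("fitness vanishes at the generating angles and grows away from them", {
  m <- arm_model()
  nf <- noise_free_target()
  expect_lt(ik_fitness(nf$truth, nf$target, m, rhythm_weight = 0), 1e-20)
  set.seed(1)
  for (k in 1:9) {
    x <- nf$truth
    x[k] <- x[k] + 0.05
    expect_gt(ik_fitness(x, nf$target, m, rhythm_weight = 0), 1e-8)
  }
})

test_that("an arm with fewer than 3 confident markers is underdetermined", {
  nf <- noise_free_target()
  fr <- nf$frame
  fr$confidence[c("RELB", "RWRI", "RHAN", "RTIP")] <- 0
  expect_error(fitness_target(fr, "right"), "underdetermined")
})

test_that("degenerate PSO coefficients freeze the swarm", {
  m <- arm_model()
  nf <- noise_free_target()
  fit_fn <- function(X) ik_fitness(X, nf$target, m)
  cfg <- swarm_config(n_particles = 10, omega = 0, c1 = 0, c2 = 0)
  lim <- m$limits
  set.seed(2)
  sw <- armassess:::.init_swarm(cfg, lim["lo", ], lim["hi", ])
  sw$V[] <- 0
  sw <- armassess:::.eval_swarm(sw, fit_fn)
  sw2 <- pso_step(sw, cfg, fit_fn)
  expect_equal(sw2$X, sw$X)
  # a particle sitting at gbest == pbest with zero velocity never moves
  cfg2 <- swarm_config(n_particles = 10, omega = 0.7)
  sw3 <- armassess:::.init_swarm(cfg2, lim["lo", ], lim["hi", ])
  sw3 <- armassess:::.eval_swarm(sw3, fit_fn)
  b <- which.min(sw3$pbest_f)
  sw3$V[b, ] <- 0
  x_b <- sw3$X[b, ]
  sw4 <- pso_step(sw3, cfg2, fit_fn)
  expect_equal(sw4$X[b, ], x_b)
})

test_that("gbest fitness is monotonically non-increasing across iterations", {
  m <- arm_model()
  nf <- noise_free_target()
  fit_fn <- function(X) ik_fitness(X, nf$target, m)
  cfg <- swarm_config(n_particles = 20)
  lim <- m$limits
  set.seed(3)
  sw <- armassess:::.init_swarm(cfg, lim["lo", ], lim["hi", ])
  sw <- armassess:::.eval_swarm(sw, fit_fn)
  hist <- numeric(50)
  for (i in 1:50) {
    sw <- pso_step(sw, cfg, fit_fn)
    sw <- crossbreed(sw, cfg)
    sw <- armassess:::.eval_swarm(sw, fit_fn)
    hist[i] <- sw$gbest_f
  }
  expect_true(all(diff(hist) <= 0))
})

test_that("the crossbreed operator blends positions and renormalizes velocity", {
  cfg <- swarm_config(n_particles = 2, pc = 1, pool_frac = 1)
  sw <- list(X = rbind(c(1, 2), c(3, 4)), V = rbind(c(1, 0), c(0, 1)),
             pbest_x = rbind(c(1, 2), c(3, 4)), pbest_f = c(5, 6),
             gbest_x = c(1, 2), gbest_f = 5, lo = c(-10, -10), hi = c(10, 10),
             evaluated = TRUE)
  set.seed(4)
  out <- crossbreed(sw, cfg)
  # pc = 1: each child keeps its first parent's position
  expect_setequal(out$X[, 1], c(1, 3))
  # velocity: normalized sum scaled to the first parent's speed
  expect_equal(abs(out$V[1, ]), c(1 / sqrt(2), 1 / sqrt(2)), tolerance = 1e-12)
  # pbest memory inherited, gbest untouched
  expect_equal(out$pbest_f, sw$pbest_f)
  expect_equal(out$gbest_f, 5)

  # pools of size < 2 leave the swarm unchanged
  cfg0 <- swarm_config(n_particles = 2, pool_frac = 0.4)  # floor -> 0
  out0 <- crossbreed(sw, cfg0)
  expect_equal(out0$X, sw$X)
})

test_that("with the crossbreed disabled the solver is classical PSO, bit for bit", {
  m <- arm_model()
  nf <- noise_free_target()
  fit_fn <- function(X) ik_fitness(X, nf$target, m, 1e-4)
  cfg <- swarm_config(n_particles = 15, max_iter = 40, hybrid_prob = 0,
                      tol = 0)
  lim <- m$limits
  set.seed(11)
  got <- solve_frame(nf$target, cfg, m)
  # reference: hand-rolled classical PSO loop with the same RNG stream
  set.seed(11)
  sw <- armassess:::.init_swarm(cfg, lim["lo", ], lim["hi", ],
                                seeds = armassess:::.analytic_seed(nf$target))
  sw <- armassess:::.eval_swarm(sw, fit_fn)
  for (i in 1:40) sw <- pso_step(sw, cfg, fit_fn)
  expect_identical(got$angles, armassess:::.vec_to_angles(sw$gbest_x))
  expect_identical(got$fitness, sw$gbest_f)
})

test_that("warm-starting at the truth returns immediately with ~zero fitness", {
  m <- arm_model()
  nf <- noise_free_target()
  set.seed(5)
  res <- solve_frame(nf$target, swarm_config(), m, warm_start = nf$truth)
  expect_lt(res$fitness, 1e-12)
  expect_lte(res$iterations, 2)
  expect_equal(unname(res$angles), unname(nf$truth), tolerance = 1e-9)
})

test_that("a constant-pose sequence yields a steady solution", {
  # successive identical frames keep refining the same optimum: the fitness
  # is non-increasing along the sequence, reconstructed markers are steady
  # to the millimeter, and angles wander only inside the redundancy manifold
  m <- arm_model()
  tj <- sim_stream("P-Nose", fps = 10, seed = 6)
  i <- 16
  nrep <- 5
  xyz <- array(rep(tj$stream$xyz[i, , ], each = nrep), c(nrep, 11, 3))
  const <- skeleton_stream(seq_len(nrep) / 10, model_markers(), xyz)
  res <- solve_sequence(const, swarm_config(max_iter = 150, seed = 7), m)
  marker_drift <- max(abs(res$reconstructed$xyz[-1, , ] -
                          res$reconstructed$xyz[-nrep, , ]))
  expect_lt(marker_drift, 2e-3)
  angle_drift <- max(abs(apply(res$angles$right, 2, diff)))
  expect_lt(angle_drift, 0.05)
  fit <- res$fitness[, "right"]
  expect_true(all(diff(fit) <= 1e-8))
  expect_error(solve_sequence(skeleton_stream(numeric(0), model_markers(),
                                              array(0, c(0, 11, 3))),
                              swarm_config(), m),
               "empty")
})

test_that("solved sequences reconstruct markers with exact bone lengths", {
  m <- arm_model()
  tj <- sim_stream("P-ContralateralShoulder", fps = 8, seed = 8)
  sub <- skeleton_stream(tj$stream$timestamps[8:12], model_markers(),
                         tj$stream$xyz[8:12, , , drop = FALSE])
  res <- solve_sequence(sub, swarm_config(max_iter = 200, seed = 9), m)
  segs <- list(c("TOR", "RSHO"), c("RSHO", "RELB"), c("RELB", "RWRI"),
               c("RWRI", "RHAN"), c("RHAN", "RTIP"))
  for (i in seq_len(n_frames(res$reconstructed))) {
    p <- matrix(res$reconstructed$xyz[i, , ], ncol = 3,
                dimnames = list(model_markers(), NULL))
    got <- vapply(segs, function(s) sqrt(sum((p[s[1], ] - p[s[2], ])^2)),
                  numeric(1))
    expect_lt(max(abs(got - unname(m$lengths)) / m$lengths), 1e-9)
  }
})

test_that("occluded distal markers are reconstructed near ground truth", {
  # hand/tip become invisible mid-sequence; warm starts plus the
  # temporal-continuity prior keep the unobserved wrist pose anchored
  m <- arm_model()
  tj <- sim_stream("P-Stomach", fps = 8, seed = 10)
  s <- tj$stream
  idx <- 8:14
  conf <- s$conf[idx, ]
  occl_frames <- 4:7                                   # later frames occluded
  conf[occl_frames, match(c("RTIP", "RHAN"), s$joints)] <- 0
  sub <- skeleton_stream(s$timestamps[idx], s$joints,
                         s$xyz[idx, , , drop = FALSE], conf)
  res <- solve_sequence(sub, swarm_config(max_iter = 250, seed = 11), m,
                        sides = "right")
  tip_err <- sqrt(rowSums((res$reconstructed$xyz[occl_frames, 6, ] -
                           s$xyz[idx[occl_frames], 6, ])^2))
  expect_lt(stats::median(tip_err), 0.03)
})

test_that("angle recovery is accurate on flexed-elbow poses (identifiable DOFs)", {
  m <- arm_model()
  tj <- sim_stream("P-Nose", fps = 6, seed = 12)
  idx <- 8:12                              # mid-reach, elbow well flexed
  sub <- skeleton_stream(tj$stream$timestamps[idx], model_markers(),
                         tj$stream$xyz[idx, , , drop = FALSE])
  res <- solve_sequence(sub, swarm_config(max_iter = 300, seed = 13), m,
                        sides = "right")
  err_deg <- abs(res$angles$right - tj$angles[idx, ]) * 180 / pi
  expect_lt(max(apply(err_deg[, c("sh_x", "elb_x")], 2, stats::median)), 2)
})
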