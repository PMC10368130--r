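# Shared fixtures, all generated in code.

# a device frame with every joint at a fixed position
device_frame_at <- function(pos = c(0, 0, 0), timestamp = 0) {
  joints <- matrix(rep(pos, each = 32), 32, 3,
                   dimnames = list(device_joints(), c("x", "y", "z")))
  structure(list(timestamp = timestamp, joints = joints,
                 confidence = stats::setNames(rep(1, 32), device_joints())),
            class = "skeleton_frame")
}

# ground-truth model stream for one action under a given impairment
sim_stream <- function(action = "RW-V90", rom = 1, tremor = 0, fps = 15,
                       seed = 1) {
  generate_trajectory(action, impairment_spec(rom_scale = rom,
                                              tremor_amp = tremor),
                      fps = fps, seed = seed)
}

# small labelled dataset for network tests: varied actions and impairments
sim_dataset <- function(n, seed0 = 100, fps = 8, rom_range = c(0.4, 1),
                        tremor_range = c(0, 4)) {
  acts <- protocol_actions()$id
  lapply(seq_len(n), function(i) {
    set.seed(seed0 + i)
    rom <- stats::runif(1, rom_range[1], rom_range[2])
    tr <- stats::runif(1, tremor_range[1], tremor_range[2])
    tj <- generate_trajectory(acts[(i - 1) %% 16 + 1],
                              impairment_spec(rom_scale = rom, tremor_amp = tr),
                              fps = fps, seed = seed0 + i)
    list(seq = skeleton_sequence(tj$stream), score = tj$score,
         action = tj$action)
  })
}

# random angle set within limits (for FK property tests)
random_angles <- function(model = arm_model()) {
  lim <- model$limits
  a <- zero_angles()
  for (side in c("right", "left"))
    a[[side]] <- stats::setNames(
      stats::runif(9, lim["lo", ], lim["hi", ]), arm_angle_names())
  a$torso_rot <- stats::runif(3, -0.3, 0.3)
  a$torso_t <- stats::runif(3, -0.5, 0.5)
  a
}

expect_stream_equal <- function(a, b, tol = 1e-9) {
  expect_equal(a$timestamps, b$timestamps, tolerance = tol)
  expect_equal(a$joints, b$joints)
  expect_lt(max(abs(a$xyz - b$xyz)), tol)
  expect_equal(a$conf, b$conf, tolerance = tol)
}
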