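test_that("the protocol catalogue holds exactly the 16 documented actions", {
  acts <- protocol_actions()
  expect_equal(nrow(acts), 16)
  expect_equal(sum(acts$type == "sweep_v"), 4)
  expect_equal(sum(acts$type == "sweep_h"), 4)
  expect_equal(sum(acts$type == "proximal"), 8)
  expect_setequal(acts$azimuth_deg[acts$type == "sweep_v"], c(0, 45, 90, 135))
  expect_equal(max(acts$elevation_deg, na.rm = TRUE), 180)
})

test_that("the impairment score is the documented clamped linear label", {
  expect_equal(impairment_spec(1, 0)$score, 100)
  expect_equal(impairment_spec(0.5, 0)$score, 50)
  expect_equal(impairment_spec(0.8, 2, c_t = 4)$score, 72)
  expect_equal(impairment_spec(0.1, 10)$score, 0)      # clamped at 0
  # monotone: non-decreasing in rom, non-increasing in tremor
  roms <- seq(0.1, 1, by = 0.1)
  s <- vapply(roms, function(r) impairment_score(r, 2), numeric(1))
  expect_true(all(diff(s) >= 0))
  trs <- seq(0, 10, by = 1)
  s2 <- vapply(trs, function(t) impairment_score(0.9, t), numeric(1))
  expect_true(all(diff(s2) <= 0))
})

test_that("identity impairment reaches the nominal sweep amplitude, rom scales it", {
  tj <- generate_trajectory("RW-V90", impairment_spec(), fps = 30, seed = 1)
  peak <- max(tj$angles[, "sh_z"]) * 180 / pi
  expect_equal(peak, 180, tolerance = 0.5)
  tj2 <- generate_trajectory("RW-V90", impairment_spec(rom_scale = 0.5),
                             fps = 30, seed = 1)
  expect_equal(max(tj2$angles[, "sh_z"]) * 180 / pi, 90, tolerance = 0.5)
  expect_error(generate_trajectory("RW-V999", impairment_spec()), "unknown")
})

test_that("generated frames are the forward-kinematics image of the angles", {
  m <- arm_model()
  tj <- generate_trajectory("P-Ear", impairment_spec(rom_scale = 0.7),
                            fps = 12, seed = 3, model = m)
  i <- 17
  ang <- zero_angles()
  ang$right <- stats::setNames(tj$angles[i, ], arm_angle_names())
  expect_equal(matrix(tj$stream$xyz[i, , ], ncol = 3),
               unname(forward_kinematics(ang, m)), tolerance = 1e-12)
})

test_that("rendering is exact without noise and invertible (round trip)", {
  cams <- default_cameras(noise_sd = 0, dropout_prob = 0, occlude = FALSE)
  tj <- sim_stream("P-Stomach", fps = 15, seed = 4)
  views <- render_views(tj$stream, cams$master, cams$subordinate, seed = 5)
  expect_length(views$master$joints, 32)
  # camera positions equal the rigid transform of ground truth, exactly
  map <- marker_device_map()
  i <- 10
  gt <- matrix(tj$stream$xyz[i, , ], ncol = 3)
  cam_pos <- matrix(views$master$xyz[i, match(map, views$master$joints), ],
                    ncol = 3)
  expect_equal(cam_pos, apply_transform(cams$master$transform, gt),
               tolerance = 1e-12)
  # applying the inverse camera transform reproduces ground truth
  back <- transform_stream(views$sub,
                           invert_transform(cams$subordinate$transform))
  got <- back$xyz[, match(map, back$joints), ]
  expect_lt(max(abs(got - tj$stream$xyz)), 1e-9)
})

test_that("dropout marks the documented fraction of joint-frames", {
  cams <- default_cameras(noise_sd = 0, dropout_prob = 0.2, occlude = FALSE)
  # ~10,000 joint-frames: 313 frames x 32 joints
  tj <- sim_stream("RW-H90", fps = 78, seed = 6)
  v <- render_views(tj$stream, cams$master, cams$subordinate, seed = 7)$master
  frac <- mean(v$conf == 0)
  expect_lt(abs(frac - 0.2), 0.01)
  # dropped joints carry the sentinel position and zero confidence
  expect_true(all(v$xyz[, , 1][v$conf == 0] == 0))
})

test_that("occlusion hides markers behind the torso plane from front cameras", {
  cams <- default_cameras(noise_sd = 0, dropout_prob = 0, occlude = TRUE)
  tj <- sim_stream("P-LumbarSpine", fps = 15, seed = 8)   # hand behind back
  v <- render_views(tj$stream, cams$master, cams$subordinate, seed = 9)$master
  tipcol <- match("HANDTIP_RIGHT", v$joints)
  # the deepest-behind frames must be occluded
  z <- tj$stream$xyz[, match("RTIP", tj$stream$joints), 3]
  expect_true(all(v$conf[z < -0.15, tipcol] == 0))
  expect_true(all(v$conf[z > 0, tipcol] == 1))
})

test_that("identical seeds give bit-identical streams, different seeds differ", {
  cams <- default_cameras(noise_sd = 0.005, dropout_prob = 0.1)
  tj <- sim_stream("RW-V0", fps = 15, seed = 10, tremor = 2)
  tj_b <- sim_stream("RW-V0", fps = 15, seed = 10, tremor = 2)
  expect_identical(tj$stream$xyz, tj_b$stream$xyz)
  v1 <- render_views(tj$stream, cams$master, cams$subordinate, seed = 11)
  v2 <- render_views(tj$stream, cams$master, cams$subordinate, seed = 11)
  expect_identical(v1$master$xyz, v2$master$xyz)
  expect_identical(v1$master$conf, v2$master$conf)
  v3 <- render_views(tj$stream, cams$master, cams$subordinate, seed = 12)
  expect_false(identical(v1$master$xyz, v3$master$xyz))
})

test_that("simulate_session writes the documented CSV/JSON artifacts", {
  dir <- withr::local_tempdir()
  ses <- simulate_session("P-Nose", impairment_spec(rom_scale = 0.7,
                                                    tremor_amp = 2),
                          fps = 10, seed = 13, out_dir = dir)
  expect_true(all(file.exists(file.path(dir,
    c("camera_master.csv", "camera_sub.csv", "ground_truth.csv",
      "session.json")))))
  meta <- jsonlite::read_json(file.path(dir, "session.json"))
  expect_equal(meta$score, impairment_score(0.7, 2))
  expect_equal(meta$action, "P-Nose")
})
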