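# armassess

Quantitative upper-limb motor assessment from marker-less motion capture,
for rehabilitation researchers and engineers who need a fully testable
pipeline without camera hardware. The package covers the complete chain:

1. **Synthetic motion & sensor simulation** — ground-truth joint-angle
   trajectories for a 16-action exercise protocol (8 reachable-workspace
   sweeps + 8 proximal reaches to body landmarks), rendered to two noisy,
   occlusion-corrupted camera views, with a documented impairment model
   (`score = clamp(100·rom_scale − 4·tremor_amp, 0, 100)`).
2. **Calibration & fusion** — Kabsch/SVD rigid registration of 3-D
   correspondences; per-joint confidence-weighted fusion of the two views.
3. **Preprocessing** — median filtering plus zero-phase 6th-order
   Butterworth low-pass; per-channel SNR in dB,
   `10·log10(var(ref)/var(raw − ref))`.
4. **Rigid-body model & inverse kinematics** — a 9-DOF-per-arm chain
   (sternoclavicular 2, shoulder 3, elbow 1, wrist 2, hand 1; 11 markers,
   10 segments) with the scapulohumeral rhythm
   `θ_fb(β), θ_ud(β)` as piecewise-linear functions of the lift angle.
   IK minimizes `Σ w_j‖y_j − F(x)_j‖²` per frame with **crossbreed particle
   swarm optimization** (PSO velocity/position updates plus a genetic-style
   blend `child(x) = Pc·parent1(x) + (1−Pc)·parent2(x)`), so every
   reconstructed pose conserves bone lengths exactly.
5. **Reachable workspace** — shoulder-centered, arm-length-normalized
   hand-tip directions; alpha-shape boundary, centripetal Catmull-Rom
   smoothing, quadrant decomposition and relative surface areas (RSA,
   fraction of the full sphere).
6. **Assessment network** — a spatial-temporal graph convolutional network
   over the 11-joint graph, extended with ConvLSTM-derived self-attention
   maps `G_k = σ(φ(Â_k ⊙ S_k) Z W_k)`, multi-kernel temporal convolutions,
   a 4-layer LSTM head and a scalar movement-quality score; trained with
   Adam, implemented natively in R with hand-derived backpropagation that
   is finite-difference-verified in the test suite. Joint-importance maps
   come from the attention modulation per node.

See the methods vignette (`vignettes/posture-assessment.Rmd`) for the
models, conventions and every open design decision.

## Worked example

Simulate one elevation sweep with a mildly impaired arm (80 % range of
motion, 2° tremor, true score 72), run the two-camera pipeline, and
summarize:

```r
library(armassess)
cams <- default_cameras(noise_sd = 0.004, dropout_prob = 0.1)
ses <- simulate_session("RW-V90",
                        impairment_spec(rom_scale = 0.8, tremor_amp = 2),
                        fps = 30, seed = 7, cameras = cams)

extr  <- calibrate_cameras(cams, seed = 7)              # sub -> master
fused <- fuse_streams(ses$views$master, ses$views$sub, extr)
world <- transform_stream(fused, invert_transform(cams$master$transform))
clean <- preprocess_stream(world)
clean
#> <skeleton_stream: 121 frames x 32 joints, 0.00-4.00 s, 98.9% tracked>

subset(snr_table(to_model_frame(world), to_model_frame(clean)),
       joint == "RWRI")
#>  joint axis    snr_db
#>   RWRI    x  5.069166
#>   RWRI    y 15.048864
#>   RWRI    z -7.753205
```

(SNR uses the processed signal as reference; the sweep moves in the x-y
plane, so the near-static wrist z channel carries almost no signal and its
SNR is low — compare channels, not absolute values.)

Fit the rigid-body model by crossbreed PSO and check against the
simulator's ground truth:

```r
ik <- solve_sequence(clean, swarm_config(max_iter = 80, seed = 7), arm_model())
err <- sqrt(apply((ik$reconstructed$xyz - ses$truth$stream$xyz)^2, 1, mean))
sprintf("mean reconstruction error: %.1f mm", 1000 * mean(err))
#> "mean reconstruction error: 10.7 mm"
```

Reachable workspace over the four vertical sweeps at the same impairment:

```r
streams <- lapply(c("RW-V0", "RW-V45", "RW-V90", "RW-V135"), function(a)
  generate_trajectory(a, impairment_spec(rom_scale = 0.8),
                      fps = 15, seed = 7)$stream)
hand <- do.call(rbind, lapply(streams, function(s) matrix(s$xyz[, 6, ], ncol = 3)))
sho  <- do.call(rbind, lapply(streams, function(s) matrix(s$xyz[, 2, ], ncol = 3)))
pts  <- to_shoulder_sphere(hand, sho, arm_length = 0.73)
quadrant_areas(smooth_boundary(boundary_alpha_shape(pts)), "right")
#> <workspace_envelope> relative surface areas (fraction of full sphere):
#> Q1_inner_above Q2_inner_below Q3_outer_above Q4_outer_below          total
#>         0.0466         0.0036         0.1774         0.1826         0.4102
```

The arm reaches 41 % of the full sphere at 80 % range of motion, almost all
of it on the outer (lateral) side — the inner-below quadrant, which needs
cross-body reaching, is nearly empty for pure elevation sweeps.

Training the score network and extracting joint-importance maps:

```r
ds <- lapply(1:40, function(i) {                 # labelled synthetic set
  tj <- generate_trajectory(protocol_actions()$id[(i - 1) %% 16 + 1],
                            impairment_spec(rom_scale = runif(1, 0.4, 1),
                                            tremor_amp = runif(1, 0, 4)),
                            fps = 8, seed = i)
  list(seq = skeleton_sequence(tj$stream), score = tj$score)
})
net <- train_assess_net(ds, net_config(), seed = 1, epochs = 60)
predict_score(net, ds[[1]]$seq)
imp <- joint_importance(net, list(sweeps = lapply(ds, `[[`, "seq")))
```

A thin command-line front end over the same functions lives in
`inst/cli/armassess.R` (`simulate`, `calibrate`, `fuse`, `preprocess`,
`snr`, `ik`, `workspace`, `train`, `assess`, `importance`, `run`).

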