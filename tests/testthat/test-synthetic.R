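test_that("model generation is deterministic: byte-identical serialization", {
  a <- generate_spine_model(geometry_params(), seed = 9)
  b <- generate_spine_model(geometry_params(), seed = 9)
  fa <- tempfile(fileext = ".json"); fb <- tempfile(fileext = ".json")
  write_spine_model(a$model, fa)
  write_spine_model(b$model, fb)
  expect_identical(readLines(fa), readLines(fb))
  c <- generate_spine_model(geometry_params(), seed = 10)
  expect_false(identical(model_to_vector(c$model, a$model),
                         model_to_vector(a$model, a$model)))
})

test_that("generated static pose reproduces the requested LL and TK", {
  for (ll in c(30, 40, 55)) {
    gm <- generate_spine_model(
      geometry_params(lumbar_lordosis = ll, thoracic_kyphosis = 35),
      seed = 4)
    bk <- joint_to_body_kinematics(
      gm$model, spinemc:::new_joint_kinematics(matrix(0, 2, 51),
                                               matrix(0, 2, 6)))
    sp <- compute_spino_pelvic(gm$model, bk)
    expect_lt(abs(sp$series[1, "LL"] - ll), 0.5)
    expect_lt(abs(sp$series[1, "TK"] - 35), 0.5)
  }
})

test_that("zero deformity severity gives a sagittally symmetric static pose", {
  gm <- generate_spine_model(geometry_params(deformity_severity = 0), seed = 2)
  for (b in spine_body_names()) {
    s <- gm$model$segments[[b]]
    expect_equal(s$pose$p[1], 0, tolerance = 1e-9)
    expect_equal(s$pose$eul[2], 0, tolerance = 1e-9)
    expect_equal(s$pose$eul[3], 0, tolerance = 1e-9)
  }
})

test_that("noise-free trajectories are exactly rigid and FK-consistent", {
  gm <- fix_model()
  tr <- fix_clean_trial()
  chain <- spinemc:::build_chain(gm$model)
  ## marker trajectories equal forward kinematics of the ground-truth angles
  for (f in c(1, 25, 50)) {
    fk <- forward_kinematics(gm$model, tr$truth$base[f, ],
                             tr$truth$angles[f, ])
    expect_equal(unname(tr$trial$data[f, , ]), unname(fk$markers),
                 tolerance = 1e-9)
  }
  ## rigid-body distance invariance across frames (the four pelvis markers)
  idx <- which(chain$marker_body == 1L)
  expect_length(idx, 4)
  d1 <- dist(tr$trial$data[1, idx, ])
  d2 <- dist(tr$trial$data[50, idx, ])
  expect_equal(as.numeric(d1), as.numeric(d2), tolerance = 1e-9)
})

test_that("imposed lumbar flexion equals the ground-truth LL range of motion", {
  gm <- fix_model()
  spec <- motion_spec(n_frames = 30, noise_sd = 0, lumbar_rom = 30)
  tr <- generate_flexion_trial(gm$model, spec, seed = 3)
  bk <- joint_to_body_kinematics(
    gm$model, spinemc:::new_joint_kinematics(tr$truth$angles, tr$truth$base))
  sp <- compute_spino_pelvic(gm$model, bk)
  expect_equal(unname(sp$rom["LL"]), 30, tolerance = 0.5)
})

test_that("retest jitter changes ROMs across seeds; disabled jitter is reproducible", {
  gm <- fix_model()
  spec_j <- motion_spec(n_frames = 30, noise_sd = 0, jitter = TRUE)
  t1 <- generate_flexion_trial(gm$model, spec_j, seed = 1)
  t2 <- generate_flexion_trial(gm$model, spec_j, seed = 2)
  expect_false(isTRUE(all.equal(t1$truth$amplitudes, t2$truth$amplitudes)))
  spec_n <- motion_spec(n_frames = 30, noise_sd = 0, jitter = FALSE)
  t3 <- generate_flexion_trial(gm$model, spec_n, seed = 1)
  t4 <- generate_flexion_trial(gm$model, spec_n, seed = 1)
  expect_identical(t3$trial$data, t4$trial$data)
})

test_that("zero-spread operator emulation reproduces the input model", {
  m <- fix_model()$model
  spec0 <- operator_variability_spec(
    marker_position = c(0, 0, 0), body_position = c(0, 0, 0),
    body_orientation = c(0, 0, 0), joint_position = c(0, 0, 0),
    joint_orientation = c(0, 0, 0))
  ops <- emulate_operators(m, spec0, 3, seed = 1)
  for (o in ops) {
    expect_equal(as.numeric(model_to_vector(o, m)), rep(0, 294),
                 tolerance = 1e-12)
  }
})

test_that("default operator spreads give marker deviations at the expected scale", {
  fx <- fix_operators()
  sm <- summarize_deviations(fx$pool)
  mk <- sm$by_group[sm$by_group$component == "marker", ]
  expect_true(all(mk$median_abs > 0.05 & mk$median_abs < 0.3))
})

test_that("sampled operator deviations match the requested spread (LLN)", {
  m <- fix_model()$model
  spec <- operator_variability_spec()
  ops <- emulate_operators(m, spec, n_operators = 100, seed = 6)
  ## deviations vs the ground-truth model are direct draws from the spec
  sigma <- spinemc:::spec_sigma_vector(m, spec)
  devs <- vapply(ops, function(o) as.numeric(model_to_vector(o, m)),
                 numeric(294))
  i <- which(parameter_layout(m)$component == "joint" &
               parameter_layout(m)$parameter == "orientation")
  emp_sd <- apply(devs[i, ], 1, sd)
  expect_true(all(abs(emp_sd / sigma[i] - 1) < 0.45))
  ## pooled over the whole block the estimate is tight
  expect_lt(abs(mean(emp_sd / sigma[i]) - 1), 0.15)
})
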