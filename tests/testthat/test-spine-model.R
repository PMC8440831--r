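test_that("generated model satisfies the structural invariants", {
  m <- fix_model()$model
  expect_s3_class(m, "spine_model")
  expect_length(m$segments, 18)
  expect_length(m$joints, 17)
  expect_length(m$markers, 28)
  expect_silent(validate_spine_model(m))
  ## serial chain pelvis -> T1
  bodies <- spine_body_names()
  for (i in 1:17) {
    j <- m$joints[[spine_joint_names()[i]]]
    expect_identical(j$parent, bodies[i])
    expect_identical(j$child, bodies[i + 1])
  }
})

test_that("forward kinematics: identity pose reproduces the static model", {
  m <- fix_model()$model
  fk <- forward_kinematics(m)
  for (b in spine_body_names()) {
    i <- match(b, spine_body_names())
    expect_equal(as.numeric(fk$body_p[, i]), m$segments[[b]]$pose$p,
                 tolerance = 1e-9)
  }
  ## marker ground positions equal their static positions
  chain <- spinemc:::build_chain(m)
  static_markers <- t(vapply(seq_len(28), function(k) {
    b <- chain$marker_body[k]
    as.numeric(chain$static_R[, , b] %*% chain$marker_pos[k, ] +
                 chain$static_p[, b])
  }, numeric(3)))
  expect_equal(unname(fk$markers), static_markers, tolerance = 1e-9)
})

test_that("forward kinematics: single-joint rotation moves only cranial markers", {
  m <- fix_model()$model
  fk0 <- forward_kinematics(m)
  angles <- numeric(51)
  j <- match("L2_L3", spine_joint_names())
  angles[3 * j - 2] <- 10  # FE about the joint x axis
  fk1 <- forward_kinematics(m, joint_angles = angles)
  chain <- spinemc:::build_chain(m)
  caudal <- chain$marker_depth < j
  expect_equal(fk1$markers[caudal, ], fk0$markers[caudal, ], tolerance = 1e-9)
  ## cranial markers match a hand-composed rotation of 10 deg about the
  ## joint's x axis through the joint centre
  ax <- fk0$joint_R[, 1, j]
  cp <- fk0$joint_p[, j]
  th <- 10 * pi / 180
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3)
  Rod <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  for (k in which(!caudal)) {
    expected <- as.numeric(Rod %*% (fk0$markers[k, ] - cp)) + cp
    expect_equal(unname(fk1$markers[k, ]), expected, tolerance = 1e-8)
  }
})

test_that("forward kinematics: base translation shifts every marker rigidly", {
  m <- fix_model()$model
  fk0 <- forward_kinematics(m)
  fk1 <- forward_kinematics(m, base_pose = c(0, 0, 50, 0, 0, 0))
  expect_equal(fk1$markers - fk0$markers,
               matrix(rep(c(0, 0, 50), each = 28), 28, 3,
                      dimnames = dimnames(fk0$markers)),
               tolerance = 1e-9)
})

test_that("forward kinematics is exactly rigid within a body", {
  m <- fix_model()$model
  chain <- spinemc:::build_chain(m)
  set.seed(5)
  for (rep in 1:5) {
    fk <- forward_kinematics(m, base_pose = c(rnorm(3, 0, 40), rnorm(3, 0, 20)),
                             joint_angles = rnorm(51, 0, 6))
    for (b in unique(chain$marker_body)) {
      idx <- which(chain$marker_body == b)
      if (length(idx) < 2) next
      d_model <- dist(chain$marker_pos[idx, , drop = FALSE])
      d_world <- dist(fk$markers[idx, , drop = FALSE])
      expect_equal(as.numeric(d_world), as.numeric(d_model), tolerance = 1e-9)
    }
  }
})

test_that("average_models is idempotent, symmetric and permutation-invariant", {
  m <- fix_model()$model
  expect_equal(average_models(list(m, m, m)), m, tolerance = 1e-9)
  ## +theta / -theta body orientations average to the midpoint
  d <- numeric(294)
  layout <- parameter_layout(m)
  i_l3x <- which(layout$component == "body" & layout$element == "L3" &
                   layout$parameter == "orientation" & layout$direction == "x")
  d[i_l3x] <- 4
  m_plus <- apply_perturbation(m, d)
  m_minus <- apply_perturbation(m, -d)
  avg <- average_models(list(m_plus, m_minus))
  expect_equal(avg$segments$L3$align$eul, m$segments$L3$align$eul,
               tolerance = 1e-9)
  ## arithmetic mean of marker positions
  d2 <- numeric(294); d2[1] <- 3
  d3 <- numeric(294); d3[1] <- 6
  avg2 <- average_models(list(m, apply_perturbation(m, d2),
                              apply_perturbation(m, d3)))
  expect_equal(avg2$markers[[1]]$pos[1], m$markers[[1]]$pos[1] + 3,
               tolerance = 1e-9)
  ## permutation invariance
  ops <- fix_operators()$ops
  a <- average_models(ops)
  b <- average_models(ops[c(3, 1, 2)])
  expect_equal(model_to_vector(a, b), model_to_vector(b, b), tolerance = 1e-9)
})

test_that("topology mismatches are structural errors", {
  m <- fix_model()$model
  bad <- m
  names(bad$markers)[1] <- "NOT_A_MARKER"
  bad$markers[[1]]$name <- "NOT_A_MARKER"
  expect_error(average_models(list(m, bad)), class = "spinemc_structural_error")
  bad2 <- m
  bad2$segments$L3$landmarks$center <- NULL
  expect_error(validate_spine_model(bad2), "landmark",
               class = "spinemc_structural_error")
})
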