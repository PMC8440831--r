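#' Geometry parameters for synthetic spino-pelvic models
#'
#' Controls the static (model-building) pose of a generated subject:
#' sagittal alignment (lumbar lordosis, thoracic kyphosis, sacral slope,
#' static pelvic tilt), vertebral stacking dimensions, and a deformity
#' severity scalar that scales the coronal offset and axial rotation of a
#' scoliotic-like curve (0 = perfectly sagittally symmetric). Defaults are
#' plausible for an adult-spinal-deformity subject.
#'
#' @param lumbar_lordosis target LL of the static pose, deg (sacral plate vs
#'   L1 superior endplate).
#' @param thoracic_kyphosis target TK, deg (T1 superior vs T12 inferior
#'   endplate).
#' @param sacral_slope inclination of the sacral plate from horizontal, deg.
#' @param pelvic_tilt static pelvic tilt, deg.
#' @param lumbar_height,lumbar_disc,thoracic_height,thoracic_disc vertebral
#'   body heights and disc spacings, mm.
#' @param deformity_severity scalar >= 0 (0 = sagittally symmetric; 1 gives a
#'   ~25 mm coronal apex offset).
#' @param height_jitter_sd per-level random variation of the stacking step,
#'   mm (makes subjects distinct while preserving the requested LL/TK
#'   exactly).
#' @return list of class `geometry_params`.
#' @export
geometry_params <- function(lumbar_lordosis = 45, thoracic_kyphosis = 40,
                            sacral_slope = 35, pelvic_tilt = 20,
                            lumbar_height = 30, lumbar_disc = 10,
                            thoracic_height = 22, thoracic_disc = 5,
                            deformity_severity = 0.5,
                            height_jitter_sd = 1) {
  p <- list(lumbar_lordosis = lumbar_lordosis,
            thoracic_kyphosis = thoracic_kyphosis,
            sacral_slope = sacral_slope, pelvic_tilt = pelvic_tilt,
            lumbar_height = lumbar_height, lumbar_disc = lumbar_disc,
            thoracic_height = thoracic_height, thoracic_disc = thoracic_disc,
            deformity_severity = deformity_severity,
            height_jitter_sd = height_jitter_sd)
  if (any(unlist(p[c("lumbar_height", "lumbar_disc", "thoracic_height",
                     "thoracic_disc")]) <= 0))
    stop("infeasible geometry: vertebral heights and disc spacings must be > 0")
  if (p$deformity_severity < 0) stop("deformity_severity must be >= 0")
  class(p) <- "geometry_params"
  p
}

## per-joint shares of the requested lumbar lordosis (caudal to cranial,
## lordosis concentrated caudally as in physiological alignment) and of the
## thoracic kyphosis (largest mid-thoracic wedge)
LUMBAR_SHARES <- c(0.30, 0.25, 0.20, 0.15, 0.10)
thoracic_shares <- function() {
  w <- seq(1.5, 0.5, length.out = 11)
  w / sum(w)
}

#' Generate a synthetic subject-specific spine model
#'
#' Builds an 18-body / 17-joint / 28-marker spino-pelvic model whose static
#' pose reproduces the requested lumbar lordosis and thoracic kyphosis
#' exactly (by construction, and within 0.5 deg when re-measured through
#' [compute_spino_pelvic()]). The marker layout — 4 pelvis markers, one
#' spinous-process marker per vertebra (17), and 7 paraspinal markers on
#' alternating levels placed off the midline — is a synthetic stand-in chosen
#' for observability of the 57-DOF inverse kinematics, not a clinical
#' protocol.
#'
#' @param params a [geometry_params()] object.
#' @param seed integer seed; the generator is fully deterministic given it.
#' @return list with `model` (a `spine_model`) and `truth` (the generating
#'   parameters, per-level tilts and shares).
#' @export
generate_spine_model <- function(params = geometry_params(), seed = 1) {
  stopifnot(inherits(params, "geometry_params"))
  with_seed(seed, generate_spine_model_impl(params, seed))
}

generate_spine_model_impl <- function(params, seed) {
  bodies <- spine_body_names()
  sev <- params$deformity_severity

  ## sagittal tilt of each vertebra (x rotation, deg); endplates are
  ## perpendicular to the body y axis so the superior-endplate inclination of
  ## a vertebra equals its tilt
  ss <- params$sacral_slope
  tilt <- numeric(17)                      # L5..L1, T12..T1
  tilt[1:5] <- ss - cumsum(LUMBAR_SHARES) * params$lumbar_lordosis
  tilt[6] <- tilt[5]                       # thoracolumbar transition
  tilt[7:17] <- tilt[6] + cumsum(thoracic_shares()) * params$thoracic_kyphosis

  ## coronal deformity: lateral offset and axial rotation along the curve
  s_frac <- seq_len(17) / 17
  lat <- sev * 25 * sin(pi * s_frac)
  axi <- sev * 5 * sin(pi * s_frac)
  cor <- sev * 8 * cos(pi * s_frac)

  ## pelvis: chain frame at the bicoxofemoral midpoint, identity orientation
  pt0 <- params$pelvic_tilt * DEG2RAD
  plate <- c(0, 110 * cos(pt0), -110 * sin(pt0))
  n_s <- c(0, cos(ss * DEG2RAD), sin(ss * DEG2RAD))   # plate normal
  t_s <- c(0, -sin(ss * DEG2RAD), cos(ss * DEG2RAD))  # plate anterior tangent
  pelvis_landmarks <- list(
    sacral_plate = plate,
    sacral_tip = plate + 10 * n_s,
    sacral_corner_ps = plate - 25 * t_s,
    hip_l = c(-90, 0, 0),
    hip_r = c(90, 0, 0))

  heights <- c(rep(params$lumbar_height, 5), rep(params$thoracic_height, 12))
  discs <- c(rep(params$lumbar_disc, 6), rep(params$thoracic_disc, 11))

  segments <- list()
  segments[["pelvis"]] <- list(
    name = "pelvis",
    pose = list(p = c(0, 0, 0), eul = c(0, 0, 0)),
    align = list(p = c(0, 0, 0), eul = c(0, 0, 0)),
    landmarks = pelvis_landmarks)

  centers <- matrix(0, 17, 3)
  prev_top <- plate
  prev_tilt <- ss
  for (i in seq_len(17)) {
    step0 <- discs[i] + heights[i] / 2
    step <- max(step0 + stats::rnorm(1, 0, params$height_jitter_sd), 0.5 * step0)
    dir_tilt <- (prev_tilt + tilt[i]) / 2 * DEG2RAD
    centers[i, ] <- prev_top + step * c(0, cos(dir_tilt), sin(dir_tilt))
    centers[i, 1] <- lat[i]
    h2 <- heights[i] / 2
    eul <- c(tilt[i], axi[i], cor[i])
    Rb <- eul_to_rot(eul)
    segments[[bodies[i + 1]]] <- list(
      name = bodies[i + 1],
      pose = list(p = centers[i, ], eul = eul),
      align = list(p = centers[i, ], eul = eul),
      landmarks = list(
        center = c(0, 0, 0),
        sup_center = c(0, h2, 0),
        sup_tip = c(0, h2 + 10, 0),
        inf_center = c(0, -h2, 0),
        inf_tip = c(0, -h2 - 10, 0)))
    prev_top <- centers[i, ] + as.numeric(Rb %*% c(0, h2, 0))
    prev_tilt <- tilt[i]
  }

  ## joints: midway between the adjacent endplates, orientation interpolated
  joints <- list()
  jnames <- spine_joint_names()
  for (i in seq_len(17)) {
    parent <- bodies[i]; child <- bodies[i + 1]
    ps <- segments[[parent]]
    pc <- segments[[child]]
    T_parent <- tf_pose(ps$pose$p, ps$pose$eul)
    T_child <- tf_pose(pc$pose$p, pc$pose$eul)
    top_parent <- if (i == 1) plate else
      tf_apply(T_parent, segments[[parent]]$landmarks$sup_center)
    bot_child <- tf_apply(T_child, pc$landmarks$inf_center)
    pos_g <- (top_parent + bot_child) / 2
    ## orientation midway between parent and child frames
    Rg <- mean_rotation(list(T_parent$R, T_child$R))
    jl <- tf_compose(tf_inv(T_parent), tf(Rg, pos_g))
    joints[[jnames[i]]] <- list(name = jnames[i], parent = parent,
                                child = child, pos = jl$p,
                                eul = rot_to_eul(jl$R))
  }

  ## markers: 4 pelvis + 17 spinous-process + 7 paraspinal (alternating side)
  markers <- list(
    RASIS = list(name = "RASIS", body = "pelvis", pos = c(110, 30, 70)),
    LASIS = list(name = "LASIS", body = "pelvis", pos = c(-110, 30, 70)),
    RPSIS = list(name = "RPSIS", body = "pelvis", pos = c(40, 60, -80)),
    LPSIS = list(name = "LPSIS", body = "pelvis", pos = c(-40, 60, -80)))
  ## spinous-process tips point caudally, so the markers sit below the body
  ## center — which also gives every level lateroflexion observability
  for (b in bodies[-1]) {
    depth <- if (startsWith(b, "L")) -45 else -38
    nm <- paste0("SP_", b)
    markers[[nm]] <- list(name = nm, body = b, pos = c(0, -18, depth))
  }
  para_levels <- c("L4", "L2", "T12", "T9", "T6", "T3", "T1")
  side <- rep(c(1, -1), length.out = 7)
  for (k in seq_along(para_levels)) {
    nm <- paste0("PS_", para_levels[k], if (side[k] > 0) "_R" else "_L")
    markers[[nm]] <- list(name = nm, body = para_levels[k],
                          pos = c(side[k] * 28, 0, -28))
  }

  model <- spine_model(segments, joints, markers)
  list(model = model,
       truth = list(params = params, tilt = tilt,
                    lumbar_shares = LUMBAR_SHARES,
                    thoracic_shares = thoracic_shares(), seed = seed))
}

#' Motion specification for a synthetic seated maximal trunk flexion
#'
#' The task emulated is a maximal forward trunk flexion from an upright
#' seated position: the pelvis rotates anteriorly about the hip axis while
#' the lumbar and thoracic joints flex, each following a smoothstep ramp.
#' Default amplitudes give spino-pelvic parameter ranges of motion in the
#' ranges observed for adult-spinal-deformity subjects performing this task
#' (LL and TK around 20 deg, pelvic tilt around 50 deg). Per-joint flexion
#' shares are lumbar-dominant, matching flexion physiology; the true
#' per-level distribution in deformity patients is unknown and this is a
#' documented modeling choice.
#'
#' @param n_frames number of frames (default 300, i.e. 3 s at 100 Hz).
#' @param rate sampling rate, Hz.
#' @param pelvis_rom anterior pelvis rotation amplitude, deg.
#' @param lumbar_rom summed flexion of the five lumbar joints, deg.
#' @param thoracolumbar_rom flexion at T12/L1, deg.
#' @param thoracic_rom summed flexion of the eleven thoracic joints, deg.
#' @param noise_sd i.i.d. Gaussian marker noise SD, mm (default 0.5 mm,
#'   typical optical-capture noise; marker-based systems are usually quoted
#'   at 1-5 mm error, so this is deliberately at the clean end).
#' @param jitter enable test-retest execution jitter (amplitude and timing).
#' @param rom_jitter_sd log-normal SD of per-session amplitude scaling.
#' @param timing_jitter_sd log-normal SD of the time-warp exponent.
#' @return list of class `motion_spec`.
#' @export
motion_spec <- function(n_frames = 300, rate = 100, pelvis_rom = 50,
                        lumbar_rom = 20, thoracolumbar_rom = 4,
                        thoracic_rom = 20, noise_sd = 0.5, jitter = FALSE,
                        rom_jitter_sd = 0.15, timing_jitter_sd = 0.1) {
  stopifnot(n_frames >= 2, rate > 0, noise_sd >= 0)
  structure(list(n_frames = n_frames, rate = rate, pelvis_rom = pelvis_rom,
                 lumbar_rom = lumbar_rom, thoracolumbar_rom = thoracolumbar_rom,
                 thoracic_rom = thoracic_rom, noise_sd = noise_sd,
                 jitter = jitter, rom_jitter_sd = rom_jitter_sd,
                 timing_jitter_sd = timing_jitter_sd),
            class = "motion_spec")
}

smoothstep <- function(s) s * s * (3 - 2 * s)

#' Generate a synthetic flexion trial with known ground truth
#'
#' Marker trajectories are the exact forward kinematics of a smooth
#' ground-truth joint-angle series plus i.i.d. Gaussian noise; with
#' `noise_sd = 0` they satisfy rigid-body invariance exactly, which makes the
#' trial a parameter-recovery oracle for the inverse-kinematics pipeline.
#' With `jitter = TRUE` the session's amplitudes and timing are randomly
#' rescaled, emulating the intrinsic execution variability that separates
#' test-retest from inter-operator reliability.
#'
#' @param model a `spine_model`.
#' @param spec a [motion_spec()].
#' @param seed integer seed.
#' @return list with `trial` (a `motion_trial`) and `truth` (list with
#'   `base` frames x 6, `angles` frames x 51, `time`, and the realized ROMs).
#' @export
generate_flexion_trial <- function(model, spec = motion_spec(), seed = 1) {
  stopifnot(inherits(spec, "motion_spec"))
  with_seed(seed, generate_flexion_trial_impl(model, spec))
}

generate_flexion_trial_impl <- function(model, spec) {
  n <- spec$n_frames
  tt <- (seq_len(n) - 1) / (n - 1)

  amp <- c(pelvis = spec$pelvis_rom, lumbar = spec$lumbar_rom,
           tl = spec$thoracolumbar_rom, thoracic = spec$thoracic_rom)
  gamma <- 1
  if (spec$jitter) {
    amp <- amp * exp(stats::rnorm(4, 0, spec$rom_jitter_sd))
    gamma <- exp(stats::rnorm(1, 0, spec$timing_jitter_sd))
  }
  s <- smoothstep(tt^gamma)

  shares51 <- numeric(51)
  fe_idx <- seq(1, 51, by = 3)
  shares51[fe_idx[1:5]] <- LUMBAR_SHARES * amp["lumbar"]
  shares51[fe_idx[6]] <- amp["tl"]
  shares51[fe_idx[7:17]] <- thoracic_shares() * amp["thoracic"]
  angles <- outer(s, shares51)

  base <- matrix(0, n, 6)
  base[, 4] <- amp["pelvis"] * s               # anterior rotation about hips
  base[, 2] <- -15 * s                          # slight seat sink
  base[, 3] <- 20 * s                           # slight anterior drift

  chain <- build_chain(model)
  data <- array(0, c(n, 28, 3))
  for (f in seq_len(n)) {
    data[f, , ] <- fk_chain(chain, base[f, ], angles[f, ])$markers
  }
  if (spec$noise_sd > 0) {
    data <- data + array(stats::rnorm(length(data), 0, spec$noise_sd), dim(data))
  }
  trial <- motion_trial(data, chain$marker_names, rate = spec$rate)
  list(trial = trial,
       truth = list(base = base, angles = angles, time = trial$time,
                    amplitudes = amp, timing_exponent = gamma))
}

#' Inter-operator variability specification
#'
#' Zero-mean Gaussian spreads (SD) for the operator-dependent parameter
#' groups, per direction. Defaults are calibrated in closed form so that
#' three emulated operators, measured against their average (baseline) model,
#' show median absolute deviations typical of radiograph-based model
#' reconstruction by trained operators: ~0.11-0.12 mm for virtual markers,
#' ~0.55-0.74 mm / 1.0-1.7 deg for body alignment, and ~0.57-1.06 mm /
#' 1.2-2.0 deg for intervertebral joint frames. For k operators the deviation
#' from their mean has SD sigma*sqrt((k-1)/k), so
#' sigma = median_abs / (qnorm(0.75) * sqrt(2/3)) for k = 3.
#'
#' @param marker_position,body_position,joint_position SD per direction, mm.
#' @param body_orientation,joint_orientation SD per direction, deg.
#' @return list of class `operator_variability_spec`.
#' @export
operator_variability_spec <- function(
    marker_position = c(0.112, 0.120, 0.120) / MEDIAN_ABS_FACTOR,
    body_position = c(0.672, 0.552, 0.739) / MEDIAN_ABS_FACTOR,
    body_orientation = c(1.19, 1.68, 0.96) / MEDIAN_ABS_FACTOR,
    joint_position = c(0.782, 0.566, 1.058) / MEDIAN_ABS_FACTOR,
    joint_orientation = c(1.65, 1.95, 1.16) / MEDIAN_ABS_FACTOR) {
  spec <- list(marker_position = marker_position,
               body_position = body_position,
               body_orientation = body_orientation,
               joint_position = joint_position,
               joint_orientation = joint_orientation)
  stopifnot(all(vapply(spec, length, 1L) == 3L), all(unlist(spec) >= 0))
  class(spec) <- "operator_variability_spec"
  spec
}

## median|N(0, s)| = s * qnorm(0.75); deviation of one of 3 operators from
## their mean has SD s * sqrt(2/3)
MEDIAN_ABS_FACTOR <- stats::qnorm(0.75) * sqrt(2 / 3)

## SD vector over the 294-entry layout for a variability spec
spec_sigma_vector <- function(model, spec) {
  layout <- parameter_layout(model)
  key <- paste(layout$component, layout$parameter, sep = "_")
  dir_idx <- match(layout$direction, c("x", "y", "z"))
  vapply(seq_len(294L), function(i) spec[[key[i]]][dir_idx[i]], numeric(1))
}

#' Emulate independent operators building the same subject's model
#'
#' Each emulated operator is the input model with an independent zero-mean
#' Gaussian perturbation of all 294 operator-dependent parameters, drawn
#' from the per-group spreads of the variability specification.
#'
#' @param model the ground-truth `spine_model`.
#' @param spec an [operator_variability_spec()].
#' @param n_operators number of operator variants (>= 2; the study design
#'   uses 3).
#' @param seed integer seed; deterministic given it.
#' @return list of `n_operators` `spine_model`s.
#' @export
emulate_operators <- function(model, spec = operator_variability_spec(),
                              n_operators = 3, seed = 1) {
  stopifnot(inherits(spec, "operator_variability_spec"), n_operators >= 2)
  sigma <- spec_sigma_vector(model, spec)
  with_seed(seed, lapply(seq_len(n_operators), function(k) {
    apply_perturbation(model, stats::rnorm(294, 0, sigma))
  }))
}

## evaluate code under a given seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}
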