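#' Sagittal spino-pelvic parameters from body kinematics
#'
#' Computes the six conventional sagittal-plane (y-z) alignment parameters
#' per frame from anatomical landmarks identified a priori on the model:
#' \itemize{
#'   \item LL (deg): lumbar lordosis, angle between the sacral plate and the
#'     superior endplate of L1 (via their sagittal-plane normals; positive in
#'     lordosis).
#'   \item TK (deg): thoracic kyphosis, angle between the superior endplate
#'     of T1 and the inferior endplate of T12.
#'   \item SVA (cm): sagittal vertical axis, anterior (+z) offset of the T1
#'     body center from the posterior-superior corner of the sacral endplate.
#'   \item PT (deg): pelvic tilt, angle from vertical of the line from the
#'     bicoxofemoral midpoint to the sacral-plate center, positive posterior.
#'   \item T1_SPI, T9_SPI (deg): spino-pelvic inclination, angle from
#'     vertical of the line from the bicoxofemoral midpoint to the T1 / T9
#'     body center, positive anterior.
#' }
#' These are standard literature conventions; a cranial plumbline based on T1
#' is used for the SVA since the model's most cranial body is T1. Landmark
#' geometry follows each body's alignment pose, so spinal-alignment
#' (body-component) perturbations move these parameters while leaving the
#' intervertebral joint kinematics untouched.
#'
#' @param model a `spine_model`.
#' @param bodykin a `body_kinematics` object (see
#'   [joint_to_body_kinematics()]).
#' @return a `spino_pelvic_series`: `series` (frames x 6 matrix with columns
#'   LL, TK, SVA, PT, T1_SPI, T9_SPI), `rom` (named vector), `units`.
#' @export
compute_spino_pelvic <- function(model, bodykin) {
  stopifnot(inherits(bodykin, "body_kinematics"))
  n <- dim(bodykin$p)[3]
  bidx <- function(b) match(b, bodykin$bodies)

  ## landmark positions in each body's *chain* frame, folding in the
  ## alignment pose: lm_chain = chain_static^-1 o align o lm_local
  lm_chain <- function(body, lm) {
    s <- model$segments[[body]]
    T_corr <- tf_compose(tf_inv(tf_pose(s$pose$p, s$pose$eul)),
                         tf_pose(s$align$p, s$align$eul))
    tf_apply(T_corr, s$landmarks[[lm]])
  }
  lm_ground <- function(body, lm, f) {
    i <- bidx(body)
    as.numeric(bodykin$R[, , i, f] %*% lm_chain(body, lm)) + bodykin$p[, i, f]
  }
  ## sagittal inclination of a direction vector: atan2(z, y), deg
  incl <- function(v) atan2(v[3], v[2]) * RAD2DEG

  out <- matrix(NA_real_, n, 6,
                dimnames = list(NULL, c("LL", "TK", "SVA", "PT",
                                        "T1_SPI", "T9_SPI")))
  for (f in seq_len(n)) {
    sac_n <- lm_ground("pelvis", "sacral_tip", f) -
      lm_ground("pelvis", "sacral_plate", f)
    l1_n <- lm_ground("L1", "sup_tip", f) - lm_ground("L1", "sup_center", f)
    t1_n <- lm_ground("T1", "sup_tip", f) - lm_ground("T1", "sup_center", f)
    t12_n <- -(lm_ground("T12", "inf_tip", f) - lm_ground("T12", "inf_center", f))
    hip_mid <- (lm_ground("pelvis", "hip_l", f) +
                  lm_ground("pelvis", "hip_r", f)) / 2
    t1_c <- lm_ground("T1", "center", f)
    t9_c <- lm_ground("T9", "center", f)
    corner <- lm_ground("pelvis", "sacral_corner_ps", f)
    plate <- lm_ground("pelvis", "sacral_plate", f)

    out[f, "LL"] <- incl(sac_n) - incl(l1_n)
    out[f, "TK"] <- incl(t1_n) - incl(t12_n)
    out[f, "SVA"] <- (t1_c[3] - corner[3]) / 10
    v_pt <- plate - hip_mid
    out[f, "PT"] <- atan2(-v_pt[3], v_pt[2]) * RAD2DEG
    v1 <- t1_c - hip_mid
    out[f, "T1_SPI"] <- atan2(v1[3], v1[2]) * RAD2DEG
    v9 <- t9_c - hip_mid
    out[f, "T9_SPI"] <- atan2(v9[3], v9[2]) * RAD2DEG
  }
  structure(list(series = out, rom = rom(out),
                 units = c(LL = "deg", TK = "deg", SVA = "cm", PT = "deg",
                           T1_SPI = "deg", T9_SPI = "deg")),
            class = "spino_pelvic_series")
}

#' @export
print.spino_pelvic_series <- function(x, ...) {
  cat("<spino_pelvic_series>", nrow(x$series), "frames\n")
  cat("  ROM:", paste(sprintf("%s %.1f %s", names(x$rom), x$rom,
                              x$units[names(x$rom)]), collapse = ", "), "\n")
  invisible(x)
}

#' Full marker-to-parameter processing chain
#'
#' Convenience wrapper running the study's processing order: low-pass filter
#' the trial, solve inverse kinematics, time-normalize to 100 frames, smooth
#' with a three-frame moving average, convert to body kinematics and extract
#' the spino-pelvic parameter series and ROMs.
#'
#' @param model a `spine_model`.
#' @param trial a `motion_trial`.
#' @param cutoff_hz low-pass cutoff (default 6 Hz).
#' @param n_frames normalized frame count (default 100).
#' @param ma_width moving-average width (default 3).
#' @param ... passed to [solve_ik()].
#' @return list with `kinematics` (normalized, smoothed `joint_kinematics`),
#'   `raw_kinematics`, `spino_pelvic` (a `spino_pelvic_series`).
#' @export
run_pipeline <- function(model, trial, cutoff_hz = 6, n_frames = 100,
                         ma_width = 3, ...) {
  filtered <- lowpass_filter(trial, cutoff_hz)
  kin <- solve_ik(model, filtered, ...)
  norm <- normalize_kinematics(kin, n_frames)
  norm$angles <- moving_average(norm$angles, ma_width)
  norm$base <- moving_average(norm$base, ma_width)
  bodykin <- joint_to_body_kinematics(model, norm)
  sp <- compute_spino_pelvic(model, bodykin)
  list(kinematics = norm, raw_kinematics = kin, spino_pelvic = sp)
}
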