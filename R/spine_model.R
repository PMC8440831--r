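#' Canonical body, joint and angle-channel names of the spino-pelvic model
#'
#' The model is a serial chain of 18 rigid bodies — the pelvis (including the
#' sacrum) plus the five lumbar and twelve thoracic vertebrae — connected by
#' 17 spherical joints from L5/S1 up to T1/T2. Each joint carries three
#' rotational degrees of freedom: flexion-extension (FE, about x), axial
#' rotation (AR, about y) and lateroflexion (LF, about z), giving 51 reported
#' joint-angle channels; the pelvis additionally floats on a 6-DOF base joint
#' whose coordinates are solved but not reported.
#'
#' @return character vectors of names, caudal to cranial.
#' @export
spine_body_names <- function() {
  c("pelvis", paste0("L", 5:1), paste0("T", 12:1))
}

#' @rdname spine_body_names
#' @export
spine_joint_names <- function() {
  bodies <- spine_body_names()
  vapply(seq_len(17), function(i) {
    child <- bodies[i + 1L]
    parent <- if (i == 1L) "S1" else bodies[i]
    paste0(child, "_", parent)
  }, character(1))
}

#' @rdname spine_body_names
#' @export
spine_angle_channels <- function() {
  as.vector(t(outer(spine_joint_names(), c("FE", "AR", "LF"), paste, sep = "_")))
}

#' @rdname spine_body_names
#' @export
spine_base_channels <- function() {
  c("base_tx", "base_ty", "base_tz", "base_rx", "base_ry", "base_rz")
}

VERTEBRA_LANDMARKS <- c("center", "sup_center", "sup_tip", "inf_center", "inf_tip")
PELVIS_LANDMARKS <- c("sacral_plate", "sacral_tip", "sacral_corner_ps",
                      "hip_l", "hip_r")
MODEL_SCHEMA_VERSION <- "1.0"

#' Construct a spino-pelvic rigid-body model
#'
#' A `spine_model` holds, per body, a static chain pose in the ground frame
#' (the kinematic skeleton), an alignment pose carrying the landmark geometry,
#' and named anatomical landmarks in the body frame; per joint, its position
#' and orientation in the parent's chain frame; and 28 virtual markers with
#' positions in their attached body's chain frame. Ground frame: x
#' mediolateral, y inferosuperior, z posterior-anterior; millimetres and
#' degrees throughout.
#'
#' The chain pose and the alignment pose coincide in a freshly built model;
#' operator perturbations of the "body" component act on the alignment pose
#' only, so that spinal-alignment variability moves the landmark geometry
#' (and hence the spino-pelvic parameters) without touching the joint frames
#' that drive the inverse kinematics.
#'
#' @param segments named list of body segments; each has `name`, `pose`
#'   (`list(p, eul)`), `align` (`list(p, eul)`) and `landmarks` (named list of
#'   length-3 numerics).
#' @param joints named list of joints; each has `name`, `parent`, `child`,
#'   `pos` and `eul` (in the parent chain frame).
#' @param markers named list of virtual markers; each has `name`, `body`,
#'   `pos` (body chain frame).
#' @param schema_version serialization schema version string.
#' @return an object of class `spine_model`.
#' @export
spine_model <- function(segments, joints, markers,
                        schema_version = MODEL_SCHEMA_VERSION) {
  m <- structure(
    list(segments = segments, joints = joints, markers = markers,
         schema_version = schema_version),
    class = "spine_model")
  validate_spine_model(m)
  m
}

#' Validate a spine model's structural invariants
#'
#' Checks the 18-body / 17-joint / 28-marker composition, unique names, the
#' single serial chain pelvis to T1, the completeness of the anatomical
#' landmark set used by the spino-pelvic parameter definitions, and that every
#' marker is attached to an existing body.
#'
#' @param m a `spine_model`.
#' @return `m`, invisibly; otherwise an error of class `spinemc_structural_error`.
#' @export
validate_spine_model <- function(m) {
  fail <- function(...) {
    stop(structure(class = c("spinemc_structural_error", "error", "condition"),
                   list(message = sprintf(...), call = sys.call(-1))))
  }
  bodies <- spine_body_names()
  if (!identical(sort(names(m$segments)), sort(bodies)) ||
      length(m$segments) != 18L)
    fail("model must contain exactly the 18 bodies pelvis, L5..L1, T12..T1")
  joints <- spine_joint_names()
  if (!identical(sort(names(m$joints)), sort(joints)))
    fail("model must contain exactly the 17 joints %s..%s", joints[1], joints[17])
  for (i in seq_along(joints)) {
    j <- m$joints[[joints[i]]]
    if (!identical(j$parent, bodies[i]) || !identical(j$child, bodies[i + 1L]))
      fail("joint %s must connect %s -> %s (single serial chain)",
           joints[i], bodies[i], bodies[i + 1L])
  }
  if (length(m$markers) != 28L)
    fail("model must have exactly 28 virtual markers, got %d", length(m$markers))
  if (anyDuplicated(names(m$markers)))
    fail("marker names must be unique")
  for (mk in m$markers) {
    if (!mk$body %in% bodies) fail("marker %s attached to unknown body %s",
                                   mk$name, mk$body)
  }
  for (b in bodies) {
    need <- if (b == "pelvis") PELVIS_LANDMARKS else VERTEBRA_LANDMARKS
    have <- names(m$segments[[b]]$landmarks)
    miss <- setdiff(need, have)
    if (length(miss))
      fail("body %s is missing landmark(s): %s", b, paste(miss, collapse = ", "))
  }
  invisible(m)
}

## Precompute the kinematic chain: joint local transforms (A), child body
## offsets in the joint frame at q = 0 (B), static poses, marker matrix with
## attachment indices and chain depth. Offsets are derived so that zero joint
## angles with an identity base pose reproduce the stored static chain poses.
build_chain <- function(model) {
  bodies <- spine_body_names()
  joints <- spine_joint_names()
  static <- lapply(bodies, function(b) {
    s <- model$segments[[b]]
    tf_pose(s$pose$p, s$pose$eul)
  })
  names(static) <- bodies
  A <- vector("list", 17L); B <- vector("list", 17L)
  for (i in seq_len(17L)) {
    j <- model$joints[[joints[i]]]
    A[[i]] <- tf_pose(j$pos, j$eul)
    j_static <- tf_compose(static[[j$parent]], A[[i]])
    B[[i]] <- tf_compose(tf_inv(j_static), static[[j$child]])
  }
  marker_names <- names(model$markers)
  marker_pos <- t(vapply(model$markers, function(mk) mk$pos, numeric(3)))
  marker_body <- vapply(model$markers, function(mk) match(mk$body, bodies),
                        integer(1))
  ## flat-array copies for the fast kinematics path
  static_R <- array(0, c(3, 3, 18)); static_p <- matrix(0, 3, 18)
  A_R <- array(0, c(3, 3, 17)); A_p <- matrix(0, 3, 17)
  B_R <- array(0, c(3, 3, 17)); B_p <- matrix(0, 3, 17)
  for (i in seq_len(18L)) {
    static_R[, , i] <- static[[i]]$R; static_p[, i] <- static[[i]]$p
  }
  for (i in seq_len(17L)) {
    A_R[, , i] <- A[[i]]$R; A_p[, i] <- A[[i]]$p
    B_R[, , i] <- B[[i]]$R; B_p[, i] <- B[[i]]$p
  }
  list(bodies = bodies, joints = joints, static = static, A = A, B = B,
       static_R = static_R, static_p = static_p,
       A_R = A_R, A_p = A_p, B_R = B_R, B_p = B_p,
       marker_names = marker_names, marker_pos = marker_pos,
       marker_body = marker_body,
       ## chain depth: pelvis = 0, L5 = 1, ..., T1 = 17; a marker is affected
       ## by joint k iff its body depth >= k
       marker_depth = marker_body - 1L)
}

#' Forward kinematics of the spino-pelvic chain
#'
#' Composes the 6-DOF base pose and the 17 spherical-joint rotations serially
#' from the pelvis to T1 using the body-fixed xyz Euler sequence, and maps the
#' virtual markers into the ground frame. The base pose is expressed relative
#' to the static model-building pose: an identity base pose with all joint
#' angles zero reproduces the static marker positions exactly.
#'
#' @param model a `spine_model`.
#' @param base_pose numeric length-6: translation (mm) then rotation (deg),
#'   applied as ground-frame translation and rotation about the ground origin.
#' @param joint_angles numeric length-51, degrees, ordered as
#'   [spine_angle_channels()].
#' @param chain optional precomputed chain from an earlier call (internal).
#' @return list with `body_R` (3x3x18), `body_p` (3x18), `markers` (28x3,
#'   ground, mm), `joint_R`, `joint_p` (joint frames in ground, for Jacobians).
#' @export
forward_kinematics <- function(model, base_pose = numeric(6),
                               joint_angles = numeric(51), chain = NULL) {
  if (is.null(chain)) chain <- build_chain(model)
  stopifnot(length(base_pose) == 6L, length(joint_angles) == 51L)
  fk_chain(chain, base_pose, joint_angles)
}

## fast path used by the IK loop: operates on the precomputed chain only.
## Plain-array arithmetic; avoid per-call validation and list transforms.
fk_chain <- function(chain, base_pose, joint_angles) {
  Rb <- rot_xyz(base_pose[4], base_pose[5], base_pose[6])
  body_R <- array(0, c(3, 3, 18)); body_p <- matrix(0, 3, 18)
  joint_R <- array(0, c(3, 3, 17)); joint_p <- matrix(0, 3, 17)
  pR <- Rb %*% chain$static_R[, , 1]
  pp <- Rb %*% chain$static_p[, 1] + base_pose[1:3]
  body_R[, , 1] <- pR; body_p[, 1] <- pp
  for (i in seq_len(17L)) {
    jR <- pR %*% chain$A_R[, , i]
    jp <- pR %*% chain$A_p[, i] + pp
    joint_R[, , i] <- jR; joint_p[, i] <- jp
    k <- 3L * i
    Q <- rot_xyz(joint_angles[k - 2L], joint_angles[k - 1L], joint_angles[k])
    jRQ <- jR %*% Q
    pR <- jRQ %*% chain$B_R[, , i]
    pp <- jRQ %*% chain$B_p[, i] + jp
    body_R[, , i + 1L] <- pR; body_p[, i + 1L] <- pp
  }
  n_mk <- nrow(chain$marker_pos)
  markers <- matrix(0, n_mk, 3, dimnames = list(chain$marker_names, c("x", "y", "z")))
  for (b in unique(chain$marker_body)) {
    idx <- chain$marker_body == b
    markers[idx, ] <- chain$marker_pos[idx, , drop = FALSE] %*%
      t(body_R[, , b]) + rep(body_p[, b], each = sum(idx))
  }
  list(body_R = body_R, body_p = body_p, markers = markers,
       joint_R = joint_R, joint_p = joint_p, bodies = chain$bodies)
}

#' Average a set of spine models into a baseline model
#'
#' Per-subject baseline construction: every position-valued field (marker
#' local positions, body chain/alignment positions, joint positions,
#' landmarks) is averaged arithmetically per direction, and every orientation
#' is averaged with the quaternion chordal mean ([mean_rotation()]). The
#' result is the reference ("baseline") model against which operator
#' deviations are measured.
#'
#' @param models list of >= 2 `spine_model`s with identical topology.
#' @return a `spine_model`.
#' @export
average_models <- function(models) {
  if (length(models) < 2L)
    stop("average_models() needs at least two models")
  ref <- models[[1]]
  for (m in models[-1]) check_same_topology(ref, m)
  avg_p <- function(get) Reduce(`+`, lapply(models, get)) / length(models)
  avg_eul <- function(get) {
    rot_to_eul(mean_rotation(lapply(models, function(m) eul_to_rot(get(m)))))
  }
  out <- ref
  for (b in names(ref$segments)) {
    out$segments[[b]]$pose$p <- avg_p(function(m) m$segments[[b]]$pose$p)
    out$segments[[b]]$pose$eul <- avg_eul(function(m) m$segments[[b]]$pose$eul)
    out$segments[[b]]$align$p <- avg_p(function(m) m$segments[[b]]$align$p)
    out$segments[[b]]$align$eul <- avg_eul(function(m) m$segments[[b]]$align$eul)
    for (lm in names(ref$segments[[b]]$landmarks)) {
      out$segments[[b]]$landmarks[[lm]] <-
        avg_p(function(m) m$segments[[b]]$landmarks[[lm]])
    }
  }
  for (j in names(ref$joints)) {
    out$joints[[j]]$pos <- avg_p(function(m) m$joints[[j]]$pos)
    out$joints[[j]]$eul <- avg_eul(function(m) m$joints[[j]]$eul)
  }
  for (k in names(ref$markers)) {
    out$markers[[k]]$pos <- avg_p(function(m) m$markers[[k]]$pos)
  }
  out
}

check_same_topology <- function(a, b) {
  ok <- identical(names(a$segments), names(b$segments)) &&
    identical(names(a$joints), names(b$joints)) &&
    identical(names(a$markers), names(b$markers)) &&
    all(vapply(names(a$segments), function(s) {
      identical(names(a$segments[[s]]$landmarks), names(b$segments[[s]]$landmarks))
    }, logical(1)))
  if (!ok)
    stop(structure(class = c("spinemc_structural_error", "error", "condition"),
                   list(message = "models differ in topology", call = sys.call(-1))))
  invisible(TRUE)
}

#' @export
print.spine_model <- function(x, ...) {
  cat("<spine_model> 18 bodies, 17 spherical joints, 28 virtual markers\n")
  cat("  schema_version:", x$schema_version, "\n")
  cat("  chain:", paste(spine_body_names()[c(1, 2, 18)], collapse = " .. "), "\n")
  invisible(x)
}
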