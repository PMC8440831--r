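#' Layout of the 294 operator-dependent model parameters
#'
#' The operator-dependent inputs of the modeling workflow form a fixed-length
#' vector: 28 virtual-marker positions (x, y, z; mm), 18 body positions (mm)
#' and orientations (deg), and 17 joint positions (mm) and orientations
#' (deg) — 28x3 + 18x6 + 17x6 = 294 scalars. The layout is a bijection onto
#' the model's operator inputs: marker-position block first, then
#' body-position, body-orientation, joint-position and joint-orientation
#' blocks, each ordered caudal to cranial and x, y, z within an element.
#'
#' @param model a `spine_model`; marker names are taken from it, the body
#'   and joint blocks follow the fixed chain topology.
#' @return data.frame with columns `component` (marker/body/joint),
#'   `element`, `parameter` (position/orientation), `direction` (x/y/z).
#' @export
parameter_layout <- function(model) {
  dirs <- c("x", "y", "z")
  blk <- function(component, elements, parameter) {
    data.frame(component = component,
               element = rep(elements, each = 3L),
               parameter = parameter,
               direction = rep(dirs, times = length(elements)),
               stringsAsFactors = FALSE)
  }
  layout <- rbind(
    blk("marker", names(model$markers), "position"),
    blk("body", spine_body_names(), "position"),
    blk("body", spine_body_names(), "orientation"),
    blk("joint", spine_joint_names(), "position"),
    blk("joint", spine_joint_names(), "orientation")
  )
  stopifnot(nrow(layout) == 294L)
  layout
}

#' Express a model as signed parameter deviations from a reference
#'
#' Computes the 294-entry deviation vector of `model` relative to
#' `reference`: marker deltas are local-position differences in the attached
#' body frame; body deltas are ground-frame alignment-position differences
#' and the body-fixed xyz Euler angles of the relative alignment rotation;
#' joint deltas likewise in the parent chain frame.
#' `apply_perturbation(reference, model_to_vector(model, reference))`
#' reproduces `model` (round-trip identity).
#'
#' @param model,reference `spine_model`s with identical topology.
#' @return numeric length-294 with a `layout` attribute (see
#'   [parameter_layout()]); class `parameter_vector`.
#' @export
model_to_vector <- function(model, reference) {
  check_same_topology(model, reference)
  v <- numeric(0)
  for (k in names(reference$markers)) {
    v <- c(v, model$markers[[k]]$pos - reference$markers[[k]]$pos)
  }
  for (b in spine_body_names()) {
    v <- c(v, model$segments[[b]]$align$p - reference$segments[[b]]$align$p)
  }
  for (b in spine_body_names()) {
    Rrel <- t(eul_to_rot(reference$segments[[b]]$align$eul)) %*%
      eul_to_rot(model$segments[[b]]$align$eul)
    v <- c(v, rot_to_eul(Rrel))
  }
  for (j in spine_joint_names()) {
    v <- c(v, model$joints[[j]]$pos - reference$joints[[j]]$pos)
  }
  for (j in spine_joint_names()) {
    Rrel <- t(eul_to_rot(reference$joints[[j]]$eul)) %*%
      eul_to_rot(model$joints[[j]]$eul)
    v <- c(v, rot_to_eul(Rrel))
  }
  structure(v, layout = parameter_layout(reference), class = "parameter_vector")
}

#' Apply a parameter perturbation to a model
#'
#' Adds a 294-entry deviation vector to a model's operator-dependent inputs.
#' Marker deltas displace the marker in its attached body's frame; joint
#' deltas move/re-orient the joint frame in the parent chain frame (the child
#' body's static pose is preserved — the perturbation relocates the centre
#' and axes of rotation, which changes the solved kinematics for any
#' non-neutral pose); body deltas act on the alignment pose only, relocating
#' the landmark geometry without touching joint frames or marker locals, so
#' intervertebral joint kinematics are invariant to them (isolation
#' contract).
#'
#' @param model a `spine_model`.
#' @param delta numeric length-294 in [parameter_layout()] order.
#' @return a new `spine_model`.
#' @export
apply_perturbation <- function(model, delta) {
  if (length(delta) != 294L)
    stop("delta must have exactly 294 entries, got ", length(delta))
  delta <- as.numeric(delta)
  out <- model
  i <- 0L
  take3 <- function() {
    i <<- i + 3L
    delta[(i - 2L):i]
  }
  for (k in names(model$markers)) {
    out$markers[[k]]$pos <- model$markers[[k]]$pos + take3()
  }
  for (b in spine_body_names()) {
    out$segments[[b]]$align$p <- model$segments[[b]]$align$p + take3()
  }
  for (b in spine_body_names()) {
    d <- take3()
    if (all(d == 0)) next  # exact no-op keeps the stored angles bit-identical
    R <- eul_to_rot(model$segments[[b]]$align$eul) %*% eul_to_rot(d)
    out$segments[[b]]$align$eul <- rot_to_eul(R)
  }
  for (j in spine_joint_names()) {
    out$joints[[j]]$pos <- model$joints[[j]]$pos + take3()
  }
  for (j in spine_joint_names()) {
    d <- take3()
    if (all(d == 0)) next
    R <- eul_to_rot(model$joints[[j]]$eul) %*% eul_to_rot(d)
    out$joints[[j]]$eul <- rot_to_eul(R)
  }
  out
}
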