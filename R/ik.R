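#' Solve marker-driven inverse kinematics of a flexion trial
#'
#' Per frame, finds the 6 base coordinates and 51 intervertebral joint angles
#' minimizing the weighted least-squares marker tracking cost
#' \deqn{\sum_i w_i \| x_i^{obs} - x_i^{model}(q) \|^2}
#' (plus a small pose-prior term, see below) over the 57-DOF generalized
#' coordinates, with an analytic Jacobian and an adaptive Levenberg-Marquardt
#' iteration. Frame 1 starts from the static model pose (or a supplied warm
#' start, e.g. a baseline solution in the Monte-Carlo loop); subsequent
#' frames are warm-started from the previous frame. Only cost-decreasing
#' steps are accepted, so the objective is non-increasing within each frame.
#'
#' @param model a `spine_model` whose marker names match the trial.
#' @param trial a `motion_trial`.
#' @param weights per-marker tracking weights (named or positional, length
#'   28); defaults to uniform. Weights are normalized to mean 1, so the
#'   solution is invariant to their overall scale.
#' @param init optional warm start: numeric length-57 (base then angles) or a
#'   `frames x 57` matrix.
#' @param damping floor of the adaptive Levenberg damping on the normal
#'   equations (raised tenfold on rejected steps, lowered on accepted ones).
#' @param pose_prior weight of a small quadratic prior pulling each frame's
#'   solution toward its warm start (the previous frame). This is the damped
#'   least-squares resolution of the near-redundant DOFs: with roughly one
#'   marker per vertebra, one rotational direction per level is only weakly
#'   observed through the chain, and the prior keeps those directions from
#'   drifting while leaving well-observed DOFs essentially untouched (the
#'   marker term dominates by 3-5 orders of magnitude).
#' @param tol relative cost-change convergence tolerance per frame.
#' @param max_iter iteration cap per frame; frames hitting it are flagged.
#' @param max_flagged_frac error if more than this fraction of frames flag.
#' @return a `joint_kinematics` object: `angles` (frames x 51, deg), `base`
#'   (frames x 6), `residual_rms` (mm, per frame), `flagged`, `time`, `rate`.
#' @export
solve_ik <- function(model, trial, weights = NULL, init = NULL,
                     damping = 1e-6, pose_prior = 0.3, tol = 1e-8,
                     max_iter = 200, max_flagged_frac = 0.05) {
  chain <- build_chain(model)
  if (!setequal(trial$marker_names, chain$marker_names))
    stop("trial marker names do not match the model's marker set")
  ## order trial columns as the model orders markers
  perm <- match(chain$marker_names, trial$marker_names)

  if (is.null(weights)) weights <- rep(1, 28)
  if (!is.null(names(weights))) weights <- weights[chain$marker_names]
  stopifnot(length(weights) == 28L, all(weights > 0))
  weights <- weights / mean(weights)

  n <- dim(trial$data)[1]
  q <- matrix(0, n, 57L)
  if (!is.null(init)) {
    if (is.null(dim(init))) {
      q[1, ] <- init
      init <- NULL
    } else {
      stopifnot(nrow(init) == n, ncol(init) == 57L)
    }
  }
  residual_rms <- numeric(n)
  flagged <- logical(n)
  cost_trace <- vector("list", n)
  for (f in seq_len(n)) {
    obs <- trial$data[f, perm, , drop = TRUE]
    miss <- trial$mask[f, perm]
    ## warm start / prior centre: supplied per-frame starts, else a
    ## constant-velocity extrapolation of the two previous solutions (which
    ## keeps the pose-prior lag second order in the frame step)
    q0 <- if (!is.null(init)) init[f, ]
      else if (f == 1L) q[1, ]
      else if (f == 2L) q[1, ]
      else 2 * q[f - 1L, ] - q[f - 2L, ]
    sol <- ik_frame(chain, obs, miss, weights, q0, damping, tol, max_iter,
                    pose_prior)
    q[f, ] <- sol$q
    residual_rms[f] <- sol$rms
    flagged[f] <- !sol$converged
    cost_trace[[f]] <- sol$costs
  }
  if (mean(flagged) > max_flagged_frac)
    stop(sprintf("inverse kinematics failed to converge on %.1f%% of frames",
                 100 * mean(flagged)))
  out <- new_joint_kinematics(angles = q[, 7:57, drop = FALSE],
                              base = q[, 1:6, drop = FALSE],
                              residual_rms = residual_rms, flagged = flagged,
                              time = trial$time, rate = trial$rate)
  out$cost_trace <- cost_trace
  out
}

new_joint_kinematics <- function(angles, base, residual_rms = NULL,
                                 flagged = NULL, time = NULL, rate = NULL,
                                 normalized = FALSE) {
  colnames(angles) <- spine_angle_channels()
  colnames(base) <- spine_base_channels()
  structure(list(angles = angles, base = base, residual_rms = residual_rms,
                 flagged = flagged, time = time, rate = rate,
                 normalized = normalized),
            class = "joint_kinematics")
}

#' @export
print.joint_kinematics <- function(x, ...) {
  cat(sprintf("<joint_kinematics> %d frames x 51 joint-angle channels (+6 base)%s\n",
              nrow(x$angles), if (x$normalized) ", time-normalized" else ""))
  if (!is.null(x$residual_rms))
    cat(sprintf("  marker residual RMS: median %.4g mm, max %.4g mm\n",
                stats::median(x$residual_rms), max(x$residual_rms)))
  invisible(x)
}

## vectorized cross product a x P for a length-3 a and an n x 3 matrix P
cross_rows <- function(a, P) {
  cbind(a[2] * P[, 3] - a[3] * P[, 2],
        a[3] * P[, 1] - a[1] * P[, 3],
        a[1] * P[, 2] - a[2] * P[, 1])
}

## single-frame Levenberg-Marquardt solve: the damping parameter is adapted
## (up on rejected steps, down on accepted ones, never below the configured
## floor), which keeps the weakly observed axial rotations well conditioned
## while preserving Gauss-Newton convergence near the optimum. The cost is
## non-increasing by construction (only improving steps are accepted).
ik_frame <- function(chain, obs, miss, weights, q0, damping, tol, max_iter,
                     pose_prior = 1e-3) {
  use <- !miss & !apply(is.na(obs), 1, any)
  if (!any(use)) stop("frame has no valid marker samples")
  w3 <- rep(weights[use], each = 3L)
  q <- q0
  frame_cost <- function(qv, fkv) {
    resv <- as.vector(t(obs[use, , drop = FALSE] -
                          fkv$markers[use, , drop = FALSE]))
    list(res = resv,
         cost = sum(w3 * resv^2) + pose_prior * sum((qv - q0)^2))
  }
  fk <- fk_chain(chain, q[1:6], q[7:57])
  cc <- frame_cost(q, fk)
  res <- cc$res; cost <- cc$cost
  costs <- cost
  converged <- FALSE
  lambda <- max(damping, 1e-3)
  for (it in seq_len(max_iter)) {
    J <- ik_jacobian(chain, fk, q, use)
    H <- crossprod(J, w3 * J)
    diag(H) <- diag(H) + pose_prior
    g <- crossprod(J, w3 * res) + pose_prior * (q0 - q)
    accepted <- FALSE
    for (try in 1:10) {
      Hl <- H
      diag(Hl) <- diag(Hl) + lambda
      step <- tryCatch(as.numeric(solve(Hl, g)), error = function(e) NULL)
      if (!is.null(step)) {
        q_new <- q + step
        fk_new <- fk_chain(chain, q_new[1:6], q_new[7:57])
        cc_new <- frame_cost(q_new, fk_new)
        if (cc_new$cost <= cost) { accepted <- TRUE; break }
      }
      lambda <- lambda * 10
    }
    if (!accepted) { converged <- TRUE; break }  # no improving step exists
    lambda <- max(lambda / 10, damping)
    improved <- (cost - cc_new$cost) / max(cost, .Machine$double.eps)
    q <- q_new; fk <- fk_new; res <- cc_new$res; cost <- cc_new$cost
    costs <- c(costs, cost)
    if (improved < tol || cost < 1e-16) { converged <- TRUE; break }
  }
  err <- matrix(res, ncol = 3, byrow = TRUE)
  list(q = q, cost = cost, costs = costs,
       rms = sqrt(mean(rowSums(err^2))),
       converged = converged || max_iter == 0L)
}

## analytic Jacobian of marker residuals (-d marker / d q), rows ordered
## marker-major (x, y, z per marker), columns = 6 base + 51 joint DOFs.
## Rotational columns are in degrees. Signs: J columns are +d marker/d q so
## that solving J step = residual moves markers toward the observations.
ik_jacobian <- function(chain, fk, q, use) {
  mk <- fk$markers[use, , drop = FALSE]
  depth <- chain$marker_depth[use]
  nm <- nrow(mk)
  ## rows are marker-major coordinate triplets; assemble as a 3 x nm x 57
  ## array (coordinate fastest) and flatten at the end
  Jarr <- array(0, c(3L, nm, 57L))
  Jarr[1L, , 1L] <- 1; Jarr[2L, , 2L] <- 1; Jarr[3L, , 3L] <- 1
  ## base rotation: intrinsic xyz axes about the ground origin
  a <- q[4] * DEG2RAD; b <- q[5] * DEG2RAD
  ca <- cos(a); sa <- sin(a); cb <- cos(b); sb <- sin(b)
  axes_base <- list(c(1, 0, 0), c(0, ca, sa),
                    c(sb, -sa * cb, ca * cb))
  rel <- mk - rep(q[1:3], each = nm)
  for (k in 1:3) {
    Jarr[, , 3L + k] <- t(cross_rows(axes_base[[k]], rel)) * DEG2RAD
  }
  ## joint rotations: markers at depth >= j move with joint j
  for (j in seq_len(17L)) {
    sel <- depth >= j
    if (!any(sel)) next
    Rj <- fk$joint_R[, , j]
    a <- q[6L + 3L * j - 2L] * DEG2RAD; b <- q[6L + 3L * j - 1L] * DEG2RAD
    ca <- cos(a); sa <- sin(a); cb <- cos(b); sb <- sin(b)
    ## local axes of the intrinsic xyz sequence, mapped to ground
    axes <- list(Rj[, 1],
                 as.numeric(Rj %*% c(0, ca, sa)),
                 as.numeric(Rj %*% c(sb, -sa * cb, ca * cb)))
    nsel <- sum(sel)
    relj <- mk[sel, , drop = FALSE] - rep(fk$joint_p[, j], each = nsel)
    col <- 6L + 3L * (j - 1L)
    for (k in 1:3) {
      Jarr[, sel, col + k] <- t(cross_rows(axes[[k]], relj)) * DEG2RAD
    }
  }
  dim(Jarr) <- c(3L * nm, 57L)
  Jarr
}

#' Convert joint kinematics to absolute body kinematics
#'
#' Serially composes the solved base pose and joint rotations into per-frame
#' poses of every body in the ground reference frame; identical to running
#' [forward_kinematics()] frame by frame.
#'
#' @param model a `spine_model`.
#' @param series a `joint_kinematics` object.
#' @return a `body_kinematics` object: `R` (3 x 3 x 18 x frames), `p`
#'   (3 x 18 x frames), `bodies`, `markers` (frames x 28 x 3).
#' @export
joint_to_body_kinematics <- function(model, series) {
  stopifnot(inherits(series, "joint_kinematics"))
  chain <- build_chain(model)
  n <- nrow(series$angles)
  R <- array(0, c(3, 3, 18, n)); p <- array(0, c(3, 18, n))
  markers <- array(0, c(n, 28, 3))
  for (f in seq_len(n)) {
    fk <- fk_chain(chain, series$base[f, ], series$angles[f, ])
    R[, , , f] <- fk$body_R; p[, , f] <- fk$body_p
    markers[f, , ] <- fk$markers
  }
  structure(list(R = R, p = p, bodies = chain$bodies, markers = markers,
                 marker_names = chain$marker_names, time = series$time),
            class = "body_kinematics")
}

#' Time-normalize a joint-kinematics series to 100 frames
#'
#' @param series a `joint_kinematics` object.
#' @param n_frames output frames (default 100).
#' @return a normalized `joint_kinematics` object.
#' @export
normalize_kinematics <- function(series, n_frames = 100) {
  stopifnot(inherits(series, "joint_kinematics"))
  new_joint_kinematics(
    angles = time_normalize(series$angles, n_frames),
    base = time_normalize(series$base, n_frames),
    residual_rms = if (!is.null(series$residual_rms))
      as.numeric(time_normalize(series$residual_rms, n_frames)),
    time = seq(0, 100, length.out = n_frames),
    rate = NULL, normalized = TRUE)
}
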