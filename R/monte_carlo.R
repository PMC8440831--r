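#' Pool operator-parameter deviations across levels and subjects
#'
#' For every subject, each operator-built model is expressed as a signed
#' 294-entry deviation vector from the subject's baseline (average) model;
#' the deviations are then pooled over all vertebral levels and subjects and
#' separated by component (marker/body/joint), parameter
#' (position/orientation) and direction (x/y/z), giving the 15 groups from
#' which the perturbation distributions are estimated (markers carry
#' positions only).
#'
#' @param operator_models list (one entry per subject) of lists of
#'   `spine_model`s (>= 2 operators per subject).
#' @param baselines list of baseline `spine_model`s, one per subject,
#'   typically from [average_models()].
#' @return a `deviation_pool` data.frame with columns `subject`, `operator`,
#'   `component`, `element`, `parameter`, `direction`, `value`.
#' @export
pool_deviations <- function(operator_models, baselines) {
  stopifnot(length(operator_models) == length(baselines))
  rows <- list()
  for (s in seq_along(operator_models)) {
    ops <- operator_models[[s]]
    if (length(ops) < 2L)
      stop("each subject needs >= 2 operator models")
    for (o in seq_along(ops)) {
      v <- model_to_vector(ops[[o]], baselines[[s]])
      layout <- attr(v, "layout")
      rows[[length(rows) + 1L]] <- data.frame(
        subject = s, operator = o, layout, value = as.numeric(v),
        stringsAsFactors = FALSE)
    }
  }
  structure(do.call(rbind, rows), class = c("deviation_pool", "data.frame"))
}

group_key <- function(component, parameter, direction) {
  paste(component, parameter, direction, sep = ".")
}

#' Summarize pooled operator deviations
#'
#' Median and maximum of the absolute deviations per component / parameter /
#' direction group, plus — for the virtual markers — the median and maximum
#' 3D Euclidean displacement per marker. This is the conventional summary of
#' operator-dependent input variability.
#'
#' @param pool a `deviation_pool`.
#' @return list with `by_group` (data.frame: component, parameter,
#'   direction, median_abs, max_abs, n) and `marker_3d` (median and max
#'   Euclidean distance, mm).
#' @export
summarize_deviations <- function(pool) {
  stopifnot(inherits(pool, "deviation_pool"), nrow(pool) > 0)
  key <- group_key(pool$component, pool$parameter, pool$direction)
  groups <- split(abs(pool$value), key)
  by_group <- do.call(rbind, lapply(names(groups), function(k) {
    parts <- strsplit(k, ".", fixed = TRUE)[[1]]
    data.frame(component = parts[1], parameter = parts[2],
               direction = parts[3],
               median_abs = stats::median(groups[[k]]),
               max_abs = max(groups[[k]]), n = length(groups[[k]]),
               stringsAsFactors = FALSE)
  }))
  mk <- pool[pool$component == "marker", ]
  d3 <- vapply(split(mk$value,
                     paste(mk$subject, mk$operator, mk$element)),
               function(v) sqrt(sum(v^2)), numeric(1))
  list(by_group = by_group,
       marker_3d = c(median = stats::median(d3), max = max(d3)))
}

#' Fit kernel-density perturbation distributions to pooled deviations
#'
#' One Gaussian-kernel density estimate per pooled group, fitted on the
#' signed deviations (perturbations must be able to go in both directions;
#' absolute values are used only for summaries). Bandwidths follow
#' Silverman's rule of thumb with a small floor so that degenerate
#' (all-identical) groups still yield a valid sampler. Sampling draws a
#' source deviation uniformly and adds kernel noise, which is exactly a draw
#' from the KDE.
#'
#' @param pool a `deviation_pool`; every group needs at least `min_samples`
#'   deviations.
#' @param min_samples minimum pooled sample count per group (default 5).
#' @param bw_floor bandwidth floor (mm or deg).
#' @return a `perturbation_distributions` object.
#' @export
fit_kde <- function(pool, min_samples = 5, bw_floor = 1e-8) {
  stopifnot(inherits(pool, "deviation_pool"))
  key <- group_key(pool$component, pool$parameter, pool$direction)
  groups <- split(pool$value, key)
  if (length(groups) != 15L)
    stop("deviation pool must cover all 15 component/parameter/direction groups")
  small <- names(groups)[vapply(groups, length, 1L) < min_samples]
  if (length(small))
    stop("too few pooled samples in group(s) ", paste(small, collapse = ", "),
         "; supply spreads directly via perturbation_distributions()")
  samplers <- lapply(groups, function(v) {
    ## Silverman rule; degenerate (zero-spread) groups fall back to the
    ## floor rather than bw.nrd0's unit-scale fallback
    bw <- if (stats::sd(v) == 0) 0 else
      tryCatch(stats::bw.nrd0(v), error = function(e) 0)
    list(type = "kde", samples = v, bw = max(bw, bw_floor), n = length(v))
  })
  structure(list(samplers = samplers), class = "perturbation_distributions")
}

#' Gaussian perturbation distributions from explicit spreads
#'
#' Alternative to [fit_kde()] when no operator models are available: zero-mean
#' Gaussian samplers with the per-group SDs of an
#' [operator_variability_spec()]. A spread of zero gives a degenerate sampler
#' that always returns zero.
#'
#' @param spec an [operator_variability_spec()].
#' @return a `perturbation_distributions` object.
#' @export
perturbation_distributions <- function(spec = operator_variability_spec()) {
  stopifnot(inherits(spec, "operator_variability_spec"))
  combos <- expand.grid(direction = c("x", "y", "z"),
                        parameter = c("position", "orientation"),
                        component = c("marker", "body", "joint"),
                        stringsAsFactors = FALSE)
  combos <- combos[!(combos$component == "marker" &
                       combos$parameter == "orientation"), ]
  samplers <- list()
  for (i in seq_len(nrow(combos))) {
    cmp <- combos$component[i]; par <- combos$parameter[i]
    dir <- combos$direction[i]
    sdv <- spec[[paste(cmp, par, sep = "_")]][match(dir, c("x", "y", "z"))]
    samplers[[group_key(cmp, par, dir)]] <- list(type = "gaussian", sd = sdv)
  }
  structure(list(samplers = samplers), class = "perturbation_distributions")
}

#' @export
print.perturbation_distributions <- function(x, ...) {
  cat("<perturbation_distributions>", length(x$samplers), "group samplers\n")
  for (k in names(x$samplers)) {
    s <- x$samplers[[k]]
    if (s$type == "kde")
      cat(sprintf("  %-26s kde, n = %d, bw = %.4g\n", k, s$n, s$bw))
    else
      cat(sprintf("  %-26s gaussian, sd = %.4g\n", k, s$sd))
  }
  invisible(x)
}

#' Draw one 294-entry perturbation vector
#'
#' One independent draw per scalar parameter from its group's sampler, in
#' [parameter_layout()] order. Consumes the current RNG stream.
#'
#' @param dists a `perturbation_distributions` object.
#' @param model the model defining the layout.
#' @return numeric length-294.
#' @export
draw_perturbation <- function(dists, model) {
  layout <- parameter_layout(model)
  key <- group_key(layout$component, layout$parameter, layout$direction)
  out <- numeric(294L)
  ## iterate groups in fixed layout-appearance order for a reproducible
  ## consumption of the RNG stream
  for (k in unique(key)) {
    idx <- which(key == k)
    s <- dists$samplers[[k]]
    if (is.null(s)) stop("no sampler for group ", k)
    out[idx] <- if (s$type == "kde") {
      s$samples[sample.int(s$n, length(idx), replace = TRUE)] +
        stats::rnorm(length(idx), 0, s$bw)
    } else {
      if (s$sd == 0) rep(0, length(idx)) else stats::rnorm(length(idx), 0, s$sd)
    }
  }
  out
}

#' Monte-Carlo simulation settings
#'
#' @param max_iter iteration cap (the full-scale analysis converges around a
#'   thousand iterations; scaled-down runs use a few hundred).
#' @param min_iter iterations before convergence checking starts.
#' @param window_frac convergence window as a fraction of the iterations.
#' @param tol relative tolerance of the convergence criterion.
#' @param abs_tol absolute tolerance replacing the relative test for output
#'   variables whose final value is below `near_zero` (deg) — the relative
#'   criterion is ill-posed at zero.
#' @param near_zero threshold (deg) below which `abs_tol` applies.
#' @param seed integer seed governing every random draw of the run.
#' @param n_norm_frames normalized time base (default 100).
#' @param ma_width moving-average width applied to normalized curves.
#' @return list of class `mc_settings`.
#' @export
mc_settings <- function(max_iter = 300, min_iter = 100, window_frac = 0.1,
                        tol = 0.02, abs_tol = 0.01, near_zero = 0.5,
                        seed = 1, n_norm_frames = 100, ma_width = 3) {
  stopifnot(max_iter >= 1, min_iter >= 2, window_frac > 0, window_frac <= 1,
            tol > 0, abs_tol > 0)
  structure(list(max_iter = max_iter, min_iter = min_iter,
                 window_frac = window_frac, tol = tol, abs_tol = abs_tol,
                 near_zero = near_zero, seed = seed,
                 n_norm_frames = n_norm_frames, ma_width = ma_width),
            class = "mc_settings")
}

## convergence criterion at a single candidate n (shared by the scanning
## check and the Monte-Carlo loop): every running mean and SD over the last
## window must be within tolerance of the value at n, for every variable
converged_at <- function(cmean, csd, n, window_frac, tol, abs_tol, near_zero) {
  w <- ceiling(window_frac * n)
  idx <- seq.int(max(2L, n - w + 1L), n)
  ok_stat <- function(running, final) {
    tolv <- ifelse(abs(final) < near_zero, abs_tol, tol * abs(final))
    all(abs(sweep(running, 2, final)) <= rep(tolv, each = nrow(running)))
  }
  ok_stat(cmean[idx, , drop = FALSE], cmean[n, ]) &&
    ok_stat(csd[idx, , drop = FALSE], csd[n, ])
}

running_stats <- function(history) {
  n <- nrow(history)
  cs <- apply(history, 2, cumsum)
  cs2 <- apply(history^2, 2, cumsum)
  i <- seq_len(n)
  cmean <- cs / i
  var <- (cs2 - cs^2 / i) / pmax(i - 1, 1)
  csd <- sqrt(pmax(var, 0))
  csd[1, ] <- NA_real_
  list(cmean = cmean, csd = csd)
}

#' First iteration at which a Monte-Carlo history has converged
#'
#' The convergence criterion: at candidate n, the running mean and running
#' standard deviation of every output variable (the motion-averaged joint
#' angles, one per DOF), evaluated over the last `window_frac` of the
#' iterations, must all be within `tol` (relative; `abs_tol` absolute for
#' near-zero variables) of their values at n.
#'
#' @param history numeric matrix, iterations x output variables.
#' @inheritParams mc_settings
#' @return the first converged iteration count, or `NA_integer_` if the
#'   history never converges (or is shorter than `min_iter`).
#' @export
check_convergence <- function(history, window_frac = 0.1, tol = 0.02,
                              min_iter = 100, abs_tol = 0.01,
                              near_zero = 0.5) {
  if (is.null(dim(history))) history <- matrix(history, ncol = 1L)
  n <- nrow(history)
  start <- max(min_iter, 3L)
  if (n < start) return(NA_integer_)
  rs <- running_stats(history)
  for (cand in start:n) {
    if (converged_at(rs$cmean, rs$csd, cand, window_frac, tol, abs_tol,
                     near_zero))
      return(cand)
  }
  NA_integer_
}

#' Run the Monte-Carlo probabilistic simulation
#'
#' Repeatedly perturbs the baseline model with statistically probable
#' operator-error combinations (one draw per operator-dependent parameter
#' from its group's distribution), re-runs the inverse kinematics of the
#' trial for each perturbed model, time-normalizes and smooths the joint
#' angles, and expresses them relative to the baseline solution. Iterations
#' stop at the first n satisfying the convergence criterion (or at
#' `max_iter`). The result carries the per-iteration draws and relative
#' curves, the convergence trace, 5-95% confidence bands, box statistics at
#' the time of maximal variance, and the 294 x 51 sensitivity-factor matrix.
#'
#' Fully reproducible: identical settings (including the seed) give
#' identical results.
#'
#' @param baseline the baseline `spine_model` (see [average_models()]).
#' @param dists a `perturbation_distributions` object.
#' @param trial a `motion_trial` (filter it beforehand if desired).
#' @param settings an [mc_settings()] object.
#' @param weights optional IK marker weights.
#' @param ... further arguments to [solve_ik()] (e.g. `pose_prior`).
#' @return a `monte_carlo_result` object.
#' @export
run_monte_carlo <- function(baseline, dists, trial, settings = mc_settings(),
                            weights = NULL, ...) {
  stopifnot(inherits(dists, "perturbation_distributions"),
            inherits(settings, "mc_settings"))
  ## solve the baseline twice: a frame-to-frame pass to obtain the warm-start
  ## matrix, then a re-solve under exactly the per-frame warm starts used for
  ## every perturbed iteration. This makes the baseline the fixed point of
  ## the iteration protocol, so a zero perturbation reproduces it bit for bit
  ## and the relative curves measure only the imposed model error.
  base_pass1 <- solve_ik(baseline, trial, weights = weights, ...)
  warm <- cbind(base_pass1$base, base_pass1$angles)
  base_kin <- solve_ik(baseline, trial, weights = weights, init = warm, ...)
  base_norm <- normalize_kinematics(base_kin, settings$n_norm_frames)
  base_curves <- moving_average(base_norm$angles, settings$ma_width)

  nf <- settings$n_norm_frames
  max_iter <- settings$max_iter
  draws <- matrix(NA_real_, max_iter, 294L)
  curves <- array(NA_real_, c(max_iter, 51L, nf))
  outvars <- matrix(NA_real_, max_iter, 51L)
  n_fail <- 0L
  converged_n <- NA_integer_

  with_seed(settings$seed, {
    n <- 0L
    for (it in seq_len(max_iter)) {
      delta <- draw_perturbation(dists, baseline)
      kin <- tryCatch(
        solve_ik(apply_perturbation(baseline, delta), trial,
                 weights = weights, init = warm, ...),
        error = function(e) e)
      if (inherits(kin, "error")) {
        n_fail <- n_fail + 1L
        if (n_fail > 0.05 * it)
          stop("Monte-Carlo aborted: >5% of iterations failed in IK (",
               conditionMessage(kin), ")")
        next
      }
      n <- n + 1L
      ang <- moving_average(
        time_normalize(kin$angles, nf), settings$ma_width)
      draws[n, ] <- delta
      curves[n, , ] <- t(ang - base_curves)
      outvars[n, ] <- colMeans(ang)
      if (n >= settings$min_iter) {
        rs <- running_stats(outvars[seq_len(n), , drop = FALSE])
        if (converged_at(rs$cmean, rs$csd, n, settings$window_frac,
                         settings$tol, settings$abs_tol, settings$near_zero)) {
          converged_n <- n
          break
        }
      }
    }
  })

  n_used <- sum(!is.na(outvars[, 1]))
  draws <- draws[seq_len(n_used), , drop = FALSE]
  curves <- curves[seq_len(n_used), , , drop = FALSE]
  outvars <- outvars[seq_len(n_used), , drop = FALSE]
  colnames(outvars) <- spine_angle_channels()
  rs <- running_stats(outvars)

  bands <- confidence_bands(curves)
  tstats <- t_sigma_max_stats(curves)
  sens <- sensitivity_factors(draws, curves)
  structure(list(n = n_used, converged_n = converged_n, n_failed = n_fail,
                 draws = draws, curves = curves, outvars = outvars,
                 convergence_trace = rs, bands = bands,
                 t_sigma_max = tstats, sensitivity = sens,
                 baseline_curves = base_curves, baseline_warm = warm,
                 settings = settings),
            class = "monte_carlo_result")
}

#' @export
print.monte_carlo_result <- function(x, ...) {
  cat("<monte_carlo_result>", x$n, "iterations",
      if (!is.na(x$converged_n)) sprintf("(converged at n = %d)", x$converged_n)
      else "(not converged)", "\n")
  cat(sprintf("  mean 90%%-CI width at t_sigma_max: %.3f deg, max: %.3f deg\n",
              mean(x$t_sigma_max$ci_width), max(x$t_sigma_max$ci_width)))
  invisible(x)
}

#' Pointwise 5-95% confidence bands of relative joint-angle curves
#'
#' The 5th and 95th percentiles across iterations, per DOF and per
#' normalized time frame (linear interpolation between order statistics). By
#' construction at least 90% of the iterations lie inside the band at every
#' frame, up to one sample due to percentile interpolation.
#'
#' @param curves numeric array, iterations x 51 x frames.
#' @param probs the two band probabilities (default `c(0.05, 0.95)`).
#' @return list with `low`, `high`, `width` (51 x frames matrices).
#' @export
confidence_bands <- function(curves, probs = c(0.05, 0.95)) {
  stopifnot(length(dim(curves)) == 3L)
  qs <- apply(curves, c(2, 3), stats::quantile, probs = probs, names = FALSE)
  dn <- list(spine_angle_channels()[seq_len(dim(curves)[2])], NULL)
  low <- matrix(qs[1, , ], dim(curves)[2], dim(curves)[3], dimnames = dn)
  high <- matrix(qs[2, , ], dim(curves)[2], dim(curves)[3], dimnames = dn)
  list(low = low, high = high, width = high - low)
}

#' Box statistics at the time of maximal variance
#'
#' For each DOF, finds the normalized frame at which the across-iteration
#' variance of the relative joint angle is maximal (ties broken to the
#' earliest frame) and reports the five-number summary of the relative
#' angles at that frame, together with the 90%-CI width there.
#'
#' @param curves numeric array, iterations x 51 x frames (n >= 5).
#' @return data.frame: `dof`, `t_index`, `min`, `q25`, `median`, `q75`,
#'   `max`, `sd`, `ci_width`.
#' @export
t_sigma_max_stats <- function(curves) {
  stopifnot(length(dim(curves)) == 3L, dim(curves)[1] >= 5L)
  channels <- spine_angle_channels()[seq_len(dim(curves)[2])]
  rows <- lapply(seq_len(dim(curves)[2]), function(d) {
    v <- apply(curves[, d, , drop = TRUE], 2, stats::var)
    t_idx <- which.max(v)  # which.max takes the earliest maximal frame
    at <- curves[, d, t_idx]
    q <- stats::quantile(at, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
    ci <- stats::quantile(at, c(0.05, 0.95), names = FALSE)
    data.frame(dof = channels[d], t_index = t_idx, min = q[1], q25 = q[2],
               median = q[3], q75 = q[4], max = q[5], sd = sqrt(v[t_idx]),
               ci_width = ci[2] - ci[1], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Sensitivity factors: input perturbations vs. output deviations
#'
#' Pearson correlation between each sampled parameter perturbation and the
#' maximal absolute deviation over the motion of each joint-angle curve from
#' the baseline, giving a 294 x 51 grid. Iterations from several subjects
#' may be concatenated along the first axis beforehand. Correlations
#' undefined because of a zero-variance column are reported as 0 and
#' flagged.
#'
#' @param draws numeric matrix, iterations x 294.
#' @param curves numeric array, iterations x 51 x frames.
#' @return list with `r` (294 x 51), `flags` (logical 294 x 51, TRUE where
#'   undefined), `by_group` (data.frame of mean and max |r| per
#'   component/parameter group).
#' @export
sensitivity_factors <- function(draws, curves) {
  stopifnot(nrow(draws) == dim(curves)[1], nrow(draws) >= 3L)
  y <- apply(abs(curves), c(1, 2), max)
  sd_x <- apply(draws, 2, stats::sd)
  sd_y <- apply(y, 2, stats::sd)
  r <- matrix(0, ncol(draws), ncol(y))
  ok <- outer(sd_x > 0, sd_y > 0, `&`)
  if (any(ok)) {
    rr <- suppressWarnings(stats::cor(draws, y))
    r[ok] <- rr[ok]
  }
  channels <- spine_angle_channels()[seq_len(ncol(y))]
  colnames(r) <- channels
  groups <- c("marker.position", "body.position", "body.orientation",
              "joint.position", "joint.orientation")
  sizes <- c(84, 54, 54, 51, 51)
  grp <- rep(groups, sizes)
  by_group <- do.call(rbind, lapply(groups, function(g) {
    block <- abs(r[grp == g, , drop = FALSE])
    data.frame(group = g, mean_abs_r = mean(block), max_abs_r = max(block),
               stringsAsFactors = FALSE)
  }))
  list(r = r, flags = !ok, by_group = by_group)
}
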