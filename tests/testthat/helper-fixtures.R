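# Shared fixtures, built once per test run. Everything is generated in code
# (no binary data); the cache avoids re-running the generators and the IK in
# every test file.

fixture_env <- new.env()

fixture <- function(name, builder) {
  if (!exists(name, envir = fixture_env)) {
    assign(name, builder(), envir = fixture_env)
  }
  get(name, envir = fixture_env)
}

## default synthetic subject
fix_model <- function() {
  fixture("model", function() generate_spine_model(geometry_params(), seed = 42))
}

## short noise-free flexion trial with ground truth
fix_clean_trial <- function() {
  fixture("clean_trial", function() {
    generate_flexion_trial(fix_model()$model,
                           motion_spec(n_frames = 50, noise_sd = 0),
                           seed = 11)
  })
}

## IK solution of the clean trial
fix_clean_ik <- function() {
  fixture("clean_ik", function() {
    solve_ik(fix_model()$model, fix_clean_trial()$trial)
  })
}

## three emulated operators + baseline + pooled deviations
fix_operators <- function() {
  fixture("operators", function() {
    model <- fix_model()$model
    ops <- emulate_operators(model, operator_variability_spec(), 3, seed = 7)
    baseline <- average_models(ops)
    pool <- pool_deviations(list(ops), list(baseline))
    list(ops = ops, baseline = baseline, pool = pool)
  })
}

## brute-force two-way ANOVA ICC(2,1) oracle, written independently of
## icc_2_1(): explicit double loops over the cell-mean decomposition
oracle_icc21 <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); k <- ncol(x)
  grand <- sum(x) / (n * k)
  ssr <- 0
  for (i in seq_len(n)) ssr <- ssr + (mean(x[i, ]) - grand)^2
  ssr <- ssr * k
  ssc <- 0
  for (j in seq_len(k)) ssc <- ssc + (mean(x[, j]) - grand)^2
  ssc <- ssc * n
  sse <- 0
  for (i in seq_len(n)) for (j in seq_len(k)) {
    sse <- sse + (x[i, j] - mean(x[i, ]) - mean(x[, j]) + grand)^2
  }
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

## literal brute-force re-computation of the convergence criterion
oracle_convergence <- function(history, window_frac = 0.1, tol = 0.02,
                               min_iter = 100, abs_tol = 0.01,
                               near_zero = 0.5) {
  if (is.null(dim(history))) history <- matrix(history, ncol = 1)
  n <- nrow(history)
  within <- function(value, final) {
    lim <- if (abs(final) < near_zero) abs_tol else tol * abs(final)
    abs(value - final) <= lim
  }
  for (cand in seq(max(min_iter, 3), n)) {
    w <- ceiling(window_frac * cand)
    ok <- TRUE
    for (i in seq(max(2, cand - w + 1), cand)) {
      for (v in seq_len(ncol(history))) {
        m_i <- mean(history[1:i, v]); m_n <- mean(history[1:cand, v])
        s_i <- stats::sd(history[1:i, v]); s_n <- stats::sd(history[1:cand, v])
        if (!within(m_i, m_n) || !within(s_i, s_n)) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (ok) return(cand)
  }
  NA_integer_
}
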