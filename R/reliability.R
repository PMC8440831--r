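#' Intraclass correlation ICC(2,1): two-way random effects, absolute
#' agreement, single measure
#'
#' Computes the single-measure absolute-agreement ICC from the two-way
#' random-effects ANOVA decomposition (McGraw & Wong formulation), with the
#' 95% confidence interval from the corresponding F distributions and a
#' p-value from the F test of the between-subjects mean square against the
#' error mean square (the conventional test of no subject-to-subject
#' consistency, as reported by standard statistical software).
#'
#' Because agreement (not just consistency) is assessed, a systematic offset
#' between sessions or raters lowers the ICC even when subjects keep their
#' rank order.
#'
#' @param table numeric matrix, subjects x raters/sessions (>= 2 each, no
#'   missing cells).
#' @param conf_level confidence level for the interval (default 0.95).
#' @return list with `icc`, `ci` (length-2), `p`, and the mean squares
#'   `msr`, `msc`, `mse`.
#' @export
icc_2_1 <- function(table, conf_level = 0.95) {
  x <- as.matrix(table)
  if (any(is.na(x))) stop("reliability table must have no missing cells")
  n <- nrow(x); k <- ncol(x)
  if (n < 2L || k < 2L) stop("need >= 2 subjects and >= 2 columns")
  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sse <- sum((x - outer(row_m, col_m, `+`) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k / n * (msc - mse)
  if (denom <= .Machine$double.eps * max(1, abs(msr)))
    stop("ICC undefined: no between-subject variance and no error variance")
  icc <- (msr - mse) / denom

  ## McGraw-Wong confidence interval for ICC(A,1)
  alpha <- 1 - conf_level
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  ci <- c(NA_real_, NA_real_)
  if (is.finite(a) && is.finite(b)) {
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- stats::qf(1 - alpha / 2, n - 1, v)
    f_u <- stats::qf(1 - alpha / 2, v, n - 1)
    lower <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
    ci <- c(lower, upper)
  }
  f0 <- msr / mse
  p <- stats::pf(f0, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  list(icc = icc, ci = ci, p = p, msr = msr, msc = msc, mse = mse)
}

#' Standard error of measurement
#'
#' SEM = SD * sqrt(1 - ICC), with SD the standard deviation of the
#' between-session (or between-rater) differences of the outcome; see
#' [reliability_sd()] for the SD conventions offered.
#'
#' @param sd non-negative standard deviation (units of the outcome).
#' @param icc intraclass correlation (<= 1).
#' @return SEM, same units as `sd`.
#' @export
sem <- function(sd, icc) {
  if (any(icc > 1)) stop("icc must be <= 1")
  if (any(sd < 0)) stop("sd must be >= 0")
  sd * sqrt(1 - icc)
}

#' Smallest detectable difference
#'
#' SDD = SEM * 1.96 * sqrt(2): the change exceeding measurement noise of a
#' test-retest design with 95% confidence.
#'
#' @param sem_value non-negative SEM.
#' @return SDD, same units.
#' @export
sdd <- function(sem_value) {
  if (any(sem_value < 0)) stop("sem must be >= 0")
  sem_value * 1.96 * sqrt(2)
}

#' Classify an ICC value
#'
#' Conventional bands: poor (< 0.40), fair to good (0.40-0.75, boundaries
#' included), excellent (> 0.75).
#'
#' @param icc intraclass correlation (<= 1).
#' @return character label.
#' @export
classify_icc <- function(icc) {
  if (any(icc > 1)) stop("icc must be <= 1")
  vapply(icc, function(v) {
    if (v < 0.40) "poor" else if (v <= 0.75) "fair to good" else "excellent"
  }, character(1))
}

#' Summary SD of between-column differences
#'
#' Two conventions for the SD entering the SEM formula are offered:
#' `"pairwise"` (default) takes, per subject, the mean absolute difference
#' over all column pairs (for two sessions simply the absolute
#' between-session difference) and returns the standard deviation of those
#' values across subjects; `"from_mean"` uses each measurement's absolute
#' deviation from its subject mean and returns the SD of those pooled
#' deviations. The two agree up to a factor for two columns; the ambiguity
#' between "SD of the absolute differences between sessions" and "SD of the
#' absolute difference relative to the mean output" is resolved by exposing
#' both.
#'
#' @param table numeric matrix, subjects x columns.
#' @param method `"pairwise"` or `"from_mean"`.
#' @return scalar SD.
#' @export
reliability_sd <- function(table, method = c("pairwise", "from_mean")) {
  method <- match.arg(method)
  x <- as.matrix(table)
  if (method == "pairwise") {
    pairs <- utils::combn(ncol(x), 2)
    d <- apply(x, 1, function(row) {
      mean(abs(row[pairs[1, ]] - row[pairs[2, ]]))
    })
    stats::sd(d)
  } else {
    dev <- abs(x - rowMeans(x))
    stats::sd(as.vector(dev))
  }
}

#' Reliability analysis of ROM tables
#'
#' Runs the full reliability summary for one or more spino-pelvic parameters:
#' ICC(2,1) with 95% CI and p, the summary SD, SEM, SDD, the ICC
#' classification, and the mean (range) of the measured ROMs — one row per
#' parameter, mirroring a conventional test-retest/inter-operator table.
#'
#' @param tables a named list of subjects x sessions matrices (one per
#'   parameter), or a single matrix.
#' @param sd_method see [reliability_sd()].
#' @return data.frame with one row per parameter.
#' @export
reliability_summary <- function(tables, sd_method = "pairwise") {
  if (is.matrix(tables) || is.data.frame(tables)) tables <- list(value = tables)
  rows <- lapply(names(tables), function(nm) {
    tab <- as.matrix(tables[[nm]])
    res <- icc_2_1(tab)
    s <- reliability_sd(tab, sd_method)
    se <- sem(s, res$icc)
    data.frame(parameter = nm, icc = res$icc,
               ci_low = res$ci[1], ci_high = res$ci[2], p = res$p,
               sd = s, sem = se, sdd = sdd(se),
               classification = classify_icc(res$icc),
               mean_rom = mean(tab), min_rom = min(tab), max_rom = max(tab),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
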