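#' Read a TRC marker-trajectory file
#'
#' Parses the de-facto standard tab-delimited TRC motion-capture format:
#' a `PathFileType` line, a header key line (`DataRate ... NumFrames
#' NumMarkers Units ...`) with its value line, the marker-name line
#' (`Frame# Time <name> ...`), the coordinate-label line, then one row per
#' frame. Positions are normalized to millimetres (`Units m` are multiplied
#' by 1000); blank cells are treated as missing samples and masked.
#'
#' @param path file path.
#' @return a [motion_trial()].
#' @export
read_trc <- function(path) {
  lines <- readLines(path, warn = FALSE)
  perr <- function(line, msg) stop(sprintf("TRC parse error at line %d of %s: %s",
                                           line, basename(path), msg))
  if (length(lines) < 6L) perr(length(lines), "truncated file")
  hdr_keys <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  hdr_vals <- strsplit(lines[3], "\t", fixed = TRUE)[[1]]
  need <- c("DataRate", "NumFrames", "NumMarkers", "Units")
  if (!all(need %in% hdr_keys)) perr(2, paste("header must declare",
                                              paste(need, collapse = ", ")))
  hv <- function(k) hdr_vals[match(k, hdr_keys)]
  rate <- as.numeric(hv("DataRate"))
  n_frames <- as.integer(hv("NumFrames"))
  n_markers <- as.integer(hv("NumMarkers"))
  units <- hv("Units")
  if (is.na(rate) || rate <= 0) perr(3, "invalid DataRate")
  scale <- switch(units, mm = 1, m = 1000, cm = 10,
                  perr(3, paste("unsupported Units", units)))
  name_row <- strsplit(lines[4], "\t", fixed = TRUE)[[1]]
  marker_names <- name_row[-(1:2)]
  marker_names <- marker_names[marker_names != ""]
  if (length(marker_names) != n_markers)
    perr(4, sprintf("found %d marker names, header declares %d",
                    length(marker_names), n_markers))
  data_lines <- lines[-(1:5)]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  if (length(data_lines) != n_frames)
    perr(5, sprintf("found %d data rows, header declares %d",
                    length(data_lines), n_frames))
  data <- array(NA_real_, c(n_frames, n_markers, 3))
  time <- numeric(n_frames)
  n_cols <- 2L + 3L * n_markers
  for (f in seq_len(n_frames)) {
    raw <- data_lines[f]
    ## blank cells are missing samples, so the tab count (not the non-empty
    ## cell count) decides whether a row is truncated
    n_tabs <- nchar(raw) - nchar(gsub("\t", "", raw, fixed = TRUE))
    if (n_tabs < n_cols - 1L)
      perr(5L + f, sprintf("truncated row for frame %d (%d of %d columns)",
                           f, n_tabs + 1L, n_cols))
    cells <- strsplit(raw, "\t", fixed = TRUE)[[1]]
    if (length(cells) < n_cols) cells <- c(cells, rep("", n_cols - length(cells)))
    time[f] <- as.numeric(cells[2])
    vals <- suppressWarnings(as.numeric(cells[3:n_cols]))
    data[f, , ] <- matrix(vals, n_markers, 3, byrow = TRUE) * scale
  }
  motion_trial(data, marker_names, rate = rate, time = time)
}

#' Write a TRC marker-trajectory file
#'
#' @param trial a `motion_trial` (positions mm).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trc <- function(trial, path) {
  n <- dim(trial$data)[1]; nm <- dim(trial$data)[2]
  l1 <- sprintf("PathFileType\t4\t(X/Y/Z)\t%s", basename(path))
  l2 <- paste(c("DataRate", "CameraRate", "NumFrames", "NumMarkers", "Units",
                "OrigDataRate", "OrigDataStartFrame", "OrigNumFrames"),
              collapse = "\t")
  l3 <- paste(c(fmt_num(trial$rate), fmt_num(trial$rate), n, nm, "mm",
                fmt_num(trial$rate), 1, n), collapse = "\t")
  l4 <- paste(c("Frame#", "Time",
                as.vector(rbind(trial$marker_names, "", ""))), collapse = "\t")
  l5 <- paste(c("", "", as.vector(vapply(seq_len(nm), function(i)
    paste0(c("X", "Y", "Z"), i), character(3)))), collapse = "\t")
  rows <- vapply(seq_len(n), function(f) {
    vals <- as.vector(t(trial$data[f, , ]))
    cells <- ifelse(is.na(vals), "", sprintf("%.6f", vals))
    paste(c(f, sprintf("%.6f", trial$time[f]), cells), collapse = "\t")
  }, character(1))
  writeLines(c(l1, l2, l3, l4, l5, rows), path)
  invisible(path)
}

fmt_num <- function(x) sub("\\.?0+$", "", sprintf("%.6f", x))

#' Serialize a spine model to JSON
#'
#' Versioned JSON schema (`schema_version` field), one file per model; all
#' positions in mm, orientations as body-fixed xyz Euler angles in degrees.
#' Serialization is deterministic: identical models produce byte-identical
#' files, and a write/read round trip reproduces the model to full numeric
#' precision.
#'
#' @param model a `spine_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spine_model <- function(model, path) {
  obj <- list(
    schema_version = model$schema_version,
    segments = lapply(unname(model$segments), function(s) list(
      name = s$name,
      pose = list(position = s$pose$p, orientation_deg = s$pose$eul),
      align = list(position = s$align$p, orientation_deg = s$align$eul),
      landmarks = s$landmarks)),
    joints = lapply(unname(model$joints), function(j) list(
      name = j$name, parent = j$parent, child = j$child,
      position = j$pos, orientation_deg = j$eul)),
    markers = lapply(unname(model$markers), function(mk) list(
      name = mk$name, body = mk$body, position = mk$pos)))
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Read a spine model from JSON
#'
#' Validates the schema version and the structural invariants (18 bodies, 17
#' joints in a single serial chain, 28 markers, complete landmark sets);
#' violations raise errors naming the offending element.
#'
#' @param path file path.
#' @return a `spine_model`.
#' @export
read_spine_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(obj$schema_version))
    stop("model file ", basename(path), " lacks a schema_version field")
  if (!identical(obj$schema_version, MODEL_SCHEMA_VERSION))
    stop("unsupported model schema_version ", obj$schema_version,
         " (expected ", MODEL_SCHEMA_VERSION, ")")
  num3 <- function(v, what) {
    v <- as.numeric(unlist(v))
    if (length(v) != 3L || any(!is.finite(v)))
      stop("invalid 3-vector at ", what, " in ", basename(path))
    v
  }
  segments <- list()
  for (s in obj$segments) {
    segments[[s$name]] <- list(
      name = s$name,
      pose = list(p = num3(s$pose$position, paste0("segments/", s$name, "/pose")),
                  eul = num3(s$pose$orientation_deg,
                             paste0("segments/", s$name, "/pose"))),
      align = list(p = num3(s$align$position,
                            paste0("segments/", s$name, "/align")),
                   eul = num3(s$align$orientation_deg,
                              paste0("segments/", s$name, "/align"))),
      landmarks = lapply(s$landmarks, function(lm)
        num3(lm, paste0("segments/", s$name, "/landmarks"))))
  }
  joints <- list()
  for (j in obj$joints) {
    joints[[j$name]] <- list(
      name = j$name, parent = j$parent, child = j$child,
      pos = num3(j$position, paste0("joints/", j$name)),
      eul = num3(j$orientation_deg, paste0("joints/", j$name)))
  }
  markers <- list()
  for (mk in obj$markers) {
    markers[[mk$name]] <- list(name = mk$name, body = mk$body,
                               pos = num3(mk$position,
                                          paste0("markers/", mk$name)))
  }
  spine_model(segments, joints, markers, schema_version = obj$schema_version)
}

#' Write a joint-kinematics series as a MOT/STO-style file
#'
#' Tab-delimited time series with the conventional plain-text header
#' (`nRows`, `nColumns`, `inDegrees=yes`, `endheader`), columns: time, the 6
#' base coordinates, the 51 joint angles.
#'
#' @param series a `joint_kinematics` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mot <- function(series, path) {
  stopifnot(inherits(series, "joint_kinematics"))
  n <- nrow(series$angles)
  time <- if (!is.null(series$time)) series$time else seq_len(n) - 1
  tab <- cbind(time = time, series$base, series$angles)
  hdr <- c("spinemc joint kinematics", "version=1",
           sprintf("nRows=%d", n), sprintf("nColumns=%d", ncol(tab)),
           "inDegrees=yes", "endheader",
           paste(colnames(tab), collapse = "\t"))
  rows <- apply(tab, 1, function(v) paste(sprintf("%.8f", v), collapse = "\t"))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a MOT/STO-style joint-kinematics file written by [write_mot()]
#'
#' @param path file path.
#' @return a `joint_kinematics` object.
#' @export
read_mot <- function(path) {
  lines <- readLines(path, warn = FALSE)
  end <- match("endheader", lines)
  if (is.na(end)) stop("not a MOT/STO file (no endheader): ", path)
  cols <- strsplit(lines[end + 1L], "\t", fixed = TRUE)[[1]]
  dat <- utils::read.table(text = lines[-seq_len(end + 1L)], sep = "\t",
                           col.names = cols, check.names = FALSE)
  dat <- as.matrix(dat)
  base_cols <- spine_base_channels()
  angle_cols <- spine_angle_channels()
  if (!all(c(base_cols, angle_cols) %in% cols))
    stop("MOT file lacks expected base/joint channels: ", path)
  new_joint_kinematics(angles = dat[, angle_cols, drop = FALSE],
                       base = dat[, base_cols, drop = FALSE],
                       time = dat[, "time"])
}

#' Write a run manifest
#'
#' Records tool version, seed(s), input-file digests, settings and the
#' convergence iteration count so that a run can be audited and reproduced;
#' identical inputs, settings and seed reproduce identical outputs
#' (the `created` timestamp aside).
#'
#' @param path output JSON path.
#' @param seed integer seed(s) used.
#' @param inputs character vector of input file paths (digested with MD5).
#' @param settings named list of settings to record.
#' @param extra named list of extra fields (e.g. `convergence_n`).
#' @return the manifest list, invisibly.
#' @export
write_manifest <- function(path, seed, inputs = character(),
                           settings = list(), extra = list()) {
  digests <- if (length(inputs)) {
    d <- tools::md5sum(inputs)
    stats::setNames(as.vector(d), basename(names(d)))
  } else NULL
  manifest <- c(list(tool = "spinemc",
                     version = as.character(utils::packageVersion("spinemc")),
                     created = format(Sys.time(), tz = "UTC",
                                      "%Y-%m-%dT%H:%M:%SZ"),
                     seed = seed,
                     inputs = as.list(digests),
                     settings = settings),
                extra)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = I(17)), path)
  invisible(manifest)
}
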