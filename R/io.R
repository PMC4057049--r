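#' Read a TRC motion-capture file
#'
#' Parses the standard tab-delimited TRC text format (header lines
#' `PathFileType`, the `DataRate ... Units ...` pair, marker-name row,
#' X/Y/Z row, then one row per frame). Positions are converted to metres
#' when the units line says `mm`. Missing coordinates are kept as `NA` and
#' the affected frames flagged. Frames are renumbered from 1 internally
#' regardless of the file's starting frame number.
#'
#' @param path Path to a `.trc` file.
#' @return A tibble `frame`, `time`, `marker`, `x`, `y`, `z` (m) with
#'   attributes `rate` (Hz) and `missing_frames`.
#' @export
read_trc <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 5 || !grepl("^PathFileType", lines[1])) {
    abort_input(sprintf("%s: line 1 is not a TRC PathFileType header", path),
                class = "screwgait_error_parse")
  }
  hdr_names <- strsplit(lines[2], "\t")[[1]]
  hdr_vals <- strsplit(lines[3], "\t")[[1]]
  hdr <- stats::setNames(as.list(hdr_vals), hdr_names[seq_along(hdr_vals)])
  rate <- as.numeric(hdr[["DataRate"]])
  units <- hdr[["Units"]]
  if (is.null(units) || !(units %in% c("mm", "m"))) {
    abort_input(sprintf("%s: line 3: Units must be 'mm' or 'm'", path),
                class = "screwgait_error_parse")
  }
  scale <- if (units == "mm") 1e-3 else 1
  label_row <- strsplit(lines[4], "\t")[[1]]
  labels <- label_row[-(1:2)]
  labels <- labels[labels != ""]
  ncol_expected <- 2 + 3 * length(labels)
  data_lines <- lines[-(1:5)]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  rows <- purrr::imap_dfr(data_lines, function(ln, i) {
    f <- strsplit(ln, "\t")[[1]]
    if (length(f) < ncol_expected) f <- c(f, rep("", ncol_expected - length(f)))
    if (length(f) > ncol_expected) {
      abort_input(sprintf("%s: data line %d has %d fields, expected %d",
                          path, i, length(f), ncol_expected),
                  class = "screwgait_error_parse")
    }
    v <- suppressWarnings(as.numeric(f))
    xyz <- matrix(v[-(1:2)], ncol = 3, byrow = TRUE)
    tibble::tibble(frame = i, time = v[2], marker = labels,
                   x = xyz[, 1] * scale, y = xyz[, 2] * scale, z = xyz[, 3] * scale)
  })
  miss <- sort(unique(rows$frame[!stats::complete.cases(rows[, c("x", "y", "z")])]))
  attr(rows, "rate") <- rate
  attr(rows, "missing_frames") <- miss
  rows
}

#' Write marker trajectories as a TRC file
#'
#' @param markers Tidy marker tibble (`frame`, `time`, `marker`, `x`, `y`,
#'   `z`, metres).
#' @param path Output path.
#' @param rate Sampling rate (Hz).
#' @param units `"mm"` (conventional) or `"m"`.
#' @return `path`, invisibly.
#' @export
write_trc <- function(markers, path, rate = attr(markers, "rate"), units = "mm") {
  if (is.null(rate)) rate <- 1 / stats::median(diff(unique(markers$time)))
  scale <- if (units == "mm") 1e3 else 1
  labels <- unique(markers$marker)
  frames <- sort(unique(markers$frame))
  l1 <- sprintf("PathFileType\t4\t(X/Y/Z)\t%s", basename(path))
  l2 <- paste(c("DataRate", "CameraRate", "NumFrames", "NumMarkers", "Units",
                "OrigDataRate", "OrigDataStartFrame", "OrigNumFrames"), collapse = "\t")
  l3 <- paste(c(rate, rate, length(frames), length(labels), units, rate, 1,
                length(frames)), collapse = "\t")
  l4 <- paste(c("Frame#", "Time",
                as.vector(rbind(labels, "", ""))), collapse = "\t")
  l5 <- paste(c("", "", paste0(rep(c("X", "Y", "Z"), length(labels)),
                               rep(seq_along(labels), each = 3))), collapse = "\t")
  wide <- markers |>
    dplyr::arrange(.data$frame, match(.data$marker, labels))
  body <- vapply(frames, function(f) {
    d <- wide[wide$frame == f, ]
    vals <- as.vector(t(as.matrix(d[match(labels, d$marker), c("x", "y", "z")]) * scale))
    paste(c(f, format(d$time[1], digits = 10), format(vals, digits = 10)),
          collapse = "\t")
  }, "")
  writeLines(c(l1, l2, l3, l4, l5, body), path)
  invisible(path)
}

#' Read a force-plate CSV
#'
#' Expects columns `time, Fx, Fy, Fz, COPx, COPy, COPz, Tz` in SI units
#' (N, m, N m). A stance mask is computed from the vertical force: frames
#' with `Fz >= threshold` are stance (the boundary value is inclusive).
#'
#' @param path CSV path.
#' @param stance_threshold Vertical-force cutoff (N); default 20 N.
#' @return Tibble with the input columns plus logical `stance`.
#' @export
read_forceplate_csv <- function(path, stance_threshold = 20) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("time", "Fx", "Fy", "Fz", "COPx", "COPy", "COPz", "Tz")
  missing <- setdiff(need, names(d))
  if (length(missing)) {
    abort_input(sprintf("%s: missing force-plate columns: %s", path,
                        paste(missing, collapse = ", ")),
                class = "screwgait_error_schema")
  }
  dplyr::mutate(d[, need], stance = .data$Fz >= stance_threshold)
}

#' Read knee constraint geometry from JSON
#'
#' The geometry file is a JSON object keyed by constraint name. Ligaments
#' give `origin` (femoral) and `insertion` (tibial) points in metres, tibia
#' frame; contacts give `point` and `normal`. Each entry becomes a
#' zero-pitch line: through the insertion toward the origin, or through the
#' contact point along the normal.
#'
#' @param path JSON path.
#' @return A `constraint_set`.
#' @export
read_constraint_geometry <- function(path) {
  g <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  lines <- lapply(names(g), function(nm) {
    e <- g[[nm]]
    if (!is.null(e$normal)) {
      screw_from_axis(as.numeric(e$point), as.numeric(e$normal))
    } else if (!is.null(e$origin) && !is.null(e$insertion)) {
      screw_from_axis(as.numeric(e$insertion),
                      as.numeric(e$origin) - as.numeric(e$insertion))
    } else {
      abort_input(sprintf("%s: constraint '%s' needs origin/insertion or point/normal",
                          path, nm), class = "screwgait_error_schema")
    }
  })
  names(lines) <- names(g)
  constraint_set(lines, source = list(kind = "file", path = path))
}

#' Write a constraint set to the JSON geometry format
#'
#' Lines are written as `point` (axis point) and `normal` (direction)
#' records; [read_constraint_geometry()] reproduces the same lines.
#'
#' @param constraints A `constraint_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_constraint_geometry <- function(constraints, path) {
  out <- lapply(constraints, function(s) {
    list(point = axis_point(s), normal = s$d)
  })
  jsonlite::write_json(out, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' Write synthetic trial inputs to disk in the reader formats
#'
#' @param trial A [gen_stance_trial()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly; writes `markers.trc`, `forceplate.csv`,
#'   `geometry.json`, `truth_intensities.csv`, `truth_iak.csv`.
#' @export
write_trial <- function(trial, dir) {
  stopifnot(inherits(trial, "synthetic_trial"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_trc(trial$markers, file.path(dir, "markers.trc"), rate = trial$rate)
  readr::write_csv(dplyr::select(trial$grf, -"stance"),
                   file.path(dir, "forceplate.csv"))
  write_constraint_geometry(trial$geometry, file.path(dir, "geometry.json"))
  readr::write_csv(trial$truth$intensities, file.path(dir, "truth_intensities.csv"))
  readr::write_csv(trial$truth$iak_track, file.path(dir, "truth_iak.csv"))
  invisible(dir)
}

#' Run the full perception-action pipeline on a trial
#'
#' Orchestrates the stages end to end: fit per-frame thigh and shank poses
#' from the marker clusters, extract the segment screws, form the IAK as the
#' relative twist, build the per-frame GRF wrench, decompose it over the
#' constraint lines (mapped through the shank pose) into medial/lateral
#' contact forces, and trace the reciprocity-seeking policy over the
#' constraint lines. Deterministic given inputs and configuration; the
#' result carries provenance (configuration hash, package version, stage
#' log).
#'
#' @param markers Tidy marker tibble for both clusters.
#' @param grf Force-plate tibble (with `stance` column, see
#'   [read_forceplate_csv()]).
#' @param geometry A `constraint_set` in the tibia (shank reference) frame.
#' @param config List of options: `thigh`, `shank` (label vectors; defaults
#'   `T*`/`S*` prefixes), `span` (ISA differencing half-width, frames),
#'   `smooth_window` (odd moving-average window, 1 = off),
#'   `stance_threshold` (N), `check_iak` (logical: consistency-check the
#'   wrench against the measured IAK), `tol`.
#' @return A list of class `gait_results`: `poses` (thigh/shank), `isa`
#'   tracks, `iak` track, `forces` ([decompose_trial()] tibble), `policy`
#'   ([stance_policy()] trace), `provenance`.
#' @export
run_pipeline <- function(markers, grf, geometry, config = list()) {
  cfg <- utils::modifyList(list(
    thigh = NULL, shank = NULL, span = 1, smooth_window = 1,
    stance_threshold = 20, check_iak = FALSE, tol = 1e-6), config)
  labels <- unique(markers$marker)
  if (is.null(cfg$thigh)) cfg$thigh <- grep("^T", labels, value = TRUE)
  if (is.null(cfg$shank)) cfg$shank <- grep("^S", labels, value = TRUE)
  log <- list()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("pipeline stage '%s' failed: %s", name,
                           conditionMessage(e)),
                   class = "screwgait_error_pipeline", parent = e)
    })
    log[[name]] <<- list(elapsed_s = as.numeric(Sys.time() - t0, units = "secs"))
    out
  }
  if (!length(cfg$thigh) || !length(cfg$shank)) {
    abort_input("could not identify thigh/shank marker labels; set config$thigh/shank")
  }
  if (cfg$smooth_window > 1) {
    markers <- stage("smooth", smooth_markers(markers, cfg$smooth_window))
  }
  rate <- attr(markers, "rate")
  if (is.null(rate)) rate <- 1 / stats::median(diff(sort(unique(markers$time))))
  thigh_poses <- stage("fit_thigh", fit_poses(markers, cfg$thigh, rate = rate))
  shank_poses <- stage("fit_shank", fit_poses(markers, cfg$shank, rate = rate))
  thigh_isa <- stage("twist_thigh", twist_from_poses(thigh_poses, rate, span = cfg$span))
  shank_isa <- stage("twist_shank", twist_from_poses(shank_poses, rate, span = cfg$span))
  iak <- stage("iak", relative_twist(thigh_isa, shank_isa))

  if (!"stance" %in% names(grf)) {
    grf <- dplyr::mutate(grf, stance = .data$Fz >= cfg$stance_threshold)
  }
  if (!any(grf$stance)) {
    rlang::warn("stance mask is empty: no frame exceeds the vertical-force threshold",
                class = "screwgait_warning_empty_stance")
  }
  cs_at <- function(i) {
    transform_constraints(geometry, shank_poses$rotation[[i]],
                          shank_poses$translation[[i]])
  }
  forces <- stage("decompose",
                  decompose_trial(grf, cs_at,
                                  iak_track = if (cfg$check_iak) iak else NULL,
                                  tol = cfg$tol))
  policy <- stage("policy", stance_policy(iak, unclass(geometry)))
  out <- list(
    poses = list(thigh = thigh_poses, shank = shank_poses),
    isa = list(thigh = thigh_isa, shank = shank_isa),
    iak = iak, forces = forces, policy = policy,
    provenance = list(
      package_version = as.character(utils::packageVersion("screwgait")),
      config = cfg, config_hash = rlang::hash(cfg),
      input_hash = rlang::hash(list(markers, grf, lapply(geometry, screw_6vec))),
      stages = log))
  class(out) <- "gait_results"
  out
}

#' @export
print.gait_results <- function(x, ...) {
  st <- dplyr::filter(x$forces, .data$stance)
  cat(sprintf("<gait_results: %d frames (%d stance), peak medial %.1f N, peak lateral %.1f N>\n",
              nrow(x$forces), nrow(st),
              if (nrow(st)) max(st$medial_N) else NA, if (nrow(st)) max(st$lateral_N) else NA))
  invisible(x)
}

#' Write pipeline results to CSV
#'
#' @param results A [run_pipeline()] result.
#' @param dir Output directory.
#' @return The directory, invisibly; writes `iak.csv`, `forces.csv`,
#'   `policy.csv`, `provenance.json`.
#' @export
write_results <- function(results, dir) {
  stopifnot(inherits(results, "gait_results"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(dplyr::select(results$iak, -"screw"), file.path(dir, "iak.csv"))
  readr::write_csv(results$forces, file.path(dir, "forces.csv"))
  readr::write_csv(results$policy, file.path(dir, "policy.csv"))
  prov <- results$provenance
  prov$stages <- NULL    # elapsed times are not reproducible content
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
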