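#' Write a movie stack as a multi-frame TIFF with a metadata sidecar
#'
#' Frames are stored as 16-bit integer TIFF (ADU values roundtrip
#' bit-exactly); pixel size and frame interval go to a YAML sidecar
#' `<path>.yml`. Writes are atomic (temp file then rename).
#'
#' @param movie a [movie_stack()].
#' @param path output TIFF path.
#' @return the path, invisibly.
#' @export
write_movie <- function(movie, path) {
  mx <- max(vapply(movie$frames, max, numeric(1)))
  if (mx > 65535) stop_param("ADU values exceed 16-bit range")
  imgs <- lapply(movie$frames, function(f) pmax(round(f), 0) / 65535)
  write_atomic(function(p) tiff::writeTIFF(imgs, p, bits.per.sample = 16),
               path)
  write_atomic(function(p) yaml::write_yaml(
    list(pixel_size_nm = movie$pixel_size,
         frame_interval_s = movie$frame_interval), p),
    paste0(path, ".yml"))
  invisible(path)
}

#' Read a movie stack from a multi-frame TIFF
#'
#' Metadata come from the YAML sidecar `<path>.yml` unless overridden by
#' the arguments; a missing field is an explicit error naming it.
#'
#' @param path TIFF path.
#' @param pixel_size nm/px (overrides sidecar).
#' @param frame_interval s (overrides sidecar).
#' @return a [movie_stack()] with integer ADU frames.
#' @export
read_movie <- function(path, pixel_size = NULL, frame_interval = NULL) {
  if (!file.exists(path)) stop_param("no such file: ", path)
  side <- paste0(path, ".yml")
  meta <- if (file.exists(side)) yaml::read_yaml(side) else list()
  if (is.null(pixel_size)) pixel_size <- meta$pixel_size_nm
  if (is.null(frame_interval)) frame_interval <- meta$frame_interval_s
  if (is.null(pixel_size))
    stop_param("missing metadata field `pixel_size` (no sidecar value and no argument)")
  if (is.null(frame_interval))
    stop_param("missing metadata field `frame_interval` (no sidecar value and no argument)")
  imgs <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(imgs)) imgs <- list(imgs)
  frames <- lapply(imgs, function(m) matrix(as.numeric(m), nrow(m), ncol(m)))
  movie_stack(frames, pixel_size, frame_interval)
}

#' Write / read ground-truth filament tables
#'
#' CSV with columns `filament_id, birth_s, death_s, angle0_deg, speed_nm_s,
#' direction, immobile`.
#'
#' @param truth data frame from [simulate_filaments()].
#' @param path CSV path.
#' @export
write_truth_csv <- function(truth, path) {
  write_csv_atomic(truth, path)
}

#' @rdname write_truth_csv
#' @export
read_truth_csv <- function(path) {
  utils::read.csv(path)
}

#' Write / read long-format filament trace tables
#'
#' CSV columns `trace_id, t_s, angle_deg`; the ring radius travels in a
#' `# radius_nm:` header comment line.
#'
#' @param traces long-format data frame.
#' @param radius_nm ring radius, nm.
#' @param path CSV path.
#' @export
write_trace_csv <- function(traces, radius_nm, path) {
  write_atomic(function(p) {
    con <- file(p, "w")
    on.exit(close(con))
    writeLines(sprintf("# radius_nm: %.6g", radius_nm), con)
    utils::write.csv(traces, con, row.names = FALSE)
  }, path)
}

#' @rdname write_trace_csv
#' @return `read_trace_csv`: list with `traces` and `radius_nm`.
#' @export
read_trace_csv <- function(path) {
  first <- readLines(path, n = 1L)
  radius <- NA_real_
  skip <- 0L
  if (startsWith(first, "#")) {
    radius <- as.numeric(sub(".*radius_nm:\\s*", "", first))
    skip <- 1L
  }
  list(traces = utils::read.csv(path, skip = skip), radius_nm = radius)
}

#' Kymograph CSV export
#'
#' One row per frame, one column per angular sample, preceded by metadata
#' comment lines.
#'
#' @param kymo a [kymograph()].
#' @param path CSV path.
#' @export
write_kymograph_csv <- function(kymo, path) {
  write_atomic(function(p) {
    con <- file(p, "w")
    on.exit(close(con))
    writeLines(c(sprintf("# radius_nm: %.6g", kymo$radius_nm),
                 sprintf("# frame_interval_s: %.6g", kymo$frame_interval),
                 sprintf("# doubled: %s", kymo$doubled)), con)
    utils::write.table(kymo$values, con, sep = ",", row.names = FALSE,
                       col.names = sprintf("deg_%g", kymo$angles))
  }, path)
}

#' Pipeline run configuration
#'
#' Bundles the simulation settings with the analysis thresholds the
#' pipeline applies: 400 nm axial thickness (nascent vs condensed), 0.9
#' relative diameter (mature vs constricting), 0.5 normalised synthase
#' intensity (low vs high), 10 nm/s mobility threshold, 50 nm minimum
#' condensation step, 356 nm low-thickness rule.
#'
#' @param sim a [sim_config()].
#' @param out_dir output directory.
#' @param thresholds named list; missing entries take the defaults above.
#' @param seed seed for the run (overrides `sim$seed` when given).
#' @return list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), out_dir = tempfile("vercini_"),
                       thresholds = list(), seed = NULL) {
  def <- list(thickness_nm = 400, rel_diameter = 0.9, pbp2b = 0.5,
              immobile_nm_s = 10, step_nm = 50, d213a_nm = 356)
  thresholds <- utils::modifyList(def, thresholds)
  if (any(unlist(thresholds) <= 0)) stop_param("thresholds must be positive")
  if (!is.null(seed)) sim$seed <- as.integer(seed)
  structure(list(sim = sim, out_dir = out_dir, thresholds = thresholds),
            class = "run_config")
}

#' Run the simulation-to-statistics pipeline
#'
#' Stages: simulate a septal movie, fit the ring model per frame, extract
#' the circumferential kymograph, measure ground-truth-guided filament
#' traces and speeds, summarise speeds (violin summary and bootstrap CI),
#' and write per-stage CSV outputs plus a structured log of every
#' parameter and threshold applied. A stage failure halts the run with the
#' failing stage named; outputs written so far are preserved.
#'
#' @param config a [run_config()].
#' @param fit_every fit the ring model every this many frames (see
#'   [fit_ring_movie()]).
#' @return list with `fits` (fit table), `kymograph`, `traces` (metrics
#'   table), `speed_summary`, `median_intensity`, `log`.
#' @export
run_pipeline <- function(config, fit_every = 10L) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list(seed = config$sim$seed, thresholds = config$thresholds)
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE))
    log[[paste0("stage_", name)]] <<- "ok"
    res
  }
  sim <- stage("simulate", simulate_ring_movie(config$sim))
  write_truth_csv(sim$truth, file.path(config$out_dir, "ground_truth.csv"))
  fits <- stage("fit_rings", fit_ring_movie(sim$movie, every = fit_every))
  fit_tab <- ring_fit_table(fits)
  write_csv_atomic(fit_tab, file.path(config$out_dir, "ring_fits.csv"))
  kymo <- stage("kymograph", extract_kymograph(sim$movie, fits))
  write_kymograph_csv(kymo, file.path(config$out_dir, "kymograph.csv"))
  med_int <- median_septal_intensity(kymo)
  traces <- stage("speeds", {
    tl <- guided_traces(kymo, sim$truth, config$sim$ring_diameter)
    if (length(tl) == 0) {
      data.frame(trace_id = integer(0), speed_nm_s = numeric(0),
                 lifetime_s = numeric(0), distance_nm = numeric(0),
                 immobile = logical(0))
    } else {
      do.call(rbind, lapply(names(tl), function(id)
        cbind(trace_id = as.integer(id), trace_metrics(tl[[id]]))))
    }
  })
  write_csv_atomic(traces, file.path(config$out_dir, "trace_metrics.csv"))
  speed_summary <- if (nrow(traces) >= 4)
    stage("stats", violin_summary(traces$speed_nm_s)) else NULL
  log$n_traces <- nrow(traces)
  log$median_intensity <- med_int
  write_atomic(function(p) yaml::write_yaml(log, p),
               file.path(config$out_dir, "run_log.yml"))
  list(fits = fit_tab, kymograph = kymo, traces = traces,
       speed_summary = speed_summary, median_intensity = med_int,
       log = log)
}
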