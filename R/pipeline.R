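# End-to-end orchestration: segment -> register -> track -> measure ->
# summarize -> visualize, from one validated config, with a manifest of
# every artifact written (content-hashed for reproducibility checks).

pipeline_config_fields <- c(
  "input", "output_dir", "direction", "registration", "segmentation",
  "min_overlap_px", "n_levels", "width_feature", "color_feature", "log_level")

#' Pipeline configuration
#'
#' @param input Frame source: a directory/glob pattern for
#'   [read_sequence()].
#' @param output_dir Directory for all artifacts (created if needed).
#' @param direction Tracking direction; backward is the default (splitting,
#'   which segmentation handles well, then covers forward-time merging).
#' @param registration A [registration_params()] list.
#' @param segmentation A [segmentation_params()] list.
#' @param min_overlap_px Tracking overlap significance threshold.
#' @param n_levels Entropy quantization bins.
#' @param width_feature,color_feature Features for the stream plot.
#' @param log_level `"info"` or `"quiet"`.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(input, output_dir,
                            direction = c("backward", "forward"),
                            registration = registration_params(),
                            segmentation = segmentation_params(),
                            min_overlap_px = 10L,
                            n_levels = 256L,
                            width_feature = "area_px",
                            color_feature = "circularity",
                            log_level = c("info", "quiet")) {
  direction <- match.arg(direction)
  log_level <- match.arg(log_level)
  if (!is.character(input) || length(input) < 1) stopf("config: 'input' must be a path/pattern")
  if (!is.character(output_dir) || length(output_dir) != 1) {
    stopf("config: 'output_dir' must be a single path")
  }
  if (n_levels < 2) stopf("config: n_levels must be >= 2")
  structure(list(input = input, output_dir = output_dir, direction = direction,
                 registration = registration, segmentation = segmentation,
                 min_overlap_px = as.integer(min_overlap_px),
                 n_levels = as.integer(n_levels),
                 width_feature = width_feature, color_feature = color_feature,
                 log_level = log_level),
            class = "pipeline_config")
}

#' Read a pipeline configuration file
#'
#' YAML (or JSON) config with the same fields as [pipeline_config()];
#' `registration` and `segmentation` are nested parameter maps. Unknown keys
#' are rejected before any computation.
#'
#' @param path Config file path.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), pipeline_config_fields)
  if (length(unknown) > 0) {
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  check_sub <- function(sub, ctor) {
    if (is.null(sub)) return(ctor())
    bad <- setdiff(names(sub), names(formals(ctor)))
    if (length(bad) > 0) stopf("unknown config key(s): %s", paste(bad, collapse = ", "))
    do.call(ctor, sub)
  }
  args <- raw
  args$registration <- check_sub(raw$registration, registration_params)
  args$segmentation <- check_sub(raw$segmentation, segmentation_params)
  do.call(pipeline_config, args)
}

pipe_log <- function(config, fmt, ...) {
  if (config$log_level == "info") {
    message(sprintf("[colonytrack] %s", sprintf(fmt, ...)))
  }
}

#' Run the full analysis pipeline
#'
#' Reads the frame sequence, tracks colonies (registration + segmentation +
#' reconciliation), measures features, writes per-frame masks and fields,
#' the track graph, the feature and summary tables and the stream plot, and
#' finally a manifest JSON listing every artifact with its MD5 content hash.
#' The pipeline is deterministic: identical config and inputs give identical
#' hashes.
#'
#' @param config A [pipeline_config()] (or path to a config file).
#' @param frames Optional pre-loaded frame list (overrides `config$input`).
#' @return Invisibly, a tibble manifest (`artifact`, `path`, `md5`).
#' @export
run_pipeline <- function(config, frames = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "fields"), showWarnings = FALSE)

  if (is.null(frames)) {
    pipe_log(config, "reading frames from %s", config$input)
    frames <- read_sequence(config$input)
  }
  pipe_log(config, "tracking %d frames (%s)", length(frames), config$direction)
  tp <- tracking_params(min_overlap_px = config$min_overlap_px,
                        direction = config$direction,
                        registration = config$registration,
                        segmentation = config$segmentation)
  trk <- track_sequence(frames, tp)

  artifacts <- character(0)
  for (t in seq_along(trk$masks)) {
    p <- file.path(out_dir, "masks", sprintf("mask_%03d.tif", t - 1))
    write_label_mask(trk$masks[[t]], p)
    artifacts <- c(artifacts, p)
  }
  for (t in seq_along(trk$fields)) {
    p <- file.path(out_dir, "fields", sprintf("field_%03d.tif", t - 1))
    write_displacement_field(trk$fields[[t]], p)
    artifacts <- c(artifacts, p)
  }
  graph_path <- file.path(out_dir, "track_graph.json")
  write_track_graph(trk$graph, graph_path)
  artifacts <- c(artifacts, graph_path)

  pipe_log(config, "measuring colonies")
  records <- measure_sequence(frames, trk$masks, trk$fields,
                              n_levels = config$n_levels)
  feat_path <- file.path(out_dir, "features.csv")
  if (nrow(records) > 0) {
    write_feature_table(records, feat_path)
    artifacts <- c(artifacts, feat_path)
  }

  summaries <- dplyr::bind_rows(lapply(
    c("area_px", "elongation", "circularity", "entropy", "mean_displacement"),
    function(f) summarize_frames(records, f)))
  coverage <- tibble::tibble(
    frame = seq_along(trk$masks) - 1L,
    covered_area_fraction = vapply(trk$masks, covered_area_fraction, numeric(1)))
  sum_path <- file.path(out_dir, "summary.csv")
  readr::write_csv(summaries, sum_path)
  cov_path <- file.path(out_dir, "coverage.csv")
  readr::write_csv(coverage, cov_path)
  artifacts <- c(artifacts, sum_path, cov_path)

  if (nrow(records) > 0) {
    pipe_log(config, "rendering stream plot")
    layout <- layout_streams(trk$graph, records,
                             width_feature = config$width_feature,
                             color_feature = config$color_feature)
    plot_path <- file.path(out_dir, "streams.svg")
    render_streams(layout, stream_style(), plot_path,
                   color_feature_name = config$color_feature)
    artifacts <- c(artifacts, plot_path)
  }

  rel <- ifelse(startsWith(artifacts, paste0(out_dir, "/")),
                substring(artifacts, nchar(out_dir) + 2L), artifacts)
  manifest <- tibble::tibble(
    artifact = rel,
    path = artifacts,
    md5 = unname(tools::md5sum(artifacts)))
  man_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(
    purrr::pmap(manifest, function(artifact, path, md5) {
      list(artifact = artifact, md5 = md5)
    }),
    man_path, auto_unbox = TRUE)
  pipe_log(config, "wrote %d artifacts to %s", nrow(manifest), out_dir)
  invisible(manifest)
}
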