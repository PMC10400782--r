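# Pipeline orchestration: frame -> host void -> surface -> descriptors,
# aggregation, optional regression, run manifest.

#' Pipeline configuration
#'
#' Collects every tunable of the simulate -> extract -> describe ->
#' aggregate -> fit chain.  Defaults are the standard cavity-analysis
#' parameters (probe 1.2 A, bottleneck 1.1 A, branch threshold 5 A).
#'
#' @param input Character vector of snapshot paths (GRO/PDB/XYZ), or NULL
#'   when frames are passed to \code{\link{run_pipeline}} directly.
#' @param solute_selector Passed to \code{\link{read_configuration}}.
#' @param probe_radius,bottleneck_radius,pbc_shell Extraction parameters (A).
#' @param branch_threshold,dc Branch detection parameters (A).
#' @param alpha_factor Alpha radius = factor x probe radius.
#' @param sample_area Surface sampling density (A^2 per point).
#' @param stride,max_frames Frame subsampling (uniform stride; random
#'   sampling when \code{random_frames} is TRUE).
#' @param random_frames,seed Random frame sampling toggle and seed.
#' @param out_dir Output directory.
#' @param sd_type,criterion Regression conventions.
#' @param periodic Periodic boundaries.
#' @return A \code{pipeline_config} list.
#' @export
pipeline_config <- function(input = NULL, solute_selector = NULL,
                            probe_radius = 1.2, bottleneck_radius = 1.1,
                            pbc_shell = 6, branch_threshold = 5,
                            dc = branch_threshold / 2, alpha_factor = 2,
                            sample_area = 0.8, stride = 1L,
                            max_frames = Inf, random_frames = FALSE,
                            seed = 1L, out_dir = ".",
                            sd_type = "population", criterion = "loo_mse",
                            periodic = TRUE) {
  if (probe_radius <= 0 || bottleneck_radius <= 0 || branch_threshold <= 0)
    stop("radii and threshold must be positive")
  structure(as.list(environment()), class = "pipeline_config")
}

#' Descriptors of a single frame
#'
#' Extracts the host void of one configuration and computes its descriptor
#' row (V, S, L, nbr, dmin, dmax, dave, dtotal, branch density).
#'
#' @param config A \code{\link{solvated_configuration}} with a solute.
#' @param pcfg A \code{\link{pipeline_config}} (defaults used when omitted).
#' @return A \code{void_descriptors} row with \code{frame_id} prepended.
#' @export
describe_frame <- function(config, pcfg = pipeline_config()) {
  params <- extraction_params(pcfg$probe_radius, pcfg$bottleneck_radius,
                              pcfg$pbc_shell)
  ext <- extract_host_void(config, params, periodic = pcfg$periodic)
  if (is.null(ext$host)) stop("no host void found in frame ", config$frame_id)
  surf <- build_surface(ext$host, ext$graph, alpha_factor = pcfg$alpha_factor,
                        sample_area = pcfg$sample_area)
  br <- detect_branches(surf, config, threshold = pcfg$branch_threshold,
                        dc = pcfg$dc)
  desc <- summarize_descriptors(surf, br, n_heavy_atoms(config))
  cbind(data.frame(frame_id = config$frame_id), desc)
}

#' Run the full pipeline
#'
#' Processes each frame (files from \code{config$input} or in-memory
#' configurations passed as \code{frames}), writes per-frame descriptors and
#' the aggregate row as CSV, and a run manifest as JSON.  Frames failing
#' extraction are logged, skipped and counted; the run errors only when more
#' than half of the frames fail.
#'
#' @param pcfg A \code{\link{pipeline_config}}.
#' @param frames Optional list of \code{solvated_configuration} objects
#'   (overrides \code{pcfg$input}).
#' @return The manifest (list), invisibly; files under \code{pcfg$out_dir}.
#' @export
run_pipeline <- function(pcfg, frames = NULL) {
  stopifnot(inherits(pcfg, "pipeline_config"))
  t0 <- Sys.time()
  if (is.null(frames)) {
    if (is.null(pcfg$input) || length(pcfg$input) == 0)
      stop("no input frames (empty input)")
    paths <- pcfg$input
    loader <- function(i) read_configuration(paths[i],
                                             solute_selector = pcfg$solute_selector)
    n_in <- length(paths)
  } else {
    loader <- function(i) frames[[i]]
    n_in <- length(frames)
  }
  idx <- seq(1, n_in, by = pcfg$stride)
  if (pcfg$random_frames)
    idx <- with_seed(pcfg$seed, sort(sample(idx, min(length(idx),
                                                     pcfg$max_frames))))
  else if (length(idx) > pcfg$max_frames) idx <- idx[seq_len(pcfg$max_frames)]

  dir.create(pcfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  status <- character(length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    res <- tryCatch({
      cfg <- loader(i)
      rows[[length(rows) + 1]] <- describe_frame(cfg, pcfg)
      "ok"
    }, error = function(e) paste0("failed: ", conditionMessage(e)))
    status[k] <- res
    if (res != "ok")
      message("frame ", i, " ", res)
  }
  n_fail <- sum(status != "ok")
  desc <- if (length(rows)) do.call(rbind, rows) else NULL
  manifest <- list(
    config = unclass(pcfg)[setdiff(names(pcfg), "input")],
    input = pcfg$input,
    n_frames = length(idx),
    n_failed = n_fail,
    frame_status = status,
    versions = list(voidshape = as.character(utils::packageVersion("voidshape")),
                    R = paste(R.version$major, R.version$minor, sep = ".")),
    wall_clock_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(pcfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  if (!is.null(desc)) {
    utils::write.csv(desc, file.path(pcfg$out_dir, "descriptors.csv"),
                     row.names = FALSE)
    agg <- aggregate_frames(desc[, setdiff(names(desc), "frame_id")])
    agg_out <- rbind(as.numeric(agg), attr(agg, "se"))
    agg_df <- as.data.frame(agg_out)
    names(agg_df) <- names(agg)
    agg_df <- cbind(data.frame(stat = c("mean", "se")), agg_df)
    utils::write.csv(agg_df, file.path(pcfg$out_dir, "aggregate.csv"),
                     row.names = FALSE)
  }
  if (n_fail > length(idx) / 2)
    stop("more than half of the frames failed (", n_fail, "/", length(idx),
         "); see manifest")
  invisible(manifest)
}
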