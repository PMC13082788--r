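# On-disk session layout and the programmatic entry points behind the
# command-line interface: generate a synthetic dataset directory, track a
# dataset into a session directory, evaluate a session against ground truth.
# All randomness flows from the single seed recorded in metrics.json;
# re-running with an identical config and seed reproduces metrics.json.

#' Read a pipeline configuration file
#'
#' YAML with optional `generator:` and `tracking:` sections (fields as in
#' [generator_config()] and [tracking_config()]) and an optional top-level
#' `seed`. Parsing then serialising then parsing is the identity.
#'
#' @param path YAML file.
#' @return List with `generator` (`pairtrack_gen_config` or `NULL`),
#'   `tracking` (`pairtrack_config`) and `seed`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_invalid_config(paste("no such config:", path))
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop_invalid_config(conditionMessage(e)))
  seed <- raw$seed %||% 1L
  gen <- NULL
  if (!is.null(raw$generator)) {
    args <- raw$generator
    if (is.null(args$seed)) args$seed <- seed
    gen <- tryCatch(do.call(generator_config, args),
                    pairtrack_invalid_input = function(e)
                      stop_invalid_config(conditionMessage(e)),
                    error = function(e)
                      if (inherits(e, "pairtrack_error")) stop(e)
                      else stop_invalid_config(conditionMessage(e)))
  }
  targs <- raw$tracking %||% list()
  if (is.null(targs$seed)) targs$seed <- seed
  if (is.null(targs$n_animals) && !is.null(gen)) targs$n_animals <- gen$n_animals
  trk <- tryCatch(do.call(tracking_config, targs),
                  error = function(e)
                    if (inherits(e, "pairtrack_error")) stop(e)
                    else stop_invalid_config(conditionMessage(e)))
  list(generator = gen, tracking = trk, seed = as.integer(seed))
}

#' Generate a synthetic dataset directory
#'
#' @param config Path to a YAML config with a `generator:` section, or a
#'   config list from [read_config()].
#' @param out_dir Output dataset directory.
#' @param frames Also render full frames as PNGs.
#' @return The dataset directory, invisibly.
#' @export
run_generate <- function(config, out_dir, frames = TRUE) {
  cfg <- if (is.character(config)) read_config(config) else config
  if (is.null(cfg$generator))
    stop_invalid_config("config has no generator section")
  ds <- generate_dataset(cfg$generator, crop_size = cfg$tracking$crop_size)
  write_dataset(ds, out_dir, frames = frames)
  invisible(out_dir)
}

#' Track a dataset directory into a session directory
#'
#' Reads frames (`frames/*.png`) from the input directory, segments them,
#' runs the full pipeline, and writes the session artifacts: `config.yaml`,
#' `fragments.csv`, `model.json`, `cluster_report.json`, `trajectories.csv`,
#' `metrics.json` and `log.jsonl`. Every warning (e.g. low fragment
#' connectivity) is emitted on the console and recorded in `metrics.json`.
#'
#' @param input_dir Dataset directory containing `frames/`.
#' @param out_dir Session directory (created).
#' @param config Path to a YAML config, or a list from [read_config()].
#' @return The `pairtrack` fit, invisibly.
#' @export
run_track <- function(input_dir, out_dir, config) {
  cfg <- if (is.character(config)) read_config(config) else config
  tc <- cfg$tracking
  if (is.null(tc$n_animals))
    stop_invalid_config("tracking config must set n_animals")
  fdir <- file.path(input_dir, "frames")
  if (!dir.exists(fdir))
    stop_invalid_input(paste("no frames/ directory in", input_dir))
  files <- sort(list.files(fdir, pattern = "\\.png$", full.names = TRUE))
  if (!length(files)) stop_invalid_input("no PNG frames found")

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "log.jsonl")
  log_line <- function(...) {
    cat(jsonlite::toJSON(list(time = format(Sys.time()), ...),
                         auto_unbox = TRUE), "\n",
        file = logf, append = TRUE)
  }
  log_line(stage = "segment", n_frames = length(files))

  blobs <- vector("list", length(files))
  for (t in seq_along(files)) {
    img <- png::readPNG(files[t])
    if (length(dim(img)) == 3L) img <- rowMeans(img, dims = 2L)
    blobs[[t]] <- segment_frame(img, tc$intensity_threshold,
                                min_blob_area = tc$min_blob_area,
                                crop_size = tc$crop_size,
                                frame_index = t - 1L)
  }

  log_line(stage = "track", seed = cfg$seed)
  fit <- track(blobs, n_animals = tc$n_animals, config = tc, seed = cfg$seed)
  for (w in fit$warnings) message("warning: ", w)

  yaml::write_yaml(unclass(tc), file.path(out_dir, "config.yaml"))
  utils::write.csv(fragment_table(fit$graph),
                   file.path(out_dir, "fragments.csv"), row.names = FALSE)
  save_model(fit$model, file.path(out_dir, "model.json"))
  jsonlite::write_json(
    list(cluster_sizes = as.integer(table(factor(fit$space$labels,
                                                 levels = seq_len(tc$n_animals)))),
         cluster_silhouettes = fit$space$cluster_silhouettes,
         mean_silhouette = fit$space$mean_silhouette,
         temperature = fit$space$temperature),
    file.path(out_dir, "cluster_report.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(fit$assignment$table,
                   file.path(out_dir, "identities.csv"), row.names = FALSE)
  write_trajectories(fit$trajectories, file.path(out_dir, "trajectories.csv"))
  jsonlite::write_json(
    list(seed = cfg$seed,
         n_animals = fit$graph$n_animals,
         n_frames = fit$graph$n_frames,
         n_fragments = length(fit$graph$fragments),
         connectivity = fit$connectivity,
         n_global_fragments = fit$n_global_fragments,
         n_training_batches = length(fit$history$loss),
         stop_reason = fit$history$stop_reason,
         mean_silhouette = fit$space$mean_silhouette,
         estimated_accuracy = fit$trajectories$estimated_accuracy,
         warnings = fit$warnings),
    file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  log_line(stage = "done", silhouette = fit$space$mean_silhouette)
  invisible(fit)
}

#' Read trajectories written by [write_trajectories()]
#'
#' @param path CSV file.
#' @return A `pairtrack_trajectories` object.
#' @export
read_trajectories <- function(path) {
  if (!file.exists(path)) stop_invalid_input(paste("no such file:", path))
  df <- utils::read.csv(path)
  N <- max(df$id); T <- max(df$frame) + 1L
  pos <- array(NA_real_, c(N, T, 2))
  idx <- cbind(df$id, df$frame + 1L)
  pos[cbind(idx, 1L)] <- df$x
  pos[cbind(idx, 2L)] <- df$y
  prob <- matrix(0, N, T)
  prob[idx] <- if (!is.null(df$probability)) df$probability else 1
  prov <- matrix("missing", N, T)
  prov[idx] <- if (!is.null(df$provenance)) df$provenance else "detected"
  prov[is.na(pos[, , 1])] <- "missing"
  cross <- NULL
  if (!is.null(df$in_crossing)) {
    cross <- matrix(FALSE, N, T); cross[idx] <- as.logical(df$in_crossing)
  }
  new_trajectory_set(pos, prob, prov, in_crossing = cross)
}

#' Evaluate a session against ground truth
#'
#' Computes IDF1 both excluding animal crossings (the core identification
#' accuracy) and including them (the accuracy the user experiences), and
#' writes `evaluation.csv` into the session directory.
#'
#' @param session_dir A directory produced by [run_track()].
#' @param groundtruth Path to a `groundtruth.csv`
#'   (`frame,id,x,y,in_crossing`).
#' @param match_radius Matching radius in pixels.
#' @return Data frame with both scores.
#' @export
run_evaluate <- function(session_dir, groundtruth, match_radius = 7) {
  pred <- read_trajectories(file.path(session_dir, "trajectories.csv"))
  if (!file.exists(groundtruth))
    stop_invalid_input(paste("no such file:", groundtruth))
  gtdf <- utils::read.csv(groundtruth)
  gt <- read_trajectories(groundtruth)
  if (dim(gt$positions)[2] != dim(pred$positions)[2])
    stop_invalid_input("ground truth and session differ in frame count")
  if (is.null(gt$in_crossing)) gt$in_crossing <-
    matrix(FALSE, dim(gt$positions)[1], dim(gt$positions)[2])
  excl <- idf1(pred, gt, match_radius, include_crossings = FALSE)
  incl <- idf1(pred, gt, match_radius, include_crossings = TRUE)
  out <- data.frame(idf1_excl = excl$idf1, idf1_incl = incl$idf1,
                    idtp_excl = excl$idtp, idtp_incl = incl$idtp)
  utils::write.csv(out, file.path(session_dir, "evaluation.csv"),
                   row.names = FALSE)
  out
}
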