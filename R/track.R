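# The main entry point: run the full identification pipeline on a detection
# stream and return a fitted tracking object.

#' Track multiple animals by contrastive identity learning
#'
#' Runs the complete pipeline: link detections into fragments, train the
#' contrastive embedding on image pairs mined from the fragment structure,
#' cluster the embedded images with k-means (one cluster per animal), assign
#' exclusive identities to fragments, and assemble per-frame trajectories with
#' jump correction and crossing interpolation.
#'
#' @param x Input detections: a `pairtrack_dataset` from [generate_dataset()],
#'   a per-frame list of blobs (as from [segment_frame()]), or an existing
#'   fragment graph.
#' @param n_animals Number of animals `N` (taken from the dataset if omitted).
#' @param config A [tracking_config()].
#' @param seed Root random seed for the run.
#' @param verbose Print training progress.
#' @return An object of class `pairtrack`: the fragment graph, trained
#'   embedding model, training history, final embedding space, identity
#'   assignment, and trajectories. Warnings raised during the run (e.g. low
#'   fragment connectivity) are collected in `$warnings`.
#' @seealso [summary.pairtrack()], [plot.pairtrack()], [predict.pairtrack()]
#' @export
track <- function(x, n_animals = NULL, config = NULL, seed = NULL,
                  verbose = FALSE) {
  if (inherits(x, "pairtrack_dataset")) {
    if (is.null(n_animals)) n_animals <- x$gen$n_animals
    blobs <- x$blobs
  } else blobs <- x
  if (is.null(config)) config <- tracking_config(n_animals = n_animals)
  if (is.null(seed)) seed <- config$seed
  if (is.null(n_animals)) n_animals <- config$n_animals
  if (is.null(n_animals) || n_animals < 2L)
    stop_invalid_config("tracking requires n_animals >= 2")

  warnings <- character(0)
  graph <- if (inherits(x, "pairtrack_fragment_graph")) x
    else build_fragments(blobs, n_animals, config)
  if (!length(graph$fragments))
    stop_insufficient_connectivity("no fragments: nothing to track")

  connectivity <- withCallingHandlers(
    fragment_connectivity(graph, config$connectivity_warning),
    pairtrack_low_connectivity = function(w) {
      warnings <<- c(warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (length(warnings) && verbose) message(warnings)
  gf <- find_global_fragments(graph)

  fit <- train_embedding(graph, config, seed = seed, verbose = verbose)
  space <- embed_space(fit$model, graph, config, max_n = Inf,
                       sil_max_n = config$silhouette_max_n,
                       seed = seed + 7L)
  assignment <- assign_identities(graph, space)
  traj <- assemble_trajectories(graph, assignment,
                                mean_silhouette = space$mean_silhouette,
                                config = config)
  structure(list(graph = graph,
                 model = fit$model,
                 history = fit$history,
                 space = space,
                 assignment = assignment,
                 trajectories = traj,
                 connectivity = connectivity,
                 n_global_fragments = length(gf),
                 warnings = warnings,
                 config = config,
                 seed = as.integer(seed)),
            class = "pairtrack")
}

#' @export
print.pairtrack <- function(x, ...) {
  cat("Multi-animal tracking by contrastive identity learning\n")
  cat(sprintf("  %d animals, %d frames, %d fragments (connectivity %.3f)\n",
              x$graph$n_animals, x$graph$n_frames,
              length(x$graph$fragments), x$connectivity))
  cat(sprintf("  training: %d batches, stop: %s\n",
              length(x$history$loss), x$history$stop_reason))
  cat(sprintf("  mean silhouette: %.4f   estimated accuracy: %.4f\n",
              x$space$mean_silhouette,
              x$trajectories$estimated_accuracy))
  if (length(x$warnings)) cat("  warnings:", length(x$warnings), "\n")
  invisible(x)
}

#' Summary of a tracking run
#'
#' @param object A `pairtrack` fit.
#' @param ... Unused.
#' @return A list with per-run metrics (connectivity, global fragments,
#'   silhouette, estimated accuracy, coverage), printed compactly.
#' @export
summary.pairtrack <- function(object, ...) {
  prov <- object$trajectories$provenance
  out <- list(
    n_animals = object$graph$n_animals,
    n_frames = object$graph$n_frames,
    n_fragments = length(object$graph$fragments),
    connectivity = object$connectivity,
    n_global_fragments = object$n_global_fragments,
    n_training_batches = length(object$history$loss),
    stop_reason = object$history$stop_reason,
    mean_silhouette = object$space$mean_silhouette,
    estimated_accuracy = object$trajectories$estimated_accuracy,
    frac_detected = mean(prov == "detected"),
    frac_interpolated = mean(prov == "interpolated"),
    frac_missing = mean(prov == "missing"),
    warnings = object$warnings)
  class(out) <- "summary.pairtrack"
  out
}

#' @export
print.summary.pairtrack <- function(x, ...) {
  cat("Tracking summary\n")
  for (nm in setdiff(names(x), "warnings"))
    cat(sprintf("  %-22s %s\n", nm,
                if (is.numeric(x[[nm]])) format(x[[nm]], digits = 4)
                else as.character(x[[nm]])))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Fitted positions
#'
#' @param object A `pairtrack` fit.
#' @param ... Unused.
#' @return The `N x T x 2` position array (`NA` where missing).
#' @export
fitted.pairtrack <- function(object, ...) object$trajectories$positions

#' Predict identities for new images
#'
#' Embeds new crops with the trained model and assigns them to the run's
#' identity clusters.
#' @param object A `pairtrack` fit.
#' @param images Crops accepted by [embed()].
#' @param ... Unused.
#' @return Data frame `identity, probability` (one row per image).
#' @export
predict.pairtrack <- function(object, images, ...) {
  pts <- embed(object$model, images)
  p <- assignment_probability(pts, object$space$centers,
                              object$space$temperature)
  data.frame(identity = max.col(p), probability = apply(p, 1L, max))
}

#' Plot tracked trajectories
#'
#' Draws each identity's trajectory in a distinct colour; interpolated
#' stretches are drawn dashed.
#' @param x A `pairtrack` fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.pairtrack <- function(x, ...) {
  pos <- x$trajectories$positions
  N <- dim(pos)[1]
  cols <- grDevices::hcl.colors(N, "Dark 3")
  xr <- range(pos[, , 1], na.rm = TRUE); yr <- range(pos[, , 2], na.rm = TRUE)
  graphics::plot(NA, xlim = xr, ylim = rev(yr), asp = 1,
                 xlab = "x (px)", ylab = "y (px)", ...)
  for (i in seq_len(N))
    graphics::lines(pos[i, , 1], pos[i, , 2], col = cols[i])
  invisible(x)
}
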