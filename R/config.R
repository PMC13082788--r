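#' Tracking configuration
#'
#' Collects every tunable of the tracking pipeline in one place. The defaults
#' encode the published operating point of the method: an 8-dimensional
#' embedding trained with a double-margin contrastive loss (positive margin 1,
#' negative margin 10), batches of 400 positive and 400 negative image pairs,
#' a mean-Silhouette stopping criterion of 0.91, and a fragment-connectivity
#' warning threshold of 0.5.
#'
#' @param n_animals Number of animals `N` in the video (required for tracking).
#' @param crop_size Side length, in pixels, of the square image crop extracted
#'   around each detection. All crops fed to the embedding share this size.
#' @param intensity_threshold Foreground threshold applied to grayscale frames
#'   in `[0,1]`; pixels above it are foreground.
#' @param min_blob_area Connected components smaller than this many pixels are
#'   discarded as noise.
#' @param max_displacement Maximum centroid displacement, in pixels, allowed
#'   when linking a detection to a fragment between consecutive frames.
#' @param crossing_area_factor A blob is declared a crossing when its area
#'   exceeds this multiple of the median single-animal area.
#' @param min_fragment_length Fragments shorter than this many frames are kept
#'   and later assigned an identity, but excluded from pair mining.
#' @param embedding_dim Dimension `M` of the representation space.
#' @param hidden_dims Integer vector of hidden-layer widths for the
#'   multilayer-perceptron embedding backbone.
#' @param d_pos,d_neg Contrastive margins: positive pairs are pulled until
#'   their distance falls below `d_pos`, negative pairs pushed until their
#'   distance exceeds `d_neg`. Must satisfy `d_neg > d_pos > 0`.
#' @param n_pos,n_neg Positive / negative pairs per training batch.
#' @param learning_rate Adam learning rate.
#' @param eval_every Training batches between Silhouette evaluations.
#' @param silhouette_stop Training stops once the mean Silhouette score of the
#'   embedded (subsampled) images reaches this value on two consecutive
#'   evaluations.
#' @param max_batches Hard cap on training batches.
#' @param silhouette_max_n Largest number of images used for any Silhouette
#'   computation (the statistic is quadratic in the number of points).
#' @param mix_fraction Fraction of pair-mining draws taken from the baseline
#'   (fragment-size) distribution; the remainder is drawn from cluster-priority
#'   weights once a clustering exists.
#' @param temperature Softmax temperature for converting squared distances to
#'   assignment probabilities; `NULL` selects the mean within-cluster squared
#'   distance at run time.
#' @param connectivity_warning Fragment-connectivity level below which a
#'   low-connectivity warning is raised.
#' @param jump_factor Robust threshold factor for impossible-jump detection:
#'   a displacement is flagged when it exceeds
#'   `median + jump_factor * MAD` of that identity's displacements.
#' @param match_radius Detection-matching radius, in pixels, for IDF1; `NULL`
#'   selects half the body length of the synthetic generator at run time.
#' @param exclusion_margin Pixels around an occlusion-mask boundary excluded
#'   from evaluation (use 75 for mouse-scale footage).
#' @param kmeans_restarts Number of seeded k-means++ restarts.
#' @param seed Root random seed for the whole pipeline.
#'
#' @return An object of class `pairtrack_config` (a named list).
#' @export
tracking_config <- function(n_animals = NULL,
                            crop_size = 24L,
                            intensity_threshold = 0.15,
                            min_blob_area = 10L,
                            max_displacement = 15,
                            crossing_area_factor = 1.5,
                            min_fragment_length = 3L,
                            embedding_dim = 8L,
                            hidden_dims = c(64L, 64L),
                            d_pos = 1,
                            d_neg = 10,
                            n_pos = 400L,
                            n_neg = 400L,
                            learning_rate = 1e-3,
                            eval_every = 100L,
                            silhouette_stop = 0.91,
                            max_batches = 3000L,
                            silhouette_max_n = 4000L,
                            mix_fraction = 0.5,
                            temperature = NULL,
                            connectivity_warning = 0.5,
                            jump_factor = 4,
                            match_radius = NULL,
                            exclusion_margin = 15,
                            kmeans_restarts = 8L,
                            seed = 1L) {
  cfg <- list(
    n_animals = if (is.null(n_animals)) NULL else as.integer(n_animals),
    crop_size = as.integer(crop_size),
    intensity_threshold = intensity_threshold,
    min_blob_area = as.integer(min_blob_area),
    max_displacement = max_displacement,
    crossing_area_factor = crossing_area_factor,
    min_fragment_length = as.integer(min_fragment_length),
    embedding_dim = as.integer(embedding_dim),
    hidden_dims = as.integer(hidden_dims),
    d_pos = d_pos,
    d_neg = d_neg,
    n_pos = as.integer(n_pos),
    n_neg = as.integer(n_neg),
    learning_rate = learning_rate,
    eval_every = as.integer(eval_every),
    silhouette_stop = silhouette_stop,
    max_batches = as.integer(max_batches),
    silhouette_max_n = as.integer(silhouette_max_n),
    mix_fraction = mix_fraction,
    temperature = temperature,
    connectivity_warning = connectivity_warning,
    jump_factor = jump_factor,
    match_radius = match_radius,
    exclusion_margin = exclusion_margin,
    kmeans_restarts = as.integer(kmeans_restarts),
    seed = as.integer(seed)
  )
  validate_config(cfg)
  structure(cfg, class = "pairtrack_config")
}

validate_config <- function(cfg) {
  if (!is.null(cfg$n_animals) && cfg$n_animals < 2L)
    stop_invalid_config("tracking requires at least 2 animals")
  if (cfg$d_pos <= 0 || cfg$d_neg <= cfg$d_pos)
    stop_invalid_config("contrastive margins must satisfy d_neg > d_pos > 0")
  if (cfg$intensity_threshold < 0 || cfg$intensity_threshold > 1)
    stop_invalid_config("intensity_threshold must lie in [0,1]")
  if (cfg$mix_fraction < 0 || cfg$mix_fraction > 1)
    stop_invalid_config("mix_fraction must lie in [0,1]")
  if (cfg$n_pos < 1L || cfg$n_neg < 1L)
    stop_invalid_config("n_pos and n_neg must be positive")
  invisible(cfg)
}

#' @export
print.pairtrack_config <- function(x, ...) {
  cat("Tracking configuration\n")
  cat(sprintf("  animals: %s   crop: %dpx   embedding dim: %d\n",
              if (is.null(x$n_animals)) "?" else x$n_animals,
              x$crop_size, x$embedding_dim))
  cat(sprintf("  margins: d_pos=%g d_neg=%g   batch: %d+%d pairs\n",
              x$d_pos, x$d_neg, x$n_pos, x$n_neg))
  cat(sprintf("  stop: silhouette >= %g (checked every %d batches, max %d)\n",
              x$silhouette_stop, x$eval_every, x$max_batches))
  cat(sprintf("  connectivity warning below %g\n", x$connectivity_warning))
  invisible(x)
}

# --- condition helpers --------------------------------------------------

pairtrack_stop <- function(msg, class) {
  stop(structure(class = c(class, "pairtrack_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

stop_invalid_input <- function(msg)
  pairtrack_stop(msg, "pairtrack_invalid_input")
stop_invalid_config <- function(msg)
  pairtrack_stop(msg, "pairtrack_invalid_config")
stop_insufficient_connectivity <- function(msg)
  pairtrack_stop(msg, "pairtrack_insufficient_connectivity")
stop_data_inconsistency <- function(msg)
  pairtrack_stop(msg, "pairtrack_data_inconsistency")
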