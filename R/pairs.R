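# Label-free pair mining. Positive pairs: two images from one fragment (same
# animal by construction). Negative pairs: one image from each of two
# temporally coexisting fragments (different animals by construction).
# Batches mix a baseline fragment-size distribution with priority sampling
# of fragments in poorly formed clusters.

#' Sampling weights for pair mining
#'
#' Baseline weights are proportional to fragment image counts over the
#' fragments eligible for pair mining (at least `min_fragment_length` images).
#' Once a clustering exists, per-cluster priorities proportional to
#' `max(0, 1 - silhouette_c)` concentrate sampling on underperforming
#' clusters while the baseline keeps every fragment in play.
#'
#' @param graph A fragment graph.
#' @param config A [tracking_config()].
#' @param cluster_silhouettes Optional per-cluster mean Silhouette scores from
#'   the most recent clustering.
#' @param fragment_clusters Optional integer vector: current cluster of each
#'   fragment (`NA` allowed), parallel to `graph$fragments`.
#' @return An object of class `pairtrack_weights`.
#' @export
sampling_weights <- function(graph, config = graph$config,
                             cluster_silhouettes = NULL,
                             fragment_clusters = NULL) {
  fr <- graph$fragments
  n_img <- vapply(fr, `[[`, integer(1), "n_images")
  eligible <- n_img >= max(2L, config$min_fragment_length)
  baseline <- ifelse(eligible, n_img, 0)
  if (sum(baseline) == 0)
    stop_insufficient_connectivity("no fragment is long enough for pair mining")
  baseline <- baseline / sum(baseline)

  priority <- NULL
  if (!is.null(cluster_silhouettes) && !is.null(fragment_clusters)) {
    cw <- pmax(0, 1 - cluster_silhouettes)
    if (sum(cw) == 0) cw <- rep(1, length(cw))
    cw <- cw / sum(cw)
    priority <- numeric(length(fr))
    for (c in seq_along(cw)) {
      members <- which(fragment_clusters == c & eligible)
      if (length(members)) {
        within <- n_img[members] / sum(n_img[members])
        priority[members] <- cw[c] * within
      }
    }
    priority <- if (sum(priority) > 0) priority / sum(priority) else NULL
  }
  structure(list(baseline = baseline, priority = priority,
                 eligible = eligible,
                 mix_fraction = config$mix_fraction),
            class = "pairtrack_weights")
}

#' Sample a positive pair
#'
#' Two distinct images of the same (unknown) individual, drawn from within one
#' fragment.
#' @param fragment A fragment with at least 2 images.
#' @param seed Optional seed for reproducibility.
#' @return List with `fragment_id`, image indices `i`, `j` and the two crops.
#' @export
sample_positive_pair <- function(fragment, seed = NULL) {
  if (fragment$n_images < 2L)
    stop_invalid_input("positive pairs need a fragment with at least 2 images")
  draw <- function() {
    ij <- sample.int(fragment$n_images, 2L)
    list(fragment_id = fragment$id, i = ij[1], j = ij[2],
         images = fragment$images[ij])
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Sample a negative pair
#'
#' One image from each of two coexisting fragments. Coexistence is the only
#' label-free guarantee that the images show different animals, so
#' non-coexisting fragments are a contract violation.
#' @param a,b Coexisting fragments, each with at least one image.
#' @param seed Optional seed.
#' @return List with fragment ids, image indices and the two crops.
#' @export
sample_negative_pair <- function(a, b, seed = NULL) {
  if (!coexist(a, b))
    stop_invalid_input("negative pairs require temporally coexisting fragments")
  draw <- function() {
    i <- sample.int(a$n_images, 1L); j <- sample.int(b$n_images, 1L)
    list(fragment_a = a$id, fragment_b = b$id, i = i, j = j,
         images = list(a$images[[i]], b$images[[j]]))
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Compose a training batch of image pairs
#'
#' Draws `n_pos` positive and `n_neg` negative pairs. Fragment selection mixes
#' the baseline distribution (fraction `mix_fraction`) with cluster-priority
#' weights; before any clustering exists only the baseline is used. The second
#' fragment of a negative pair is chosen uniformly among coexisting eligible
#' partners.
#'
#' @param graph A fragment graph.
#' @param weights A [sampling_weights()] object.
#' @param n_pos,n_neg Pair counts.
#' @param seed Optional seed.
#' @return An object of class `pairtrack_batch` with index matrices
#'   `positives` (`fragment, i, j`) and `negatives`
#'   (`fragment_a, i, fragment_b, j`), and `images_total`.
#' @export
make_batch <- function(graph, weights, n_pos = 400L, n_neg = 400L,
                       seed = NULL) {
  run <- function() make_batch_impl(graph, weights, n_pos, n_neg)
  if (is.null(seed)) run() else with_seed(seed, run())
}

make_batch_impl <- function(graph, weights, n_pos, n_neg) {
  fr <- graph$fragments
  w <- fragment_draw_weights(weights)
  if (sum(w > 0) == 0)
    stop_insufficient_connectivity("no fragments available for pair mining")

  # adjacency restricted to eligible fragments
  adj <- coexistence_partners(graph, weights$eligible)
  has_partner <- lengths(adj) > 0
  w_neg <- w * has_partner
  if (n_neg > 0L && sum(w_neg) == 0)
    stop_insufficient_connectivity(
      "no coexisting fragment pairs: cannot mine negative pairs")

  n_img <- vapply(fr, `[[`, integer(1), "n_images")

  fa <- sample.int(length(fr), n_pos, replace = TRUE, prob = w)
  positives <- matrix(0L, n_pos, 3,
                      dimnames = list(NULL, c("fragment", "i", "j")))
  for (r in seq_len(n_pos)) {
    ij <- sample.int(n_img[fa[r]], 2L)
    positives[r, ] <- c(fa[r], ij)
  }

  negatives <- matrix(0L, n_neg, 4,
                      dimnames = list(NULL, c("fragment_a", "i", "fragment_b", "j")))
  if (n_neg > 0L) {
    na_ <- sample.int(length(fr), n_neg, replace = TRUE, prob = w_neg)
    for (r in seq_len(n_neg)) {
      partners <- adj[[na_[r]]]
      nb <- partners[sample.int(length(partners), 1L)]
      negatives[r, ] <- c(na_[r], sample.int(n_img[na_[r]], 1L),
                          nb, sample.int(n_img[nb], 1L))
    }
  }
  structure(list(positives = positives, negatives = negatives,
                 images_total = 2L * (n_pos + n_neg)),
            class = "pairtrack_batch")
}

fragment_draw_weights <- function(weights) {
  if (is.null(weights$priority)) return(weights$baseline)
  b <- weights$mix_fraction
  b * weights$baseline + (1 - b) * weights$priority
}

coexistence_partners <- function(graph, eligible = NULL) {
  F <- length(graph$fragments)
  adj <- vector("list", F)
  for (i in seq_len(F)) adj[[i]] <- integer()
  if (nrow(graph$edges)) for (r in seq_len(nrow(graph$edges))) {
    a <- graph$edges[r, 1]; b <- graph$edges[r, 2]
    ok_a <- is.null(eligible) || eligible[a]
    ok_b <- is.null(eligible) || eligible[b]
    if (ok_b) adj[[a]] <- c(adj[[a]], b)
    if (ok_a) adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# Gather the pixel matrices for both members of every pair in a batch.
# Rows 1..B of each matrix correspond to the B = n_pos + n_neg pairs,
# positives first.
batch_matrices <- function(graph, batch) {
  fr <- graph$fragments
  p <- batch$positives; q <- batch$negatives
  X1 <- rbind(
    gather_images(fr, p[, "fragment"], p[, "i"]),
    gather_images(fr, q[, "fragment_a"], q[, "i"]))
  X2 <- rbind(
    gather_images(fr, p[, "fragment"], p[, "j"]),
    gather_images(fr, q[, "fragment_b"], q[, "j"]))
  list(X1 = X1, X2 = X2,
       is_positive = c(rep(TRUE, nrow(p)), rep(FALSE, nrow(q))))
}

gather_images <- function(fragments, frag_idx, img_idx) {
  if (!length(frag_idx)) return(NULL)
  d <- ncol(fragments[[frag_idx[1]]]$images_mat)
  X <- matrix(0, length(frag_idx), d)
  for (r in seq_along(frag_idx))
    X[r, ] <- fragments[[frag_idx[r]]]$images_mat[img_idx[r], ]
  X
}
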