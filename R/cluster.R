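# Identity assignment: k-means with one cluster per animal on the embedded
# images, mean Silhouette score as the clustering quality gauge, soft
# assignment probabilities from distances to cluster centers, and exclusive
# per-fragment identities via optimal matching within sets of coexisting
# fragments.

#' k-means clustering with k-means++ seeding
#'
#' Deterministic given the seed: k-means++ initialisation followed by Lloyd
#' iterations, best of `restarts` seeded restarts by total within-cluster sum
#' of squares. Degenerate inputs (fewer distinct points than clusters) are
#' handled by re-seeding duplicate centers with small jitter and flagged via
#' the `degenerate` attribute.
#'
#' @param points `n x M` numeric matrix.
#' @param k Number of clusters (`2 <= k <= n`).
#' @param seed Random seed.
#' @param restarts Number of restarts.
#' @return List with `centers` (`k x M`) and `labels` (length `n`).
#' @export
kmeans_cluster <- function(points, k, seed = 1L, restarts = 8L) {
  n <- nrow(points)
  if (n < k) stop_invalid_input("k-means needs at least k points")
  if (k < 2L) stop_invalid_input("k must be at least 2")
  degenerate <- nrow(unique(points)) < k
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(restarts)) {
      init <- kmeanspp_init(points, k)
      if (degenerate || anyDuplicated(init))
        init <- init + matrix(stats::rnorm(length(init), sd = 1e-6),
                              nrow(init))
      fit <- suppressWarnings(
        stats::kmeans(points, centers = init, iter.max = 100L,
                      algorithm = "Lloyd"))
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    structure(list(centers = best$centers, labels = best$cluster,
                   tot_withinss = best$tot.withinss),
              degenerate = degenerate)
  })
}

kmeanspp_init <- function(points, k) {
  n <- nrow(points)
  centers <- matrix(NA_real_, k, ncol(points))
  centers[1L, ] <- points[sample.int(n, 1L), ]
  d2 <- rowSums(sweep(points, 2L, centers[1L, ])^2)
  for (j in seq_len(k - 1L) + 1L) {
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j, ] <- points[sample.int(n, 1L, prob = prob), ]
    d2 <- pmin(d2, rowSums(sweep(points, 2L, centers[j, ])^2))
  }
  centers
}

#' Assignment probabilities from distances to cluster centers
#'
#' Each image is assigned to a cluster with probability increasing the closer
#' it lies to the cluster center: `p_c` proportional to
#' `exp(-||x - center_c||^2 / temperature)`, normalised per image.
#'
#' @param points `n x M` matrix (or a single point).
#' @param centers `k x M` matrix of cluster centers.
#' @param temperature Positive softmax temperature.
#' @return `n x k` matrix of probabilities; rows sum to 1.
#' @export
assignment_probability <- function(points, centers, temperature) {
  if (temperature <= 0) stop_invalid_input("temperature must be positive")
  if (!is.matrix(points)) points <- matrix(points, 1L)
  d2 <- squared_distances(points, centers)
  logp <- -d2 / temperature
  logp <- logp - apply(logp, 1L, max)
  p <- exp(logp)
  p / rowSums(p)
}

squared_distances <- function(A, B) {
  # ||a||^2 + ||b||^2 - 2 a.b, clipped at 0 against rounding
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  pmax(d2, 0)
}

#' Mean Silhouette score
#'
#' Standard Silhouette: per point `(b - a) / max(a, b)` with `a` the mean
#' distance to its own cluster and `b` the smallest mean distance to another
#' cluster; singletons score 0. The mean over points gauges intra-cluster
#' cohesion and inter-cluster separation; 1 indicates ideal clustering.
#' Computed in chunks so no full `n x n` distance matrix is ever held.
#'
#' @param points `n x M` matrix.
#' @param labels Integer cluster labels.
#' @param by_cluster Also return per-cluster mean scores.
#' @return The mean Silhouette in `[-1, 1]`, or (with `by_cluster = TRUE`) a
#'   list with `mean`, `per_cluster` and `per_point`.
#' @export
mean_silhouette <- function(points, labels, by_cluster = FALSE) {
  labels <- as.integer(factor(labels))
  k <- max(labels)
  if (k < 2L) stop_invalid_input("Silhouette requires at least 2 clusters")
  n <- nrow(points)
  sizes <- tabulate(labels, k)
  ind <- matrix(0, n, k)
  ind[cbind(seq_len(n), labels)] <- 1
  s <- numeric(n)
  chunk <- 1024L
  for (lo in seq(1L, n, by = chunk)) {
    hi <- min(lo + chunk - 1L, n)
    D <- sqrt(squared_distances(points[lo:hi, , drop = FALSE], points))
    sums <- D %*% ind                       # chunk x k distance sums
    own <- labels[lo:hi]
    rows <- seq_len(hi - lo + 1L)
    a <- sums[cbind(rows, own)] / pmax(1L, sizes[own] - 1L)
    mean_other <- sweep(sums, 2L, sizes, "/")
    mean_other[cbind(rows, own)] <- Inf
    b <- apply(mean_other, 1L, min)
    si <- (b - a) / pmax(a, b)
    si[sizes[own] == 1L] <- 0               # singleton convention
    s[lo:hi] <- si
  }
  if (!by_cluster) return(mean(s))
  list(mean = mean(s),
       per_cluster = vapply(seq_len(k), function(c) mean(s[labels == c]),
                            numeric(1)),
       per_point = s)
}

# ---- embedding space ------------------------------------------------------

# Take up to max_n images, at least one per fragment where possible,
# proportionally to fragment size. Returns index vectors (fragment, image).
subsample_images <- function(graph, max_n = Inf) {
  n_img <- vapply(graph$fragments, `[[`, integer(1), "n_images")
  keep <- which(n_img > 0L)
  total <- sum(n_img)
  if (total <= max_n) {
    frag <- rep(keep, n_img[keep])
    img <- unlist(lapply(keep, function(f) seq_len(n_img[f])))
    return(list(frag = frag, img = img))
  }
  alloc <- pmax(1L, floor(max_n * n_img[keep] / total))
  while (sum(alloc) > max_n) {
    j <- which.max(alloc)
    alloc[j] <- alloc[j] - 1L
  }
  frag <- integer(0); img <- integer(0)
  for (t in seq_along(keep)) {
    f <- keep[t]
    take <- sort(sample.int(n_img[f], min(alloc[t], n_img[f])))
    frag <- c(frag, rep(f, length(take)))
    img <- c(img, take)
  }
  list(frag = frag, img = img)
}

#' Embed and cluster the video's images
#'
#' Embeds (a subsample of) all fragment images, clusters them with k-means
#' (`k = N`), converts distances to per-image assignment probabilities, and
#' scores the clustering with the mean Silhouette. The softmax temperature
#' defaults to the mean within-cluster squared distance of the fit.
#'
#' @param model An embedding model.
#' @param graph A fragment graph.
#' @param config A [tracking_config()].
#' @param max_n Cap on the number of images used (default: all).
#' @param sil_max_n Cap on the number of points entering the Silhouette score
#'   (quadratic cost); clustering and probabilities always use all `max_n`
#'   images.
#' @param seed Random seed for the subsample and k-means.
#' @return An object of class `pairtrack_embedding_space`.
#' @export
embed_space <- function(model, graph, config = graph$config, max_n = Inf,
                        sil_max_n = config$silhouette_max_n, seed = 1L) {
  sub <- with_seed(seed, subsample_images(graph, max_n))
  X <- gather_images(graph$fragments, sub$frag, sub$img)
  points <- mlp_forward(model, X)
  km <- kmeans_cluster(points, graph$n_animals, seed = seed,
                       restarts = config$kmeans_restarts)
  tau <- config$temperature
  if (is.null(tau)) tau <- max(km$tot_withinss / nrow(points), 1e-6)
  probs <- assignment_probability(points, km$centers, tau)
  sil_rows <- if (nrow(points) > sil_max_n)
    with_seed(seed + 1L, sort(sample.int(nrow(points), sil_max_n)))
    else seq_len(nrow(points))
  sil <- mean_silhouette(points[sil_rows, , drop = FALSE],
                         km$labels[sil_rows], by_cluster = TRUE)
  cluster_sil <- rep(0, graph$n_animals)
  cluster_sil[sort(unique(km$labels[sil_rows]))] <- sil$per_cluster
  structure(list(points = points, frag = sub$frag, img = sub$img,
                 centers = km$centers, labels = km$labels,
                 probabilities = probs, temperature = tau,
                 mean_silhouette = sil$mean,
                 cluster_silhouettes = cluster_sil,
                 degenerate = isTRUE(attr(km, "degenerate"))),
            class = "pairtrack_embedding_space")
}

#' @export
print.pairtrack_embedding_space <- function(x, ...) {
  cat(sprintf("Embedding space: %d images, %d clusters, mean Silhouette %.3f\n",
              nrow(x$points), nrow(x$centers), x$mean_silhouette))
  invisible(x)
}

# Majority cluster of each fragment under the current space (NA if unseen).
fragment_clusters <- function(graph, space) {
  F <- length(graph$fragments)
  out <- rep(NA_integer_, F)
  tab <- tapply(space$labels, space$frag, function(l)
    as.integer(names(which.max(table(l)))))
  out[as.integer(names(tab))] <- unlist(tab)
  out
}

# ---- exclusive identity assignment ---------------------------------------

#' Assign identities to fragments
#'
#' Each fragment's identity is the cluster with the highest mean per-image
#' assignment probability; its confidence is that mean. Coexisting fragments
#' must hold different animals, so conflicts are resolved by maximum-weight
#' one-to-one matching (summed confidence) within each maximal set of mutually
#' coexisting fragments.
#'
#' @param graph A fragment graph.
#' @param space An [embed_space()] result with `k = N` clusters.
#' @return A list with `table` (data frame `fragment_id, identity,
#'   confidence`), `prob_matrix` (fragments x identities mean probabilities),
#'   and `estimated_accuracy` (mean assignment confidence over all images).
#' @export
assign_identities <- function(graph, space) {
  F <- length(graph$fragments)
  k <- nrow(space$centers)
  if (k != graph$n_animals)
    stop_invalid_input("the embedding space must be clustered with k = N")

  pm <- matrix(0, F, k)
  counts <- integer(F)
  for (r in seq_len(nrow(space$probabilities))) {
    f <- space$frag[r]
    pm[f, ] <- pm[f, ] + space$probabilities[r, ]
    counts[f] <- counts[f] + 1L
  }
  seen <- counts > 0L
  pm[seen, ] <- pm[seen, ] / counts[seen]
  pm[!seen, ] <- 1 / k

  identity <- rep(NA_integer_, F)
  g <- igraph::make_graph(as.vector(t(graph$edges)), n = F, directed = FALSE)
  cliques <- igraph::max_cliques(g, min = 1L)
  sizes <- lengths(cliques)
  starts <- vapply(cliques, function(cl)
    min(vapply(graph$fragments[as.integer(cl)], `[[`, numeric(1), "start")),
    numeric(1))
  for (ci in order(-sizes, starts)) {
    members <- as.integer(cliques[[ci]])
    if (length(members) > k)
      stop_data_inconsistency(sprintf(
        "%d mutually coexisting fragments exceed the %d animals",
        length(members), k))
    locked <- members[!is.na(identity[members])]
    # unlock lower-confidence duplicates if earlier cliques disagreed
    if (anyDuplicated(identity[locked])) {
      for (idv in unique(identity[locked][duplicated(identity[locked])])) {
        dup <- locked[identity[locked] == idv]
        conf <- pm[cbind(dup, identity[dup])]
        identity[dup[-which.max(conf)]] <- NA_integer_
      }
      locked <- members[!is.na(identity[members])]
    }
    free <- members[is.na(identity[members])]
    if (!length(free)) next
    avail <- setdiff(seq_len(k), identity[locked])
    sol <- solve_assignment_max(pm[free, avail, drop = FALSE])
    identity[free] <- avail[sol]
  }
  confidence <- pm[cbind(seq_len(F), identity)]
  est_acc <- sum(confidence * counts) / sum(counts)
  list(table = data.frame(fragment_id = vapply(graph$fragments, `[[`,
                                               integer(1), "id"),
                          identity = identity,
                          confidence = confidence),
       prob_matrix = pm,
       estimated_accuracy = est_acc)
}

# Maximum-weight one-to-one assignment of rows to columns (nrow <= ncol),
# exact via weighted bipartite matching. Returns the column index chosen for
# each row.
solve_assignment_max <- function(benefit) {
  n <- nrow(benefit); m <- ncol(benefit)
  if (n == 0L) return(integer())
  if (n > m) stop_invalid_input("assignment needs at least as many columns as rows")
  if (n == 1L) return(which.max(benefit[1L, ]))
  w <- benefit - min(benefit) + 1          # strictly positive weights
  edges <- rbind(rep(seq_len(n), each = m), n + rep(seq_len(m), n))
  g <- igraph::make_bipartite_graph(c(rep(FALSE, n), rep(TRUE, m)),
                                    as.vector(edges))
  mm <- igraph::max_bipartite_match(g, weights = as.vector(t(w)))
  as.integer(mm$matching[seq_len(n)]) - n
}
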