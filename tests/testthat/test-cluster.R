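# k-means clustering, assignment probabilities, the Silhouette score, and
# exclusive identity assignment.

blob_points <- function(centers, per = 20, sd = 0.1, seed = 1) {
  set.seed(seed)
  pts <- do.call(rbind, lapply(seq_len(nrow(centers)), function(k)
    sweep(matrix(stats::rnorm(per * ncol(centers), sd = sd), per), 2,
          centers[k, ], "+")))
  list(points = pts, labels = rep(seq_len(nrow(centers)), each = per))
}

test_that("k-means recovers well-separated blobs deterministically", {
  b <- blob_points(rbind(c(0, 0), c(10, 0), c(0, 10)))
  fit <- kmeans_cluster(b$points, 3, seed = 2)
  # same partition as ground truth up to label permutation
  expect_equal(length(unique(paste(fit$labels, b$labels))), 3L)
  fit2 <- kmeans_cluster(b$points, 3, seed = 2)
  expect_identical(fit$labels, fit2$labels)
  expect_identical(fit$centers, fit2$centers)
  expect_error(kmeans_cluster(b$points[1:2, ], 3),
               class = "pairtrack_invalid_input")
})

test_that("degenerate inputs are flagged but still clustered", {
  pts <- matrix(1, 10, 2)           # one distinct point, k = 2
  fit <- kmeans_cluster(pts, 2, seed = 1)
  expect_true(attr(fit, "degenerate"))
  expect_length(fit$labels, 10L)
})

test_that("assignment probabilities behave like a distance softmax", {
  centers <- rbind(c(0, 0), c(4, 0), c(0, 4))
  # equidistant point: uniform probabilities
  p <- assignment_probability(c(4 / 2, 0), rbind(c(0, 0), c(4, 0)), 1)
  expect_equal(drop(p), c(0.5, 0.5))
  # probability rows sum to one and respect distance ordering
  pts <- matrix(stats::rnorm(40), 20)
  P <- assignment_probability(pts, centers, 0.7)
  expect_equal(rowSums(P), rep(1, 20))
  d2 <- pairtrack:::squared_distances(pts, centers)
  expect_identical(apply(P, 1, which.max), apply(d2, 1, which.min))
  # low temperature concentrates on the nearest center
  Pcold <- assignment_probability(pts, centers, 1e-4)
  expect_true(all(apply(Pcold, 1, max) > 0.999))
  # permuting centers permutes the columns
  perm <- c(3, 1, 2)
  Pp <- assignment_probability(pts, centers[perm, ], 0.7)
  expect_equal(Pp, P[, perm])
  expect_error(assignment_probability(pts, centers, 0),
               class = "pairtrack_invalid_input")
})

test_that("ideal clusterings score a Silhouette of exactly 1", {
  # identical points within each cluster, distinct across clusters
  pts <- rbind(matrix(0, 5, 2),
               matrix(rep(c(10, 0), each = 5), 5),
               matrix(rep(c(0, 10), each = 5), 5))
  labels <- rep(1:3, each = 5)
  expect_identical(mean_silhouette(pts, labels), 1)
})

test_that("the Silhouette matches worked examples and reference code", {
  # 1-d worked example: {0, 1} vs {10, 11}
  pts <- matrix(c(0, 1, 10, 11), ncol = 1)
  labels <- c(1L, 1L, 2L, 2L)
  a <- 1; b <- mean(c(10, 11))   # for the first point: a = 1, b = 10.5
  s1 <- (b - a) / max(a, b)
  expect_equal(mean_silhouette(pts, labels),
               mean(c(s1, (9.5 - 1) / 9.5, (9.5 - 1) / 9.5, s1)))
  # a deliberately bad labelling gives a negative mean score
  expect_lt(mean_silhouette(pts, c(1L, 2L, 1L, 2L)), 0)
  # random data: chunked computation equals the textbook formula and the
  # cluster package, and singletons score 0
  set.seed(4)
  for (rep in 1:5) {
    n <- sample(5:60, 1)
    k <- sample(2:4, 1)
    pts <- matrix(stats::rnorm(2 * n), n)
    labels <- c(seq_len(k), sample(k, n - k, replace = TRUE))
    got <- mean_silhouette(pts, labels, by_cluster = TRUE)
    expect_gte(got$mean, -1); expect_lte(got$mean, 1)
    expect_equal(got$mean, direct_silhouette(pts, labels))
    sizes <- tabulate(labels, k)
    if (all(sizes > 1L)) {
      ref <- cluster::silhouette(labels, stats::dist(pts))
      expect_equal(got$mean, mean(ref[, "sil_width"]))
    }
  }
  expect_error(mean_silhouette(matrix(1:4, 2), c(1L, 1L)),
               class = "pairtrack_invalid_input")
})

test_that("exact matching equals brute force on random benefit matrices", {
  set.seed(9)
  for (rep in 1:30) {
    n <- sample(1:4, 1)
    m <- n + sample(0:2, 1)
    B <- matrix(stats::runif(n * m), n, m)
    sol <- pairtrack:::solve_assignment_max(B)
    expect_length(sol, n)
    expect_equal(anyDuplicated(sol), 0L)
    expect_equal(sum(B[cbind(seq_len(n), sol)]),
                 brute_assignment_max(B)$value, tolerance = 1e-12)
  }
})

test_that("identity assignment picks the highest-confidence clusters", {
  fit <- small_fit()
  asg <- fit$assignment
  # every fragment has an identity and confidence equal to the row maximum
  # reachable under the exclusivity constraint; unconflicted fragments simply
  # take their best cluster
  expect_false(anyNA(asg$table$identity))
  expect_equal(asg$table$confidence,
               asg$prob_matrix[cbind(seq_len(nrow(asg$prob_matrix)),
                                     asg$table$identity)])
  expect_true(all(asg$table$confidence > 0))
})

test_that("conflicting fragments are split by optimal matching", {
  # two coexisting fragments, both preferring cluster 1 (0.9 vs 0.6): the
  # optimal split gives cluster 1 to the stronger one
  g <- toy_graph(list(c(0, 10), c(0, 10)), 2)
  space <- structure(list(
    points = matrix(0, 4, 2), frag = c(1L, 1L, 2L, 2L), img = c(1L, 2L, 1L, 2L),
    centers = matrix(0, 2, 2), labels = c(1L, 1L, 1L, 2L),
    probabilities = rbind(c(0.9, 0.1), c(0.9, 0.1), c(0.6, 0.4), c(0.6, 0.4)),
    temperature = 1, mean_silhouette = 1, cluster_silhouettes = c(1, 1),
    degenerate = FALSE), class = "pairtrack_embedding_space")
  asg <- assign_identities(g, space)
  expect_equal(asg$table$identity, c(1L, 2L))
  # matching value agrees with the permutation brute force
  expect_equal(sum(asg$prob_matrix[cbind(1:2, asg$table$identity)]),
               brute_assignment_max(asg$prob_matrix)$value)
  # swapping the two fragments' evidence swaps the identities
  space2 <- space
  space2$probabilities <- space$probabilities[c(3, 4, 1, 2), ]
  asg2 <- assign_identities(g, space2)
  expect_equal(asg2$table$identity, c(2L, 1L))
})

test_that("coexisting identities are always exclusive", {
  fit <- small_fit()
  ids <- fit$assignment$table$identity
  e <- fit$graph$edges
  if (nrow(e)) expect_true(all(ids[e[, 1]] != ids[e[, 2]]))
})

test_that("more mutually coexisting fragments than animals is an error", {
  g <- toy_graph(list(c(0, 10), c(0, 10), c(0, 10)), 2)
  space <- structure(list(
    points = matrix(0, 3, 2), frag = 1:3, img = rep(1L, 3),
    centers = matrix(0, 2, 2), labels = c(1L, 2L, 1L),
    probabilities = matrix(0.5, 3, 2), temperature = 1,
    mean_silhouette = 0, cluster_silhouettes = c(0, 0),
    degenerate = FALSE), class = "pairtrack_embedding_space")
  expect_error(assign_identities(g, space),
               class = "pairtrack_data_inconsistency")
})
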