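# Fixtures built in code: toy fragment graphs with chosen frame intervals,
# synthetic blob streams, and small cached datasets shared across tests.

# A fragment graph from explicit half-open intervals. Images are random L x L
# crops; gt_id labels each fragment's (simulated) true identity.
toy_graph <- function(intervals, n_animals, gt_ids = seq_along(intervals),
                      L = 8L, seed = 42L) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  fragments <- lapply(seq_along(intervals), function(f) {
    iv <- intervals[[f]]
    frames <- seq.int(iv[1], iv[2] - 1L)
    images <- lapply(frames, function(t)
      matrix(stats::runif(L * L), L, L))
    pairtrack:::new_fragment(
      id = f, frames = frames,
      centroids = cbind(10 * gt_ids[f] + 0.1 * frames, frames * 0),
      images = images, gt_ids = rep(gt_ids[f], length(frames)))
  })
  g <- structure(list(fragments = fragments,
                      n_animals = as.integer(n_animals),
                      n_frames = max(vapply(intervals, `[`, numeric(1), 2)),
                      crossings = data.frame(frame = integer(), x = numeric(),
                                             y = numeric()),
                      config = tracking_config(n_animals = n_animals)),
                 class = "pairtrack_fragment_graph")
  pairtrack:::refresh_coexistence(g)
}

# A per-frame blob stream for n animals moving on parallel horizontal lines,
# far apart, with per-identity constant crops (plus optional crossing runs).
line_blobs <- function(n, T, L = 8L, crossing_frames = integer(),
                       crossing_ids = seq_len(min(2L, n)), seed = 7L) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  base <- lapply(seq_len(n), function(i) matrix(stats::runif(L * L), L, L))
  lapply(seq_len(T) - 1L, function(t) {
    fb <- list()
    if (t %in% crossing_frames) {
      ctr <- c(t + 1, mean(100 * crossing_ids))
      fb[[1]] <- pairtrack:::new_blob(frame = t, centroid = ctr,
                                      pixel_count = 60 * length(crossing_ids),
                                      bbox = c(ctr[1] - 5, ctr[2] - 5, ctr[1] + 5, ctr[2] + 5),
                                      crop = base[[1]], kind = "crossing")
    }
    solo <- if (t %in% crossing_frames) setdiff(seq_len(n), crossing_ids)
      else seq_len(n)
    for (i in solo) {
      crop <- pmin(1, pmax(0, base[[i]] + matrix(stats::rnorm(L * L, 0, 0.02), L, L)))
      fb[[length(fb) + 1L]] <- pairtrack:::new_blob(
        frame = t, centroid = c(t + 1, 100 * i), pixel_count = 60,
        bbox = c(t - 4, 100 * i - 4, t + 6, 100 * i + 6),
        crop = crop, kind = "individual", gt_id = i)
    }
    fb
  })
}

# Small shared dataset + fit, computed once per test run.
small_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_dataset(generator_config(
        n_animals = 4, n_frames = 600, arena_radius = 150, seed = 5))
    cache
  }
})

small_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- tracking_config(n_animals = 4, n_pos = 100, n_neg = 100,
                             eval_every = 20, max_batches = 400)
      cache <<- track(small_dataset(), config = cfg, seed = 2)
    }
    cache
  }
})

# Trajectories of n straight-line walkers over T frames, optionally with the
# identity labels permuted or swapped from frame swap_at onwards.
walkers <- function(n, T, relabel = seq_len(n), swap_at = NULL) {
  pos <- array(NA_real_, c(n, T, 2))
  for (i in seq_len(n)) {
    pos[i, , 1] <- seq_len(T)
    pos[i, , 2] <- 50 * i
  }
  pos <- pos[relabel, , , drop = FALSE]
  if (!is.null(swap_at) && n >= 2) {
    later <- swap_at:T
    tmp <- pos[1, later, ]
    pos[1, later, ] <- pos[2, later, ]
    pos[2, later, ] <- tmp
  }
  prob <- matrix(1, n, T)
  prov <- matrix("detected", n, T)
  pairtrack:::new_trajectory_set(pos, prob, prov)
}

# Per-image ground-truth identity for every row of a fit's embedding space.
space_gt_ids <- function(fit) {
  mapply(function(f, i) fit$graph$fragments[[f]]$gt_ids[i],
         fit$space$frag, fit$space$img)
}

# Per-image identification error under the best cluster-to-identity bijection.
clustering_error <- function(fit) {
  gt <- space_gt_ids(fit)
  k <- fit$graph$n_animals
  C <- unclass(table(factor(fit$space$labels, seq_len(k)),
                     factor(gt, seq_len(k))))
  best <- pairtrack:::solve_assignment_max(C)
  1 - sum(C[cbind(seq_len(k), best)]) / sum(C)
}
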