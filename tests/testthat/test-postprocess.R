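# Trajectory post-processing: fragment identity enforcement, crossing
# interpolation, and impossible-jump correction.

# A minimal trajectory set built directly from position matrices.
traj_from <- function(positions, probabilities = NULL) {
  N <- dim(positions)[1]; T <- dim(positions)[2]
  if (is.null(probabilities)) probabilities <- matrix(1, N, T)
  prov <- matrix("missing", N, T)
  prov[!is.na(positions[, , 1])] <- "detected"
  pairtrack:::new_trajectory_set(positions, probabilities, prov)
}

test_that("fragment identity enforcement overrides per-image predictions", {
  r <- enforce_fragment_identity(c(2L, 2L, 3L, 2L), 2L)
  expect_equal(r$identities, rep(2L, 4))
  expect_equal(r$corrections, 1L)
  r2 <- enforce_fragment_identity(c(1L, NA, 1L), 1L)
  expect_equal(r2$identities, rep(1L, 3))
  expect_equal(r2$corrections, 0L)
})

test_that("crossing gaps are filled by linear interpolation", {
  # one animal detected at frame 9 at (0,0) and frame 12 at (10,10); frames
  # 10 and 11 are crossing frames
  pos <- array(NA_real_, c(1, 15, 2))
  pos[1, 10, ] <- c(0, 0)     # frame 9 (0-based)
  pos[1, 13, ] <- c(10, 10)   # frame 12
  prob <- matrix(0, 1, 15); prob[1, 10] <- 0.8; prob[1, 13] <- 0.6
  traj <- traj_from(pos, prob)
  crossings <- data.frame(frame = c(10L, 11L), x = 0, y = 0)
  out <- interpolate_crossings(traj, crossings)
  expect_equal(out$positions[1, 11, ], c(10, 10) / 3, tolerance = 1e-12)
  expect_equal(out$positions[1, 12, ], 2 * c(10, 10) / 3, tolerance = 1e-12)
  expect_equal(out$provenance[1, 11:12], rep("interpolated", 2))
  # interpolated probability is the minimum of the anchors
  expect_equal(out$probabilities[1, 11:12], rep(0.6, 2))
  # anchors untouched
  expect_equal(out$positions[1, 10, ], c(0, 0))
  expect_equal(out$provenance[1, 10], "detected")
})

test_that("interpolated points lie on the segment between the anchors", {
  set.seed(12)
  for (rep in 1:10) {
    T <- 30L
    pos <- array(NA_real_, c(1, T, 2))
    f0 <- sample(1:10, 1); f1 <- f0 + sample(2:10, 1)
    pos[1, f0, ] <- stats::runif(2, 0, 100)
    pos[1, f1, ] <- stats::runif(2, 0, 100)
    crossings <- data.frame(frame = (f0:(f1 - 2L)), x = 0, y = 0)
    out <- interpolate_crossings(traj_from(pos), crossings)
    inner <- (f0 + 1L):(f1 - 1L)
    lo <- pmin(pos[1, f0, ], pos[1, f1, ]); hi <- pmax(pos[1, f0, ], pos[1, f1, ])
    for (t in inner) {
      expect_true(all(out$positions[1, t, ] >= lo - 1e-9))
      expect_true(all(out$positions[1, t, ] <= hi + 1e-9))
    }
    # collinearity
    v <- pos[1, f1, ] - pos[1, f0, ]
    w <- out$positions[1, inner[1], ] - pos[1, f0, ]
    expect_equal(v[1] * w[2] - v[2] * w[1], 0, tolerance = 1e-9)
  }
})

test_that("gaps that are not crossings and one-sided gaps are never filled", {
  pos <- array(NA_real_, c(1, 10, 2))
  pos[1, 2, ] <- c(0, 0); pos[1, 6, ] <- c(5, 5)
  # only part of the gap is flagged as crossing frames
  out <- interpolate_crossings(traj_from(pos), data.frame(frame = 2L, x = 0, y = 0))
  expect_true(all(is.na(out$positions[1, 3:5, 1])))
  # an identity detected only before a crossing is not extrapolated
  pos2 <- array(NA_real_, c(1, 10, 2))
  pos2[1, 2, ] <- c(0, 0)
  out2 <- interpolate_crossings(traj_from(pos2),
                                data.frame(frame = 2:9, x = 0, y = 0))
  expect_true(all(is.na(out2$positions[1, 3:10, 1])))
})

test_that("an impossible jump reverts the offending fragment", {
  # identity 1: fragment A on frames [0,10) near x=0, fragment B on frames
  # [10,20) teleported to x=500 -> B is the suspect and reverts to missing
  frames_a <- 0:9; frames_b <- 10:19
  fr_a <- pairtrack:::new_fragment(1L, frames_a,
                                   cbind(frames_a * 1.0, 0 * frames_a),
                                   lapply(frames_a, function(t) matrix(0, 4, 4)),
                                   gt_ids = rep(1L, 10))
  fr_b <- pairtrack:::new_fragment(2L, frames_b,
                                   cbind(500 + frames_b, 0 * frames_b),
                                   lapply(frames_b, function(t) matrix(0, 4, 4)),
                                   gt_ids = rep(2L, 10))
  g <- structure(list(fragments = list(fr_a, fr_b), n_animals = 2L,
                      n_frames = 20L,
                      crossings = data.frame(frame = integer(), x = numeric(),
                                             y = numeric()),
                      config = tracking_config(n_animals = 2)),
                 class = "pairtrack_fragment_graph")
  g <- pairtrack:::refresh_coexistence(g)
  assignment <- list(
    table = data.frame(fragment_id = 1:2, identity = c(1L, 1L),
                       confidence = c(0.9, 0.8)),
    prob_matrix = rbind(c(0.9, 0.1), c(0.8, 0.2)),
    estimated_accuracy = 0.85)
  pos <- array(NA_real_, c(2, 20, 2))
  pos[1, 1:10, 1] <- frames_a; pos[1, 1:10, 2] <- 0
  pos[1, 11:20, 1] <- 500 + frames_b; pos[1, 11:20, 2] <- 0
  prob <- matrix(0, 2, 20); prob[1, ] <- c(rep(0.9, 10), rep(0.8, 10))
  prov <- matrix("missing", 2, 20); prov[1, ] <- "detected"
  traj <- pairtrack:::new_trajectory_set(pos, prob, prov)
  frag_of <- matrix(NA_integer_, 2, 20)
  frag_of[1, 1:10] <- 1L; frag_of[1, 11:20] <- 2L
  out <- correct_impossible_jumps(traj, g, assignment, frag_of, factor = 4)
  expect_equal(attr(out, "jump_fragments"), 2L)
  # fragment A's frames survive; fragment B moved off identity 1
  expect_equal(out$positions[1, 1:10, 1], frames_a)
  expect_true(all(is.na(out$positions[1, 11:20, 1])))
  # and was re-assigned to the free identity 2 on its open frames
  expect_equal(out$positions[2, 11:20, 1], 500 + frames_b)
  expect_equal(out$provenance[2, 11:20], rep("detected", 10))
})

test_that("a smooth trajectory passes jump correction untouched", {
  fit <- small_fit()
  tr <- fit$trajectories
  # detected speeds of the final trajectories stay physically plausible
  for (i in seq_len(dim(tr$positions)[1])) {
    det <- which(tr$provenance[i, ] == "detected")
    if (length(det) < 2) next
    d <- sqrt(diff(tr$positions[i, det, 1])^2 +
              diff(tr$positions[i, det, 2])^2) / diff(det)
    expect_lt(max(d), 20 * stats::median(d) + 10)
  }
})

test_that("assembled trajectories keep one position per identity per frame", {
  fit <- small_fit()
  tr <- fit$trajectories
  N <- dim(tr$positions)[1]; T <- dim(tr$positions)[2]
  expect_equal(dim(tr$positions), c(N, T, 2))
  expect_true(all(tr$provenance %in% c("detected", "interpolated", "missing")))
  # missing entries are exactly the NA positions
  expect_identical(tr$provenance == "missing", is.na(tr$positions[, , 1]))
  # no two identities share the exact same detected blob centroid in a frame
  for (t in seq_len(T)) {
    det <- which(tr$provenance[, t] == "detected")
    if (length(det) < 2) next
    xy <- tr$positions[det, t, , drop = FALSE]
    expect_equal(anyDuplicated(matrix(xy, length(det), 2)), 0L)
  }
})

test_that("trajectory CSV round-trips", {
  pos <- array(NA_real_, c(2, 5, 2))
  pos[1, , 1] <- 1:5; pos[1, , 2] <- 0
  pos[2, 2:4, 1] <- 8:10; pos[2, 2:4, 2] <- 3
  traj <- traj_from(pos)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path), add = TRUE)
  write_trajectories(traj, path)
  back <- read_trajectories(path)
  expect_equal(back$positions, traj$positions)
  expect_equal(back$provenance, traj$provenance)
})
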