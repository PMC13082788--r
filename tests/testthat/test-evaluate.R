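# The IDF1 identification metric and the sector occlusion harness.
# (The straight-line `walkers()` fixture lives in helper-fixtures.R.)

test_that("perfect predictions score IDF1 = 1", {
  gt <- walkers(3, 40)
  r <- idf1(gt, gt, match_radius = 2)
  expect_equal(r$idf1, 1)
  expect_equal(r$idfp, 0L)
  expect_equal(r$idfn, 0L)
  expect_equal(r$idtp, 3L * 40L)
})

test_that("IDF1 is invariant to a consistent relabelling", {
  gt <- walkers(4, 30)
  pred <- walkers(4, 30, relabel = c(3, 1, 4, 2))
  r <- idf1(pred, gt, match_radius = 2)
  expect_equal(r$idf1, 1)
})

test_that("a half-video identity swap scores exactly 0.5", {
  # two animals, 40 frames, identities swapped for the last 20 frames: the
  # best bijection can credit at most 20 of each animal's 40 frames
  gt <- walkers(2, 40)
  pred <- walkers(2, 40, swap_at = 21)
  r <- idf1(pred, gt, match_radius = 2)
  expect_equal(r$idf1, 0.5)
  expect_equal(r$idtp, 40L)
})

test_that("the identity bijection maximises IDTP (brute force, N <= 4)", {
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(2:4, 1)
    T <- 24L
    gt <- walkers(n, T)
    # corrupt the prediction with random per-segment relabellings
    pred <- walkers(n, T)
    cut <- sort(sample(2:(T - 1), 2))
    for (seg in list(1:cut[1], (cut[1] + 1):cut[2], (cut[2] + 1):T)) {
      p <- sample(n)
      pred$positions[, seg, ] <- pred$positions[p, seg, ]
    }
    r <- idf1(pred, gt, match_radius = 2)
    # count matrix rebuilt independently: exact same-position matches
    C <- matrix(0L, n, n)
    for (t in seq_len(T)) for (i in seq_len(n)) for (j in seq_len(n)) {
      if (sqrt(sum((pred$positions[i, t, ] - gt$positions[j, t, ])^2)) <= 2)
        C[i, j] <- C[i, j] + 1L
    }
    expect_equal(r$idtp, brute_assignment_max(C)$value)
  }
})

test_that("unmatched detections count as IDFP and IDFN", {
  gt <- walkers(2, 20)
  pred <- walkers(2, 20)
  pred$positions[2, , ] <- NA          # animal 2 never predicted
  r <- idf1(pred, gt, match_radius = 2)
  expect_equal(r$idtp, 20L)
  expect_equal(r$idfp, 0L)
  expect_equal(r$idfn, 20L)
  expect_equal(r$idf1, 20 / (20 + 0.5 * 20))
  expect_error(idf1(walkers(2, 19), gt, 2), class = "pairtrack_invalid_input")
})

test_that("excluding crossings drops flagged frames on both sides", {
  gt <- walkers(2, 20)
  gt$in_crossing <- matrix(FALSE, 2, 20)
  gt$in_crossing[, 5:8] <- TRUE
  pred <- walkers(2, 20)
  # prediction wrong exactly during the crossing frames
  pred$positions[, 5:8, 2] <- 1000
  pred$provenance[, 5:8] <- "interpolated"
  incl <- idf1(pred, gt, 2, include_crossings = TRUE)
  excl <- idf1(pred, gt, 2, include_crossings = FALSE)
  expect_lt(incl$idf1, 1)
  expect_equal(excl$idf1, 1)
  expect_equal(excl$idtp, 2L * 16L)
})

test_that("sector membership follows the angle convention", {
  ctr <- c(100, 100)
  # theta = 0: nothing masked, even on the positive-x ray
  s0 <- occlusion_spec(0, ctr)
  expect_false(any(pairtrack:::in_sector(rbind(c(150, 100), c(100, 50)), s0)))
  expect_false(any(pairtrack:::mask_exclusion(rbind(c(150, 100)), s0)))
  # theta = 360: everything masked
  s360 <- occlusion_spec(360, ctr)
  expect_true(all(pairtrack:::in_sector(rbind(c(150, 100), c(3, 7)), s360)))
  # theta = 90 with y down: (150, 150) is at 45 degrees -> inside;
  # (150, 50) is at -45 degrees (= 315) -> outside
  s90 <- occlusion_spec(90, ctr)
  expect_true(pairtrack:::in_sector(rbind(c(150, 150)), s90))
  expect_false(pairtrack:::in_sector(rbind(c(150, 50)), s90))
  expect_error(occlusion_spec(400, ctr), class = "pairtrack_invalid_input")
  expect_error(occlusion_spec(-5, ctr), class = "pairtrack_invalid_input")
})

test_that("a half-plane sector masks about half of uniform points", {
  set.seed(6)
  ctr <- c(0, 0)
  ang <- stats::runif(20000, 0, 2 * pi)
  r <- sqrt(stats::runif(20000)) * 100
  pts <- cbind(r * cos(ang), r * sin(ang))
  s <- occlusion_spec(180, ctr)
  frac <- mean(pairtrack:::in_sector(pts, s))
  expect_equal(frac, 0.5, tolerance = 0.02)
})

test_that("the exclusion margin removes points near the sector boundary", {
  ctr <- c(0, 0)
  s <- occlusion_spec(90, ctr, exclusion_margin = 15)
  pts <- rbind(c(80, -5),    # 5 px outside the 0-degree ray: margin excludes
               c(80, -20),   # 20 px outside: kept
               c(40, 40),    # inside the sector: excluded
               c(-50, -50))  # opposite quadrant, far from both rays: kept
  excl <- pairtrack:::mask_exclusion(pts, s)
  expect_identical(as.vector(excl), c(TRUE, FALSE, TRUE, FALSE))
})

test_that("masking a frame blanks exactly the sector pixels", {
  img <- matrix(1, 40, 40)
  spec <- occlusion_spec(90, c(19.5, 19.5))
  out <- apply_sector_mask(img, spec)
  # bottom-right quadrant (x > cx, y > cy) is zeroed, opposite corner kept
  expect_equal(out[30, 30], 0)
  expect_equal(out[10, 10], 1)
  expect_lt(mean(out == 0), 0.35)
  expect_gt(mean(out == 0), 0.15)
})

test_that("masking a blob stream drops exactly the blobs in the sector", {
  ds <- small_dataset()
  ctr <- pairtrack:::arena_center(ds$gen)
  spec <- occlusion_spec(120, ctr)
  masked <- apply_sector_mask(ds$blobs, spec)
  for (t in seq(1, length(ds$blobs), by = 53)) {
    for (b in ds$blobs[[t]]) {
      inside <- pairtrack:::in_sector(matrix(b$centroid, 1), spec)
      survives <- any(vapply(masked[[t]], function(m)
        identical(m$centroid, b$centroid), logical(1)))
      expect_equal(survives, !inside)
    }
  }
})
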