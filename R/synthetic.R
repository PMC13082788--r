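# Ground-truthed synthetic multi-animal videos: correlated random walks in a
# circular arena, each animal drawn as a disc with an identity-specific radial
# texture. Serves every pipeline stage without external data.

#' Synthetic video generator configuration
#'
#' Describes a synthetic multi-animal recording: `n_animals` textured discs
#' performing correlated random walks inside a circular arena, merging into
#' crossing blobs whenever they come within `crossing_distance` of each other.
#'
#' Appearance is a radial ring pattern per identity. `separability` in `[0,1]`
#' scales all inter-identity appearance differences: at 0 every animal has the
#' same expected appearance, at 1 the identity patterns are fully expressed.
#'
#' @param n_animals Number of animals (>= 2).
#' @param n_frames Number of frames.
#' @param arena_radius Arena radius in pixels.
#' @param body_radius Disc radius of one animal, pixels.
#' @param crossing_distance Centre-to-centre distance below which animals are
#'   considered crossing and their blobs merge. Defaults to 2.5 body radii.
#' @param separability Appearance separability in `[0,1]`.
#' @param base_intensity Mean disc intensity shared by all identities.
#' @param pattern_contrast Amplitude of the identity ring pattern.
#' @param speed_mean,speed_sd Per-frame step length distribution, pixels.
#' @param turn_sd Standard deviation of the per-frame heading change, radians.
#' @param noise_sd Pixel noise standard deviation.
#' @param seed Random seed; identical seeds give identical datasets.
#' @return An object of class `pairtrack_gen_config`.
#' @export
generator_config <- function(n_animals = 8L,
                             n_frames = 3000L,
                             arena_radius = 200,
                             body_radius = 7,
                             crossing_distance = 2.5 * body_radius,
                             separability = 0.9,
                             base_intensity = 0.55,
                             pattern_contrast = 0.3,
                             speed_mean = 2.5,
                             speed_sd = 0.8,
                             turn_sd = 0.4,
                             noise_sd = 0.02,
                             seed = 1L) {
  if (n_animals < 2L)
    stop_invalid_config("a synthetic video needs at least 2 animals")
  if (separability < 0 || separability > 1)
    stop_invalid_config("separability must lie in [0,1]")
  # crude packing check: the animals must fit with room to move
  if (pi * (arena_radius - body_radius)^2 < 8 * n_animals * pi * body_radius^2)
    stop_invalid_input("arena too small for this many animals")
  structure(list(
    n_animals = as.integer(n_animals),
    n_frames = as.integer(n_frames),
    arena_radius = arena_radius,
    body_radius = body_radius,
    crossing_distance = crossing_distance,
    separability = separability,
    base_intensity = base_intensity,
    pattern_contrast = pattern_contrast,
    speed_mean = speed_mean,
    speed_sd = speed_sd,
    turn_sd = turn_sd,
    noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "pairtrack_gen_config")
}

# Run expr with a locally seeded RNG, restoring the global state afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

arena_center <- function(gen) {
  m <- ceiling(gen$arena_radius + 2 * gen$body_radius + 2)
  c(m, m)
}

frame_size <- function(gen) {
  2L * as.integer(ceiling(gen$arena_radius + 2 * gen$body_radius + 2))
}

#' Generate ground-truth trajectories
#'
#' Correlated random walks reflected at the arena wall. A crossing is recorded
#' whenever two animals come within `crossing_distance`; crossing frequency
#' therefore grows with speed and with animal density.
#'
#' @param gen A [generator_config()].
#' @return A list with `positions` (an `N x T x 2` array of pixel coordinates,
#'   x right / y down, origin top-left), `in_crossing` (an `N x T` logical
#'   matrix), and `crossing_frames` (frames containing at least one crossing).
#' @export
generate_trajectories <- function(gen) {
  stopifnot(inherits(gen, "pairtrack_gen_config"))
  with_seed(gen$seed, generate_trajectories_impl(gen))
}

generate_trajectories_impl <- function(gen) {
  N <- gen$n_animals; T <- gen$n_frames
  ctr <- arena_center(gen)
  rmax <- gen$arena_radius - gen$body_radius

  # initial positions: rejection-sample until pairwise separated
  pos <- matrix(NA_real_, N, 2)
  for (i in seq_len(N)) {
    repeat {
      r <- rmax * sqrt(runif(1)); a <- runif(1, 0, 2 * pi)
      p <- ctr + r * c(cos(a), sin(a))
      if (i == 1L) { pos[i, ] <- p; break }
      d <- sqrt(rowSums((pos[seq_len(i - 1L), , drop = FALSE] -
                           matrix(p, i - 1L, 2, byrow = TRUE))^2))
      if (all(d > gen$crossing_distance)) { pos[i, ] <- p; break }
    }
  }
  heading <- runif(N, 0, 2 * pi)

  positions <- array(NA_real_, c(N, T, 2))
  for (t in seq_len(T)) {
    positions[, t, ] <- pos
    heading <- heading + rnorm(N, 0, gen$turn_sd)
    speed <- pmax(0.2, rnorm(N, gen$speed_mean, gen$speed_sd))
    step <- cbind(cos(heading), sin(heading)) * speed
    cand <- pos + step
    # reflect at the wall: bounce the heading off the boundary normal
    off <- cand - matrix(ctr, N, 2, byrow = TRUE)
    rr <- sqrt(rowSums(off^2))
    out <- rr > rmax
    if (any(out)) {
      for (i in which(out)) {
        n <- off[i, ] / rr[i]
        v <- step[i, ]
        v <- v - 2 * sum(v * n) * n
        heading[i] <- atan2(v[2], v[1])
        cand[i, ] <- ctr + n * (rmax - 1e-6) * (2 - rr[i] / rmax)
        # keep inside if the fold-back overshoots
        o2 <- cand[i, ] - ctr; r2 <- sqrt(sum(o2^2))
        if (r2 > rmax) cand[i, ] <- ctr + o2 / r2 * (rmax - 1e-6)
      }
    }
    pos <- cand
  }

  in_crossing <- matrix(FALSE, N, T)
  for (t in seq_len(T)) {
    g <- crossing_groups(positions[, t, ], gen$crossing_distance)
    for (grp in g) in_crossing[grp, t] <- TRUE
  }
  list(positions = positions,
       in_crossing = in_crossing,
       crossing_frames = which(colSums(in_crossing) > 0) - 1L)
}

# Groups of mutually chained animals closer than `dist` (single-linkage).
crossing_groups <- function(pos, dist) {
  N <- nrow(pos)
  parent <- seq_len(N)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (i in seq_len(N - 1L)) for (j in seq.int(i + 1L, N)) {
    if (sum((pos[i, ] - pos[j, ])^2) < dist^2) {
      parent[find(i)] <- find(j)
    }
  }
  roots <- vapply(seq_len(N), find, integer(1))
  gs <- split(seq_len(N), roots)
  gs[lengths(gs) >= 2L]
}

# Identity-specific radial intensity profile. At separability 0 every identity
# collapses to the flat base intensity.
identity_profile_params <- function(gen) {
  N <- gen$n_animals
  i <- seq_len(N) - 1L
  list(freq = 1 + (i %% 3L),
       phase = 2 * pi * (i %/% 3L) / max(1, ceiling(N / 3)),
       offset = 0.25 * (i / max(1L, N - 1L) - 0.5))
}

disc_intensity <- function(r, id, gen, pp) {
  base <- gen$base_intensity
  dev <- pp$offset[id] +
    gen$pattern_contrast * cos(2 * pi * pp$freq[id] * r / gen$body_radius + pp$phase[id])
  pmin(1, pmax(0.1, base + gen$separability * dev))
}

# Draw the discs listed in `ids` (positions given in crop/frame coordinates)
# onto the image `img` (matrix indexed [row=y+1, col=x+1]); soft 0.5px edge.
draw_discs <- function(img, xy, ids, gen, pp) {
  nr <- nrow(img); nc <- ncol(img)
  R <- gen$body_radius
  for (k in seq_along(ids)) {
    cx <- xy[k, 1]; cy <- xy[k, 2]
    x0 <- max(0L, floor(cx - R - 1)); x1 <- min(nc - 1L, ceiling(cx + R + 1))
    y0 <- max(0L, floor(cy - R - 1)); y1 <- min(nr - 1L, ceiling(cy + R + 1))
    if (x1 < x0 || y1 < y0) next
    xs <- x0:x1; ys <- y0:y1
    dx <- outer(rep(1, length(ys)), xs - cx)
    dy <- outer(ys - cy, rep(1, length(xs)))
    r <- sqrt(dx^2 + dy^2)
    cov <- pmin(1, pmax(0, R + 0.5 - r))
    val <- disc_intensity(r, ids[k], gen, pp) * cov
    sub <- img[ys + 1L, xs + 1L, drop = FALSE]
    img[ys + 1L, xs + 1L] <- pmax(sub, val)
  }
  img
}

#' Render one full video frame
#'
#' @param positions_t `N x 2` matrix of animal positions at one frame.
#' @param gen A [generator_config()].
#' @param noise Add pixel noise (default `TRUE`).
#' @return A grayscale matrix in `[0,1]`, indexed `[y + 1, x + 1]`.
#' @export
render_frame <- function(positions_t, gen, noise = TRUE) {
  side <- frame_size(gen)
  pp <- identity_profile_params(gen)
  img <- matrix(0, side, side)
  img <- draw_discs(img, positions_t, seq_len(nrow(positions_t)), gen, pp)
  if (noise && gen$noise_sd > 0)
    img <- img + matrix(rnorm(side * side, 0, gen$noise_sd), side, side)
  pmin(pmax(img, 0), 1)
}

# Render the centred square crop of the group `ids` around centroid `ctr_xy`.
render_crop <- function(ctr_xy, xy, ids, L, gen, pp, noise = TRUE) {
  ox <- round(ctr_xy[1]) - (L - 1) / 2
  oy <- round(ctr_xy[2]) - (L - 1) / 2
  img <- matrix(0, L, L)
  local_xy <- cbind(xy[, 1] - ox, xy[, 2] - oy)
  img <- draw_discs(img, local_xy, ids, gen, pp)
  if (noise && gen$noise_sd > 0)
    img <- img + matrix(rnorm(L * L, 0, gen$noise_sd), L, L)
  pmin(pmax(img, 0), 1)
}

#' Generate a complete synthetic dataset
#'
#' Produces ground-truth trajectories plus a pre-segmented detection table:
#' one individual blob (with rendered crop) per visible animal per frame, and
#' one merged crossing blob per group of overlapping animals. The detection
#' table lets fast tests bypass frame segmentation; [render_frame()] provides
#' raw frames for the full segmentation path.
#'
#' @param gen A [generator_config()].
#' @param crop_size Crop side in pixels (defaults to the tracking default).
#' @return A list of class `pairtrack_dataset` with elements `gen`,
#'   `positions`, `in_crossing`, `blobs` (per-frame blob lists carrying true
#'   identities in `$gt_id`), and `gt` (a long-format data frame
#'   `frame,id,x,y,in_crossing`).
#' @export
generate_dataset <- function(gen, crop_size = 24L) {
  stopifnot(inherits(gen, "pairtrack_gen_config"))
  with_seed(gen$seed, {
    tr <- generate_trajectories_impl(gen)
    blobs <- render_detections(tr$positions, gen, crop_size)
    gt <- data.frame(
      frame = rep(seq_len(gen$n_frames) - 1L, each = gen$n_animals),
      id = rep(seq_len(gen$n_animals), gen$n_frames),
      x = as.vector(tr$positions[, , 1]),
      y = as.vector(tr$positions[, , 2]),
      in_crossing = as.vector(tr$in_crossing)
    )
    structure(list(gen = gen, positions = tr$positions,
                   in_crossing = tr$in_crossing,
                   crossing_frames = tr$crossing_frames,
                   blobs = blobs, gt = gt),
              class = "pairtrack_dataset")
  })
}

# Build per-frame blob lists directly from ground-truth positions.
render_detections <- function(positions, gen, crop_size) {
  N <- dim(positions)[1]; T <- dim(positions)[2]
  pp <- identity_profile_params(gen)
  L <- as.integer(crop_size)
  area1 <- pi * gen$body_radius^2
  out <- vector("list", T)
  for (t in seq_len(T)) {
    xy <- positions[, t, , drop = TRUE]
    if (N == 1L) xy <- matrix(xy, 1L)
    groups <- crossing_groups(xy, gen$crossing_distance)
    crossing_ids <- unlist(groups)
    frame_blobs <- list()
    for (i in setdiff(seq_len(N), crossing_ids)) {
      crop <- render_crop(xy[i, ], xy[i, , drop = FALSE], i, L, gen, pp)
      frame_blobs[[length(frame_blobs) + 1L]] <- new_blob(
        frame = t - 1L, centroid = xy[i, ], pixel_count = round(area1),
        bbox = c(floor(xy[i, 1] - gen$body_radius), floor(xy[i, 2] - gen$body_radius),
                 ceiling(xy[i, 1] + gen$body_radius) + 1, ceiling(xy[i, 2] + gen$body_radius) + 1),
        crop = crop, kind = "individual", gt_id = i)
    }
    for (grp in groups) {
      ctr <- colMeans(xy[grp, , drop = FALSE])
      crop <- render_crop(ctr, xy[grp, , drop = FALSE], grp, L, gen, pp)
      frame_blobs[[length(frame_blobs) + 1L]] <- new_blob(
        frame = t - 1L, centroid = ctr,
        pixel_count = round(area1 * length(grp) * 0.9),
        bbox = c(floor(min(xy[grp, 1]) - gen$body_radius), floor(min(xy[grp, 2]) - gen$body_radius),
                 ceiling(max(xy[grp, 1]) + gen$body_radius) + 1, ceiling(max(xy[grp, 2]) + gen$body_radius) + 1),
        crop = crop, kind = "crossing", gt_id = NA_integer_)
    }
    out[[t]] <- frame_blobs
  }
  out
}

#' Ground truth as a trajectory set
#'
#' Wraps the generator output in the same container the tracker emits, for
#' direct use with [idf1()].
#' @param dataset A `pairtrack_dataset`.
#' @return A `pairtrack_trajectories` object.
#' @export
ground_truth_trajectories <- function(dataset) {
  stopifnot(inherits(dataset, "pairtrack_dataset"))
  N <- dataset$gen$n_animals; T <- dataset$gen$n_frames
  pos <- dataset$positions
  new_trajectory_set(
    positions = pos,
    probabilities = matrix(1, N, T),
    provenance = matrix("detected", N, T),
    in_crossing = dataset$in_crossing
  )
}

#' Write a dataset directory
#'
#' Writes `detections.csv`, `groundtruth.csv`, `config.yaml` and, optionally,
#' `frames/` as grayscale PNGs.
#' @param dataset A `pairtrack_dataset`.
#' @param dir Output directory (created if missing).
#' @param frames Also render and write full frames (slow for long videos).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir, frames = FALSE) {
  stopifnot(inherits(dataset, "pairtrack_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  det <- do.call(rbind, lapply(dataset$blobs, function(fb) {
    if (!length(fb)) return(NULL)
    data.frame(frame = vapply(fb, `[[`, integer(1), "frame"),
               x = vapply(fb, function(b) b$centroid[1], numeric(1)),
               y = vapply(fb, function(b) b$centroid[2], numeric(1)),
               area = vapply(fb, `[[`, numeric(1), "pixel_count"),
               kind = vapply(fb, `[[`, character(1), "kind"))
  }))
  utils::write.csv(det, file.path(dir, "detections.csv"), row.names = FALSE)
  utils::write.csv(dataset$gt, file.path(dir, "groundtruth.csv"), row.names = FALSE)
  yaml::write_yaml(unclass(dataset$gen), file.path(dir, "config.yaml"))
  if (frames) {
    fdir <- file.path(dir, "frames")
    dir.create(fdir, showWarnings = FALSE)
    with_seed(dataset$gen$seed + 1L, {
      for (t in seq_len(dataset$gen$n_frames)) {
        img <- render_frame(dataset$positions[, t, , drop = TRUE], dataset$gen)
        png::writePNG(img, file.path(fdir, sprintf("frame_%05d.png", t - 1L)))
      }
    })
  }
  invisible(dir)
}
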