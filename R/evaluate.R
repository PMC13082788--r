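# Evaluation: the Identification F1 score (IDF1) against ground truth under
# the identity bijection maximising true identifications, and the angular
# sector occlusion harness for stress-testing tracking without global
# fragments.

#' Identification F1 score
#'
#' Per frame, predicted detections are matched to ground-truth detections by
#' greedy nearest-neighbour within `match_radius`. A single global
#' predicted-to-true identity bijection is then chosen to maximise the number
#' of identity-consistent matches (IDTP); remaining predicted and ground-truth
#' detections count as IDFP and IDFN, and
#' `IDF1 = IDTP / (IDTP + 0.5 IDFP + 0.5 IDFN)`. The score is invariant to
#' any global relabelling of predicted identities.
#'
#' @param pred Predicted trajectories (`pairtrack_trajectories`).
#' @param gt Ground-truth trajectories with the same frame count; a ground
#'   truth from [ground_truth_trajectories()] carries per-frame crossing
#'   flags.
#' @param match_radius Matching radius in pixels.
#' @param include_crossings If `FALSE`, ground-truth positions during
#'   crossings and interpolated predicted positions are excluded from the
#'   counts (the metric for the core identification algorithm); if `TRUE`,
#'   every frame counts (the accuracy the end user experiences).
#' @param exclude_gt Optional `N x T` logical matrix of additional
#'   ground-truth entries to exclude (e.g. positions near an occlusion mask).
#' @return A list of class `pairtrack_idf1`: `idf1`, `idtp`, `idfp`, `idfn`,
#'   and the identity `matching` used.
#' @export
idf1 <- function(pred, gt, match_radius, include_crossings = TRUE,
                 exclude_gt = NULL) {
  Tp <- dim(pred$positions)[2]; Tg <- dim(gt$positions)[2]
  if (Tp != Tg) stop_invalid_input("trajectory sets differ in frame count")
  Np <- dim(pred$positions)[1]; Ng <- dim(gt$positions)[1]

  C <- matrix(0L, Np, Ng)
  total_pred <- 0L; total_gt <- 0L
  for (t in seq_len(Tp)) {
    pi_ <- which(!is.na(pred$positions[, t, 1]))
    if (!include_crossings) {
      pi_ <- pi_[pred$provenance[pi_, t] == "detected"]
      if (!is.null(pred$in_crossing))
        pi_ <- pi_[!pred$in_crossing[pi_, t]]
    }
    gi <- which(!is.na(gt$positions[, t, 1]))
    if (!include_crossings && !is.null(gt$in_crossing))
      gi <- gi[!gt$in_crossing[gi, t]]
    if (!is.null(exclude_gt)) gi <- gi[!exclude_gt[gi, t]]
    total_pred <- total_pred + length(pi_)
    total_gt <- total_gt + length(gi)
    if (!length(pi_) || !length(gi)) next
    P <- matrix(pred$positions[pi_, t, ], length(pi_), 2)
    G <- matrix(gt$positions[gi, t, ], length(gi), 2)
    D <- sqrt(squared_distances(P, G))
    ok <- which(D <= match_radius, arr.ind = TRUE)
    if (!nrow(ok)) next
    ord <- order(D[ok])
    used_p <- logical(length(pi_)); used_g <- logical(length(gi))
    for (r in ord) {
      a <- ok[r, 1]; b <- ok[r, 2]
      if (!used_p[a] && !used_g[b]) {
        used_p[a] <- TRUE; used_g[b] <- TRUE
        C[pi_[a], gi[b]] <- C[pi_[a], gi[b]] + 1L
      }
    }
  }

  # identity bijection maximising IDTP
  flip <- Np > Ng
  B <- if (flip) t(C) else C
  sol <- solve_assignment_max(B)
  idtp <- sum(B[cbind(seq_len(nrow(B)), sol)])
  matching <- if (flip) {
    m <- rep(NA_integer_, Np); m[sol] <- seq_len(Ng); m
  } else sol
  idfp <- total_pred - idtp
  idfn <- total_gt - idtp
  structure(list(idf1 = idtp / (idtp + 0.5 * idfp + 0.5 * idfn),
                 idtp = idtp, idfp = idfp, idfn = idfn,
                 matching = matching),
            class = "pairtrack_idf1")
}

#' @export
print.pairtrack_idf1 <- function(x, ...) {
  cat(sprintf("IDF1 = %.4f (IDTP %d, IDFP %d, IDFN %d)\n",
              x$idf1, x$idtp, x$idfp, x$idfn))
  invisible(x)
}

#' Angular occlusion mask specification
#'
#' A sector of width `theta` degrees anchored at the arena center (measured
#' from the positive x axis, y pointing down). Everything inside the sector is
#' treated as background before tracking, and ground-truth positions within
#' `exclusion_margin` pixels of the sector boundary are excluded from
#' evaluation to avoid scoring partial detections (use 75 px for mouse-scale
#' footage, 15 px otherwise).
#'
#' @param theta Sector angle in degrees, in `[0, 360]`.
#' @param center Arena center `(x, y)` in pixels.
#' @param exclusion_margin Evaluation exclusion margin in pixels.
#' @return An object of class `pairtrack_occlusion`.
#' @export
occlusion_spec <- function(theta, center, exclusion_margin = 15) {
  if (theta < 0 || theta > 360)
    stop_invalid_input("theta must lie in [0, 360] degrees")
  structure(list(theta = theta, center = as.numeric(center),
                 exclusion_margin = exclusion_margin),
            class = "pairtrack_occlusion")
}

in_sector <- function(xy, spec) {
  if (spec$theta <= 0) return(rep(FALSE, nrow(xy)))
  if (spec$theta >= 360) return(rep(TRUE, nrow(xy)))
  a <- atan2(xy[, 2] - spec$center[2], xy[, 1] - spec$center[1])
  deg <- (a * 180 / pi) %% 360
  deg < spec$theta
}

# Ground-truth exclusion set for evaluation under a sector mask: inside the
# sector, or within the exclusion margin of its boundary. No mask, no
# exclusion.
mask_exclusion <- function(xy, spec) {
  if (spec$theta <= 0) return(rep(FALSE, nrow(xy)))
  if (spec$theta >= 360) return(rep(TRUE, nrow(xy)))
  in_sector(xy, spec) | dist_to_sector_boundary(xy, spec) < spec$exclusion_margin
}

# Euclidean distance to the nearest of the two boundary rays of the sector.
dist_to_sector_boundary <- function(xy, spec) {
  v <- cbind(xy[, 1] - spec$center[1], xy[, 2] - spec$center[2])
  ray_dist <- function(angle_deg) {
    u <- c(cos(angle_deg * pi / 180), sin(angle_deg * pi / 180))
    t <- pmax(0, v %*% u)
    sqrt(rowSums((v - cbind(t * u[1], t * u[2]))^2))
  }
  pmin(ray_dist(0), ray_dist(spec$theta))
}

#' Apply a sector occlusion mask
#'
#' Removes all information inside the angular sector before tracking: for a
#' per-frame blob list, every blob whose centroid lies in the sector is
#' dropped (the animal is lost and its fragment breaks — no artificial links
#' are added across the mask); for a frame matrix, pixels inside the sector
#' are set to background.
#'
#' @param x A per-frame list of blob lists, or a grayscale frame matrix.
#' @param spec An [occlusion_spec()].
#' @return The masked input, same shape as `x`.
#' @export
apply_sector_mask <- function(x, spec) {
  if (spec$theta < 0 || spec$theta > 360)
    stop_invalid_input("theta must lie in [0, 360] degrees")
  if (is.matrix(x)) {
    nr <- nrow(x); nc <- ncol(x)
    xy <- cbind(rep(seq_len(nc) - 1L, each = nr),
                rep(seq_len(nr) - 1L, nc))
    x[in_sector(xy, spec)] <- 0
    return(x)
  }
  lapply(x, function(fb) {
    if (!length(fb)) return(fb)
    ctr <- do.call(rbind, lapply(fb, `[[`, "centroid"))
    fb[!in_sector(ctr, spec)]
  })
}

#' Sector-occlusion experiment
#'
#' Masks the video with sectors of increasing angle and re-tracks each masked
#' version, reporting fragment connectivity, whether any global fragment
#' survives, and IDF1 restricted to ground-truth positions outside the mask
#' and farther than the exclusion margin from its boundary (crossings
#' excluded). Runs where pair mining is impossible report `NA` accuracy.
#'
#' @param dataset A `pairtrack_dataset`.
#' @param thetas Sector angles (degrees) to test.
#' @param config A [tracking_config()]; defaults to the dataset's animal
#'   count.
#' @param seed Random seed per tracking run.
#' @param exclusion_margin Evaluation margin in pixels.
#' @return Data frame `theta, connectivity, global_fragments, idf1_excl,
#'   idf1_incl`.
#' @export
occlusion_experiment <- function(dataset, thetas,
                                 config = tracking_config(n_animals = dataset$gen$n_animals),
                                 seed = 1L, exclusion_margin = 15) {
  stopifnot(inherits(dataset, "pairtrack_dataset"))
  ctr <- arena_center(dataset$gen)
  gt <- ground_truth_trajectories(dataset)
  radius <- if (is.null(config$match_radius)) dataset$gen$body_radius
    else config$match_radius
  N <- dataset$gen$n_animals; T <- dataset$gen$n_frames

  rows <- lapply(thetas, function(th) {
    spec <- occlusion_spec(th, ctr, exclusion_margin)
    blobs <- apply_sector_mask(dataset$blobs, spec)
    n_blobs <- sum(lengths(blobs))
    if (n_blobs == 0L)
      return(data.frame(theta = th, connectivity = NA_real_,
                        global_fragments = FALSE,
                        idf1_excl = NA_real_, idf1_incl = NA_real_))
    graph <- build_fragments(blobs, N, config)
    conn <- if (length(graph$fragments)) graph$connectivity else NA_real_
    has_gf <- length(find_global_fragments(graph)) > 0L

    # ground-truth entries hidden by the mask or near its boundary
    excl <- matrix(FALSE, N, T)
    for (i in seq_len(N)) {
      xy <- cbind(dataset$positions[i, , 1], dataset$positions[i, , 2])
      excl[i, ] <- mask_exclusion(xy, spec)
    }

    res <- tryCatch({
      fit <- track(graph, n_animals = N, config = config, seed = seed)
      e <- idf1(fit$trajectories, gt, radius, include_crossings = FALSE,
                exclude_gt = excl)
      i <- idf1(fit$trajectories, gt, radius, include_crossings = TRUE,
                exclude_gt = excl)
      c(e$idf1, i$idf1)
    }, pairtrack_insufficient_connectivity = function(cnd) c(NA_real_, NA_real_))
    data.frame(theta = th, connectivity = conn, global_fragments = has_gf,
               idf1_excl = res[1], idf1_incl = res[2])
  })
  do.call(rbind, rows)
}
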