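# Post-processing: fragment-level identity enforcement, impossible-jump
# correction with a robust speed threshold, and linear interpolation of
# positions during crossings anchored on the identities immediately before
# and after each crossing.

new_trajectory_set <- function(positions, probabilities, provenance,
                               in_crossing = NULL, estimated_accuracy = NA_real_,
                               mean_silhouette = NA_real_) {
  structure(list(positions = positions,
                 probabilities = probabilities,
                 provenance = provenance,
                 in_crossing = in_crossing,
                 estimated_accuracy = estimated_accuracy,
                 mean_silhouette = mean_silhouette),
            class = "pairtrack_trajectories")
}

#' @export
print.pairtrack_trajectories <- function(x, ...) {
  N <- dim(x$positions)[1]; T <- dim(x$positions)[2]
  det <- mean(x$provenance == "detected")
  itp <- mean(x$provenance == "interpolated")
  cat(sprintf("Trajectories: %d animals x %d frames (%.1f%% detected, %.1f%% interpolated, %.1f%% missing)\n",
              N, T, 100 * det, 100 * itp, 100 * (1 - det - itp)))
  if (!is.na(x$estimated_accuracy))
    cat(sprintf("  estimated accuracy: %.4f   mean silhouette: %.4f\n",
                x$estimated_accuracy, x$mean_silhouette))
  invisible(x)
}

#' Enforce a single identity on a fragment
#'
#' All images between two crossings show the same animal, so per-image
#' identity predictions inside a fragment are overwritten with the
#' fragment-level identity; disagreements are counted as corrected
#' misidentifications.
#'
#' @param per_image_identities Integer vector of per-image predictions.
#' @param fragment_identity The fragment-level identity.
#' @return List with the corrected `identities` and the number of
#'   `corrections`.
#' @export
enforce_fragment_identity <- function(per_image_identities, fragment_identity) {
  corrections <- sum(per_image_identities != fragment_identity, na.rm = TRUE)
  list(identities = rep(fragment_identity, length(per_image_identities)),
       corrections = corrections)
}

#' Assemble per-frame trajectories
#'
#' Fills detected positions from blob centroids according to the per-fragment
#' identities, then corrects impossible jumps, then interpolates positions
#' during crossings. Attaches the run's estimated accuracy (mean assignment
#' confidence over all images) and mean Silhouette score.
#'
#' @param graph A fragment graph.
#' @param assignment Output of [assign_identities()].
#' @param mean_silhouette Mean Silhouette of the final embedding space.
#' @param config A [tracking_config()].
#' @return A `pairtrack_trajectories` object: `N x T x 2` positions (`NA`
#'   where missing), per-frame assignment probabilities, and provenance
#'   (`detected`, `interpolated` or `missing`).
#' @export
assemble_trajectories <- function(graph, assignment,
                                  mean_silhouette = NA_real_,
                                  config = graph$config) {
  N <- graph$n_animals; T <- graph$n_frames
  positions <- array(NA_real_, c(N, T, 2))
  probabilities <- matrix(0, N, T)
  provenance <- matrix("missing", N, T)
  frag_of <- matrix(NA_integer_, N, T)   # which fragment supplied each entry

  ids <- assignment$table$identity
  for (f in seq_along(graph$fragments)) {
    fr <- graph$fragments[[f]]
    i <- ids[f]
    if (is.na(i)) next
    cols <- fr$frames + 1L
    positions[i, cols, 1] <- fr$centroids[, 1]
    positions[i, cols, 2] <- fr$centroids[, 2]
    probabilities[i, cols] <- assignment$table$confidence[f]
    provenance[i, cols] <- "detected"
    frag_of[i, cols] <- f
  }
  traj <- new_trajectory_set(positions, probabilities, provenance,
                             estimated_accuracy = assignment$estimated_accuracy,
                             mean_silhouette = mean_silhouette)
  traj <- correct_impossible_jumps(traj, graph, assignment, frag_of,
                                   config$jump_factor)
  interpolate_crossings(traj, graph$crossings)
}

#' Correct impossible jumps
#'
#' A displacement between two *different* fragments of the same identity that
#' is larger than `median + factor * MAD` of that identity's displacements
#' marks the fragment supplying the later position as unreliably assigned: its
#' frames revert to missing and the fragment is re-assigned to its best
#' identity that conflicts with no coexisting fragment, if one exists. Jumps
#' inside a single fragment are never flagged: a fragment follows one animal
#' by construction, so a fast step within it is real motion, not a
#' misassignment.
#'
#' @param traj A `pairtrack_trajectories`.
#' @param graph The fragment graph the trajectories came from.
#' @param assignment Output of [assign_identities()].
#' @param frag_of `N x T` matrix of supplying fragments (built internally by
#'   [assemble_trajectories()]).
#' @param factor Robust threshold factor.
#' @return The corrected trajectory set; the ids of re-examined fragments are
#'   attached as attribute `jump_fragments`.
#' @export
correct_impossible_jumps <- function(traj, graph, assignment, frag_of,
                                     factor = 4) {
  N <- dim(traj$positions)[1]; T <- dim(traj$positions)[2]
  suspects <- integer(0)
  for (i in seq_len(N)) {
    det <- which(!is.na(traj$positions[i, , 1]))
    if (length(det) < 3L) next
    dx <- diff(traj$positions[i, det, 1])
    dy <- diff(traj$positions[i, det, 2])
    dt <- diff(det)
    speed <- sqrt(dx^2 + dy^2) / dt
    med <- stats::median(speed)
    mad <- stats::mad(speed)
    thr <- med + factor * max(mad, 1e-6)
    jumps <- which(speed > thr & speed > 2 * med)
    for (j in jumps) {
      f_before <- frag_of[i, det[j]]
      f_after <- frag_of[i, det[j + 1L]]
      if (!is.na(f_after) && !identical(f_before, f_after))
        suspects <- c(suspects, f_after)
    }
  }
  suspects <- unique(suspects)
  if (!length(suspects)) {
    attr(traj, "jump_fragments") <- integer(0)
    return(traj)
  }

  ids <- assignment$table$identity
  pm <- assignment$prob_matrix
  adj <- coexistence_partners(graph)
  for (f in suspects) {
    fr <- graph$fragments[[f]]
    i <- ids[f]
    cols <- fr$frames + 1L
    traj$positions[i, cols, ] <- NA_real_
    traj$probabilities[i, cols] <- 0
    traj$provenance[i, cols] <- "missing"
    # best non-conflicting identity, if any
    taken <- unique(ids[adj[[f]]])
    free <- setdiff(order(pm[f, ], decreasing = TRUE), c(taken, i))
    if (length(free)) {
      new_id <- free[1]
      # only claim frames not already supplied by another fragment
      open <- cols[is.na(traj$positions[new_id, cols, 1])]
      sel <- match(open, cols)
      traj$positions[new_id, open, 1] <- fr$centroids[sel, 1]
      traj$positions[new_id, open, 2] <- fr$centroids[sel, 2]
      traj$probabilities[new_id, open] <- pm[f, new_id]
      traj$provenance[new_id, open] <- "detected"
    }
  }
  attr(traj, "jump_fragments") <- suspects
  traj
}

#' Interpolate positions during crossings
#'
#' Gaps in an identity's trajectory whose frames fall inside crossing-blob
#' runs are filled by linear interpolation between the last detected position
#' before and the first after the crossing. The probability of interpolated
#' frames is the minimum of the two anchors. An identity present on only one
#' side of a crossing is never extrapolated.
#'
#' @param traj A `pairtrack_trajectories`.
#' @param crossings Data frame of crossing blobs (`frame, x, y`).
#' @return The trajectory set with crossing gaps filled.
#' @export
interpolate_crossings <- function(traj, crossings) {
  N <- dim(traj$positions)[1]; T <- dim(traj$positions)[2]
  crossing_frames <- unique(crossings$frame)
  for (i in seq_len(N)) {
    det <- which(!is.na(traj$positions[i, , 1]))
    if (length(det) < 2L) next
    gaps <- which(diff(det) > 1L)
    for (g in gaps) {
      f0 <- det[g]; f1 <- det[g + 1L]
      inner <- (f0 + 1L):(f1 - 1L)
      if (!all((inner - 1L) %in% crossing_frames)) next
      w <- (inner - f0) / (f1 - f0)
      traj$positions[i, inner, 1] <-
        (1 - w) * traj$positions[i, f0, 1] + w * traj$positions[i, f1, 1]
      traj$positions[i, inner, 2] <-
        (1 - w) * traj$positions[i, f0, 2] + w * traj$positions[i, f1, 2]
      traj$probabilities[i, inner] <- min(traj$probabilities[i, f0],
                                          traj$probabilities[i, f1])
      traj$provenance[i, inner] <- "interpolated"
    }
  }
  traj
}

#' Write trajectories to CSV
#'
#' Long format: `frame, id, x, y, probability, provenance`.
#' @param traj A `pairtrack_trajectories`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(traj, path) {
  N <- dim(traj$positions)[1]; T <- dim(traj$positions)[2]
  df <- data.frame(
    frame = rep(seq_len(T) - 1L, each = N),
    id = rep(seq_len(N), T),
    x = as.vector(traj$positions[, , 1]),
    y = as.vector(traj$positions[, , 2]),
    probability = as.vector(traj$probabilities),
    provenance = as.vector(traj$provenance))
  if (!is.null(traj$in_crossing)) df$in_crossing <- as.vector(traj$in_crossing)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
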