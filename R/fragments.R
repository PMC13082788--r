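# Fragments: maximal runs of single-animal blobs between two crossings, the
# unit of label-free pair mining. Linking is pixel-overlap first with a
# nearest-centroid fallback; a fragment ends when its blob disappears, merges
# into a crossing, or is removed by a mask.

new_fragment <- function(id, frames, centroids, images, gt_ids) {
  images_mat <- if (length(images))
    do.call(rbind, lapply(images, as.vector)) else matrix(0, 0, 0)
  structure(list(id = as.integer(id),
                 start = frames[1],
                 end = frames[length(frames)] + 1L,   # half-open [start, end)
                 frames = as.integer(frames),
                 centroids = centroids,
                 images = images,
                 images_mat = images_mat,
                 n_images = length(images),
                 gt_ids = gt_ids),
            class = "pairtrack_fragment")
}

#' Do two fragments coexist in time?
#'
#' Fragments coexist when their half-open frame ranges share at least one
#' frame; coexisting fragments are guaranteed to hold different animals, the
#' only label-free identity information in the video.
#' @param a,b Fragments.
#' @return `TRUE` or `FALSE`.
#' @export
coexist <- function(a, b) {
  a$start < b$end && b$start < a$end
}

#' Link blobs over time into a fragment graph
#'
#' Consecutive-frame individual blobs are linked by maximal pixel overlap,
#' falling back to nearest centroid within `max_displacement` when pixel sets
#' are unavailable; ties break by larger overlap, then smaller distance. A
#' fragment terminates when its blob disappears or touches a crossing blob; a
#' frame gap is never bridged. Blobs without a `kind` set by the producer are
#' classified by [classify_blob()] using the median blob area of the video,
#' and an unclassified blob overlapping two previous-frame fragments is
#' promoted to a crossing.
#'
#' @param blobs_per_frame List (one entry per frame, possibly empty) of blob
#'   lists, as produced by [segment_frame()] or [generate_dataset()].
#' @param n_animals Number of animals `N`.
#' @param config A [tracking_config()].
#' @return An object of class `pairtrack_fragment_graph`: fragments,
#'   coexistence edges, per-fragment degrees, fragment connectivity, the
#'   crossing-blob table, and the total frame count.
#' @export
build_fragments <- function(blobs_per_frame, n_animals,
                            config = tracking_config()) {
  T <- length(blobs_per_frame)
  all_areas <- unlist(lapply(blobs_per_frame, function(fb)
    vapply(fb, `[[`, numeric(1), "pixel_count")))
  med_area <- if (length(all_areas)) stats::median(all_areas) else 1

  fragments <- list()
  crossings <- list()
  # active fragment buffers: list of list(frames, centroids(list), images,
  # gt_ids, last_blob)
  active <- list()

  close_fragment <- function(buf) {
    if (!length(buf$frames)) return()
    fragments[[length(fragments) + 1L]] <<- new_fragment(
      id = length(fragments) + 1L,
      frames = unlist(buf$frames),
      centroids = do.call(rbind, buf$centroids),
      images = buf$images,
      gt_ids = unlist(buf$gt_ids))
  }

  for (t in seq_len(T)) {
    blobs <- blobs_per_frame[[t]]
    nb <- length(blobs)

    # classification (kept if the producer already set it)
    kinds <- character(nb)
    for (j in seq_len(nb)) {
      b <- blobs[[j]]
      kinds[j] <- if (!is.null(b$kind) && b$kind == "crossing") "crossing"
        else classify_blob(b, med_area, config$crossing_area_factor,
                           n_overlapping_fragments = if (is.null(b$pixels)) 0L
                             else n_pixel_overlaps(b, active))
    }

    # candidate links between active fragments and this frame's blobs
    na <- length(active)
    if (na && nb) {
      ov <- matrix(0, na, nb); dd <- matrix(Inf, na, nb)
      for (i in seq_len(na)) {
        lb <- active[[i]]$last_blob
        for (j in seq_len(nb)) {
          b <- blobs[[j]]
          if (!is.null(lb$pixels) && !is.null(b$pixels))
            ov[i, j] <- length(intersect(lb$pixels, b$pixels))
          dd[i, j] <- sqrt(sum((lb$centroid - b$centroid)^2))
        }
      }
      cand <- ov > 0 | dd <= config$max_displacement
    } else {
      cand <- matrix(FALSE, na, nb)
      ov <- matrix(0, na, nb); dd <- matrix(Inf, na, nb)
    }

    # fragments touching a crossing blob terminate there
    ended <- rep(FALSE, na)
    if (na) for (j in which(kinds == "crossing")) {
      touching <- which(cand[, j])
      for (i in touching) ended[i] <- TRUE
    }

    # greedy one-to-one matching on individual blobs: larger overlap first,
    # then smaller centroid distance
    matched_frag <- rep(NA_integer_, nb)
    idx <- if (na && nb)
      which(cand & !ended & matrix(kinds == "individual", na, nb, byrow = TRUE),
            arr.ind = TRUE)
      else matrix(integer(), 0, 2)
    if (nrow(idx)) {
      ord <- order(-ov[idx], dd[idx])
      used_f <- rep(FALSE, na); used_b <- rep(FALSE, nb)
      for (r in ord) {
        i <- idx[r, 1]; j <- idx[r, 2]
        if (!used_f[i] && !used_b[j]) {
          used_f[i] <- TRUE; used_b[j] <- TRUE
          matched_frag[j] <- i
        }
      }
    }

    # extend matched fragments, close the rest
    new_active <- list()
    extended <- rep(FALSE, na)
    for (j in seq_len(nb)) {
      if (kinds[j] == "crossing") {
        b <- blobs[[j]]
        crossings[[length(crossings) + 1L]] <-
          c(frame = b$frame, x = b$centroid[1], y = b$centroid[2])
        next
      }
      b <- blobs[[j]]
      i <- matched_frag[j]
      if (!is.na(i)) {
        buf <- active[[i]]
        buf$frames[[length(buf$frames) + 1L]] <- b$frame
        buf$centroids[[length(buf$centroids) + 1L]] <- b$centroid
        buf$images[[length(buf$images) + 1L]] <- b$crop
        buf$gt_ids[[length(buf$gt_ids) + 1L]] <- b$gt_id
        buf$last_blob <- b
        new_active[[length(new_active) + 1L]] <- buf
        extended[i] <- TRUE
      } else {
        new_active[[length(new_active) + 1L]] <- list(
          frames = list(b$frame), centroids = list(b$centroid),
          images = list(b$crop), gt_ids = list(b$gt_id), last_blob = b)
      }
    }
    for (i in seq_len(na)) if (!extended[i]) close_fragment(active[[i]])
    active <- new_active
  }
  for (buf in active) close_fragment(buf)

  graph <- structure(list(fragments = fragments,
                          n_animals = as.integer(n_animals),
                          n_frames = T,
                          crossings = if (length(crossings))
                            as.data.frame(do.call(rbind, crossings))
                            else data.frame(frame = integer(), x = numeric(),
                                            y = numeric()),
                          config = config),
                     class = "pairtrack_fragment_graph")
  refresh_coexistence(graph)
}

n_pixel_overlaps <- function(blob, active) {
  n <- 0L
  for (a in active) {
    lb <- a$last_blob
    if (!is.null(lb$pixels) &&
        length(intersect(lb$pixels, blob$pixels)) > 0L) n <- n + 1L
  }
  n
}

# (Re)compute coexistence edges, degrees and connectivity.
refresh_coexistence <- function(graph) {
  fr <- graph$fragments
  F <- length(fr)
  if (F == 0L) {
    graph$edges <- matrix(integer(), 0, 2)
    graph$degrees <- integer()
    graph$connectivity <- NA_real_
    return(graph)
  }
  s <- vapply(fr, `[[`, numeric(1), "start")
  e <- vapply(fr, `[[`, numeric(1), "end")
  ovl <- outer(s, e, "<") & t(outer(s, e, "<"))
  diag(ovl) <- FALSE
  idx <- which(ovl & upper.tri(ovl), arr.ind = TRUE)
  graph$edges <- cbind(idx[, 1], idx[, 2])
  graph$degrees <- as.integer(rowSums(ovl))
  graph$connectivity <- mean(graph$degrees) / (graph$n_animals - 1)
  graph
}

#' Fragment connectivity
#'
#' The mean number of other fragments each fragment coexists with, divided by
#' `N - 1`. Low connectivity starves pair mining of negative examples; a
#' warning of class `pairtrack_low_connectivity` is signalled when the value
#' falls below the configured threshold (default 0.5), the regime in which
#' tracking accuracy is expected to degrade.
#'
#' @param graph A fragment graph from [build_fragments()].
#' @param warn_below Warning threshold.
#' @return Connectivity in `[0,1]`.
#' @export
fragment_connectivity <- function(graph, warn_below = graph$config$connectivity_warning %||% 0.5) {
  if (!length(graph$fragments))
    stop_invalid_input("connectivity is undefined for an empty fragment graph")
  if (graph$n_animals < 2L)
    stop_invalid_input("connectivity requires at least 2 animals")
  v <- graph$connectivity
  if (v < warn_below)
    warning(structure(class = c("pairtrack_low_connectivity", "warning", "condition"),
                      list(message = sprintf(
                        "fragment connectivity %.3f is below %.2f: tracking accuracy is expected to degrade",
                        v, warn_below), call = sys.call(-1))))
  v
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Find global fragments
#'
#' A global fragment is a set of `N` individual fragments that coexist during
#' one or more consecutive frames. The method does not require any to exist;
#' an empty list is a valid result.
#'
#' @param graph A fragment graph.
#' @return A list of global fragments, each a list with `member_fragment_ids`
#'   and the half-open `common_frame_range`.
#' @export
find_global_fragments <- function(graph) {
  fr <- graph$fragments
  N <- graph$n_animals
  if (!length(fr)) return(list())
  s <- vapply(fr, `[[`, numeric(1), "start")
  e <- vapply(fr, `[[`, numeric(1), "end")
  # sweep over event frames; the alive set is constant between events
  ev <- sort(unique(c(s, e)))
  out <- list()
  current <- NULL
  for (k in seq_len(length(ev) - 1L)) {
    f0 <- ev[k]; f1 <- ev[k + 1L]
    alive <- which(s <= f0 & e >= f1)
    if (length(alive) == N) {
      if (!is.null(current) && identical(current$members, alive) &&
          current$range[2] == f0) {
        current$range[2] <- f1
      } else {
        if (!is.null(current)) out[[length(out) + 1L]] <- current
        current <- list(members = alive, range = c(f0, f1))
      }
    } else if (!is.null(current)) {
      out[[length(out) + 1L]] <- current
      current <- NULL
    }
  }
  if (!is.null(current)) out[[length(out) + 1L]] <- current
  lapply(out, function(g) list(
    member_fragment_ids = vapply(fr[g$members], `[[`, integer(1), "id"),
    common_frame_range = as.integer(g$range)))
}

#' @export
print.pairtrack_fragment_graph <- function(x, ...) {
  cat(sprintf("Fragment graph: %d fragments over %d frames, N = %d animals\n",
              length(x$fragments), x$n_frames, x$n_animals))
  cat(sprintf("  connectivity: %.3f   coexistence edges: %d   crossings: %d\n",
              x$connectivity, nrow(x$edges), nrow(x$crossings)))
  invisible(x)
}

#' Fragment table
#'
#' @param graph A fragment graph.
#' @return Data frame `fragment_id,start,end,n_images`.
#' @export
fragment_table <- function(graph) {
  data.frame(
    fragment_id = vapply(graph$fragments, `[[`, integer(1), "id"),
    start = vapply(graph$fragments, function(f) as.integer(f$start), integer(1)),
    end = vapply(graph$fragments, function(f) as.integer(f$end), integer(1)),
    n_images = vapply(graph$fragments, `[[`, integer(1), "n_images"))
}
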