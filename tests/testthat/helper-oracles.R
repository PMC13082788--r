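# Independent brute-force oracles used to cross-check the package's
# implementations on small instances.

# Connected components by flood fill (8-connectivity) on a logical matrix.
flood_components <- function(fg) {
  lab <- matrix(0L, nrow(fg), ncol(fg))
  cur <- 0L
  for (r in seq_len(nrow(fg))) for (c in seq_len(ncol(fg))) {
    if (fg[r, c] && lab[r, c] == 0L) {
      cur <- cur + 1L
      stack <- list(c(r, c))
      while (length(stack)) {
        p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        pr <- p[1]; pc <- p[2]
        if (pr < 1 || pc < 1 || pr > nrow(fg) || pc > ncol(fg)) next
        if (!fg[pr, pc] || lab[pr, pc] != 0L) next
        lab[pr, pc] <- cur
        for (dr in -1:1) for (dc in -1:1)
          if (dr || dc) stack[[length(stack) + 1L]] <- c(pr + dr, pc + dc)
      }
    }
  }
  lab
}

# Brute-force pairwise interval overlap (half-open intervals).
brute_edges <- function(starts, ends) {
  F <- length(starts)
  out <- NULL
  for (a in seq_len(F - 1L)) for (b in seq.int(a + 1L, F)) {
    if (max(starts[a], starts[b]) < min(ends[a], ends[b]))
      out <- rbind(out, c(a, b))
  }
  if (is.null(out)) matrix(integer(), 0, 2) else out
}

brute_connectivity <- function(starts, ends, N) {
  e <- brute_edges(starts, ends)
  deg <- tabulate(c(e[, 1], e[, 2]), nbins = length(starts))
  mean(deg) / (N - 1)
}

# Brute-force global fragments: scan every frame, group maximal runs where
# exactly N fragments are alive with constant membership.
brute_global_fragments <- function(starts, ends, N) {
  T <- max(ends)
  out <- list(); current <- NULL
  for (f in seq_len(T) - 1L) {
    alive <- which(starts <= f & ends > f)
    if (length(alive) == N) {
      if (!is.null(current) && identical(current$members, alive))
        current$range[2] <- f + 1L
      else {
        if (!is.null(current)) out[[length(out) + 1L]] <- current
        current <- list(members = alive, range = c(f, f + 1L))
      }
    } else if (!is.null(current)) {
      out[[length(out) + 1L]] <- current; current <- NULL
    }
  }
  if (!is.null(current)) out[[length(out) + 1L]] <- current
  out
}

# Brute-force maximum-sum one-to-one assignment over all permutations.
brute_assignment_max <- function(benefit) {
  n <- nrow(benefit); m <- ncol(benefit)
  perms <- all_perms(seq_len(m))
  best <- -Inf; best_sol <- NULL
  for (p in perms) {
    sol <- p[seq_len(n)]
    v <- sum(benefit[cbind(seq_len(n), sol)])
    if (v > best) { best <- v; best_sol <- sol }
  }
  list(value = best, solution = best_sol)
}

all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  out
}

# Direct (textbook) Silhouette computation from the full distance matrix.
direct_silhouette <- function(points, labels) {
  D <- as.matrix(stats::dist(points))
  n <- nrow(points)
  ks <- sort(unique(labels))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels[i]
    same <- which(labels == own & seq_len(n) != i)
    if (!length(same)) { s[i] <- 0; next }
    a <- mean(D[i, same])
    b <- min(vapply(setdiff(ks, own), function(c)
      mean(D[i, labels == c]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}
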