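# Training loop: mine a batch of pairs, embed both members, take an Adam step
# on the mean double-margin contrastive loss, and periodically evaluate the
# clustering quality of the representation with the mean Silhouette score.
# Training stops when the Silhouette reaches the stopping criterion (0.91 by
# default) on two consecutive evaluations, the level at which per-image
# identification error falls below 1%.

#' Train the contrastive embedding
#'
#' @param graph A fragment graph from [build_fragments()].
#' @param config A [tracking_config()].
#' @param seed Random seed governing initialisation, pair sampling, and the
#'   evaluation subsamples; identical seeds give identical training runs.
#' @param verbose Print evaluation progress.
#' @return A list with `model` (the trained embedding), and `history`
#'   (per-step `loss`, evaluation records `eval` with batch index, mean
#'   Silhouette and per-cluster Silhouettes, and `stop_reason`, one of
#'   `"silhouette_reached"` or `"max_batches"`).
#' @export
train_embedding <- function(graph, config = graph$config, seed = 1L,
                            verbose = FALSE) {
  L <- config$crop_size
  model <- new_embedding_model(L * L, config$hidden_dims,
                               config$embedding_dim, L, seed = seed)
  history <- list(loss = numeric(0),
                  eval = data.frame(batch = integer(), silhouette = numeric()),
                  stop_reason = "max_batches")
  if (config$max_batches < 1L)
    return(list(model = model, history = history))

  with_seed(seed + 1L, {
    weights <- sampling_weights(graph, config)
    # negatives are essential: fail fast if no coexisting eligible pair exists
    adj <- coexistence_partners(graph, weights$eligible)
    if (!any(lengths(adj) > 0 & weights$eligible))
      stop_insufficient_connectivity(
        "no coexisting fragment pairs: cannot mine negative pairs")

    opt <- adam_state(model)
    consecutive <- 0L
    losses <- numeric(config$max_batches)

    for (step in seq_len(config$max_batches)) {
      batch <- make_batch(graph, weights, config$n_pos, config$n_neg)
      mats <- batch_matrices(graph, batch)
      B <- nrow(mats$X1)
      fwd <- mlp_forward(model, rbind(mats$X1, mats$X2), cache = TRUE)
      E <- fwd$out
      e1 <- E[seq_len(B), , drop = FALSE]
      e2 <- E[B + seq_len(B), , drop = FALSE]
      diff <- e1 - e2
      d <- sqrt(pmax(rowSums(diff^2), 1e-12))
      loss_vec <- contrastive_loss(d, mats$is_positive, config)
      loss <- mean(loss_vec)
      if (!is.finite(loss)) stop(sprintf(
        "non-finite contrastive loss at batch %d; aborting training", step))
      losses[step] <- loss

      # dL/dd: 2(d - d_pos)+ for positives, -2(d_neg - d)+ for negatives
      dLdd <- ifelse(mats$is_positive,
                     2 * pmax(0, d - config$d_pos),
                     -2 * pmax(0, config$d_neg - d))
      gpair <- diff * (dLdd / d) / B
      grads <- mlp_backward(model, fwd$As, rbind(gpair, -gpair))
      upd <- adam_step(model, grads, opt, config$learning_rate)
      model <- upd$model; opt <- upd$state

      if (step %% config$eval_every == 0L) {
        space <- embed_space(model, graph, config,
                             max_n = config$silhouette_max_n,
                             seed = seed + step)
        history$eval <- rbind(history$eval,
                              data.frame(batch = step,
                                         silhouette = space$mean_silhouette))
        if (verbose)
          message(sprintf("batch %d: loss %.4f, silhouette %.4f",
                          step, loss, space$mean_silhouette))
        weights <- sampling_weights(graph, config,
                                    cluster_silhouettes = space$cluster_silhouettes,
                                    fragment_clusters = fragment_clusters(graph, space))
        if (space$mean_silhouette >= config$silhouette_stop) {
          consecutive <- consecutive + 1L
          if (consecutive >= 2L) {
            history$stop_reason <- "silhouette_reached"
            losses <- losses[seq_len(step)]
            break
          }
        } else consecutive <- 0L
      }
    }
    history$loss <- losses
  })
  list(model = model, history = history)
}
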