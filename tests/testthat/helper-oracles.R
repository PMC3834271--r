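# Shared fixtures and independent oracles.

# Small symmetric network from an edge triple list.
make_net <- function(edges, node_weights = NULL) {
  ids <- unique(c(rbind(edges[[1]], edges[[2]])))
  lw <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_along(edges[[1]])) {
    lw[edges[[1]][i], edges[[2]][i]] <- edges[[3]][i]
    lw[edges[[2]][i], edges[[1]][i]] <- edges[[3]][i]
  }
  knowledge_network(lw, node_weights = node_weights)
}

# Random connected-ish weighted network on n nodes (complete graph with
# uniform weights; some weights optionally zeroed).
random_net <- function(n, zero_frac = 0, node_weights = TRUE) {
  lw <- matrix(0, n, n)
  ut <- upper.tri(lw)
  w <- runif(sum(ut))
  if (zero_frac > 0)
    w[sample(length(w), floor(zero_frac * length(w)))] <- 0
  lw[ut] <- w
  lw <- lw + t(lw)
  knowledge_network(lw,
                    node_weights = if (node_weights) runif(n, 0.1, 1),
                    node_ids = paste0("n", seq_len(n)))
}

# Oracle for the propagation fixed point: dense linear solve of
# (I - (1 - beta) Q) Po = beta Pr.
solve_posterior <- function(q, pr, beta) {
  po <- solve(diag(nrow(q)) - (1 - beta) * q, beta * pr)
  names(po) <- names(pr)
  po
}

# Oracle for rank -> AUC: per-list ROC built by an explicit threshold
# sweep over list positions, trapezoid rule, averaged over lists.
# Integer ranks only (one positive among L positions).
roc_sweep_auc <- function(ranks, L) {
  per_list <- vapply(ranks, function(r) {
    tpr <- as.numeric(0:L >= r)            # sensitivity at thresholds 0..L
    fpr <- ((0:L) - tpr) / (L - 1)         # negatives above threshold
    sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  }, numeric(1))
  mean(per_list)
}
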