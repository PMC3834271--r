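#' AUC from left-out ranks
#'
#' Converts the ranks of left-out root nodes in their candidate lists
#' into the area under the ROC curve. Each list has one positive (the
#' left-out root) among `list_size` nodes; sweeping a threshold rank
#' over the list positions traces a ROC curve whose area, for a list
#' where the positive sits at (possibly tied, average) rank r, is
#' \eqn{(L - r)/(L - 1)}. The protocol AUC is the mean over all lists,
#' which equals the average of the per-list threshold-sweep trapezoid
#' areas.
#'
#' @param ranks numeric vector of ranks, each in \[1, `list_size`\]
#'   (average-rank ties give half-integer values).
#' @param list_size the list length L (the protocol uses 100).
#' @return AUC in \[0, 1\].
#' @examples
#' auc_from_ranks(rep(1, 5), 100)   # 1
#' auc_from_ranks(1:100, 100)       # 0.5
#' @export
auc_from_ranks <- function(ranks, list_size) {
  if (length(ranks) == 0) stop("empty rank list")
  if (!is.numeric(ranks) || any(!is.finite(ranks)) ||
      any(ranks < 1 | ranks > list_size))
    stop("ranks must lie in [1, ", list_size, "]")
  mean((list_size - ranks) / (list_size - 1))
}

# Deterministic per-(root, sample) sub-seed derived from a master seed
# and the root's identity (not its position, so a reordered root file
# scores identical lists), independent of f and beta so every point of
# a parameter sweep scores the same lists too.
subseed <- function(seed, root_id, sample_index) {
  h <- 0
  for (b in utf8ToInt(as.character(root_id)))
    h <- (h * 131 + b) %% 1048573
  as.integer((as.double(seed) %% 1e6 * 1000003 +
              h * 1009 + sample_index) %% 2147483647)
}

#' Leave-one-out cross-validated AUC
#'
#' Scores a (network, root set, f, beta) configuration by how highly it
#' re-ranks known roots. Each root r is left out in turn: the model is
#' refit with the remaining roots (r keeps its links and node weight,
#' it just loses root status), and r is embedded in `k` lists of
#' `list_size` nodes — r plus `list_size - 1` filler nodes sampled
#' uniformly without replacement from outside the full root set. In
#' each list r's rank by posterior (average-rank ties) is recorded;
#' the AUC over all `m * k` lists summarizes performance.
#'
#' All m left-out priors share one transition matrix, so they are
#' propagated jointly in a single matrix iteration (the update is
#' linear; results are identical to m separate runs). Filler sampling
#' is driven by per-(root, sample) sub-seeds derived from `seed` only,
#' so an f or beta sweep with the same seed scores identical lists and
#' repeated calls are bit-reproducible.
#'
#' @inheritParams kngp
#' @param k samples (lists) per root; the protocol uses 10.
#' @param list_size nodes per list; the protocol uses 100.
#' @param seed master seed for filler sampling.
#' @return Object of class `kngp_auc`: list with `f`, `beta`, `auc`,
#'   `ranks` (m x k matrix, rows named by left-out root), `k`,
#'   `list_size`, `prior_type`, `seed`.
#' @seealso [find_best_f()] for the f grid search, [auc_from_ranks()].
#' @examples
#' net <- synthetic_network(2, seed = 1, n_nodes = 80, n_roots = 8)
#' loocv_auc(net$network, net$roots, f = 0, beta = 0.3,
#'           k = 2, list_size = 20, seed = 7)
#' @export
loocv_auc <- function(net, roots, f = 1, beta = 0.3, k = 10L,
                      list_size = 100L, seed = 1L,
                      prior = c("kngp", "prp"),
                      delta = 1e-9, max_iter = 10000L) {
  stopifnot(inherits(net, "knowledge_network"))
  prior <- match.arg(prior)
  roots <- resolve_roots(net, roots)
  if (k < 1) stop("'k' must be at least 1")
  m <- length(roots)
  if (m < 2) stop("need at least 2 roots to leave one out")
  nonroot <- setdiff(net$node_ids, roots)
  if (list_size - 1 > length(nonroot))
    stop("not enough non-root nodes (", length(nonroot),
         ") to fill lists of size ", list_size)

  q <- transition_matrix(net)
  prm <- vapply(seq_len(m), function(ri) {
    held_in <- roots[-ri]
    switch(prior,
           kngp = kngp_prior(net, held_in, f),
           prp  = prp_prior(net, held_in))
  }, numeric(length(net$node_ids)))
  pom <- propagate(q, prm, beta, delta = delta, max_iter = max_iter)

  ranks <- matrix(NA_real_, m, k, dimnames = list(roots, NULL))
  for (ri in seq_len(m)) {
    po <- pom[, ri]
    for (s in seq_len(k)) {
      set.seed(subseed(seed, roots[ri], s))
      fill <- sample(nonroot, list_size - 1)
      vals <- po[c(roots[ri], fill)]
      ranks[ri, s] <- rank(-vals, ties.method = "average")[1]
    }
  }
  structure(
    list(f = if (prior == "kngp") f else NA_real_,
         beta = beta, prior_type = prior,
         auc = auc_from_ranks(as.numeric(ranks), list_size),
         ranks = ranks, k = k, list_size = list_size, seed = seed),
    class = "kngp_auc"
  )
}

#' @export
print.kngp_auc <- function(x, ...) {
  cat("Leave-one-out AUC:", format(round(x$auc, 4)), "\n")
  cat("  prior:", if (x$prior_type == "kngp") paste0("knowledge (f = ",
      format(x$f), ")") else "uniform over roots",
      " beta:", format(x$beta), "\n")
  cat("  lists:", nrow(x$ranks), "roots x", x$k, "samples of size",
      x$list_size, "\n")
  invisible(x)
}

#' Search the f grid for the best cross-validated AUC
#'
#' Runs the leave-one-out protocol at every value of the f grid with a
#' shared master seed (so every f scores the same candidate lists) and
#' returns the f maximizing the AUC; ties go to the smallest f. The
#' grid's optimum reflects where the knowledge lies: large best-f means
#' link weights dominate the ranking, small best-f means node weights
#' do, and mid-grid optima use both.
#'
#' @inheritParams loocv_auc
#' @param f_grid non-negative f values to evaluate. The default is the
#'   benchmark grid `c(0, 1, 15, 100, 1e4, 1e10)`.
#' @return Object of class `kngp_eval`: list with `best_f`, `table`
#'   (data.frame of `f`, `auc`), and `results` (per-f [loocv_auc()]
#'   objects).
#' @examples
#' net <- synthetic_network(1, seed = 1, n_nodes = 80, n_roots = 8)
#' ev <- find_best_f(net$network, net$roots, f_grid = c(0, 1, 100),
#'                   k = 2, list_size = 20, seed = 7)
#' ev
#' @export
find_best_f <- function(net, roots, f_grid = c(0, 1, 15, 100, 1e4, 1e10),
                        beta = 0.3, k = 10L, list_size = 100L, seed = 1L,
                        delta = 1e-9, max_iter = 10000L) {
  if (length(f_grid) == 0) stop("'f_grid' must be non-empty")
  if (any(f_grid < 0)) stop("'f_grid' values must be >= 0")
  f_grid <- sort(unique(f_grid))
  results <- lapply(f_grid, function(f)
    loocv_auc(net, roots, f = f, beta = beta, k = k,
              list_size = list_size, seed = seed,
              delta = delta, max_iter = max_iter))
  aucs <- vapply(results, `[[`, numeric(1), "auc")
  structure(
    list(best_f = f_grid[which.max(aucs)],   # ties: first = smallest f
         table = data.frame(f = f_grid, auc = aucs),
         beta = beta,
         results = results),
    class = "kngp_eval"
  )
}

#' @export
print.kngp_eval <- function(x, ...) {
  cat("Cross-validated f search (beta =", format(x$beta), ")\n")
  tab <- x$table
  tab$best <- ifelse(tab$f == x$best_f, "*", "")
  print(tab, row.names = FALSE)
  cat("best f:", format(x$best_f), "\n")
  invisible(x)
}

#' Plot the AUC against f
#'
#' @param x a [find_best_f()] result.
#' @param ... passed to [graphics::plot()].
#' @export
plot.kngp_eval <- function(x, ...) {
  f <- x$table$f
  xpos <- log10(pmax(f, min(f[f > 0], 1) / 10))
  graphics::plot(xpos, x$table$auc, type = "b", pch = 19,
                 xlab = "log10(f)  (leftmost point: f = 0)",
                 ylab = "leave-one-out AUC", ylim = c(0, 1), ...)
  graphics::points(xpos[f == x$best_f], x$table$auc[f == x$best_f],
                   col = "firebrick", pch = 19, cex = 1.5)
  invisible(x)
}

#' Calibrate the back probability
#'
#' The back probability beta is a free parameter of the walk. This
#' sweep scores each candidate beta by its mean leave-one-out AUC over
#' the f grid (same seed, hence same candidate lists, for every point)
#' and returns the beta with the highest mean; ties go to the smallest
#' beta.
#'
#' @inheritParams find_best_f
#' @param betas candidate back probabilities; default
#'   `c(0.1, 0.3, 0.5, 0.7)`.
#' @return List with `best_beta`, `summary` (data.frame of `beta`,
#'   `mean_auc`, `best_f`), and per-beta [find_best_f()] results in
#'   `evals`.
#' @export
calibrate_beta <- function(net, roots, betas = c(0.1, 0.3, 0.5, 0.7),
                           f_grid = c(0, 1, 15, 100, 1e4, 1e10),
                           k = 10L, list_size = 100L, seed = 1L,
                           delta = 1e-9, max_iter = 10000L) {
  if (length(betas) == 0) stop("'betas' must be non-empty")
  evals <- lapply(betas, function(b)
    find_best_f(net, roots, f_grid = f_grid, beta = b, k = k,
                list_size = list_size, seed = seed,
                delta = delta, max_iter = max_iter))
  mean_auc <- vapply(evals, function(e) mean(e$table$auc), numeric(1))
  list(best_beta = betas[which.max(mean_auc)],
       summary = data.frame(beta = betas, mean_auc = mean_auc,
                            best_f = vapply(evals, `[[`, numeric(1),
                                            "best_f")),
       evals = evals)
}
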