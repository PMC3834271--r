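#' Fit a knowledge-network prioritization model
#'
#' Runs the full prioritization pipeline on a knowledge network: builds
#' the column-stochastic transition matrix from the link weights,
#' builds the restart prior from the node weights and the root set
#' (either the f-scaled knowledge prior of [kngp_prior()] or the
#' uniform-over-roots baseline of [prp_prior()]), and propagates it to
#' the stationary posterior node-importance vector with [propagate()].
#'
#' The posterior is the prioritization score: the long-run fraction of
#' time a restarted random walker spends at each node. Candidates —
#' by default every non-root node — are ranked by it via
#' [predict.kngp()].
#'
#' @param net a [knowledge_network()].
#' @param roots root node set (character ids or integer indices): the
#'   genes already known to be associated with the condition of
#'   interest.
#' @param f non-negative scalar of the knowledge prior; ignored when
#'   `prior = "prp"`. See [kngp_prior()] for its meaning; [find_best_f()]
#'   selects it by cross-validated AUC.
#' @param beta back (restart) probability in \[0, 1\].
#' @param prior `"kngp"` for the f-scaled node-weight prior, `"prp"`
#'   for the uniform-over-roots baseline.
#' @param delta,max_iter convergence controls passed to [propagate()].
#' @return An object of class `kngp`: a list with the call, the network,
#'   `roots`, `f`, `beta`, `prior_type`, the prior vector `pr`, the
#'   posterior vector `po`, and `iterations`/`converged` diagnostics.
#' @seealso [predict.kngp()] for the ranked candidate table,
#'   [find_best_f()] and [loocv_auc()] for evaluation.
#' @examples
#' net <- synthetic_network(2, seed = 1, n_nodes = 60, n_roots = 10)
#' fit <- kngp(net$network, net$roots, f = 1, beta = 0.3)
#' fit
#' head(predict(fit))
#' @export
kngp <- function(net, roots, f = 1, beta = 0.3,
                 prior = c("kngp", "prp"),
                 delta = 1e-9, max_iter = 10000L) {
  stopifnot(inherits(net, "knowledge_network"))
  prior <- match.arg(prior)
  roots <- resolve_roots(net, roots)
  q <- transition_matrix(net)
  pr <- switch(prior,
               kngp = kngp_prior(net, roots, f),
               prp  = prp_prior(net, roots))
  po <- propagate(q, pr, beta, delta = delta, max_iter = max_iter)
  structure(
    list(call = match.call(),
         network = net,
         roots = roots,
         f = if (prior == "kngp") f else NA_real_,
         beta = beta,
         prior_type = prior,
         pr = `attributes<-`(pr, list(names = names(pr))),
         po = `attributes<-`(po, list(names = names(po))),
         iterations = attr(po, "iterations"),
         converged = attr(po, "converged")),
    class = "kngp"
  )
}

#' @export
print.kngp <- function(x, ...) {
  cat("Knowledge-network prioritization (",
      if (x$prior_type == "kngp") paste0("knowledge prior, f = ", format(x$f))
      else "uniform-over-roots prior", ")\n", sep = "")
  cat("  nodes:", length(x$network$node_ids),
      " roots:", length(x$roots),
      " beta:", format(x$beta), "\n")
  cat("  propagation:", x$iterations, "iterations,",
      if (x$converged) "converged" else "NOT converged", "\n")
  invisible(x)
}

#' @export
summary.kngp <- function(object, n_top = 10L, ...) {
  ranking <- predict(object)
  structure(list(fit = object,
                 top = utils::head(ranking, n_top),
                 posterior_sum = sum(object$po)),
            class = "summary.kngp")
}

#' @export
print.summary.kngp <- function(x, ...) {
  print(x$fit)
  cat("  posterior mass:", format(x$posterior_sum), "\n\n")
  cat("Top candidates:\n")
  print(x$top, row.names = FALSE)
  invisible(x)
}

#' Posterior node-importance coefficients
#'
#' @param object a fitted [kngp()] model.
#' @param ... unused.
#' @return Named numeric vector of posterior importances over all nodes.
#' @export
coef.kngp <- function(object, ...) object$po

#' Ranked candidate table from a fitted model
#'
#' @param object a fitted [kngp()] model.
#' @param candidates node ids to rank; defaults to all non-root nodes.
#' @param ... unused.
#' @return A `data.frame` from [rank_candidates()]: `node`, `posterior`,
#'   `rank`, sorted by decreasing posterior.
#' @export
predict.kngp <- function(object, candidates = NULL, ...) {
  if (is.null(candidates))
    candidates <- setdiff(object$network$node_ids, object$roots)
  rank_candidates(object$po, candidates)
}

#' Plot posterior node importances
#'
#' Plots the sorted posterior importances on a log scale, marking root
#' nodes, so the separation between roots, strong candidates and the
#' bulk of the network is visible at a glance.
#'
#' @param x a fitted [kngp()] model.
#' @param ... passed to [graphics::plot()].
#' @export
plot.kngp <- function(x, ...) {
  po <- sort(x$po, decreasing = TRUE)
  is_root <- names(po) %in% x$roots
  graphics::plot(seq_along(po), pmax(po, .Machine$double.xmin),
                 log = "y", col = ifelse(is_root, "firebrick", "grey40"),
                 pch = ifelse(is_root, 19, 1), cex = 0.6,
                 xlab = "node (sorted by posterior)",
                 ylab = "posterior node importance", ...)
  graphics::legend("topright", legend = c("root", "candidate"),
                   col = c("firebrick", "grey40"), pch = c(19, 1), bty = "n")
  invisible(x)
}
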