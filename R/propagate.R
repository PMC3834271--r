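#' Propagate a prior to the stationary posterior
#'
#' Iterates the random-walk-with-restart update
#' \deqn{Po^{(i+1)} = \beta \, Pr + (1 - \beta) \, Q \, Po^{(i)}}
#' from \eqn{Po^{(0)} = 0} until the maximum elementwise change falls
#' below `delta`. `beta` is the back (restart) probability: the chance
#' per step that the walker jumps back to the prior distribution rather
#' than following a weighted link. For `beta > 0` the update is a
#' contraction with factor `1 - beta`, so the fixed point
#' \eqn{(I - (1-\beta)Q)^{-1} \beta Pr} is unique and the iteration
#' converges geometrically. At `beta = 1` the posterior is the prior
#' itself; at `beta = 0` the iteration from zero is degenerate (stays at
#' zero) — use a small positive `beta` to probe the walk's stationary
#' distribution.
#'
#' Columns of `q` belonging to isolated nodes are all-zero; the leaked
#' mass is not redistributed and the posterior is not renormalized, so
#' it may sum to less than one on such networks.
#'
#' `pr` may also be a matrix with one prior per column; each column is
#' then propagated under the shared transition matrix (the update is
#' linear, so this is exactly the per-column result, computed in one
#' pass).
#'
#' @param q column-stochastic transition matrix from
#'   [transition_matrix()].
#' @param pr prior vector (or matrix of prior columns), as produced by
#'   [kngp_prior()] or [prp_prior()].
#' @param beta back probability in \[0, 1\].
#' @param delta convergence threshold on the max-norm of successive
#'   iterates; default `1e-9`.
#' @param max_iter iteration cap; hitting it raises a warning and marks
#'   the result as not converged.
#' @return The posterior, shaped like `pr` (named vector or matrix),
#'   with attributes `iterations` (integer) and `converged` (logical).
#' @examples
#' q <- matrix(c(0, 1, 1, 0), 2, dimnames = rep(list(c("a", "b")), 2))
#' propagate(q, c(a = 1, b = 0), beta = 0.5)  # (2/3, 1/3)
#' @export
propagate <- function(q, pr, beta, delta = 1e-9, max_iter = 10000L) {
  if (!is.numeric(beta) || length(beta) != 1 || is.na(beta) ||
      beta < 0 || beta > 1)
    stop("'beta' must be a single number in [0, 1]")
  if (!is.numeric(delta) || delta <= 0)
    stop("'delta' must be a small positive number")
  vec_in <- !is.matrix(pr)
  prm <- if (vec_in) matrix(pr, ncol = 1, dimnames = list(names(pr), NULL))
         else pr
  if (nrow(prm) != nrow(q))
    stop("dimensions of 'q' (", nrow(q), ") and 'pr' (", nrow(prm),
         ") do not agree")

  po <- matrix(0, nrow(prm), ncol(prm))
  restart <- beta * prm
  converged <- FALSE
  iterations <- max_iter
  for (i in seq_len(max_iter)) {
    po_next <- restart + (1 - beta) * (q %*% po)
    if (any(!is.finite(po_next)))
      stop("non-finite values during propagation at iteration ", i)
    if (max(abs(po_next - po)) < delta) {
      po <- po_next
      converged <- TRUE
      iterations <- i
      break
    }
    po <- po_next
  }
  if (!converged)
    warning("propagation did not converge within ", max_iter, " iterations")

  dimnames(po) <- dimnames(prm)
  if (vec_in) {
    out <- po[, 1]
    names(out) <- rownames(prm)
  } else {
    out <- po
  }
  attr(out, "iterations") <- iterations
  attr(out, "converged") <- converged
  out
}

#' Rank candidate nodes by posterior importance
#'
#' Sorts the requested candidates by posterior node importance,
#' descending, and assigns ranks with the average-rank convention for
#' tied posteriors (so the rank sum over L candidates is always
#' L(L+1)/2). Output row order breaks posterior ties by node id for
#' determinism.
#'
#' @param po named posterior vector from [propagate()] (or any named
#'   numeric scores).
#' @param candidates node ids to rank; typically all non-root nodes.
#'   Ids absent from `po` are an error.
#' @return A `data.frame` with columns `node`, `posterior`, `rank`,
#'   ordered by decreasing posterior.
#' @examples
#' po <- c(a = 0.5, b = 0.3, c = 0.2)
#' rank_candidates(po, c("b", "c"))
#' @export
rank_candidates <- function(po, candidates) {
  if (is.null(names(po))) stop("'po' must be a named vector")
  candidates <- as.character(candidates)
  if (anyDuplicated(candidates)) stop("duplicate candidate ids")
  missing <- setdiff(candidates, names(po))
  if (length(missing) > 0)
    stop("unknown candidate ids: ", paste(missing, collapse = ", "))
  vals <- po[candidates]
  rk <- rank(-vals, ties.method = "average")
  ord <- order(-vals, candidates)
  data.frame(node = candidates[ord],
             posterior = as.numeric(vals[ord]),
             rank = as.numeric(rk[ord]),
             row.names = NULL,
             stringsAsFactors = FALSE)
}
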