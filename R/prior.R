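#' Restart priors: knowledge-weighted and uniform-over-roots
#'
#' `kngp_prior()` builds the prior node-importance vector that encodes
#' both node-weight knowledge and root-set membership. The unnormalized
#' mass of node v is \eqn{f \cdot w_v} if v is a root and \eqn{w_v}
#' otherwise; the vector is then normalized to sum to one. The scalar
#' `f` in \eqn{[0, \infty)} trades the two knowledge sources off: at
#' `f = 0` root nodes get prior 0 and the prior is proportional to the
#' candidate node weights alone; as `f` grows the prior concentrates on
#' the root set and, in the limit, candidate priors vanish under
#' normalization. The prior is invariant to rescaling all node weights
#' by a positive constant.
#'
#' `prp_prior()` is the classic PageRank-with-priors baseline:
#' \eqn{1/|R|} on every root and 0 elsewhere. Node weights are ignored;
#' only root-set membership enters. It equals the `kngp_prior()` limit
#' of uniform node weights and large `f`.
#'
#' @param net a [knowledge_network()].
#' @param roots root node set: character ids or integer indices into
#'   `net$node_ids`. Must be non-empty; unknown ids are an error.
#' @param f non-negative scalar scaling root node weights.
#' @return Named numeric vector over all nodes, summing to 1, with
#'   attribute `f` (for `kngp_prior`) recording the scaling used.
#' @examples
#' lw <- matrix(1, 3, 3, dimnames = rep(list(c("a", "b", "c")), 2))
#' diag(lw) <- 0
#' net <- knowledge_network(lw, node_weights = c(a = 2, b = 1, c = 1))
#' kngp_prior(net, "a", f = 1)   # (0.5, 0.25, 0.25)
#' kngp_prior(net, "a", f = 0)   # root prior exactly 0
#' prp_prior(net, c("a", "b"))   # (0.5, 0.5, 0)
#' @export
kngp_prior <- function(net, roots, f) {
  stopifnot(inherits(net, "knowledge_network"))
  if (!is.numeric(f) || length(f) != 1 || is.na(f) || f < 0)
    stop("'f' must be a single non-negative number")
  roots <- resolve_roots(net, roots)
  mass <- net$node_weights
  is_root <- net$node_ids %in% roots
  mass[is_root] <- f * mass[is_root]
  total <- sum(mass)
  if (total <= 0)
    stop("prior undefined: all node masses are zero after scaling by f = ", f)
  pr <- mass / total
  attr(pr, "f") <- f
  pr
}

#' @rdname kngp_prior
#' @export
prp_prior <- function(net, roots) {
  stopifnot(inherits(net, "knowledge_network"))
  roots <- resolve_roots(net, roots)
  pr <- numeric(length(net$node_ids))
  names(pr) <- net$node_ids
  pr[net$node_ids %in% roots] <- 1 / length(roots)
  pr
}
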