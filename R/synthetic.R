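#' Generate a synthetic benchmark knowledge network
#'
#' Builds one of four complete, weighted benchmark networks designed to
#' probe how node-weight knowledge and link-weight knowledge interact.
#' At full size each network has 1000 nodes; nodes 1–100 are the root
#' set. Nodes are partitioned into five groups — two root groups
#' (1–50, 51–100), two small candidate groups (101–150, 151–200) and
#' the candidate bulk (201–1000) — and every node weight and every
#' pairwise link weight is drawn uniformly from a range determined by
#' the group (pair):
#'
#' * **Dataset 1** — link knowledge favors roots: root–root links in
#'   \[0.5, 1\], all other links in \[0, 0.5\]; node weights all
#'   \[0, 1\].
#' * **Dataset 2** — node knowledge favors roots: root node weights in
#'   \[0.5, 1\], candidate node weights in \[0, 0.5\]; all links
#'   \[0, 1\].
#' * **Dataset 3** — both, weakly: root node weights \[0.9, 1\] vs
#'   candidate \[0.5, 1\]; root–root links \[0.55, 1\] vs \[0.5, 1\]
#'   elsewhere.
#' * **Dataset 4** — both, overlapping: root node weights \[0.95, 1\]
#'   vs candidate \[0, 1\]; links within and between the root groups
#'   and from group 1 to group 3 in \[0.1, 1\], all other links
#'   \[0, 1\].
#'
#' The graph is complete (every pair gets a positive weight almost
#' surely); no modular topology is imposed beyond the weight ranges.
#' Draws are made in a fixed order — node weights by node index, then
#' link weights in lexicographic pair order — so a seed fully
#' determines the network.
#'
#' Smaller instances for tests and examples keep the same five-group
#' layout with proportionally scaled group sizes (`n_roots` must be
#' even; the two small candidate groups each match a root group's
#' size).
#'
#' @param dataset which benchmark design, 1–4.
#' @param seed integer RNG seed; the same seed reproduces the network
#'   exactly.
#' @param n_nodes total nodes (default 1000).
#' @param n_roots size of the root set (default 100); must be even and
#'   `n_nodes >= 2 * n_roots + 1`.
#' @return List with `network` (a [knowledge_network()]), `roots`
#'   (character ids), and `groups` (integer group label per node).
#' @examples
#' net <- synthetic_network(2, seed = 42, n_nodes = 60, n_roots = 10)
#' range(net$network$node_weights[net$roots])   # within [0.5, 1]
#' @export
synthetic_network <- function(dataset, seed, n_nodes = 1000L,
                              n_roots = 100L) {
  if (!dataset %in% 1:4)
    stop("'dataset' must be 1, 2, 3 or 4; got ", dataset)
  if (n_roots %% 2 != 0 || n_roots < 4)
    stop("'n_roots' must be an even number >= 4")
  if (n_nodes < 2 * n_roots + 1)
    stop("'n_nodes' must exceed twice 'n_roots'")
  half <- n_roots %/% 2
  groups <- c(rep(1L, half), rep(2L, half), rep(3L, half), rep(4L, half),
              rep(5L, n_nodes - 2L * n_roots))
  rng <- synthetic_ranges(dataset)

  set.seed(seed)
  # node weights first, by node index
  nw_lo <- rng$node_lo[groups]
  nw_hi <- rng$node_hi[groups]
  w <- nw_lo + (nw_hi - nw_lo) * stats::runif(n_nodes)
  # then link weights, lexicographic pair order: lower.tri filled
  # column-major enumerates (1,2), (1,3), ..., (1,n), (2,3), ...
  lo_full <- rng$link_lo[groups, groups]
  hi_full <- rng$link_hi[groups, groups]
  lt <- lower.tri(lo_full)
  lw <- matrix(0, n_nodes, n_nodes)
  lw[lt] <- lo_full[lt] + (hi_full[lt] - lo_full[lt]) *
    stats::runif(sum(lt))
  lw <- lw + t(lw)

  ids <- as.character(seq_len(n_nodes))
  net <- knowledge_network(lw, node_weights = w, node_ids = ids)
  list(network = net, roots = ids[seq_len(n_roots)], groups = groups)
}

# Uniform ranges per benchmark design: node ranges per group (length 5)
# and symmetric 5x5 link-range matrices over group pairs.
synthetic_ranges <- function(dataset) {
  node_lo <- list(c(0, 0, 0, 0, 0),
                  c(.5, .5, 0, 0, 0),
                  c(.9, .9, .5, .5, .5),
                  c(.95, .95, 0, 0, 0))[[dataset]]
  node_hi <- list(c(1, 1, 1, 1, 1),
                  c(1, 1, .5, .5, .5),
                  c(1, 1, 1, 1, 1),
                  c(1, 1, 1, 1, 1))[[dataset]]
  link_lo <- matrix(0, 5, 5)
  link_hi <- matrix(1, 5, 5)
  set_range <- function(i, j, a, b) {
    link_lo[i, j] <<- a; link_lo[j, i] <<- a
    link_hi[i, j] <<- b; link_hi[j, i] <<- b
  }
  if (dataset == 1) {
    for (i in 1:5) for (j in i:5) set_range(i, j, 0, 0.5)
    set_range(1, 1, 0.5, 1); set_range(2, 2, 0.5, 1); set_range(1, 2, 0.5, 1)
  } else if (dataset == 3) {
    for (i in 1:5) for (j in i:5) set_range(i, j, 0.5, 1)
    set_range(1, 1, 0.55, 1); set_range(2, 2, 0.55, 1)
    set_range(1, 2, 0.55, 1)
  } else if (dataset == 4) {
    set_range(1, 1, 0.1, 1); set_range(2, 2, 0.1, 1)
    set_range(1, 2, 0.1, 1); set_range(1, 3, 0.1, 1)
  }
  list(node_lo = node_lo, node_hi = node_hi,
       link_lo = link_lo, link_hi = link_hi)
}
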