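#' Construct a knowledge network
#'
#' A knowledge network is an undirected weighted graph in which biological
#' knowledge is encoded twice: pairwise knowledge as non-negative link
#' weights \eqn{lw(u,v)} (e.g. interaction confidence or functional
#' similarity) and per-node knowledge as non-negative node weights
#' \eqn{w_v} (e.g. annotation counts). Link weights drive the random
#' walk's transition probabilities; node weights enter the restart prior.
#'
#' The undirected graph is stored as a symmetric matrix, which is
#' equivalent to replacing every undirected link by two directed links of
#' the same weight. Self-loops are not part of the model: a non-zero
#' diagonal is stripped with a warning. Zero-weight links are treated as
#' absent.
#'
#' @param link_weights symmetric numeric n x n matrix of non-negative,
#'   finite link weights. Dimnames, if present, must agree with
#'   `node_ids`.
#' @param node_weights numeric vector of n non-negative, finite node
#'   weights, or `NULL` for unit weights. May be named; names must then
#'   match `node_ids` (in any order).
#' @param node_ids character vector of n unique node identifiers. Defaults
#'   to the dimnames of `link_weights`, or to `"1".."n"`.
#' @return An object of class `knowledge_network`: a list with elements
#'   `node_ids` (character), `link_weights` (n x n symmetric matrix with
#'   zero diagonal, dimnames set) and `node_weights` (named numeric).
#' @seealso [read_knowledge_network()] to build one from TSV files,
#'   [transition_matrix()], [kngp()].
#' @examples
#' lw <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
#' lw["a", "b"] <- lw["b", "a"] <- 2
#' lw["a", "c"] <- lw["c", "a"] <- 3
#' net <- knowledge_network(lw, node_weights = c(a = 2, b = 1, c = 1))
#' net
#' @export
knowledge_network <- function(link_weights, node_weights = NULL,
                              node_ids = NULL) {
  if (!is.matrix(link_weights) || !is.numeric(link_weights))
    stop("'link_weights' must be a numeric matrix")
  n <- nrow(link_weights)
  if (ncol(link_weights) != n)
    stop("'link_weights' must be square; got ", n, " x ", ncol(link_weights))

  if (is.null(node_ids)) {
    node_ids <- rownames(link_weights)
    if (is.null(node_ids)) node_ids <- as.character(seq_len(n))
  }
  node_ids <- as.character(node_ids)
  if (length(node_ids) != n)
    stop("'node_ids' has length ", length(node_ids),
         " but the network has ", n, " nodes")
  if (anyDuplicated(node_ids))
    stop("duplicate node ids: ",
         paste(unique(node_ids[duplicated(node_ids)]), collapse = ", "))

  if (any(!is.finite(link_weights)))
    stop("non-finite link weights are not allowed")
  neg <- which(link_weights < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop("negative link weight at (", node_ids[neg[1, 1]], ", ",
         node_ids[neg[1, 2]], ")")
  asym <- which(link_weights != t(link_weights), arr.ind = TRUE)
  if (nrow(asym) > 0)
    stop("link weights not symmetric at (", node_ids[asym[1, 1]], ", ",
         node_ids[asym[1, 2]], ")")
  if (any(diag(link_weights) != 0)) {
    warning("self-loop weights found on the diagonal; stripped")
    diag(link_weights) <- 0
  }

  if (is.null(node_weights)) {
    node_weights <- rep(1, n)
  } else {
    if (!is.numeric(node_weights) || length(node_weights) != n)
      stop("'node_weights' must be a numeric vector of length ", n)
    if (!is.null(names(node_weights))) {
      if (!setequal(names(node_weights), node_ids))
        stop("names of 'node_weights' do not match node ids")
      node_weights <- node_weights[node_ids]
    }
  }
  if (any(!is.finite(node_weights)) || any(node_weights < 0))
    stop("node weights must be finite and >= 0")

  dimnames(link_weights) <- list(node_ids, node_ids)
  node_weights <- as.numeric(node_weights)
  names(node_weights) <- node_ids
  structure(
    list(node_ids = node_ids,
         link_weights = link_weights,
         node_weights = node_weights),
    class = "knowledge_network"
  )
}

#' @export
print.knowledge_network <- function(x, ...) {
  n <- length(x$node_ids)
  n_links <- sum(x$link_weights[upper.tri(x$link_weights)] > 0)
  cat("Knowledge network:", n, "nodes,", n_links, "weighted links\n")
  cat("  link weights : [", format(min(x$link_weights)), ",",
      format(max(x$link_weights)), "]\n")
  cat("  node weights : [", format(min(x$node_weights)), ",",
      format(max(x$node_weights)), "]\n")
  invisible(x)
}

# Resolve a root set against the network: character ids or integer indices.
# Returns a character vector of ids; errors list every unknown member.
resolve_roots <- function(net, roots) {
  stopifnot(inherits(net, "knowledge_network"))
  if (is.numeric(roots)) {
    if (any(roots < 1 | roots > length(net$node_ids) | roots != round(roots)))
      stop("numeric root indices must be integers in 1..n")
    roots <- net$node_ids[roots]
  }
  roots <- as.character(roots)
  if (length(roots) == 0) stop("root set must be non-empty")
  if (anyDuplicated(roots))
    stop("duplicate root ids: ",
         paste(unique(roots[duplicated(roots)]), collapse = ", "))
  missing <- setdiff(roots, net$node_ids)
  if (length(missing) > 0)
    stop("root ids not present in the network: ",
         paste(missing, collapse = ", "))
  roots
}

#' Transition probability matrix of the random walk
#'
#' Normalizes each node's outgoing link weights to probabilities. The
#' entry in row v, column u is \eqn{p(v|u) = lw(u,v) / \sum_{t \in
#' neighbors(u)} lw(u,t)}, the probability that a walker at node u steps
#' to node v. Nodes without weighted neighbors get an all-zero column:
#' the walk leaks probability mass there rather than teleporting, so on
#' networks with isolated nodes the stationary vector can sum to less
#' than one.
#'
#' @param net a [knowledge_network()].
#' @return n x n column-stochastic matrix (columns of isolated nodes sum
#'   to 0), with the network's node ids as dimnames.
#' @examples
#' lw <- matrix(c(0, 2, 3, 2, 0, 0, 3, 0, 0), 3,
#'              dimnames = rep(list(c("u", "v", "t")), 2))
#' transition_matrix(knowledge_network(lw))  # column u is (0, .4, .6)
#' @export
transition_matrix <- function(net) {
  stopifnot(inherits(net, "knowledge_network"))
  out_mass <- colSums(net$link_weights)
  scale <- ifelse(out_mass > 0, out_mass, 1)
  q <- sweep(net$link_weights, 2, scale, "/")
  dimnames(q) <- list(net$node_ids, net$node_ids)
  q
}
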