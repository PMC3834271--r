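#' Read a knowledge network from TSV files
#'
#' `read_edge_list()` reads an undirected weighted edge list with three
#' tab-separated columns (`node_a`, `node_b`, `weight`); a header line
#' is detected by a non-numeric third field and skipped. One line per
#' unordered pair is expected: a pair listed twice with the same weight
#' is collapsed, with conflicting weights it is an error naming the
#' pair. Self-pairs are dropped with a warning.
#'
#' `read_node_weights()` reads a two-column TSV (`node`, `weight`).
#' `read_root_list()` reads one node id per line, ignoring blank lines.
#'
#' `read_knowledge_network()` assembles a [knowledge_network()] from an
#' edge-list file and an optional node-weight file. Node order is fixed
#' by first appearance in the edge list (then the weight file). Nodes
#' present in the edges but absent from the weight file default to
#' weight 1 (with a message).
#'
#' @param path,edge_file,node_weight_file file paths.
#' @return `read_edge_list()`: data.frame `node_a`, `node_b`, `weight`;
#'   `read_node_weights()`: named numeric vector; `read_root_list()`:
#'   character vector; `read_knowledge_network()`: a
#'   [knowledge_network()].
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty edge list: ", path)
  first <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(first) >= 3 && is.na(suppressWarnings(as.numeric(first[3]))))
    lines <- lines[-1]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad) > 0)
    stop("malformed edge line ", bad[1], " in ", path, ": ", lines[bad[1]])
  df <- data.frame(node_a = vapply(parts, `[`, "", 1),
                   node_b = vapply(parts, `[`, "", 2),
                   weight = suppressWarnings(
                     as.numeric(vapply(parts, `[`, "", 3))),
                   stringsAsFactors = FALSE)
  if (any(is.na(df$weight)))
    stop("non-numeric weight on edge line ", which(is.na(df$weight))[1],
         " of ", path)
  self <- df$node_a == df$node_b
  if (any(self)) {
    warning(sum(self), " self-loop edge(s) dropped")
    df <- df[!self, , drop = FALSE]
  }
  key <- ifelse(df$node_a < df$node_b,
                paste(df$node_a, df$node_b, sep = "\t"),
                paste(df$node_b, df$node_a, sep = "\t"))
  dup <- duplicated(key)
  if (any(dup)) {
    w_first <- df$weight[match(key, key)]
    conflict <- dup & df$weight != w_first
    if (any(conflict)) {
      i <- which(conflict)[1]
      stop("conflicting duplicate edge (", df$node_a[i], ", ",
           df$node_b[i], "): weights ", w_first[i], " and ", df$weight[i])
    }
    df <- df[!dup, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' @rdname read_edge_list
#' @export
read_node_weights <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty node-weight file: ", path)
  first <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(first) >= 2 && is.na(suppressWarnings(as.numeric(first[2]))))
    lines <- lines[-1]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2)
  if (length(bad) > 0)
    stop("malformed node-weight line ", bad[1], " in ", path)
  w <- as.numeric(vapply(parts, `[`, "", 2))
  if (any(is.na(w)))
    stop("non-numeric node weight on line ", which(is.na(w))[1], " of ", path)
  names(w) <- vapply(parts, `[`, "", 1)
  if (anyDuplicated(names(w)))
    stop("duplicate node ids in ", path, ": ",
         paste(unique(names(w)[duplicated(names(w))]), collapse = ", "))
  w
}

#' @rdname read_edge_list
#' @export
read_root_list <- function(path) {
  ids <- trimws(readLines(path))
  ids[nzchar(ids)]
}

#' @rdname read_edge_list
#' @export
read_knowledge_network <- function(edge_file, node_weight_file = NULL) {
  edges <- read_edge_list(edge_file)
  ids <- unique(c(rbind(edges$node_a, edges$node_b)))
  w <- rep(1, length(ids))
  names(w) <- ids
  if (!is.null(node_weight_file)) {
    nw <- read_node_weights(node_weight_file)
    extra <- setdiff(names(nw), ids)
    if (length(extra) > 0) {
      ids <- c(ids, extra)
      w <- c(w, rep(1, length(extra)))
      names(w) <- ids
    }
    w[names(nw)] <- nw
    defaulted <- setdiff(ids, names(nw))
    if (length(defaulted) > 0)
      message(length(defaulted),
              " node(s) missing from the weight file; defaulted to 1")
  }
  lw <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  ia <- match(edges$node_a, ids)
  ib <- match(edges$node_b, ids)
  lw[cbind(ia, ib)] <- edges$weight
  lw[cbind(ib, ia)] <- edges$weight
  knowledge_network(lw, node_weights = w, node_ids = ids)
}

fmt_num <- function(x, full_precision = FALSE) {
  if (full_precision) sprintf("%.17g", x) else signif(x, 6)
}

#' Write network, ranking and evaluation files
#'
#' `write_network()` writes a network (and optionally its root set) to
#' the package's standard TSV formats: `<prefix>_edges.tsv` (only
#' positive-weight links), `<prefix>_node_weights.tsv` and, if roots
#' are given, `<prefix>_roots.txt`. `write_ranking()` writes a ranked
#' candidate table as `rank<TAB>node<TAB>posterior`.
#'
#' @param net a [knowledge_network()].
#' @param prefix output path prefix.
#' @param roots optional root ids, written one per line.
#' @param ranking a data.frame from [rank_candidates()] /
#'   [predict.kngp()].
#' @param path output file.
#' @param full_precision write numbers with 17 significant digits
#'   instead of the default 6.
#' @return `write_network()`: named vector of the files written;
#'   `write_ranking()`: `path`, invisibly.
#' @export
write_network <- function(net, prefix, roots = NULL,
                          full_precision = FALSE) {
  stopifnot(inherits(net, "knowledge_network"))
  ids <- net$node_ids
  ut <- which(upper.tri(net$link_weights) & net$link_weights > 0,
              arr.ind = TRUE)
  ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]
  edge_file <- paste0(prefix, "_edges.tsv")
  writeLines(c("node_a\tnode_b\tweight",
               paste(ids[ut[, 1]], ids[ut[, 2]],
                     fmt_num(net$link_weights[ut], full_precision),
                     sep = "\t")),
             edge_file)
  nw_file <- paste0(prefix, "_node_weights.tsv")
  writeLines(c("node\tweight",
               paste(ids, fmt_num(net$node_weights, full_precision),
                     sep = "\t")),
             nw_file)
  files <- c(edges = edge_file, node_weights = nw_file)
  if (!is.null(roots)) {
    root_file <- paste0(prefix, "_roots.txt")
    writeLines(as.character(roots), root_file)
    files <- c(files, roots = root_file)
  }
  files
}

#' @rdname write_network
#' @export
write_ranking <- function(ranking, path, full_precision = FALSE) {
  writeLines(c("rank\tnode\tposterior",
               paste(ranking$rank, ranking$node,
                     fmt_num(ranking$posterior, full_precision),
                     sep = "\t")),
             path)
  invisible(path)
}
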