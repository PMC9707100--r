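#' Build an interactome from an edge list
#'
#' Constructs the undirected, unweighted molecular interaction network on
#' which all connectivity statistics are computed. Gene identifiers are
#' opaque strings matched exactly; identifier mapping must happen upstream.
#' Self-loops and duplicate (unordered) edges are dropped silently, with
#' counts recorded in the `dropped` attribute and reported via `message()`.
#'
#' @param edges a two-column matrix or data frame of gene-identifier pairs,
#'   or an `igraph` object to adopt.
#' @return An object of class `interactome`: an igraph graph with
#'   attributes `N` (node count) and `dropped` (named counts of removed
#'   self-loops and duplicate edges).
#' @examples
#' g <- interactome(cbind(c("a", "b", "c"), c("b", "a", "c")))
#' g$N
#' @export
interactome <- function(edges) {
  if (inherits(edges, "igraph")) {
    g <- igraph::as_undirected(edges, mode = "collapse")
    dropped <- c(self_loops = sum(igraph::which_loop(g)), duplicates = 0L)
    g <- igraph::simplify(g)
  } else {
    edges <- as.matrix(edges)
    if (ncol(edges) < 2L) stop("edge input needs at least two columns")
    edges <- matrix(as.character(edges[, 1:2]), ncol = 2L)
    loops <- edges[, 1] == edges[, 2]
    edges <- edges[!loops, , drop = FALSE]
    key <- ifelse(edges[, 1] < edges[, 2],
                  paste(edges[, 1], edges[, 2], sep = "\r"),
                  paste(edges[, 2], edges[, 1], sep = "\r"))
    dup <- duplicated(key)
    dropped <- c(self_loops = sum(loops), duplicates = sum(dup))
    edges <- edges[!dup, , drop = FALSE]
    if (nrow(edges) == 0L) stop("no edges left after removing self-loops/duplicates")
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  }
  if (sum(dropped) > 0L) {
    message(sprintf("interactome: dropped %d self-loop(s) and %d duplicate edge(s)",
                    dropped[["self_loops"]], dropped[["duplicates"]]))
  }
  structure(list(graph = g,
                 N = igraph::vcount(g),
                 dropped = dropped),
            class = "interactome")
}

#' Read an interactome from a delimited edge-list file
#'
#' Expects at least two columns of gene identifiers per row; extra columns
#' are ignored. Lines starting with `#` are comments.
#'
#' @param path file path.
#' @param delimiter field delimiter, default tab.
#' @return An [interactome] object.
#' @export
read_interactome <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty edge-list file: ", path)
  parts <- strsplit(lines, delimiter, fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 2L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed edge-list row (fewer than 2 fields) at line %d of %s",
                 bad[1], path))
  }
  edges <- cbind(vapply(parts, `[[`, "", 1L), vapply(parts, `[[`, "", 2L))
  interactome(edges)
}

#' @export
print.interactome <- function(x, ...) {
  cat(sprintf("<interactome> %d genes, %d interactions\n",
              x$N, igraph::ecount(x$graph)))
  invisible(x)
}

#' Gene identifiers of an interactome
#' @param g an [interactome].
#' @return Character vector of node names.
#' @export
interactome_genes <- function(g) {
  stopifnot(inherits(g, "interactome"))
  igraph::V(g$graph)$name
}

#' Size of the largest connected component of an induced subgraph
#'
#' The connectivity statistic \eqn{S_{LCC}}: the node count of the largest
#' connected component of the subgraph induced by `genes` on the
#' interactome. Genes absent from the network are ignored (count reported
#' via message when `quiet = FALSE`).
#'
#' @param g an [interactome].
#' @param genes character vector of gene identifiers.
#' @param quiet suppress the dropped-gene message.
#' @return Non-negative integer; 0 when no gene is in the network.
#' @export
lcc_size <- function(g, genes, quiet = TRUE) {
  stopifnot(inherits(g, "interactome"))
  genes <- unique(as.character(genes))
  present <- genes[genes %in% igraph::V(g$graph)$name]
  if (!quiet && length(present) < length(genes)) {
    message(sprintf("lcc_size: %d gene(s) not in interactome ignored",
                    length(genes) - length(present)))
  }
  if (length(present) == 0L) return(0L)
  sub <- igraph::induced_subgraph(g$graph, present)
  as.integer(max(igraph::components(sub)$csize))
}

#' Members of the largest connected component of an induced subgraph
#'
#' Companion to [lcc_size()]: returns the gene identifiers in the largest
#' connected component. Ties between equal-sized components are broken by
#' the lexicographically smallest member, so the result is deterministic.
#'
#' @inheritParams lcc_size
#' @return Character vector (possibly empty).
#' @export
lcc_members <- function(g, genes) {
  stopifnot(inherits(g, "interactome"))
  genes <- unique(as.character(genes))
  present <- genes[genes %in% igraph::V(g$graph)$name]
  if (length(present) == 0L) return(character(0))
  sub <- igraph::induced_subgraph(g$graph, present)
  comp <- igraph::components(sub)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    anchors <- vapply(best, function(ci)
      min(igraph::V(sub)$name[comp$membership == ci]), "")
    best <- best[order(anchors)][1]
  }
  sort(igraph::V(sub)$name[comp$membership == best])
}

#' Shortest-path hop distance between two genes
#'
#' Breadth-first-search distance on the unweighted network. `d(a, a) = 0`.
#' Unreachable pairs return `NA` rather than `Inf` so callers choose their
#' own policy.
#'
#' @param g an [interactome].
#' @param a,b gene identifiers; both must be network nodes.
#' @return Non-negative integer hop count, or `NA` if unreachable.
#' @export
pairwise_shortest_distance <- function(g, a, b) {
  stopifnot(inherits(g, "interactome"))
  nodes <- igraph::V(g$graph)$name
  for (x in c(a, b)) {
    if (!x %in% nodes) stop("gene not in interactome: ", x)
  }
  if (a == b) return(0L)
  d <- igraph::distances(g$graph, v = a, to = b)[1, 1]
  if (is.infinite(d)) NA_integer_ else as.integer(d)
}

#' Draw random null gene sets
#'
#' Size-matched random gene sets used for connectivity and regulation
#' null models. Three strategies:
#' \describe{
#'   \item{uniform}{uniform sampling without replacement from all nodes.}
#'   \item{degree_binned}{degree-matched sampling: each member of the
#'     `reference` set is replaced by a random gene from the same
#'     logarithmic (base-2) degree bin, without replacement within a set.}
#'   \item{connected}{a uniformly seeded, randomly grown connected induced
#'     subgraph of the requested size (random start node on a sufficiently
#'     large component, then random frontier expansion).}
#' }
#' All strategies are deterministic given `seed`.
#'
#' @param g an [interactome].
#' @param size set cardinality, `1 <= size <= N`.
#' @param reps number of sets.
#' @param strategy one of `"uniform"`, `"degree_binned"`, `"connected"`.
#' @param seed integer seed (mandatory).
#' @param reference gene set whose degree sequence is matched
#'   (`degree_binned` only; defaults to a uniform draw of `size` genes).
#' @return List of `reps` character vectors, each of length `size`.
#' @export
sample_null_sets <- function(g, size, reps, strategy = c("uniform", "degree_binned", "connected"),
                             seed, reference = NULL) {
  stopifnot(inherits(g, "interactome"))
  strategy <- match.arg(strategy)
  if (reps < 1L) stop("reps must be >= 1")
  if (size < 1L || size > g$N) stop("size must be in [1, N]")
  nodes <- igraph::V(g$graph)$name
  set.seed(as.integer(seed))

  if (strategy == "uniform") {
    return(lapply(seq_len(reps), function(i) sample(nodes, size)))
  }

  if (strategy == "degree_binned") {
    deg <- igraph::degree(g$graph)
    bin <- floor(log2(pmax(deg, 1)))
    bins <- split(nodes, bin)
    if (is.null(reference)) reference <- sample(nodes, size)
    ref_bins <- bin[match(reference, nodes)]
    if (anyNA(ref_bins)) stop("reference genes must be interactome nodes")
    return(lapply(seq_len(reps), function(i) {
      out <- character(0)
      for (b in names(bins)) {
        need <- sum(ref_bins == as.numeric(b))
        if (need == 0L) next
        pool <- bins[[b]]
        if (need > length(pool)) {  # rare: bin smaller than demand, borrow uniformly
          out <- c(out, pool, sample(setdiff(nodes, c(out, pool)), need - length(pool)))
        } else {
          out <- c(out, sample(pool, need))
        }
      }
      out
    }))
  }

  # connected: random seed node + random frontier expansion
  comp <- igraph::components(g$graph)
  ok_comp <- which(comp$csize >= size)
  if (length(ok_comp) == 0L) {
    stop(sprintf("no connected component has >= %d nodes", size))
  }
  eligible <- nodes[comp$membership %in% ok_comp]
  adj <- igraph::adjacent_vertices(g$graph, igraph::V(g$graph))
  adj <- lapply(adj, function(v) v$name)
  names(adj) <- nodes
  lapply(seq_len(reps), function(i) {
    cur <- sample(eligible, 1)
    chosen <- cur
    frontier <- setdiff(adj[[cur]], chosen)
    while (length(chosen) < size) {
      nxt <- if (length(frontier) == 1L) frontier else sample(frontier, 1)
      chosen <- c(chosen, nxt)
      frontier <- setdiff(union(frontier, adj[[nxt]]), chosen)
    }
    chosen
  })
}
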