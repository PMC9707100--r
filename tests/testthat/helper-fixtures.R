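# shared fixtures and independent oracles, built in code

# path graph a-b-c-d (plus optional isolated extras)
path_graph <- function(nodes = letters[1:4]) {
  interactome(cbind(nodes[-length(nodes)], nodes[-1]))
}

# small deterministic random graph
toy_graph <- function(n = 20, p = 0.2, seed = 42) {
  set.seed(seed)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- idx[stats::runif(nrow(idx)) < p, , drop = FALSE]
  nodes <- sprintf("n%02d", 1:n)
  # guarantee at least a spanning path so the graph is connected
  edges <- rbind(cbind(nodes[-n], nodes[-1]),
                 cbind(nodes[keep[, 1]], nodes[keep[, 2]]))
  suppressMessages(interactome(edges))
}

# independent connected-components oracle: union-find on an edge list,
# no igraph involved
oracle_lcc <- function(edges, genes) {
  genes <- unique(genes)
  if (length(genes) == 0) return(0L)
  parent <- stats::setNames(genes, genes)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1]; b <- edges[k, 2]
    if (a %in% genes && b %in% genes) {
      ra <- find(a); rb <- find(b)
      if (ra != rb) parent[[ra]] <- rb
    }
  }
  roots <- vapply(genes, find, "")
  max(table(roots))
}

# construct a cline_result directly from a z vector (for pattern/ucurve tests)
fake_cline <- function(z, cutoffs = seq_along(z) / length(z),
                       degenerate = rep(FALSE, length(z)),
                       cancer = "toy", omics = "transcriptome") {
  structure(data.frame(cutoff = cutoffs, set_size = 10L, lcc = 5L,
                       null_mean = 1, null_sd = 1, zscore = z,
                       degenerate = degenerate),
            class = c("cline_result", "data.frame"),
            cancer = cancer, omics = omics, reps = 0L, seed = 0L,
            strategy = "uniform",
            ladder = NULL)
}

# session-level cache so expensive simulated fixtures are built once
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# archetype fixture: network + scores + cline at calibrated test scale
archetype_fixture <- function(archetype, seed, reps = 100L) {
  cached(sprintf("%s_%d_%d", archetype, seed, reps), {
    cfg <- synth_config(seed = seed)
    g <- make_network(cfg)
    tab <- make_scores(cfg, g, archetype)
    cl <- build_cline(g, tab, reps = reps, seed = seed)
    list(cfg = cfg, g = g, table = tab, cline = cl)
  })
}
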