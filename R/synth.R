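#' Configuration for the synthetic-data generators
#'
#' The generators emulate the shape of multi-omics perturbation data on
#' an interactome: a scale-free-like background network, a planted
#' connected core of strongly perturbed genes, a connectivity-enriched
#' weakly perturbed periphery, and heavy-ish-tailed background scores.
#' Only a quarter of the network genes carry scores (mirroring a top-25%
#' pre-filtered table). Defaults were calibrated once so that each
#' archetype passes its pattern rule in the large majority of seeds, and
#' are then frozen.
#'
#' @param n_genes network size (>= 50).
#' @param pa_m preferential-attachment edges per new node.
#' @param core_size planted connected core size (>= 2).
#' @param core_extra_edges extra random core-internal edges beyond the
#'   spanning tree.
#' @param periphery_size size of the connectivity-enriched low-score
#'   block.
#' @param table_size number of genes carrying perturbation scores.
#' @param core_score_range score range of planted top-score cores.
#' @param periphery_score_range score range of the low-score block.
#' @param background_score_range score range of scattered background
#'   genes.
#' @param noise_sd noise standard deviation for z-curve fixtures.
#' @param seed integer seed (mandatory; every generator is
#'   seed-deterministic).
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_genes = 600L,
                         pa_m = 2L,
                         core_size = 30L,
                         core_extra_edges = 15L,
                         periphery_size = 210L,
                         table_size = 150L,
                         core_score_range = c(0.928, 0.932),
                         periphery_score_range = c(0, 0.3),
                         background_score_range = c(0.2, 0.9),
                         noise_sd = 0.3,
                         seed = 1L) {
  if (n_genes < 50L) stop("n_genes must be >= 50")
  if (core_size < 2L) stop("core_size must be >= 2")
  if (core_size > periphery_size || periphery_size > n_genes)
    stop("need core_size <= periphery_size <= n_genes")
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  structure(list(n_genes = as.integer(n_genes), pa_m = as.integer(pa_m),
                 core_size = as.integer(core_size),
                 core_extra_edges = as.integer(core_extra_edges),
                 periphery_size = as.integer(periphery_size),
                 table_size = as.integer(table_size),
                 core_score_range = core_score_range,
                 periphery_score_range = periphery_score_range,
                 background_score_range = background_score_range,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a synthetic interactome with a planted connected core
#'
#' A preferential-attachment background graph (heavier degree tail than
#' an equal-density random graph) plus a planted connected subgraph on
#' `core_size` designated genes: a random spanning tree over them and
#' `core_extra_edges` extra random internal edges. Gene names are
#' `g0001`, `g0002`, ...; the planted core genes are recorded in the
#' `planted_core` attribute.
#'
#' @param cfg a [synth_config].
#' @return An [interactome] with attribute `planted_core`.
#' @export
make_network <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  g <- igraph::sample_pa(cfg$n_genes, power = 1, m = cfg$pa_m, directed = FALSE)
  names <- sprintf("g%04d", seq_len(cfg$n_genes))
  igraph::V(g)$name <- names
  core <- sort(sample(names, cfg$core_size))
  # random spanning tree over the core
  perm <- sample(core)
  tree <- cbind(perm[-1],
                vapply(seq_len(cfg$core_size - 1L),
                       function(i) perm[sample.int(i, 1L)], ""))
  extra <- t(replicate(cfg$core_extra_edges, sample(core, 2L)))
  g <- igraph::add_edges(g, t(rbind(tree, extra)))
  g <- igraph::simplify(g)
  net <- interactome(g)
  attr(net, "planted_core") <- core
  net
}

#' Generate archetype perturbation scores on a synthetic network
#'
#' Draws a 150-gene (by default) score table whose CLine follows the
#' requested wave-mode archetype:
#' \describe{
#'   \item{bimodal}{a connectivity-enriched connected block at low
#'     scores plus the planted connected core at top scores; scattered
#'     background in between. Peaks at both cutoff ends.}
#'   \item{fragment}{scores placed anti-correlated with connectivity:
#'     table genes are drawn preferring low-degree nodes, so no cutoff
#'     yields significant connectivity.}
#'   \item{unimodal}{only the planted core carries structure, at
#'     upper-middle scores; the top scores belong to scattered genes, so
#'     the curve has a single interior peak.}
#'   \item{steepest_descent}{a connected low-score block with scattered
#'     top scorers: connectivity significance decays from the low-cutoff
#'     end.}
#' }
#' The planted core (where used) is recorded in the `planted_core`
#' attribute of the returned table.
#'
#' @param cfg a [synth_config].
#' @param g the [interactome] from [make_network()] with the same `cfg`.
#' @param archetype one of `"bimodal"`, `"fragment"`, `"unimodal"`,
#'   `"steepest_descent"`.
#' @param cancer label stored on the table.
#' @return A [perturbation_table]; omics label set to the omics aspect
#'   the archetype models.
#' @export
make_scores <- function(cfg, g, archetype = c("bimodal", "fragment", "unimodal",
                                              "steepest_descent"),
                        cancer = "synthetic") {
  stopifnot(inherits(cfg, "synth_config"), inherits(g, "interactome"))
  archetype <- match.arg(archetype)
  set.seed(cfg$seed + 1000L)
  nodes <- interactome_genes(g)
  core <- attr(g, "planted_core")
  if (is.null(core)) core <- sort(sample(nodes, cfg$core_size))
  runifr <- function(n, r) stats::runif(n, r[1], r[2])
  omics <- c(bimodal = "transcriptome", fragment = "methylation",
             unimodal = "somatic_mutation", steepest_descent = "cnv")[[archetype]]

  deg <- igraph::degree(g$graph)
  # scattered genes drawn preferring low-degree nodes (independent-set-like)
  sample_scattered <- function(pool, n) {
    w <- 1 / (deg[match(pool, nodes)] + 1)^2
    sample(pool, n, prob = w)
  }

  if (archetype == "bimodal") {
    # connected block whose hubs carry the lowest scores: the block holds the
    # low-cutoff sets together, then dissolves into a low-degree remnant that
    # depresses mid-cutoff connectivity; the core sits in a narrow top band
    # (at most one ladder bin wide) so the high-cutoff local maximum captures
    # it whole; top-score scatter dilutes the high part.
    block <- sample_null_sets(g, size = cfg$periphery_size, reps = 1L,
                              strategy = "connected", seed = cfg$seed + 2000L)[[1]]
    block <- setdiff(block, core)
    sub <- igraph::induced_subgraph(g$graph, block)
    bdeg <- igraph::degree(sub)[block]
    n_hub <- round(0.4 * length(block))
    hubs <- block[order(-bdeg)][seq_len(n_hub)]
    rest <- setdiff(block, hubs)
    bg_top <- sample(setdiff(nodes, c(core, block)), 100L)
    scores <- c(stats::setNames(runifr(length(hubs), c(0, 0.25)), hubs),
                stats::setNames(runifr(length(rest), c(0.25, 0.98)), rest),
                stats::setNames(runifr(length(core), cfg$core_score_range), core),
                stats::setNames(runifr(100L, c(0.85, 1)), bg_top))
  } else if (archetype == "fragment") {
    # high scorers on low-degree nodes: no cutoff yields significant LCC
    genes <- sample_scattered(nodes, cfg$table_size)
    ranked <- genes[order(deg[match(genes, nodes)])]
    scores <- stats::setNames(sort(stats::runif(cfg$table_size), decreasing = TRUE),
                              ranked)
  } else if (archetype == "unimodal") {
    n_top <- 20L
    pool <- setdiff(nodes, core)
    top <- sample_scattered(pool, n_top)
    n_bg <- cfg$table_size - length(core) - n_top
    bg <- sample(setdiff(pool, top), n_bg)
    scores <- c(stats::setNames(runifr(length(core), c(0.5, 0.8)), core),
                stats::setNames(runifr(n_top, c(0.8, 1)), top),
                stats::setNames(runifr(n_bg, c(0, 0.55)), bg))
  } else {  # steepest_descent
    block <- sample_null_sets(g, size = 120L, reps = 1L,
                              strategy = "connected", seed = cfg$seed + 2000L)[[1]]
    # rank-match block scores to within-block degree: low-degree members exit
    # first as the cutoff rises, so the shrinking remnant stays hub-rich and
    # connected and the curve decays without a deep low-part dip
    sub <- igraph::induced_subgraph(g$graph, block)
    block <- block[order(igraph::degree(sub)[block])]
    block_scores <- sort(runifr(length(block), cfg$periphery_score_range))
    n_top <- 20L
    pool <- setdiff(nodes, block)
    top <- sample_scattered(pool, n_top)
    bg <- sample(setdiff(pool, top), 110L)
    scores <- c(stats::setNames(block_scores, block),
                stats::setNames(runifr(n_top, c(0.9, 1)), top),
                stats::setNames(runifr(110L, cfg$background_score_range), bg))
  }
  tab <- perturbation_table(scores, cancer = cancer, omics = omics)
  attr(tab, "planted_core") <- if (archetype %in% c("bimodal")) core else
    if (archetype == "unimodal") core else NULL
  tab
}

#' Generate synthetic eQTL data with planted X-to-Y regulation
#'
#' Lays every network gene on one synthetic chromosome (BED-style
#' 0-based half-open intervals of 1 kb, 1 kb apart) and draws
#' `n_pairs` SNP-to-gene regulatory pairs: each SNP is placed inside a
#' host gene drawn with weight `enrichment` for genes of X and 1
#' otherwise, and regulates a target drawn uniformly from Y plus a
#' background target pool. `enrichment = 1` gives a calibrated null;
#' larger values plant X-hosted regulation of Y.
#'
#' @param cfg a [synth_config].
#' @param X host gene set (the periphery-like set).
#' @param Y target gene set (the core-like set).
#' @param enrichment host-weight fold for X, >= 1.
#' @param n_pairs number of SNP-gene pairs.
#' @param g the [interactome] whose genes get intervals; defaults to
#'   laying out X, Y and `g0001...` names from `cfg$n_genes`.
#' @return An [eqtl_data].
#' @export
make_eqtl <- function(cfg, X, Y, enrichment = 1, n_pairs = 500L, g = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  if (enrichment < 1) stop("enrichment must be >= 1")
  set.seed(cfg$seed + 3000L)
  genes <- if (!is.null(g)) interactome_genes(g) else sprintf("g%04d", seq_len(cfg$n_genes))
  genes <- sort(union(genes, union(X, Y)))
  n <- length(genes)
  gene_intervals <- data.frame(chrom = "chr1",
                               start = (seq_len(n) - 1L) * 2000L,
                               end = (seq_len(n) - 1L) * 2000L + 1000L,
                               gene = genes)
  X <- unique(as.character(X))
  if (length(X) == 0L) {
    hosts <- sample(genes, n_pairs, replace = TRUE)
  } else {
    w <- ifelse(genes %in% X, enrichment, 1)
    hosts <- sample(genes, n_pairs, replace = TRUE, prob = w)
  }
  target_pool <- union(unique(as.character(Y)),
                       sample(setdiff(genes, Y), min(100L, length(setdiff(genes, Y)))))
  targets <- sample(target_pool, n_pairs, replace = TRUE)
  host_idx <- match(hosts, genes)
  pairs <- data.frame(snp_id = sprintf("s%05d", seq_len(n_pairs)),
                      chrom = "chr1",
                      pos = gene_intervals$start[host_idx] +
                            sample.int(1000L, n_pairs, replace = TRUE),
                      gene = targets)
  eqtl_data(pairs, gene_intervals)
}

#' Generate a gene-set collection with one planted enriched set
#'
#' Random annotation sets over the network genes plus one set built to
#' contain most of `query`, for testing over-representation ranking.
#'
#' @param cfg a [synth_config].
#' @param universe gene universe.
#' @param query gene set the planted set is enriched for.
#' @param n_sets number of random sets.
#' @param set_size size of each random set.
#' @param planted_coverage fraction of `query` included in the planted
#'   set.
#' @return A [geneset_collection] whose first set is named `"planted"`.
#' @export
make_geneset_collection <- function(cfg, universe, query, n_sets = 10L,
                                    set_size = 50L, planted_coverage = 0.8) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed + 4000L)
  universe <- unique(as.character(universe))
  query <- intersect(unique(as.character(query)), universe)
  take <- max(1L, round(planted_coverage * length(query)))
  planted <- union(sample(query, take),
                   sample(setdiff(universe, query),
                          max(0L, set_size - take)))
  sets <- c(list(planted = planted),
            stats::setNames(lapply(seq_len(n_sets), function(i)
              sample(universe, set_size)), sprintf("random%02d", seq_len(n_sets))))
  geneset_collection(sets, universe)
}
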