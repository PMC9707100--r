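#' Excess overlap of a gene set with an annotation set
#'
#' Fold enrichment of annotation set `A` within query set `B`, relative
#' to A's share of the gene universe:
#' `(|A n B| / |B|) / (|A n N| / |N|)` with `N` the universe. Values
#' above 1 mean greater overlap than random expectation.
#'
#' @param A annotation gene set.
#' @param B query gene set (non-empty).
#' @param universe gene universe (the network's node set).
#' @return Non-negative real.
#' @export
excess_overlap <- function(A, B, universe) {
  A <- unique(as.character(A)); B <- unique(as.character(B))
  universe <- unique(as.character(universe))
  if (length(B) == 0L) stop("B must be non-empty")
  AN <- length(intersect(A, universe))
  if (AN == 0L) stop("A is disjoint from the universe")
  (length(intersect(A, B)) / length(B)) / (AN / length(universe))
}

#' Gene-set collection restricted to a universe
#'
#' @param sets named list of gene sets (e.g. from [read_gmt()]).
#' @param universe character vector; members outside it are dropped with
#'   a message.
#' @return A `geneset_collection`: list with `sets`, `universe`.
#' @export
geneset_collection <- function(sets, universe) {
  stopifnot(is.list(sets), !is.null(names(sets)), !anyDuplicated(names(sets)))
  universe <- unique(as.character(universe))
  dropped <- 0L
  sets <- lapply(sets, function(s) {
    s <- unique(as.character(s))
    keep <- s %in% universe
    dropped <<- dropped + sum(!keep)
    s[keep]
  })
  if (dropped > 0L)
    message(sprintf("geneset_collection: dropped %d member(s) outside the universe", dropped))
  structure(list(sets = sets, universe = universe), class = "geneset_collection")
}

#' Hypergeometric over-representation analysis
#'
#' Per collection set, the upper-tail hypergeometric probability of the
#' observed overlap with the query ([overlap_pvalue()]), over the
#' collection's universe. Results are sorted by p-value; a
#' Benjamini-Hochberg adjusted column is included.
#'
#' @param query gene set (restricted to the universe first).
#' @param collection a [geneset_collection].
#' @return Data frame: `set`, `k`, `set_size`, `p_value`, `p_adjust`,
#'   sorted by `p_value`.
#' @export
ora <- function(query, collection) {
  stopifnot(inherits(collection, "geneset_collection"))
  query <- intersect(unique(as.character(query)), collection$universe)
  if (length(query) == 0L) stop("query is empty after restriction to the universe")
  N <- length(collection$universe)
  res <- data.frame(
    set = names(collection$sets),
    k = vapply(collection$sets, function(s) length(intersect(query, s)), 0L),
    set_size = vapply(collection$sets, length, 0L))
  res$p_value <- mapply(function(k, M) overlap_pvalue(k, length(query), M, N),
                        res$k, res$set_size)
  res$p_adjust <- stats::p.adjust(res$p_value, method = "BH")
  res <- res[order(res$p_value, res$set), ]
  rownames(res) <- NULL
  res
}

# eQTL data ------------------------------------------------------------------

#' eQTL pair data with gene intervals
#'
#' Container for SNP-to-gene regulatory pairs plus the genomic intervals
#' needed to locate each SNP inside host genes. Gene intervals follow the
#' BED convention (0-based, half-open `[start, end)`); SNP positions are
#' 1-based (VCF convention) and are converted internally when testing
#' containment.
#'
#' @param pairs data frame with columns `snp_id`, `chrom`, `pos`
#'   (1-based), `gene` (the regulated gene).
#' @param gene_intervals data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open), `gene`.
#' @return An `eqtl_data`: `pairs`, `esite` (SNP ids), `egene`
#'   (regulated genes), `gene_intervals`.
#' @export
eqtl_data <- function(pairs, gene_intervals) {
  need <- c("snp_id", "chrom", "pos", "gene")
  if (!all(need %in% names(pairs))) stop("pairs needs columns: ", paste(need, collapse = ", "))
  needi <- c("chrom", "start", "end", "gene")
  if (!all(needi %in% names(gene_intervals)))
    stop("gene_intervals needs columns: ", paste(needi, collapse = ", "))
  if (any(gene_intervals$start >= gene_intervals$end))
    stop("gene intervals must satisfy start < end")
  bad <- setdiff(unique(pairs$chrom), unique(gene_intervals$chrom))
  if (length(bad) > 0L)
    stop("chromosome name(s) in pairs absent from gene_intervals: ",
         paste(bad, collapse = ", "))
  structure(list(pairs = pairs,
                 esite = unique(as.character(pairs$snp_id)),
                 egene = unique(as.character(pairs$gene)),
                 gene_intervals = gene_intervals),
            class = "eqtl_data")
}

#' Read eQTL pairs from TSV
#'
#' Columns `snp_id`, `chrom`, `pos`, `gene` with header.
#' @param pairs_path TSV of pairs.
#' @param bed_path BED file of gene intervals (columns chrom, start,
#'   end, name).
#' @return An [eqtl_data].
#' @export
read_eqtl <- function(pairs_path, bed_path) {
  pairs <- utils::read.delim(pairs_path, stringsAsFactors = FALSE)
  bed <- utils::read.delim(bed_path, header = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#")
  if (ncol(bed) < 4L) stop("BED file needs at least 4 columns (chrom, start, end, name)")
  gene_intervals <- data.frame(chrom = bed[[1]], start = bed[[2]],
                               end = bed[[3]], gene = bed[[4]])
  eqtl_data(pairs, gene_intervals)
}

#' Map SNPs to host genes by genomic position
#'
#' A SNP is hosted by gene `g` when its (1-based) coordinate lies inside
#' any of g's BED intervals; a SNP inside several overlapping genes is
#' assigned to all of them. Uses interval overlap from the
#' GenomicRanges machinery.
#'
#' @param eqtl an [eqtl_data].
#' @return Named list: for each SNP id, the character vector of host
#'   genes (possibly empty).
#' @export
map_snps_to_genes <- function(eqtl) {
  stopifnot(inherits(eqtl, "eqtl_data"))
  snps <- unique(eqtl$pairs[, c("snp_id", "chrom", "pos")])
  gi <- eqtl$gene_intervals
  snp_gr <- GenomicRanges::GRanges(snps$chrom,
                                   IRanges::IRanges(start = snps$pos, width = 1L))
  gene_gr <- GenomicRanges::GRanges(gi$chrom,
                                    IRanges::IRanges(start = gi$start + 1L, end = gi$end))
  hits <- GenomicRanges::findOverlaps(snp_gr, gene_gr)
  out <- stats::setNames(vector("list", nrow(snps)), snps$snp_id)
  for (i in seq_along(out)) out[[i]] <- character(0)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  for (h in seq_along(q)) {
    id <- snps$snp_id[q[h]]
    out[[id]] <- union(out[[id]], gi$gene[s[h]])
  }
  out
}

#' Regulated amount between two gene sets through eQTL pairs
#'
#' With pair relation set P of (SNP s, regulated gene g) and the hosting
#' indicator I(s, q) = 1 when s lies inside gene q:
#' \describe{
#'   \item{of_Y_by_X}{`|{g : I(s,q)=1, (s,g) in P, q in X, g in Y}|` --
#'     the number of distinct Y genes regulated by SNPs hosted in X.}
#'   \item{of_X_over_Y}{`|{q : I(s,q)=1, (s,g) in P, q in X, g in Y}|` --
#'     the number of distinct X host genes whose SNPs regulate Y.}
#' }
#'
#' @param X,Y gene sets.
#' @param eqtl an [eqtl_data].
#' @param direction counting direction, see above.
#' @param hosts optional precomputed [map_snps_to_genes()] result.
#' @return Non-negative integer.
#' @export
regulated_amount <- function(X, Y, eqtl, direction = c("of_Y_by_X", "of_X_over_Y"),
                             hosts = NULL) {
  stopifnot(inherits(eqtl, "eqtl_data"))
  direction <- match.arg(direction)
  if (nrow(eqtl$pairs) == 0L) return(0L)
  if (is.null(hosts)) hosts <- map_snps_to_genes(eqtl)
  X <- unique(as.character(X)); Y <- unique(as.character(Y))
  p <- eqtl$pairs
  hosted_in_X <- vapply(as.character(p$snp_id),
                        function(s) any(hosts[[s]] %in% X), TRUE)
  live <- hosted_in_X & (p$gene %in% Y)
  if (direction == "of_Y_by_X") {
    length(unique(p$gene[live]))
  } else {
    length(unique(unlist(lapply(as.character(p$snp_id[live]),
                                function(s) intersect(hosts[[s]], X)))))
  }
}

#' Regulation z-score against random counterpart gene sets
#'
#' Significance of the observed [regulated_amount()] of Y by X against
#' `reps` random counterparts of X drawn by [sample_null_sets()]
#' (uniform size-matched, connected size-matched, or degree-matched).
#'
#' @param X,Y gene sets.
#' @param eqtl an [eqtl_data].
#' @param g an [interactome] to draw null sets from.
#' @param strategy null strategy, see [sample_null_sets()].
#' @param reps null replicates, default 1000.
#' @param seed integer seed.
#' @param direction passed to [regulated_amount()].
#' @return A one-row data frame: `observed`, `null_mean`, `null_sd`,
#'   `zscore`, `degenerate`.
#' @export
regulation_zscore <- function(X, Y, eqtl, g, strategy = "uniform",
                              reps = 1000L, seed = 1L,
                              direction = "of_Y_by_X") {
  stopifnot(inherits(eqtl, "eqtl_data"), inherits(g, "interactome"))
  hosts <- map_snps_to_genes(eqtl)
  obs <- regulated_amount(X, Y, eqtl, direction, hosts = hosts)
  X_net <- intersect(unique(as.character(X)), interactome_genes(g))
  if (length(X_net) == 0L) stop("X has no gene in the interactome")
  nulls <- sample_null_sets(g, size = length(X_net), reps = reps,
                            strategy = strategy, seed = seed, reference = X_net)
  amounts <- vapply(nulls, function(s)
    regulated_amount(s, Y, eqtl, direction, hosts = hosts), 0L)
  mu <- mean(amounts); sigma <- stats::sd(amounts)
  degenerate <- !is.finite(sigma) || sigma == 0
  data.frame(observed = obs, null_mean = mu, null_sd = sigma,
             zscore = if (degenerate) 0 else (obs - mu) / sigma,
             degenerate = degenerate)
}
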