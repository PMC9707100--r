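#' LCC z-score of a gene set against size-matched random sets
#'
#' Connectivity significance of a gene set: the size of its largest
#' connected component compared with the mean and standard deviation of
#' the LCC size of `reps` random size-matched gene sets,
#' `z = (S_LCC - mu) / sigma`.
#'
#' Degenerate situations (fewer than 2 genes, or a null with zero
#' standard deviation) set `degenerate = TRUE` and report `zscore = 0`
#' instead of `NaN`, so curves keep a fixed length.
#'
#' An exhaustive mode replaces sampling by complete enumeration of all
#' `choose(N, k)` size-k node subsets whenever that count is at most
#' `exhaustive_limit`; it exists chiefly to let tests compare the sampled
#' null against the exact one.
#'
#' @param g an [interactome].
#' @param genes gene identifiers (must be nodes of `g`).
#' @param reps null replicates, default 1000.
#' @param strategy null-set strategy passed to [sample_null_sets()].
#' @param seed integer seed.
#' @param exhaustive if `TRUE`, enumerate all subsets instead of sampling.
#' @param exhaustive_limit maximum number of subsets for exhaustive mode.
#' @return A one-row data frame: `set_size`, `lcc`, `null_mean`,
#'   `null_sd`, `zscore`, `degenerate`.
#' @export
lcc_zscore <- function(g, genes, reps = 1000L, strategy = "uniform", seed = 1L,
                       exhaustive = FALSE, exhaustive_limit = 1e5) {
  stopifnot(inherits(g, "interactome"))
  if (!exhaustive && reps < 1L) stop("reps must be >= 1")
  genes <- unique(as.character(genes))
  k <- length(genes)
  obs <- if (k == 0L) 0L else lcc_size(g, genes)

  if (k < 2L) {
    return(data.frame(set_size = k, lcc = obs, null_mean = NA_real_,
                      null_sd = NA_real_, zscore = 0, degenerate = TRUE))
  }

  if (exhaustive) {
    if (choose(g$N, k) > exhaustive_limit)
      stop("exhaustive mode infeasible: choose(N, k) exceeds exhaustive_limit")
    subsets <- utils::combn(interactome_genes(g), k, simplify = FALSE)
    sizes <- vapply(subsets, function(s) lcc_size(g, s), 0L)
  } else {
    nulls <- sample_null_sets(g, size = k, reps = reps, strategy = strategy,
                              seed = seed, reference = genes)
    sizes <- vapply(nulls, function(s) lcc_size(g, s), 0L)
  }
  mu <- mean(sizes)
  sigma <- stats::sd(sizes)
  if (!is.finite(sigma) || sigma == 0) {
    return(data.frame(set_size = k, lcc = obs, null_mean = mu,
                      null_sd = if (is.finite(sigma)) sigma else NA_real_,
                      zscore = 0, degenerate = TRUE))
  }
  data.frame(set_size = k, lcc = obs, null_mean = mu, null_sd = sigma,
             zscore = (obs - mu) / sigma, degenerate = FALSE)
}

#' Build the connectivity line (CLine) of a perturbation table
#'
#' One point per ladder cutoff: the LCC z-score of the thresholded gene
#' set `S_i = {j : w_j > f_i}`. Null sets are drawn from the full
#' interactome node set (network-random expectation, not omics-table
#' random). Each point uses `seed + point index` for its null draws, so
#' the curve is reproducible and points are independent.
#'
#' @param g an [interactome].
#' @param table a [perturbation_table] (already network-restricted).
#' @param ladder a [cutoff_ladder] built from `table`; default builds
#'   `cutoff_ladder(table, t)`.
#' @param t bin count used when `ladder` is `NULL`.
#' @param reps null replicates per point, default 1000.
#' @param strategy null strategy, see [sample_null_sets()].
#' @param seed integer base seed.
#' @return A `cline_result`: data frame with columns `cutoff`, `set_size`,
#'   `lcc`, `null_mean`, `null_sd`, `zscore`, `degenerate`, carrying
#'   attributes `cancer`, `omics`, `reps`, `seed`, `strategy`, `ladder`.
#' @export
build_cline <- function(g, table, ladder = NULL, t = 50L, reps = 1000L,
                        strategy = "uniform", seed = 1L) {
  stopifnot(inherits(g, "interactome"), inherits(table, "perturbation_table"))
  if (is.null(ladder)) ladder <- cutoff_ladder(table, t)
  stopifnot(inherits(ladder, "cutoff_ladder"))
  missing <- setdiff(names(table$scores), interactome_genes(g))
  if (length(missing) > 0L)
    stop("perturbation table contains genes outside the interactome; ",
         "apply restrict_to_network() first (", length(missing), " offending)")

  rows <- lapply(seq_along(ladder$fl), function(i) {
    genes <- threshold_set(table, ladder$fl[i])
    pt <- lcc_zscore(g, genes, reps = reps, strategy = strategy,
                     seed = as.integer(seed) + i - 1L)
    cbind(cutoff = ladder$fl[i], pt)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out,
            class = c("cline_result", "data.frame"),
            cancer = table$cancer, omics = table$omics,
            reps = reps, seed = seed, strategy = strategy, ladder = ladder)
}

#' @export
print.cline_result <- function(x, ...) {
  nz <- !x$degenerate
  cat(sprintf("<cline_result> %s / %s: %d points (%d informative), z in [%.3g, %.3g]\n",
              attr(x, "cancer"), attr(x, "omics"), nrow(x), sum(nz),
              if (any(nz)) min(x$zscore[nz]) else NA,
              if (any(nz)) max(x$zscore[nz]) else NA))
  invisible(x)
}

#' Minimal CLine plot
#'
#' Z-score against cutoff; degenerate points are hollow.
#'
#' @param x a `cline_result`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cline_result <- function(x, ...) {
  graphics::plot(x$cutoff, x$zscore, type = "l",
                 xlab = "perturbation-degree cutoff", ylab = "LCC z-score",
                 main = sprintf("CLine %s / %s", attr(x, "cancer"), attr(x, "omics")),
                 ...)
  graphics::points(x$cutoff, x$zscore, pch = ifelse(x$degenerate, 1, 19), cex = 0.6)
  invisible(x)
}

#' Write a CLine as TSV (+ JSON metadata sidecar)
#'
#' @param cline a `cline_result`.
#' @param path TSV output path; metadata goes to `paste0(path, ".json")`.
#' @export
write_cline <- function(cline, path) {
  stopifnot(inherits(cline, "cline_result"))
  utils::write.table(as.data.frame(cline), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  meta <- list(cancer = attr(cline, "cancer"), omics = attr(cline, "omics"),
               reps = attr(cline, "reps"), seed = attr(cline, "seed"),
               strategy = attr(cline, "strategy"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
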