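#' Jaccard coefficient of two gene sets
#'
#' `|A intersect B| / |A union B|`; 0 when both sets are empty.
#'
#' @param A,B character vectors (treated as sets).
#' @return Real in `[0, 1]`.
#' @export
jaccard <- function(A, B) {
  A <- unique(A); B <- unique(B)
  u <- length(union(A, B))
  if (u == 0L) return(0)
  length(intersect(A, B)) / u
}

#' Upper-tail hypergeometric overlap p-value
#'
#' Probability of observing at least `k` shared genes between a set of
#' size `n` and a set of size `M` drawn from a universe of `N` genes,
#' `P(X >= k)` for `X ~ Hypergeometric(N, M, n)`. Computed in log space
#' via [stats::phyper()] for numerical stability.
#'
#' @param k observed overlap.
#' @param n,M the two set sizes.
#' @param N universe size (all genes in the network).
#' @return p-value in (0, 1].
#' @export
overlap_pvalue <- function(k, n, M, N) {
  if (any(c(k, n, M, N) < 0) || k > min(n, M) || max(n, M) > N)
    stop("inconsistent hypergeometric parameters: need 0 <= k <= min(n, M) <= N")
  if (k == 0L) return(1)
  exp(stats::phyper(k - 1, M, N - M, n, lower.tail = FALSE, log.p = TRUE))
}

#' Overlap statistics of two gene sets
#'
#' Bundles Jaccard and hypergeometric overlap significance for a pair of
#' gene sets over a fixed universe.
#'
#' @param A,B gene sets.
#' @param universe gene universe (e.g. `interactome_genes(g)`); members
#'   of A and B outside the universe are dropped first.
#' @return Data frame: `jaccard`, `k`, `n`, `M`, `N`, `p_value`.
#' @export
overlap_stat <- function(A, B, universe) {
  A <- intersect(unique(A), universe); B <- intersect(unique(B), universe)
  k <- length(intersect(A, B))
  data.frame(jaccard = jaccard(A, B), k = k, n = length(A), M = length(B),
             N = length(unique(universe)),
             p_value = overlap_pvalue(k, length(A), length(B), length(unique(universe))))
}

# nearest-member distance matrix helpers ------------------------------------

# distances from each gene of `from` to its nearest member of `to`;
# `exclude_self` removes the zero self-distance (within-set convention)
.nearest_distances <- function(g, from, to, exclude_self = FALSE) {
  d <- igraph::distances(g$graph, v = from, to = to)
  if (exclude_self) {
    shared <- intersect(from, to)
    d[cbind(match(shared, from), match(shared, to))] <- Inf
  }
  apply(d, 1, min)
}

#' Average shortest network distance and separation of two gene sets
#'
#' `<d_AB>` averages, over every gene of A and of B, the shortest-path
#' distance to the nearest gene of the other set (`d(a, b) = 0` when a
#' and b coincide). The separation statistic is
#' `s_AB = <d_AB> - (<d_AA> + <d_BB>) / 2`, where the within-set terms
#' use each gene's nearest OTHER member by default (`within = "exclude_self"`);
#' taking the literal zero self-distance instead (`within = "include_self"`)
#' collapses `<d_AA>` to 0 and reduces `s_AB` to `<d_AB>`, so the
#' exclude-self convention of the established separation measure is the
#' default.
#'
#' Computation is restricted to the largest component of the interactome;
#' genes outside it (or outside the network) are dropped and the retained
#' fraction reported as `coverage`.
#'
#' @param g an [interactome].
#' @param A,B non-empty gene sets.
#' @param within within-set distance convention, see above.
#' @return A `distance_stat` data frame: `d_AB`, `d_AA`, `d_BB`, `s_AB`,
#'   `coverage`.
#' @export
set_distance <- function(g, A, B, within = c("exclude_self", "include_self")) {
  stopifnot(inherits(g, "interactome"))
  within <- match.arg(within)
  comp <- igraph::components(g$graph)
  main <- igraph::V(g$graph)$name[comp$membership == which.max(comp$csize)]
  A0 <- unique(as.character(A)); B0 <- unique(as.character(B))
  A <- intersect(A0, main); B <- intersect(B0, main)
  coverage <- (length(A) + length(B)) / (length(A0) + length(B0))
  if (length(A) == 0L || length(B) == 0L)
    stop(sprintf("empty gene set after restriction to the largest component (coverage %.2f)",
                 coverage))

  d_AB <- (sum(.nearest_distances(g, A, B)) + sum(.nearest_distances(g, B, A))) /
          (length(A) + length(B))
  within_mean <- function(S) {
    if (length(S) < 2L) return(0)
    if (within == "include_self") return(0)
    mean(.nearest_distances(g, S, S, exclude_self = TRUE))
  }
  d_AA <- within_mean(A); d_BB <- within_mean(B)
  out <- data.frame(d_AB = d_AB, d_AA = d_AA, d_BB = d_BB,
                    s_AB = d_AB - (d_AA + d_BB) / 2, coverage = coverage)
  class(out) <- c("distance_stat", "data.frame")
  out
}

#' Mann-Whitney U (rank-sum) test p-value
#'
#' Exact enumeration of the permutation distribution of the rank-sum
#' statistic when the combined sample size is at most `exact_limit`
#' (handles ties by enumerating group assignments of the observed,
#' possibly tied, values); otherwise the tie-corrected normal
#' approximation. When every value is tied across both samples the test
#' is uninformative and returns p = 1 with a warning.
#'
#' @param x,y non-empty numeric samples.
#' @param alternative `"two_sided"` (default), `"less"` or `"greater"`
#'   (`less` means x tends to be smaller than y).
#' @param exact_limit combined-size bound for exact enumeration.
#' @return p-value.
#' @export
mannwhitney_u <- function(x, y, alternative = c("two_sided", "less", "greater"),
                          exact_limit = 12L) {
  alternative <- match.arg(alternative)
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be non-empty")
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L) {
    warning("all values tied across both samples; test is uninformative")
    return(1)
  }
  r <- rank(pooled)
  U_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2  # U of sample x

  if (nx + ny <= exact_limit) {
    idx <- utils::combn(nx + ny, nx)
    Us <- apply(idx, 2, function(ii) sum(r[ii]) - nx * (nx + 1) / 2)
    p_greater <- mean(Us >= U_obs)
    p_less <- mean(Us <= U_obs)
  } else {
    mu <- nx * ny / 2
    ties <- table(pooled)
    n <- nx + ny
    sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    sigma <- sqrt(sigma2)
    # continuity-corrected normal tails
    p_greater <- stats::pnorm((U_obs - 0.5 - mu) / sigma, lower.tail = FALSE)
    p_less <- stats::pnorm((U_obs + 0.5 - mu) / sigma)
  }
  switch(alternative,
         greater = p_greater,
         less = p_less,
         two_sided = min(1, 2 * min(p_greater, p_less)))
}

#' Full proximity report for a pair of gene sets
#'
#' @param g an [interactome].
#' @param A,B gene sets.
#' @param universe overlap universe; default all interactome genes.
#' @return One-row data frame combining [overlap_stat()] and
#'   [set_distance()].
#' @export
proximity_report <- function(g, A, B, universe = interactome_genes(g)) {
  cbind(overlap_stat(A, B, universe), as.data.frame(set_distance(g, A, B)))
}

#' Pairwise proximity matrices over a list of gene sets
#'
#' Computes one symmetric matrix per statistic (`jaccard`, `p_value`,
#' `d_AB`, `s_AB`) over all unordered pairs of the named gene sets.
#'
#' @param g an [interactome].
#' @param sets named list of gene sets.
#' @return Named list of symmetric matrices.
#' @export
proximity_matrices <- function(g, sets) {
  stopifnot(is.list(sets), length(sets) >= 2L, !is.null(names(sets)))
  n <- length(sets); labs <- names(sets)
  mk <- function() matrix(NA_real_, n, n, dimnames = list(labs, labs))
  out <- list(jaccard = mk(), p_value = mk(), d_AB = mk(), s_AB = mk())
  universe <- interactome_genes(g)
  for (i in seq_len(n)) for (j in i:n) {
    rep <- proximity_report(g, sets[[i]], sets[[j]], universe)
    for (stat in names(out)) {
      out[[stat]][i, j] <- rep[[stat]]
      out[[stat]][j, i] <- rep[[stat]]
    }
  }
  out
}
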