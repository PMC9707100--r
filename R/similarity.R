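#' Distance-based cancer similarity matrix (simAB)
#'
#' For each unordered pair of cancers, `simAB = 1 - <d_AB> / <d>_max`,
#' where `<d_AB>` is the average shortest network distance between their
#' gene sets ([set_distance()]) and `<d>_max` the largest `<d_AB>` over
#' all pairs in the cohort (self-pairs excluded). Identical sets get 1;
#' the most distant pair gets 0.
#'
#' @param g an [interactome].
#' @param sets named list (cancer label -> gene set), length >= 2.
#' @return A `similarity_matrix`: `values` (symmetric, unit diagonal),
#'   `labels`, `method = "simAB"`, `d_max`.
#' @export
simab_matrix <- function(g, sets) {
  stopifnot(inherits(g, "interactome"), is.list(sets), length(sets) >= 2L,
            !is.null(names(sets)))
  labs <- names(sets)
  n <- length(sets)
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    dij <- set_distance(g, sets[[i]], sets[[j]])$d_AB
    d[i, j] <- dij; d[j, i] <- dij
  }
  d_max <- max(d[upper.tri(d)])
  if (d_max <= 0) stop("degenerate cohort: all pairwise distances are zero")
  values <- 1 - d / d_max
  diag(values) <- 1
  structure(list(values = values, labels = labs, method = "simAB", d_max = d_max),
            class = "similarity_matrix")
}

#' Jaccard cancer similarity matrix
#'
#' Pairwise [jaccard()] over named gene sets.
#'
#' @param sets named list of gene sets.
#' @return A `similarity_matrix` with `method = "jaccard"`.
#' @export
jaccard_matrix <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2L, !is.null(names(sets)))
  labs <- names(sets)
  n <- length(sets)
  values <- matrix(1, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    v <- jaccard(sets[[i]], sets[[j]])
    values[i, j] <- v; values[j, i] <- v
  }
  structure(list(values = values, labels = labs, method = "jaccard",
                 d_max = NA_real_),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> %s over %d labels\n", x$method,
              length(x$labels)))
  print(round(x$values, 3))
  invisible(x)
}

#' Read a square similarity matrix from CSV
#'
#' Expects a header row and first column of labels; `NA` marks undefined
#' pairs (sparse references).
#'
#' @param path CSV path.
#' @param method label recorded on the result.
#' @return A `similarity_matrix`.
#' @export
read_similarity_csv <- function(path, method = "reference") {
  m <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  if (nrow(m) != ncol(m) || !all(rownames(m) == colnames(m)))
    stop("similarity CSV must be square with matching row/column labels")
  structure(list(values = m, labels = rownames(m), method = method,
                 d_max = NA_real_),
            class = "similarity_matrix")
}

#' Write a similarity matrix as square CSV
#' @param sim a `similarity_matrix`.
#' @param path output path.
#' @export
write_similarity_csv <- function(sim, path) {
  utils::write.csv(sim$values, path)
  invisible(path)
}

#' Validate a predicted similarity matrix against a reference
#'
#' Pearson correlation over the unordered label pairs defined (non-`NA`)
#' in both matrices; the shared diagonal is excluded.
#'
#' @param pred,ref `similarity_matrix` objects (or plain labelled
#'   symmetric matrices).
#' @return List: `r` (Pearson correlation), `n_pairs`.
#' @export
validate_similarity <- function(pred, ref) {
  vp <- if (inherits(pred, "similarity_matrix")) pred$values else pred
  vr <- if (inherits(ref, "similarity_matrix")) ref$values else ref
  shared <- intersect(rownames(vp), rownames(vr))
  x <- numeric(0); y <- numeric(0)
  if (length(shared) >= 2L) {
    for (i in seq_len(length(shared) - 1L)) for (j in (i + 1L):length(shared)) {
      a <- vp[shared[i], shared[j]]; b <- vr[shared[i], shared[j]]
      if (!is.na(a) && !is.na(b)) { x <- c(x, a); y <- c(y, b) }
    }
  }
  if (length(x) < 3L) stop("need at least 3 shared defined pairs to correlate")
  list(r = stats::cor(x, y, method = "pearson"), n_pairs = length(x))
}
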