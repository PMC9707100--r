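#' Per-omics perturbation score table
#'
#' Holds one cancer x omics vector of non-negative perturbation degrees
#' w_j: |log2 fold change| for transcriptome and methylation, event
#' frequency for somatic mutation and copy-number variation. Scores of
#' genes outside the interactome carry no connectivity information; use
#' [restrict_to_network()] before building cutoff ladders.
#'
#' @param scores named numeric vector (names are gene identifiers) or a
#'   data frame with columns `gene_id` and `score`.
#' @param cancer,omics labels; `omics` is one of `"transcriptome"`,
#'   `"methylation"`, `"somatic_mutation"`, `"cnv"` or `NA`.
#' @return A `perturbation_table` object.
#' @export
perturbation_table <- function(scores, cancer = NA_character_, omics = NA_character_) {
  if (is.data.frame(scores)) {
    stopifnot(all(c("gene_id", "score") %in% names(scores)))
    v <- scores$score
    names(v) <- as.character(scores$gene_id)
    scores <- v
  }
  if (is.null(names(scores)) || any(!nzchar(names(scores))))
    stop("scores must be named by gene identifier")
  if (anyDuplicated(names(scores))) stop("duplicate gene identifiers in score table")
  nm <- names(scores)
  scores <- as.numeric(scores)
  names(scores) <- nm
  if (any(!is.finite(scores)) || any(scores < 0))
    stop("perturbation scores must be finite and non-negative")
  if (!is.na(omics)) {
    omics <- match.arg(omics, c("transcriptome", "methylation", "somatic_mutation", "cnv"))
  }
  structure(list(cancer = cancer, omics = omics, scores = scores),
            class = "perturbation_table")
}

#' @export
print.perturbation_table <- function(x, ...) {
  cat(sprintf("<perturbation_table> %s / %s: %d genes, scores in [%.4g, %.4g]\n",
              x$cancer, x$omics, length(x$scores),
              min(x$scores), max(x$scores)))
  invisible(x)
}

#' Read a perturbation score table from TSV
#'
#' Expects a header with columns `gene_id` and `score`; optional columns
#' `cancer` and `omics` populate the labels (first row wins).
#'
#' @param path file path.
#' @param cancer,omics label overrides.
#' @return A [perturbation_table].
#' @export
read_score_table <- function(path, cancer = NULL, omics = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("gene_id", "score") %in% names(df)))
    stop("score table needs columns gene_id and score: ", path)
  perturbation_table(df,
                     cancer = if (!is.null(cancer)) cancer
                              else if ("cancer" %in% names(df)) df$cancer[1] else NA_character_,
                     omics = if (!is.null(omics)) omics
                             else if ("omics" %in% names(df)) df$omics[1] else NA_character_)
}

#' Write a perturbation table as TSV
#' @param table a [perturbation_table].
#' @param path output path.
#' @export
write_score_table <- function(table, path) {
  stopifnot(inherits(table, "perturbation_table"))
  df <- data.frame(gene_id = names(table$scores), score = unname(table$scores),
                   cancer = table$cancer, omics = table$omics)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict a perturbation table to interactome genes
#'
#' Connectivity statistics are network-restricted, so genes absent from
#' the interactome are removed (count reported).
#'
#' @param table a [perturbation_table].
#' @param g an [interactome].
#' @param quiet suppress the dropped-gene message.
#' @return A [perturbation_table] over genes present in `g`.
#' @export
restrict_to_network <- function(table, g, quiet = FALSE) {
  stopifnot(inherits(table, "perturbation_table"), inherits(g, "interactome"))
  keep <- names(table$scores) %in% interactome_genes(g)
  if (!quiet && any(!keep)) {
    message(sprintf("restrict_to_network: dropped %d gene(s) not in interactome",
                    sum(!keep)))
  }
  if (!any(keep)) stop("no gene of the score table is in the interactome")
  perturbation_table(table$scores[keep], table$cancer, table$omics)
}

#' Keep the top fraction of perturbed genes
#'
#' Retains the `ceiling(fraction * n)` highest-scoring genes. Ties at the
#' retention boundary are broken by lexicographic gene identifier so the
#' result is deterministic.
#'
#' @param table a [perturbation_table].
#' @param fraction real in (0, 1]; default 0.25, the usual pre-filter.
#' @return A [perturbation_table] with the retained genes.
#' @export
top_fraction <- function(table, fraction = 0.25) {
  stopifnot(inherits(table, "perturbation_table"))
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]")
  n <- length(table$scores)
  if (n == 0L) stop("empty perturbation table")
  k <- ceiling(fraction * n)
  ord <- order(-table$scores, names(table$scores))
  keep <- names(table$scores)[ord][seq_len(k)]
  perturbation_table(table$scores[keep], table$cancer, table$omics)
}

#' Equal-bin cutoff ladder over the score range
#'
#' Divides the score range into `t` equal bins; the i-th cutoff is
#' `f_i = min(w) + (max(w) - min(w)) / t * (i + 1)` for `i = 0..t-1`, so
#' the last cutoff equals `max(w)` and (under the strict `>` rule of
#' [threshold_set()]) yields the empty set.
#'
#' @param table a [perturbation_table].
#' @param t bin count, default 50.
#' @return A `cutoff_ladder` object with fields `t`, `fl`, `min_w`, `max_w`.
#' @export
cutoff_ladder <- function(table, t = 50L) {
  stopifnot(inherits(table, "perturbation_table"))
  if (t < 2L) stop("t must be >= 2")
  w <- table$scores
  lo <- min(w); hi <- max(w)
  if (hi <= lo) stop("degenerate score range: max(w) == min(w)")
  fl <- lo + (hi - lo) / t * (seq_len(t))
  fl[t] <- hi  # guard against floating-point undershoot at the endpoint
  structure(list(t = as.integer(t), fl = fl, min_w = lo, max_w = hi),
            class = "cutoff_ladder")
}

#' @export
print.cutoff_ladder <- function(x, ...) {
  cat(sprintf("<cutoff_ladder> t = %d over scores [%.4g, %.4g]\n",
              x$t, x$min_w, x$max_w))
  invisible(x)
}

#' Genes strictly above a perturbation cutoff
#'
#' Set `S_i` of genes with `w_j > cutoff`. The inequality is strict, so
#' the final ladder cutoff returns the empty set; downstream code treats
#' such points as degenerate rather than dropping them.
#'
#' @param table a [perturbation_table].
#' @param cutoff numeric threshold.
#' @return Character vector of gene identifiers (sorted).
#' @export
threshold_set <- function(table, cutoff) {
  stopifnot(inherits(table, "perturbation_table"))
  sort(names(table$scores)[table$scores > cutoff])
}
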