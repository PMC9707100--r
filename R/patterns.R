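#' Amplitude-ratio statistic between two parts of a curve
#'
#' `d_ratio(X, Y) = (max(X) - min(Y)) / (max(ALL) - min(ALL))`, where X
#' and Y are z-score subsets (typically the low/medium/high cutoff parts)
#' and ALL holds every z-score of the curve. Values near 1 mean the rise
#' from Y's trough to X's peak spans almost the whole curve amplitude.
#'
#' @param X,Y non-empty numeric vectors of z-scores.
#' @param ALL numeric vector of all z-scores; must have positive range.
#' @return A real number in `[-1, 1]`.
#' @export
d_ratio <- function(X, Y, ALL) {
  if (length(X) == 0L || length(Y) == 0L) stop("X and Y must be non-empty")
  amp <- max(ALL) - min(ALL)
  if (!is.finite(amp) || amp <= 0) stop("degenerate amplitude: max(ALL) == min(ALL)")
  (max(X) - min(Y)) / amp
}

#' Pattern-classification criteria
#'
#' Parameters of the omics-specific omnigenic pattern rules: the
#' amplitude threshold `alpha`, the fragment-pattern z bound (1.64, the
#' one-sided 5% point of the standard normal), and the L/M/H partition of
#' point indices. With `t` points the low part is the first `floor(t/4)`
#' indices, the high part the last `floor(t/4)`, and the medium part the
#' rest.
#'
#' @param alpha amplitude-ratio threshold in (0, 1); default 0.4.
#' @param z_threshold fragment bound; default 1.64.
#' @param quarter fraction of points per outer part; default 1/4.
#' @return A `pattern_criteria` object.
#' @export
pattern_criteria <- function(alpha = 0.4, z_threshold = 1.64, quarter = 0.25) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  structure(list(alpha = alpha, z_threshold = z_threshold, quarter = quarter),
            class = "pattern_criteria")
}

#' Low / medium / high index partition of a curve
#'
#' @param t number of points.
#' @param criteria a [pattern_criteria].
#' @return List with integer index vectors `L`, `M`, `H`.
#' @export
part_indices <- function(t, criteria = pattern_criteria()) {
  q <- max(1L, floor(t * criteria$quarter))
  if (2L * q >= t) stop("too few points to partition into L/M/H")
  list(L = seq_len(q), M = seq.int(q + 1L, t - q), H = seq.int(t - q + 1L, t))
}

#' Classify a CLine into an omics-specific omnigenic pattern
#'
#' Applies the per-omics wave-mode rule:
#' \describe{
#'   \item{transcriptome (bimodal)}{`d_ratio(L, M) > alpha` and
#'     `d_ratio(H, M) > alpha` -- peaks at both ends, trough in the middle.}
#'   \item{methylation (fragment)}{every z-score `< z_threshold` (1.64):
#'     no cutoff produces significant connectivity.}
#'   \item{somatic_mutation (unimodal)}{`d_ratio(M, L) > alpha` and
#'     `d_ratio(M, H) > alpha` -- a single interior peak.}
#'   \item{cnv (steepest_descent)}{`d_ratio(L, H) > 2 * alpha` -- the curve
#'     falls from a low-cutoff peak to a high-cutoff trough.}
#' }
#' Degenerate points (empty thresholded sets, zero-variance nulls) are
#' excluded from the z-score sets but keep their index positions, so the
#' partition stays aligned with the ladder.
#'
#' @param cline a `cline_result` from [build_cline()].
#' @param omics one of the four omics labels or a pattern name
#'   (`"bimodal"`, `"fragment"`, `"unimodal"`, `"steepest_descent"`).
#' @param criteria a [pattern_criteria].
#' @return A `pattern_verdict`: list with `pattern_tested`, `passed`,
#'   `d_values`, `alpha`, `notes`.
#' @export
classify_pattern <- function(cline, omics = attr(cline, "omics"),
                             criteria = pattern_criteria()) {
  stopifnot(inherits(cline, "cline_result") || is.data.frame(cline))
  pattern <- switch(omics,
                    transcriptome = , bimodal = "bimodal",
                    methylation = , fragment = "fragment",
                    somatic_mutation = , unimodal = "unimodal",
                    cnv = , steepest_descent = "steepest_descent",
                    stop("unknown omics/pattern label: ", omics))
  t <- nrow(cline)
  ok <- !cline$degenerate
  if (sum(ok) < 8L) stop("insufficient data: fewer than 8 non-degenerate points")
  parts <- part_indices(t, criteria)
  zs <- lapply(parts, function(idx) cline$zscore[intersect(idx, which(ok))])
  if (any(vapply(zs, length, 1L) == 0L))
    stop("insufficient data: a cutoff part has no non-degenerate point")
  ALL <- cline$zscore[ok]
  a <- criteria$alpha

  verdict <- switch(pattern,
    bimodal = {
      d <- c(LM = d_ratio(zs$L, zs$M, ALL), HM = d_ratio(zs$H, zs$M, ALL))
      list(passed = all(d > a), d_values = d)
    },
    fragment = {
      list(passed = all(ALL < criteria$z_threshold), d_values = c(max_z = max(ALL)))
    },
    unimodal = {
      d <- c(ML = d_ratio(zs$M, zs$L, ALL), MH = d_ratio(zs$M, zs$H, ALL))
      list(passed = all(d > a), d_values = d)
    },
    steepest_descent = {
      d <- c(LH = d_ratio(zs$L, zs$H, ALL))
      list(passed = d[["LH"]] > 2 * a, d_values = d)
    })

  structure(list(pattern_tested = pattern,
                 passed = verdict$passed,
                 d_values = verdict$d_values,
                 alpha = a,
                 cancer = attr(cline, "cancer"),
                 omics = omics,
                 notes = sprintf("%d/%d non-degenerate points", sum(ok), t)),
            class = "pattern_verdict")
}

#' @export
print.pattern_verdict <- function(x, ...) {
  cat(sprintf("<pattern_verdict> %s: %s (%s)\n", x$pattern_tested,
              if (x$passed) "PASS" else "FAIL",
              paste(sprintf("%s=%.3f", names(x$d_values), x$d_values),
                    collapse = ", ")))
  invisible(x)
}

#' Agreement rate of pattern verdicts across cancers
#'
#' @param verdicts list of `pattern_verdict` objects (one per cancer,
#'   fixed omics) or a logical vector of pass flags.
#' @return Percentage `100 * passed / total`.
#' @export
agreement_rate <- function(verdicts) {
  if (length(verdicts) == 0L) stop("no verdicts supplied")
  passed <- if (is.logical(verdicts)) verdicts
            else vapply(verdicts, function(v) isTRUE(v$passed), TRUE)
  100 * sum(passed) / length(passed)
}
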