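#' Min-max normalize ladder cutoffs to [0, 1]
#'
#' `(f_i - min(fl)) / (max(fl) - min(fl))`; puts every omics aspect of
#' every cancer on one cutoff axis so curves can be pooled.
#'
#' @param ladder a [cutoff_ladder] or a numeric cutoff vector.
#' @return Numeric vector in `[0, 1]`, first element 0, last element 1.
#' @export
normalize_cutoffs <- function(ladder) {
  fl <- if (inherits(ladder, "cutoff_ladder")) ladder$fl else as.numeric(ladder)
  rng <- max(fl) - min(fl)
  if (!is.finite(rng) || rng <= 0) stop("degenerate ladder: zero cutoff range")
  (fl - min(fl)) / rng
}

#' Fit a uniform curve (UCurve) to pooled conforming CLines
#'
#' A single least-squares polynomial over the pooled (normalized cutoff,
#' z-score) points of every conforming CLine of one omics aspect.
#' Degenerate points are excluded before fitting.
#'
#' @param clines list of `cline_result` objects (same omics).
#' @param degree polynomial degree; default 6, the smallest degree that
#'   can carry two interior extrema plus end behaviour, covering all four
#'   archetype shapes.
#' @return A `ucurve` object: `coefficients` (ascending powers),
#'   `degree`, `omics`, `source_cancers`.
#' @export
fit_ucurve <- function(clines, degree = 6L) {
  if (inherits(clines, "cline_result")) clines <- list(clines)
  if (length(clines) == 0L) stop("need at least one conforming CLine")
  omics <- unique(vapply(clines, function(cl) as.character(attr(cl, "omics")), ""))
  if (length(omics) > 1L) stop("all CLines must share one omics aspect")
  xs <- numeric(0); ys <- numeric(0)
  for (cl in clines) {
    u <- normalize_cutoffs(cl$cutoff)
    ok <- !cl$degenerate
    xs <- c(xs, u[ok]); ys <- c(ys, cl$zscore[ok])
  }
  if (degree >= length(xs)) stop("degree must be smaller than the pooled point count")
  X <- stats::poly(xs, degree = degree, raw = TRUE)
  fit <- stats::lm.fit(cbind(1, X), ys)
  structure(list(coefficients = unname(fit$coefficients),
                 degree = as.integer(degree),
                 omics = omics,
                 source_cancers = vapply(clines, function(cl)
                   as.character(attr(cl, "cancer")), "")),
            class = "ucurve")
}

#' Evaluate a UCurve
#' @param object a `ucurve`.
#' @param x positions in `[0, 1]` (extrapolation allowed but meaningless).
#' @param ... ignored.
#' @return Fitted z-score values.
#' @export
predict.ucurve <- function(object, x, ...) {
  drop(outer(x, 0:object$degree, `^`) %*% object$coefficients)
}

#' @export
print.ucurve <- function(x, ...) {
  cat(sprintf("<ucurve> %s: degree %d, fitted from %d CLine(s)\n",
              x$omics, x$degree, length(x$source_cancers)))
  invisible(x)
}

#' Position of the high-part maximum of a UCurve
#'
#' The normalized cutoff in the high part of the domain (last quarter by
#' default) at which the fitted curve is largest; used to read the core
#' cutoff off an aligned curve.
#'
#' @param ucurve a `ucurve`.
#' @param high_from start of the high part on the normalized axis.
#' @param grid_n evaluation grid resolution.
#' @return Normalized position in `[high_from, 1]`.
#' @export
ucurve_high_peak <- function(ucurve, high_from = 0.75, grid_n = 501L) {
  xs <- seq(high_from, 1, length.out = grid_n)
  ys <- predict(ucurve, xs)
  xs[which.max(ys)]
}

#' Ricker (Mexican-hat) continuous wavelet smoothing of a signal
#'
#' Convolves the signal with a Ricker wavelet of width `scale`
#' (reflect-padded at the boundaries), retaining the quarter-scale
#' features the pattern rules look at while suppressing single-point
#' noise.
#'
#' @param y numeric signal.
#' @param scale wavelet scale in sample units; default `length(y) / 10`.
#' @return Smoothed numeric vector, same length as `y`.
#' @export
cwt_smooth <- function(y, scale = length(y) / 10) {
  n <- length(y)
  if (n < 3L) stop("signal too short for wavelet smoothing")
  half <- max(2L, ceiling(4 * scale))
  x <- seq(-half, half)
  psi <- (1 - (x / scale)^2) * exp(-x^2 / (2 * scale^2))
  psi <- psi / sum(psi[psi > 0])  # unit gain on the positive lobe
  # whole-sample symmetric reflection, period 2(n - 1), for any index
  reflect <- function(i) {
    p <- (i - 1) %% (2L * (n - 1L))
    ifelse(p < n, p + 1L, 2L * n - 1L - p)
  }
  pad <- y[reflect((1L - half):(n + half))]
  vapply(seq_len(n), function(i) sum(pad[i:(i + 2L * half)] * psi), 0)
}

#' Z-score standardization of a signal
#' @param y numeric vector.
#' @return `(y - mean(y)) / sd(y)`.
#' @export
standardize_signal <- function(y) {
  s <- stats::sd(y)
  if (!is.finite(s) || s == 0)
    stop("cannot standardize a constant signal; supply a curve with variation")
  (y - mean(y)) / s
}

#' Classical dynamic time warping with end-to-end boundary constraint
#'
#' Minimal-cost monotone alignment of two numeric signals under the
#' squared-difference local cost, unit steps (diagonal, down, right) and
#' boundary anchoring (first maps to first, last to last).
#'
#' @param a,b numeric signals.
#' @return List with `path` (two-column integer matrix of index pairs,
#'   monotone in both columns) and `cost` (summed local cost along the
#'   optimal path).
#' @export
dtw_align <- function(a, b) {
  n <- length(a); m <- length(b)
  if (n == 0L || m == 0L) stop("empty signal")
  local <- outer(a, b, function(x, y) (x - y)^2)
  D <- matrix(Inf, n + 1L, m + 1L)
  D[1, 1] <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      D[i + 1L, j + 1L] <- local[i, j] +
        min(D[i, j], D[i, j + 1L], D[i + 1L, j])
    }
  }
  # backtrack from (n, m)
  path <- matrix(NA_integer_, n + m, 2L)
  i <- n; j <- m; k <- 0L
  while (i >= 1L && j >= 1L) {
    k <- k + 1L
    path[k, ] <- c(i, j)
    if (i == 1L && j == 1L) break
    steps <- c(D[i, j], D[i, j + 1L], D[i + 1L, j])  # diag, up, left
    pick <- which.min(steps)
    if (pick == 1L) { i <- i - 1L; j <- j - 1L }
    else if (pick == 2L) i <- i - 1L
    else j <- j - 1L
  }
  path <- path[seq_len(k), , drop = FALSE][k:1, , drop = FALSE]
  colnames(path) <- c("a", "b")
  list(path = path, cost = D[n + 1L, m + 1L])
}

#' Map a non-conforming CLine onto a UCurve (CWT + DTW)
#'
#' For a CLine whose wave mode fails its omics pattern rule, aligns it
#' end-to-end onto the cross-cancer uniform curve: both signals (the
#' CLine z-vector and the UCurve sampled at the CLine's normalized
#' cutoffs) are wavelet-smoothed ([cwt_smooth()]), standardized to zero
#' mean and unit variance, then warped by classical DTW. The raw warping
#' path is thinned to one correspondence per CLine index (the lowest
#' local-cost partner; ties to the lower UCurve index), giving a key-point
#' map the regions module uses to read the core cutoff off the UCurve.
#'
#' @param cline a `cline_result` with at least 8 points.
#' @param ucurve a `ucurve` of the same omics aspect.
#' @param scale wavelet scale; default `n/10` points.
#' @return A `warp_map`: `pairs` (data frame: `cline_index`,
#'   `ucurve_position` in \[0,1\]), `cost` (total alignment distance),
#'   and the full `path`.
#' @export
cwdtw_map <- function(cline, ucurve, scale = NULL) {
  stopifnot(inherits(ucurve, "ucurve"))
  n <- nrow(cline)
  if (n < 8L) stop("CLine too short to align (need >= 8 points)")
  if (is.null(scale)) scale <- n / 10
  u <- normalize_cutoffs(cline$cutoff)
  sig_c <- standardize_signal(cwt_smooth(cline$zscore, scale))
  sig_u <- standardize_signal(cwt_smooth(predict(ucurve, u), scale))
  al <- dtw_align(sig_c, sig_u)
  # thin: one ucurve partner per cline index, lowest-local-cost match
  pairs <- data.frame(cline_index = integer(n), ucurve_index = integer(n))
  for (i in seq_len(n)) {
    js <- al$path[al$path[, "a"] == i, "b"]
    costs <- (sig_c[i] - sig_u[js])^2
    pairs$cline_index[i] <- i
    pairs$ucurve_index[i] <- js[which.min(costs)]
  }
  pairs$ucurve_position <- u[pairs$ucurve_index]
  structure(list(pairs = pairs, cost = al$cost, path = al$path),
            class = "warp_map")
}

#' @export
print.warp_map <- function(x, ...) {
  cat(sprintf("<warp_map> %d key points, alignment cost %.4g\n",
              nrow(x$pairs), x$cost))
  invisible(x)
}

#' Write a warp map as two-column TSV
#' @param warp a `warp_map`.
#' @param path output path.
#' @export
write_warp_map <- function(warp, path) {
  utils::write.table(warp$pairs[, c("cline_index", "ucurve_position")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write UCurve coefficients as JSON
#' @param ucurve a `ucurve`.
#' @param path output path.
#' @export
write_ucurve <- function(ucurve, path) {
  jsonlite::write_json(unclass(ucurve), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
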