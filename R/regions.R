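#' Extract the core region from a CLine
#'
#' The core is the largest connected component of the thresholded gene
#' set at the high-cutoff local z-score maximum: among the high-part
#' points, candidate cutoffs are local maxima (z at least as large as
#' both neighbours; boundary points compare to their single neighbour);
#' the candidate with the largest z wins, ties going to the highest
#' cutoff. When a `warp` map is supplied (a CLine that failed its pattern
#' rule, aligned to the UCurve), the selection point is instead the CLine
#' point aligned to the UCurve's high-part maximum.
#'
#' The z-score at the chosen cutoff is attached so callers can judge
#' whether the core is significantly connected (for the fragment pattern
#' it typically is not).
#'
#' @param cline a `cline_result`.
#' @param g an [interactome].
#' @param table the [perturbation_table] the CLine was built from.
#' @param criteria a [pattern_criteria] (supplies the H partition).
#' @param warp optional `warp_map` from [cwdtw_map()].
#' @param ucurve the `ucurve` the warp refers to (required with `warp`).
#' @return A list: `core` (gene set), `cutoff`, `zscore`.
#' @export
extract_core <- function(cline, g, table, criteria = pattern_criteria(),
                         warp = NULL, ucurve = NULL) {
  stopifnot(inherits(g, "interactome"), inherits(table, "perturbation_table"))
  t <- nrow(cline)
  parts <- part_indices(t, criteria)

  if (!is.null(warp)) {
    if (is.null(ucurve)) stop("supply the ucurve the warp map refers to")
    peak_pos <- ucurve_high_peak(ucurve, high_from = 1 - criteria$quarter)
    # CLine point whose aligned UCurve position is nearest the peak
    sel <- warp$pairs$cline_index[which.min(abs(warp$pairs$ucurve_position - peak_pos))]
    if (cline$degenerate[sel]) {
      usable <- which(!cline$degenerate)
      if (length(usable) == 0L) stop("all CLine points degenerate")
      sel <- usable[which.min(abs(usable - sel))]
    }
  } else {
    H <- parts$H
    H <- H[!cline$degenerate[H]]
    if (length(H) == 0L) stop("all high-part points are degenerate; no core cutoff")
    z <- cline$zscore
    # local maxima within the high part; the part's boundary points compare
    # to their single within-part neighbour
    is_local_max <- vapply(seq_along(H), function(k) {
      left <- if (k > 1L) z[H[k - 1L]] else -Inf
      right <- if (k < length(H)) z[H[k + 1L]] else -Inf
      z[H[k]] >= left && z[H[k]] >= right
    }, TRUE)
    cand <- H[is_local_max]
    best_z <- max(z[cand])
    sel <- max(cand[z[cand] == best_z])  # ties -> highest cutoff
  }

  cutoff <- cline$cutoff[sel]
  core <- lcc_members(g, threshold_set(table, cutoff))
  list(core = core, cutoff = cutoff, zscore = cline$zscore[sel])
}

#' Extract the cancer neighbourhood (top-k LCC)
#'
#' The largest connected component of the subgraph induced by the `k`
#' highest-scoring genes (ties at rank k broken lexicographically). If
#' the table holds fewer than `k` genes, all are used with a warning.
#'
#' @param g an [interactome].
#' @param table a [perturbation_table].
#' @param k number of top genes, default 1500.
#' @return Character vector: the neighbourhood gene set.
#' @export
extract_neighbourhood <- function(g, table, k = 1500L) {
  stopifnot(inherits(g, "interactome"), inherits(table, "perturbation_table"))
  n <- length(table$scores)
  if (n < 2L) stop("perturbation table needs at least 2 genes")
  if (n < k) {
    warning(sprintf("only %d genes available (< k = %d); using all", n, k))
    k <- n
  }
  ord <- order(-table$scores, names(table$scores))
  top <- names(table$scores)[ord][seq_len(k)]
  lcc_members(g, top)
}

#' Assemble a core/periphery region set
#'
#' The periphery is the neighbourhood minus the core. The core is kept
#' whole even when parts of it lie outside the neighbourhood LCC (the
#' two regions are defined independently); such disjointness is noted.
#'
#' @param core,neighbourhood gene sets.
#' @param cancer,omics labels.
#' @param core_cutoff the cutoff the core was taken at (bookkeeping).
#' @param core_zscore the z-score at that cutoff.
#' @return A `region_set`: `core`, `periphery`, `neighbourhood`
#'   (= core U periphery), labels, `core_cutoff`, `core_zscore`.
#' @export
assemble_regions <- function(core, neighbourhood, cancer = NA_character_,
                             omics = NA_character_, core_cutoff = NA_real_,
                             core_zscore = NA_real_) {
  core <- sort(unique(as.character(core)))
  neighbourhood <- sort(unique(as.character(neighbourhood)))
  outside <- setdiff(core, neighbourhood)
  if (length(outside) == length(core) && length(core) > 0L) {
    message("assemble_regions: core and neighbourhood are disjoint")
  } else if (length(outside) > 0L) {
    message(sprintf("assemble_regions: %d core gene(s) outside the neighbourhood LCC",
                    length(outside)))
  }
  periphery <- setdiff(neighbourhood, core)
  structure(list(cancer = cancer, omics = omics,
                 core = core, periphery = periphery,
                 neighbourhood = sort(union(core, periphery)),
                 core_cutoff = core_cutoff, core_zscore = core_zscore),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("<region_set> %s / %s: core %d, periphery %d (cutoff %.4g, z %.3g)\n",
              x$cancer, x$omics, length(x$core), length(x$periphery),
              x$core_cutoff, x$core_zscore))
  invisible(x)
}

#' Assemble the multi-omics periphery-and-core (MOPC) bundle
#'
#' Unions the four omics-specific region sets of one cancer into the
#' button-like MOPC structure and counts, per gene, the number of omics
#' aspects whose neighbourhood contains it (1-4). Reports the share of
#' union-periphery and union-core genes perturbed in at least two omics
#' aspects.
#'
#' @param regions list of four `region_set` objects, one per omics,
#'   same cancer.
#' @return An `mopc_bundle`: `regions`, `union_core`, `union_periphery`,
#'   `membership` (named integer vector), `multi_omics_share`
#'   (periphery/core shares, in percent).
#' @export
assemble_mopc <- function(regions) {
  stopifnot(length(regions) >= 2L,
            all(vapply(regions, inherits, TRUE, "region_set")))
  omics <- vapply(regions, function(r) as.character(r$omics), "")
  if (anyDuplicated(omics)) stop("duplicate omics label in region sets")
  cancer <- unique(vapply(regions, function(r) as.character(r$cancer), ""))
  if (length(cancer) > 1L) stop("region sets come from different cancers")

  union_core <- sort(unique(unlist(lapply(regions, `[[`, "core"))))
  union_periphery <- sort(unique(unlist(lapply(regions, `[[`, "periphery"))))
  all_genes <- sort(unique(unlist(lapply(regions, `[[`, "neighbourhood"))))
  membership <- vapply(all_genes, function(gn)
    sum(vapply(regions, function(r) gn %in% r$neighbourhood, TRUE)), 0L)

  share <- function(set) {
    if (length(set) == 0L) return(0)
    100 * mean(membership[set] >= 2L)
  }
  structure(list(cancer = cancer, regions = regions,
                 union_core = union_core, union_periphery = union_periphery,
                 membership = membership,
                 multi_omics_share = c(periphery = share(union_periphery),
                                       core = share(union_core))),
            class = "mopc_bundle")
}

#' @export
print.mopc_bundle <- function(x, ...) {
  cat(sprintf(paste0("<mopc_bundle> %s: union core %d, union periphery %d; ",
                     "multi-omics share %.1f%% (periphery), %.1f%% (core)\n"),
              x$cancer, length(x$union_core), length(x$union_periphery),
              x$multi_omics_share[["periphery"]], x$multi_omics_share[["core"]]))
  invisible(x)
}

#' Write gene sets in GMT format
#'
#' One set per line: name, description, then members, tab-separated.
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description description field (recycled).
#' @export
write_gmt <- function(sets, path, description = "mopc") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, description, sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read gene sets from GMT format
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  fgsea::gmtPathways(path)
}
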