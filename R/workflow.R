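#' Run configuration for the MOPC pipeline
#'
#' Bundles the analysis parameters (paper-style defaults: t = 50 cutoff
#' bins, 1000 null replicates, alpha = 0.4, top-25% pre-filter, top-1500
#' neighbourhood) with input paths and a mandatory seed.
#'
#' @param network_path edge-list path (or `NULL` when an interactome
#'   object is passed directly to the runners).
#' @param score_paths named list: `score_paths[[cancer]][[omics]]` = TSV
#'   path.
#' @param t cutoff bin count.
#' @param reps null replicates per CLine point.
#' @param alpha amplitude-ratio threshold.
#' @param top_fraction pre-filter fraction.
#' @param k neighbourhood size.
#' @param degree UCurve polynomial degree.
#' @param strategy null strategy.
#' @param seed integer seed (mandatory).
#' @param out_dir output directory (`NULL` = no files written).
#' @return A `run_config` list.
#' @export
run_config <- function(network_path = NULL, score_paths = list(),
                       t = 50L, reps = 1000L, alpha = 0.4,
                       top_fraction = 0.25, k = 1500L, degree = 6L,
                       strategy = "uniform", seed, out_dir = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  structure(list(network_path = network_path, score_paths = score_paths,
                 t = as.integer(t), reps = as.integer(reps), alpha = alpha,
                 top_fraction = top_fraction, k = as.integer(k),
                 degree = as.integer(degree), strategy = strategy,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

# derive a small per-stage seed, kept well under 2^31
.stage_seed <- function(seed, stage) {
  (as.integer(seed) * 101L + stage) %% 2147480000L
}

#' Run the MOPC pipeline for one cancer
#'
#' Composes the per-cancer stages: network restriction and top-fraction
#' pre-filter, CLine construction per omics aspect, pattern
#' classification, core extraction (falling back to a UCurve alignment
#' when the pattern rule fails and a UCurve is supplied), neighbourhood
#' extraction, region assembly and the multi-omics bundle. Missing omics
#' aspects degrade to a partial bundle with a warning.
#'
#' @param g an [interactome].
#' @param tables named list (omics label -> [perturbation_table]) for
#'   one cancer.
#' @param cfg a [run_config].
#' @param ucurves optional named list (omics -> `ucurve`) used for
#'   failed CLines.
#' @return A list: `cline` (per omics), `verdict` (per omics),
#'   `regions` (per omics), `bundle` (an `mopc_bundle`), `manifest`.
#' @export
run_cancer <- function(g, tables, cfg, ucurves = NULL) {
  stopifnot(inherits(g, "interactome"), is.list(tables), inherits(cfg, "run_config"))
  all_omics <- c("transcriptome", "methylation", "somatic_mutation", "cnv")
  present <- intersect(all_omics, names(tables))
  if (length(present) < length(all_omics))
    warning(sprintf("partial run: missing omics aspect(s) %s",
                    paste(setdiff(all_omics, present), collapse = ", ")))
  criteria <- pattern_criteria(alpha = cfg$alpha)

  clines <- list(); verdicts <- list(); regions <- list()
  for (om in present) {
    tab <- restrict_to_network(tables[[om]], g, quiet = TRUE)
    tab <- top_fraction(tab, cfg$top_fraction)
    ladder <- cutoff_ladder(tab, cfg$t)
    cl <- build_cline(g, tab, ladder, reps = cfg$reps,
                      strategy = cfg$strategy,
                      seed = .stage_seed(cfg$seed, match(om, all_omics)))
    vd <- tryCatch(classify_pattern(cl, omics = om, criteria = criteria),
                   error = function(e) NULL)
    warp <- NULL; uc <- NULL
    if (!is.null(vd) && !vd$passed && !is.null(ucurves) && om %in% names(ucurves)) {
      uc <- ucurves[[om]]
      warp <- cwdtw_map(cl, uc)
    }
    core <- extract_core(cl, g, tab, criteria, warp = warp, ucurve = uc)
    nb <- extract_neighbourhood(g, tab, cfg$k)
    regions[[om]] <- assemble_regions(core$core, nb,
                                      cancer = tab$cancer, omics = om,
                                      core_cutoff = core$cutoff,
                                      core_zscore = core$zscore)
    clines[[om]] <- cl; verdicts[[om]] <- vd
  }
  bundle <- if (length(regions) >= 2L) assemble_mopc(regions) else NULL

  manifest <- list(cancer = regions[[1]]$cancer, omics = present,
                   parameters = cfg[c("t", "reps", "alpha", "top_fraction",
                                      "k", "strategy", "seed")],
                   outputs = list())
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (om in present) {
      p <- file.path(cfg$out_dir, sprintf("cline_%s.tsv", om))
      write_cline(clines[[om]], p)
      manifest$outputs[[paste0("cline_", om)]] <- p
    }
    gmt <- file.path(cfg$out_dir, "regions.gmt")
    sets <- unlist(lapply(present, function(om)
      stats::setNames(list(regions[[om]]$core, regions[[om]]$periphery),
                      paste0(om, c("_core", "_periphery")))), recursive = FALSE)
    write_gmt(sets, gmt)
    manifest$outputs$regions <- gmt
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(cline = clines, verdict = verdicts, regions = regions,
       bundle = bundle, manifest = manifest)
}

#' Run the MOPC pipeline over a cancer cohort
#'
#' Per omics aspect: builds every cancer's CLine, classifies it, fits
#' the UCurve from the conforming ones, aligns the failures onto it, and
#' reports the agreement rate. Then assembles per-cancer bundles and the
#' cross-cancer similarity matrices (simAB on the chosen gene sets plus
#' Jaccard), optionally validated against reference similarity matrices.
#'
#' @param g an [interactome].
#' @param cohort named list: `cohort[[cancer]][[omics]]` =
#'   [perturbation_table].
#' @param cfg a [run_config].
#' @param references optional named list of reference
#'   `similarity_matrix` objects for [validate_similarity()].
#' @param similarity_on `"neighbourhood"` (default) or `"core"`: gene
#'   sets the similarity matrices are computed on.
#' @return A list: `per_cancer` (run_cancer outputs), `ucurves`,
#'   `agreement` (per-omics rates), `similarity` (simAB + jaccard),
#'   `validation` (per reference).
#' @export
run_cohort <- function(g, cohort, cfg, references = NULL,
                       similarity_on = c("neighbourhood", "core")) {
  stopifnot(inherits(g, "interactome"), length(cohort) >= 2L)
  similarity_on <- match.arg(similarity_on)
  all_omics <- c("transcriptome", "methylation", "somatic_mutation", "cnv")
  criteria <- pattern_criteria(alpha = cfg$alpha)

  # first pass: CLines + verdicts per cancer x omics
  prepared <- lapply(names(cohort), function(cn) {
    out <- list()
    for (om in intersect(all_omics, names(cohort[[cn]]))) {
      tab <- restrict_to_network(cohort[[cn]][[om]], g, quiet = TRUE)
      tab <- top_fraction(tab, cfg$top_fraction)
      cl <- build_cline(g, tab, cutoff_ladder(tab, cfg$t), reps = cfg$reps,
                        strategy = cfg$strategy,
                        seed = .stage_seed(cfg$seed + match(cn, names(cohort)),
                                           match(om, all_omics)))
      vd <- tryCatch(classify_pattern(cl, omics = om, criteria = criteria),
                     error = function(e) NULL)
      out[[om]] <- list(table = tab, cline = cl, verdict = vd)
    }
    out
  })
  names(prepared) <- names(cohort)

  # UCurve per omics from conforming CLines; agreement rates
  ucurves <- list(); agreement <- c()
  for (om in all_omics) {
    slots <- Filter(Negate(is.null), lapply(prepared, function(p) p[[om]]))
    if (length(slots) == 0L) next
    passed <- vapply(slots, function(s) !is.null(s$verdict) && s$verdict$passed, TRUE)
    agreement[[om]] <- agreement_rate(passed)
    if (any(passed)) {
      ucurves[[om]] <- fit_ucurve(lapply(slots[passed], `[[`, "cline"),
                                  degree = cfg$degree)
    } else {
      warning(sprintf("no conforming CLine for %s; UCurve skipped, cores fall back to local maxima", om))
    }
  }

  # second pass: regions + bundles (warping failures through the UCurve)
  per_cancer <- lapply(names(cohort), function(cn) {
    regions <- list()
    for (om in names(prepared[[cn]])) {
      s <- prepared[[cn]][[om]]
      warp <- NULL; uc <- NULL
      if ((is.null(s$verdict) || !s$verdict$passed) && om %in% names(ucurves)) {
        uc <- ucurves[[om]]
        warp <- cwdtw_map(s$cline, uc)
      }
      core <- extract_core(s$cline, g, s$table, criteria, warp = warp, ucurve = uc)
      nb <- extract_neighbourhood(g, s$table, cfg$k)
      regions[[om]] <- assemble_regions(core$core, nb, cancer = cn, omics = om,
                                        core_cutoff = core$cutoff,
                                        core_zscore = core$zscore)
    }
    list(cline = lapply(prepared[[cn]], `[[`, "cline"),
         verdict = lapply(prepared[[cn]], `[[`, "verdict"),
         regions = regions,
         bundle = if (length(regions) >= 2L) assemble_mopc(regions) else NULL)
  })
  names(per_cancer) <- names(cohort)

  sim_sets <- lapply(per_cancer, function(p) {
    b <- p$bundle
    if (is.null(b)) return(NULL)
    if (similarity_on == "core") b$union_core
    else sort(union(b$union_core, b$union_periphery))
  })
  sim_sets <- Filter(function(s) !is.null(s) && length(s) > 0, sim_sets)
  similarity <- NULL
  if (length(sim_sets) >= 2L) {
    similarity <- list(simAB = simab_matrix(g, sim_sets),
                       jaccard = jaccard_matrix(sim_sets))
  }
  validation <- NULL
  if (!is.null(references) && !is.null(similarity)) {
    validation <- lapply(references, function(ref)
      validate_similarity(similarity$simAB, ref))
  }
  list(per_cancer = per_cancer, ucurves = ucurves,
       agreement = unlist(agreement), similarity = similarity,
       validation = validation)
}
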