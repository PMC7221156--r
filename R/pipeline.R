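# End-to-end orchestration: features -> CCC/DR screen -> redundancy
# reduction -> feature-stability summary counts, over the four default region
# variants (radiologist raw/z, sphere-habitat raw/z; the two within-lesion
# median-habitat variants are opt-in) and both modalities.

#' Pipeline run configuration
#'
#' @param variants region variants to analyse (default: the four headline
#'   regions; add `HABITAT_MEDIAN_RAW`/`HABITAT_MEDIAN_Z` to include the
#'   within-lesion habitat).
#' @param modalities `"T2W"`, `"ADC"` or both.
#' @param cutoffs joint CCC-and-DR cutoffs for the summary rows.
#' @param rsqCutoffs R^2 redundancy cutoffs (one summary table each).
#' @param habitat a [habitatConfig()].
#' @param Ng grey levels for texture discretisation.
#' @param seed integer seed recorded in the run report.
#' @return list of class `RunConfig`.
#' @export
runConfig <- function(variants = c("RADIOLOGIST_RAW", "RADIOLOGIST_Z",
                                   "HABITAT_SPHERE_RAW", "HABITAT_SPHERE_Z"),
                      modalities = c("T2W", "ADC"),
                      cutoffs = seq(0.65, 0.95, by = 0.05),
                      rsqCutoffs = c(0.99, 0.95),
                      habitat = habitatConfig(),
                      Ng = 32L, seed = 1L) {
  stopifnot(length(variants) >= 1, all(variants %in% REGION_VARIANTS),
            length(modalities) >= 1, all(modalities %in% VOLUME_MODALITIES),
            length(cutoffs) >= 1, all(rsqCutoffs > 0), all(rsqCutoffs <= 1))
  structure(list(variants = variants, modalities = modalities,
                 cutoffs = sort(cutoffs), rsqCutoffs = rsqCutoffs,
                 habitat = habitat, Ng = as.integer(Ng),
                 seed = as.integer(seed)),
            class = "RunConfig")
}

#' Run the full repeatability analysis on a cohort
#'
#' For every region variant and modality: (1) gland-level z-scoring where
#' the variant asks for it (habitat convergence always uses the raw ADC
#' map; the z-score is monotone, so thresholding standardised ADC would
#' select the same voxels), (2) habitat convergence per timepoint from
#' that timepoint's lesion mask, (3) 307-feature extraction per timepoint,
#' (4) the CCC/DR screen, (5) redundancy reduction at each R^2 cutoff
#' applied to the base-cutoff passing set, with summary rows counting the
#' survivors that also pass each higher joint cutoff (this tabulation
#' makes the per-column counts monotone by construction).
#'
#' @param cohort a cohort list ([generatePhantomCohort()] / [loadCohort()]).
#' @param cfg a [runConfig()].
#' @param outputDir optional directory; when given, writes the feature
#'   matrix, repeatability table, selected-feature lists, summary tables
#'   and a JSON run report.
#' @return A list with elements `features` ([FeatureMatrix-class]),
#'   `records` (screen table), `selected` (data.frame of survivors per
#'   variant/modality/rsq cutoff, in selection order), `summary` (named
#'   list of count tables, one per rsq cutoff) and `config`.
#' @export
runPipeline <- function(cohort, cfg = runConfig(), outputDir = NULL) {
  stopifnot(inherits(cfg, "RunConfig"))
  stage <- "feature-extraction"
  result <- tryCatch({
    fm <- extractCohortFeatures(cohort, variants = cfg$variants,
                                modalities = cfg$modalities, Ng = cfg$Ng,
                                habitat = cfg$habitat)
    stage <- "screen"
    records <- screenFeatures(fm, cutoffs = cfg$cutoffs)
    stage <- "redundancy-reduction"
    base_cut <- min(cfg$cutoffs)
    base_col <- sprintf("pass_%.2f", base_cut)
    sel_rows <- list()
    for (variant in cfg$variants) for (mod in cfg$modalities) {
      rec <- records[records$region_variant == variant &
                       records$modality == mod & records[[base_col]], ]
      for (rc in cfg$rsqCutoffs) {
        if (nrow(rec)) {
          avg <- subjectAverages(fm, variant, mod, rec$feature_id)
          sel <- reduceFeatures(rec, avg, redundancyConfig(rc))
        } else sel <- character(0)
        if (length(sel))
          sel_rows[[length(sel_rows) + 1L]] <- data.frame(
            region_variant = variant, modality = mod,
            cutoff_ccc_dr = base_cut, rsq_cutoff = rc,
            rank = seq_along(sel), feature_id = sel,
            ccc = rec$ccc[match(sel, rec$feature_id)],
            dr = rec$dr[match(sel, rec$feature_id)],
            stringsAsFactors = FALSE)
      }
    }
    selected <- if (length(sel_rows)) do.call(rbind, sel_rows) else
      data.frame(region_variant = character(0), modality = character(0),
                 cutoff_ccc_dr = numeric(0), rsq_cutoff = numeric(0),
                 rank = integer(0), feature_id = character(0),
                 ccc = numeric(0), dr = numeric(0))
    stage <- "summary"
    summaries <- lapply(cfg$rsqCutoffs, function(rc)
      summaryCounts(records, selected, cfg, rc))
    names(summaries) <- sprintf("rsq_%.2f", cfg$rsqCutoffs)
    list(features = fm, records = records, selected = selected,
         summary = summaries, config = cfg)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  if (!is.null(outputDir)) writeRunReports(result, outputDir)
  result
}

# Feature-stability summary counts: rows are joint cutoffs (descending), one column per
# variant x modality; a cell counts the redundancy survivors (selected at
# the base cutoff and the given rsq cutoff) whose ccc AND dr reach the row
# cutoff. Columns are monotone non-increasing from the lowest to the
# highest row cutoff by construction.
summaryCounts <- function(records, selected, cfg, rsq_cutoff) {
  cuts <- sort(cfg$cutoffs, decreasing = TRUE)
  cols <- as.vector(outer(cfg$modalities, cfg$variants,
                          function(m, v) paste(v, m, sep = ".")))
  tab <- matrix(0L, length(cuts), length(cols),
                dimnames = list(sprintf(">=%.2f", cuts), cols))
  for (variant in cfg$variants) for (mod in cfg$modalities) {
    sel <- selected[selected$region_variant == variant &
                      selected$modality == mod &
                      selected$rsq_cutoff == rsq_cutoff, ]
    for (r in seq_along(cuts))
      tab[r, paste(variant, mod, sep = ".")] <-
        sum(is.finite(sel$ccc) & is.finite(sel$dr) &
              sel$ccc >= cuts[r] & sel$dr >= cuts[r])
  }
  as.data.frame(tab)
}

# Write CSV/JSON reports for a pipeline result.
writeRunReports <- function(result, outputDir) {
  dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
  writeFeatureMatrix(result$features, file.path(outputDir, "feature_matrix.csv"))
  utils::write.csv(result$records,
                   file.path(outputDir, "repeatability_table.csv"),
                   row.names = FALSE)
  utils::write.csv(result$selected,
                   file.path(outputDir, "selected_features.csv"),
                   row.names = FALSE)
  for (nm in names(result$summary)) {
    tab <- result$summary[[nm]]
    utils::write.csv(cbind(cutoff = rownames(tab), tab),
                     file.path(outputDir, sprintf("summary_%s.csv", nm)),
                     row.names = FALSE)
  }
  cfg <- result$config
  jsonlite::write_json(
    list(variants = cfg$variants, modalities = cfg$modalities,
         cutoffs = cfg$cutoffs, rsq_cutoffs = cfg$rsqCutoffs,
         Ng = cfg$Ng, seed = cfg$seed,
         habitat = unclass(cfg$habitat),
         status = "complete"),
    file.path(outputDir, "run_report.json"),
    auto_unbox = TRUE, pretty = TRUE)
  invisible(outputDir)
}
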