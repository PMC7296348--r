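#' Pipeline run configuration
#'
#' Bundles the stage toggles and parameters of [run_pipeline()]. The
#' configuration is schema-checked before any stage runs.
#'
#' @param norm A [normalization_config()].
#' @param k_values Cluster counts for the clustering stage.
#' @param thresholds Optional [threshold_set()]; if `NULL` and `training`
#'   is given, thresholds are fitted with [fit_thresholds()].
#' @param training Optional training table for [fit_thresholds()].
#' @param atlas_profiles Optional [regional_profiles()] for the mapping
#'   stage.
#' @param atlas_threshold Residual threshold of the selective-gene step.
#' @param genotype_map Optional `line`/`genotype` table for genotype
#'   frequencies.
#' @param min_n Minimum differentiations per line for line statistics.
#' @param stages Character vector of stages to run after normalization:
#'   any of `"variation"`, `"classify"`, `"atlas"`, `"line_stats"`.
#' @param seed Seed recorded in the provenance (the pipeline itself is
#'   deterministic given its inputs).
#' @return List of class `cortex_run_config`.
#' @export
run_config <- function(norm = normalization_config(),
                       k_values = 2:5,
                       thresholds = NULL, training = NULL,
                       atlas_profiles = NULL, atlas_threshold = 2,
                       genotype_map = NULL, min_n = 2,
                       stages = c("variation", "classify", "atlas", "line_stats"),
                       seed = NULL) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (!inherits(norm, "cortex_norm_config")) abort("norm must be a normalization_config()")
  if (!is.null(thresholds) && !inherits(thresholds, "cortex_thresholds")) {
    abort("thresholds must be a threshold_set()")
  }
  if ("classify" %in% stages && is.null(thresholds) && is.null(training)) {
    abort("classify stage needs thresholds or a training table")
  }
  if ("atlas" %in% stages && is.null(atlas_profiles)) {
    abort("atlas stage needs atlas_profiles")
  }
  structure(list(norm = norm, k_values = k_values, thresholds = thresholds,
                 training = training, atlas_profiles = atlas_profiles,
                 atlas_threshold = atlas_threshold,
                 genotype_map = genotype_map, min_n = min_n,
                 stages = stages, seed = seed),
            class = "cortex_run_config")
}

#' Run the analysis pipeline end to end
#'
#' Executes normalization, expression filtering, log2 transform and the
#' toggled analysis stages (variation analysis, regional classification,
#' atlas mapping, line statistics) over one dataset. Stage outputs are pure
#' functions of the inputs and configuration; rerunning with the same
#' inputs gives an identical bundle.
#'
#' @param counts Count tibble (`sample_id` + probe columns).
#' @param codeset The [codeset_definition()] for `counts`.
#' @param meta Sample metadata.
#' @param config A [run_config()].
#' @return List of class `cortex_pipeline` with elements `expr` (log2
#'   expression), `qc`, and one element per executed stage (`pca`,
#'   `clusters`, `thresholds`, `labels`, `selective`, `mapping`,
#'   `line_table`, `genotype_table`), plus `provenance`.
#' @export
run_pipeline <- function(counts, codeset, meta, config = run_config()) {
  stage <- "normalize"
  bundle <- list()
  tryCatch({
    norm <- normalize_dataset(counts, codeset, config$norm)
    bundle$qc <- expr_qc(norm)
    stage <- "filter"
    filt <- filter_expressed(norm, config$norm$expression_floor)
    stage <- "log2"
    expr <- log2_transform(filt, config$norm$log_floor)
    bundle$expr <- expr

    if ("variation" %in% config$stages) {
      stage <- "variation"
      bundle$pca <- run_pca(expr)
      bundle$clusters <- hier_cluster(expr, k_values = config$k_values)
      bundle$contributors <- top_contributors(bundle$pca, 1)
    }
    if ("classify" %in% config$stages) {
      stage <- "classify"
      th <- config$thresholds %||% fit_thresholds(expr, config$training)
      bundle$thresholds <- th
      bundle$labels <- classify_regional(expr, th)
    }
    if ("atlas" %in% config$stages) {
      stage <- "atlas"
      sel <- select_region_specific_genes(config$atlas_profiles,
                                          config$atlas_threshold)
      bundle$selective <- sel
      bundle$mapping <- mapping_scores(expr, config$atlas_profiles, sel)
    }
    if ("line_stats" %in% config$stages && !is.null(bundle$labels)) {
      stage <- "line_stats"
      bundle$line_table <- line_frequencies(bundle$labels, meta,
                                            min_n = config$min_n)
      if (!is.null(config$genotype_map)) {
        bundle$genotype_table <- genotype_frequencies(bundle$line_table,
                                                      config$genotype_map)
      }
    }
  }, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
  })
  bundle$provenance <- list(
    package = "cortexfate",
    version = as.character(utils::packageVersion("cortexfate")),
    stages = config$stages,
    seed = config$seed,
    n_samples = nrow(counts),
    n_probes = ncol(counts) - 1L
  )
  structure(bundle, class = "cortex_pipeline")
}

#' @export
print.cortex_pipeline <- function(x, ...) {
  cat(sprintf("<pipeline bundle: %s>\n",
              paste(setdiff(names(x), "provenance"), collapse = ", ")))
  invisible(x)
}
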