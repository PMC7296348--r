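#' Read a consolidated probe-count table
#'
#' Counts are stored as a flat TSV with one row per sample: the first column
#' is `sample_id` and the remaining columns are probe names. Probe names are
#' resolved against the codeset, which attaches probe classes.
#'
#' @param path Path to a tab-delimited count table.
#' @param codeset A [codeset_definition()].
#' @return A tibble (`sample_id` + one integer column per probe) with
#'   attributes `codeset_id` and `probe_class`.
#' @export
read_count_table <- function(path, codeset) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (names(raw)[1] != "sample_id") {
    abort("first column of a count table must be 'sample_id'")
  }
  if (anyDuplicated(raw$sample_id)) {
    abort("duplicate sample_id in count table")
  }
  probes <- setdiff(names(raw), "sample_id")
  unknown <- setdiff(probes, codeset$probe_id)
  if (length(unknown) > 0) {
    abort(paste0("probes not in codeset '", codeset_id(codeset), "': ",
                 paste(unknown, collapse = ", ")))
  }
  missing <- setdiff(codeset$probe_id, probes)
  if (length(missing) > 0) {
    warn(paste0("codeset probes absent from count table: ",
                paste(missing, collapse = ", ")))
  }
  counts <- raw["sample_id"]
  for (p in probes) {
    v <- suppressWarnings(as.numeric(raw[[p]]))
    bad <- which(is.na(v) & !is.na(raw[[p]]))
    if (length(bad) > 0) {
      abort(sprintf("malformed count '%s' at row %d, column '%s'",
                    raw[[p]][bad[1]], bad[1], p))
    }
    if (any(v < 0, na.rm = TRUE)) {
      abort(sprintf("negative count at row %d, column '%s'",
                    which(v < 0)[1], p))
    }
    if (any(abs(v - round(v)) > 1e-8, na.rm = TRUE)) {
      abort(sprintf("non-integer count at row %d, column '%s'",
                    which(abs(v - round(v)) > 1e-8)[1], p))
    }
    counts[[p]] <- as.integer(round(v))
  }
  structure(counts,
            codeset_id = codeset_id(codeset),
            probe_class = probe_classes(codeset)[probes])
}

#' Write a probe-count table
#'
#' @param counts Tibble as returned by [read_count_table()] or
#'   [simulate_dataset()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path) {
  readr::write_tsv(tibble::as_tibble(counts), path, progress = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' @param path TSV with columns `sample_id`, `uin`, `line` and optionally
#'   `individual`, `genotype`, `stage`, `dpi`, `treatment`, `operator`.
#' @return A tibble, one row per sample.
#' @export
read_sample_metadata <- function(path) {
  meta <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("sample_id", "uin", "line")
  if (!all(required %in% names(meta))) {
    abort(paste0("metadata must have columns: ", paste(required, collapse = ", ")))
  }
  if (anyDuplicated(meta$sample_id)) abort("duplicate sample_id in metadata")
  if ("dpi" %in% names(meta) && any(meta$dpi < 0, na.rm = TRUE)) {
    abort("dpi must be >= 0")
  }
  meta
}

#' Write sample metadata
#' @param meta Metadata tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(meta, path) {
  readr::write_tsv(meta, path, progress = FALSE)
  invisible(path)
}

#' Read a codeset definition table
#'
#' @param path TSV with columns `probe_id`, `gene_symbol`, `probe_class` and
#'   optionally `pos_rank`.
#' @param codeset_id Codeset name; defaults to the file name without
#'   extension.
#' @param ... Passed to [codeset_definition()] (e.g. expected control-probe
#'   counts).
#' @return A [codeset_definition()].
#' @export
read_codeset <- function(path, codeset_id = NULL, ...) {
  probes <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  codeset_definition(probes,
                     codeset_id %||% sub("\\.[^.]+$", "", basename(path)),
                     ...)
}

#' @rdname read_codeset
#' @param codeset Codeset to write.
#' @export
write_codeset <- function(codeset, path) {
  readr::write_tsv(tibble::as_tibble(codeset), path, progress = FALSE)
  invisible(path)
}

#' Construct a regional expression-energy profile set
#'
#' Holds in-situ expression energies of panel genes across brain regions of a
#' reference atlas age (e.g. E11.5), one row per region.
#'
#' @param energy Data frame with a `region` column plus one non-negative
#'   numeric column per gene.
#' @param age_label Atlas age the energies describe (e.g. `"E11.5"`).
#' @return A tibble with class `cortex_profiles` and attribute `age_label`.
#' @export
regional_profiles <- function(energy, age_label = "E11.5") {
  energy <- tibble::as_tibble(energy)
  if (names(energy)[1] != "region") abort("first column must be 'region'")
  if (anyDuplicated(energy$region)) abort("duplicate region in profiles")
  vals <- as_sample_matrix(energy, id_col = "region")
  if (any(!is.finite(vals))) abort("non-finite expression energy")
  if (any(vals < 0)) abort("negative expression energy")
  structure(energy, age_label = age_label,
            class = c("cortex_profiles", class(energy)))
}

#' Read an atlas expression-energy table
#'
#' The file contract replaces a live atlas API client: one CSV per atlas
#' age, gene rows and region columns, holding non-negative expression
#' energies. Duplicated gene rows with identical values are silently
#' deduplicated; conflicting duplicates are an error.
#'
#' @param path CSV path; first column `gene`, remaining columns regions.
#' @param age_label Atlas age label stored on the result.
#' @return A [regional_profiles()] object (regions x genes).
#' @export
read_atlas_energy <- function(path, age_label = "E11.5") {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (names(raw)[1] != "gene") abort("first column of an atlas table must be 'gene'")
  regions <- setdiff(names(raw), "gene")
  if (length(regions) == 0) abort("atlas table has no region columns")
  for (r in regions) {
    if (all(is.na(raw[[r]]))) abort(sprintf("region column '%s' is empty", r))
    if (any(is.na(raw[[r]]))) abort(sprintf("missing energy in region '%s'", r))
    if (any(raw[[r]] < 0)) abort(sprintf("negative energy in region '%s'", r))
  }
  if (anyDuplicated(raw$gene)) {
    dedup <- dplyr::distinct(raw)
    if (anyDuplicated(dedup$gene)) {
      bad <- dedup$gene[duplicated(dedup$gene)][1]
      abort(sprintf("conflicting duplicate energies for gene '%s'", bad))
    }
    raw <- dedup
  }
  energy <- as_sample_matrix(raw, id_col = "gene")  # genes x regions
  regional_profiles(as_sample_tbl(t(energy), id_col = "region"), age_label)
}

#' @rdname read_atlas_energy
#' @param profiles Profile set to write (stored gene-major, as downloaded).
#' @export
write_atlas_energy <- function(profiles, path) {
  energy <- as_sample_matrix(tibble::as_tibble(profiles), id_col = "region")
  readr::write_csv(as_sample_tbl(t(energy), id_col = "gene"), path,
                   progress = FALSE)
  invisible(path)
}

#' Read / write a normalized expression table
#'
#' @param path TSV path; first column `sample_id`, remaining columns genes.
#' @param scale Scale of the stored values (`"linear"` or `"log2"`).
#' @return An expression tibble with attribute `scale`.
#' @export
read_expression_table <- function(path, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  expr <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (names(expr)[1] != "sample_id") abort("first column must be 'sample_id'")
  new_expr(expr, scale = scale)
}

#' @rdname read_expression_table
#' @param expr Expression tibble.
#' @export
write_expression_table <- function(expr, path) {
  readr::write_tsv(tibble::as_tibble(expr), path, progress = FALSE)
  invisible(path)
}
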