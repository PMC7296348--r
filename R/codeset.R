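#' Housekeeping genes used for panel normalization
#'
#' The seven housekeeping genes whose geometric mean drives the housekeeping
#' normalization factor in [normalize_dataset()].
#'
#' @format Character vector of gene symbols.
#' @export
ncounter_housekeeping_genes <- c(
  "CLTC", "GAPDH", "GUSB", "PPIA", "RPLP1", "RPS15A", "RPS9"
)

#' Construct a codeset definition
#'
#' A codeset describes the probes of a targeted expression panel: endogenous
#' probes, negative and positive control probes, and housekeeping probes.
#' Probe ids map 1:1 to gene symbols for endogenous and housekeeping probes;
#' positive probes carry an expected-concentration rank (A highest).
#'
#' @param probes Data frame with columns `probe_id`, `gene_symbol`,
#'   `probe_class` (one of `"endogenous"`, `"negative"`, `"positive"`,
#'   `"housekeeping"`) and optionally `pos_rank` (`"A"`-`"F"`) for positive
#'   probes.
#' @param codeset_id Single string naming the codeset.
#' @param n_negative,n_positive If non-`NULL`, the number of negative /
#'   positive control probes the codeset must contain (the panels this
#'   package models carry 8 and 6).
#' @param housekeeping If non-`NULL`, the exact housekeeping gene set the
#'   codeset must contain; defaults to [ncounter_housekeeping_genes].
#'
#' @return A tibble of probes with class `cortex_codeset` and attribute
#'   `codeset_id`.
#' @export
codeset_definition <- function(probes, codeset_id,
                               n_negative = NULL, n_positive = NULL,
                               housekeeping = NULL) {
  probes <- tibble::as_tibble(probes)
  required <- c("probe_id", "gene_symbol", "probe_class")
  if (!all(required %in% names(probes))) {
    abort(paste0("codeset must have columns: ", paste(required, collapse = ", ")))
  }
  classes <- c("endogenous", "negative", "positive", "housekeeping")
  if (!all(probes$probe_class %in% classes)) {
    abort("probe_class must be one of endogenous/negative/positive/housekeeping")
  }
  if (anyDuplicated(probes$probe_id)) {
    abort("duplicate probe_id in codeset")
  }
  if (!"pos_rank" %in% names(probes)) probes$pos_rank <- NA_character_
  n_neg <- sum(probes$probe_class == "negative")
  n_pos <- sum(probes$probe_class == "positive")
  if (!is.null(n_negative) && n_neg != n_negative) {
    abort(sprintf("codeset '%s' has %d negative probes, expected %d",
                  codeset_id, n_neg, n_negative))
  }
  if (!is.null(n_positive) && n_pos != n_positive) {
    abort(sprintf("codeset '%s' has %d positive probes, expected %d",
                  codeset_id, n_pos, n_positive))
  }
  if (!is.null(housekeeping)) {
    hk <- sort(probes$gene_symbol[probes$probe_class == "housekeeping"])
    if (!identical(hk, sort(housekeeping))) {
      abort(sprintf("codeset '%s' housekeeping set does not match the expected genes",
                    codeset_id))
    }
  }
  structure(probes,
            codeset_id = as.character(codeset_id),
            class = c("cortex_codeset", class(probes)))
}

#' @export
print.cortex_codeset <- function(x, ...) {
  cat(sprintf("<codeset '%s': %d probes (%d endogenous, %d negative, %d positive, %d housekeeping)>\n",
              attr(x, "codeset_id"), nrow(x),
              sum(x$probe_class == "endogenous"),
              sum(x$probe_class == "negative"),
              sum(x$probe_class == "positive"),
              sum(x$probe_class == "housekeeping")))
  NextMethod()
}

codeset_id <- function(codeset) attr(codeset, "codeset_id")

probe_classes <- function(codeset) {
  setNames(codeset$probe_class, codeset$probe_id)
}
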