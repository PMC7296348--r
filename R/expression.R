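#' Expression tibbles
#'
#' Normalized expression is carried as a wide tibble: a `sample_id` column
#' plus one numeric column per gene, with a `scale` attribute recording
#' whether values are linear normalized counts or log2-transformed, and an
#' optional `qc` attribute holding per-sample normalization factors.
#'
#' @param x Data frame with `sample_id` first column.
#' @param scale `"linear"` or `"log2"`.
#' @param qc Optional per-sample QC tibble (see [normalize_dataset()]).
#' @return A tibble of class `cortex_expr`.
#' @export
new_expr <- function(x, scale = c("linear", "log2"), qc = NULL) {
  scale <- match.arg(scale)
  x <- tibble::as_tibble(x)
  if (names(x)[1] != "sample_id") abort("first column must be 'sample_id'")
  if (anyDuplicated(x$sample_id)) abort("duplicate sample_id")
  structure(x, scale = scale, qc = qc,
            class = unique(c("cortex_expr", class(x))))
}

#' @rdname new_expr
#' @param expr An expression tibble.
#' @export
expr_scale <- function(expr) {
  attr(expr, "scale") %||% "linear"
}

#' @rdname new_expr
#' @export
expr_qc <- function(expr) {
  attr(expr, "qc")
}

#' @rdname new_expr
#' @export
expr_genes <- function(expr) {
  setdiff(names(expr), "sample_id")
}

#' @export
print.cortex_expr <- function(x, ...) {
  cat(sprintf("<expression: %d samples x %d genes, %s scale>\n",
              nrow(x), ncol(x) - 1L, expr_scale(x)))
  NextMethod()
}
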