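#' @importFrom rlang %||% abort warn inform
#' @importFrom stats cor cutree dist hclust prcomp qgamma qnbinom qnorm rnorm
#'   sd setNames aov lm p.adjust pt qnorm rstandard t.test var complete.cases
NULL

# Convert a wide sample-by-gene tibble (first column sample_id) to a numeric
# matrix with sample_id rownames.
as_sample_matrix <- function(x, id_col = "sample_id") {
  stopifnot(is.data.frame(x), id_col %in% names(x))
  ids <- as.character(x[[id_col]])
  m <- as.matrix(x[setdiff(names(x), id_col)])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

# Inverse of as_sample_matrix().
as_sample_tbl <- function(m, id_col = "sample_id") {
  out <- tibble::as_tibble(m)
  out <- tibble::add_column(out, !!id_col := rownames(m), .before = 1)
  out
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

softmax <- function(eta) {
  e <- exp(eta - max(eta))
  e / sum(e)
}
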