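#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a PCA result
#'
#' @param x A `cortex_pca` object.
#' @param matrix Which table to return: `"scores"`, `"loadings"` (with
#'   Z-scored loadings attached), or `"variance"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.cortex_pca <- function(x, matrix = c("scores", "loadings", "variance"), ...) {
  matrix <- match.arg(matrix)
  switch(matrix,
    scores = tidyr::pivot_longer(x$scores, -"sample_id",
                                 names_to = "component", values_to = "score"),
    loadings = dplyr::inner_join(
      tidyr::pivot_longer(x$loadings, -"gene",
                          names_to = "component", values_to = "loading"),
      tidyr::pivot_longer(x$loading_z, -"gene",
                          names_to = "component", values_to = "z"),
      by = c("gene", "component")),
    variance = tibble::tibble(
      component = paste0("PC", seq_along(x$variance_explained)),
      variance_explained = x$variance_explained)
  )
}

#' @rdname tidy.cortex_pca
#' @export
glance.cortex_pca <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$scores),
    n_genes = nrow(x$loadings),
    pc1_variance = x$variance_explained[1],
    pc2_variance = x$variance_explained[2]
  )
}

#' Tidy a clustering result
#'
#' @param x A `cortex_clusters` object.
#' @param ... Unused.
#' @return Long tibble `sample_id`, `k`, `cluster`.
#' @export
tidy.cortex_clusters <- function(x, ...) {
  out <- tidyr::pivot_longer(x$labels, -"sample_id",
                             names_to = "k", values_to = "cluster")
  out$k <- as.integer(sub("^k", "", out$k))
  out
}

#' Tidy a threshold set
#'
#' @param x A `cortex_thresholds` object.
#' @param ... Unused.
#' @return Tibble `cutoff`, `value`.
#' @export
tidy.cortex_thresholds <- function(x, ...) {
  nm <- c("foxg1_low", "dlx5_low", "foxg1_verylow", "dlx5_verylow",
          "nkx21_high", "pax6_low")
  tibble::tibble(cutoff = nm, value = unlist(x[nm], use.names = FALSE))
}

#' @rdname tidy.cortex_thresholds
#' @export
glance.cortex_thresholds <- function(x, ...) {
  tibble::tibble(provenance = x$provenance,
                 agreement = attr(x, "agreement") %||% NA_real_,
                 n_misclassified = length(attr(x, "misclassified") %||% character(0)))
}
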