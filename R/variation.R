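#' Principal-component analysis of panel expression
#'
#' PCA on log2 expression, gene-centered with no unit-variance scaling (log2
#' already stabilizes variance). Loading signs follow a deterministic
#' convention: each component's largest-magnitude loading is positive.
#'
#' @param expr Log2-scale expression tibble.
#' @return An object of class `cortex_pca`: list with `scores` (samples x
#'   components tibble), `loadings` and `loading_z` (genes x components
#'   tibbles; `loading_z` holds per-component Z-scored loadings),
#'   `variance_explained`, and `center`.
#' @export
run_pca <- function(expr) {
  if (expr_scale(expr) != "log2") abort("run_pca expects log2-scale expression")
  m <- as_sample_matrix(tibble::as_tibble(expr))
  if (nrow(m) < 3 || ncol(m) < 2) abort("need at least 3 samples and 2 genes")
  if (all(apply(m, 2, sd) == 0)) abort("constant expression matrix: no variance")
  fit <- prcomp(m, center = TRUE, scale. = FALSE)
  rot <- fit$rotation
  scores <- fit$x
  for (j in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  zed <- apply(rot, 2, function(l) {
    s <- sd(l)
    if (s == 0) rep(0, length(l)) else (l - mean(l)) / s
  })
  rownames(zed) <- rownames(rot)
  structure(list(
    scores = as_sample_tbl(scores),
    loadings = as_sample_tbl(rot, id_col = "gene"),
    loading_z = as_sample_tbl(zed, id_col = "gene"),
    variance_explained = fit$sdev^2 / sum(fit$sdev^2),
    center = fit$center
  ), class = "cortex_pca")
}

#' @export
print.cortex_pca <- function(x, ...) {
  ve <- round(100 * x$variance_explained[1:min(3, length(x$variance_explained))], 1)
  cat(sprintf("<PCA: %d samples x %d genes; variance explained %s%%...>\n",
              nrow(x$scores), nrow(x$loadings), paste(ve, collapse = "/")))
  invisible(x)
}

#' Highest-contributing genes of a principal component
#'
#' Genes whose Z-scored loading on the component exceeds `z_threshold` in
#' absolute value, the rule used to label contributors on loading plots.
#'
#' @param pca A [run_pca()] result.
#' @param component Component index.
#' @param z_threshold Absolute Z cutoff (default 2).
#' @return Tibble `gene`, `loading`, `z`, ordered by decreasing `|z|`.
#' @export
top_contributors <- function(pca, component = 1, z_threshold = 2) {
  pc <- paste0("PC", component)
  if (!pc %in% names(pca$loading_z)) abort(sprintf("no component %d", component))
  out <- tibble::tibble(
    gene = pca$loading_z$gene,
    loading = pca$loadings[[pc]],
    z = pca$loading_z[[pc]]
  )
  dplyr::arrange(dplyr::filter(out, abs(.data$z) > z_threshold), dplyr::desc(abs(.data$z)))
}

#' Hierarchical clustering of samples by expression correlation
#'
#' Samples are clustered on the Pearson correlation distance `1 - r`
#' computed over genes, with agglomerative linkage (complete by default).
#' Cluster labels at each requested `k` are numbered by decreasing cluster
#' size, ties broken by the position of the cluster's first sample.
#'
#' @param expr Log2-scale expression tibble.
#' @param k_values Cluster counts at which to cut the tree.
#' @param method Linkage method passed to [stats::hclust()].
#' @return Object of class `cortex_clusters`: list with `labels` (tibble
#'   `sample_id` + one `k<k>` column per cut), `tree` (an `hclust`),
#'   `k_values`, `method`.
#' @export
hier_cluster <- function(expr, k_values = 2:5, method = "complete") {
  m <- as_sample_matrix(tibble::as_tibble(expr))
  if (nrow(m) < max(k_values)) abort("fewer samples than max(k_values)")
  sds <- apply(m, 1, sd)
  if (any(sds == 0)) {
    abort(paste0("zero-variance sample(s): ",
                 paste(rownames(m)[sds == 0], collapse = ", ")))
  }
  d <- stats::as.dist(1 - cor(t(m)))
  tree <- hclust(d, method = method)
  labels <- tibble::tibble(sample_id = rownames(m))
  for (k in k_values) {
    raw <- cutree(tree, k = k)
    labels[[paste0("k", k)]] <- relabel_by_size(raw)
  }
  structure(list(labels = labels, tree = tree, k_values = k_values,
                 method = method),
            class = "cortex_clusters")
}

# Renumber cluster labels: largest cluster first; ties broken by the
# position of each cluster's first member.
relabel_by_size <- function(raw) {
  tab <- table(raw)
  first <- vapply(names(tab), function(g) min(which(raw == as.integer(g))),
                  integer(1))
  ord <- order(-as.integer(tab), first)
  map <- setNames(seq_along(ord), names(tab)[ord])
  unname(map[as.character(raw)])
}

#' @export
print.cortex_clusters <- function(x, ...) {
  cat(sprintf("<clustering: %d samples, 1 - Pearson distance, %s linkage, k = %s>\n",
              nrow(x$labels), x$method, paste(x$k_values, collapse = ",")))
  invisible(x)
}

#' Correlate late-stage marker expression with early-stage expression
#'
#' For paired early/late profiles of the same differentiations, computes the
#' Pearson correlation across pairs between each late-stage marker and every
#' early-stage gene. Optionally restricts the table to early genes strongly
#' correlated (|r| above `r_threshold`) with at least one marker.
#'
#' @param early,late Expression tibbles (typically log2).
#' @param pairs Data frame with columns `early` and `late`: paired sample
#'   ids (at least 3 pairs).
#' @param late_markers Marker genes to take from the late matrix.
#' @param r_threshold If non-`NULL`, keep early genes with `|r| >
#'   r_threshold` for at least one marker (0.75 in the headline analysis).
#' @return Tibble `early_gene`, `marker`, `r`.
#' @export
correlate_early_late <- function(early, late, pairs, late_markers,
                                 r_threshold = NULL) {
  pairs <- tibble::as_tibble(pairs)
  if (!all(c("early", "late") %in% names(pairs))) {
    abort("pairs must have columns 'early' and 'late'")
  }
  if (nrow(pairs) < 3) abort("need at least 3 early/late pairs")
  me <- as_sample_matrix(tibble::as_tibble(early))
  ml <- as_sample_matrix(tibble::as_tibble(late))
  if (!all(pairs$early %in% rownames(me))) abort("pair sample missing from early")
  if (!all(pairs$late %in% rownames(ml))) abort("pair sample missing from late")
  if (!all(late_markers %in% colnames(ml))) {
    abort(paste0("markers missing from late matrix: ",
                 paste(setdiff(late_markers, colnames(ml)), collapse = ", ")))
  }
  me <- me[pairs$early, , drop = FALSE]
  ml <- ml[pairs$late, late_markers, drop = FALSE]
  r <- suppressWarnings(cor(me, ml))  # early genes x markers
  out <- tidyr::pivot_longer(as_sample_tbl(r, id_col = "early_gene"),
                             -"early_gene",
                             names_to = "marker", values_to = "r")
  if (!is.null(r_threshold)) {
    keep <- dplyr::summarise(dplyr::group_by(out, .data$early_gene),
                             hit = any(abs(.data$r) > r_threshold, na.rm = TRUE))
    out <- dplyr::filter(out, .data$early_gene %in% keep$early_gene[keep$hit])
  }
  out
}

#' Correlation of cross-time and within-early gene-gene correlations
#'
#' Measures persistence of co-expression modules: over all ordered gene
#' pairs (g, h), the Pearson correlation between late-g/early-h
#' correlations across differentiation pairs and the corresponding g/h
#' correlations within the early-stage samples.
#'
#' @inheritParams correlate_early_late
#' @return List with `r` (scalar), and `table`: tibble `gene_late`,
#'   `gene_early`, `r_cross`, `r_early` over ordered gene pairs (g != h).
#' @export
correlation_of_correlations <- function(early, late, pairs) {
  pairs <- tibble::as_tibble(pairs)
  me <- as_sample_matrix(tibble::as_tibble(early))
  ml <- as_sample_matrix(tibble::as_tibble(late))
  shared <- intersect(colnames(me), colnames(ml))
  if (length(shared) < 10) abort("need at least 10 shared genes")
  me <- me[pairs$early, shared, drop = FALSE]
  ml <- ml[pairs$late, shared, drop = FALSE]
  if (any(apply(me, 2, sd) == 0) || any(apply(ml, 2, sd) == 0)) {
    abort("degenerate (zero-variance) gene in paired data")
  }
  cross <- cor(ml, me)    # late gene g x early gene h
  within <- cor(me)       # early g x early h
  off <- which(row(cross) != col(cross))
  tab <- tibble::tibble(
    gene_late = shared[row(cross)[off]],
    gene_early = shared[col(cross)[off]],
    r_cross = cross[off],
    r_early = within[off]
  )
  list(r = cor(tab$r_cross, tab$r_early), table = tab)
}
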