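#' Identify region-selective genes from atlas expression energies
#'
#' Most panel genes are correlated across brain regions; region-selective
#' genes are the ones that stand out of that shared profile. Energies are
#' log-transformed (`log2(energy + 1)`); for each ordered region pair (A, B)
#' the region-A values are regressed on the region-B values across genes by
#' ordinary least squares, and a gene is selective for A if its internally
#' standardized residual exceeds `threshold` in the A-vs-B regression
#' against every other retained region B. Regions left with no selective
#' gene are removed (all at once) and the procedure repeated on the
#' remaining regions until every retained region has at least one.
#'
#' @param profiles A [regional_profiles()] set (regions x genes).
#' @param threshold Standardized-residual cutoff (default 2).
#' @return Object of class `cortex_selective`: tibble `gene`, `region`,
#'   `min_residual` (the gene's smallest pairwise standardized residual),
#'   with attributes `pruned_regions`, `regions` (retained), `threshold`.
#' @export
select_region_specific_genes <- function(profiles, threshold = 2) {
  energy <- as_sample_matrix(tibble::as_tibble(profiles), id_col = "region")
  if (nrow(energy) < 2) abort("need at least 2 regions")
  if (ncol(energy) < 5) abort("need at least 5 genes")
  E <- log2(energy + 1)
  regions <- rownames(E)
  pruned <- character(0)

  repeat {
    if (length(regions) < 2) {
      abort("fewer than 2 regions remain after pruning")
    }
    sel <- selective_pass(E[regions, , drop = FALSE], threshold)
    empty <- setdiff(regions, unique(sel$region))
    if (length(empty) == 0) break
    pruned <- c(pruned, empty)
    regions <- setdiff(regions, empty)
  }

  structure(sel,
            pruned_regions = pruned, regions = regions,
            threshold = threshold,
            class = c("cortex_selective", class(sel)))
}

# One round of pairwise-regression selectivity over a log energy matrix.
selective_pass <- function(E, threshold) {
  regions <- rownames(E)
  genes <- colnames(E)
  # resid[[A]][[B]] = standardized residuals of A ~ B across genes
  std_resid <- function(y, x) {
    fit <- lm(y ~ x)
    rstandard(fit)
  }
  out <- list()
  for (A in regions) {
    others <- setdiff(regions, A)
    res <- vapply(others, function(B) std_resid(E[A, ], E[B, ]),
                  numeric(length(genes)))
    if (length(others) == 1) res <- matrix(res, ncol = 1)
    min_res <- apply(res, 1, min)
    hit <- which(min_res > threshold)
    if (length(hit) > 0) {
      out[[A]] <- tibble::tibble(gene = genes[hit], region = A,
                                 min_residual = min_res[hit])
    }
  }
  sel <- dplyr::bind_rows(out)
  if (nrow(sel) > 0 && anyDuplicated(sel$gene)) {
    # A gene cannot be selective for two regions; keep the stronger call.
    warn("gene selective for multiple regions; keeping the strongest assignment")
    sel <- sel |>
      dplyr::group_by(.data$gene) |>
      dplyr::slice_max(.data$min_residual, n = 1, with_ties = FALSE) |>
      dplyr::ungroup()
  }
  sel
}

#' @export
print.cortex_selective <- function(x, ...) {
  cat(sprintf("<selective genes: %d genes over %d regions (pruned: %s)>\n",
              nrow(x), length(attr(x, "regions")),
              if (length(attr(x, "pruned_regions"))) {
                paste(attr(x, "pruned_regions"), collapse = ", ")
              } else "none"))
  NextMethod()
}

#' Atlas mapping scores for each differentiation
#'
#' Scores each sample's regional identity as the Spearman correlation,
#' over the union of region-selective genes present in the expression data,
#' between the sample's expression and each region's expression energy;
#' scores are then z-normalized within each sample across regions.
#'
#' @param expr Log2-scale expression tibble.
#' @param profiles A [regional_profiles()] set.
#' @param sel A [select_region_specific_genes()] result.
#' @return Tibble of class `cortex_mapping`: `sample_id`, `region`, `rho`,
#'   `z`.
#' @export
mapping_scores <- function(expr, profiles, sel) {
  energy <- as_sample_matrix(tibble::as_tibble(profiles), id_col = "region")
  regions <- attr(sel, "regions") %||% rownames(energy)
  genes <- intersect(unique(sel$gene), expr_genes(expr))
  if (length(genes) < 5) abort("fewer than 5 selective genes present in expression")
  m <- as_sample_matrix(tibble::as_tibble(expr))[, genes, drop = FALSE]
  e <- energy[regions, genes, drop = FALSE]

  rho <- matrix(NA_real_, nrow(m), length(regions),
                dimnames = list(rownames(m), regions))
  for (s in seq_len(nrow(m))) {
    if (sd(m[s, ]) == 0) {
      warn(sprintf("constant expression over selective genes for sample '%s'; score missing",
                   rownames(m)[s]))
      next
    }
    for (r in seq_along(regions)) {
      if (sd(e[r, ]) == 0) {
        warn(sprintf("constant energy over selective genes for region '%s'; score missing",
                     regions[r]))
        next
      }
      rho[s, r] <- cor(m[s, ], e[r, ], method = "spearman")
    }
  }
  z <- t(apply(rho, 1, function(v) {
    s <- sd(v)
    if (is.na(s) || s == 0) rep(NA_real_, length(v)) else (v - mean(v)) / s
  }))
  dimnames(z) <- dimnames(rho)
  out <- dplyr::inner_join(
    tidyr::pivot_longer(as_sample_tbl(rho), -"sample_id",
                        names_to = "region", values_to = "rho"),
    tidyr::pivot_longer(as_sample_tbl(z), -"sample_id",
                        names_to = "region", values_to = "z"),
    by = c("sample_id", "region"))
  structure(out, class = c("cortex_mapping", class(out)))
}
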