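#' Geometric mean
#'
#' @param values Positive numeric values. Callers replace zeros by 1 before
#'   the call (the convention used for control-probe summaries).
#' @return `exp(mean(log(values)))`.
#' @export
geometric_mean <- function(values) {
  if (length(values) == 0) abort("geometric_mean of empty input")
  if (any(!is.finite(values)) || any(values <= 0)) {
    abort("geometric_mean requires positive finite values")
  }
  exp(mean(log(values)))
}

# Control-probe geometric mean: all-zero vectors summarize to 0 (no signal);
# otherwise zeros are replaced by 1 before taking the geometric mean.
control_geomean <- function(values) {
  if (length(values) == 0) abort("no control probes")
  if (all(values == 0)) return(0)
  geometric_mean(pmax(values, 1))
}

#' Normalization configuration
#'
#' @param factor_max,factor_min Acceptance band for the positive-control and
#'   housekeeping normalization factors; samples outside it are removed as
#'   outliers and the survivors re-normalized once.
#' @param expression_floor Linear normalized-count floor for
#'   [filter_expressed()]: a gene is kept if it exceeds this in at least one
#'   sample.
#' @param log_floor Linear counts are clamped to at least this value before
#'   [log2_transform()].
#' @param reference_rule How the factor reference is formed; the only rule
#'   implemented is the geometric mean over samples of per-sample control
#'   geometric means.
#' @return A list of class `cortex_norm_config`.
#' @export
normalization_config <- function(factor_max = 4, factor_min = 0.25,
                                 expression_floor = 30, log_floor = 1,
                                 reference_rule = "dataset_geomean") {
  stopifnot(factor_min < 1, factor_max > 1, expression_floor > 0, log_floor > 0)
  reference_rule <- match.arg(reference_rule, "dataset_geomean")
  structure(list(factor_max = factor_max, factor_min = factor_min,
                 expression_floor = expression_floor, log_floor = log_floor,
                 reference_rule = reference_rule),
            class = "cortex_norm_config")
}

# One normalization pass over a counts matrix (samples x probes).
# Returns per-sample factors and the normalized endogenous submatrix.
normalize_pass <- function(m, classes, gene_symbols) {
  neg <- names(classes)[classes == "negative"]
  pos <- names(classes)[classes == "positive"]
  hk  <- names(classes)[classes == "housekeeping"]
  endo <- names(classes)[classes == "endogenous"]

  background <- apply(m[, neg, drop = FALSE], 1, control_geomean)
  sub <- pmax(m[, c(endo, hk, pos), drop = FALSE] - background, 0)

  pos_gm <- apply(sub[, pos, drop = FALSE], 1, control_geomean)
  valid <- pos_gm > 0
  pos_factor <- rep(NA_real_, nrow(m))
  if (any(valid)) {
    ref_pos <- geometric_mean(pos_gm[valid])
    pos_factor[valid] <- ref_pos / pos_gm[valid]
  }
  sub2 <- sub * ifelse(is.na(pos_factor), 1, pos_factor)

  hk_gm <- apply(sub2[, hk, drop = FALSE], 1, control_geomean)
  valid <- valid & hk_gm > 0
  hk_factor <- rep(NA_real_, nrow(m))
  if (any(valid)) {
    ref_hk <- geometric_mean(hk_gm[valid])
    hk_factor[valid] <- ref_hk / hk_gm[valid]
  }
  out <- sub2[, endo, drop = FALSE] * ifelse(is.na(hk_factor), 1, hk_factor)
  colnames(out) <- unname(gene_symbols[endo])

  list(values = out, background = background,
       pos_factor = pos_factor, hk_factor = hk_factor, valid = valid)
}

#' Normalize a panel count matrix
#'
#' Implements the control-probe normalization used for nCounter-style
#' panels: per sample, (1) the geometric mean of the negative control probes
#' is subtracted as background (clamped at 0); (2) counts are multiplied by a
#' positive-control factor, the ratio of the dataset geometric mean of
#' per-sample positive-probe geometric means to the sample's own; (3) a
#' housekeeping factor computed the same way on the housekeeping probes
#' (after step 2) is applied; (4) samples whose positive or housekeeping
#' factor falls outside `[factor_min, factor_max]` are flagged as outliers,
#' removed, and the survivors re-normalized once. Samples whose positive or
#' housekeeping geometric mean is zero after background subtraction are
#' removed as invalid.
#'
#' @param raw Count tibble (`sample_id` + probe columns), e.g. from
#'   [read_count_table()] or [simulate_dataset()].
#' @param codeset The [codeset_definition()] supplying probe classes.
#' @param cfg A [normalization_config()].
#' @return A linear-scale expression tibble of endogenous genes for the
#'   retained samples, with attribute `qc`: a tibble with columns
#'   `sample_id`, `background`, `pos_factor`, `hk_factor`, `outlier_flag`,
#'   `reason`.
#' @export
normalize_dataset <- function(raw, codeset, cfg = normalization_config()) {
  classes <- probe_classes(codeset)
  m <- as_sample_matrix(tibble::as_tibble(raw))
  missing <- setdiff(colnames(m), names(classes))
  if (length(missing) > 0) {
    abort(paste0("probes without codeset class: ", paste(missing, collapse = ", ")))
  }
  classes <- classes[colnames(m)]
  if (nrow(m) < 2) abort("need at least 2 samples")
  for (cl in c("negative", "positive", "housekeeping")) {
    if (sum(classes == cl) == 0) abort(paste0("codeset has no ", cl, " probes"))
  }
  gene_symbols <- setNames(codeset$gene_symbol, codeset$probe_id)

  pass1 <- normalize_pass(m, classes, gene_symbols)
  in_band <- function(f) {
    !is.na(f) & f >= cfg$factor_min & f <= cfg$factor_max
  }
  keep <- pass1$valid & in_band(pass1$pos_factor) & in_band(pass1$hk_factor)
  reason <- dplyr::case_when(
    !pass1$valid ~ "zero control geometric mean",
    !in_band(pass1$pos_factor) ~ "positive factor out of range",
    !in_band(pass1$hk_factor) ~ "housekeeping factor out of range",
    TRUE ~ NA_character_
  )

  qc <- tibble::tibble(
    sample_id = rownames(m),
    background = unname(pass1$background),
    pos_factor = unname(pass1$pos_factor),
    hk_factor = unname(pass1$hk_factor),
    outlier_flag = !keep,
    reason = reason
  )

  if (!all(keep)) {
    if (sum(keep) < 2) abort("fewer than 2 samples survive outlier removal")
    inform(paste0("removed ", sum(!keep), " sample(s): ",
                  paste(rownames(m)[!keep], collapse = ", ")))
    pass2 <- normalize_pass(m[keep, , drop = FALSE], classes, gene_symbols)
    qc$background[keep] <- pass2$background
    qc$pos_factor[keep] <- pass2$pos_factor
    qc$hk_factor[keep] <- pass2$hk_factor
    values <- pass2$values
  } else {
    values <- pass1$values
  }

  new_expr(as_sample_tbl(values), scale = "linear", qc = qc)
}

#' Filter to expressed genes
#'
#' Retains genes whose linear normalized expression is strictly above `floor`
#' in at least one sample. The filter is defined on normalized counts, so a
#' log2-scale input is an error.
#'
#' @param expr Linear-scale expression tibble.
#' @param floor Expression floor (normalized counts).
#' @return The expression tibble restricted to retained genes.
#' @export
filter_expressed <- function(expr, floor = 30) {
  if (expr_scale(expr) != "linear") {
    abort("filter_expressed is defined on linear normalized counts")
  }
  m <- as_sample_matrix(tibble::as_tibble(expr))
  keep <- apply(m, 2, max) > floor
  new_expr(as_sample_tbl(m[, keep, drop = FALSE]),
           scale = "linear", qc = expr_qc(expr))
}

#' Log2-transform an expression tibble
#'
#' Values are clamped to at least `log_floor` (so zeros map to 0) and
#' log2-transformed, to decrease skewness and stabilize variance before
#' correlation, PCA and classification.
#'
#' @param expr Linear-scale expression tibble.
#' @param log_floor Clamp applied before the log.
#' @return Expression tibble on the log2 scale.
#' @export
log2_transform <- function(expr, log_floor = 1) {
  if (expr_scale(expr) == "log2") abort("expression is already log2-transformed")
  m <- as_sample_matrix(tibble::as_tibble(expr))
  new_expr(as_sample_tbl(log2(pmax(m, log_floor))),
           scale = "log2", qc = expr_qc(expr))
}

#' Merge expression datasets from two codesets
#'
#' Bridge samples profiled with both codesets anchor per-gene scale factors:
#' for each shared gene the factor is the geometric mean over bridge pairs of
#' `(a + eps) / (b + eps)`, applied to every sample of `b`. The merged table
#' contains the shared genes only, with the bridge duplicates collapsed to
#' their `a` version.
#'
#' @param a,b Linear-scale expression tibbles.
#' @param bridge Data frame with columns `a` and `b`: ids of samples profiled
#'   with both codesets (at least 2 pairs).
#' @param eps Stabilizer added to numerator and denominator of each ratio.
#' @return A linear-scale expression tibble over the union of samples, with
#'   attribute `merge_report`: a tibble of per-gene scale factors.
#' @export
merge_codesets <- function(a, b, bridge, eps = 0.5) {
  if (expr_scale(a) != "linear" || expr_scale(b) != "linear") {
    abort("merge_codesets operates on linear-scale expression")
  }
  bridge <- tibble::as_tibble(bridge)
  if (!all(c("a", "b") %in% names(bridge)) || nrow(bridge) < 2) {
    abort("bridge must have columns 'a' and 'b' with at least 2 pairs")
  }
  shared <- intersect(expr_genes(a), expr_genes(b))
  if (length(shared) == 0) abort("no shared genes between codesets")
  ma <- as_sample_matrix(tibble::as_tibble(a))[, shared, drop = FALSE]
  mb <- as_sample_matrix(tibble::as_tibble(b))[, shared, drop = FALSE]
  if (!all(bridge$a %in% rownames(ma))) abort("bridge sample missing from 'a'")
  if (!all(bridge$b %in% rownames(mb))) abort("bridge sample missing from 'b'")

  ratio <- log((ma[bridge$a, , drop = FALSE] + eps) /
               (mb[bridge$b, , drop = FALSE] + eps))
  factors <- exp(colMeans(ratio))

  mb_scaled <- sweep(mb, 2, factors, `*`)
  keep_b <- setdiff(rownames(mb), bridge$b)
  merged <- rbind(ma, mb_scaled[keep_b, , drop = FALSE])

  qc_a <- expr_qc(a)
  qc_b <- expr_qc(b)
  qc <- if (!is.null(qc_a) && !is.null(qc_b)) {
    dplyr::bind_rows(qc_a, dplyr::filter(qc_b, !.data$sample_id %in% bridge$b))
  }
  out <- new_expr(as_sample_tbl(merged), scale = "linear", qc = qc)
  attr(out, "merge_report") <- tibble::tibble(gene = shared, factor = unname(factors))
  out
}
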