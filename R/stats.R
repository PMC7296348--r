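#' Welch's two-sample t test
#'
#' Unpaired, two-sided, without assuming equal variance (the group
#' comparison used throughout the signaling analyses). If both groups have
#' zero variance and equal means the test is degenerate and `p = 1` is
#' returned by convention.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param comparison Optional id carried into the result.
#' @return One-row tibble: `comparison`, `statistic`, `df`, `p_value`,
#'   `effect` (mean of `a` minus mean of `b`), `n1`, `n2`.
#' @export
welch_test <- function(a, b, comparison = NA_character_) {
  if (length(a) < 2 || length(b) < 2) abort("need n >= 2 per group")
  va <- var(a); vb <- var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b)) {
      inform("both groups constant and equal; p = 1 by convention")
      return(tibble::tibble(comparison = comparison, statistic = 0, df = NA_real_,
                            p_value = 1, effect = 0,
                            n1 = length(a), n2 = length(b)))
    }
    warn("both groups constant with different means; p = 0 limit")
    return(tibble::tibble(comparison = comparison,
                          statistic = sign(mean(a) - mean(b)) * Inf,
                          df = NA_real_, p_value = 0,
                          effect = mean(a) - mean(b),
                          n1 = length(a), n2 = length(b)))
  }
  fit <- t.test(a, b, var.equal = FALSE)
  tibble::tibble(comparison = comparison,
                 statistic = unname(fit$statistic),
                 df = unname(fit$parameter),
                 p_value = fit$p.value,
                 effect = mean(a) - mean(b),
                 n1 = length(a), n2 = length(b))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p values with monotonicity enforcement; input order is
#' preserved.
#'
#' @param pvals Numeric p values in `[0, 1]`.
#' @return Adjusted p values, same order and length.
#' @export
fdr_adjust <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    abort("p values must lie in [0, 1]")
  }
  p.adjust(pvals, method = "fdr")
}

#' One-way analysis of variance
#'
#' @param groups Named or unnamed list of numeric vectors (>= 2 groups, each
#'   non-empty, total n greater than the number of groups).
#' @return One-row tibble: `statistic` (F), `df1`, `df2`, `p_value`, `n`.
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2) abort("need at least 2 groups")
  if (any(lengths(groups) < 1)) abort("each group must be non-empty")
  n <- sum(lengths(groups))
  k <- length(groups)
  if (n <= k) abort("total n must exceed the number of groups")
  dat <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(seq_along(groups), lengths(groups)))
  )
  gm <- mean(dat$value)
  ss_between <- sum(tapply(dat$value, dat$group, function(v) length(v) * (mean(v) - gm)^2))
  ss_within <- sum(tapply(dat$value, dat$group, function(v) sum((v - mean(v))^2)))
  if (ss_between == 0) {
    return(tibble::tibble(statistic = 0, df1 = k - 1, df2 = n - k, p_value = 1, n = n))
  }
  if (ss_within == 0) {
    warn("zero within-group variance with unequal means; p = 0 limit")
    return(tibble::tibble(statistic = Inf, df1 = k - 1, df2 = n - k, p_value = 0, n = n))
  }
  fit <- summary(aov(value ~ group, data = dat))[[1]]
  tibble::tibble(statistic = fit[["F value"]][1],
                 df1 = fit[["Df"]][1], df2 = fit[["Df"]][2],
                 p_value = fit[["Pr(>F)"]][1], n = n)
}

#' One-sample t test
#'
#' Two-sided Student's t test of the mean against `mu`; used per gene on
#' within-differentiation treated-minus-control log2 fold changes
#' (`mu = 0`), followed by FDR adjustment across genes.
#'
#' @param values Numeric vector, n >= 2, nonzero variance.
#' @param mu Null mean.
#' @return One-row tibble: `statistic`, `df`, `p_value`, `effect` (mean
#'   minus `mu`), `n`.
#' @export
one_sample_t <- function(values, mu = 0) {
  if (length(values) < 2) abort("need n >= 2")
  if (var(values) == 0) abort("zero variance")
  fit <- t.test(values, mu = mu)
  tibble::tibble(statistic = unname(fit$statistic),
                 df = unname(fit$parameter),
                 p_value = fit$p.value,
                 effect = mean(values) - mu,
                 n = length(values))
}

#' Time-point pooling windows
#'
#' @param windows Named list of `c(lo, hi)` dpi ranges; the defaults pool
#'   samples into the ~17.5 (17-18 dpi) and ~35 (30-39 dpi) time points.
#'   Windows must not overlap.
#' @return Tibble `window`, `lo`, `hi` of class `cortex_pooling`.
#' @export
timepoint_pooling <- function(windows = list("17.5" = c(17, 18),
                                             "35" = c(30, 39))) {
  tab <- tibble::tibble(
    window = names(windows),
    lo = vapply(windows, `[`, numeric(1), 1, USE.NAMES = FALSE),
    hi = vapply(windows, `[`, numeric(1), 2, USE.NAMES = FALSE)
  )
  if (any(tab$lo > tab$hi)) abort("window lo must not exceed hi")
  tab <- dplyr::arrange(tab, .data$lo)
  if (nrow(tab) > 1 && any(tab$lo[-1] <= tab$hi[-nrow(tab)])) {
    abort("pooling windows overlap")
  }
  structure(tab, class = c("cortex_pooling", class(tab)))
}

#' Pooled time-course group comparison
#'
#' Within each pooling window, replicate samples of the same differentiation
#' (same `uin`) are averaged first; per gene, the two line groups are then
#' compared with Welch's t test, and p values are FDR-adjusted across genes
#' within the window. Windows where either group has fewer than 2
#' differentiations are skipped with a warning, and samples whose dpi falls
#' in no window are excluded.
#'
#' @param expr Expression tibble (typically log2).
#' @param meta Metadata with `sample_id`, `uin`, `line`, `dpi`.
#' @param pooling A [timepoint_pooling()] table.
#' @param grouping Data frame with columns `line`, `group` (exactly two
#'   groups); the reported effect is mean(first group) - mean(second group),
#'   groups ordered as first encountered in `grouping`.
#' @return Tibble `window`, `gene`, `statistic`, `df`, `p_value`,
#'   `p_adjusted`, `effect`, `n1`, `n2`.
#' @export
pool_and_compare_timecourse <- function(expr, meta,
                                        pooling = timepoint_pooling(),
                                        grouping) {
  meta <- tibble::as_tibble(meta)
  grouping <- tibble::as_tibble(grouping)
  if (!all(c("line", "group") %in% names(grouping))) {
    abort("grouping must have columns 'line' and 'group'")
  }
  glev <- unique(grouping$group)
  if (length(glev) != 2) abort("grouping must define exactly 2 groups")
  m <- as_sample_matrix(tibble::as_tibble(expr))
  meta <- dplyr::filter(meta, .data$sample_id %in% rownames(m))
  meta$window <- NA_character_
  for (i in seq_len(nrow(pooling))) {
    hit <- meta$dpi >= pooling$lo[i] & meta$dpi <= pooling$hi[i]
    meta$window[hit] <- pooling$window[i]
  }
  dropped <- sum(is.na(meta$window))
  if (dropped > 0) {
    inform(sprintf("%d sample(s) fall in no pooling window; excluded", dropped))
  }
  meta <- dplyr::filter(meta, !is.na(.data$window))
  meta <- dplyr::inner_join(meta, grouping, by = "line")

  out <- list()
  for (w in unique(pooling$window)) {
    mw <- dplyr::filter(meta, .data$window == w)
    if (nrow(mw) == 0) next
    # average replicates of the same differentiation
    agg <- rowsum(m[mw$sample_id, , drop = FALSE], group = mw$uin) /
      as.vector(table(mw$uin)[sort(unique(mw$uin))])
    uin_group <- dplyr::distinct(mw, .data$uin, .data$group)
    g1 <- uin_group$uin[uin_group$group == glev[1]]
    g2 <- uin_group$uin[uin_group$group == glev[2]]
    if (length(g1) < 2 || length(g2) < 2) {
      warn(sprintf("window '%s' skipped: fewer than 2 differentiations in a group", w))
      next
    }
    tests <- purrr::map_dfr(colnames(agg), function(g) {
      res <- welch_test(agg[g1, g], agg[g2, g], comparison = g)
      tibble::tibble(window = w, gene = g,
                     statistic = res$statistic, df = res$df,
                     p_value = res$p_value, effect = res$effect,
                     n1 = res$n1, n2 = res$n2)
    })
    tests$p_adjusted <- fdr_adjust(tests$p_value)
    out[[w]] <- tests
  }
  dplyr::bind_rows(out)
}
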