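#' Regional outcome labels
#'
#' The five regional differentiation outcomes assigned by [classify_regional()].
#' @export
outcome_levels <- c("dorsalized", "partially_ventralized", "highly_ventralized",
                    "partially_caudalized", "highly_caudalized")

# Default marker-gene names used by the threshold classifier.
default_markers <- c(foxg1 = "FOXG1", dlx5 = "DLX5",
                     nkx21 = "NKX2-1", pax6 = "PAX6")

#' Marker-gene threshold set
#'
#' Log2 expression cutoffs driving the five-class regional classifier:
#' jointly low FOXG1 and DLX5 call a partially caudalized outcome (extremely
#' low values, a highly caudalized one); among the remaining rostral samples,
#' high NKX2-1 splits ventralized from dorsalized, with PAX6 separating
#' highly from partially ventralized.
#'
#' @param foxg1_low,dlx5_low Log2 cutoffs for the caudal call.
#' @param foxg1_verylow,dlx5_verylow Stricter cutoffs for the highly caudal
#'   call; must not exceed the corresponding `_low` cutoff.
#' @param nkx21_high Log2 cutoff above which NKX2-1 is "high".
#' @param pax6_low Log2 cutoff separating PAX6-low from PAX6-high.
#' @param provenance `"config"` for hand-set cutoffs, `"fitted"` when
#'   produced by [fit_thresholds()].
#' @return A list of class `cortex_thresholds`.
#' @export
threshold_set <- function(foxg1_low, dlx5_low, nkx21_high, pax6_low,
                          foxg1_verylow = foxg1_low - 2,
                          dlx5_verylow = dlx5_low - 2,
                          provenance = c("config", "fitted")) {
  provenance <- match.arg(provenance)
  vals <- c(foxg1_low, dlx5_low, nkx21_high, pax6_low,
            foxg1_verylow, dlx5_verylow)
  if (any(!is.finite(vals))) abort("all cutoffs must be finite")
  if (foxg1_verylow > foxg1_low || dlx5_verylow > dlx5_low) {
    abort("verylow cutoffs must not exceed low cutoffs")
  }
  structure(list(foxg1_low = foxg1_low, dlx5_low = dlx5_low,
                 foxg1_verylow = foxg1_verylow, dlx5_verylow = dlx5_verylow,
                 nkx21_high = nkx21_high, pax6_low = pax6_low,
                 provenance = provenance),
            class = "cortex_thresholds")
}

#' @export
print.cortex_thresholds <- function(x, ...) {
  cat(sprintf(paste0(
    "<thresholds (%s): FOXG1 low %.2f / verylow %.2f; DLX5 low %.2f / verylow %.2f;\n",
    "  NKX2-1 high %.2f; PAX6 low %.2f>\n"),
    x$provenance, x$foxg1_low, x$foxg1_verylow, x$dlx5_low, x$dlx5_verylow,
    x$nkx21_high, x$pax6_low))
  invisible(x)
}

marker_matrix <- function(expr, markers) {
  m <- as_sample_matrix(tibble::as_tibble(expr))
  missing <- setdiff(markers, colnames(m))
  if (length(missing) > 0) {
    abort(paste0("marker gene(s) missing: ", paste(missing, collapse = ", ")))
  }
  m[, markers, drop = FALSE]
}

#' Classify differentiations into regional outcomes
#'
#' Decision tree over four marker genes, evaluated in order (caudal calls
#' take precedence): (1) FOXG1 below `foxg1_verylow` and DLX5 below
#' `dlx5_verylow` - highly caudalized; (2) FOXG1 below `foxg1_low` and DLX5
#' below `dlx5_low` - partially caudalized; (3) NKX2-1 at or above
#' `nkx21_high` with PAX6 below `pax6_low` - highly ventralized; (4) NKX2-1
#' high with PAX6 at or above `pax6_low` - partially ventralized;
#' (5) otherwise dorsalized.
#'
#' @param expr Log2-scale expression tibble containing the marker genes.
#' @param th A [threshold_set()].
#' @param markers Named gene symbols for the four markers (names `foxg1`,
#'   `dlx5`, `nkx21`, `pax6`).
#' @return Tibble `sample_id`, `label` (factor over [outcome_levels]).
#' @export
classify_regional <- function(expr, th, markers = default_markers) {
  if (expr_scale(expr) != "log2") abort("classify_regional expects log2 expression")
  m <- marker_matrix(expr, unname(markers[c("foxg1", "dlx5", "nkx21", "pax6")]))
  foxg1 <- m[, 1]; dlx5 <- m[, 2]; nkx21 <- m[, 3]; pax6 <- m[, 4]
  label <- dplyr::case_when(
    foxg1 < th$foxg1_verylow & dlx5 < th$dlx5_verylow ~ "highly_caudalized",
    foxg1 < th$foxg1_low & dlx5 < th$dlx5_low ~ "partially_caudalized",
    nkx21 >= th$nkx21_high & pax6 < th$pax6_low ~ "highly_ventralized",
    nkx21 >= th$nkx21_high & pax6 >= th$pax6_low ~ "partially_ventralized",
    TRUE ~ "dorsalized"
  )
  tibble::tibble(sample_id = rownames(m),
                 label = factor(label, levels = outcome_levels))
}

# Candidate cutoffs for one marker: midpoints between consecutive distinct
# training values, plus sentinels below and above the observed range.
cutoff_candidates <- function(v) {
  u <- sort(unique(v))
  c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
}

# Margin of a cutoff: distance to the nearest training value.
cutoff_margin <- function(t, v) min(abs(v - t))

# Exhaustive search over candidate cutoff pairs for a two-marker AND rule.
# rule(x1, x2, t1, t2) must return a logical prediction vector. Returns the
# pair maximizing agreement with `target`; ties broken by largest combined
# margin, then by smallest t1, then smallest t2.
fit_pair_rule <- function(x1, x2, target, rule) {
  c1 <- cutoff_candidates(x1)
  c2 <- cutoff_candidates(x2)
  best <- NULL
  for (t1 in c1) {
    for (t2 in c2) {
      agree <- mean(rule(x1, x2, t1, t2) == target)
      margin <- cutoff_margin(t1, x1) + cutoff_margin(t2, x2)
      cand <- c(agree = agree, margin = margin, t1 = t1, t2 = t2)
      if (is.null(best) ||
          agree > best["agree"] + 1e-12 ||
          (abs(agree - best["agree"]) <= 1e-12 &&
           margin > best["margin"] + 1e-12)) {
        best <- cand
      }
    }
  }
  best
}

#' Fit classifier thresholds from paired early/late data
#'
#' Re-derives the marker cutoffs from training differentiations whose
#' late-stage cluster outcome is known, choosing cutoffs so the decision
#' tree reproduces the late outcomes with maximal agreement. Caudal cutoffs
#' are fitted first (FOXG1 and DLX5 jointly separating the caudalized
#' late cluster, LC3, from the rest); ventral cutoffs (NKX2-1, PAX6
#' separating the highly ventralized cluster, LC1) are then fitted on the
#' samples not called caudal. Candidate cutoffs are midpoints between
#' adjacent training values; among equally optimal candidates the pair with
#' the largest combined margin to the training data is taken. Very-low
#' (highly caudal) cutoffs are fitted only if highly caudal training
#' examples exist; otherwise they are set `verylow_offset` below the low
#' cutoffs.
#'
#' @param early Log2-scale expression tibble of early-stage samples.
#' @param training Data frame with columns `sample_id` (early sample) and
#'   `class`: the paired late-stage outcome, one of `"LC1"` (highly
#'   ventralized), `"LC2"` (dorsalized), `"LC3"` (partially caudalized), or
#'   `"EC5"` for highly caudalized training examples.
#' @param markers Named marker genes as in [classify_regional()].
#' @param verylow_offset Log2 offset used for the very-low cutoffs when no
#'   highly caudal training examples exist.
#' @return A [threshold_set()] with `provenance = "fitted"` and attributes
#'   `agreement` (training agreement of the full tree against the mapped
#'   training classes) and `misclassified` (sample ids, if any).
#' @export
fit_thresholds <- function(early, training, markers = default_markers,
                           verylow_offset = 1.5) {
  training <- tibble::as_tibble(training)
  if (!all(c("sample_id", "class") %in% names(training))) {
    abort("training must have columns 'sample_id' and 'class'")
  }
  if (!all(training$class %in% c("LC1", "LC2", "LC3", "EC5"))) {
    abort("training classes must be LC1, LC2, LC3 or EC5")
  }
  if (!all(c("LC1", "LC2", "LC3") %in% training$class)) {
    abort("training must cover LC1, LC2 and LC3")
  }
  m <- marker_matrix(early, unname(markers[c("foxg1", "dlx5", "nkx21", "pax6")]))
  if (!all(training$sample_id %in% rownames(m))) {
    abort("training sample missing from early expression")
  }
  m <- m[training$sample_id, , drop = FALSE]
  foxg1 <- m[, 1]; dlx5 <- m[, 2]; nkx21 <- m[, 3]; pax6 <- m[, 4]
  caudal_target <- training$class %in% c("LC3", "EC5")

  caudal_rule <- function(x1, x2, t1, t2) x1 < t1 & x2 < t2
  cfit <- fit_pair_rule(foxg1, dlx5, caudal_target, caudal_rule)
  called_caudal <- caudal_rule(foxg1, dlx5, cfit[["t1"]], cfit[["t2"]])

  rest <- !called_caudal
  ventral_rule <- function(x1, x2, t1, t2) x1 >= t1 & x2 < t2
  vfit <- fit_pair_rule(nkx21[rest], pax6[rest],
                        (training$class == "LC1")[rest], ventral_rule)

  if (any(training$class == "EC5")) {
    hfit <- fit_pair_rule(foxg1, dlx5, training$class == "EC5", caudal_rule)
    verylow <- c(min(hfit[["t1"]], cfit[["t1"]]), min(hfit[["t2"]], cfit[["t2"]]))
  } else {
    verylow <- c(cfit[["t1"]], cfit[["t2"]]) - verylow_offset
  }

  th <- threshold_set(foxg1_low = cfit[["t1"]], dlx5_low = cfit[["t2"]],
                      nkx21_high = vfit[["t1"]], pax6_low = vfit[["t2"]],
                      foxg1_verylow = verylow[1], dlx5_verylow = verylow[2],
                      provenance = "fitted")

  pred <- classify_regional(new_expr(as_sample_tbl(m), scale = "log2"),
                            th, markers = setNames(colnames(m),
                                                   c("foxg1", "dlx5", "nkx21", "pax6")))
  has_ec5 <- any(training$class == "EC5")
  caudal_levels <- c("partially_caudalized", "highly_caudalized")
  ok <- dplyr::case_when(
    training$class == "EC5" ~ pred$label == "highly_caudalized",
    # without highly-caudal training examples the verylow cutoffs are
    # offsets, so either caudal label satisfies an LC3 example
    training$class == "LC3" & !has_ec5 ~ pred$label %in% caudal_levels,
    training$class == "LC3" ~ pred$label == "partially_caudalized",
    training$class == "LC1" ~ pred$label == "highly_ventralized",
    TRUE ~ pred$label %in% c("dorsalized", "partially_ventralized")
  )
  attr(th, "agreement") <- mean(ok)
  attr(th, "misclassified") <- training$sample_id[!ok]
  if (!all(ok)) {
    warn(paste0("thresholds do not separate training data; misclassified: ",
                paste(training$sample_id[!ok], collapse = ", ")))
  }
  th
}

#' Wilson score interval for a binomial proportion
#'
#' @param x Successes.
#' @param n Trials (>= 1).
#' @param conf Confidence level.
#' @return Named vector `lo`, `hi`.
#' @export
wilson_interval <- function(x, n, conf = 0.95) {
  if (n < 1) abort("n must be >= 1")
  z <- qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lo = center - half, hi = center + half)
}

#' Newcombe hybrid score interval for a difference of proportions
#'
#' Confidence interval for `p1 - p2` built from the Wilson intervals of the
#' two proportions (Newcombe's hybrid score method), the construction used
#' to flag line-specific dorsal-outcome bias.
#'
#' @param x1,n1 Successes and trials of the first proportion (the line).
#' @param x2,n2 Successes and trials of the second proportion (the overall
#'   rate, excluding the line under test so the two are independent).
#' @param conf Confidence level.
#' @return Tibble `estimate`, `lo`, `hi`, `excludes_zero`.
#' @export
line_bias_interval <- function(x1, n1, x2, n2, conf = 0.95) {
  if (n1 < 1) abort("line total must be >= 1")
  if (n2 < 1) abort("overall total (excluding the line) must be >= 1")
  p1 <- x1 / n1
  p2 <- x2 / n2
  w1 <- wilson_interval(x1, n1, conf)
  w2 <- wilson_interval(x2, n2, conf)
  lo <- p1 - p2 - sqrt((p1 - w1["lo"])^2 + (w2["hi"] - p2)^2)
  hi <- p1 - p2 + sqrt((w1["hi"] - p1)^2 + (p2 - w2["lo"])^2)
  tibble::tibble(estimate = p1 - p2, lo = unname(lo), hi = unname(hi),
                 excludes_zero = unname(lo > 0 | hi < 0))
}

#' Per-line differentiation-outcome frequencies and bias flags
#'
#' Tabulates outcome frequencies by PSC line (lines with fewer than `min_n`
#' differentiations are excluded), and flags lines whose dorsal-outcome
#' frequency differs from the overall frequency: the Newcombe/Wilson
#' interval for the difference between the line's dorsal proportion and the
#' overall proportion (computed excluding that line) must exclude zero.
#'
#' @param labels Tibble `sample_id`, `label` from [classify_regional()].
#' @param meta Sample metadata with `sample_id` and `line`.
#' @param min_n Minimum differentiations per line for inclusion.
#' @param conf Confidence level of the bias interval.
#' @return Tibble with one row per retained line: `line`, `n`, one count and
#'   one frequency column per outcome, `dorsal_diff`, `wilson_lo`,
#'   `wilson_hi`, `biased_flag`; attribute `overall_dorsal` holds the
#'   overall dorsal frequency over included differentiations.
#' @export
line_frequencies <- function(labels, meta, min_n = 2, conf = 0.95) {
  dat <- dplyr::inner_join(tibble::as_tibble(labels),
                           dplyr::select(tibble::as_tibble(meta),
                                         "sample_id", "line"),
                           by = "sample_id")
  if (nrow(dat) < nrow(tibble::as_tibble(labels))) {
    warn("some labeled samples have no metadata line; dropped")
  }
  keep_lines <- dplyr::filter(dplyr::count(dat, .data$line), .data$n >= min_n)$line
  dat <- dplyr::filter(dat, .data$line %in% keep_lines)
  counts <- dat |>
    dplyr::count(.data$line, .data$label, .drop = FALSE) |>
    tidyr::pivot_wider(names_from = "label", values_from = "n",
                       names_prefix = "n_", values_fill = 0L)
  counts$n <- rowSums(counts[paste0("n_", outcome_levels)])
  for (lv in outcome_levels) {
    counts[[paste0("freq_", lv)]] <- counts[[paste0("n_", lv)]] / counts$n
  }
  total_dorsal <- sum(counts$n_dorsalized)
  total_n <- sum(counts$n)
  overall <- total_dorsal / total_n

  bias <- purrr::pmap_dfr(
    list(counts$n_dorsalized, counts$n),
    function(x1, n1) {
      line_bias_interval(x1, n1, total_dorsal - x1, total_n - n1, conf = conf)
    })
  counts$dorsal_diff <- counts$freq_dorsalized - overall
  counts$wilson_lo <- bias$lo
  counts$wilson_hi <- bias$hi
  counts$biased_flag <- bias$excludes_zero
  out <- dplyr::relocate(counts, "line", "n")
  attr(out, "overall_dorsal") <- overall
  out
}

#' Outcome frequencies by genotype, line-weighted
#'
#' Averages per-line outcome-frequency vectors within each genotype, so each
#' line counts once regardless of its number of differentiations; genotypes
#' represented by fewer than `min_lines` lines are excluded. Also reports the
#' partly cortical rate (dorsalized plus partially ventralized).
#'
#' @param line_table Output of [line_frequencies()].
#' @param genotype_map Data frame with columns `line`, `genotype`, covering
#'   all lines in `line_table`.
#' @param min_lines Minimum lines per genotype.
#' @return Tibble `genotype`, `n_lines`, one `freq_` column per outcome,
#'   `partly_cortical`.
#' @export
genotype_frequencies <- function(line_table, genotype_map, min_lines = 3) {
  genotype_map <- tibble::as_tibble(genotype_map)
  if (!all(line_table$line %in% genotype_map$line)) {
    abort("genotype_map must cover all lines")
  }
  dat <- dplyr::inner_join(line_table, genotype_map, by = "line")
  out <- dat |>
    dplyr::group_by(.data$genotype) |>
    dplyr::summarise(
      n_lines = dplyr::n(),
      dplyr::across(dplyr::all_of(paste0("freq_", outcome_levels)), mean),
      .groups = "drop") |>
    dplyr::filter(.data$n_lines >= min_lines)
  out$partly_cortical <- out$freq_dorsalized + out$freq_partially_ventralized
  out
}
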