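# Independent brute-force oracles shared by the unit and acceptance tests.

# Brute-force complete-linkage agglomeration: O(n^3) over all pair merges.
brute_complete_linkage_heights <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1)) {
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best[1]) best <- c(h, i, j)
      }
    }
    heights <- c(heights, best[1])
    keep <- setdiff(seq_along(clusters), best[2:3])
    clusters <- c(clusters[keep], list(c(clusters[[best[2]]], clusters[[best[3]]])))
  }
  sort(heights)
}

partition_sets <- function(labels, ids) {
  unname(lapply(split(ids, labels), sort))
}


# Independent truth-table oracle: enumerate the five disjoint regions of
# marker space directly from the rule definitions.
oracle_label <- function(f, d, n, p, th) {
  caudal_very <- f < th$foxg1_verylow && d < th$dlx5_verylow
  caudal <- f < th$foxg1_low && d < th$dlx5_low
  nk_high <- n >= th$nkx21_high
  p_low <- p < th$pax6_low
  if (caudal_very) "highly_caudalized"
  else if (caudal) "partially_caudalized"
  else if (nk_high && p_low) "highly_ventralized"
  else if (nk_high && !p_low) "partially_ventralized"
  else "dorsalized"
}

# Independent exhaustive fit oracle: plain loops over midpoint candidates,
# same documented objective (agreement, then combined margin, then smallest
# cutoffs).
oracle_fit_pair <- function(x1, x2, target, rule) {
  cands <- function(v) {
    u <- sort(unique(v))
    mids <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else numeric(0)
    c(u[1] - 1, mids, u[length(u)] + 1)
  }
  best <- NULL
  for (t1 in cands(x1)) {
    for (t2 in cands(x2)) {
      agree <- mean(rule(x1, x2, t1, t2) == target)
      margin <- min(abs(x1 - t1)) + min(abs(x2 - t2))
      if (is.null(best) || agree > best$agree + 1e-12 ||
          (abs(agree - best$agree) <= 1e-12 && margin > best$margin + 1e-12)) {
        best <- list(agree = agree, margin = margin, t1 = t1, t2 = t2)
      }
    }
  }
  best
}

random_marker_expr <- function(n, lo = 2, hi = 14) {
  m <- cbind(FOXG1 = runif(n, lo, hi), DLX5 = runif(n, lo, hi),
             `NKX2-1` = runif(n, lo, hi), PAX6 = runif(n, lo, hi))
  rownames(m) <- sprintf("S%04d", seq_len(n))
  expr_from_matrix(m)
}

# Separable three-class training set in marker space: caudal (low FOXG1 and
# DLX5), highly ventral (high NKX2-1, low PAX6), dorsal/partial-ventral rest.
random_separable_training <- function(n_caudal = 4, n_ventral = 6,
                                      n_dorsal = 8, n_pv = 4) {
  n <- n_caudal + n_ventral + n_dorsal + n_pv
  cls <- c(rep("LC3", n_caudal), rep("LC1", n_ventral),
           rep("LC2", n_dorsal + n_pv))
  f <- c(runif(n_caudal, 4, 6), runif(n_ventral + n_dorsal + n_pv, 9, 12))
  d <- c(runif(n_caudal, 2, 4), runif(n_ventral, 7, 9),
         runif(n_dorsal, 5.5, 7.5), runif(n_pv, 7, 9))
  nk <- c(runif(n_caudal, 2, 10), runif(n_ventral, 9, 11),
          runif(n_dorsal, 3, 6), runif(n_pv, 9, 11))
  p <- c(runif(n_caudal, 8, 11), runif(n_ventral, 6, 8),
         runif(n_dorsal, 10.5, 12), runif(n_pv, 10.5, 12))
  m <- cbind(FOXG1 = f, DLX5 = d, `NKX2-1` = nk, PAX6 = p)
  rownames(m) <- sprintf("T%03d", seq_len(n))
  list(expr = expr_from_matrix(m),
       training = tibble::tibble(sample_id = rownames(m), class = cls))
}


# Normal-equations brute force: fit y ~ x by solving X'X b = X'y directly,
# standardize residuals with hand-computed leverages, threshold, and apply
# the same simultaneous pruning loop.
oracle_selective <- function(energy, threshold) {
  E <- log2(energy + 1)
  regions <- rownames(E)
  repeat {
    sel <- list()
    for (A in regions) {
      hits <- rep(TRUE, ncol(E))
      for (B in setdiff(regions, A)) {
        y <- E[A, ]; x <- E[B, ]
        X <- cbind(1, x)
        b <- solve(t(X) %*% X, t(X) %*% y)
        e <- y - X %*% b
        n <- length(y)
        s2 <- sum(e^2) / (n - 2)
        h <- diag(X %*% solve(t(X) %*% X) %*% t(X))
        std <- e / sqrt(s2 * (1 - h))
        hits <- hits & (std > threshold)
      }
      if (any(hits)) sel[[A]] <- colnames(E)[hits]
    }
    empty <- setdiff(regions, names(sel))
    if (length(empty) == 0) break
    regions <- setdiff(regions, empty)
    if (length(regions) < 2) stop("pruned below 2 regions")
  }
  sel
}

random_profiles <- function(n_regions = 6, n_genes = 60, n_selective = 8) {
  base <- 2^runif(n_genes, 2, 7)
  energy <- matrix(rep(base, each = n_regions) *
                     exp(rnorm(n_regions * n_genes, 0, 0.15)),
                   n_regions, n_genes,
                   dimnames = list(paste0("R", seq_len(n_regions)),
                                   paste0("g", seq_len(n_genes))))
  picks <- sample(n_genes, n_selective)
  homes <- sample(n_regions, n_selective, replace = TRUE)
  for (k in seq_len(n_selective)) {
    energy[homes[k], picks[k]] <- energy[homes[k], picks[k]] * 50
  }
  regional_profiles(as_sample_tbl(energy, id_col = "region"))
}


# Welch formulas recomputed from first principles.
oracle_welch <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

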