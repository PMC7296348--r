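test_that("the decision tree matches the spec'd panel readings", {
  th <- threshold_set(foxg1_low = 10, dlx5_low = 6, nkx21_high = 8,
                      pax6_low = 9.5, foxg1_verylow = 8.5, dlx5_verylow = 5)
  m <- rbind(
    high_pax6_high_nkx21 = c(11, 7, 9, 11),
    all_high_but_nkx21 = c(12, 8, 5, 12),
    caudal_despite_nkx21 = c(9, 5.5, 12, 11),
    very_caudal = c(8, 4, 3, 10)
  )
  colnames(m) <- c("FOXG1", "DLX5", "NKX2-1", "PAX6")
  out <- classify_regional(expr_from_matrix(m), th)
  expect_equal(as.character(out$label),
               c("partially_ventralized", "dorsalized",
                 "partially_caudalized", "highly_caudalized"))
})

test_that("classification equals the truth-table oracle on random marker vectors", {
  set.seed(61)
  th <- threshold_set(foxg1_low = 10, dlx5_low = 6.5, nkx21_high = 8,
                      pax6_low = 9.5, foxg1_verylow = 8.8, dlx5_verylow = 5.2)
  expr <- random_marker_expr(1000)
  got <- classify_regional(expr, th)
  m <- as.matrix(tibble::as_tibble(expr)[-1])
  want <- vapply(seq_len(nrow(m)),
                 function(i) oracle_label(m[i, "FOXG1"], m[i, "DLX5"],
                                          m[i, "NKX2-1"], m[i, "PAX6"], th),
                 character(1))
  expect_identical(as.character(got$label), want)
  # total and single-valued
  expect_false(anyNA(got$label))
})

test_that("marker monotonicity holds: NKX2-1 up never dorsalizes, FOXG1/DLX5 down never leaves caudal", {
  set.seed(62)
  th <- threshold_set(foxg1_low = 10, dlx5_low = 6.5, nkx21_high = 8,
                      pax6_low = 9.5)
  expr <- random_marker_expr(300)
  m <- as.matrix(tibble::as_tibble(expr)[-1])
  base <- classify_regional(expr, th)$label
  up <- m; up[, "NKX2-1"] <- up[, "NKX2-1"] + 3
  lab_up <- classify_regional(expr_from_matrix(up), th)$label
  ventral <- c("highly_ventralized", "partially_ventralized")
  expect_false(any(base %in% ventral & lab_up == "dorsalized"))
  down <- m
  down[, "FOXG1"] <- down[, "FOXG1"] - 3
  down[, "DLX5"] <- down[, "DLX5"] - 3
  lab_down <- classify_regional(expr_from_matrix(down), th)$label
  caudal <- c("partially_caudalized", "highly_caudalized")
  expect_false(any(base %in% caudal & !(lab_down %in% caudal)))
})

test_that("missing marker genes are reported by name", {
  m <- cbind(FOXG1 = c(10, 11), DLX5 = c(6, 7), PAX6 = c(10, 10))
  th <- threshold_set(10, 6, 8, 9.5)
  expect_error(classify_regional(expr_from_matrix(m), th), "NKX2-1")
})

test_that("fitted thresholds separate separable training data with unit agreement", {
  set.seed(63)
  fix <- random_separable_training()
  th <- fit_thresholds(fix$expr, fix$training)
  expect_equal(attr(th, "agreement"), 1)
  expect_length(attr(th, "misclassified"), 0)
  m <- as.matrix(tibble::as_tibble(fix$expr)[-1])
  # each caudal cutoff lies strictly between the classes' extreme values
  caudal <- fix$training$class == "LC3"
  expect_gt(th$foxg1_low, max(m[caudal, "FOXG1"]))
  expect_lt(th$foxg1_low, min(m[!caudal, "FOXG1"]))
})

test_that("threshold fitting equals the exhaustive grid-search oracle", {
  set.seed(64)
  for (i in 1:10) {
    fix <- random_separable_training()
    th <- fit_thresholds(fix$expr, fix$training)
    m <- as.matrix(tibble::as_tibble(fix$expr)[-1])
    cls <- fix$training$class
    o_caudal <- oracle_fit_pair(m[, "FOXG1"], m[, "DLX5"], cls == "LC3",
                                function(x1, x2, t1, t2) x1 < t1 & x2 < t2)
    expect_equal(th$foxg1_low, o_caudal$t1, tolerance = 1e-12)
    expect_equal(th$dlx5_low, o_caudal$t2, tolerance = 1e-12)
    rest <- !(m[, "FOXG1"] < o_caudal$t1 & m[, "DLX5"] < o_caudal$t2)
    o_ventral <- oracle_fit_pair(m[rest, "NKX2-1"], m[rest, "PAX6"],
                                 (cls == "LC1")[rest],
                                 function(x1, x2, t1, t2) x1 >= t1 & x2 < t2)
    expect_equal(th$nkx21_high, o_ventral$t1, tolerance = 1e-12)
    expect_equal(th$pax6_low, o_ventral$t2, tolerance = 1e-12)
  }
})

test_that("fitted training labels are stable under small jitter", {
  set.seed(65)
  fix <- random_separable_training()
  th <- fit_thresholds(fix$expr, fix$training)
  m <- as.matrix(tibble::as_tibble(fix$expr)[-1])
  rownames(m) <- fix$training$sample_id
  lab1 <- classify_regional(fix$expr, th)$label
  m2 <- m + matrix(runif(length(m), -0.01, 0.01), nrow(m))
  th2 <- fit_thresholds(expr_from_matrix(m2), fix$training)
  lab2 <- classify_regional(expr_from_matrix(m2), th2)$label
  expect_identical(lab1, lab2)
})

test_that("non-separable training yields best-agreement thresholds with a warning", {
  set.seed(66)
  fix <- random_separable_training()
  m <- as.matrix(tibble::as_tibble(fix$expr)[-1])
  rownames(m) <- fix$training$sample_id
  # corrupt one caudal sample into dorsal marker territory
  i <- which(fix$training$class == "LC3")[1]
  m[i, ] <- c(11, 7, 4, 11.5)
  expect_warning(th <- fit_thresholds(expr_from_matrix(m), fix$training),
                 "misclassified")
  expect_lt(attr(th, "agreement"), 1)
  expect_true(fix$training$sample_id[i] %in% attr(th, "misclassified"))
})

test_that("line frequencies count outcomes per line and exclude singletons", {
  labels <- tibble::tibble(
    sample_id = paste0("S", 1:6),
    label = factor(c("dorsalized", "dorsalized", "highly_ventralized",
                     "dorsalized", "partially_caudalized", "dorsalized"),
                   levels = outcome_levels))
  meta <- tibble::tibble(sample_id = paste0("S", 1:6),
                         line = c("A", "A", "A", "B", "B", "C"))
  tab <- line_frequencies(labels, meta, min_n = 2)
  expect_setequal(tab$line, c("A", "B"))
  expect_equal(tab$freq_dorsalized[tab$line == "A"], 2 / 3)
  expect_equal(sum(tab[tab$line == "A", paste0("freq_", outcome_levels)]), 1)
  expect_equal(attr(tab, "overall_dorsal"), 3 / 5)
})

test_that("Wilson intervals match the score-test construction", {
  # prop.test without continuity correction inverts the same score test
  for (case in list(c(7, 20), c(0, 26), c(12, 12), c(40, 55))) {
    w <- wilson_interval(case[1], case[2])
    ref <- suppressWarnings(prop.test(case[1], case[2], correct = FALSE))$conf.int
    expect_equal(unname(w), as.numeric(ref), tolerance = 1e-9)
  }
})

test_that("the Newcombe hybrid interval matches its closed form and flags strong bias", {
  # independent re-computation from the published construction
  x1 <- 5; n1 <- 20; x2 <- 60; n2 <- 100
  p1 <- x1 / n1; p2 <- x2 / n2
  wi <- function(x, n) {
    z <- qnorm(0.975)
    p <- x / n
    c((p + z^2 / (2 * n) - z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) / (1 + z^2 / n),
      (p + z^2 / (2 * n) + z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) / (1 + z^2 / n))
  }
  w1 <- wi(x1, n1); w2 <- wi(x2, n2)
  lo <- p1 - p2 - sqrt((p1 - w1[1])^2 + (w2[2] - p2)^2)
  hi <- p1 - p2 + sqrt((w1[2] - p1)^2 + (p2 - w2[1])^2)
  got <- line_bias_interval(x1, n1, x2, n2)
  expect_equal(got$lo, lo, tolerance = 1e-12)
  expect_equal(got$hi, hi, tolerance = 1e-12)
  expect_true(got$excludes_zero)

  # a 0/26 line against a high overall dorsal rate is flagged
  res <- line_bias_interval(0, 26, 80, 120)
  expect_true(res$excludes_zero)
  expect_lt(res$hi, 0)
  # equal proportions from small n are not
  expect_false(line_bias_interval(5, 10, 50, 100)$excludes_zero)
  expect_error(line_bias_interval(1, 2, 0, 0), "overall")
})

test_that("line bias flags integrate with per-line tables", {
  set.seed(67)
  labels <- tibble::tibble(
    sample_id = sprintf("S%03d", 1:126),
    label = factor(c(rep("dorsalized", 80), rep("highly_ventralized", 20),
                     rep("dorsalized", 0), rep("partially_caudalized", 26)),
                   levels = outcome_levels))
  meta <- tibble::tibble(sample_id = labels$sample_id,
                         line = c(rep("good", 100), rep("caudal_line", 26)))
  tab <- line_frequencies(labels, meta)
  expect_true(tab$biased_flag[tab$line == "caudal_line"])
})

test_that("genotype frequencies weight lines equally and respect the line minimum", {
  line_table <- tibble::tibble(
    line = c("A", "B", "C", "D"),
    n = c(10, 2, 4, 3),
    freq_dorsalized = c(1, 0.5, 0.25, 0.5),
    freq_partially_ventralized = c(0, 0.5, 0.25, 0),
    freq_highly_ventralized = c(0, 0, 0.5, 0.5),
    freq_partially_caudalized = 0,
    freq_highly_caudalized = 0
  )
  map <- tibble::tibble(line = c("A", "B", "C", "D"),
                        genotype = c("ctl", "ctl", "ctl", "mut"))
  out <- genotype_frequencies(line_table, map, min_lines = 3)
  expect_equal(out$genotype, "ctl")
  # unweighted mean across lines, regardless of per-line n
  expect_equal(out$freq_dorsalized, mean(c(1, 0.5, 0.25)))
  expect_equal(out$partly_cortical,
               mean(c(1, 0.5, 0.25)) + mean(c(0, 0.5, 0.25)))
  expect_error(genotype_frequencies(line_table,
                                    map[map$line != "D", ], min_lines = 3),
               "cover all lines")
})
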