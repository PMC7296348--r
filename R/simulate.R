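#' Simulation configuration
#'
#' Parameters of the synthetic nCounter-like data generator. Counts arise as
#' mixtures of five regional expression programs whose mixing proportions
#' are Dirichlet draws driven by latent Wnt and Hedgehog activity, with
#' lane-specific scale factors, control probes, and negative-binomial
#' counting noise.
#'
#' @param dispersion Negative-binomial size parameter of endogenous counts
#'   (larger = less overdispersion); housekeeping/positive probes use
#'   `control_dispersion`.
#' @param control_dispersion NB size for control and housekeeping probes.
#' @param lane_sd Standard deviation of the log-normal lane scale factor.
#' @param concentration Dirichlet precision of the mixture draw: higher
#'   values give tighter within-line outcome spread.
#' @param neg_mean Mean negative-control probe count.
#' @param link 2-column matrix (wnt, hh) of per-program coefficients mapping
#'   latent signaling to mixture log-odds: Wnt pushes mass toward the
#'   cortical and mid/hindbrain programs, Hedgehog toward the MGE/LGE
#'   programs, low Wnt toward the MGE program.
#' @param signaling_coef Named log2-fold coefficients scaling the pathway
#'   readout genes with the latent activities (SHH/PTCH1/GLI1 up and GAS1
#'   down with Hedgehog; AXIN2/TNFRSF19 up with Wnt).
#' @param label_rule Mixture-proportion thresholds of the ground-truth
#'   outcome label (see [label_from_proportions()]).
#' @return List of class `cortex_sim_config`.
#' @export
sim_config <- function(dispersion = 80,
                       control_dispersion = 150,
                       lane_sd = 0.12,
                       concentration = 120,
                       neg_mean = 8,
                       link = default_signaling_link(),
                       signaling_coef = c(SHH = 0.8, PTCH1 = 0.5, GLI1 = 0.6,
                                          GAS1 = -0.5, AXIN2 = 0.6,
                                          TNFRSF19 = 0.5),
                       label_rule = c(caudal_partial = 0.25, caudal_high = 0.6,
                                      ventral_partial = 0.15, ventral_high = 0.4)) {
  stopifnot(dispersion > 0, lane_sd >= 0, concentration > 0)
  structure(list(dispersion = dispersion,
                 control_dispersion = control_dispersion,
                 lane_sd = lane_sd, concentration = concentration,
                 neg_mean = neg_mean, link = link,
                 signaling_coef = signaling_coef,
                 label_rule = label_rule),
            class = "cortex_sim_config")
}

sim_regions <- c("cortex", "LGE", "MGE", "mid_hindbrain", "hypothalamus")

#' @rdname sim_config
#' @export
default_signaling_link <- function() {
  matrix(c(
    # wnt   hh
     1.2, -0.8,   # cortex
    -0.3,  0.6,   # LGE
    -1.0,  1.4,   # MGE
     0.5, -0.2,   # mid_hindbrain
     0.0,  0.0),  # hypothalamus
    ncol = 2, byrow = TRUE,
    dimnames = list(sim_regions, c("wnt", "hh")))
}

#' Regional expression programs of the synthetic panel
#'
#' Per-gene mean expression (linear normalized-count scale) of the five
#' regional programs the generator mixes: cortex, LGE, MGE, mid/hindbrain
#' and hypothalamus. Regional marker genes are elevated at least 8-fold in
#' their home program; FOXG1 is shared across the forebrain programs;
#' pan-neural, progenitor, signaling, cell-state and control genes complete
#' a panel of the size used on targeted neural codesets.
#'
#' @return List with `programs` (5 x G matrix of means), `marker_map`
#'   (tibble `gene`, `home`), and `genes` (endogenous gene symbols).
#' @export
default_programs <- function() {
  # regional and signaling genes: one row per gene, means per program
  spec <- tibble::tribble(
    ~gene,       ~cortex, ~LGE, ~MGE, ~mid_hindbrain, ~hypothalamus, ~home,
    "EMX1",       1800,    25,   25,     25,   25,  "cortex",
    "EMX2",       2200,    60,   60,     40,   60,  "cortex",
    "EOMES",      1500,    25,   25,     25,   25,  "cortex",
    "NEUROG2",    1600,    40,   40,     60,   40,  "cortex",
    "PAX6",       3000,   200,   30,    350,  120,  "cortex",
    "TBR1",       1200,    40,   40,     40,   40,  "cortex",
    "SLC17A7",     900,    30,   30,     30,   30,  "cortex",
    "GLI3",       1400,   160,   60,    160,  160,  "cortex",
    "NEUROD2",    1100,    60,   60,     60,   60,  "cortex",
    "FEZF2",       800,    30,   30,     30,   30,  "cortex",
    "SOX5",       1000,   120,  120,    120,  120,  "cortex",
    "MAP2",       2000,   900,  900,    500,  500,  NA,
    "GAS1",       1200,   150,  150,    150,  150,  NA,
    "DLX1",         20,  1500,  180,     20,   20,  "LGE",
    "DLX5",         20,  2000,  150,     20,   20,  "LGE",
    "DLX2",         20,  1300,  160,     20,   20,  "LGE",
    "GSX2",         30,   900,  110,     30,   30,  "LGE",
    "EBF1",         40,   800,   90,     40,   40,  "LGE",
    "NKX2-1",       20,    20, 2500,     20,  250,  "MGE",
    "LHX6",         20,    20, 1600,     20,   20,  "MGE",
    "LHX8",         20,    20, 1400,     20,   20,  "MGE",
    "OLIG2",        40,    90, 1100,     90,   40,  "MGE",
    "GSC",          15,    15,  600,     40,   15,  "MGE",
    "GAD2",         40,   700, 1500,     60,   60,  NA,
    "SST",          30,   120, 1000,     60,   60,  "MGE",
    "HOXA2",        15,    15,   15,   1200,   15,  "mid_hindbrain",
    "HOXB2",        15,    15,   15,   1400,   15,  "mid_hindbrain",
    "PAX3",         25,    25,   25,   1300,   25,  "mid_hindbrain",
    "EN2",          20,    20,   20,   1500,   20,  "mid_hindbrain",
    "GBX2",         25,    25,   25,   1000,   25,  "mid_hindbrain",
    "TFAP2A",       30,    30,   30,   1100,   30,  "mid_hindbrain",
    "DDC",          25,    25,   25,    800,   60,  "mid_hindbrain",
    "NR4A2",        20,    20,   20,    900,   20,  "mid_hindbrain",
    "OTX2",        150,   150,  150,   1200,  300,  NA,
    "NKX6-1",       15,    15,   60,    700,   40,  "mid_hindbrain",
    "LHX9",         40,    40,   40,    700,  100,  NA,
    "POU4F1",       30,    30,   30,    800,   30,  "mid_hindbrain",
    "RELN",        150,   150,  150,    900,  150,  NA,
    "OTP",          20,    20,   20,     20, 1500,  "hypothalamus",
    "SIM1",         20,    20,   20,     20, 1300,  "hypothalamus",
    "GPC3",         60,    60,   60,     60, 1100,  "hypothalamus",
    "FOXP2",       110,   110,  110,    250, 1000,  NA,
    "SATB2",       110,    30,   30,     30,  900,  "hypothalamus",
    "RAX",          15,    15,   15,     15, 1200,  "hypothalamus",
    "PTGDS",        80,    80,   80,     80,  800,  "hypothalamus",
    "FOXG1",      3000,  3000, 3000,     25,  300,  NA,
    "SHH",          15,    60,  300,     40,  300,  NA,
    "PTCH1",       120,   120,  150,    120,  600,  NA,
    "GLI1",        100,   100,  130,    100,  130,  NA,
    "AXIN2",       150,   150,  150,    150,  150,  NA,
    "TNFRSF19",    200,   200,  200,    200,  200,  NA
  )
  # pan-neural and neuronal-differentiation genes, modestly higher in the
  # neurogenic ventral programs
  neuronal <- c("DCX", "TUBB3", "SYP", "DLG4", "SOX4", "SOX11", "MAPT",
                "NEFL", "STMN2", "GAP43")
  # progenitor / cell-state / signaling-pathway / lineage background genes
  flat <- c("VIM", "NES", "SOX2", "SOX1", "HES1", "HES5", "NOTCH1", "DLL1",
            "DLL3", "JAG1", "MKI67", "CCNB1", "CCND1", "TOP2A", "PCNA",
            "CASP3", "BCL2", "TP53", "CDKN1A", "CDKN2A", "FGF2", "FGF8",
            "SPRY2", "ETV4", "ETV5", "BMP4", "BMP7", "ID1", "ID3", "MSX1",
            "WNT3A", "WNT5A", "FZD3", "LRP6", "DKK1", "CTNNB1", "TCF7L2",
            "LEF1", "SMO", "GLI2", "SUFU", "HHIP", "NTRK2", "BDNF", "GRIN1",
            "GRIA1", "SLC1A3", "AQP4", "GFAP", "S100B", "OLIG1", "PDGFRA",
            "CSPG4", "CLDN5", "PECAM1", "COL1A1", "TWIST1", "SNAI2", "SOX17",
            "AFP", "T", "MIXL1", "POU5F1", "NANOG", "LIN28A", "DPPA4")
  base_rows <- dplyr::bind_rows(
    tibble::tibble(gene = neuronal, cortex = 800, LGE = 1300, MGE = 1300,
                   mid_hindbrain = 900, hypothalamus = 800, home = NA_character_),
    tibble::tibble(gene = flat, cortex = 400, LGE = 400, MGE = 400,
                   mid_hindbrain = 400, hypothalamus = 400, home = NA_character_)
  )
  # deterministic gene-specific abundance spread for the flat background
  ab <- 2^(seq(-2, 2.5, length.out = length(flat)))
  base_rows[base_rows$gene %in% flat, sim_regions] <-
    base_rows[base_rows$gene %in% flat, sim_regions] *
    ab[match(base_rows$gene[base_rows$gene %in% flat], flat)]

  all_rows <- dplyr::bind_rows(spec, base_rows)
  programs <- t(as.matrix(all_rows[, sim_regions]))
  colnames(programs) <- all_rows$gene
  rownames(programs) <- sim_regions
  list(programs = programs,
       marker_map = dplyr::filter(all_rows[, c("gene", "home")], !is.na(.data$home)),
       genes = all_rows$gene)
}

#' Build the codeset of the synthetic panel
#'
#' @param genes Endogenous gene symbols.
#' @param codeset_id Codeset name.
#' @return A [codeset_definition()] with 8 negative probes, 6 positive
#'   probes and the 7 standard housekeeping probes.
#' @export
sim_codeset <- function(genes, codeset_id = "SimCodeset1") {
  probes <- dplyr::bind_rows(
    tibble::tibble(probe_id = genes, gene_symbol = genes,
                   probe_class = "endogenous", pos_rank = NA_character_),
    tibble::tibble(probe_id = ncounter_housekeeping_genes,
                   gene_symbol = ncounter_housekeeping_genes,
                   probe_class = "housekeeping", pos_rank = NA_character_),
    tibble::tibble(probe_id = paste0("NEG_", LETTERS[1:8]),
                   gene_symbol = paste0("NEG_", LETTERS[1:8]),
                   probe_class = "negative", pos_rank = NA_character_),
    tibble::tibble(probe_id = paste0("POS_", LETTERS[1:6]),
                   gene_symbol = paste0("POS_", LETTERS[1:6]),
                   probe_class = "positive", pos_rank = LETTERS[1:6])
  )
  codeset_definition(probes, codeset_id, n_negative = 8, n_positive = 6,
                     housekeeping = ncounter_housekeeping_genes)
}

hk_means <- c(CLTC = 900, GAPDH = 3000, GUSB = 500, PPIA = 2500,
              RPLP1 = 4000, RPS15A = 2200, RPS9 = 1800)
pos_means <- c(POS_A = 12000, POS_B = 3000, POS_C = 750,
               POS_D = 190, POS_E = 47, POS_F = 12)

#' Ground-truth outcome label from mixture proportions
#'
#' Fixed thresholds on the generating mixture define the true outcome:
#' a mid/hindbrain fraction above `caudal_high` is highly caudalized, above
#' `caudal_partial` partially caudalized; otherwise an MGE fraction above
#' `ventral_high` is highly ventralized, above `ventral_partial` partially
#' ventralized; anything else (cortex/LGE/hypothalamus-dominated) is
#' dorsalized. Caudal thresholds sit higher than ventral ones because bulk
#' forebrain-marker dilution is sublinear in the caudal fraction.
#'
#' @param props Numeric matrix (samples x 5 programs) or vector of mixture
#'   proportions in program order cortex, LGE, MGE, mid_hindbrain,
#'   hypothalamus.
#' @param rule Named thresholds (see [sim_config()]).
#' @return Factor of [outcome_levels].
#' @export
label_from_proportions <- function(props, rule = sim_config()$label_rule) {
  if (is.null(dim(props))) props <- matrix(props, nrow = 1)
  mh <- props[, 4]
  mge <- props[, 3]
  lab <- dplyr::case_when(
    mh > rule[["caudal_high"]] ~ "highly_caudalized",
    mh > rule[["caudal_partial"]] ~ "partially_caudalized",
    mge > rule[["ventral_high"]] ~ "highly_ventralized",
    mge > rule[["ventral_partial"]] ~ "partially_ventralized",
    TRUE ~ "dorsalized"
  )
  factor(lab, levels = outcome_levels)
}

#' Default line panel of the synthetic study
#'
#' 27 PSC lines with 2-26 differentiations each (149 in total), covering
#' dorsal-prone, partially and highly ventral-prone, and caudal-prone lines,
#' plus one consistently highly caudal line - the per-line design of the
#' study the generator emulates. Latent signaling means (`wnt_mu`, `hh_mu`),
#' per-differentiation spread (`sig_sd`) and mid/hindbrain baseline bias
#' (`mh_bias`, `hypo_bias`) set each line's outcome tendency.
#'
#' @return Tibble, one row per line.
#' @export
default_line_panel <- function() {
  dorsal_n <- c(13, 7, 6, 5, 5, 4, 4, 4, 4, 3, 3, 3, 2, 2, 2, 2)
  panel <- dplyr::bind_rows(
    tibble::tibble(
      line = sprintf("iPSC%02d.1", 1:16), type = "dorsal",
      n_diffs = dorsal_n,
      wnt_mu = rep(c(0.7, 0.5, 0.6, 0.8), 4),
      hh_mu = rep(c(-0.7, -0.5, -0.6, -0.4), 4),
      sig_sd = 0.3, mh_bias = 0, lge_bias = 0,
      hypo_bias = rep(c(0, 0, 0.8, 0), 4)),
    tibble::tibble(
      line = c("iPSC22.1", "iPSC23.1"), type = "partial_ventral",
      n_diffs = c(26, 5),
      wnt_mu = -0.2, hh_mu = 0.45, sig_sd = 0.2, mh_bias = 0, lge_bias = 0,
      hypo_bias = 0),
    tibble::tibble(
      line = sprintf("iPSC%02d.1", c(1, 6, 14, 24, 25, 26) + 30), type = "high_ventral",
      n_diffs = c(11, 8, 6, 4, 3, 2),
      wnt_mu = -0.6, hh_mu = 1.25, sig_sd = 0.25, mh_bias = 0, lge_bias = 0,
      hypo_bias = 0),
    tibble::tibble(
      line = c("iPSC27.1", "iPSC28.1"), type = "partial_caudal",
      n_diffs = c(7, 5),
      wnt_mu = 0.9, hh_mu = -0.5, sig_sd = 0.25, mh_bias = 4.2, lge_bias = -1.5,
      hypo_bias = 0),
    tibble::tibble(
      line = "iPSC17.2", type = "high_caudal",
      n_diffs = 3,
      wnt_mu = 1.2, hh_mu = -0.6, sig_sd = 0.25, mh_bias = 6.1, lge_bias = -1.5,
      hypo_bias = 0)
  )
  panel$individual <- sub("\\..*$", "", panel$line)
  panel$genotype <- rep(c("control", "MAPT", "TS21", "control", "AD", "control"),
                        length.out = nrow(panel))
  panel$genotype[panel$line == "iPSC17.2"] <- "MAPT"
  panel
}

# Base mixture log-odds of a line: dorsal-leaning neutral state plus the
# line's regional biases.
line_base_eta <- function(mh_bias = 0, hypo_bias = 0, lge_bias = 0) {
  c(cortex = 1.6, LGE = 0.0 + lge_bias, MGE = -0.4,
    mid_hindbrain = -1.6 + mh_bias, hypothalamus = -1.4 + hypo_bias)
}

# Mixture proportions from latent signaling for one sample.
mixture_from_signaling <- function(wnt, hh, base_eta, link) {
  softmax(base_eta + link[, "wnt"] * wnt + link[, "hh"] * hh)
}

# Draw counts for one set of expected expression values via the
# quantile transform (so paired arms can share uniforms).
counts_from_mu <- function(u, mu, size) {
  qnbinom(u, size = size, mu = mu)
}

# Core generator: one sample per row of `samples` (needs columns sample_id,
# wnt, hh, base_eta columns are provided via mh_bias/hypo_bias, lane_z,
# plus uniform draw matrices). Returns counts matrix and truth tibble.
sim_core <- function(samples, cfg, u_dir, u_cnt) {
  pg <- default_programs()
  programs <- pg$programs
  genes <- pg$genes
  n <- nrow(samples)
  hk <- names(hk_means)
  neg <- paste0("NEG_", LETTERS[1:8])
  pos <- names(pos_means)
  probe_ids <- c(genes, hk, neg, pos)
  counts <- matrix(0L, n, length(probe_ids),
                   dimnames = list(samples$sample_id, probe_ids))
  props <- matrix(NA_real_, n, 5, dimnames = list(samples$sample_id, sim_regions))

  sc <- cfg$signaling_coef
  lge_bias <- if ("lge_bias" %in% names(samples)) samples$lge_bias else rep(0, n)
  for (i in seq_len(n)) {
    p <- mixture_from_signaling(samples$wnt[i], samples$hh[i],
                                line_base_eta(samples$mh_bias[i],
                                              samples$hypo_bias[i],
                                              lge_bias[i]),
                                cfg$link)
    alpha <- cfg$concentration * p
    g <- qgamma(u_dir[i, ], shape = alpha, rate = 1)
    if (sum(g) <= 0) abort("degenerate Dirichlet draw")
    p <- g / sum(g)
    props[i, ] <- p

    mu <- as.vector(p %*% programs)
    names(mu) <- genes
    mu["SHH"] <- mu["SHH"] * 2^(sc[["SHH"]] * samples$hh[i])
    mu["PTCH1"] <- mu["PTCH1"] * 2^(sc[["PTCH1"]] * samples$hh[i])
    mu["GLI1"] <- mu["GLI1"] * 2^(sc[["GLI1"]] * samples$hh[i])
    mu["GAS1"] <- mu["GAS1"] * 2^(sc[["GAS1"]] * samples$hh[i])
    mu["AXIN2"] <- mu["AXIN2"] * 2^(sc[["AXIN2"]] * samples$wnt[i])
    mu["TNFRSF19"] <- mu["TNFRSF19"] * 2^(sc[["TNFRSF19"]] * samples$wnt[i])

    lane <- exp(samples$lane_z[i] * cfg$lane_sd)
    mu_all <- c(mu, hk_means, setNames(rep(cfg$neg_mean, 8), neg), pos_means) * lane
    size_all <- c(rep(cfg$dispersion, length(genes)),
                  rep(cfg$control_dispersion, length(hk)),
                  rep(cfg$control_dispersion, length(neg)),
                  rep(cfg$control_dispersion, length(pos)))
    counts[i, ] <- counts_from_mu(u_cnt[i, ], mu_all, size_all)
  }
  lane_factor <- exp(samples$lane_z * cfg$lane_sd)
  truth <- tibble::tibble(
    sample_id = samples$sample_id,
    line = samples$line,
    wnt = samples$wnt, hh = samples$hh,
    lane_factor = lane_factor,
    treatment = samples$treatment %||% "none"
  )
  truth <- dplyr::bind_cols(truth,
                            tibble::as_tibble(props, .name_repair = ~paste0("p_", sim_regions)))
  truth$true_label <- label_from_proportions(props, cfg$label_rule)
  list(counts = counts, truth = truth, probe_ids = probe_ids)
}

n_sim_probes <- function() {
  length(default_programs()$genes) + 7 + 8 + 6
}

#' Simulate a panel dataset of differentiations
#'
#' Generates a full nCounter-like study: for each differentiation of each
#' line, latent Wnt/Hedgehog activities are drawn around the line's means,
#' mapped through a logistic link to Dirichlet mixture proportions over the
#' five regional programs, converted to expected expression, and observed as
#' lane-scaled negative-binomial counts together with negative, positive and
#' housekeeping control probes. The generator is a pure function of its
#' configuration and seed.
#'
#' @param lines Line panel tibble (see [default_line_panel()]).
#' @param cfg A [sim_config()].
#' @param seed Integer seed fixing every draw.
#' @return List of class `cortex_sim`: `counts` (tibble, `sample_id` +
#'   probes), `codeset`, `meta` (sample metadata), `truth` (per-sample
#'   mixture proportions, latent signaling, lane factor and true label).
#' @export
simulate_dataset <- function(lines = default_line_panel(),
                             cfg = sim_config(), seed = 1) {
  samples <- tidyr::uncount(lines, .data$n_diffs, .remove = FALSE)
  n <- nrow(samples)
  samples$sample_id <- sprintf("UIN%03d", seq_len(n))

  with_seed(seed, {
    z <- matrix(rnorm(n * 3), n, 3)
    u_dir <- matrix(stats::runif(n * 5), n, 5)
    u_cnt <- matrix(stats::runif(n * n_sim_probes()), n, n_sim_probes())
  })
  samples$wnt <- samples$wnt_mu + samples$sig_sd * z[, 1]
  samples$hh <- samples$hh_mu + samples$sig_sd * z[, 2]
  samples$lane_z <- z[, 3]
  samples$treatment <- "none"

  core <- sim_core(samples, cfg, u_dir, u_cnt)
  meta <- tibble::tibble(
    sample_id = samples$sample_id,
    uin = samples$sample_id,
    line = samples$line,
    individual = samples$individual %||% samples$line,
    genotype = samples$genotype %||% "control",
    stage = "early",
    dpi = 30 + (seq_len(n) %% 11),
    treatment = "none",
    operator = sprintf("op%d", 1 + (seq_len(n) %% 7))
  )
  codeset <- sim_codeset(default_programs()$genes)
  structure(list(
    counts = structure(as_sample_tbl(core$counts),
                       codeset_id = codeset_id(codeset),
                       probe_class = probe_classes(codeset)[core$probe_ids]),
    codeset = codeset,
    meta = meta,
    truth = core$truth
  ), class = "cortex_sim")
}

#' @export
print.cortex_sim <- function(x, ...) {
  cat(sprintf("<simulated dataset: %d samples x %d probes, %d lines>\n",
              nrow(x$counts), ncol(x$counts) - 1L,
              length(unique(x$meta$line))))
  invisible(x)
}

#' Simulate a differentiation time course
#'
#' Gene-expression trajectories for dorsal-prone and ventral-prone line
#' groups sampled at fixed days post-induction. Latent signaling (and hence
#' regional mixture and pathway readouts) is identical across groups before
#' `divergence_dpi` and ramps apart afterwards, emulating divergence of
#' dorsoventral markers and of Wnt/Hedgehog readouts from that time point.
#'
#' @param lines Tibble with columns `line`, `group` (`"dorsal"` or
#'   `"ventral"`), `n_diffs`. The default mirrors one dorsal-prone line (2
#'   differentiations) against five ventral-prone lines (11).
#' @param timepoints Days post-induction at which each differentiation is
#'   sampled.
#' @param divergence_dpi First dpi at which the groups differ; `Inf` gives a
#'   null dataset with indistinguishable groups.
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @return A `cortex_sim` list (counts, codeset, meta with `dpi`, truth).
#' @export
simulate_timecourse <- function(lines = tibble::tibble(
                                  line = c("D21", "V01", "V02", "V03", "V04", "V05"),
                                  group = c("dorsal", rep("ventral", 5)),
                                  n_diffs = c(2, 3, 2, 2, 2, 2)),
                                timepoints = c(0, 4, 7, 12, 17, 35),
                                divergence_dpi = 17,
                                cfg = sim_config(), seed = 1) {
  if (is.finite(divergence_dpi) &&
      divergence_dpi > max(timepoints)) {
    abort("divergence_dpi must lie within the timepoint range (or be Inf)")
  }
  diffs <- tidyr::uncount(lines, .data$n_diffs, .remove = FALSE)
  diffs$uin <- sprintf("TC%02d", seq_len(nrow(diffs)))
  samples <- tidyr::crossing(diffs, dpi = timepoints)
  n <- nrow(samples)
  samples$sample_id <- sprintf("%s_d%02d", samples$uin, samples$dpi)

  with_seed(seed, {
    z_diff <- matrix(rnorm(nrow(diffs) * 2), nrow(diffs), 2)
    z_lane <- rnorm(n)
    u_dir <- matrix(stats::runif(n * 5), n, 5)
    u_cnt <- matrix(stats::runif(n * n_sim_probes()), n, n_sim_probes())
  })

  # group-level latent targets after divergence
  target <- list(dorsal = c(wnt = 1.5, hh = -1.0),
                 ventral = c(wnt = -1.0, hh = 1.5))
  ramp <- function(t) {
    if (!is.finite(divergence_dpi)) return(rep(0, length(t)))
    r <- ifelse(t < divergence_dpi, 0,
                0.5 + 0.5 * (t - divergence_dpi) /
                  max(max(timepoints) - divergence_dpi, 1))
    pmin(r, 1)
  }
  idx <- match(samples$uin, diffs$uin)
  r <- ramp(samples$dpi)
  tg <- do.call(rbind, target[samples$group])
  samples$wnt <- r * tg[, "wnt"] + 0.25 * z_diff[idx, 1]
  samples$hh <- r * tg[, "hh"] + 0.25 * z_diff[idx, 2]
  samples$lane_z <- z_lane
  samples$mh_bias <- 0
  samples$hypo_bias <- 0
  samples$treatment <- "none"

  core <- sim_core(samples, cfg, u_dir, u_cnt)
  meta <- tibble::tibble(
    sample_id = samples$sample_id,
    uin = samples$uin,
    line = samples$line,
    individual = samples$line,
    genotype = "control",
    stage = "timecourse",
    dpi = samples$dpi,
    treatment = "none",
    operator = "op1"
  )
  codeset <- sim_codeset(default_programs()$genes)
  truth <- core$truth
  truth$group <- samples$group
  structure(list(
    counts = structure(as_sample_tbl(core$counts),
                       codeset_id = codeset_id(codeset),
                       probe_class = probe_classes(codeset)[core$probe_ids]),
    codeset = codeset, meta = meta, truth = truth,
    grouping = lines[, c("line", "group")]
  ), class = "cortex_sim")
}

#' Simulate a paired treatment experiment
#'
#' Generates treated and control arms of the same differentiations. Both
#' arms share every random draw (latent noise, mixture and count uniforms);
#' the treated arm's latent signaling is shifted by the effect before the
#' mixture draw, so the contrast between arms isolates the treatment effect
#' and a zero-magnitude effect reproduces the control arm exactly. Emulates
#' window-restricted small-molecule Wnt/Hedgehog manipulations profiled at a
#' fixed endpoint.
#'
#' @param lines Tibble `line`, `n_diffs`, `wnt_mu`, `hh_mu`, `sig_sd` of the
#'   lines treated; the default is four ventral-prone lines with 7
#'   differentiations in total.
#' @param effect One of `"wnt_up"`, `"wnt_down"`, `"hh_up"`, `"hh_down"`.
#' @param magnitude Size of the latent shift (> 0).
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @return List of class `cortex_treatment`: `control` and `treated`
#'   (each a `cortex_sim`-like list), `effect`, `magnitude`, `pairs`
#'   (tibble of control/treated sample ids per differentiation).
#' @export
simulate_treatment <- function(lines = tibble::tibble(
                                 line = c("V01", "V02", "V03", "V22"),
                                 n_diffs = c(2, 2, 1, 2),
                                 wnt_mu = -0.8, hh_mu = 1.3, sig_sd = 0.3),
                               effect = c("wnt_up", "wnt_down", "hh_up", "hh_down"),
                               magnitude = 2,
                               cfg = sim_config(), seed = 1) {
  effect <- match.arg(effect)
  if (magnitude < 0) abort("magnitude must be >= 0")
  samples <- tidyr::uncount(lines, .data$n_diffs, .remove = FALSE)
  n <- nrow(samples)
  samples$uin <- sprintf("TR%02d", seq_len(n))

  with_seed(seed, {
    z <- matrix(rnorm(n * 3), n, 3)
    u_dir <- matrix(stats::runif(n * 5), n, 5)
    u_cnt <- matrix(stats::runif(n * n_sim_probes()), n, n_sim_probes())
  })
  base <- samples
  base$wnt <- base$wnt_mu + base$sig_sd * z[, 1]
  base$hh <- base$hh_mu + base$sig_sd * z[, 2]
  base$lane_z <- z[, 3]
  base$mh_bias <- 0
  base$hypo_bias <- 0

  shift <- switch(effect,
                  wnt_up = c(magnitude, 0), wnt_down = c(-magnitude, 0),
                  hh_up = c(0, magnitude), hh_down = c(0, -magnitude))

  make_arm <- function(wnt_shift, hh_shift, suffix, treatment) {
    arm <- base
    arm$wnt <- arm$wnt + wnt_shift
    arm$hh <- arm$hh + hh_shift
    arm$sample_id <- paste0(arm$uin, suffix)
    arm$treatment <- treatment
    core <- sim_core(arm, cfg, u_dir, u_cnt)
    codeset <- sim_codeset(default_programs()$genes)
    meta <- tibble::tibble(
      sample_id = arm$sample_id, uin = arm$uin, line = arm$line,
      individual = arm$line, genotype = "control", stage = "early",
      dpi = 35, treatment = treatment, operator = "op1")
    list(counts = structure(as_sample_tbl(core$counts),
                            codeset_id = codeset_id(codeset),
                            probe_class = probe_classes(codeset)[core$probe_ids]),
         codeset = codeset, meta = meta, truth = core$truth)
  }

  control <- make_arm(0, 0, "_C", "vehicle")
  treated <- make_arm(shift[1], shift[2], "_T", effect)
  structure(list(control = control, treated = treated,
                 effect = effect, magnitude = magnitude,
                 pairs = tibble::tibble(uin = base$uin,
                                        control = paste0(base$uin, "_C"),
                                        treated = paste0(base$uin, "_T"))),
            class = "cortex_treatment")
}

#' Generator-implied classifier thresholds
#'
#' The marker cutoffs implied by the synthetic study design. For each line
#' type the noise-free expected mixture is computed from the line's mean
#' latent signaling and the mixture link; each cutoff is then the expected
#' log2 marker expression (program-weighted means minus the
#' negative-control background) at the exact ground-truth label boundary,
#' obtained by interpolating between the two adjacent line types in latent
#' parameter space (signaling means and regional biases) to the point where
#' the mixture hits the boundary proportion of
#' [label_from_proportions()]. DLX5 does not
#' separate partially from highly caudalized outcomes (both have near-zero
#' LGE content), so the very-low DLX5 cutoff equals the low one and the
#' highly-caudal call is driven by FOXG1.
#'
#' @param cfg A [sim_config()].
#' @return A [threshold_set()] with `provenance = "config"`.
#' @export
default_thresholds <- function(cfg = sim_config()) {
  panel <- default_line_panel()
  pg <- default_programs()
  markers <- c("FOXG1", "DLX5", "NKX2-1", "PAX6")
  # mean latent parameters (wnt_mu, hh_mu, mh_bias, hypo_bias) per line type
  type_latent <- function(type) {
    rows <- dplyr::filter(panel, .data$type == !!type)
    colMeans(rows[, c("wnt_mu", "hh_mu", "mh_bias", "hypo_bias", "lge_bias")])
  }
  latents <- vapply(c("dorsal", "partial_ventral", "high_ventral",
                      "partial_caudal", "high_caudal"),
                    type_latent, numeric(5))
  mix_at <- function(l) {
    mixture_from_signaling(l[["wnt_mu"]], l[["hh_mu"]],
                           line_base_eta(l[["mh_bias"]], l[["hypo_bias"]],
                                         l[["lge_bias"]]),
                           cfg$link)
  }
  # latent point between two line types where mixture component `comp`
  # equals the label-rule boundary value
  boundary_mix <- function(from, to, comp, value) {
    a <- latents[, from]
    b <- latents[, to]
    f <- function(t) mix_at(a + t * (b - a))[comp] - value
    t <- stats::uniroot(f, c(0, 1), tol = 1e-8)$root
    mix_at(a + t * (b - a))
  }
  marker_at <- function(p) {
    log2(pmax(as.vector(p %*% pg$programs[, markers]) - cfg$neg_mean, 1))
  }
  rule <- cfg$label_rule
  mh <- "mid_hindbrain"; mge <- "MGE"
  e_caudal <- marker_at(boundary_mix("dorsal", "partial_caudal", mh,
                                     rule[["caudal_partial"]]))
  e_hicaudal <- marker_at(boundary_mix("partial_caudal", "high_caudal", mh,
                                       rule[["caudal_high"]]))
  e_ventral <- marker_at(boundary_mix("dorsal", "partial_ventral", mge,
                                      rule[["ventral_partial"]]))
  e_hiventral <- marker_at(boundary_mix("partial_ventral", "high_ventral", mge,
                                        rule[["ventral_high"]]))
  names(e_caudal) <- names(e_hicaudal) <- names(e_ventral) <-
    names(e_hiventral) <- markers
  threshold_set(
    foxg1_low = e_caudal[["FOXG1"]],
    dlx5_low = e_caudal[["DLX5"]],
    foxg1_verylow = e_hicaudal[["FOXG1"]],
    dlx5_verylow = e_caudal[["DLX5"]],
    nkx21_high = e_ventral[["NKX2-1"]],
    pax6_low = e_hiventral[["PAX6"]],
    provenance = "config")
}

# Region gene sets of the reference-atlas fixture: the selective-gene
# partition the fixture is constructed to carry.
atlas_fixture_assignments <- function() {
  tibble::tibble(
    gene = c("GPC3", "FOXP2", "PTCH1", "SATB2", "RAX",
             "LHX6", "OLIG2", "DLX1", "LHX8", "GSC",
             "MAP2", "FOXG1", "TBR1", "SLC17A7", "GLI3", "EOMES", "GAS1",
             "EMX1", "NEUROG2", "EMX2",
             "DDC", "NR4A2", "OTX2", "EN2",
             "HOXB2", "NKX6-1", "HOXA2"),
    region = c(rep("RSP", 5), rep("subpallium", 5), rep("pallium", 10),
               rep("midbrain", 4), rep("hindbrain", 3))
  )
}

#' Construct a synthetic atlas expression-energy fixture
#'
#' Builds a regions-by-genes energy matrix in the image of an embryonic
#' developing-brain atlas export: every gene shares a correlated baseline
#' profile across regions, and each region-selective gene (27 genes over
#' RSP, pallium, subpallium, midbrain and hindbrain) is elevated `fold`-fold
#' in its home region. Optionally includes two derived regions
#' (diencephalon-like blends of the others) that carry no selective genes
#' and are therefore removed by the pruning step of
#' [select_region_specific_genes()]. This is a synthetic stand-in
#' constructed for testing; it is not downloaded atlas data.
#'
#' @param seed Integer seed for the baseline abundances.
#' @param fold Home-region elevation of selective genes.
#' @param include_prunable Include the two prunable blend regions.
#' @param age_label Age label stored on the profile set.
#' @return A [regional_profiles()] set; attribute `assignments` holds the
#'   constructed gene-to-region partition.
#' @export
make_atlas_fixture <- function(seed = 1, fold = 40, include_prunable = TRUE,
                               age_label = "E11.5") {
  assign <- atlas_fixture_assignments()
  pg <- default_programs()
  background <- setdiff(pg$genes, assign$gene)
  genes <- c(assign$gene, background)
  regions <- c("RSP", "pallium", "subpallium", "midbrain", "hindbrain")

  with_seed(seed, {
    base <- 2^stats::runif(length(genes), 2, 7)
    jitter <- matrix(exp(rnorm(length(regions) * length(genes), 0, 0.1)),
                     length(regions), length(genes))
    blend_jitter <- matrix(exp(rnorm(2 * length(genes), 0, 0.05)),
                           2, length(genes))
  })
  energy <- sweep(jitter, 2, base, `*`)
  dimnames(energy) <- list(regions, genes)
  for (i in seq_len(nrow(assign))) {
    energy[assign$region[i], assign$gene[i]] <-
      energy[assign$region[i], assign$gene[i]] * fold
  }
  if (include_prunable) {
    blend <- exp(rbind(
      0.4 * log(energy["RSP", ]) + 0.3 * log(energy["pallium", ]) +
        0.3 * log(energy["midbrain", ]),
      0.5 * log(energy["RSP", ]) + 0.25 * log(energy["subpallium", ]) +
        0.25 * log(energy["hindbrain", ])
    ) + log(blend_jitter))
    rownames(blend) <- c("diencephalon", "peduncular_hypothalamus")
    energy <- rbind(energy, blend)
  }
  out <- regional_profiles(as_sample_tbl(energy, id_col = "region"), age_label)
  attr(out, "assignments") <- assign
  out
}
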