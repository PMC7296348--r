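# Small builders shared across tests.

# Toy codeset: `n_endo` endogenous genes plus 2 negative, 2 positive and 2
# housekeeping probes (control-probe counts are configurable where a test
# needs the full 8/6/7 layout, via sim_codeset()).
toy_codeset <- function(n_endo = 2) {
  genes <- paste0("G", seq_len(n_endo))
  codeset_definition(
    tibble::tibble(
      probe_id = c(genes, "NEG1", "NEG2", "POS1", "POS2", "HK1", "HK2"),
      gene_symbol = c(genes, "NEG1", "NEG2", "POS1", "POS2", "HK1", "HK2"),
      probe_class = c(rep("endogenous", n_endo), "negative", "negative",
                      "positive", "positive", "housekeeping", "housekeeping")
    ),
    codeset_id = "toy")
}

toy_counts <- function(m, codeset) {
  stopifnot(ncol(m) == nrow(codeset))
  if (all(m == round(m))) storage.mode(m) <- "integer"
  colnames(m) <- codeset$probe_id
  out <- tibble::as_tibble(m)
  tibble::add_column(out, sample_id = paste0("S", seq_len(nrow(m))),
                     .before = 1)
}

# Random integer count tibble over a codeset, with class-appropriate
# magnitudes (low negatives, abundant controls).
random_counts <- function(codeset, n_samples = 4) {
  lambda <- c(endogenous = 500, negative = 5, positive = 300,
              housekeeping = 400)[codeset$probe_class]
  m <- t(vapply(seq_len(n_samples),
                function(i) rpois(nrow(codeset), lambda = lambda),
                numeric(nrow(codeset))))
  toy_counts(m, codeset)
}

# Expression tibble straight from a matrix.
expr_from_matrix <- function(m, scale = "log2") {
  if (is.null(rownames(m))) rownames(m) <- paste0("S", seq_len(nrow(m)))
  tbl <- tibble::as_tibble(m)
  tbl <- tibble::add_column(tbl, sample_id = rownames(m), .before = 1)
  new_expr(tbl, scale = scale)
}

quiet <- function(expr) suppressWarnings(suppressMessages(expr))

# Normalize -> filter -> log2 on a simulated dataset.
sim_log2_expr <- function(sim, cfg = normalization_config()) {
  quiet(log2_transform(filter_expressed(
    normalize_dataset(sim$counts, sim$codeset, cfg),
    cfg$expression_floor), cfg$log_floor))
}

# Plain value comparison: drop every attribute except names/row.names.
strip_tbl <- function(x) {
  x <- as.data.frame(x)
  keep <- c("names", "row.names", "class")
  for (a in setdiff(names(attributes(x)), keep)) attr(x, a) <- NULL
  class(x) <- "data.frame"
  x
}
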