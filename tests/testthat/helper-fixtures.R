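# Shared fixtures, built in code. The small simulation is memoised per option
# set so independent test files do not pay for it repeatedly.

.fixture_env <- new.env(parent = emptyenv())

small_sim <- function(seed = 4) {
  key <- paste0("sim", seed)
  if (is.null(.fixture_env[[key]])) {
    cfg <- sim_config(n_genes = 500,
                      n_cells_per_group = c(WT6m = 40, WT24m = 30,
                                            XO4neg = 30, XO4pos = 60),
                      seed = seed)
    .fixture_env[[key]] <- simulate_sc_counts(cfg)
  }
  .fixture_env[[key]]
}

small_norm <- function(seed = 4) {
  key <- paste0("norm", seed)
  if (is.null(.fixture_env[[key]])) {
    f <- filter_cells_and_genes(small_sim(seed)$counts)
    .fixture_env[[key]] <- normalize_log_cpm(f)
  }
  .fixture_env[[key]]
}

# dense matrix -> glx_norm with made-up ids
as_norm <- function(v, groups = NULL) {
  v <- as.matrix(v)
  if (is.null(rownames(v))) rownames(v) <- sprintf("g%04d", seq_len(nrow(v)))
  if (is.null(colnames(v))) colnames(v) <- sprintf("c%04d", seq_len(ncol(v)))
  meta <- data.frame(cell_id = colnames(v), stringsAsFactors = FALSE)
  if (!is.null(groups)) meta$group <- groups
  glx_norm(v - min(v), rep(1, ncol(v)), meta)
}

# reference Benjamini-Hochberg step-up, written independently of p.adjust
bh_reference <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}
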