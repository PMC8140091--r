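#' Simulation configuration for the two-axis microglia count generator
#'
#' The generator emulates four FACS-sorted microglial populations -- adult
#' wild-type (WT6m), aged wild-type (WT24m), and
#' plaque-non-phagocytic (XO4neg) / plaque-phagocytic (XO4pos) 5xFAD microglia
#' -- driven by two latent axes: a continuous ageing value `a` (Gaussian per
#' group) and a switch-like phagocytosis state `f` (Bernoulli per group).
#' Counts are negative binomial with a log-linear mean,
#' `mu_gj = s_j * mu_g * 2^(a_j * beta_g_age + f_j * beta_g_phago)`,
#' gamma-distributed baseline gene means, lognormal library sizes and a
#' dispersion mean trend `phi_g = a0 + a1 / mu_g`.
#'
#' @param n_genes Number of genes.
#' @param n_cells_per_group Named integer vector, cells per group. Defaults
#'   to typical sorted-population sizes (243, 121, 95, 434).
#' @param groups Ordered group labels.
#' @param ageing_params Per-group `c(mean, sd)` of the latent ageing value;
#'   list named by group.
#' @param phagocytosis_params Per-group Bernoulli probability of the
#'   phagocytosis switch; named numeric vector.
#' @param n_ageing_genes,n_phago_genes Numbers of genes carrying each axis
#'   effect (sets are drawn independently and may overlap).
#' @param lfc_scale_age,lfc_scale_phago Log2-fold-change magnitude scales.
#' @param regulons List of `list(tf = <gene index>, n_targets, coupling)`;
#'   each regulon's targets share a latent activity `coupling * f_j` that
#'   multiplies their means (on the log2 scale) in phagocytosing cells.
#' @param libsize_lognormal `c(meanlog, sdlog)` of the relative library size.
#' @param gene_mean_gamma `c(shape, rate)` of baseline gene means.
#' @param dispersion `c(a0, a1)` of the trend `phi = a0 + a1/mu`.
#' @param mito_gene_fraction Fraction of genes flagged mitochondrial
#'   (ids prefixed `mt-`).
#' @param mito_inflate `c(prop, factor)`: a fraction `prop` of cells gets its
#'   mitochondrial gene means multiplied by `factor`, planting QC failures.
#' @param seed Integer seed.
#' @param gene_params Optional `data.frame(gene_id, mu, phi, beta_age,
#'   beta_phago)` overriding the per-gene draws (used to check order
#'   independence and to replay simulations).
#' @return A list of class `glx_sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       n_cells_per_group = c(WT6m = 243, WT24m = 121,
                                             XO4neg = 95, XO4pos = 434),
                       groups = names(n_cells_per_group),
                       ageing_params = list(WT6m = c(0, 0.2), WT24m = c(1, 0.2),
                                            XO4neg = c(0.5, 0.3),
                                            XO4pos = c(0.5, 0.3)),
                       phagocytosis_params = c(WT6m = 0, WT24m = 0,
                                               XO4neg = 0, XO4pos = 1),
                       n_ageing_genes = 200, n_phago_genes = 300,
                       lfc_scale_age = 1, lfc_scale_phago = 2,
                       regulons = list(list(tf = 1L, n_targets = 100L,
                                            coupling = 1)),
                       libsize_lognormal = c(meanlog = log(5000), sdlog = 0.35),
                       gene_mean_gamma = c(shape = 0.5, rate = 1),
                       dispersion = c(a0 = 0.1, a1 = 0.5),
                       mito_gene_fraction = 0.05,
                       mito_inflate = c(prop = 0.05, factor = 10),
                       seed = 1L, gene_params = NULL) {
  cfg <- list(n_genes = .assert_scalar_count(n_genes, "n_genes"),
              n_cells_per_group = n_cells_per_group, groups = groups,
              ageing_params = ageing_params,
              phagocytosis_params = phagocytosis_params,
              n_ageing_genes = n_ageing_genes, n_phago_genes = n_phago_genes,
              lfc_scale_age = lfc_scale_age, lfc_scale_phago = lfc_scale_phago,
              regulons = regulons, libsize_lognormal = libsize_lognormal,
              gene_mean_gamma = gene_mean_gamma, dispersion = dispersion,
              mito_gene_fraction = mito_gene_fraction,
              mito_inflate = mito_inflate, seed = as.integer(seed),
              gene_params = gene_params)
  validate_sim_config(cfg)
  structure(cfg, class = "glx_sim_config")
}

validate_sim_config <- function(cfg) {
  if (anyDuplicated(cfg$groups)) stop("group labels must be unique")
  if (!setequal(names(cfg$n_cells_per_group), cfg$groups))
    stop("n_cells_per_group must be named by the group labels")
  if (any(cfg$n_cells_per_group < 1)) stop("all group sizes must be positive")
  p <- cfg$phagocytosis_params[cfg$groups]
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("phagocytosis probabilities must lie in [0, 1] for every group")
  if (any(cfg$dispersion < 0) || sum(cfg$dispersion) <= 0)
    stop("dispersion trend must be positive")
  for (r in cfg$regulons) {
    tf <- r$tf
    if (tf < 1 || tf > cfg$n_genes)
      stop("regulon TF index out of range: ", tf)
  }
  invisible(cfg)
}

# Per-gene parameter table: either taken verbatim from cfg$gene_params or
# drawn once from the configured distributions. All draws here depend only on
# the seed, never on gene order downstream.
.sim_gene_params <- function(cfg) {
  if (!is.null(cfg$gene_params)) {
    gp <- as.data.frame(cfg$gene_params)
    stopifnot(all(c("gene_id", "mu", "phi", "beta_age", "beta_phago") %in% names(gp)))
    if (is.null(gp$regulon)) gp$regulon <- NA_character_
    if (is.null(gp$is_mito)) gp$is_mito <- grepl("^mt-", gp$gene_id)
    return(gp)
  }
  G <- cfg$n_genes
  n_mito <- ceiling(cfg$mito_gene_fraction * G)
  ids <- sprintf("gene%05d", seq_len(G))
  if (n_mito > 0) {
    mito_idx <- seq_len(n_mito)
    ids[mito_idx] <- sprintf("mt-gene%05d", mito_idx)
  }
  mu <- stats::rgamma(G, shape = cfg$gene_mean_gamma[["shape"]],
                      rate = cfg$gene_mean_gamma[["rate"]]) + 1e-4
  # dispersion trend evaluated at the gene's expected baseline count
  mcount <- mu / sum(mu) * exp(cfg$libsize_lognormal[["meanlog"]] +
                                 cfg$libsize_lognormal[["sdlog"]]^2 / 2)
  phi <- cfg$dispersion[["a0"]] + cfg$dispersion[["a1"]] / mcount
  age_idx <- sample.int(G, min(cfg$n_ageing_genes, G))
  phago_idx <- sample.int(G, min(cfg$n_phago_genes, G))
  beta_age <- beta_phago <- numeric(G)
  beta_age[age_idx] <- cfg$lfc_scale_age *
    sample(c(-1, 1), length(age_idx), TRUE) * stats::runif(length(age_idx), 0.5, 1.5)
  beta_phago[phago_idx] <- cfg$lfc_scale_phago *
    sample(c(-1, 1), length(phago_idx), TRUE) * stats::runif(length(phago_idx), 0.5, 1.5)
  gp <- data.frame(gene_id = ids, mu = mu, phi = phi,
                   beta_age = beta_age, beta_phago = beta_phago,
                   regulon = NA_character_, stringsAsFactors = FALSE)
  for (r in cfg$regulons) {
    pool <- setdiff(seq_len(G), r$tf)
    tgt <- sample(pool, min(r$n_targets, length(pool)))
    gp$regulon[tgt] <- gp$gene_id[r$tf]
    attr(gp, "regulon_coupling") <-
      c(attr(gp, "regulon_coupling"),
        stats::setNames(r$coupling, gp$gene_id[r$tf]))
  }
  gp$is_mito <- grepl("^mt-", gp$gene_id)
  gp
}

#' Simulate a single-cell count matrix with two latent axes and ground truth
#'
#' Per-cell latents are drawn first (ageing value `a` per group Gaussian,
#' phagocytosis switch `f` per group Bernoulli, lognormal relative library
#' size); counts are then drawn gene by gene under a gene-id-keyed RNG
#' substream, so results are reproducible and independent of gene order.
#'
#' @param cfg `glx_sim_config`.
#' @return `list(counts = glx_counts, truth)` where `truth` holds `cells`
#'   (cell_id, group, a, f, mito_high) and `genes` (gene_id, is_ageing_gene,
#'   is_phago_gene, beta_age, beta_phago, regulon, is_mito).
#' @export
simulate_sc_counts <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  gp <- .sim_gene_params(cfg)
  G <- nrow(gp)
  groups <- rep(cfg$groups, times = cfg$n_cells_per_group[cfg$groups])
  n <- length(groups)
  cell_ids <- sprintf("cell%05d", seq_len(n))
  a <- vapply(groups, function(g) {
    pr <- cfg$ageing_params[[g]]
    stats::rnorm(1, pr[1], pr[2])
  }, numeric(1))
  f <- stats::rbinom(n, 1, cfg$phagocytosis_params[groups])
  # library size IS the lognormal draw: relative expression sums to 1, so the
  # expected total count of cell j equals s_j
  s <- stats::rlnorm(n, cfg$libsize_lognormal[["meanlog"]],
                     cfg$libsize_lognormal[["sdlog"]])
  mito_high <- stats::runif(n) < cfg$mito_inflate[["prop"]]

  coupling <- attr(gp, "regulon_coupling")
  log2fc <- outer(gp$beta_age, a) + outer(gp$beta_phago, f)
  reg_rows <- which(!is.na(gp$regulon))
  if (length(reg_rows)) {
    w <- coupling[gp$regulon[reg_rows]]
    log2fc[reg_rows, ] <- log2fc[reg_rows, ] +
      outer(w, f)  # shared latent activity in phagocytosing cells
  }
  mu <- (gp$mu / sum(gp$mu)) * 2^log2fc
  mu <- sweep(mu, 2, s, `*`)
  if (any(mito_high) && any(gp$is_mito))
    mu[gp$is_mito, mito_high] <- mu[gp$is_mito, mito_high] *
      cfg$mito_inflate[["factor"]]

  counts <- matrix(0L, G, n)
  gseed <- .hash_string(paste0(cfg$seed, ":", gp$gene_id))
  for (g in seq_len(G)) {
    set.seed(gseed[g])
    counts[g, ] <- stats::rnbinom(n, size = 1 / gp$phi[g], mu = mu[g, ])
  }
  meta <- data.frame(cell_id = cell_ids, group = groups,
                     stringsAsFactors = FALSE)
  truth <- list(
    cells = data.frame(cell_id = cell_ids, group = groups, a = a, f = f,
                       mito_high = mito_high, stringsAsFactors = FALSE),
    genes = data.frame(gene_id = gp$gene_id,
                       is_ageing_gene = gp$beta_age != 0,
                       is_phago_gene = gp$beta_phago != 0,
                       beta_age = gp$beta_age, beta_phago = gp$beta_phago,
                       regulon = gp$regulon, is_mito = gp$is_mito,
                       stringsAsFactors = FALSE))
  list(counts = glx_counts(counts, gp$gene_id, cell_ids, meta), truth = truth)
}

#' Simulate a bulk RNA-seq count table from a sample design
#'
#' Counts follow a negative binomial log-link linear model on the design
#' matrix of the supplied covariates; the truth records which genes carry a
#' nonzero coefficient for each covariate.
#'
#' @param design `data.frame` of sample covariates (e.g. XO4, age, region,
#'   batch, genotype, sex); factors and numerics both allowed. At least two
#'   samples per used factor level.
#' @param effects Numeric matrix, genes x non-intercept columns of
#'   `model.matrix(~ ., design)`, of log2-scale coefficients. Column names
#'   must match the model matrix. Missing columns are taken as zero.
#' @param cfg `glx_sim_config` supplying gene means, dispersion trend,
#'   library sizes and the seed.
#' @return `list(counts = glx_counts, truth)`; `truth$genes` holds the full
#'   coefficient matrix and per-covariate nonzero flags.
#' @export
simulate_bulk_counts <- function(design, effects, cfg) {
  design <- as.data.frame(design)
  X <- stats::model.matrix(~ ., data = design)
  if (qr(X)$rank < ncol(X))
    stop("design_rank_deficient: the covariate design matrix is rank deficient")
  lev_counts <- lapply(design, function(col)
    if (is.character(col) || is.factor(col)) table(col) else NULL)
  for (nm in names(lev_counts))
    if (!is.null(lev_counts[[nm]]) && any(lev_counts[[nm]] < 2))
      stop("each level of covariate '", nm, "' needs >= 2 samples")

  set.seed(cfg$seed)
  gp <- .sim_gene_params(cfg)
  G <- nrow(gp)
  terms <- setdiff(colnames(X), "(Intercept)")
  B <- matrix(0, G, length(terms), dimnames = list(gp$gene_id, terms))
  if (!is.null(effects)) {
    effects <- as.matrix(effects)
    unknown <- setdiff(colnames(effects), terms)
    if (length(unknown))
      stop("effects columns not in the design matrix: ",
           paste(unknown, collapse = ", "))
    B[, colnames(effects)] <- effects
  }
  n <- nrow(X)
  s <- stats::rlnorm(n, cfg$libsize_lognormal[["meanlog"]],
                     cfg$libsize_lognormal[["sdlog"]])
  log2mu <- B %*% t(X[, terms, drop = FALSE])
  mu <- sweep((gp$mu / sum(gp$mu)) * 2^log2mu, 2, s, `*`)
  counts <- matrix(0L, G, n)
  gseed <- .hash_string(paste0(cfg$seed, ":bulk:", gp$gene_id))
  for (g in seq_len(G)) {
    set.seed(gseed[g])
    counts[g, ] <- stats::rnbinom(n, size = 1 / gp$phi[g], mu = mu[g, ])
  }
  sample_ids <- if (!is.null(rownames(design)) &&
                    !identical(rownames(design), as.character(seq_len(n))))
    rownames(design) else sprintf("sample%03d", seq_len(n))
  meta <- cbind(data.frame(cell_id = sample_ids, stringsAsFactors = FALSE),
                design)
  nonzero <- lapply(names(design), function(cov) {
    cols <- grep(paste0("^", cov), terms, value = TRUE)
    rowSums(abs(B[, cols, drop = FALSE])) > 0
  })
  names(nonzero) <- names(design)
  truth <- list(genes = data.frame(gene_id = gp$gene_id,
                                   as.data.frame(nonzero),
                                   stringsAsFactors = FALSE),
                coefficients = B, design = design)
  list(counts = glx_counts(counts, gp$gene_id, sample_ids, meta),
       truth = truth)
}

#' Write a simulation (counts + truth) to disk
#'
#' Counts go out as a Matrix Market bundle; the per-cell and per-gene truth as
#' CSV.
#' @param sim Result of [simulate_sc_counts()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  write_counts_mtx(sim$counts, dir)
  if (!is.null(sim$truth$cells))
    utils::write.csv(sim$truth$cells, file.path(dir, "truth_cells.csv"),
                     row.names = FALSE)
  utils::write.csv(sim$truth$genes, file.path(dir, "truth_genes.csv"),
                   row.names = FALSE)
  invisible(dir)
}
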