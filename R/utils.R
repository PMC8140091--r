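# Internal helpers shared across modules.

# Deterministic per-stage seed fan-out: one global seed yields a distinct,
# reproducible seed for every named pipeline stage, so that toggling a stage
# on/off never shifts the random stream of the others.
.glx_stages <- c("simulate", "qc", "features", "cluster", "de", "cytometry",
                 "trajectory", "regulon", "signature", "projection")

#' Derive a stage-specific seed from the global seed
#'
#' @param seed Global integer seed.
#' @param stage Stage name (one of the pipeline stage labels) or an integer
#'   counter.
#' @return Integer seed, strictly below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  idx <- if (is.character(stage)) match(stage, .glx_stages) else as.integer(stage)
  if (is.na(idx)) stop("unknown stage: ", stage)
  as.integer((as.double(seed) * 1009 + idx * 9973) %% 2147483647)
}

# Small stable string hash (polynomial rolling hash mod 2^31-1); used to give
# every simulated gene its own RNG substream keyed by gene id, so the counts a
# gene receives do not depend on the order genes are listed in.
.hash_string <- function(s) {
  h <- vapply(s, function(si) {
    x <- utf8ToInt(si)
    acc <- 0
    for (v in x) acc <- (acc * 131 + v) %% 2147483647
    acc
  }, numeric(1))
  as.integer(h)
}

# Benjamini-Hochberg adjusted p-values; NAs are carried through untouched.
.bh <- function(p) stats::p.adjust(p, method = "BH")

# -log10 with underflow cap so gene scores stay finite.
.neglog10 <- function(p, cap = 320) pmin(-log10(pmax(p, 1e-320)), cap)

.assert_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != round(x))
    stop(name, " must be a positive integer")
  invisible(as.integer(x))
}
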