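# Shared fixtures and independent brute-force oracles used across test files.

# Small hand-sized expression container: g genes x (4 genotypes x reps).
toy_expr_data <- function(g = 5, reps = 3, seed = 42, chrom = NULL) {
  set.seed(seed)
  genotypes <- c("WT", "mes4", "lin54", "double")
  samples <- data.frame(
    sample = paste0(rep(genotypes, each = reps), "_", seq_len(reps)),
    genotype = rep(genotypes, each = reps),
    replicate = rep(seq_len(reps), 4))
  m <- matrix(rnorm(g * nrow(samples), 7, 1), g, nrow(samples),
              dimnames = list(paste0("g", seq_len(g)), samples$sample))
  if (is.null(chrom)) chrom <- rep(c("I", "X"), length.out = g)
  genes <- data.frame(gene = rownames(m), chrom = chrom,
                      strand = "+", start = 1000 * seq_len(g),
                      end = 1000 * seq_len(g) + 500,
                      tss = 1000 * seq_len(g))
  expression_data(m, samples, genes)
}

# One default-condition simulation + pipeline run, computed once per test
# session and reused (the default conditions are the study design the
# recovery and calibration checks are defined on).
.fixture_cache <- new.env(parent = emptyenv())

default_bundle <- function() {
  if (is.null(.fixture_cache$bundle))
    .fixture_cache$bundle <- run_pipeline(pipeline_config(seed = 7))
  .fixture_cache$bundle
}

# Brute-force q-values: direct evaluation of the min-over-tail formula.
bf_qvalues <- function(p, pi0 = 1) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    tail_vals <- vapply(i:m, function(j) pi0 * m * p[o[j]] / j, numeric(1))
    q[o[i]] <- min(1, min(tail_vals))
  }
  q
}

# Brute-force upper hypergeometric tail P(K >= k) by direct combinatorial
# summation.
bf_hyper_upper <- function(k, n_a, n_b, N) {
  js <- max(k, 0):min(n_a, n_b)
  if (!length(js) || k > min(n_a, n_b)) return(0)
  sum(choose(n_a, js) * choose(N - n_a, n_b - js)) / choose(N, n_b)
}

# Brute-force promoter-binding call for a single gene: per-peak overlap
# with [tss - w, tss + w] (1-based inclusive) of >= min_ov bp.
bf_promoter_bound <- function(peaks_df, chrom, tss, w = 500, min_ov = 200) {
  win_s <- max(1, tss - w); win_e <- tss + w
  any(peaks_df$chrom == chrom &
        pmin(peaks_df$end, win_e) - pmax(peaks_df$start, win_s) + 1 >= min_ov)
}

# Random peak table on a toy genome (1-based inclusive coordinates).
random_peaks_df <- function(n, chroms = c("I", "X"), max_pos = 20000,
                            max_len = 1500) {
  s <- sample.int(max_pos, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = s, end = s + sample.int(max_len, n, replace = TRUE))
}

granges_df <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr))
}

peaks_df_to_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start, end = df$end))
}
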