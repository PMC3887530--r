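gr <- function(chrom, start, end) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start, end = end))
}

test_that("ChIP track scaling fixes the median at 1 and the MAD at 1", {
  v <- c(0, 1, 2, 3, 4)
  # raw MAD of v is 1 (absolute deviations 2,1,0,1,2), so only the median shifts
  out <- scale_chip_track(v)
  expect_equal(out, c(-1, 0, 1, 2, 3))
  expect_equal(median(out), 1)
  expect_equal(mad(out, constant = 1), 1)

  set.seed(40)
  for (i in 1:5) {
    w <- rlnorm(101)
    out <- scale_chip_track(w)
    expect_equal(median(out), 1)
    expect_equal(mad(out, constant = 1), 1)
    expect_equal(rank(out), rank(w))
  }
  # fixed point when both conditions already hold
  ok <- scale_chip_track(rnorm(51))
  expect_equal(scale_chip_track(ok), ok)
  expect_error(scale_chip_track(rep(c(1, 1, 1, 5), c(10, 10, 10, 2))), "zero")
  expect_error(scale_chip_track(rep(2, 5)), "distinct")
})

test_that("replicate-consistent peak retention keeps reference coordinates", {
  a <- gr("I", c(100, 500, 900), c(200, 600, 1000))
  expect_identical(consistent_peaks(list(a, a)), a)
  b <- gr("I", c(2000, 3000), c(2100, 3100))
  expect_length(consistent_peaks(list(a, b)), 0)
  # partial overlap keeps the reference replicate's coordinates unchanged
  c1 <- gr("I", 150, 550)
  kept <- consistent_peaks(list(a, c1))
  expect_equal(GenomicRanges::start(kept), c(100, 500))
  expect_error(consistent_peaks(list(a)), ">= 2 replicates")
})

test_that("replicate consistency matches a brute-force pairwise overlap scan", {
  set.seed(41)
  for (i in 1:40) {
    ref_df <- random_peaks_df(sample(5:25, 1))
    o1_df <- random_peaks_df(sample(5:25, 1))
    o2_df <- random_peaks_df(sample(5:25, 1))
    reps <- lapply(list(ref_df, o1_df, o2_df), peaks_df_to_granges)
    kept <- consistent_peaks(reps)
    overlaps <- function(p, q)
      p$chrom == q$chrom && min(p$end, q$end) - max(p$start, q$start) + 1 >= 1
    want <- vapply(seq_len(nrow(ref_df)), function(k) {
      p <- ref_df[k, ]
      any(vapply(seq_len(nrow(o1_df)), function(j) overlaps(p, o1_df[j, ]),
                 logical(1))) ||
        any(vapply(seq_len(nrow(o2_df)), function(j) overlaps(p, o2_df[j, ]),
                   logical(1)))
    }, logical(1))
    got <- as.data.frame(GenomicRanges::sort(kept))[, c("seqnames", "start", "end")]
    ref_sorted <- GenomicRanges::sort(peaks_df_to_granges(ref_df)[want])
    expect_equal(nrow(got), sum(want))
    expect_equal(got$start, GenomicRanges::start(ref_sorted))
  }
})

test_that("promoter binding follows the TSS-window rule at its exact boundary", {
  ann <- data.frame(gene = c("gA", "gB"), chrom = c("I", "I"),
                    strand = c("+", "-"), start = c(10000, 30000),
                    end = c(12000, 32000), tss = c(10000, 32000))
  # peak exactly covering TSS +/- 500 -> bound
  calls <- call_promoter_bound(gr("I", 9500, 10500), ann)
  expect_identical(unname(calls$bound), c(TRUE, FALSE))
  # overlap of exactly 199 bp -> not bound; 200 bp -> bound
  # (window starts at 9500, so a peak ending 9698 overlaps 199 bp)
  expect_false(call_promoter_bound(gr("I", 9301, 9698), ann)$bound[["gA"]])
  expect_true(call_promoter_bound(gr("I", 9301, 9699), ann)$bound[["gA"]])
  # minus-strand gene: window around its TSS at the gene end
  expect_true(call_promoter_bound(gr("I", 31700, 33000), ann)$bound[["gB"]])
  # missing TSS is an explicit error
  ann_na <- ann; ann_na$tss[2] <- NA
  expect_error(call_promoter_bound(gr("I", 1, 2), ann_na), "missing TSS")
})

test_that("promoter binding matches brute-force interval arithmetic on random toy genomes", {
  set.seed(42)
  n_cases <- 0
  for (i in 1:30) {
    n_genes <- 40
    tss <- sample.int(20000, n_genes)
    ann <- data.frame(gene = paste0("g", seq_len(n_genes)),
                      chrom = sample(c("I", "X"), n_genes, replace = TRUE),
                      strand = sample(c("+", "-"), n_genes, replace = TRUE),
                      start = tss, end = tss + 1000, tss = tss)
    pk_df <- random_peaks_df(sample(10:60, 1))
    calls <- call_promoter_bound(peaks_df_to_granges(pk_df), ann)
    for (k in seq_len(n_genes)) {
      expect_identical(unname(calls$bound[k]),
                       bf_promoter_bound(pk_df, ann$chrom[k], ann$tss[k]))
      n_cases <- n_cases + 1
    }
  }
  expect_gte(n_cases, 1000)
})

test_that("binding calls are monotone in the overlap threshold and per-peak, not per-union", {
  ann <- data.frame(gene = "gA", chrom = "I", strand = "+",
                    start = 10000, end = 12000, tss = 10000)
  # two abutting 150 bp fragments inside the window: each < 200 bp, so unbound
  frags <- gr("I", c(9700, 9850), c(9849, 9999))
  expect_false(call_promoter_bound(frags, ann)$bound[["gA"]])
  expect_true(call_promoter_bound(GenomicRanges::reduce(frags), ann)$bound[["gA"]])
  # decreasing min_overlap never un-binds
  set.seed(43)
  pk <- peaks_df_to_granges(random_peaks_df(80))
  ann40 <- data.frame(gene = paste0("g", 1:40), chrom = "I", strand = "+",
                      start = seq(500, 20000, length.out = 40),
                      end = seq(500, 20000, length.out = 40) + 800,
                      tss = round(seq(500, 20000, length.out = 40)))
  prev <- NULL
  for (mo in c(400, 200, 50, 1)) {
    now <- call_promoter_bound(pk, ann40, min_overlap = mo)$bound
    if (!is.null(prev)) expect_true(all(now[prev]))
    prev <- now
  }
})

test_that("gene-body binding coverage equals per-base counting", {
  ann <- data.frame(gene = c("gA", "gB"), chrom = "I", strand = "+",
                    start = c(1000, 5000), end = c(2000, 6000),
                    tss = c(1000, 5000))
  expect_true(all(call_body_bound(gr("I", c(900, 4000), c(2100, 6500)),
                                  ann, min_fraction = 1)$bound))
  expect_false(any(call_body_bound(gr("X", 900, 2100), ann)$bound))
  set.seed(44)
  for (i in 1:20) {
    pk_df <- random_peaks_df(sample(5:30, 1), chroms = "I", max_pos = 7000,
                             max_len = 700)
    calls <- call_body_bound(peaks_df_to_granges(pk_df), ann,
                             min_fraction = 0.5)
    for (k in 1:2) {
      bases <- ann$start[k]:ann$end[k]
      covered <- rep(FALSE, length(bases))
      for (j in seq_len(nrow(pk_df)))
        covered <- covered | (bases >= pk_df$start[j] & bases <= pk_df$end[j])
      frac <- mean(covered)
      expect_equal(unname(calls$coverage[k]), frac, tolerance = 1e-12)
      expect_identical(unname(calls$bound[k]), frac >= 0.5)
    }
  }
  expect_error(call_body_bound(gr("I", 1, 10), ann, min_fraction = 0), "0, 1")
  expect_error(call_body_bound(gr("I", 1, 10), ann, min_fraction = 1.2), "0, 1")
})

test_that("co-binding Venn counts and overlap test match enumeration on a 15-gene toy", {
  universe <- paste0("g", 1:15)
  a <- setNames(universe %in% paste0("g", 1:6), universe)
  b <- setNames(universe %in% paste0("g", 4:10), universe)
  v <- cobinding_venn(a, b)
  expect_equal(v$n_both, 3)
  expect_equal(v$a_only, 3)
  expect_equal(v$b_only, 4)
  expect_equal(v$neither, 5)
  expect_equal(v$test$p, bf_hyper_upper(3, 6, 7, 15), tolerance = 1e-12)
  same <- cobinding_venn(a, a)
  expect_equal(same$n_both, sum(a))
  expect_error(cobinding_venn(a, b[1:10]), "universes")
})

test_that("binding enrichment in gene sets matches brute-force tail sums", {
  universe <- paste0("g", 1:18)
  bound <- setNames(universe %in% paste0("g", c(1:5, 9, 12)), universe)
  sets <- list(up = gene_set("up", paste0("g", 1:6)),
               down = gene_set("down", paste0("g", 13:18)))
  res <- binding_enrichment_in_sets(list(F1 = bound), sets, universe)
  for (i in seq_len(nrow(res))) {
    ids <- sets[[res$set[i]]]$genes
    obs <- sum(bound[ids])
    expect_equal(res$observed[i], obs)
    expect_equal(res$expected[i], length(ids) * sum(bound) / 18)
    expect_equal(res$p_enrichment[i],
                 bf_hyper_upper(obs, sum(bound), length(ids), 18),
                 tolerance = 1e-12)
  }
  all_bound <- gene_set("allb", universe[bound])
  res2 <- binding_enrichment_in_sets(list(F1 = bound), list(ab = all_bound),
                                     universe)
  expect_equal(res2$observed, length(all_bound$genes))
})

test_that("BED round trips are byte-identical and coordinates convert correctly", {
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "a.bed"); p2 <- file.path(dir, "b.bed")
  writeLines(c("I\t100\t200", "I\t500\t900", "X\t0\t50"), p1)
  g <- read_peaks_bed(p1)
  # 0-based half-open [100, 200) -> 1-based inclusive [101, 200]
  expect_equal(GenomicRanges::start(g), c(101, 501, 1))
  expect_equal(GenomicRanges::end(g), c(200, 900, 50))
  write_peaks_bed(g, p2)
  expect_identical(readLines(p2), readLines(p1))
  expect_error(read_peaks_bed(file.path(dir, "missing.bed")), "not found")
})
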