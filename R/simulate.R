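#' Configuration for the germline-expression simulator
#'
#' Defines the study design emulated by [simulate_experiment()]: four
#' genotypes (WT, mes-4, lin-54, double mutant) with replicate microarrays,
#' genes spread over chromosomes I-V and X, and planted antagonistic gene
#' classes whose single-mutant effects are opposite-signed and cancel in the
#' double mutant.
#'
#' Defaults describe a germline microarray experiment at desk scale:
#' 6000 genes, 3 replicates per genotype, planted log2 effects of 1.0 with
#' replicate noise whose gene-level variances follow a scaled-inverse-
#' chi-square hierarchy (prior df `var_df`, prior scale `noise_sd^2`) -- the
#' exact model assumed by the moderated t-test, so that empirical-Bayes
#' hyperparameter recovery is testable.
#'
#' @param n_genes total number of genes
#' @param chrom_weights named proportions of genes per chromosome (I-V, X);
#'   must sum to 1
#' @param n_replicates biological replicates per genotype
#' @param baseline_mean,baseline_sd log2-intensity mean and sd of the
#'   gene-level baseline distribution
#' @param noise_sd prior scale (sd, log2 units) of replicate noise; per-gene
#'   variances are `var_df * noise_sd^2 / rchisq(var_df)`
#' @param var_df prior degrees of freedom of the gene-variance hierarchy
#' @param class_sizes named counts of planted genes: `x_up`, `a_up`,
#'   `a_down`, `other_de`
#' @param effect_size magnitude (log2 units) of planted single-mutant shifts
#' @param double_restoration fraction of the mes-4 effect retained by the
#'   double mutant (0 = exact cancellation, the default)
#' @param x_dampening log2 units subtracted from X-linked baselines in all
#'   genotypes, emulating germline X repression
#' @param category_probs matrix of expression-category probabilities, one
#'   row per planted class (x_up, a_up, a_down, other_de, null), one column
#'   per category; rows sum to 1
#' @param call_threshold,call_margin detection-call rule on the true
#'   baseline: below `threshold - margin` is Absent, within `margin` of the
#'   threshold is Marginal, above is Present
#' @param call_noise per-sample probability a call label is replaced by a
#'   uniformly random label
#' @param peak_enrichment probability a germline-category gene is
#'   promoter-bound by each factor
#' @param peak_background probability a non-germline gene is bound
#' @param background_peak_rate decoy peaks per megabase, placed uniformly
#' @param n_peak_replicates ChIP replicates per factor
#' @param seed master seed; all randomness derives from it via fixed
#'   substreams per data product
#' @return a validated list of class `sim_config`
#' @export
sim_config <- function(n_genes = 6000,
                       chrom_weights = c(I = 0.17, II = 0.17, III = 0.15,
                                         IV = 0.17, V = 0.19, X = 0.15),
                       n_replicates = 3,
                       baseline_mean = 7, baseline_sd = 1.5,
                       noise_sd = 0.25, var_df = 4,
                       class_sizes = c(x_up = 200, a_up = 200,
                                       a_down = 200, other_de = 100),
                       effect_size = 1.0,
                       double_restoration = 0,
                       x_dampening = 0.5,
                       category_probs = default_category_probs(),
                       call_threshold = 6, call_margin = 0.5,
                       call_noise = 0.05,
                       peak_enrichment = 0.8,
                       peak_background = 0.05,
                       background_peak_rate = 2,
                       n_peak_replicates = 2,
                       seed = 1) {
  chrom_weights <- unlist(chrom_weights)
  class_sizes <- unlist(class_sizes)
  if (is.list(category_probs))
    category_probs <- do.call(rbind, lapply(category_probs, unlist))
  cfg <- list(n_genes = n_genes, chrom_weights = chrom_weights,
              n_replicates = n_replicates, baseline_mean = baseline_mean,
              baseline_sd = baseline_sd, noise_sd = noise_sd, var_df = var_df,
              class_sizes = class_sizes, effect_size = effect_size,
              double_restoration = double_restoration,
              x_dampening = x_dampening, category_probs = category_probs,
              call_threshold = call_threshold, call_margin = call_margin,
              call_noise = call_noise, peak_enrichment = peak_enrichment,
              peak_background = peak_background,
              background_peak_rate = background_peak_rate,
              n_peak_replicates = n_peak_replicates, seed = seed)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' Default expression-category distributions per planted class
#'
#' Categories follow the five labels used for germline expression profiling:
#' germline_specific, germline_enriched, ubiquitous, soma_specific, other.
#' A-up-class genes are biased toward ubiquitous/soma-specific expression
#' and depleted of germline-enriched genes; A-down-class genes toward
#' germline-enriched/-specific expression; X-up toward ubiquitous and
#' germline expression -- the direction of the enrichments the analysis is
#' expected to detect.
#'
#' @return a 5x5 row-stochastic matrix
#' @export
default_category_probs <- function() {
  cats <- c("germline_specific", "germline_enriched", "ubiquitous",
            "soma_specific", "other")
  m <- rbind(
    x_up     = c(0.15, 0.30, 0.40, 0.05, 0.10),
    a_up     = c(0.02, 0.08, 0.40, 0.35, 0.15),
    a_down   = c(0.30, 0.45, 0.15, 0.02, 0.08),
    other_de = c(0.05, 0.15, 0.25, 0.15, 0.40),
    null     = c(0.05, 0.15, 0.25, 0.15, 0.40))
  colnames(m) <- cats
  m
}

#' @keywords internal
validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_genes >= 1, cfg$n_replicates >= 2)
  if (abs(sum(cfg$chrom_weights) - 1) > 1e-8)
    stop("chrom_weights must sum to 1")
  if (!setequal(names(cfg$chrom_weights), CHROMOSOMES))
    stop("chrom_weights must be named I, II, III, IV, V, X")
  if (cfg$baseline_sd <= 0 || cfg$noise_sd <= 0)
    stop("sd parameters must be > 0")
  if (cfg$var_df <= 0) stop("var_df must be > 0")
  req <- c("x_up", "a_up", "a_down", "other_de")
  if (!all(req %in% names(cfg$class_sizes)))
    stop("class_sizes must name x_up, a_up, a_down, other_de")
  if (sum(cfg$class_sizes) > cfg$n_genes)
    stop("class sizes sum exceeds n_genes")
  probs <- c(cfg$call_noise, cfg$peak_enrichment, cfg$peak_background)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (any(abs(rowSums(cfg$category_probs) - 1) > 1e-8))
    stop("category_probs rows must sum to 1")
  invisible(cfg)
}

# Fixed substream offsets: one master seed, an independent stream per data
# product so that e.g. regenerating peaks does not perturb the matrix.
.SIM_STREAMS <- c(annotation = 11L, baseline = 23L, effects = 37L,
                  noise = 53L, calls = 71L, categories = 89L,
                  binding = 107L, peaks = 131L)

#' @keywords internal
substream_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + .SIM_STREAMS[[stream]] * 1048573) %%
               2147483647)
}

#' Simulate a four-genotype germline expression experiment
#'
#' Generates a log2 expression matrix (genes x samples) for WT, mes-4,
#' lin-54 and the double mutant, together with a gene annotation table,
#' a Present/Marginal/Absent detection-call matrix, and the planted ground
#' truth. Planted sign patterns, relative to WT: X-up and A-up genes are
#' shifted +effect in mes-4 and -effect in lin-54 and (by default) 0 in the
#' double mutant; A-down genes carry the mirrored pattern; `other_de` genes
#' are shifted in the same direction in every mutant (non-antagonistic);
#' null genes carry no effect. Replicate values are
#' baseline + genotype effect + independent Gaussian noise with per-gene
#' variance drawn from the scaled-inverse-chi-square hierarchy.
#'
#' @param config a [sim_config()] object
#' @return a list with elements `data` (an [expression_data()] object),
#'   `calls` (character matrix of P/M/A labels), and `truth` (data.frame:
#'   gene, class, per-genotype planted effect, category, per-factor
#'   promoter-bound flags)
#' @export
simulate_experiment <- function(config) {
  validate_sim_config(config)
  cfg <- config
  ann <- simulate_annotation(cfg)
  n <- nrow(ann)

  # planted classes, respecting chromosome constraints
  set.seed(substream_seed(cfg$seed, "effects"))
  x_genes <- which(ann$chrom == "X")
  a_genes <- which(ann$chrom != "X")
  cs <- cfg$class_sizes
  if (cs[["x_up"]] > length(x_genes))
    stop("class sizes exceed chromosome capacity: x_up > X-linked genes")
  if (cs[["a_up"]] + cs[["a_down"]] + cs[["other_de"]] > length(a_genes))
    stop("class sizes exceed chromosome capacity: autosomal classes > autosomal genes")
  class <- rep("null", n)
  class[sample(x_genes, cs[["x_up"]])] <- "x_up"
  pick_a <- sample(a_genes, cs[["a_up"]] + cs[["a_down"]] + cs[["other_de"]])
  class[pick_a[seq_len(cs[["a_up"]])]] <- "a_up"
  class[pick_a[cs[["a_up"]] + seq_len(cs[["a_down"]])]] <- "a_down"
  class[pick_a[cs[["a_up"]] + cs[["a_down"]] + seq_len(cs[["other_de"]])]] <- "other_de"

  e <- cfg$effect_size
  eff <- matrix(0, n, 3, dimnames = list(ann$gene, c("mes4", "lin54", "double")))
  up <- class %in% c("x_up", "a_up")
  eff[up, "mes4"] <- e
  eff[up, "lin54"] <- -e
  eff[class == "a_down", "mes4"] <- -e
  eff[class == "a_down", "lin54"] <- e
  eff[, "double"] <- cfg$double_restoration * eff[, "mes4"]
  other <- class == "other_de"
  if (any(other)) {
    sgn <- sample(c(-1, 1), sum(other), replace = TRUE)
    eff[other, "mes4"] <- sgn * e
    eff[other, "lin54"] <- sgn * e
    eff[other, "double"] <- 2 * sgn * e
  }

  # gene-level baseline, dampened on X
  set.seed(substream_seed(cfg$seed, "baseline"))
  baseline <- stats::rnorm(n, cfg$baseline_mean, cfg$baseline_sd)
  baseline[ann$chrom == "X"] <- baseline[ann$chrom == "X"] - cfg$x_dampening
  gene_var <- cfg$var_df * cfg$noise_sd^2 / stats::rchisq(n, cfg$var_df)

  genotypes <- c("WT", "mes4", "lin54", "double")
  nr <- cfg$n_replicates
  samples <- data.frame(
    sample = paste0(rep(genotypes, each = nr), "_", seq_len(nr)),
    genotype = rep(genotypes, each = nr),
    replicate = rep(seq_len(nr), times = length(genotypes)),
    stringsAsFactors = FALSE)

  set.seed(substream_seed(cfg$seed, "noise"))
  mu <- cbind(WT = 0, eff)[, samples$genotype] + baseline
  noise <- matrix(stats::rnorm(n * nrow(samples), sd = sqrt(gene_var)),
                  n, nrow(samples))
  m <- mu + noise
  dimnames(m) <- list(ann$gene, samples$sample)

  # expression categories conditional on planted class
  set.seed(substream_seed(cfg$seed, "categories"))
  cats <- colnames(cfg$category_probs)
  category <- vapply(class, function(cl) {
    sample(cats, 1, prob = cfg$category_probs[cl, ])
  }, character(1), USE.NAMES = FALSE)
  ann$category <- category

  # detection calls from the true (dampened) baseline, with label noise
  set.seed(substream_seed(cfg$seed, "calls"))
  true_call <- ifelse(baseline < cfg$call_threshold - cfg$call_margin, "A",
               ifelse(baseline < cfg$call_threshold + cfg$call_margin, "M", "P"))
  calls <- matrix(rep(true_call, nrow(samples)), n, nrow(samples),
                  dimnames = list(ann$gene, samples$sample))
  flip <- matrix(stats::runif(length(calls)) < cfg$call_noise,
                 n, nrow(samples))
  calls[flip] <- sample(c("P", "M", "A"), sum(flip), replace = TRUE)

  # per-factor promoter-bound flags, enriched at germline-category genes
  set.seed(substream_seed(cfg$seed, "binding"))
  germline <- category %in% c("germline_specific", "germline_enriched")
  p_bound <- ifelse(germline, cfg$peak_enrichment, cfg$peak_background)
  bound <- sapply(c("MES4", "LIN54", "EFL1"),
                  function(f) stats::runif(n) < p_bound)

  truth <- data.frame(gene = ann$gene, class = class,
                      effect_mes4 = eff[, "mes4"],
                      effect_lin54 = eff[, "lin54"],
                      effect_double = eff[, "double"],
                      category = category,
                      bound_MES4 = bound[, "MES4"],
                      bound_LIN54 = bound[, "LIN54"],
                      bound_EFL1 = bound[, "EFL1"],
                      stringsAsFactors = FALSE)
  rownames(truth) <- truth$gene

  list(data = expression_data(m, samples, ann), calls = calls, truth = truth)
}

#' @keywords internal
simulate_annotation <- function(cfg) {
  set.seed(substream_seed(cfg$seed, "annotation"))
  counts <- round(cfg$n_genes * cfg$chrom_weights[CHROMOSOMES])
  counts[length(counts)] <- cfg$n_genes - sum(counts[-length(counts)])
  spacing <- 5000L
  out <- lapply(CHROMOSOMES, function(ch) {
    k <- counts[[ch]]
    if (k == 0) return(NULL)
    slot <- (seq_len(k) - 1L) * spacing + 1000L
    len <- 1500L + floor(stats::runif(k, 0, 2000))
    start <- slot + floor(stats::runif(k, 0, 1000))
    strand <- sample(c("+", "-"), k, replace = TRUE)
    data.frame(gene = sprintf("%s_g%04d", ch, seq_len(k)),
               chrom = ch, strand = strand,
               start = start, end = start + len,
               tss = ifelse(strand == "+", start, start + len),
               stringsAsFactors = FALSE)
  })
  ann <- do.call(rbind, out)
  rownames(ann) <- ann$gene
  ann
}

#' Simulate ChIP peak sets from planted binding truth
#'
#' For each factor and replicate, every gene flagged promoter-bound in the
#' truth table receives a peak overlapping its TSS +/- 500 bp window by well
#' over 200 bp (for MES-4 the peak extends over the full gene body, so
#' body-binding calls also recover the flag); decoy background peaks are
#' placed uniformly along each chromosome at `background_peak_rate` per Mb.
#'
#' @param truth truth data.frame from [simulate_experiment()]
#' @param annotation gene annotation data.frame (needs chrom, strand, tss,
#'   start, end)
#' @param config the [sim_config()] used
#' @return nested list `peaks[[factor]][[replicate]]`, each a `GRanges`
#' @export
simulate_peaks <- function(truth, annotation, config) {
  validate_sim_config(config)
  if (!all(c("tss", "chrom") %in% names(annotation)))
    stop("annotation TSSs must be defined")
  set.seed(substream_seed(config$seed, "peaks"))
  chrom_len <- tapply(annotation$end, annotation$chrom, max) + 10000
  factors <- grep("^bound_", names(truth), value = TRUE)
  out <- list()
  for (fcol in factors) {
    fac <- sub("^bound_", "", fcol)
    idx <- which(truth[[fcol]])
    reps <- vector("list", config$n_peak_replicates)
    for (r in seq_len(config$n_peak_replicates)) {
      if (length(idx)) {
        tss <- annotation$tss[idx]
        jit <- floor(stats::runif(length(idx), -100, 100))
        if (fac == "MES4") {
          s <- pmin(annotation$start[idx], tss - 250L) + jit
          e <- pmax(annotation$end[idx], tss + 250L) + jit
        } else {
          s <- tss - 250L + jit
          e <- tss + 250L + jit
        }
        signal <- GenomicRanges::GRanges(
          annotation$chrom[idx],
          IRanges::IRanges(start = pmax(1L, as.integer(s)), end = as.integer(e)))
      } else {
        signal <- GenomicRanges::GRanges()
      }
      bg <- lapply(names(chrom_len), function(ch) {
        k <- stats::rpois(1, config$background_peak_rate * chrom_len[[ch]] / 1e6)
        if (k == 0) return(GenomicRanges::GRanges())
        s <- floor(stats::runif(k, 1, chrom_len[[ch]] - 600))
        GenomicRanges::GRanges(ch, IRanges::IRanges(start = as.integer(s),
                                                    width = 500L))
      })
      reps[[r]] <- GenomicRanges::sort(
        do.call(c, c(list(signal), bg)))
    }
    names(reps) <- paste0("rep", seq_along(reps))
    out[[fac]] <- reps
  }
  out
}

#' Write a complete simulated bundle to disk
#'
#' Writes the expression bundle (matrix, sample sheet, annotation), the
#' detection calls, the truth table, and one BED3 file per factor and
#' replicate under `dir/peaks/`.
#'
#' @param sim result of [simulate_experiment()]
#' @param peaks result of [simulate_peaks()] (optional)
#' @param dir output directory
#' @return invisibly, the output directory
#' @export
write_sim_bundle <- function(sim, dir, peaks = NULL) {
  write_expression_bundle(sim$data, dir)
  write_tsv(data.frame(gene = rownames(sim$calls), sim$calls,
                       check.names = FALSE),
            file.path(dir, "calls.tsv"))
  write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  if (!is.null(peaks)) {
    pd <- file.path(dir, "peaks")
    dir.create(pd, showWarnings = FALSE)
    for (fac in names(peaks))
      for (r in names(peaks[[fac]]))
        write_peaks_bed(peaks[[fac]][[r]],
                        file.path(pd, sprintf("%s_%s.bed", fac, r)))
  }
  invisible(dir)
}
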