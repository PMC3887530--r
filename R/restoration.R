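#' Percentiles used for expression box statistics
#'
#' Whisker-to-whisker summary: 2.5th and 97.5th (whiskers), 25th and 75th
#' (box), 50th (median).
#' @keywords internal
BOX_PROBS <- c(2.5, 25, 50, 75, 97.5) / 100

#' @keywords internal
box_stats <- function(v) {
  stats::quantile(v, probs = BOX_PROBS, names = FALSE)
}

#' Log2 fold-change profile of a gene set across genotypes
#'
#' Per gene and mutant genotype, log2FC relative to WT = mean over the
#' genotype's replicates minus mean over the WT replicates. The WT entry of
#' the profile holds the per-replicate deviations from each gene's WT mean
#' (one value per gene and replicate), so its median sits near zero --
#' mirroring the WT reference box of a fold-change boxplot. Per-gene
#' replicate-averaged absolute expression values are kept for the
#' restoration t-tests.
#'
#' @param x a normalized `expr_data` object
#' @param genes a `gene_set` or character vector of gene ids
#' @param genotypes mutant genotypes to profile (default: all non-WT)
#' @return list of class `fc_profile`: `name`, `fc` (genes x genotypes
#'   matrix of log2FC vs WT), `wt_deviation` (vector), `means` (genes x all
#'   genotypes matrix of replicate-averaged log2 expression), `box`
#'   (data.frame of box statistics per genotype, WT first)
#' @export
log2fc_profile <- function(x, genes,
                           genotypes = setdiff(unique(x$samples$genotype), "WT")) {
  ids <- if (inherits(genes, "gene_set")) genes$genes else as.character(genes)
  if (!length(ids)) stop("empty gene set")
  missing <- setdiff(ids, rownames(x$exprs))
  if (length(missing))
    stop("gene(s) not in matrix: ", paste(utils::head(missing, 5), collapse = ", "))
  wt <- x$exprs[ids, genotype_samples(x, "WT"), drop = FALSE]
  wt_mean <- rowMeans(wt)
  all_gt <- c("WT", genotypes)
  means <- vapply(all_gt, function(g) {
    rowMeans(x$exprs[ids, genotype_samples(x, g), drop = FALSE])
  }, numeric(length(ids)))
  rownames(means) <- ids
  fc <- means[, genotypes, drop = FALSE] - wt_mean
  wt_dev <- as.vector(wt - wt_mean)
  box <- rbind(WT = box_stats(wt_dev),
               t(apply(fc, 2, box_stats)))
  colnames(box) <- c("p2.5", "p25", "p50", "p75", "p97.5")
  structure(list(name = if (inherits(genes, "gene_set")) genes$name else "set",
                 fc = fc, wt_deviation = wt_dev, means = means,
                 box = as.data.frame(box)),
            class = "fc_profile")
}

#' Test restoration of a gene set's expression to wild type
#'
#' For each mutant genotype, a Student's t-test (two-sample, equal
#' variance) of the gene set's replicate-averaged log2 expression values
#' against the WT values, pooling genes as observations (a paired variant
#' across genes is available via `paired = TRUE`). The set is called
#' restored when both single mutants differ from WT (p < alpha) with
#' opposite-signed median fold changes while the double mutant does not
#' differ (p >= alpha).
#'
#' @param profile an `fc_profile` including WT, mes4, lin54 and double
#' @param alpha significance level (default 0.001, the level used for the
#'   boxplot comparisons)
#' @param paired pair observations by gene instead of pooling
#' @return list of class `restoration_verdict`: `p` (named vector of
#'   p-values vs WT), `median_fc` (named vector), `alpha`, `verdict`
#' @export
restoration_test <- function(profile, alpha = 0.001, paired = FALSE) {
  need <- c("WT", "mes4", "lin54", "double")
  if (!all(need %in% colnames(profile$means)))
    stop("profile must include genotypes WT, mes4, lin54, double")
  if (nrow(profile$means) < 3) stop("gene set too small (< 3 genes)")
  wt <- profile$means[, "WT"]
  muts <- setdiff(colnames(profile$means), "WT")
  p <- vapply(muts, function(g) {
    v <- profile$means[, g]
    if (isTRUE(all.equal(v, wt, tolerance = 0))) return(1)
    if (stats::sd(v - wt) == 0 && !paired) {
      if (stats::sd(v) == 0 && stats::sd(wt) == 0) return(1)
    }
    stats::t.test(v, wt, var.equal = TRUE, paired = paired)$p.value
  }, numeric(1))
  med <- vapply(muts, function(g) stats::median(profile$fc[, g]), numeric(1))
  singles_differ <- p[["mes4"]] < alpha && p[["lin54"]] < alpha
  opposite <- sign(med[["mes4"]]) * sign(med[["lin54"]]) < 0
  double_same <- p[["double"]] >= alpha
  verdict <- if (singles_differ && opposite && double_same)
    "restored" else "not_restored"
  structure(list(p = p, median_fc = med, alpha = alpha, verdict = verdict),
            class = "restoration_verdict")
}

#' @export
print.restoration_verdict <- function(x, ...) {
  cat(sprintf("restoration verdict: %s (alpha = %g)\n", x$verdict, x$alpha))
  for (g in names(x$p))
    cat(sprintf("  %-7s p = %.3g, median log2FC = %+.3f\n",
                g, x$p[[g]], x$median_fc[[g]]))
  invisible(x)
}

#' Chromosome-wide fold-change summaries
#'
#' Treats each chromosome's expressed genes as a gene set and profiles it
#' across genotypes, capturing chromosome-scale behavior such as the
#' X-linked expression changes in the mutants. Also records WT
#' absolute-expression box statistics per chromosome (X dampening shows up
#' as a lower X median).
#'
#' @param x a normalized `expr_data` object
#' @param expressed named logical vector (from [call_expressed()] on the WT
#'   replicates), or `NULL` to fall back to the top `top_n` genes per
#'   chromosome by WT expression
#' @param genotypes mutant genotypes (default all non-WT)
#' @param top_n fallback set size per chromosome when `expressed` is NULL
#' @return list of class `chromosome_summary`: per chromosome, a list with
#'   `profile` (an `fc_profile`), `n_genes`, `wt_expression_box`
#' @export
chromosome_summary <- function(x, expressed = NULL,
                               genotypes = setdiff(unique(x$samples$genotype), "WT"),
                               top_n = 720) {
  wt_samples <- genotype_samples(x, "WT")
  out <- list()
  for (ch in intersect(CHROMOSOMES, unique(x$genes$chrom))) {
    on_ch <- x$genes$gene[x$genes$chrom == ch]
    ids <- if (is.null(expressed)) {
      top_expressed(x, top_n, chrom = ch)
    } else {
      intersect(on_ch, names(expressed)[expressed])
    }
    if (!length(ids)) {
      warning("no expressed genes on chromosome ", ch, "; omitted")
      next
    }
    wt_abs <- rowMeans(x$exprs[ids, wt_samples, drop = FALSE])
    out[[ch]] <- list(profile = log2fc_profile(x, ids, genotypes),
                      n_genes = length(ids),
                      wt_expression_box = box_stats(wt_abs))
  }
  structure(out, class = "chromosome_summary")
}

#' Significance stars at the tiers 0.05, 0.001, 1e-10
#' @keywords internal
signif_tier <- function(p) {
  ifelse(p < 1e-10, "***", ifelse(p < 0.001, "**", ifelse(p < 0.05, "*", "")))
}

#' Expression-category enrichment of a gene set
#'
#' For each category label, compares the observed number of set members in
#' the category with the expectation |set| * n_category / N under uniform
#' draws from the universe; enrichment p is the upper hypergeometric tail
#' at the observed count, depletion p the lower tail. Significance tiers
#' are flagged at 0.05 (*), 0.001 (**) and 1e-10 (***).
#'
#' @param genes a `gene_set` or character vector (must be contained in the
#'   universe)
#' @param categories named character vector: gene id -> category label
#'   (genes without a label are counted under no category)
#' @param universe character vector of universe gene ids
#' @return data.frame of class `enrichment_result`: category, n_category,
#'   observed, expected, p_enrichment, p_depletion, tier columns
#' @export
category_enrichment <- function(genes, categories, universe) {
  ids <- if (inherits(genes, "gene_set")) genes$genes else unique(as.character(genes))
  outside <- setdiff(ids, universe)
  if (length(outside))
    stop("gene set not contained in universe: ",
         paste(utils::head(outside, 5), collapse = ", "))
  n_univ <- length(unique(universe))
  n_set <- length(ids)
  cats <- sort(unique(categories[universe][!is.na(categories[universe])]))
  rows <- lapply(cats, function(cl) {
    in_cat <- universe[!is.na(categories[universe]) & categories[universe] == cl]
    k <- length(in_cat)
    obs <- length(intersect(ids, in_cat))
    p_enr <- stats::phyper(obs - 1, k, n_univ - k, n_set, lower.tail = FALSE)
    p_dep <- stats::phyper(obs, k, n_univ - k, n_set, lower.tail = TRUE)
    data.frame(category = cl, n_category = k, observed = obs,
               expected = n_set * k / n_univ,
               p_enrichment = p_enr, p_depletion = p_dep,
               tier_enrichment = signif_tier(p_enr),
               tier_depletion = signif_tier(p_dep),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "set_size") <- n_set
  attr(out, "universe_size") <- n_univ
  class(out) <- c("enrichment_result", "data.frame")
  out
}
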