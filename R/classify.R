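#' Build a gene set from one contrast's significance calls
#'
#' Genes with q <= cutoff whose fold change has the requested sign,
#' optionally restricted to a chromosome class. Genes with log2FC exactly 0
#' carry no direction and never enter a directional set.
#'
#' @param contrast a `contrast_result` with q-values
#' @param direction "up", "down", or "any"
#' @param chrom_filter chromosomes to keep: e.g. "X", the autosomes, or
#'   `NULL` for all
#' @param q_cutoff significance cutoff (default 0.05)
#' @param name set name; defaults to a label built from the rule
#' @return list of class `gene_set`: `name`, `genes` (character vector),
#'   `provenance` (the rule applied)
#' @export
significant_set <- function(contrast, direction = c("any", "up", "down"),
                            chrom_filter = NULL, q_cutoff = 0.05,
                            name = NULL) {
  direction <- match.arg(direction)
  keep <- !is.na(contrast$q) & contrast$q <= q_cutoff
  if (direction != "any") keep <- keep & contrast$direction == direction
  if (!is.null(chrom_filter)) {
    if (is.null(contrast$chrom)) stop("contrast lacks a chrom column")
    keep <- keep & contrast$chrom %in% chrom_filter
  }
  if (is.null(name))
    name <- paste0(attr(contrast, "contrast"), "_", direction,
                   if (!is.null(chrom_filter))
                     paste0("_", paste(chrom_filter, collapse = "")))
  gene_set(name, contrast$gene[keep],
           provenance = list(contrast = attr(contrast, "contrast"),
                             direction = direction, q_cutoff = q_cutoff,
                             chrom_filter = chrom_filter))
}

#' Construct a gene set
#' @param name set name
#' @param genes member gene ids (de-duplicated)
#' @param provenance free-form record of the rule that produced the set
#' @return a `gene_set` list
#' @export
gene_set <- function(name, genes, provenance = list()) {
  structure(list(name = name, genes = unique(as.character(genes)),
                 provenance = provenance),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set '%s': %d genes\n", x$name, length(x$genes)))
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$genes)

#' Classify antagonistically regulated gene classes
#'
#' Intersects significance calls from the mes-4 vs WT contrast (effect of
#' losing MES-4) and the double vs mes-4 contrast (effect of additionally
#' losing LIN-54):
#' \describe{
#'   \item{X-up}{X-linked, up in mes-4 vs WT and down in double vs mes-4}
#'   \item{A-up}{autosomal, the same sign pattern}
#'   \item{A-down}{autosomal, down in mes-4 vs WT and up in double vs mes-4}
#' }
#' Genes significant in both contrasts with the same sign form the
#' non-antagonistic remainder (`same_sign`).
#'
#' @param mes4_vs_wt,double_vs_mes4 `contrast_result` tables on the same
#'   gene universe, with chromosome annotations
#' @param q_cutoff significance cutoff applied to both contrasts
#' @return list of `gene_set`s: `x_up`, `a_up`, `a_down`, `same_sign`, plus
#'   `both_significant` (all genes significant in both contrasts)
#' @export
classify_antagonistic <- function(mes4_vs_wt, double_vs_mes4,
                                  q_cutoff = 0.05) {
  if (!setequal(mes4_vs_wt$gene, double_vs_mes4$gene))
    stop("contrasts are on different gene universes")
  b <- double_vs_mes4[match(mes4_vs_wt$gene, double_vs_mes4$gene), ]
  a <- mes4_vs_wt
  sig_both <- a$q <= q_cutoff & b$q <= q_cutoff
  up_a <- a$direction == "up"; down_a <- a$direction == "down"
  up_b <- b$direction == "up"; down_b <- b$direction == "down"
  on_x <- a$chrom == "X"
  prov <- function(rule) list(contrasts = c(attr(a, "contrast"),
                                            attr(b, "contrast")),
                              q_cutoff = q_cutoff, rule = rule)
  list(
    x_up = gene_set("X-up", a$gene[sig_both & up_a & down_b & on_x],
                    prov("X-linked, up in mes4_vs_WT, down in double_vs_mes4")),
    a_up = gene_set("A-up", a$gene[sig_both & up_a & down_b & !on_x],
                    prov("autosomal, up in mes4_vs_WT, down in double_vs_mes4")),
    a_down = gene_set("A-down", a$gene[sig_both & down_a & up_b & !on_x],
                      prov("autosomal, down in mes4_vs_WT, up in double_vs_mes4")),
    same_sign = gene_set("same-sign",
                         a$gene[sig_both & ((up_a & up_b) | (down_a & down_b))],
                         prov("significant in both contrasts, same sign")),
    both_significant = gene_set("both-significant", a$gene[sig_both],
                                prov("significant in both contrasts")))
}

#' Exact hypergeometric test for gene-set overlap
#'
#' Upper-tail probability that two sets of the observed sizes, drawn
#' without replacement from a universe of `universe_size` genes, share at
#' least the observed number of members. Computed exactly, in log space, so
#' that extreme enrichments (p ~ 1e-300 and below) remain representable via
#' `log10_p`.
#'
#' @param set_a,set_b `gene_set`s or character vectors; alternatively pass
#'   sizes via `n_a`, `n_b`, `n_overlap`
#' @param universe_size number of genes in the universe
#' @param n_a,n_b,n_overlap optional explicit counts (used when `set_a` is
#'   missing)
#' @return list of class `overlap_test`: `n_a`, `n_b`, `n_overlap`,
#'   `universe`, `p`, `log10_p`
#' @export
hypergeometric_overlap <- function(set_a = NULL, set_b = NULL, universe_size,
                                   n_a = NULL, n_b = NULL, n_overlap = NULL) {
  if (!is.null(set_a)) {
    ga <- if (inherits(set_a, "gene_set")) set_a$genes else set_a
    gb <- if (inherits(set_b, "gene_set")) set_b$genes else set_b
    n_a <- length(unique(ga)); n_b <- length(unique(gb))
    n_overlap <- length(intersect(ga, gb))
  }
  if (n_a > universe_size || n_b > universe_size)
    stop("set larger than universe")
  if (n_overlap > min(n_a, n_b))
    stop("overlap exceeds the smaller set")
  # P(K >= k) for K ~ Hypergeometric(N, n_a, n_b)
  log_p <- stats::phyper(n_overlap - 1, n_a, universe_size - n_a, n_b,
                         lower.tail = FALSE, log.p = TRUE)
  structure(list(n_a = n_a, n_b = n_b, n_overlap = n_overlap,
                 universe = universe_size,
                 p = exp(log_p), log10_p = log_p / log(10)),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf("overlap %d of |A|=%d, |B|=%d in N=%d: p = %.3g (log10 p = %.1f)\n",
              x$n_overlap, x$n_a, x$n_b, x$universe, x$p, x$log10_p))
  invisible(x)
}

#' Fold-change anti-correlation between two contrasts
#'
#' Restricted to genes significant (q <= cutoff) in both contrasts
#' (optionally chromosome-filtered), regresses the second contrast's log2
#' fold changes on the first's by ordinary least squares and reports the
#' slope, intercept, Pearson R, regression p-value, and the count and
#' fraction of genes whose fold changes have opposite signs (the
#' antagonistically regulated share).
#'
#' @param contrast_a,contrast_b `contrast_result` tables on the same
#'   universe
#' @param chrom_filter optional chromosome restriction
#' @param q_cutoff significance cutoff (default 0.05)
#' @return list of class `anticorrelation_result`: `n`, `slope`,
#'   `intercept`, `r`, `p`, `n_opposite`, `fraction_opposite`
#' @export
anticorrelation <- function(contrast_a, contrast_b, chrom_filter = NULL,
                            q_cutoff = 0.05) {
  b <- contrast_b[match(contrast_a$gene, contrast_b$gene), ]
  keep <- contrast_a$q <= q_cutoff & b$q <= q_cutoff
  if (!is.null(chrom_filter)) keep <- keep & contrast_a$chrom %in% chrom_filter
  keep <- keep & !is.na(keep)
  n <- sum(keep)
  if (n < 3) stop("fewer than 3 genes significant in both contrasts")
  fa <- contrast_a$log2fc[keep]
  fb <- b$log2fc[keep]
  fit <- stats::lm(fb ~ fa)
  sm <- summary(fit)
  n_opp <- sum(sign(fa) * sign(fb) < 0)
  structure(list(n = n,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r = stats::cor(fa, fb),
                 p = sm$coefficients[2, 4],
                 n_opposite = n_opp,
                 fraction_opposite = n_opp / n),
            class = "anticorrelation_result")
}

#' Antagonistically regulated percentage
#'
#' Share of the genes significant in both contrasts that fall in the
#' antagonistic classes, as a percentage; e.g. 203 of the 205 X-linked
#' genes significant in both comparisons gives 99 percent.
#'
#' @param n_significant_both genes significant in both contrasts
#' @param n_antagonistic of these, genes in the antagonistic classes
#' @return list: `percent` (exact), `percent_rounded` (nearest integer)
#' @export
antagonistic_fraction <- function(n_significant_both, n_antagonistic) {
  if (n_significant_both == 0) stop("zero genes significant in both contrasts")
  if (n_antagonistic > n_significant_both)
    stop("antagonistic count exceeds total")
  pct <- 100 * n_antagonistic / n_significant_both
  list(percent = pct, percent_rounded = round(pct))
}
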