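#' Quantile-normalize an expression matrix across samples
#'
#' Forces every sample (column) onto the same empirical distribution: the
#' across-sample mean of order statistics. Within-column rank order is
#' preserved; ties share the mean of their tied ranks' reference values.
#' Applied to an already-normalized matrix it is a fixed point; exact
#' idempotence and exact distribution equality hold whenever the input has
#' no within-column ties (tied values are averaged, which perturbs their
#' column's empirical distribution by construction).
#'
#' By default all samples of all genotypes are normalized jointly, which is
#' required for cross-genotype fold changes to be comparable; set
#' `within = x$samples$genotype` to normalize within genotype groups
#' instead.
#'
#' @param x an `expr_data` object, or a bare numeric matrix
#' @param within optional grouping vector (one entry per sample); samples
#'   are normalized within each group separately
#' @return same type as the input, with normalized intensities
#' @export
quantile_normalize <- function(x, within = NULL) {
  m <- if (inherits(x, "expr_data")) x$exprs else x
  if (!is.matrix(m)) stop("input must be a matrix or expr_data")
  if (ncol(m) < 2) stop("quantile normalization needs >= 2 samples")
  if (is.null(within)) {
    out <- qnorm_matrix(m)
  } else {
    if (length(within) != ncol(m)) stop("`within` must have one entry per sample")
    out <- m
    for (g in unique(within)) {
      j <- which(within == g)
      if (length(j) < 2) stop("group '", g, "' has < 2 samples")
      out[, j] <- qnorm_matrix(m[, j, drop = FALSE])
    }
  }
  if (inherits(x, "expr_data")) {
    x$exprs <- out
    x
  } else out
}

#' @keywords internal
qnorm_matrix <- function(m) {
  ref <- rowMeans(apply(m, 2, sort))
  out <- apply(m, 2, function(col) {
    r <- rank(col, ties.method = "average")
    # fractional ranks (ties) take the mean of the bracketing order stats
    (ref[floor(r)] + ref[ceiling(r)]) / 2
  })
  dimnames(out) <- dimnames(m)
  out
}

#' Collapse probe sets to genes by averaging
#'
#' One output row per gene; each sample's value is the arithmetic mean of
#' the gene's probe-set values.
#'
#' @param x an `expr_data` object or matrix whose rows are probe sets
#' @param mapping data.frame with columns `probe_set`, `gene`; every probe
#'   set maps to exactly one gene
#' @return matrix with one row per gene (gene order = first appearance in
#'   `mapping` restricted to measured probe sets)
#' @export
collapse_probesets_mean <- function(x, mapping) {
  m <- if (inherits(x, "expr_data")) x$exprs else x
  mapping <- check_mapping(mapping, rownames(m))
  genes <- unique(mapping$gene)
  out <- t(vapply(genes, function(g) {
    ps <- mapping$probe_set[mapping$gene == g]
    colMeans(m[ps, , drop = FALSE])
  }, numeric(ncol(m))))
  rownames(out) <- genes
  colnames(out) <- colnames(m)
  out
}

#' Collapse probe-set level contrast results to genes by best significance
#'
#' For each gene, retains the probe set with the smallest q-value (ties
#' broken by smallest p, then lexicographic probe-set id) -- the rule for
#' carrying the most statistically significant evidence of misexpression to
#' the gene level.
#'
#' @param contrast a contrast result data.frame with a `gene` column holding
#'   probe-set ids and columns `p` and `q`
#' @param mapping data.frame with columns `probe_set`, `gene`
#' @return the input rows, one per gene, with `probe_set` recording the
#'   winning probe set and `gene` the gene id
#' @export
collapse_probesets_best <- function(contrast, mapping) {
  mapping <- check_mapping(mapping, contrast$gene)
  rows <- lapply(unique(mapping$gene), function(g) {
    ps <- mapping$probe_set[mapping$gene == g]
    sub <- contrast[contrast$gene %in% ps, , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    sub <- sub[order(sub$q, sub$p, sub$gene), , drop = FALSE]
    best <- sub[1, , drop = FALSE]
    best$probe_set <- best$gene
    best$gene <- g
    best
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  rownames(out) <- out$gene
  out
}

#' @keywords internal
check_mapping <- function(mapping, measured) {
  if (!all(c("probe_set", "gene") %in% names(mapping)))
    stop("mapping needs columns 'probe_set' and 'gene'")
  dup <- mapping$probe_set[duplicated(mapping$probe_set)]
  if (length(dup))
    stop("probe set(s) mapped to more than one gene: ",
         paste(unique(dup), collapse = ", "))
  uncovered <- setdiff(measured, mapping$probe_set)
  if (length(uncovered))
    stop("probe set(s) without a gene mapping: ",
         paste(utils::head(uncovered, 5), collapse = ", "))
  mapping[mapping$probe_set %in% measured, , drop = FALSE]
}

#' Call expressed genes from detection labels
#'
#' A gene is called expressed when, among its replicates, it has two or
#' more Present calls, or at least one Present call together with at least
#' one Marginal call.
#'
#' @param calls character matrix of labels in P (Present), M (Marginal),
#'   A (Absent); rows = genes, columns = the replicates of one group
#'   (e.g. the wild-type samples)
#' @return named logical vector, one entry per gene
#' @export
call_expressed <- function(calls) {
  if (is.vector(calls)) calls <- matrix(calls, nrow = 1)
  bad <- setdiff(unique(as.vector(calls)), c("P", "M", "A"))
  if (length(bad)) stop("unknown detection label(s): ", paste(bad, collapse = ", "))
  n_p <- rowSums(calls == "P")
  n_m <- rowSums(calls == "M")
  out <- (n_p >= 2) | (n_p >= 1 & n_m >= 1)
  names(out) <- rownames(calls)
  out
}

#' Select the top-N most highly expressed genes
#'
#' Ranks genes by mean expression over a set of samples (typically the WT
#' replicates); used in place of detection calls when none are available,
#' e.g. selecting the most highly expressed X-linked genes.
#'
#' @param x an `expr_data` object
#' @param n number of genes to keep
#' @param samples sample ids to average over (default: WT genotype)
#' @param chrom optional chromosome filter
#' @return character vector of gene ids
#' @export
top_expressed <- function(x, n, samples = genotype_samples(x, "WT"),
                          chrom = NULL) {
  keep <- if (is.null(chrom)) rep(TRUE, nrow(x$exprs)) else x$genes$chrom %in% chrom
  mu <- rowMeans(x$exprs[keep, samples, drop = FALSE])
  names(sort(mu, decreasing = TRUE))[seq_len(min(n, length(mu)))]
}
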