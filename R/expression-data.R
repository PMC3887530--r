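#' Expression data container
#'
#' Bundles a genes x samples matrix of log2 intensities with sample metadata
#' (genotype, replicate) and gene metadata (chromosome, coordinates,
#' optional expression category). The lightweight list layout follows the
#' style of limma's EList.
#'
#' @param exprs numeric matrix, rows = genes/probe sets, columns = samples.
#'   Row and column names are required and must be unique.
#' @param samples data.frame with columns `sample`, `genotype`, `replicate`;
#'   one row per column of `exprs`.
#' @param genes data.frame with at least columns `gene` and `chrom`
#'   (chromosome in I, II, III, IV, V, X); optionally `strand`, `tss`,
#'   `start`, `end`, `category`. One row per row of `exprs`.
#'
#' @return An object of class `expr_data`: a list with elements `exprs`,
#'   `samples`, `genes`.
#' @export
expression_data <- function(exprs, samples, genes) {
  if (!is.matrix(exprs) || !is.numeric(exprs))
    stop("`exprs` must be a numeric matrix")
  if (is.null(rownames(exprs)) || is.null(colnames(exprs)))
    stop("`exprs` must have row and column names")
  if (anyDuplicated(colnames(exprs)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(exprs)[duplicated(colnames(exprs))]), collapse = ", "))
  if (any(!is.finite(exprs))) {
    bad <- which(!is.finite(exprs), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite intensity at gene '%s', sample '%s'",
                 rownames(exprs)[bad[1]], colnames(exprs)[bad[2]]))
  }
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  req <- setdiff(c("sample", "genotype", "replicate"), names(samples))
  if (length(req)) stop("sample sheet missing column(s): ", paste(req, collapse = ", "))
  missing_meta <- setdiff(colnames(exprs), samples$sample)
  if (length(missing_meta))
    stop("sample(s) in matrix absent from sample sheet: ",
         paste(missing_meta, collapse = ", "))
  samples <- samples[match(colnames(exprs), samples$sample), , drop = FALSE]
  rownames(samples) <- samples$sample
  if (anyDuplicated(samples$sample))
    stop("duplicate sample ids in sample sheet")
  req <- setdiff(c("gene", "chrom"), names(genes))
  if (length(req)) stop("gene annotation missing column(s): ", paste(req, collapse = ", "))
  missing_ann <- setdiff(rownames(exprs), genes$gene)
  if (length(missing_ann))
    stop("gene(s) in matrix absent from annotation: ",
         paste(utils::head(missing_ann, 5), collapse = ", "))
  genes <- genes[match(rownames(exprs), genes$gene), , drop = FALSE]
  rownames(genes) <- genes$gene
  bad_chrom <- setdiff(unique(genes$chrom), CHROMOSOMES)
  if (length(bad_chrom))
    stop("unknown chromosome label(s): ", paste(bad_chrom, collapse = ", "))
  structure(list(exprs = exprs, samples = samples, genes = genes),
            class = "expr_data")
}

#' Chromosome labels of the C. elegans nuclear genome
#' @keywords internal
CHROMOSOMES <- c("I", "II", "III", "IV", "V", "X")

#' Autosome labels
#' @keywords internal
AUTOSOMES <- c("I", "II", "III", "IV", "V")

#' @export
print.expr_data <- function(x, ...) {
  cat(sprintf("expr_data: %d genes x %d samples\n", nrow(x$exprs), ncol(x$exprs)))
  tab <- table(x$samples$genotype)
  cat("genotypes:", paste(sprintf("%s (n=%d)", names(tab), tab), collapse = ", "), "\n")
  cat("chromosomes:",
      paste(sprintf("%s:%d", names(table(x$genes$chrom)), table(x$genes$chrom)),
            collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.expr_data <- function(x) dim(x$exprs)

#' Subset an expression container by gene and/or sample
#'
#' @param x an `expr_data` object
#' @param i gene index, logical vector, or character vector of gene ids
#' @param j sample index, logical vector, or character vector of sample ids
#' @param ... ignored
#' @export
`[.expr_data` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$exprs))
  if (missing(j)) j <- seq_len(ncol(x$exprs))
  expression_data(x$exprs[i, j, drop = FALSE],
                  x$samples[j, , drop = FALSE],
                  x$genes[i, , drop = FALSE])
}

#' Sample ids belonging to one genotype
#'
#' @param x an `expr_data` object
#' @param genotype genotype label as used in the sample sheet
#' @return character vector of sample ids
#' @export
genotype_samples <- function(x, genotype) {
  s <- x$samples$sample[x$samples$genotype == genotype]
  if (!length(s)) stop("no samples with genotype '", genotype, "'")
  s
}
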