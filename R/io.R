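#' Read an expression matrix with its sample sheet and gene annotation
#'
#' Reads the tab-separated layout written by [write_expression_bundle()]:
#' a matrix file (first column gene id, one numeric column per sample), a
#' sample sheet (`sample`, `genotype`, `replicate`) and a gene annotation
#' table (`gene`, `chrom`, `strand`, `tss`, `start`, `end`, optional
#' `category`; 1-based inclusive coordinates).
#'
#' @param matrix_path path to the expression TSV
#' @param sample_sheet_path path to the sample sheet TSV
#' @param annotation_path path to the annotation TSV
#' @return an [expression_data()] object
#' @export
read_expression_matrix <- function(matrix_path, sample_sheet_path, annotation_path) {
  for (p in c(matrix_path, sample_sheet_path, annotation_path))
    if (!file.exists(p)) stop("file not found: ", p)
  raw <- utils::read.table(matrix_path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("expression matrix needs a gene column and >=1 sample column")
  ids <- as.character(raw[[1]])
  vals <- raw[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(vals[[j]]))))[1]
      stop(sprintf("non-numeric cell in column '%s', row %d of %s",
                   names(vals)[j], bad, matrix_path))
    }
  }
  if (anyDuplicated(ids))
    stop("duplicate gene id(s) in ", matrix_path, ": ",
         paste(utils::head(unique(ids[duplicated(ids)]), 5), collapse = ", "))
  m <- as.matrix(vals)
  rownames(m) <- ids
  samples <- utils::read.table(sample_sheet_path, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
  genes <- read_annotation(annotation_path)
  expression_data(m, samples, genes)
}

#' Read a gene annotation table
#'
#' @param path annotation TSV with columns `gene`, `chrom`, and usually
#'   `strand`, `tss`, `start`, `end` (1-based inclusive), `category`
#' @return data.frame keyed by gene id
#' @export
read_annotation <- function(path) {
  ann <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("gene", "chrom") %in% names(ann)))
    stop("annotation must have 'gene' and 'chrom' columns")
  if (all(c("start", "end") %in% names(ann)) &&
      any(ann$end < ann$start))
    stop("annotation has end < start at gene ",
         ann$gene[which(ann$end < ann$start)[1]])
  rownames(ann) <- ann$gene
  ann
}

#' Read a detection-call matrix
#'
#' Present/Marginal/Absent labels, one row per gene, one column per sample.
#'
#' @param path calls TSV (first column gene id)
#' @return character matrix with P/M/A entries
#' @export
read_detection_calls <- function(path) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(raw[, -1, drop = FALSE])
  rownames(m) <- as.character(raw[[1]])
  bad <- setdiff(unique(as.vector(m)), c("P", "M", "A"))
  if (length(bad)) stop("unknown detection label(s): ", paste(bad, collapse = ", "))
  m
}

#' Write an expression bundle to a directory
#'
#' Writes matrix.tsv, samples.tsv and annotation.tsv in the dialect read by
#' [read_expression_matrix()].
#'
#' @param x an `expr_data` object
#' @param dir output directory (created if absent)
#' @return invisibly, the paths written
#' @export
write_expression_bundle <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(matrix = file.path(dir, "matrix.tsv"),
             samples = file.path(dir, "samples.tsv"),
             annotation = file.path(dir, "annotation.tsv"))
  write_tsv(data.frame(gene = rownames(x$exprs), x$exprs, check.names = FALSE),
            paths["matrix"])
  write_tsv(x$samples, paths["samples"])
  write_tsv(x$genes, paths["annotation"])
  invisible(paths)
}

#' @keywords internal
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read ChIP peaks from a BED file
#'
#' Accepts BED3 or more columns (extra columns ignored). BED coordinates are
#' 0-based half-open; the returned GRanges is 1-based inclusive, the
#' convention used throughout the package.
#'
#' @param path BED file
#' @return a `GRanges` of peak intervals, sorted
#' @export
read_peaks_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  info <- file.info(path)
  if (info$size == 0)
    return(GenomicRanges::GRanges())
  bed <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(bed) < 3) stop("BED file needs >=3 columns: ", path)
  if (any(bed[[3]] <= bed[[2]]))
    stop("BED interval with end <= start at line ",
         which(bed[[3]] <= bed[[2]])[1], " of ", path)
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(bed[[1]]),
    ranges = IRanges::IRanges(start = bed[[2]] + 1L, end = bed[[3]]))
  GenomicRanges::sort(gr)
}

#' Write a GRanges of peaks as BED3
#'
#' Inverse of [read_peaks_bed()]: converts the internal 1-based inclusive
#' intervals back to 0-based half-open BED. Round-tripping a sorted BED3
#' file through read and write is byte-identical.
#'
#' @param gr a `GRanges`
#' @param path output path
#' @return invisibly, `path`
#' @export
write_peaks_bed <- function(gr, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
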