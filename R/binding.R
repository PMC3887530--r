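#' Scale a ChIP intensity track
#'
#' Scales intensity ratios to a median absolute deviation of exactly 1 and
#' shifts the median to exactly 1 (divide by the raw MAD, then add
#' 1 - median). The MAD is the unscaled median absolute deviation (no
#' 1.4826 consistency constant).
#'
#' @param values numeric vector of intensity ratios (>= 2 distinct finite
#'   values)
#' @return scaled vector with median 1 and MAD 1
#' @export
scale_chip_track <- function(values) {
  if (any(!is.finite(values))) stop("values must be finite")
  if (length(unique(values)) < 2) stop("need >= 2 distinct values")
  md <- stats::mad(values, constant = 1)
  if (md == 0) stop("median absolute deviation is zero")
  out <- values / md
  out - stats::median(out) + 1
}

#' Retain peaks consistent across biological replicates
#'
#' Keeps the peaks of a designated reference replicate that overlap (by at
#' least `min_overlap` bp, default 1) a peak in at least one other
#' replicate. Coordinates of the reference replicate are kept unchanged.
#'
#' @param replicate_peaks list of >= 2 `GRanges`, one per replicate
#' @param reference index of the replicate whose coordinates are retained
#' @param min_overlap minimum overlap in bp (default 1)
#' @return `GRanges` of retained reference peaks
#' @export
consistent_peaks <- function(replicate_peaks, reference = 1, min_overlap = 1) {
  if (length(replicate_peaks) < 2) stop("need >= 2 replicates")
  ref <- replicate_peaks[[reference]]
  others <- replicate_peaks[-reference]
  hit <- rep(FALSE, length(ref))
  for (o in others) {
    ml <- merge_seqlevels(ref, o)
    ov <- GenomicRanges::findOverlaps(ml[[1]], ml[[2]],
                                      minoverlap = min_overlap)
    hit[unique(S4Vectors::queryHits(ov))] <- TRUE
  }
  ref[hit]
}

# findOverlaps warns when the two objects share no seqlevels (e.g. peaks
# restricted to one chromosome); putting both on the union avoids that.
#' @keywords internal
merge_seqlevels <- function(a, b) {
  lv <- union(GenomeInfoDb::seqlevels(a), GenomeInfoDb::seqlevels(b))
  GenomeInfoDb::seqlevels(a) <- lv
  GenomeInfoDb::seqlevels(b) <- lv
  list(a, b)
}

#' @keywords internal
annotation_granges <- function(annotation, what = c("body", "promoter"),
                               window = 500) {
  what <- match.arg(what)
  if (what == "promoter") {
    if (!"tss" %in% names(annotation) || any(is.na(annotation$tss)))
      stop("gene(s) missing TSS: ",
           paste(utils::head(annotation$gene[is.na(annotation$tss)], 5),
                 collapse = ", "))
    start <- pmax(1L, annotation$tss - window)
    end <- annotation$tss + window
  } else {
    start <- annotation$start
    end <- annotation$end
  }
  GenomicRanges::GRanges(annotation$chrom,
                         IRanges::IRanges(start = start, end = end),
                         gene = annotation$gene)
}

#' Call promoter-bound genes
#'
#' A gene is promoter bound when some single peak overlaps the window from
#' `window` bp upstream of the transcript start site to `window` bp
#' downstream by at least `min_overlap` bp. The overlap requirement applies
#' per individual peak, not to the union of peaks. The window is symmetric,
#' so strand only matters for asymmetric variants.
#'
#' @param peaks a `GRanges` of peaks (1-based inclusive, as returned by
#'   [read_peaks_bed()])
#' @param annotation gene annotation data.frame with `gene`, `chrom`, `tss`
#' @param window half-width of the TSS window in bp (default 500)
#' @param min_overlap minimum per-peak overlap in bp (default 200)
#' @return list of class `binding_calls`: `bound` (named logical vector
#'   over all annotation genes), `rule` (parameters used)
#' @export
call_promoter_bound <- function(peaks, annotation, window = 500,
                                min_overlap = 200) {
  prom <- annotation_granges(annotation, "promoter", window = window)
  ml <- merge_seqlevels(prom, peaks)
  ov <- GenomicRanges::findOverlaps(ml[[1]], ml[[2]], minoverlap = min_overlap)
  bound <- rep(FALSE, nrow(annotation))
  names(bound) <- annotation$gene
  bound[unique(S4Vectors::queryHits(ov))] <- TRUE
  structure(list(bound = bound,
                 rule = list(type = "promoter", window = window,
                             min_overlap = min_overlap)),
            class = "binding_calls")
}

#' Call gene-body-bound genes by coverage fraction
#'
#' A gene is body bound when the union of peak overlaps covers at least
#' `min_fraction` of the gene body. The default fraction (0.5) is an
#' explicit package choice standing in for factor-specific definitions
#' delegated to upstream studies, and is recorded in the call provenance.
#'
#' @param peaks a `GRanges` of peaks
#' @param annotation gene annotation with `gene`, `chrom`, `start`, `end`
#' @param min_fraction required covered fraction of the gene body, in (0, 1]
#' @return a `binding_calls` list (with per-gene `coverage` fractions)
#' @export
call_body_bound <- function(peaks, annotation, min_fraction = 0.5) {
  if (min_fraction <= 0 || min_fraction > 1)
    stop("min_fraction must lie in (0, 1]")
  ml <- merge_seqlevels(annotation_granges(annotation, "body"),
                        GenomicRanges::reduce(peaks))
  body <- ml[[1]]; merged <- ml[[2]]
  ov <- GenomicRanges::findOverlaps(body, merged)
  covered <- numeric(nrow(annotation))
  if (length(ov)) {
    inter <- GenomicRanges::pintersect(body[S4Vectors::queryHits(ov)],
                                       merged[S4Vectors::subjectHits(ov)])
    w <- tapply(GenomicRanges::width(inter), S4Vectors::queryHits(ov), sum)
    covered[as.integer(names(w))] <- w
  }
  frac <- covered / GenomicRanges::width(body)
  names(frac) <- annotation$gene
  bound <- frac >= min_fraction
  structure(list(bound = bound, coverage = frac,
                 rule = list(type = "body", min_fraction = min_fraction)),
            class = "binding_calls")
}

#' Co-binding overlap of two factors
#'
#' Venn-style counts of genes bound by each of two factors, with the exact
#' hypergeometric overlap test (log10 p reported for extreme overlaps).
#'
#' @param calls_a,calls_b `binding_calls` (or named logical vectors) on the
#'   same gene universe
#' @param universe optional character vector restricting the universe
#'   (default: the genes the calls are defined on)
#' @return list: `n_a`, `n_b`, `n_both`, `a_only`, `b_only`, `neither`,
#'   `test` (an `overlap_test`)
#' @export
cobinding_venn <- function(calls_a, calls_b, universe = NULL) {
  a <- if (inherits(calls_a, "binding_calls")) calls_a$bound else calls_a
  b <- if (inherits(calls_b, "binding_calls")) calls_b$bound else calls_b
  if (is.null(universe)) {
    if (!setequal(names(a), names(b))) stop("calls are on different universes")
    universe <- names(a)
  } else {
    if (!all(universe %in% names(a)) || !all(universe %in% names(b)))
      stop("calls are on different universes")
  }
  a <- a[universe]; b <- b[universe]
  n_both <- sum(a & b)
  test <- hypergeometric_overlap(universe_size = length(universe),
                                 n_a = sum(a), n_b = sum(b),
                                 n_overlap = n_both)
  list(n_a = sum(a), n_b = sum(b), n_both = n_both,
       a_only = sum(a & !b), b_only = sum(!a & b),
       neither = sum(!a & !b), test = test)
}

#' Binding enrichment within gene sets
#'
#' For each factor's binding calls and each gene set, compares the observed
#' number of bound set members with the expectation under uniform sampling
#' from the universe, with enrichment and depletion hypergeometric tails
#' tiered at 0.05 / 0.001 / 1e-10.
#'
#' @param calls named list of `binding_calls` (or named logical vectors),
#'   one per factor; combinations like "MES4+LIN54" can be passed as
#'   pre-computed logical vectors
#' @param gene_sets named list of `gene_set`s (e.g. X-up, A-up, A-down)
#' @param universe character vector of universe gene ids
#' @return data.frame: factor, set, n_set, n_bound, observed, expected,
#'   p_enrichment, p_depletion, tiers
#' @export
binding_enrichment_in_sets <- function(calls, gene_sets, universe) {
  rows <- list()
  for (fac in names(calls)) {
    bound <- if (inherits(calls[[fac]], "binding_calls"))
      calls[[fac]]$bound else calls[[fac]]
    if (!all(universe %in% names(bound)))
      stop("calls for '", fac, "' do not cover the universe")
    bound <- bound[universe]
    bound_ids <- universe[bound]
    for (sn in names(gene_sets)) {
      gs <- gene_sets[[sn]]
      ids <- if (inherits(gs, "gene_set")) gs$genes else gs
      if (length(setdiff(ids, universe)))
        stop("set '", sn, "' not contained in universe")
      obs <- length(intersect(ids, bound_ids))
      k <- length(bound_ids); n_set <- length(ids); N <- length(universe)
      p_enr <- stats::phyper(obs - 1, k, N - k, n_set, lower.tail = FALSE)
      p_dep <- stats::phyper(obs, k, N - k, n_set, lower.tail = TRUE)
      rows[[length(rows) + 1]] <- data.frame(
        factor = fac, set = sn, n_set = n_set, n_bound = k,
        observed = obs, expected = n_set * k / N,
        p_enrichment = p_enr, p_depletion = p_dep,
        tier_enrichment = signif_tier(p_enr),
        tier_depletion = signif_tier(p_dep),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
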