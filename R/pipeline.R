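#' Pipeline configuration
#'
#' Collects every tunable parameter of the end-to-end analysis. Either a
#' `simulate` block (arguments to [sim_config()]) or an `inputs` block
#' (paths: `matrix`, `samples`, `annotation`, optionally `calls` and a
#' named list `peaks` of per-factor BED path vectors) must be given.
#'
#' @param simulate list of [sim_config()] arguments, or NULL
#' @param inputs list of input paths, or NULL
#' @param q_cutoff significance cutoff for all contrasts (default 0.05)
#' @param alpha restoration-test significance level (default 0.001)
#' @param binding list: `window`, `min_overlap`, `body_min_fraction`,
#'   `replicate_min_overlap`
#' @param outdir output directory for the report bundle, or NULL to skip
#'   writing
#' @param seed master seed (overrides any seed in the simulate block)
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(simulate = list(), inputs = NULL,
                            q_cutoff = 0.05, alpha = 0.001,
                            binding = list(window = 500, min_overlap = 200,
                                           body_min_fraction = 0.5,
                                           replicate_min_overlap = 1),
                            outdir = NULL, seed = 1) {
  if (is.null(simulate) && is.null(inputs))
    stop("config needs a 'simulate' block or an 'inputs' block")
  if (q_cutoff <= 0 || q_cutoff > 1) stop("q_cutoff must lie in (0, 1]")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  structure(list(simulate = simulate, inputs = inputs, q_cutoff = q_cutoff,
                 alpha = alpha, binding = binding, outdir = outdir,
                 seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose top-level keys are the arguments of
#'   [pipeline_config()]
#' @return a `pipeline_config`
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  defaults <- formals(pipeline_config)
  args <- utils::modifyList(
    list(q_cutoff = 0.05, alpha = 0.001,
         binding = eval(defaults$binding), outdir = NULL, seed = 1,
         simulate = list(), inputs = NULL),
    y)
  do.call(pipeline_config, args)
}

#' Run the full antagonism analysis pipeline
#'
#' Stages: load or simulate the data; quantile-normalize; fit the five
#' genotype contrasts with moderated t and q-values; classify the
#' antagonistic gene classes (X-up, A-up, A-down); profile and
#' restoration-test each class; summarize chromosomes; test
#' expression-category enrichment; process ChIP peaks (replicate
#' consistency, promoter/body binding, co-binding, binding enrichment in
#' the classes). All randomness derives from the configured seed, and a
#' rerun with the same config writes a byte-identical summary.
#'
#' @param config a `pipeline_config` (or list coercible to one)
#' @return list of class `report_bundle`: `data`, `contrasts`, `sets`,
#'   `profiles`, `verdicts`, `chromosomes`, `enrichment`, `binding`,
#'   `anticorrelation`, `summary`, `provenance` (and `truth` when
#'   simulated)
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    config <- do.call(pipeline_config, config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  truth <- NULL; peaks <- NULL; calls <- NULL
  if (!is.null(config$inputs)) {
    inp <- config$inputs
    x <- stage("load", read_expression_matrix(inp$matrix, inp$samples,
                                              inp$annotation))
    if (!is.null(inp$calls)) calls <- read_detection_calls(inp$calls)
    if (!is.null(inp$peaks))
      peaks <- lapply(inp$peaks, function(paths) lapply(paths, read_peaks_bed))
    if (!is.null(inp$truth))
      truth <- utils::read.table(inp$truth, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE)
  } else {
    sc <- do.call(sim_config, utils::modifyList(config$simulate,
                                                list(seed = config$seed)))
    sim <- stage("simulate", simulate_experiment(sc))
    x <- sim$data; calls <- sim$calls; truth <- sim$truth
    peaks <- stage("simulate_peaks", simulate_peaks(truth, x$genes, sc))
  }

  xn <- stage("normalize", quantile_normalize(x))
  contrasts <- stage("de", run_all_contrasts(xn, q_cutoff = config$q_cutoff))
  sets <- stage("classify",
                classify_antagonistic(contrasts$mes4_vs_WT,
                                      contrasts$double_vs_mes4,
                                      q_cutoff = config$q_cutoff))

  class_sets <- sets[c("x_up", "a_up", "a_down")]
  profiles <- list(); verdicts <- list()
  for (nm in names(class_sets)) {
    if (length(class_sets[[nm]]$genes) >= 3) {
      profiles[[nm]] <- stage("profile", log2fc_profile(xn, class_sets[[nm]]))
      verdicts[[nm]] <- stage("restore",
                              restoration_test(profiles[[nm]],
                                               alpha = config$alpha))
    }
  }

  expressed <- NULL
  if (!is.null(calls)) {
    wt <- genotype_samples(xn, "WT")
    expressed <- call_expressed(calls[rownames(xn$exprs), wt, drop = FALSE])
  }
  chroms <- stage("chromosomes", chromosome_summary(xn, expressed))

  categories <- NULL; enrich <- list()
  if (!is.null(xn$genes$category)) {
    categories <- stats::setNames(xn$genes$category, xn$genes$gene)
    auto_univ <- xn$genes$gene[xn$genes$chrom %in% AUTOSOMES]
    x_univ <- xn$genes$gene[xn$genes$chrom == "X"]
    enrich <- stage("enrich", list(
      x_up = category_enrichment(sets$x_up$genes, categories, x_univ),
      a_up = category_enrichment(sets$a_up$genes, categories, auto_univ),
      a_down = category_enrichment(sets$a_down$genes, categories, auto_univ)))
  }

  binding <- NULL
  if (!is.null(peaks)) {
    binding <- stage("bind", run_binding_stage(peaks, xn$genes, class_sets,
                                               config$binding))
  }

  anticorr <- NULL
  auto_n <- sum(contrasts$mes4_vs_WT$chrom %in% AUTOSOMES &
                  contrasts$mes4_vs_WT$significant &
                  contrasts$double_vs_mes4[contrasts$mes4_vs_WT$gene, "significant"])
  if (auto_n >= 3)
    anticorr <- stage("anticorrelation",
                      anticorrelation(contrasts$mes4_vs_WT,
                                      contrasts$double_vs_mes4,
                                      chrom_filter = AUTOSOMES,
                                      q_cutoff = config$q_cutoff))

  summary <- build_summary(contrasts, sets, anticorr, verdicts, config)
  bundle <- structure(list(data = xn, contrasts = contrasts, sets = sets,
                           profiles = profiles, verdicts = verdicts,
                           chromosomes = chroms, enrichment = enrich,
                           binding = binding, anticorrelation = anticorr,
                           truth = truth, summary = summary,
                           provenance = list(
                             config = unclass(config),
                             package_version = as.character(
                               utils::packageVersion("mesdrm")),
                             seed = config$seed)),
                      class = "report_bundle")
  if (!is.null(config$outdir)) write_report_bundle(bundle, config$outdir)
  bundle
}

#' @keywords internal
run_binding_stage <- function(peaks, annotation, class_sets, bp) {
  calls <- list()
  for (fac in names(peaks)) {
    pk <- if (length(peaks[[fac]]) >= 2)
      consistent_peaks(peaks[[fac]], min_overlap = bp$replicate_min_overlap)
    else peaks[[fac]][[1]]
    calls[[fac]] <- if (fac == "MES4")
      call_body_bound(pk, annotation, min_fraction = bp$body_min_fraction)
    else
      call_promoter_bound(pk, annotation, window = bp$window,
                          min_overlap = bp$min_overlap)
  }
  venns <- list()
  if (all(c("MES4", "LIN54") %in% names(calls)))
    venns$MES4_LIN54 <- cobinding_venn(calls$MES4, calls$LIN54)
  if (all(c("MES4", "EFL1") %in% names(calls)))
    venns$MES4_EFL1 <- cobinding_venn(calls$MES4, calls$EFL1)
  enr_calls <- lapply(calls, `[[`, "bound")
  if (all(c("MES4", "LIN54") %in% names(calls)))
    enr_calls[["MES4+LIN54"]] <- calls$MES4$bound & calls$LIN54$bound
  if (all(c("MES4", "EFL1") %in% names(calls)))
    enr_calls[["MES4+EFL1"]] <- calls$MES4$bound & calls$EFL1$bound
  enrichment <- binding_enrichment_in_sets(enr_calls, class_sets,
                                           annotation$gene)
  list(calls = calls, venns = venns, enrichment = enrichment)
}

#' @keywords internal
build_summary <- function(contrasts, sets, anticorr, verdicts, config) {
  per_contrast <- lapply(contrasts, function(ct) {
    sig <- ct$significant
    list(n_significant = sum(sig),
         x_up = sum(sig & ct$chrom == "X" & ct$direction == "up"),
         x_down = sum(sig & ct$chrom == "X" & ct$direction == "down"),
         autosomal_up = sum(sig & ct$chrom != "X" & ct$direction == "up"),
         autosomal_down = sum(sig & ct$chrom != "X" & ct$direction == "down"),
         pi0 = attr(ct, "pi0"))
  })
  both_x <- sum(sets$both_significant$genes %in%
                  contrasts$mes4_vs_WT$gene[contrasts$mes4_vs_WT$chrom == "X"])
  both_a <- length(sets$both_significant$genes) - both_x
  n_xup <- length(sets$x_up$genes)
  n_antag_a <- length(sets$a_up$genes) + length(sets$a_down$genes)
  list(
    contrasts = per_contrast,
    class_sizes = list(x_up = n_xup,
                       a_up = length(sets$a_up$genes),
                       a_down = length(sets$a_down$genes),
                       same_sign = length(sets$same_sign$genes)),
    antagonistic_fraction_x = if (both_x > 0)
      antagonistic_fraction(both_x, n_xup) else NULL,
    antagonistic_fraction_autosomal = if (both_a > 0)
      antagonistic_fraction(both_a, n_antag_a) else NULL,
    anticorrelation = if (!is.null(anticorr))
      anticorr[c("n", "slope", "intercept", "r", "fraction_opposite")] else NULL,
    restoration = lapply(verdicts, `[[`, "verdict"),
    q_cutoff = config$q_cutoff)
}

#' Write a report bundle to disk
#'
#' Writes one TSV per contrast and per gene set, profile and enrichment
#' TSVs, binding-call TSVs, and `summary.json` / `provenance.json`. The
#' JSON files are written deterministically (no timestamps), so identical
#' runs produce byte-identical summaries.
#'
#' @param bundle a `report_bundle`
#' @param dir output directory
#' @return invisibly, `dir`
#' @export
write_report_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(bundle$contrasts)) {
    ct <- bundle$contrasts[[nm]]
    write_tsv(ct[, c("gene", "chrom", "log2fc", "t", "p", "q", "direction")],
              file.path(dir, paste0("contrast_", nm, ".tsv")))
  }
  for (nm in c("x_up", "a_up", "a_down", "same_sign")) {
    gs <- bundle$sets[[nm]]
    a <- bundle$contrasts$mes4_vs_WT
    b <- bundle$contrasts$double_vs_mes4
    df <- data.frame(gene = gs$genes,
                     chrom = a[gs$genes, "chrom"],
                     log2fc_mes4_vs_WT = a[gs$genes, "log2fc"],
                     q_mes4_vs_WT = a[gs$genes, "q"],
                     log2fc_double_vs_mes4 = b[gs$genes, "log2fc"],
                     q_double_vs_mes4 = b[gs$genes, "q"])
    write_tsv(df, file.path(dir, paste0("set_", nm, ".tsv")))
  }
  for (nm in names(bundle$profiles)) {
    pr <- bundle$profiles[[nm]]
    write_tsv(data.frame(gene = rownames(pr$fc), pr$fc, check.names = FALSE),
              file.path(dir, paste0("profile_", nm, ".tsv")))
  }
  for (nm in names(bundle$enrichment))
    write_tsv(bundle$enrichment[[nm]],
              file.path(dir, paste0("enrichment_", nm, ".tsv")))
  if (!is.null(bundle$binding)) {
    for (fac in names(bundle$binding$calls)) {
      bc <- bundle$binding$calls[[fac]]
      write_tsv(data.frame(gene = names(bc$bound), bound = bc$bound),
                file.path(dir, paste0("binding_", fac, ".tsv")))
    }
    write_tsv(bundle$binding$enrichment,
              file.path(dir, "binding_enrichment.tsv"))
    venns <- lapply(bundle$binding$venns, function(v) {
      v$test <- v$test[c("n_overlap", "p", "log10_p")]
      v
    })
    jsonlite::write_json(venns, file.path(dir, "binding_venns.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  jsonlite::write_json(bundle$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  jsonlite::write_json(bundle$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", force = TRUE)
  invisible(dir)
}
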