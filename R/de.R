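#' Fit a two-group contrast
#'
#' Per-gene log2 fold change and pooled within-group variance for a
#' B-versus-A comparison (log2FC = mean B - mean A, so positive values mean
#' higher expression in group B).
#'
#' @param x an `expr_data` object or log2 matrix
#' @param group_a,group_b character vectors of sample ids (disjoint, each
#'   with >= 2 samples)
#' @param label contrast label, e.g. "mes4_vs_WT" (B_vs_A)
#' @return list of class `contrast_fit`: `log2fc`, `s2` (pooled variance),
#'   `df` (residual degrees of freedom, n_A + n_B - 2), `n_a`, `n_b`,
#'   `genes`, `label`
#' @export
fit_contrast <- function(x, group_a, group_b, label = "B_vs_A") {
  m <- if (inherits(x, "expr_data")) x$exprs else x
  if (length(intersect(group_a, group_b)))
    stop("groups must be disjoint")
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs >= 2 samples")
  missing <- setdiff(c(group_a, group_b), colnames(m))
  if (length(missing)) stop("unknown sample id(s): ", paste(missing, collapse = ", "))
  a <- m[, group_a, drop = FALSE]
  b <- m[, group_b, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  mean_a <- rowMeans(a); mean_b <- rowMeans(b)
  ss_a <- rowSums((a - mean_a)^2)
  ss_b <- rowSums((b - mean_b)^2)
  df <- na + nb - 2L
  structure(list(log2fc = mean_b - mean_a,
                 s2 = (ss_a + ss_b) / df,
                 df = df, n_a = na, n_b = nb,
                 genes = rownames(m), label = label),
            class = "contrast_fit")
}

#' Estimate empirical-Bayes variance hyperparameters
#'
#' Method-of-moments fit of the scaled-inverse-chi-square prior on gene
#' variances, using the digamma/trigamma moment identities for log sample
#' variances: with e_g = log(s_g^2) - digamma(d_g/2) + log(d_g/2),
#' E[e] = log(s0^2) + digamma(d0/2) - log(d0/2) and
#' Var[e] = trigamma(d_g/2) + trigamma(d0/2). The trigamma equation is
#' inverted by Newton iteration (tolerance 1e-8). If the empirical variance
#' of e does not exceed its sampling component, the prior is degenerate:
#' d0 = Inf and every posterior variance equals s0^2.
#'
#' Genes with s_g^2 = 0 are excluded from estimation but still receive a
#' (strictly positive) posterior variance via [moderated_t_test()].
#'
#' @param s2 vector of per-gene pooled variances
#' @param df residual degrees of freedom (scalar or per-gene vector)
#' @return list of class `ebayes_hyper`: `d0` (prior df, possibly Inf),
#'   `s0_2` (prior variance), `s2_post` (posterior variances, same length
#'   as `s2`)
#' @export
estimate_hyperparams <- function(s2, df) {
  if (length(df) == 1) df <- rep(df, length(s2))
  if (any(df <= 0)) stop("degrees of freedom must be > 0")
  pos <- s2 > 0
  if (all(!pos)) stop("all variances are zero")
  if (sum(pos) < 10) stop("need >= 10 genes with positive variance")
  z <- log(s2[pos])
  e <- z - digamma(df[pos] / 2) + log(df[pos] / 2)
  emean <- mean(e)
  evar <- stats::var(e) - mean(trigamma(df[pos] / 2))
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_2 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_2 <- exp(emean)
  }
  s2_post <- posterior_var(s2, df, d0, s0_2)
  structure(list(d0 = d0, s0_2 = s0_2, s2_post = s2_post),
            class = "ebayes_hyper")
}

#' @keywords internal
posterior_var <- function(s2, df, d0, s0_2) {
  if (is.infinite(d0)) rep(s0_2, length(s2))
  else (d0 * s0_2 + df * s2) / (d0 + df)
}

#' Invert the trigamma function by Newton iteration
#'
#' Solves trigamma(x) = y for x > 0 to a tolerance of 1e-8.
#' @param y positive target value
#' @return x with trigamma(x) = y
#' @keywords internal
trigamma_inverse <- function(y) {
  if (y <= 0) stop("trigamma_inverse needs y > 0")
  # trigamma(x) ~ 1/x for large x, ~ 1/x^2 for small x: start in between
  x <- 0.5 + 1 / y
  for (i in 1:100) {
    f <- trigamma(x) - y
    step <- f / psigamma(x, 2)          # derivative is negative
    x_new <- x - step
    if (x_new <= 0) x_new <- x / 2
    if (abs(x_new - x) < 1e-8 * max(1, x)) return(x_new)
    x <- x_new
  }
  x
}

#' Moderated t-statistics and p-values
#'
#' Shrinks each gene's variance toward the prior, then computes
#' t = log2FC / (s_post * sqrt(1/n_A + 1/n_B)) with d0 + d_g degrees of
#' freedom (standard normal in the d0 = Inf limit). Setting
#' `hyper = NULL` bypasses moderation and yields the classical pooled
#' two-sample t-test.
#'
#' @param fit a `contrast_fit` from [fit_contrast()]
#' @param hyper an `ebayes_hyper` from [estimate_hyperparams()], or `NULL`
#' @return data.frame of class `contrast_result`: gene, log2fc, s2, df, t,
#'   p, q (NA until [estimate_qvalues()] fills it), direction
#' @export
moderated_t_test <- function(fit, hyper = NULL) {
  if (is.null(hyper)) {
    s2_post <- fit$s2
    df_total <- fit$df
  } else {
    s2_post <- posterior_var(fit$s2, fit$df, hyper$d0, hyper$s0_2)
    df_total <- hyper$d0 + fit$df
  }
  se <- sqrt(s2_post * (1 / fit$n_a + 1 / fit$n_b))
  t_stat <- ifelse(se > 0, fit$log2fc / se,
                   ifelse(fit$log2fc == 0, 0, sign(fit$log2fc) * Inf))
  if (any(se == 0 & fit$log2fc != 0))
    warning("zero posterior variance with nonzero fold change: p set to 0")
  p <- 2 * stats::pt(-abs(t_stat), df = df_total)
  p[is.infinite(t_stat)] <- 0
  res <- data.frame(gene = fit$genes, log2fc = fit$log2fc,
                    s2 = fit$s2, df = if (length(fit$df) == 1)
                      rep(fit$df, length(fit$s2)) else fit$df,
                    t = t_stat, p = p, q = NA_real_,
                    direction = ifelse(fit$log2fc > 0, "up",
                                ifelse(fit$log2fc < 0, "down", "none")),
                    stringsAsFactors = FALSE)
  rownames(res) <- res$gene
  attr(res, "contrast") <- fit$label
  class(res) <- c("contrast_result", "data.frame")
  res
}

#' Storey q-values with smoothed pi0 estimation
#'
#' Estimates the proportion of true nulls pi0 from the tail of the p-value
#' distribution -- pi0(lambda) = #\{p > lambda\} / (m (1 - lambda)) over the
#' grid lambda = 0.05, 0.10, ..., 0.95 -- smooths pi0(lambda) and evaluates
#' the smoother at lambda = 0.95, clipping to (0, 1]. The q-value of the
#' i-th ordered p-value is min over j >= i of pi0 * m * p_(j) / j, capped
#' at 1. With fewer than 100 p-values the smoothing is unreliable and
#' pi0 = 1 (q-values then reduce to Benjamini-Hochberg).
#'
#' @param p numeric vector of p-values in [0, 1]
#' @param pi0_method smoother for pi0(lambda): cubic "polynomial" (default)
#'   or smoothing "spline"
#' @return list of class `qvalue_result`: `q` (same order as `p`), `pi0`,
#'   `lambda`, `pi0_lambda`
#' @export
estimate_qvalues <- function(p, pi0_method = c("polynomial", "spline")) {
  pi0_method <- match.arg(pi0_method)
  if (any(p < 0 | p > 1 | is.na(p))) stop("p-values must lie in [0, 1]")
  m <- length(p)
  lambda <- seq(0.05, 0.95, by = 0.05)
  pi0_lambda <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  if (m < 100) {
    pi0 <- 1
  } else {
    pi0 <- switch(pi0_method,
      polynomial = {
        fit <- stats::lm(pi0_lambda ~ stats::poly(lambda, 3))
        stats::predict(fit, data.frame(lambda = 0.95))[[1]]
      },
      spline = {
        fit <- stats::smooth.spline(lambda, pi0_lambda, df = 3)
        stats::predict(fit, x = 0.95)$y
      })
    if (pi0 > 1) pi0 <- 1
    if (pi0 <= 0) {
      pos <- pi0_lambda[pi0_lambda > 0]
      pi0 <- if (length(pos)) min(min(pos), 1) else 1
    }
  }
  o <- order(p)
  q_sorted <- pi0 * m * p[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted
  structure(list(q = q, pi0 = pi0, lambda = lambda,
                 pi0_lambda = pi0_lambda),
            class = "qvalue_result")
}

#' Names of the genotype comparisons the analysis reports
#' @keywords internal
CONTRASTS <- list(
  mes4_vs_WT = c("WT", "mes4"),
  lin54_vs_WT = c("WT", "lin54"),
  double_vs_mes4 = c("mes4", "double"),
  double_vs_lin54 = c("lin54", "double"),
  double_vs_WT = c("WT", "double"))

#' Run the five reported genotype contrasts
#'
#' Fits mes-4 vs WT, lin-54 vs WT, double vs mes-4, double vs lin-54 and
#' double vs WT; each contrast gets its own empirical-Bayes moderation and
#' its own q-values (computed within contrast, not pooled).
#'
#' @param x an `expr_data` object with genotypes WT, mes4, lin54, double
#' @param q_cutoff significance cutoff recorded on the results (default
#'   0.05); genes with q <= cutoff are flagged `significant`
#' @param pi0_method passed to [estimate_qvalues()]
#' @return named list of `contrast_result` data.frames, each with `q`
#'   filled and a logical `significant` column
#' @export
run_all_contrasts <- function(x, q_cutoff = 0.05,
                              pi0_method = c("polynomial", "spline")) {
  pi0_method <- match.arg(pi0_method)
  need <- unique(unlist(CONTRASTS))
  have <- unique(x$samples$genotype)
  absent <- setdiff(need, have)
  if (length(absent)) stop("missing genotype(s): ", paste(absent, collapse = ", "))
  out <- lapply(names(CONTRASTS), function(lab) {
    gt <- CONTRASTS[[lab]]
    fit <- fit_contrast(x, genotype_samples(x, gt[1]),
                        genotype_samples(x, gt[2]), label = lab)
    hyper <- estimate_hyperparams(fit$s2, fit$df)
    res <- moderated_t_test(fit, hyper)
    qv <- estimate_qvalues(res$p, pi0_method = pi0_method)
    res$q <- qv$q
    res$significant <- res$q <= q_cutoff
    res$chrom <- x$genes[res$gene, "chrom"]
    attr(res, "pi0") <- qv$pi0
    attr(res, "hyper") <- list(d0 = hyper$d0, s0_2 = hyper$s0_2)
    attr(res, "q_cutoff") <- q_cutoff
    res
  })
  names(out) <- names(CONTRASTS)
  out
}
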