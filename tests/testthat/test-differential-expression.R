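test_that("contrast fitting matches the textbook pooled-variance formulas", {
  m <- rbind(g1 = c(1, 1, 3, 3))
  colnames(m) <- c("a1", "a2", "b1", "b2")
  fit <- fit_contrast(m, c("a1", "a2"), c("b1", "b2"))
  expect_equal(unname(fit$log2fc), 2)
  expect_equal(unname(fit$s2), 0)
  expect_equal(fit$df, 2L)

  set.seed(5)
  r <- matrix(rnorm(5 * 7), 5, 7,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:7)))
  ga <- paste0("s", 1:3); gb <- paste0("s", 4:7)
  fit <- fit_contrast(r, ga, gb)
  for (g in rownames(r)) {
    a <- r[g, ga]; b <- r[g, gb]
    expect_equal(unname(fit$log2fc[g]), mean(b) - mean(a))
    pooled <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
      (length(a) + length(b) - 2)
    expect_equal(unname(fit$s2[g]), pooled)
  }
  expect_error(fit_contrast(r, "s1", gb), ">= 2 samples")
  expect_error(fit_contrast(r, ga, c("s3", "s4")), "disjoint")
})

test_that("variance hyperparameters are recovered from the exact hierarchy", {
  set.seed(6)
  d0 <- 4; s0_2 <- 0.05; dg <- 4; m <- 10000
  sigma2 <- d0 * s0_2 / rchisq(m, d0)
  s2 <- sigma2 * rchisq(m, dg) / dg
  h <- estimate_hyperparams(s2, dg)
  expect_lt(abs(h$d0 - d0) / d0, 0.20)
  expect_lt(abs(h$s0_2 - s0_2) / s0_2, 0.10)
  # posterior variances lie between the prior and the observed variance
  expect_true(all(h$s2_post >= pmin(s2, h$s0_2) - 1e-12))
  expect_true(all(h$s2_post <= pmax(s2, h$s0_2) + 1e-12))
})

test_that("zero excess dispersion takes the degenerate d0 = Inf branch", {
  h <- estimate_hyperparams(rep(0.3, 500), 4)
  expect_identical(h$d0, Inf)
  expect_true(all(h$s2_post == h$s0_2))
  expect_error(estimate_hyperparams(rep(0, 50), 4), "all variances are zero")
})

test_that("moderated t matches the stated formula on a hand-set toy", {
  fit <- structure(list(log2fc = c(g1 = 0.8, g2 = -0.4, g3 = 0),
                        s2 = c(g1 = 0.5, g2 = 2, g3 = 1),
                        df = 4L, n_a = 3L, n_b = 3L,
                        genes = c("g1", "g2", "g3"), label = "toy"),
                   class = "contrast_fit")
  hyper <- structure(list(d0 = 3, s0_2 = 1,
                          s2_post = (3 * 1 + 4 * c(0.5, 2, 1)) / 7),
                     class = "ebayes_hyper")
  res <- moderated_t_test(fit, hyper)
  s_tilde <- sqrt((3 * 1 + 4 * c(0.5, 2, 1)) / (3 + 4))
  t_hand <- c(0.8, -0.4, 0) / (s_tilde * sqrt(1 / 3 + 1 / 3))
  p_hand <- 2 * pt(-abs(t_hand), df = 3 + 4)
  expect_equal(unname(res$t), t_hand)
  expect_equal(unname(res$p), p_hand)
  expect_equal(res$p[res$log2fc == 0], 1)
  expect_identical(unname(res$direction), c("up", "down", "none"))
})

test_that("bypassing moderation reproduces the classical pooled two-sample t-test", {
  set.seed(7)
  m <- matrix(rnorm(20 * 6), 20, 6,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:6)))
  ga <- paste0("s", 1:3); gb <- paste0("s", 4:6)
  res <- moderated_t_test(fit_contrast(m, ga, gb), hyper = NULL)
  for (g in rownames(m)) {
    tt <- t.test(m[g, gb], m[g, ga], var.equal = TRUE)
    expect_equal(unname(res$t[res$gene == g]), unname(tt$statistic))
    expect_equal(res$p[res$gene == g], tt$p.value)
  }
})

test_that("the d0 = Inf limit collapses to the s0-based z-form", {
  fit <- fit_contrast(matrix(rnorm(40 * 6), 40, 6,
                             dimnames = list(paste0("g", 1:40),
                                             paste0("s", 1:6))),
                      paste0("s", 1:3), paste0("s", 4:6))
  hyper <- structure(list(d0 = Inf, s0_2 = 0.25,
                          s2_post = rep(0.25, 40)), class = "ebayes_hyper")
  res <- moderated_t_test(fit, hyper)
  z <- fit$log2fc / (0.5 * sqrt(1 / 3 + 1 / 3))
  expect_equal(unname(res$t), unname(z))
  expect_equal(unname(res$p), unname(2 * pnorm(-abs(z))))
})

test_that("moderated t interpolates between the s_g and s0 t-statistics", {
  set.seed(8)
  m <- matrix(rnorm(300 * 6, sd = rep(sqrt(0.1 + rchisq(300, 3) / 10), 6)),
              300, 6, dimnames = list(paste0("g", 1:300), paste0("s", 1:6)))
  fit <- fit_contrast(m, paste0("s", 1:3), paste0("s", 4:6))
  h <- estimate_hyperparams(fit$s2, fit$df)
  res <- moderated_t_test(fit, h)
  se_fac <- sqrt(1 / 3 + 1 / 3)
  bracket <- fit$s2 > 0
  t_raw <- abs(fit$log2fc / (sqrt(fit$s2) * se_fac))[bracket]
  t_prior <- abs(fit$log2fc / (sqrt(h$s0_2) * se_fac))[bracket]
  t_mod <- abs(res$t)[bracket]
  expect_true(all(t_mod >= pmin(t_raw, t_prior) - 1e-10))
  expect_true(all(t_mod <= pmax(t_raw, t_prior) + 1e-10))
})

test_that("moderated analysis agrees with limma's independent implementation", {
  skip_if_not_installed("limma")
  set.seed(9)
  sigma2 <- 0.02 * 5 / rchisq(300, 5)
  m <- matrix(rnorm(300 * 6, sd = sqrt(rep(sigma2, 6))), 300, 6,
              dimnames = list(paste0("g", 1:300), paste0("s", 1:6)))
  m[1:30, 4:6] <- m[1:30, 4:6] + 1
  ga <- paste0("s", 1:3); gb <- paste0("s", 4:6)
  fit <- fit_contrast(m, ga, gb)
  h <- estimate_hyperparams(fit$s2, fit$df)
  res <- moderated_t_test(fit, h)

  design <- cbind(1, rep(0:1, each = 3))
  lf <- limma::eBayes(limma::lmFit(m, design))
  expect_equal(h$d0, lf$df.prior, tolerance = 0.02)
  expect_equal(h$s0_2, lf$s2.prior, tolerance = 0.02)
  expect_equal(unname(res$t), unname(lf$t[, 2]), tolerance = 1e-6)
  expect_equal(unname(res$p), unname(lf$p.value[, 2]), tolerance = 1e-6)
})

test_that("q-values equal the brute-force min-over-tail evaluation", {
  set.seed(10)
  p <- c(runif(15), runif(5)^3)
  q <- estimate_qvalues(p)
  expect_equal(q$pi0, 1)             # m < 100: no smoothing
  expect_equal(q$q, bf_qvalues(p, pi0 = 1))
  # invariance to input order
  perm <- sample(length(p))
  expect_equal(estimate_qvalues(p[perm])$q, q$q[perm])
  # monotone in sorted p
  o <- order(p)
  expect_true(all(diff(q$q[o]) >= -1e-15))
  expect_error(estimate_qvalues(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("degenerate and null p-value inputs behave as documented", {
  q1 <- estimate_qvalues(rep(1, 200))
  expect_true(all(q1$q == 1))
  expect_equal(q1$pi0, 1)
  set.seed(11)
  pi0s <- vapply(1:5, function(i) estimate_qvalues(runif(5000))$pi0, numeric(1))
  expect_lt(abs(mean(pi0s) - 1), 0.05)
  # the spline smoother is an accepted alternative
  expect_lt(abs(estimate_qvalues(runif(5000), pi0_method = "spline")$pi0 - 1),
            0.1)
})

test_that("all five genotype contrasts run, with per-contrast q-values and order invariance", {
  sim <- simulate_experiment(
    sim_config(n_genes = 800,
               class_sizes = c(x_up = 40, a_up = 40, a_down = 40,
                               other_de = 20), seed = 12))
  x <- quantile_normalize(sim$data)
  cts <- run_all_contrasts(x)
  expect_named(cts, c("mes4_vs_WT", "lin54_vs_WT", "double_vs_mes4",
                      "double_vs_lin54", "double_vs_WT"))
  planted <- sim$truth$gene[sim$truth$class == "x_up"]
  up <- cts$mes4_vs_WT[planted, ]
  dn <- cts$double_vs_mes4[planted, ]
  expect_gt(mean(up$significant & up$direction == "up"), 0.3)
  expect_gt(mean(dn$significant & dn$direction == "down"), 0.3)

  perm <- sample(ncol(x$exprs))
  x2 <- x[, perm]
  cts2 <- run_all_contrasts(x2)
  expect_equal(cts2$mes4_vs_WT$t, cts$mes4_vs_WT$t)
  expect_equal(cts2$double_vs_mes4$q, cts$double_vs_mes4$q)

  x_missing <- x[, x$samples$genotype != "lin54"]
  expect_error(run_all_contrasts(x_missing), "lin54")
})
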