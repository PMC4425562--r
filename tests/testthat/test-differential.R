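test_that("sam_statistic follows the regularized d formula", {
  # identical group values -> zero numerator
  expect_equal(sam_statistic(c(1, 2, 3, 1, 2, 3),
                             rep(c("a", "b"), each = 3), s0 = 0.5), 0)
  # zero within-group spread: d = (2 - 0) / (0 + 1)
  expect_equal(sam_statistic(c(0, 0, 2, 2), c("a", "a", "b", "b"), s0 = 1), 2)
  # antisymmetry under label swap
  x <- c(0.3, 1.2, -0.5, 2.1, 1.8, 0.4)
  lab <- rep(c("a", "b"), each = 3)
  swapped <- rep(c("b", "a"), each = 3)
  expect_equal(sam_statistic(x, lab, 0.2), -sam_statistic(x, swapped, 0.2))
  expect_error(sam_statistic(c(1, 2, 3), c("a", "a", "b"), 0.1),
               "degenerate")
})

test_that("fudge-factor search matches a brute-force grid search", {
  withr::with_seed(42, {
    s <- sqrt(rchisq(500, df = 3) / 3) * runif(500, 0.2, 2)  # heteroscedastic
    r <- rnorm(500) * (s + 0.3)
  })
  chosen <- estimate_s0(r, s)
  # brute force over the same candidate grid, recomputed independently
  cands <- quantile(s, seq(0, 1, 0.05), names = FALSE)
  breaks <- unique(quantile(s, seq(0, 1, 0.1), names = FALSE))
  bins <- cut(s, breaks, include.lowest = TRUE)
  cv <- sapply(cands, function(a) {
    med <- tapply(abs(r / (s + a)), bins, median)
    sd(med, na.rm = TRUE) / mean(med, na.rm = TRUE)
  })
  expect_equal(chosen, cands[which.min(cv)])
})

test_that("fudge-factor search tie and degenerate rules hold", {
  # constant spread: every candidate equals the same value
  expect_equal(estimate_s0(rnorm(20), rep(0.7, 20)), 0.7)
  expect_warning(s0 <- estimate_s0(rnorm(20), rep(0, 20)), "zero")
  expect_gt(s0, 0)
  expect_error(estimate_s0(1:5, 1:4), "equal length")
  expect_error(estimate_s0(1:5, 1:5), "at least 10")
})

test_that("sam_analyze with exhaustive 3v3 enumeration matches brute force", {
  co <- toy_cohort(n_genes = 8, n_per_group = 3, seed = 7)
  expect_warning(
    res <- sam_analyze(co, sam_config(n_permutations = 100, seed = 1,
                                      s0_method = "fixed", s0_fixed = 0.2)),
    "exhaustively")
  expect_identical(attr(res, "n_permutations_used"), 20L)  # C(6, 3)
  X <- co$values
  D <- sapply(asplit(combn(6, 3), 2), function(ix) abs(bf_sam_d(X, ix, 0.2)))
  d_obs <- bf_sam_d(X, which(co$groups == "A"), 0.2)
  expect_equal(res$statistic, unname(d_obs), tolerance = 1e-12)
  pooled <- as.numeric(D)
  p_bf <- sapply(abs(d_obs), function(a)
    max(sum(pooled >= a), 1) / length(pooled))
  expect_equal(res$p, unname(p_bf), tolerance = 1e-12)
})

test_that("sam_analyze consumes the configured number of relabelings", {
  sim <- generate_expression_cohort(
    cohort_design(c(A = 10, B = 10), n_genes = 50, n_planted = 5, seed = 2))
  res <- sam_analyze(sim$cohort, sam_config(n_permutations = 100, seed = 3))
  expect_identical(attr(res, "n_permutations_used"), 100L)
  # fixed fudge bypasses the search
  res2 <- sam_analyze(sim$cohort,
                      sam_config(n_permutations = 10, s0_method = "fixed",
                                 s0_fixed = 0.3, seed = 3))
  expect_identical(attr(res2, "s0"), 0.3)
})

test_that("sam_analyze multiclass mode runs and is permutation-calibrated", {
  sim <- generate_expression_cohort(
    cohort_design(c(A = 8, B = 8, C = 8), n_genes = 300, n_planted = 20,
                  effect_log2 = 2, case_group = "A", seed = 4))
  res <- sam_analyze(sim$cohort,
                     sam_config(n_permutations = 60, mode = "multiclass",
                                seed = 5))
  expect_true(all(res$statistic >= 0))
  expect_true(all(res$rfold >= 1))
  planted <- sim$truth$planted_genes
  expect_gt(median(res$statistic[res$gene %in% planted]),
            median(res$statistic[!res$gene %in% planted]))
})

test_that("moderated t collapses to the ordinary pooled t when d0 = 0", {
  co <- toy_cohort(n_genes = 30, n_per_group = 5)
  mt <- moderated_t(co, contrast = c("B", "A"), d0 = 0)
  ordinary <- apply(co$values, 1, function(v)
    t.test(v[co$groups == "B"], v[co$groups == "A"],
           var.equal = TRUE)$statistic)
  expect_lt(max(abs(mt$statistic - unname(ordinary))), 1e-10)
})

test_that("moderated t is antisymmetric and shrinks variances", {
  co <- toy_cohort(n_genes = 200, n_per_group = 6, seed = 13)
  a <- moderated_t(co, c("B", "A"))
  b <- moderated_t(co, c("A", "B"))
  expect_equal(a$statistic, -b$statistic)
  # equal true variances: large fitted d0, moderated spread below raw spread
  expect_gt(attr(a, "d0"), 50)
  dg <- 10
  s2 <- apply(co$values, 1, function(v) {
    va <- v[co$groups == "A"]; vb <- v[co$groups == "B"]
    (sum((va - mean(va))^2) + sum((vb - mean(vb))^2)) / dg
  })
  d0 <- attr(a, "d0"); s0sq <- attr(a, "s0sq")
  s2t <- if (is.infinite(d0)) rep(s0sq, length(s2))
         else (d0 * s0sq + dg * s2) / (d0 + dg)
  expect_lt(var(s2t), var(s2))
})

test_that("moderated t agrees with an independent empirical-Bayes fit", {
  skip_if_not_installed("limma")
  sim <- generate_expression_cohort(
    cohort_design(c(A = 10, B = 12), n_genes = 800, n_planted = 40,
                  var_prior_df = 4, var_prior_scale = 0.25, seed = 17))
  co <- sim$cohort
  mt <- moderated_t(co, c("A", "B"))
  design <- cbind(1, co$groups == "A")
  fit <- limma::eBayes(limma::lmFit(co$values, design))
  expect_equal(attr(mt, "d0"), fit$df.prior, tolerance = 1e-4)
  expect_equal(attr(mt, "s0sq"), fit$s2.prior, tolerance = 1e-4)
  expect_equal(mt$statistic, unname(fit$t[, 2]), tolerance = 1e-6)
  expect_equal(mt$p, unname(fit$p.value[, 2]), tolerance = 1e-6)
})

test_that("rfold anti-logs group mean differences", {
  expect_equal(rfold(c(6, 6, 4, 4), c("x", "x", "y", "y"),
                     case = "x", reference = "y"), 4)
  expect_equal(rfold(c(5, 5, 5, 5), c("x", "x", "y", "y"),
                     case = "x", reference = "y"), 1)
  expect_equal(rfold(c(5, 5, 5, 3, 4, 5), rep(c("c", "r"), each = 3),
                     case = "c", reference = "r"), 2)
  expect_error(rfold(c(1, 2), c("x", "x"), case = "y", reference = "x"),
               "non-empty")
})

test_that("Benjamini-Hochberg adjustment follows the step-up rule", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(benjamini_hochberg(1), 1)
  expect_error(benjamini_hochberg(c(0.1, NaN)), "index 2")
  expect_error(benjamini_hochberg(c(0.1, 1.2)), "index 2")
  # permutation equivariance and the q >= p bound
  withr::with_seed(8, p <- runif(50))
  q <- benjamini_hochberg(p)
  perm <- sample(50)
  expect_equal(benjamini_hochberg(p[perm]), q[perm])
  expect_true(all(q >= p & q <= 1))
})
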