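# Inverse of the trigamma function by Newton iteration on 1/psi'(x)
# (monotone, well conditioned); used by the variance-prior moment fit.
.trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  x <- 0.5 + 1 / y
  for (i in 1:75) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2)
    x <- x + dif
    if (abs(dif) < 1e-10 * x) break
  }
  x
}

#' Fit the scaled-inverse-chi-square variance prior by moment matching
#'
#' Assumes per-gene sample variances `s2` on `df` residual degrees of freedom
#' arise from gene-wise true variances drawn from a scaled inverse chi-square
#' with hyperparameters `d0` (prior df) and `s0^2` (prior scale).  The fit
#' matches the mean and variance of `log(s2)` to their closed-form
#' expectations under that model (a log-F distribution), so it is
#' deterministic and requires no optimizer.
#'
#' @param s2 Per-gene sample variances (zeros are excluded from the fit).
#' @param df Residual degrees of freedom of each `s2` (scalar).
#' @return List with `d0` (possibly `Inf`) and `s0sq`.
#' @export
fit_variance_prior <- function(s2, df) {
  s2 <- s2[is.finite(s2) & s2 > 0]
  if (length(s2) < 2)
    stop("need at least two positive variances to fit the prior",
         call. = FALSE)
  z <- log(s2)
  ev <- stats::var(z) - trigamma(df / 2)
  if (ev <= 0) {
    d0 <- Inf
    s0sq <- exp(mean(z) - digamma(df / 2) + log(df / 2))
  } else {
    d0 <- 2 * .trigamma_inverse(ev)
    s0sq <- exp(mean(z) - digamma(df / 2) + log(df / 2) +
                  digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s0sq = s0sq)
}

# Core moderated-t on a matrix for a two-group index split; returns the
# pieces needed by both the public API and the subsampling selector.
.modt_core <- function(X, idx_ref, idx_case, d0 = NULL, s0sq = NULL) {
  n1 <- length(idx_ref); n2 <- length(idx_case)
  if (n1 < 2 || n2 < 2)
    stop("degenerate design: both groups need >= 2 samples", call. = FALSE)
  dg <- n1 + n2 - 2
  if (dg <= 0)
    stop("degenerate design: zero residual degrees of freedom", call. = FALSE)
  X1 <- X[, idx_ref, drop = FALSE]; X2 <- X[, idx_case, drop = FALSE]
  m1 <- rowMeans(X1); m2 <- rowMeans(X2)
  ss <- rowSums((X1 - m1)^2) + rowSums((X2 - m2)^2)
  s2 <- ss / dg
  if (is.null(d0) || is.null(s0sq)) {
    prior <- fit_variance_prior(s2, dg)
    if (is.null(d0)) d0 <- prior$d0
    if (is.null(s0sq)) s0sq <- prior$s0sq
  }
  s2_tilde <- if (is.infinite(d0)) rep(s0sq, length(s2))
              else (d0 * s0sq + dg * s2) / (d0 + dg)
  se <- sqrt(s2_tilde * (1 / n1 + 1 / n2))
  tt <- (m2 - m1) / se
  df_total <- d0 + dg
  p <- 2 * stats::pt(-abs(tt), df = df_total)
  list(t = tt, p = p, lfc = m2 - m1, s2 = s2, s2_tilde = s2_tilde,
       d0 = d0, s0sq = s0sq, df = df_total)
}

#' Empirical-Bayes moderated t differential expression
#'
#' For each gene the pooled two-group variance is shrunk toward a prior scale
#' fitted across genes ([fit_variance_prior()]): `s2_tilde = (d0*s0^2 +
#' dg*s2) / (d0 + dg)`, and the t-statistic on `d0 + dg` degrees of freedom
#' is `(mean_case - mean_ref) / sqrt(s2_tilde * (1/n1 + 1/n2))`.  Two-sided
#' p-values are adjusted by Benjamini-Hochberg.  Forcing `d0 = 0` recovers
#' the ordinary pooled-variance two-sample t exactly.
#'
#' @param cohort An [expression_cohort()].
#' @param contrast Character pair `c(case, reference)`: the statistic and the
#'   fold change are case minus reference.
#' @param fdr_cutoff FDR threshold for the `called` flag (default 0.05).
#' @param d0,s0sq Optional overrides of the fitted prior hyperparameters.
#'
#' @return A data.frame with columns `gene`, `statistic`, `rfold`, `p`, `q`,
#'   `called`; attributes `d0` and `s0sq` record the prior actually used.
#' @export
moderated_t <- function(cohort, contrast, fdr_cutoff = 0.05,
                        d0 = NULL, s0sq = NULL) {
  stopifnot(inherits(cohort, "expression_cohort"))
  if (length(contrast) != 2)
    stop("`contrast` must be c(case, reference)", call. = FALSE)
  case <- contrast[1]; ref <- contrast[2]
  bad <- setdiff(contrast, unique(cohort$groups))
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  idx_case <- which(cohort$groups == case)
  idx_ref <- which(cohort$groups == ref)
  core <- .modt_core(cohort$values, idx_ref, idx_case, d0 = d0, s0sq = s0sq)
  q <- benjamini_hochberg(core$p)
  res <- data.frame(gene = cohort$genes, statistic = unname(core$t),
                    rfold = unname(2^core$lfc), p = unname(core$p), q = q,
                    called = q < fdr_cutoff,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "d0") <- core$d0
  attr(res, "s0sq") <- core$s0sq
  res
}

#' Linear-scale fold change between two groups ("R fold")
#'
#' Anti-logged difference of group means: `2^(mean_case - mean_ref)` of the
#' log2 values.  Values below 1 indicate under-expression in the case group.
#'
#' @param values_g Per-sample log2 values for one gene.
#' @param labels Group label per sample.
#' @param case,reference Labels of the case (numerator) and reference group;
#'   default to the second and first factor level of `labels`.
#' @return Positive fold-change ratio.
#'
#' @examples
#' rfold(c(5, 5, 5, 3, 4, 5), rep(c("case", "ref"), each = 3),
#'       case = "case", reference = "ref")  # 2
#' @export
rfold <- function(values_g, labels,
                  case = levels(factor(labels))[2],
                  reference = levels(factor(labels))[1]) {
  stopifnot(length(values_g) == length(labels))
  if (!any(labels == case) || !any(labels == reference))
    stop("both groups must be non-empty", call. = FALSE)
  2^(mean(values_g[labels == case]) - mean(values_g[labels == reference]))
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Thin validating wrapper around `stats::p.adjust(method = "BH")`: the
#' adjusted values are monotone in p-rank and capped at 1.
#'
#' @param p Numeric vector of p-values in `[0, 1]`; missing or out-of-range
#'   entries raise an error naming the first offending index.
#' @return Adjusted q-values, same length and order as `p`.
#' @export
benjamini_hochberg <- function(p) {
  bad <- which(!is.finite(p) | p < 0 | p > 1)
  if (length(bad))
    stop("invalid p-value at index ", bad[1], call. = FALSE)
  stats::p.adjust(p, method = "BH")
}
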