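#' SAM analysis configuration
#'
#' @param n_permutations Number of sample relabelings for the permutation
#'   null (default 100, the usual cycle count for microarray SAM runs).
#' @param fdr_cutoff FDR threshold for the `called` flag (default 0.05).
#' @param s0_method `"percentile_search"` (Tusher-style fudge-factor search)
#'   or `"fixed"`.
#' @param s0_fixed Fudge value used when `s0_method = "fixed"`.
#' @param mode `"two_class_unpaired"` or `"multiclass"`.
#' @param seed Integer seed for the permutations.
#' @return A `sam_config` list.
#' @export
sam_config <- function(n_permutations = 100, fdr_cutoff = 0.05,
                       s0_method = c("percentile_search", "fixed"),
                       s0_fixed = NULL,
                       mode = c("two_class_unpaired", "multiclass"),
                       seed = 1) {
  s0_method <- match.arg(s0_method)
  mode <- match.arg(mode)
  if (n_permutations < 1)
    stop("`n_permutations` must be >= 1", call. = FALSE)
  if (fdr_cutoff <= 0 || fdr_cutoff >= 1)
    stop("`fdr_cutoff` must lie in (0, 1)", call. = FALSE)
  if (s0_method == "fixed" && (is.null(s0_fixed) || s0_fixed < 0))
    stop("`s0_fixed` must be a non-negative value when s0_method = 'fixed'",
         call. = FALSE)
  structure(list(n_permutations = as.integer(n_permutations),
                 fdr_cutoff = fdr_cutoff, s0_method = s0_method,
                 s0_fixed = s0_fixed, mode = mode, seed = as.integer(seed)),
            class = "sam_config")
}

# Vectorized numerator r and spread s for the SAM statistic on a matrix.
#
# Two-class (unequal variances): r = mean2 - mean1, s = sqrt(s1^2/n1 +
# s2^2/n2) (Welch-style standard error).  Multiclass: with c = sum(1/n_k),
# r = sqrt(c * SSB / (K - 1)), s = sqrt(c * SSW / (n - K)), so that
# d = r / (s + s0) reduces to sqrt(F) when s0 = 0 -- an F-like ratio of
# between- to within-group variation with the fudge in the denominator.
.sam_rs <- function(X, labels) {
  f <- factor(labels)
  lev <- levels(f)
  K <- length(lev)
  nk <- table(f)
  if (K < 2) stop("degenerate design: need at least two groups", call. = FALSE)
  if (any(nk < 2))
    stop("degenerate design: every group needs >= 2 samples", call. = FALSE)
  means <- sapply(lev, function(l) rowMeans(X[, f == l, drop = FALSE]))
  vars <- sapply(lev, function(l) {
    Xi <- X[, f == l, drop = FALSE]
    rowSums((Xi - rowMeans(Xi))^2) / (ncol(Xi) - 1)
  })
  if (is.null(dim(means))) { means <- rbind(means); vars <- rbind(vars) }
  if (K == 2) {
    r <- means[, 2] - means[, 1]
    s <- sqrt(vars[, 1] / nk[1] + vars[, 2] / nk[2])
  } else {
    n <- ncol(X)
    gm <- rowMeans(X)
    ssb <- rowSums(sweep((means - gm)^2, 2, as.numeric(nk), `*`))
    ssw <- rowSums(sweep(vars, 2, as.numeric(nk) - 1, `*`))
    cc <- sum(1 / nk)
    r <- sqrt(cc * ssb / (K - 1))
    s <- sqrt(cc * ssw / (n - K))
  }
  list(r = unname(r), s = unname(s), means = means, levels = lev)
}

#' SAM regularized statistic for one gene
#'
#' Two-class: `d = (mean2 - mean1) / (s + s0)` with `s` the unequal-variance
#' (Welch) standard error; group 1 and 2 are the first and second factor
#' levels of `labels`.  With more than two groups an F-like statistic
#' `sqrt(c * SSB/(K-1)) / (sqrt(c * SSW/(n-K)) + s0)` is returned, where
#' `c = sum(1/n_k)`.
#'
#' @param values_g Numeric vector of per-sample log2 values for one gene.
#' @param labels Group label per sample.
#' @param s0 Fudge factor (>= 0).
#' @return The statistic (numeric scalar).
#'
#' @examples
#' sam_statistic(c(0, 0, 2, 2), c("a", "a", "b", "b"), s0 = 1)
#' @export
sam_statistic <- function(values_g, labels, s0) {
  stopifnot(length(values_g) == length(labels), s0 >= 0)
  rs <- .sam_rs(matrix(values_g, nrow = 1), labels)
  unname(rs$r / (rs$s + s0))
}

#' Tusher-style fudge-factor search
#'
#' Candidates are the percentiles 0, 5, ..., 100 of the per-gene spreads `s`.
#' For each candidate the genes are binned by deciles of `s`; the candidate
#' minimizing the coefficient of variation of the per-bin median absolute
#' statistic is returned.  Ties resolve to the lowest-percentile candidate,
#' so constant `s` returns the 0th percentile.
#'
#' @param per_gene_r Numerators (e.g. mean differences), length >= 10.
#' @param per_gene_s Per-gene spreads (standard errors), same length.
#' @return The chosen fudge value `s0`.
#' @export
estimate_s0 <- function(per_gene_r, per_gene_s) {
  if (length(per_gene_r) != length(per_gene_s))
    stop("`per_gene_r` and `per_gene_s` must have equal length", call. = FALSE)
  if (length(per_gene_s) < 10)
    stop("need at least 10 genes to search for s0", call. = FALSE)
  if (all(per_gene_s == 0)) {
    warning("all spreads are zero; returning a small positive fudge")
    return(1e-8)
  }
  cands <- stats::quantile(per_gene_s, probs = seq(0, 1, by = 0.05),
                           names = FALSE, type = 7)
  breaks <- unique(stats::quantile(per_gene_s, probs = seq(0, 1, by = 0.1),
                                   names = FALSE, type = 7))
  bins <- if (length(breaks) > 2)
    cut(per_gene_s, breaks = breaks, include.lowest = TRUE)
  else
    factor(rep(1L, length(per_gene_s)))
  cv <- vapply(cands, function(a) {
    d <- per_gene_r / (per_gene_s + a)
    med <- tapply(abs(d), bins, stats::median)
    med <- med[!is.na(med)]
    if (length(med) < 2 || mean(med) == 0) return(0)
    stats::sd(med) / mean(med)
  }, numeric(1))
  cands[which.min(cv)]  # which.min takes the first minimum: lowest percentile
}

# All distinct two-class label assignments (choose which samples take the
# first level); columns of the returned index matrix are sample subsets.
.exhaustive_two_class <- function(n, n1) utils::combn(n, n1)

# All distinct permutations of a label multiset (for small multiclass
# enumeration); returns a list of label vectors.
.multiset_permutations <- function(labels) {
  rec <- function(counts, lev) {
    if (sum(counts) == 0) return(list(character(0)))
    out <- list()
    for (i in seq_along(lev)) {
      if (counts[i] == 0) next
      c2 <- counts; c2[i] <- c2[i] - 1
      for (tail in rec(c2, lev))
        out[[length(out) + 1]] <- c(lev[i], tail)
    }
    out
  }
  f <- factor(labels)
  rec(as.integer(table(f)), levels(f))
}

#' SAM permutation analysis of an expression cohort
#'
#' Computes the per-gene SAM statistic, builds a permutation null by
#' relabeling the samples `n_permutations` times, and derives pooled
#' permutation p-values, empirical-FDR q-values and call flags.
#'
#' Details: the per-gene p-value is the fraction of permuted absolute
#' statistics, pooled across genes and permutations, at or above the observed
#' absolute statistic (floored at `1/(n_permutations * n_genes)` so p > 0).
#' The q-value of gene g is the median across permutations of the number of
#' permuted `|d|` at or above `|d_g|` (taking pi0 = 1), divided by the number
#' of genes at or above `|d_g|`, capped at 1 and made monotone in rank.  If
#' more permutations are requested than distinct relabelings exist, the
#' distinct relabelings are enumerated exhaustively, with a warning.
#'
#' @param cohort An [expression_cohort()] whose groups match `config$mode`
#'   (exactly two groups for `"two_class_unpaired"`).
#' @param config A [sam_config()].
#'
#' @return A data.frame with columns `gene`, `statistic`, `rfold`, `p`, `q`,
#'   `called`, ordered as in the cohort; attribute `s0` records the fudge
#'   used and attribute `n_permutations_used` the relabelings consumed.
#'   For two-class runs `rfold` is `2^(mean2 - mean1)` (second group level
#'   over first); for multiclass it is the ratio of the largest to the
#'   smallest group mean on the linear scale.
#' @export
sam_analyze <- function(cohort, config = sam_config()) {
  stopifnot(inherits(cohort, "expression_cohort"))
  if (!inherits(config, "sam_config")) config <- do.call(sam_config, config)
  labels <- cohort$groups
  K <- length(unique(labels))
  if (config$mode == "two_class_unpaired" && K != 2)
    stop("two_class_unpaired mode needs exactly two groups (got ", K, ")",
         call. = FALSE)
  if (config$mode == "multiclass" && K < 3)
    stop("multiclass mode needs at least three groups", call. = FALSE)
  X <- cohort$values
  G <- nrow(X)
  obs <- .sam_rs(X, labels)
  s0 <- if (config$s0_method == "fixed") config$s0_fixed
        else estimate_s0(obs$r, obs$s)
  d <- obs$r / (obs$s + s0)

  f <- factor(labels)
  nk <- table(f)
  n <- length(labels)
  n_distinct <- if (K == 2) choose(n, nk[1])
                else exp(lfactorial(n) - sum(lfactorial(nk)))
  B <- config$n_permutations
  exhaustive <- B > n_distinct
  if (exhaustive) {
    warning("requested ", B, " permutations but only ", round(n_distinct),
            " distinct relabelings exist; enumerating exhaustively")
    if (K == 2) {
      idx <- .exhaustive_two_class(n, nk[1])
      perm_labels <- apply(idx, 2, function(ix) {
        l <- rep(levels(f)[2], n); l[ix] <- levels(f)[1]; l
      })
      perm_list <- split(perm_labels, col(perm_labels))
    } else {
      perm_list <- .multiset_permutations(labels)
    }
  }
  B_used <- if (exhaustive) length(perm_list) else B

  Dperm <- withr::with_seed(config$seed, {
    vapply(seq_len(B_used), function(b) {
      lab <- if (exhaustive) perm_list[[b]] else sample(as.character(f))
      rs <- .sam_rs(X, lab)
      abs(rs$r / (rs$s + s0))
    }, numeric(G))
  })

  absd <- abs(d)
  pooled <- sort(as.numeric(Dperm))
  # count of pooled permuted |d| >= each observed |d| (inclusive ties)
  n_ge <- length(pooled) - findInterval(absd, pooled, left.open = TRUE)
  p <- pmax(n_ge, 1) / (B_used * G)

  # empirical-FDR q-values: median permutation exceedance count over rank
  ord <- order(absd, decreasing = TRUE)
  rank_ge <- G - findInterval(absd, sort(absd), left.open = TRUE) # ties: max rank
  V <- matrix(0, G, B_used)
  for (b in seq_len(B_used)) {
    colb <- sort(Dperm[, b])
    V[, b] <- G - findInterval(absd, colb, left.open = TRUE)
  }
  q <- pmin(apply(V, 1, stats::median) / rank_ge, 1)
  # enforce monotone non-increasing q with increasing |d|
  q[ord] <- rev(cummin(rev(q[ord])))

  rfold <- if (ncol(obs$means) == 2) 2^(obs$means[, 2] - obs$means[, 1])
           else 2^(apply(obs$means, 1, max) - apply(obs$means, 1, min))

  res <- data.frame(gene = cohort$genes, statistic = unname(d),
                    rfold = unname(rfold), p = p, q = q,
                    called = q < config$fdr_cutoff,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "s0") <- s0
  attr(res, "n_permutations_used") <- B_used
  attr(res, "group_levels") <- obs$levels
  res
}
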