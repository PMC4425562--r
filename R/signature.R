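#' Configuration of the subsampling consensus-signature selector
#'
#' @param k_per_class Samples drawn per class in each contrast (>= 2).
#' @param n_contrasts Number of random balanced contrasts to run.
#' @param fdr_cutoff Per-contrast q-value cutoff for counting a gene as
#'   significant.
#' @param top_n Signature size: number of top-frequency genes to keep.
#' @param min_contrasts Optional minimum selection frequency a gene must
#'   reach to be eligible for the signature.
#' @param seed Integer seed.
#' @return A `subsample_config` list.
#'
#' @seealso [signature_preset()] for the two study presets.
#' @export
subsample_config <- function(k_per_class, n_contrasts, fdr_cutoff, top_n,
                             min_contrasts = NULL, seed = 1) {
  if (k_per_class < 2) stop("`k_per_class` must be >= 2", call. = FALSE)
  if (n_contrasts < 1) stop("`n_contrasts` must be >= 1", call. = FALSE)
  if (fdr_cutoff <= 0 || fdr_cutoff >= 1)
    stop("`fdr_cutoff` must lie in (0, 1)", call. = FALSE)
  if (top_n < 1) stop("`top_n` must be >= 1", call. = FALSE)
  if (!is.null(min_contrasts) && min_contrasts > n_contrasts)
    stop("`min_contrasts` cannot exceed `n_contrasts`", call. = FALSE)
  structure(list(k_per_class = as.integer(k_per_class),
                 n_contrasts = as.integer(n_contrasts),
                 fdr_cutoff = fdr_cutoff, top_n = as.integer(top_n),
                 min_contrasts = min_contrasts, seed = as.integer(seed)),
            class = "subsample_config")
}

#' Study presets for the signature selector
#'
#' `"mut200"`: the spliceosome-mutation split (22 mutated vs 13 unmutated
#' low-risk MDS samples) analyzed as 7-vs-7 subsets over 10000 contrasts at
#' q < 0.01, keeping the 200 most frequently significant genes.  `"rs75"`:
#' the SF3B1-mutated vs unmutated MDS-RS split (13 vs 6) analyzed as 4-vs-4
#' subsets over 7425 contrasts at FDR < 0.10, keeping 75 genes that were
#' significant in at least ten contrasts.
#'
#' @param name `"mut200"` or `"rs75"`.
#' @param n_contrasts Optional override of the preset contrast count (e.g.
#'   for scaled-down runs).
#' @param seed Integer seed.
#' @return A [subsample_config()].
#' @export
signature_preset <- function(name = c("mut200", "rs75"), n_contrasts = NULL,
                             seed = 1) {
  name <- match.arg(name)
  cfg <- switch(name,
    mut200 = list(k_per_class = 7, n_contrasts = 10000, fdr_cutoff = 0.01,
                  top_n = 200, min_contrasts = NULL),
    rs75 = list(k_per_class = 4, n_contrasts = 7425, fdr_cutoff = 0.10,
                top_n = 75, min_contrasts = 10))
  if (!is.null(n_contrasts)) cfg$n_contrasts <- n_contrasts
  cfg$seed <- seed
  do.call(subsample_config, cfg)
}

#' Consensus gene signature by repeated balanced subsampling
#'
#' Repeatedly draws `k_per_class` samples without replacement from each of
#' two classes, runs the moderated-t engine on the subset, and counts, per
#' gene, the contrasts in which it reached `q < fdr_cutoff`.  The signature
#' is the `top_n` genes by selection frequency (after the optional
#' `min_contrasts` filter).  Ties at the signature boundary are broken by
#' mean absolute moderated t across contrasts, then by gene ID.
#'
#' @param cohort An [expression_cohort()].
#' @param class_a,class_b Disjoint character vectors of sample IDs, each of
#'   size >= `k_per_class`.
#' @param config A [subsample_config()].
#'
#' @return A `consensus_signature`: list with `frequency` (named integer
#'   vector over all genes), `mean_abs_stat`, `n_contrasts_run`, `top_genes`
#'   and `config`.
#' @export
subsample_signature <- function(cohort, class_a, class_b, config) {
  stopifnot(inherits(cohort, "expression_cohort"))
  if (!inherits(config, "subsample_config"))
    config <- do.call(subsample_config, config)
  bad <- setdiff(c(class_a, class_b), cohort$samples)
  if (length(bad))
    stop("unknown samples: ", paste(bad, collapse = ", "), call. = FALSE)
  if (length(intersect(class_a, class_b)))
    stop("classes must be disjoint", call. = FALSE)
  k <- config$k_per_class
  if (length(class_a) < k || length(class_b) < k)
    stop("`k_per_class` (", k, ") exceeds a class size (",
         length(class_a), ", ", length(class_b), ")", call. = FALSE)
  X <- cohort$values
  ia_all <- match(class_a, cohort$samples)
  ib_all <- match(class_b, cohort$samples)
  G <- nrow(X)
  freq <- integer(G)
  sum_abs_t <- numeric(G)
  withr::with_seed(config$seed, {
    for (b in seq_len(config$n_contrasts)) {
      ia <- if (length(ia_all) == k) ia_all else sample(ia_all, k)
      ib <- if (length(ib_all) == k) ib_all else sample(ib_all, k)
      core <- .modt_core(X, idx_ref = ia, idx_case = ib)
      q <- stats::p.adjust(core$p, method = "BH")
      freq <- freq + (q < config$fdr_cutoff)
      sum_abs_t <- sum_abs_t + abs(core$t)
    }
  })
  names(freq) <- cohort$genes
  mean_abs_t <- sum_abs_t / config$n_contrasts
  names(mean_abs_t) <- cohort$genes

  eligible <- if (!is.null(config$min_contrasts))
    which(freq >= config$min_contrasts) else which(freq > 0)
  ord <- eligible[order(-freq[eligible], -mean_abs_t[eligible],
                        cohort$genes[eligible])]
  if (is.null(config$min_contrasts) && length(ord) < config$top_n)
    warning("only ", length(ord), " genes were ever significant; ",
            "returning a signature shorter than top_n = ", config$top_n)
  top_genes <- cohort$genes[utils::head(ord, config$top_n)]

  structure(list(frequency = freq, mean_abs_stat = mean_abs_t,
                 n_contrasts_run = config$n_contrasts,
                 top_genes = top_genes, config = config),
            class = "consensus_signature")
}

#' @export
print.consensus_signature <- function(x, ...) {
  cat("consensus_signature:", length(x$top_genes), "genes from",
      x$n_contrasts_run, "contrasts",
      sprintf("(k = %d/class, q < %g)\n",
              x$config$k_per_class, x$config$fdr_cutoff))
  invisible(x)
}

#' Permutation global association test of a gene signature
#'
#' Checks whether a signature's expression jointly predicts a binary class:
#' with row-standardized expression `x` and centered labels `y`, the
#' statistic is `Q = sum_g (sum_s x[g, s] * y[s])^2`, and the p-value is the
#' permutation tail `(1 + #{Q_perm >= Q_obs}) / (1 + n_permutations)` over
#' random relabelings.
#'
#' @param cohort An [expression_cohort()].
#' @param signature Character vector of gene IDs (subset of the cohort).
#' @param labels Binary class per sample: either a vector in cohort sample
#'   order or named by sample ID.
#' @param n_permutations Number of label permutations (default 9999).
#' @param seed Integer seed.
#'
#' @return The permutation p-value, with the observed statistic in attribute
#'   `Q`.
#' @export
global_association_test <- function(cohort, signature, labels,
                                    n_permutations = 9999, seed = 1) {
  stopifnot(inherits(cohort, "expression_cohort"))
  bad <- setdiff(signature, cohort$genes)
  if (length(bad))
    stop("signature genes absent from cohort: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  if (!is.null(names(labels))) labels <- labels[cohort$samples]
  if (length(labels) != length(cohort$samples))
    stop("`labels` must cover every sample", call. = FALSE)
  if (length(unique(labels)) != 2)
    stop("`labels` must contain exactly two classes", call. = FALSE)
  X <- cohort$values[signature, , drop = FALSE]
  mu <- rowMeans(X)
  sdv <- sqrt(rowSums((X - mu)^2) / (ncol(X) - 1))
  Xs <- (X - mu) / ifelse(sdv > 0, sdv, 1)
  Xs[sdv == 0, ] <- 0
  y <- as.numeric(factor(labels)) - 1
  y <- y - mean(y)
  Q <- sum((Xs %*% y)^2)
  exceed <- withr::with_seed(seed, {
    sum(vapply(seq_len(n_permutations),
               function(b) sum((Xs %*% sample(y))^2) >= Q, logical(1)))
  })
  p <- (1 + exceed) / (1 + n_permutations)
  attr(p, "Q") <- Q
  p
}
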