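#' Expression cohort container
#'
#' An `expression_cohort` bundles a log2 expression matrix (genes x samples)
#' with the sample grouping and, optionally, spliceosome-gene mutation status
#' per sample.  It is the substrate of all differential expression statistics
#' in the package.
#'
#' @param values Numeric matrix of log2 intensities with gene IDs as rownames
#'   and sample IDs as colnames.  All values must be finite.
#' @param groups Named character vector mapping every sample ID to a group
#'   label (e.g. `"RARS"`, `"RCUD"`, `"CTRL"`).
#' @param mutation_status Optional named character vector mapping sample IDs
#'   to `"mutated"` or `"unmutated"`.
#'
#' @return An object of class `expression_cohort`: a list with elements
#'   `genes`, `samples`, `values`, `groups` and `mutation_status`.
#'
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' grp <- setNames(rep(c("A", "B"), each = 2), colnames(m))
#' co <- expression_cohort(m, grp)
#' co
#' @export
expression_cohort <- function(values, groups, mutation_status = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  genes <- rownames(values)
  samples <- colnames(values)
  if (is.null(genes) || is.null(samples))
    stop("`values` must carry gene rownames and sample colnames", call. = FALSE)
  if (anyDuplicated(genes))
    stop("duplicate gene IDs: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "), call. = FALSE)
  if (anyDuplicated(samples))
    stop("duplicate sample IDs: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "),
         call. = FALSE)
  if (!all(is.finite(values)))
    stop("`values` contains non-finite entries", call. = FALSE)
  if (is.null(names(groups)))
    stop("`groups` must be named by sample ID", call. = FALSE)
  missing_grp <- setdiff(samples, names(groups))
  if (length(missing_grp))
    stop("samples without a group label: ",
         paste(missing_grp, collapse = ", "), call. = FALSE)
  unknown <- setdiff(names(groups), samples)
  if (length(unknown))
    stop("group labels for unknown samples: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  groups <- as.character(groups[samples])
  names(groups) <- samples
  if (!is.null(mutation_status)) {
    if (is.null(names(mutation_status)))
      stop("`mutation_status` must be named by sample ID", call. = FALSE)
    bad <- setdiff(names(mutation_status), samples)
    if (length(bad))
      stop("mutation status for unknown samples: ",
           paste(bad, collapse = ", "), call. = FALSE)
    if (!all(mutation_status %in% c("mutated", "unmutated")))
      stop("mutation status values must be 'mutated' or 'unmutated'",
           call. = FALSE)
  }
  structure(
    list(genes = genes, samples = samples, values = values,
         groups = groups, mutation_status = mutation_status),
    class = "expression_cohort"
  )
}

#' @export
print.expression_cohort <- function(x, ...) {
  cat("expression_cohort:", length(x$genes), "genes x",
      length(x$samples), "samples\n")
  tab <- table(x$groups)
  cat("groups:", paste(sprintf("%s(%d)", names(tab), tab), collapse = ", "),
      "\n")
  if (!is.null(x$mutation_status)) {
    mt <- table(x$mutation_status)
    cat("mutation status:",
        paste(sprintf("%s(%d)", names(mt), mt), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Subset an expression cohort by samples or groups
#'
#' @param cohort An [expression_cohort()].
#' @param samples Optional character vector of sample IDs to keep.
#' @param groups Optional character vector of group labels to keep (applied
#'   after `samples`).
#'
#' @return A new `expression_cohort` containing only the selected samples.
#' @export
subset_cohort <- function(cohort, samples = NULL, groups = NULL) {
  stopifnot(inherits(cohort, "expression_cohort"))
  keep <- cohort$samples
  if (!is.null(samples)) {
    bad <- setdiff(samples, cohort$samples)
    if (length(bad))
      stop("unknown samples: ", paste(bad, collapse = ", "), call. = FALSE)
    keep <- intersect(keep, samples)
  }
  if (!is.null(groups))
    keep <- keep[cohort$groups[keep] %in% groups]
  if (!length(keep))
    stop("no samples left after subsetting", call. = FALSE)
  ms <- cohort$mutation_status
  if (!is.null(ms)) ms <- ms[intersect(names(ms), keep)]
  expression_cohort(cohort$values[, keep, drop = FALSE],
                    cohort$groups[keep], ms)
}
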