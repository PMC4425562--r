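#' 2x2 contingency table of integer counts
#'
#' Cell layout follows the usual case/control by carrier/non-carrier (or
#' in-both / in-one-list) convention:
#' \preformatted{        col1  col2
#'   row1    a     b
#'   row2    c     d}
#' For gene-list overlap, `a` is the in-both count.
#'
#' @param a,b,c,d Non-negative integer counts; total must be >= 1.
#' @return A `contingency_2x2` object.
#' @export
contingency_2x2 <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(cells)) || any(cells < 0) ||
      any(cells != round(cells)))
    stop("all cells must be non-negative integers", call. = FALSE)
  if (sum(cells) < 1)
    stop("table total must be >= 1", call. = FALSE)
  cells <- as.integer(round(cells))
  structure(list(a = cells[1], b = cells[2], c = cells[3], d = cells[4]),
            class = "contingency_2x2")
}

.as_table2x2 <- function(table) {
  if (inherits(table, "contingency_2x2")) return(table)
  if (is.numeric(table) && length(table) == 4)
    return(contingency_2x2(table[1], table[2], table[3], table[4]))
  stop("expected a contingency_2x2 or a length-4 numeric (a, b, c, d)",
       call. = FALSE)
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("row1", "row2"), c("col1", "col2")))
  print(m)
  invisible(x)
}

#' Overlap contingency table of two gene lists
#'
#' Builds the 2x2 table underlying a gene-list overlap odds ratio:
#' `a = |A intersect B|`, `b = |A \ B|`, `c = |B \ A|`,
#' `d = |universe \ (A union B)|`.
#'
#' @param list_a,list_b Character vectors of gene IDs, subsets of `universe`.
#' @param universe Character vector: the gene background (for expression
#'   signatures, the genes measured on the array).
#' @return A [contingency_2x2()].
#'
#' @examples
#' overlap_table(c("g1", "g2"), c("g2", "g3"), paste0("g", 1:10))
#' @export
overlap_table <- function(list_a, list_b, universe) {
  list_a <- unique(list_a); list_b <- unique(list_b)
  offenders <- setdiff(c(setdiff(list_a, universe), setdiff(list_b, universe)),
                       character(0))
  if (length(offenders))
    stop("genes outside the universe: ",
         paste(utils::head(offenders, 10), collapse = ", "), call. = FALSE)
  a <- length(intersect(list_a, list_b))
  b <- length(setdiff(list_a, list_b))
  c <- length(setdiff(list_b, list_a))
  d <- length(universe) - a - b - c
  contingency_2x2(a, b, c, d)
}

#' Odds ratio with Woolf confidence interval
#'
#' `OR = ad / bc`.  When any cell is zero the Haldane-Anscombe correction
#' (adding 0.5 to every cell) is applied before both the estimate and the
#' interval.  The CI is the Woolf log-scale interval
#' `exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`.
#'
#' @param table A [contingency_2x2()] (or length-4 numeric `(a, b, c, d)`).
#' @param confidence Coverage of the interval, in (0, 1); default 0.95.
#' @return Named numeric vector `c(or, lower, upper)`.
#' @export
odds_ratio_ci <- function(table, confidence = 0.95) {
  t <- .as_table2x2(table)
  if (confidence <= 0 || confidence >= 1)
    stop("`confidence` must lie in (0, 1)", call. = FALSE)
  cells <- c(t$a, t$b, t$c, t$d)
  if (any(cells == 0)) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  se <- sqrt(sum(1 / cells))
  c(or = or, lower = exp(log(or) - z * se), upper = exp(log(or) + z * se))
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric tail probabilities with the margins fixed, computed
#' by summing point masses (`stats::dhyper`, evaluated in log space
#' internally, safe for totals up to about 1e6).  `"one_greater"` sums all
#' tables with the top-left cell at or above the observed `a`;
#' `"two_sided"` sums every table whose point probability does not exceed
#' the observed one (the standard two-sided convention).
#'
#' @param table A [contingency_2x2()] or length-4 numeric `(a, b, c, d)`.
#' @param sidedness `"two_sided"` or `"one_greater"`.
#' @return The exact p-value.
#' @export
fisher_exact <- function(table, sidedness = c("two_sided", "one_greater")) {
  t <- .as_table2x2(table)
  sidedness <- match.arg(sidedness)
  m <- t$a + t$b          # size of row 1
  n2 <- t$c + t$d         # size of row 2
  k <- t$a + t$c          # size of column 1
  lo <- max(0L, k - n2)
  hi <- min(m, k)
  xs <- lo:hi
  probs <- stats::dhyper(xs, m, n2, k)
  if (sidedness == "one_greater") {
    p <- sum(probs[xs >= t$a])
  } else {
    p_obs <- probs[xs == t$a]
    p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
  min(p, 1)
}

#' Chi-square test for a 2x2 table
#'
#' Classical formula `X2 = n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`; with
#' Yates continuity correction `|ad - bc|` is reduced by `n/2` (floored at
#' zero) before squaring.  The p-value is the upper tail of chi-square with
#' one degree of freedom.
#'
#' @param table A [contingency_2x2()] or length-4 numeric `(a, b, c, d)`.
#' @param yates Apply the continuity correction?  Default `FALSE`.
#' @return Named numeric vector `c(statistic, p)`.
#' @export
chi_square_2x2 <- function(table, yates = FALSE) {
  t <- .as_table2x2(table)
  a <- t$a; b <- t$b; c <- t$c; d <- t$d
  n <- a + b + c + d
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0))
    stop("chi-square undefined: a margin is zero", call. = FALSE)
  num <- abs(a * d - b * c)
  if (yates) num <- max(0, num - n / 2)
  stat <- n * num^2 / prod(margins)
  c(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Over-representation enrichment of a gene list in a collection
#'
#' For each set in the collection, tests whether the query list overlaps it
#' more than expected under hypergeometric sampling from the universe.
#' `mode = "fisher"` uses the one-sided exact tail at the observed overlap;
#' `mode = "ease"` first decrements the overlap by one (floored at zero), the
#' conservative EASE-score convention.  P-values are Benjamini-Hochberg
#' adjusted across sets.
#'
#' @param query Character vector of gene IDs, a subset of the collection's
#'   universe.
#' @param collection A [gene_set_collection()].
#' @param mode `"fisher"` or `"ease"`.
#' @return A data.frame sorted by p: `set_name`, `n_set`, `overlap`,
#'   `expected`, `p`, `q`.
#' @export
enrich <- function(query, collection, mode = c("fisher", "ease")) {
  mode <- match.arg(mode)
  stopifnot(inherits(collection, "gene_set_collection"))
  query <- unique(query)
  bad <- setdiff(query, collection$universe)
  if (length(bad))
    stop("query genes outside the universe: ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  N <- length(collection$universe)
  nq <- length(query)
  if (nq == 0)
    warning("empty query: all enrichment p-values are 1")
  rows <- lapply(names(collection$sets), function(nm) {
    set <- collection$sets[[nm]]
    K <- length(set)
    ov <- length(intersect(query, set))
    a <- if (mode == "ease") max(ov - 1L, 0L) else ov
    p <- if (nq == 0) 1 else
      fisher_exact(contingency_2x2(a, K - a, nq - a, N - K - nq + a),
                   sidedness = "one_greater")
    data.frame(set_name = nm, n_set = K, overlap = ov,
               expected = nq * K / N, p = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res))
    return(data.frame(set_name = character(0), n_set = integer(0),
                      overlap = integer(0), expected = numeric(0),
                      p = numeric(0), q = numeric(0)))
  res$q <- benjamini_hochberg(res$p)
  res[order(res$p, res$set_name), , drop = FALSE]
}
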