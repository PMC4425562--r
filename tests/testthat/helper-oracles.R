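# Independent oracles and small fixture builders shared across tests.

# Exact hypergeometric tail by direct log-binomial enumeration (independent
# of the dhyper-based implementation path).
bf_fisher <- function(a, b, c, d, sidedness = c("two_sided", "one_greater")) {
  sidedness <- match.arg(sidedness)
  m <- a + b; n2 <- c + d; k <- a + c; N <- m + n2
  lo <- max(0, k - n2); hi <- min(m, k)
  logp <- vapply(lo:hi, function(x)
    lchoose(m, x) + lchoose(n2, k - x) - lchoose(N, k), numeric(1))
  probs <- exp(logp)
  xs <- lo:hi
  if (sidedness == "one_greater") sum(probs[xs >= a])
  else sum(probs[probs <= probs[xs == a] * (1 + 1e-7)])
}

# Welch-style SAM d for one relabeling, written independently of .sam_rs.
bf_sam_d <- function(X, idx1, s0) {
  X1 <- X[, idx1, drop = FALSE]
  X2 <- X[, -idx1, drop = FALSE]
  r <- rowMeans(X2) - rowMeans(X1)
  s <- sqrt(apply(X1, 1, var) / ncol(X1) + apply(X2, 1, var) / ncol(X2))
  r / (s + s0)
}

# Brute-force codon translation through seqinr (independent of Biostrings).
bf_translate_cds <- function(cds) {
  paste(seqinr::translate(strsplit(tolower(cds), "")[[1]]), collapse = "")
}

# Tiny fully-specified cohort: deterministic values, two groups.
toy_cohort <- function(n_genes = 6, n_per_group = 4, seed = 99) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n_genes * 2 * n_per_group, mean = 7), n_genes,
                dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                                sprintf("s%02d", seq_len(2 * n_per_group))))
    grp <- setNames(rep(c("A", "B"), each = n_per_group), colnames(m))
    expression_cohort(m, grp)
  })
}

# Toy 4-codon transcript: M V R * on chr1, CDS at 101..112, forward strand.
toy_model <- function() {
  transcript_model("TOY", "chr1", "+", cbind(101, 112), "ATGGTTCGTTAA")
}

# Minus-strand mirror of toy_model: same coding sequence read off the
# reverse strand of chr2 at 201..212.
toy_model_minus <- function() {
  transcript_model("TOYM", "chr2", "-", cbind(201, 212), "ATGGTTCGTTAA")
}

variant_rec <- function(chrom, pos, ref, alt, sample = "s1",
                        genotype = "het", id = NA_character_) {
  data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
             sample = sample, genotype = genotype, id = id,
             stringsAsFactors = FALSE)
}
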