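#' Transcript model with a spliced CDS
#'
#' A minimal coding model: one gene on one chromosome, an ordered set of
#' 1-based inclusive CDS intervals, and the spliced CDS nucleotide sequence
#' given on the coding strand.  Interval lengths must sum to the sequence
#' length, which must be a multiple of 3.
#'
#' @param gene Gene name.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param cds_intervals Integer matrix with two columns (start, end), 1-based
#'   inclusive, in increasing genomic order.
#' @param cds_sequence Spliced CDS string over A/C/G/T (coding strand).
#' @return A `transcript_model` object.
#' @export
transcript_model <- function(gene, chrom, strand, cds_intervals,
                             cds_sequence) {
  if (!strand %in% c("+", "-"))
    stop("`strand` must be '+' or '-'", call. = FALSE)
  cds_intervals <- matrix(as.integer(cds_intervals), ncol = 2)
  if (any(cds_intervals[, 2] < cds_intervals[, 1]))
    stop("model integrity error: interval end before start", call. = FALSE)
  if (nrow(cds_intervals) > 1 &&
      any(cds_intervals[-1, 1] <= cds_intervals[-nrow(cds_intervals), 2]))
    stop("model integrity error: intervals must be disjoint and increasing",
         call. = FALSE)
  len <- sum(cds_intervals[, 2] - cds_intervals[, 1] + 1)
  cds_sequence <- toupper(cds_sequence)
  if (len != nchar(cds_sequence))
    stop("model integrity error: interval lengths (", len,
         ") do not match CDS length (", nchar(cds_sequence), ")",
         call. = FALSE)
  if (nchar(cds_sequence) %% 3 != 0)
    stop("model integrity error: CDS length not divisible by 3",
         call. = FALSE)
  if (grepl("[^ACGT]", cds_sequence))
    stop("model integrity error: CDS contains non-ACGT characters",
         call. = FALSE)
  structure(list(gene = gene, chrom = chrom, strand = strand,
                 cds_intervals = cds_intervals, cds_sequence = cds_sequence),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("transcript_model %s (%s%s): %d CDS bp in %d exon(s)\n",
              x$gene, x$chrom, x$strand, nchar(x$cds_sequence),
              nrow(x$cds_intervals)))
  invisible(x)
}

#' Known-SNP catalog
#'
#' Holds (chrom, pos, alt) keys and/or dbSNP-style IDs of known
#' polymorphisms; a variant matches the catalog if either its positional key
#' or its ID is present.
#'
#' @param entries data.frame with columns `chrom`, `pos`, `alt` and
#'   optionally `id`.
#' @return A `snp_catalog` object.
#' @export
snp_catalog <- function(entries) {
  stopifnot(is.data.frame(entries),
            all(c("chrom", "pos", "alt") %in% names(entries)))
  keys <- unique(paste(entries$chrom, entries$pos, entries$alt))
  ids <- if ("id" %in% names(entries))
    unique(entries$id[!is.na(entries$id) & nzchar(entries$id)])
  else character(0)
  structure(list(keys = keys, ids = ids, entries = entries),
            class = "snp_catalog")
}

#' @export
print.snp_catalog <- function(x, ...) {
  cat("snp_catalog:", length(x$keys), "positional keys,",
      length(x$ids), "IDs\n")
  invisible(x)
}

.check_variants_df <- function(variants) {
  need <- c("chrom", "pos", "ref", "alt", "sample")
  miss <- setdiff(need, names(variants))
  if (length(miss))
    stop("variant table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  indel <- nchar(variants$ref) != 1 | nchar(variants$alt) != 1
  if (any(indel))
    stop("only single-nucleotide substitutions are supported; ",
         sum(indel), " indel-like record(s) found (first at row ",
         which(indel)[1], ")", call. = FALSE)
  if (any(variants$ref == variants$alt))
    stop("ref and alt alleles must differ", call. = FALSE)
  if (any(variants$pos < 1))
    stop("positions must be >= 1", call. = FALSE)
  invisible(variants)
}

#' Stage 1 of the triage cascade: remove known SNPs
#'
#' A variant is discarded iff its `(chrom, pos, alt)` key or its `id` is in
#' the catalog; the kept and discarded sets partition the input.
#'
#' @param variants data.frame of variant records (`chrom`, `pos`, `ref`,
#'   `alt`, `sample`, optional `id`).
#' @param catalog A [snp_catalog()].
#' @return List with data.frames `kept` and `discarded`.
#' @export
filter_known_snps <- function(variants, catalog) {
  .check_variants_df(variants)
  stopifnot(inherits(catalog, "snp_catalog"))
  key <- paste(variants$chrom, variants$pos, variants$alt)
  hit <- key %in% catalog$keys
  if ("id" %in% names(variants))
    hit <- hit | (!is.na(variants$id) & variants$id %in% catalog$ids)
  list(kept = variants[!hit, , drop = FALSE],
       discarded = variants[hit, , drop = FALSE])
}

#' Coding / non-coding classification of a variant position
#'
#' A position is coding iff it lies inside some CDS interval (1-based
#' inclusive containment) of a model on the variant's chromosome.
#'
#' @param chrom,pos Variant location.
#' @param models List of [transcript_model()] objects.
#' @return `"coding"` or `"non_coding"`.
#' @export
classify_coding <- function(chrom, pos, models) {
  for (m in models) {
    if (m$chrom != chrom) next
    if (any(pos >= m$cds_intervals[, 1] & pos <= m$cds_intervals[, 2]))
      return("coding")
  }
  "non_coding"
}

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

.translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

# genomic position -> 1-based offset into the spliced CDS (coding strand)
.genomic_to_cds_offset <- function(model, pos) {
  iv <- model$cds_intervals
  hit <- which(pos >= iv[, 1] & pos <= iv[, 2])
  if (!length(hit)) return(NA_integer_)
  if (model$strand == "+") {
    before <- if (hit > 1) sum(iv[seq_len(hit - 1), 2] -
                                 iv[seq_len(hit - 1), 1] + 1) else 0L
    as.integer(before + pos - iv[hit, 1] + 1)
  } else {
    n_iv <- nrow(iv)
    after <- if (hit < n_iv) sum(iv[seq(hit + 1, n_iv), 2] -
                                   iv[seq(hit + 1, n_iv), 1] + 1) else 0L
    as.integer(after + iv[hit, 2] - pos + 1)
  }
}

# 1-based CDS offset -> genomic position (used by the generator)
.cds_offset_to_genomic <- function(model, offset) {
  iv <- model$cds_intervals
  lens <- iv[, 2] - iv[, 1] + 1
  if (model$strand == "+") {
    cum <- cumsum(lens)
    e <- which(offset <= cum)[1]
    prev <- if (e > 1) cum[e - 1] else 0L
    as.integer(iv[e, 1] + (offset - prev) - 1)
  } else {
    cum <- cumsum(rev(lens))
    e_rev <- which(offset <= cum)[1]
    e <- nrow(iv) - e_rev + 1
    prev <- if (e_rev > 1) cum[e_rev - 1] else 0L
    as.integer(iv[e, 2] - (offset - prev) + 1)
  }
}

#' Codon-level annotation of a coding single-nucleotide variant
#'
#' Maps the genomic position to its offset in the spliced CDS (on the minus
#' strand the offset is counted from the rightmost CDS base and both alleles
#' are complemented), mutates the affected codon, and translates reference
#' and alternative codons with the standard nuclear genetic code.
#'
#' @param variant One variant record: a list or one-row data.frame with
#'   `chrom`, `pos`, `ref`, `alt`.
#' @param model A [transcript_model()] containing the position.
#' @return List with `codon_index`, `ref_aa`, `alt_aa` and `consequence`
#'   (`"synonymous"`, `"missense"`, `"nonsense"` or `"start_loss"`).
#'
#' @examples
#' m <- transcript_model("TOY", "chr1", "+", cbind(101, 112), "ATGGTTCGTTAA")
#' annotate_amino_acid_change(
#'   list(chrom = "chr1", pos = 105, ref = "T", alt = "C"), m)  # V -> A
#' @export
annotate_amino_acid_change <- function(variant, model) {
  stopifnot(inherits(model, "transcript_model"))
  pos <- as.integer(variant$pos)
  ref <- as.character(variant$ref); alt <- as.character(variant$alt)
  if (variant$chrom != model$chrom)
    stop("variant chromosome does not match the model", call. = FALSE)
  off <- .genomic_to_cds_offset(model, pos)
  if (is.na(off))
    stop("variant at ", model$chrom, ":", pos, " is not coding in this model",
         call. = FALSE)
  if (model$strand == "-") {
    ref <- .COMPLEMENT[[ref]]
    alt <- .COMPLEMENT[[alt]]
  }
  cds_ref <- substr(model$cds_sequence, off, off)
  if (cds_ref != ref)
    stop("reference mismatch at ", model$chrom, ":", pos,
         " (CDS has ", cds_ref, ", variant claims ", ref, ")", call. = FALSE)
  ci <- (off - 1L) %/% 3L + 1L
  within <- (off - 1L) %% 3L + 1L
  codon <- substr(model$cds_sequence, (ci - 1L) * 3L + 1L, ci * 3L)
  alt_codon <- codon
  substr(alt_codon, within, within) <- alt
  ref_aa <- .translate_codon(codon)
  alt_aa <- .translate_codon(alt_codon)
  consequence <- if (ref_aa == alt_aa) "synonymous"
    else if (alt_aa == "*") "nonsense"
    else if (ci == 1L && ref_aa == "M") "start_loss"
    else "missense"
  list(codon_index = ci, ref_aa = ref_aa, alt_aa = alt_aa,
       consequence = consequence)
}

#' Targeted-capture variant triage cascade
#'
#' Applies, in order: (1) removal of known SNPs against the catalog, (2)
#' removal of non-coding variants against the transcript models, (3) removal
#' of variants that do not change the encoded amino acid.  Survivors are
#' exactly the variants with consequence missense, nonsense or start-loss.
#'
#' @param variants data.frame of variant records.
#' @param catalog A [snp_catalog()].
#' @param models Named list of [transcript_model()] objects.
#' @return List with `survivors` (annotated data.frame gaining `gene`,
#'   `codon_index`, `ref_aa`, `alt_aa`, `consequence`) and `report` (a
#'   data.frame of per-stage input / discarded / retained counts and
#'   discard fractions).
#' @export
run_cascade <- function(variants, catalog, models) {
  .check_variants_df(variants)
  n_input <- nrow(variants)

  st1 <- filter_known_snps(variants, catalog)
  after_snp <- nrow(st1$kept)

  is_coding <- vapply(seq_len(after_snp), function(i)
    classify_coding(st1$kept$chrom[i], st1$kept$pos[i], models) == "coding",
    logical(1))
  if (after_snp == 0) is_coding <- logical(0)
  coding <- st1$kept[is_coding, , drop = FALSE]
  after_coding <- nrow(coding)

  if (after_coding > 0) {
    ann <- lapply(seq_len(after_coding), function(i) {
      v <- coding[i, ]
      m <- NULL
      for (cand in models)
        if (cand$chrom == v$chrom &&
            !is.na(.genomic_to_cds_offset(cand, v$pos))) { m <- cand; break }
      c(annotate_amino_acid_change(v, m), gene = m$gene)
    })
    coding$gene <- vapply(ann, `[[`, "", "gene")
    coding$codon_index <- vapply(ann, `[[`, 1L, "codon_index")
    coding$ref_aa <- vapply(ann, `[[`, "", "ref_aa")
    coding$alt_aa <- vapply(ann, `[[`, "", "alt_aa")
    coding$consequence <- vapply(ann, `[[`, "", "consequence")
    survivors <- coding[coding$consequence %in%
                          c("missense", "nonsense", "start_loss"), ,
                        drop = FALSE]
  } else {
    coding$gene <- character(0); coding$codon_index <- integer(0)
    coding$ref_aa <- character(0); coding$alt_aa <- character(0)
    coding$consequence <- character(0)
    survivors <- coding
  }
  after_nonsyn <- nrow(survivors)

  inputs <- c(n_input, after_snp, after_coding)
  retained <- c(after_snp, after_coding, after_nonsyn)
  report <- data.frame(
    stage = c("known_snp", "non_coding", "synonymous"),
    n_input = inputs,
    n_discarded = inputs - retained,
    n_retained = retained,
    frac_discarded = ifelse(inputs > 0, (inputs - retained) / inputs, 0),
    stringsAsFactors = FALSE
  )
  list(survivors = survivors, report = report)
}

#' Two-SNP haplotype classification
#'
#' Classifies each sample by its alleles at two linked sites: `"variant"`
#' if the variant allele is carried at both sites, `"common"` if at neither,
#' `"other"` (discordant) otherwise.  Samples with a missing genotype at
#' either site are skipped with a warning.
#'
#' @param genotypes data.frame with columns `sample`, `site1`, `site2`;
#'   each genotype is a string like `"T/C"` (unphased alleles).  `NA` or
#'   `"./."` marks a missing genotype.
#' @param site_defs List of two `c(common = , variant = )` allele pairs, one
#'   per site.
#' @return data.frame with columns `sample` and `class`; attribute
#'   `n_skipped` counts samples dropped for missing genotypes.
#'
#' @examples
#' defs <- list(site1 = c(common = "T", variant = "C"),
#'              site2 = c(common = "C", variant = "T"))
#' gt <- data.frame(sample = c("p1", "p2", "p3"),
#'                  site1 = c("T/C", "T/T", "C/C"),
#'                  site2 = c("C/T", "C/C", "C/C"))
#' call_haplotypes(gt, defs)  # variant, common, other
#' @export
call_haplotypes <- function(genotypes, site_defs) {
  stopifnot(is.data.frame(genotypes),
            all(c("sample", "site1", "site2") %in% names(genotypes)),
            length(site_defs) == 2)
  carries <- function(gt, allele) {
    if (is.na(gt) || gt == "./.") return(NA)
    allele %in% strsplit(gt, "[/|]")[[1]]
  }
  v1 <- vapply(genotypes$site1, carries, NA,
               allele = site_defs[[1]][["variant"]])
  v2 <- vapply(genotypes$site2, carries, NA,
               allele = site_defs[[2]][["variant"]])
  missing <- is.na(v1) | is.na(v2)
  if (any(missing))
    warning(sum(missing), " sample(s) skipped for missing genotypes: ",
            paste(utils::head(genotypes$sample[missing], 5), collapse = ", "))
  cls <- ifelse(v1 & v2, "variant", ifelse(!v1 & !v2, "common", "other"))
  out <- data.frame(sample = genotypes$sample[!missing],
                    class = cls[!missing], stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- sum(missing)
  out
}

#' Case-control comparison of haplotype carrier frequencies
#'
#' Counts variant-haplotype carriers in cases and controls, builds the 2x2
#' table (rows case/control, columns carrier/non-carrier) and reports the
#' odds ratio, the uncorrected chi-square p-value and the one-sided Fisher
#' p-value (the study-level test for such comparisons is conventionally
#' unnamed, so both are emitted).
#'
#' @param cases,controls Haplotype call data.frames from [call_haplotypes()].
#' @return List with `table` (a [contingency_2x2()]), `or` (estimate and CI),
#'   `chisq_p`, `fisher_one_sided_p` and `fisher_two_sided_p`.
#' @export
compare_carrier_frequencies <- function(cases, controls) {
  if (!nrow(cases) || !nrow(controls))
    stop("both case and control call sets must be non-empty", call. = FALSE)
  a <- sum(cases$class == "variant")
  b <- nrow(cases) - a
  c <- sum(controls$class == "variant")
  d <- nrow(controls) - c
  tab <- contingency_2x2(a, b, c, d)
  chi <- chi_square_2x2(tab, yates = FALSE)
  list(table = tab,
       or = odds_ratio_ci(tab),
       chisq = unname(chi["statistic"]),
       chisq_p = unname(chi["p"]),
       fisher_one_sided_p = fisher_exact(tab, "one_greater"),
       fisher_two_sided_p = fisher_exact(tab, "two_sided"))
}
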