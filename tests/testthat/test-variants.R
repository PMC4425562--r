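test_that("known-SNP filtering partitions by key or by id", {
  vars <- do.call(rbind, lapply(1:10, function(i)
    variant_rec("chr1", 1000 + i, "A", "G", sample = "s1")))
  vars$id[7] <- "rs000123"
  cat <- snp_catalog(data.frame(chrom = "chr1", pos = 1001:1003, alt = "G",
                                id = NA_character_))
  res <- filter_known_snps(vars, cat)
  expect_identical(nrow(res$kept), 7L)
  expect_identical(nrow(res$discarded), 3L)
  expect_identical(nrow(res$kept) + nrow(res$discarded), nrow(vars))
  # id-only match also discards
  cat2 <- snp_catalog(data.frame(chrom = "chrX", pos = 1L, alt = "T",
                                 id = "rs000123"))
  res2 <- filter_known_snps(vars, cat2)
  expect_identical(nrow(res2$discarded), 1L)
  # empty catalog keeps everything
  cat0 <- snp_catalog(data.frame(chrom = character(0), pos = integer(0),
                                 alt = character(0)))
  expect_identical(nrow(filter_known_snps(vars, cat0)$kept), nrow(vars))
})

test_that("coding classification is 1-based inclusive on CDS intervals", {
  m <- toy_model()  # CDS 101..112
  models <- list(TOY = m)
  expect_identical(classify_coding("chr1", 101, models), "coding")
  expect_identical(classify_coding("chr1", 112, models), "coding")
  expect_identical(classify_coding("chr1", 113, models), "non_coding")
  expect_identical(classify_coding("chr1", 100, models), "non_coding")
  expect_identical(classify_coding("chr9", 105, models), "non_coding")
})

test_that("amino-acid annotation reproduces hallmark substitution patterns", {
  m <- toy_model()  # ATG GTT CGT TAA = M V R *
  # valine -> alanine (the V97A pattern): codon 2, second base T>C
  va <- annotate_amino_acid_change(
    variant_rec("chr1", 105, "T", "C"), m)
  expect_identical(va[c("codon_index", "ref_aa", "alt_aa", "consequence")],
                   list(codon_index = 2L, ref_aa = "V", alt_aa = "A",
                        consequence = "missense"))
  # arginine -> cysteine (the R174C pattern): codon 3, first base C>T
  rc <- annotate_amino_acid_change(variant_rec("chr1", 107, "C", "T"), m)
  expect_identical(rc[c("ref_aa", "alt_aa", "consequence")],
                   list(ref_aa = "R", alt_aa = "C",
                        consequence = "missense"))
  expect_identical(rc$codon_index, 3L)
  # wobble: third-base change GTT -> GTC stays valine
  syn <- annotate_amino_acid_change(variant_rec("chr1", 106, "T", "C"), m)
  expect_identical(syn$consequence, "synonymous")
  # reference-mismatch and non-coding errors name the position
  expect_error(annotate_amino_acid_change(variant_rec("chr1", 105, "G", "C"),
                                          m), "105")
  expect_error(annotate_amino_acid_change(variant_rec("chr1", 400, "A", "C"),
                                          m), "not coding")
})

test_that("exhaustive single-base mutation agrees with a translation oracle", {
  skip_if_not_installed("seqinr")
  cds <- "ATGGTTCGTTAA"
  for (model in list(toy_model(), toy_model_minus())) {
    start <- model$cds_intervals[1, 1]
    for (off in 1:nchar(cds)) {
      ref_cds <- substr(cds, off, off)
      gpos <- if (model$strand == "+") start + off - 1
              else model$cds_intervals[1, 2] - off + 1
      gref <- if (model$strand == "+") ref_cds
              else chartr("ACGT", "TGCA", ref_cds)
      for (alt_cds in setdiff(c("A", "C", "G", "T"), ref_cds)) {
        galt <- if (model$strand == "+") alt_cds
                else chartr("ACGT", "TGCA", alt_cds)
        ann <- annotate_amino_acid_change(
          variant_rec(model$chrom, gpos, gref, galt), model)
        mut <- cds
        substr(mut, off, off) <- alt_cds
        prot_ref <- bf_translate_cds(cds)
        prot_mut <- bf_translate_cds(mut)
        ci <- (off - 1) %/% 3 + 1
        aa_ref <- substr(prot_ref, ci, ci)
        aa_mut <- substr(prot_mut, ci, ci)
        expect_identical(ann$codon_index, as.integer(ci))
        expect_identical(ann$ref_aa, aa_ref)
        expect_identical(ann$alt_aa, aa_mut)
        expected <- if (aa_ref == aa_mut) "synonymous"
          else if (aa_mut == "*") "nonsense"
          else if (ci == 1 && aa_ref == "M") "start_loss"
          else "missense"
        expect_identical(ann$consequence, expected)
      }
    }
  }
})

test_that("strand-mirrored annotation is consistent", {
  plus <- toy_model(); minus <- toy_model_minus()
  # same CDS change (codon 2 pos 2, T>C) expressed on each strand
  on_plus <- annotate_amino_acid_change(variant_rec("chr1", 105, "T", "C"),
                                        plus)
  # CDS offset 5 on the minus model sits at genomic 212 - 5 + 1 = 208,
  # with complemented alleles
  on_minus <- annotate_amino_acid_change(variant_rec("chr2", 208, "A", "G"),
                                         minus)
  expect_identical(on_plus, on_minus)
})

test_that("the triage cascade reproduces a hand-built stage accounting", {
  m <- toy_model()
  models <- list(TOY = m)
  known <- do.call(rbind, lapply(1:5, function(i)
    variant_rec("chr1", 10 + i, "A", "G", sample = sprintf("s%d", i))))
  noncoding <- do.call(rbind, lapply(1:8, function(i)
    variant_rec("chr1", 300 + i, "C", "T", sample = sprintf("s%d", i))))
  synonymous <- do.call(rbind, lapply(1:4, function(i)
    variant_rec("chr1", 106, "T", "C", sample = sprintf("s%d", i))))
  missense <- rbind(
    variant_rec("chr1", 105, "T", "C", sample = "s1"),   # V>A
    variant_rec("chr1", 107, "C", "T", sample = "s2"),   # R>C
    variant_rec("chr1", 104, "G", "A", sample = "s3"))   # GTT>ATT, V>I
  vars <- rbind(known, noncoding, synonymous, missense)
  cat <- snp_catalog(data.frame(chrom = "chr1", pos = 11:15, alt = "G"))
  res <- run_cascade(vars, cat, models)
  expect_identical(res$report$n_input, c(20L, 15L, 7L))
  expect_identical(res$report$n_retained, c(15L, 7L, 3L))
  expect_identical(nrow(res$survivors), 3L)
  expect_setequal(res$survivors$consequence, "missense")
  # conservation at every stage
  expect_identical(res$report$n_input - res$report$n_discarded,
                   res$report$n_retained)
  expect_identical(res$report$n_input[-1], res$report$n_retained[-3])
})

test_that("cascade handles the all-known and synthetic-cohort cases", {
  m <- toy_model()
  vars <- do.call(rbind, lapply(1:4, function(i)
    variant_rec("chr1", 20 + i, "A", "G")))
  cat <- snp_catalog(data.frame(chrom = "chr1", pos = 21:24, alt = "G"))
  res <- run_cascade(vars, cat, list(TOY = m))
  expect_identical(res$report$n_retained, c(0L, 0L, 0L))
  expect_identical(nrow(res$survivors), 0L)
  # generated cohort: stage fractions near generator parameters
  vc <- generate_variant_cohort(n_samples = 3, per_sample_mean = 400,
                                seed = 17)
  out <- run_cascade(vc$variants, vc$catalog, vc$models)
  n <- nrow(vc$variants)
  expect_lt(abs(out$report$frac_discarded[1] - 0.56),
            3 * sqrt(0.56 * 0.44 / n))
  expect_identical(out$report$n_retained[3], nrow(out$survivors))
  # survivors are exactly the planted amino-acid-changing novelties
  expect_identical(sort(paste(out$survivors$chrom, out$survivors$pos,
                              out$survivors$alt, out$survivors$sample)),
                   sort(paste(vc$truth$planted_missense$chrom,
                              vc$truth$planted_missense$pos,
                              vc$truth$planted_missense$alt,
                              vc$truth$planted_missense$sample)))
})

test_that("two-site haplotype calls partition the samples", {
  defs <- list(site1 = c(common = "T", variant = "C"),
               site2 = c(common = "C", variant = "T"))
  gt <- data.frame(
    sample = sprintf("p%d", 1:6),
    site1 = c("C/T", "T/T", "C/C", "T/T", NA, "C/T"),
    site2 = c("T/C", "C/C", "C/C", "C/T", "C/C", "T/T"),
    stringsAsFactors = FALSE)
  expect_warning(calls <- call_haplotypes(gt, defs), "skipped")
  expect_identical(attr(calls, "n_skipped"), 1L)
  expect_identical(calls$class[calls$sample == "p1"], "variant")
  expect_identical(calls$class[calls$sample == "p2"], "common")
  expect_identical(calls$class[calls$sample == "p3"], "other")
  expect_identical(calls$class[calls$sample == "p4"], "other")
  expect_identical(nrow(calls) + attr(calls, "n_skipped"), nrow(gt))
})

test_that("carrier-frequency comparison rebuilds the case-control table", {
  cases <- data.frame(sample = sprintf("c%d", 1:100),
                      class = c(rep("variant", 12), rep("common", 88)))
  controls <- data.frame(sample = sprintf("k%d", 1:100),
                         class = c(rep("variant", 5), rep("common", 90),
                                   rep("other", 5)))
  cmp <- compare_carrier_frequencies(cases, controls)
  expect_identical(c(cmp$table$a, cmp$table$b, cmp$table$c, cmp$table$d),
                   c(12L, 88L, 5L, 95L))
  expect_equal(cmp$chisq, 3.1501, tolerance = 1e-4)
  # equal carrier proportions: no association
  eq <- compare_carrier_frequencies(
    data.frame(sample = sprintf("a%d", 1:10),
               class = rep(c("variant", "common"), each = 5)),
    data.frame(sample = sprintf("b%d", 1:10),
               class = rep(c("variant", "common"), each = 5)))
  expect_equal(eq$chisq, 0)
  expect_error(compare_carrier_frequencies(cases[0, ], controls),
               "non-empty")
})

test_that("indels and malformed variant tables are rejected", {
  bad <- variant_rec("chr1", 105, "TT", "C")
  expect_error(filter_known_snps(bad, snp_catalog(
    data.frame(chrom = "chr1", pos = 1, alt = "A"))), "single-nucleotide")
  expect_error(run_cascade(variant_rec("chr1", 105, "A", "A"),
                           snp_catalog(data.frame(chrom = "chr1", pos = 1,
                                                  alt = "A")),
                           list(TOY = toy_model())), "differ")
})
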