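#' Design of a synthetic expression cohort
#'
#' Describes the simulated study: group sizes, number of genes, how many genes
#' are truly up-regulated in the case group, the size of that shift, and the
#' residual noise.  Defaults mirror a low-risk MDS expression profiling study
#' with 30 RARS cases, 39 RCUD cases and 31 controls, with planted effects on
#' the scale typically seen for strongly deregulated iron/mitochondrial genes.
#'
#' @param group_sizes Named integer vector: samples per group.  The default is
#'   `c(RARS = 30, RCUD = 39, CTRL = 31)`.
#' @param n_genes Number of genes on the simulated array.
#' @param n_planted Number of genes truly up-regulated in `case_group`.
#' @param effect_log2 Mean log2 shift of planted genes (log2 units).
#' @param noise_sd Per-gene residual SD on the log2 scale.
#' @param case_group Group label receiving the planted up-regulation; defaults
#'   to the first group.
#' @param var_prior_df,var_prior_scale Optional scaled-inverse-chi-square
#'   hyperparameters (`d0`, `s0^2`): when both are given, per-gene variances
#'   are drawn as `d0 * s0^2 / rchisq(d0)` instead of being constant at
#'   `noise_sd^2`, which exercises the moderated-t hyperparameter fit.
#' @param seed Integer seed; all randomness in the generator flows from it.
#'
#' @return A `cohort_design` list.
#' @export
cohort_design <- function(group_sizes = c(RARS = 30, RCUD = 39, CTRL = 31),
                          n_genes = 2000,
                          n_planted = 100,
                          effect_log2 = 2,
                          noise_sd = 0.7,
                          case_group = names(group_sizes)[1],
                          var_prior_df = NULL,
                          var_prior_scale = NULL,
                          seed = 1) {
  if (is.null(names(group_sizes)) || any(!nzchar(names(group_sizes))))
    stop("invalid design: `group_sizes` must be named", call. = FALSE)
  if (any(group_sizes < 1))
    stop("invalid design: `group_sizes` must all be >= 1", call. = FALSE)
  if (n_genes < 1)
    stop("invalid design: `n_genes` must be >= 1", call. = FALSE)
  if (n_planted < 0 || n_planted > n_genes)
    stop("invalid design: `n_planted` must lie in [0, n_genes]", call. = FALSE)
  if (!is.finite(noise_sd) || noise_sd <= 0)
    stop("invalid design: `noise_sd` must be > 0", call. = FALSE)
  if (!case_group %in% names(group_sizes))
    stop("invalid design: `case_group` is not a group label", call. = FALSE)
  if (xor(is.null(var_prior_df), is.null(var_prior_scale)))
    stop("invalid design: supply both or neither of `var_prior_df` and `var_prior_scale`",
         call. = FALSE)
  structure(
    list(group_sizes = group_sizes, n_genes = as.integer(n_genes),
         n_planted = as.integer(n_planted), effect_log2 = effect_log2,
         noise_sd = noise_sd, case_group = case_group,
         var_prior_df = var_prior_df, var_prior_scale = var_prior_scale,
         seed = as.integer(seed)),
    class = "cohort_design"
  )
}

#' Generate a synthetic expression cohort with known ground truth
#'
#' Baseline per-gene means are drawn from Normal(7, 1.5) on the log2 scale
#' (the rough shape of RMA-normalized microarray data); residuals are i.i.d.
#' Normal(0, `noise_sd`) unless a variance prior is configured in the design,
#' in which case per-gene SDs come from a scaled inverse chi-square.  A random
#' subset of `n_planted` genes is shifted up by `effect_log2` in the case
#' group only.
#'
#' @param design A [cohort_design()].
#'
#' @return A list with elements `cohort` (an [expression_cohort()]) and
#'   `truth` (planted gene IDs, the case group, and the per-gene SDs used).
#'
#' @examples
#' sim <- generate_expression_cohort(
#'   cohort_design(c(A = 5, B = 5), n_genes = 50, n_planted = 5, seed = 7))
#' sim$cohort
#' head(sim$truth$planted_genes)
#' @export
generate_expression_cohort <- function(design) {
  if (!inherits(design, "cohort_design"))
    design <- do.call(cohort_design, design)
  withr::with_seed(design$seed, {
    G <- design$n_genes
    n <- sum(design$group_sizes)
    genes <- sprintf("g%05d", seq_len(G))
    samples <- unlist(lapply(names(design$group_sizes), function(gr)
      sprintf("%s_%02d", gr, seq_len(design$group_sizes[[gr]]))))
    groups <- rep(names(design$group_sizes), design$group_sizes)
    names(groups) <- samples
    mu <- stats::rnorm(G, mean = 7, sd = 1.5)
    if (!is.null(design$var_prior_df)) {
      sd_g <- sqrt(design$var_prior_df * design$var_prior_scale /
                     stats::rchisq(G, df = design$var_prior_df))
    } else {
      sd_g <- rep(design$noise_sd, G)
    }
    values <- mu + matrix(stats::rnorm(G * n), G, n) * sd_g
    dimnames(values) <- list(genes, samples)
    planted <- sort(sample(genes, design$n_planted))
    case_cols <- groups == design$case_group
    values[planted, case_cols] <-
      values[planted, case_cols] + design$effect_log2
    list(
      cohort = expression_cohort(values, groups),
      truth = list(planted_genes = planted,
                   case_group = design$case_group,
                   gene_sd = stats::setNames(sd_g, genes))
    )
  })
}

#' Attach mutation-status labels to a cohort
#'
#' Convenience for the mutation-split contrasts of the signature selector:
#' marks the first `n_mutated` samples of `within_groups` as `"mutated"` and
#' the rest as `"unmutated"`.
#'
#' @param cohort An [expression_cohort()].
#' @param n_mutated Number of mutated samples.
#' @param within_groups Group labels eligible for labelling (default: all).
#' @return The cohort with `mutation_status` filled in.
#' @export
label_mutation_status <- function(cohort, n_mutated, within_groups = NULL) {
  stopifnot(inherits(cohort, "expression_cohort"))
  pool <- cohort$samples
  if (!is.null(within_groups))
    pool <- pool[cohort$groups[pool] %in% within_groups]
  if (n_mutated > length(pool))
    stop("`n_mutated` exceeds the eligible sample count", call. = FALSE)
  status <- stats::setNames(rep("unmutated", length(pool)), pool)
  status[seq_len(n_mutated)] <- "mutated"
  expression_cohort(cohort$values[, pool, drop = FALSE],
                    cohort$groups[pool], status)
}

#' Generate a random gene-set collection
#'
#' Named sets are sampled without replacement from the gene universe; used as
#' fixtures for enrichment testing (the category structure mirrors functional
#' annotation tables such as a 106-gene MITOCHONDRION category).
#'
#' @param universe Character vector of gene IDs.
#' @param n_sets Number of sets to draw.
#' @param set_size_range Length-2 integer vector `(min, max)` of set sizes.
#' @param seed Integer seed.
#'
#' @return A `gene_set_collection`: list with `sets` (named list of character
#'   vectors) and `universe`.
#' @export
generate_gene_sets <- function(universe, n_sets,
                               set_size_range = c(10, 100), seed = 1) {
  if (!length(universe))
    stop("`universe` must be non-empty", call. = FALSE)
  if (anyDuplicated(universe))
    stop("`universe` contains duplicate gene IDs", call. = FALSE)
  if (n_sets == 0)
    return(gene_set_collection(stats::setNames(list(), character(0)),
                               universe))
  if (max(set_size_range) > length(universe))
    stop("set sizes exceed the universe size", call. = FALSE)
  if (set_size_range[1] > set_size_range[2])
    stop("`set_size_range` must be (min, max)", call. = FALSE)
  withr::with_seed(seed, {
    sets <- lapply(seq_len(n_sets), function(i) {
      size <- if (set_size_range[1] == set_size_range[2]) set_size_range[1]
              else sample(seq(set_size_range[1], set_size_range[2]), 1)
      sort(sample(universe, size))
    })
    names(sets) <- sprintf("SET_%03d", seq_len(n_sets))
    gene_set_collection(sets, universe)
  })
}

#' Gene-set collection constructor
#'
#' @param sets Named list of character vectors (gene IDs).
#' @param universe Character vector of gene IDs; every set must be a subset.
#' @return A `gene_set_collection` object.
#' @export
gene_set_collection <- function(sets, universe) {
  if (length(sets)) {
    if (is.null(names(sets)) || any(!nzchar(names(sets))))
      stop("every gene set must have a non-blank name", call. = FALSE)
    outside <- setdiff(unique(unlist(sets)), universe)
    if (length(outside))
      stop("set members outside the universe: ",
           paste(utils::head(outside, 5), collapse = ", "), call. = FALSE)
  }
  structure(list(sets = sets, universe = universe),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection:", length(x$sets), "sets over",
      length(x$universe), "universe genes\n")
  invisible(x)
}

# ---- variant cohort -------------------------------------------------------

.BASES <- c("A", "C", "G", "T")
.STOPS <- c("TAA", "TAG", "TGA")

# random CDS: ATG + non-stop codons + TAA, length 3*n_codons
.random_cds <- function(n_codons) {
  all_codons <- apply(expand.grid(.BASES, .BASES, .BASES), 1, paste0,
                      collapse = "")
  body <- sample(setdiff(all_codons, .STOPS), n_codons - 2, replace = TRUE)
  paste0(c("ATG", body, "TAA"), collapse = "")
}

#' Generate a set of synthetic transcript models
#'
#' One pseudo-chromosome per model; CDS split into 1-3 forward-strand exons
#' with intronic gaps, placed inside a large chromosome span so that
#' non-coding positions are plentiful.
#'
#' @param n_models Number of models.
#' @param codon_range Range of CDS length in codons.
#' @param seed Integer seed.
#' @return A named list of [transcript_model()] objects.
#' @export
generate_transcript_models <- function(n_models = 12,
                                       codon_range = c(120, 400),
                                       seed = 1) {
  withr::with_seed(seed, {
    models <- lapply(seq_len(n_models), function(i) {
      n_codons <- sample(seq(codon_range[1], codon_range[2]), 1)
      cds <- .random_cds(n_codons)
      len <- nchar(cds)
      n_exons <- sample(1:3, 1)
      # split CDS length into n_exons positive pieces
      cuts <- sort(sample(seq_len(len - 1), n_exons - 1))
      sizes <- diff(c(0, cuts, len))
      start <- sample(5000:20000, 1)
      iv <- matrix(NA_integer_, n_exons, 2)
      pos <- start
      for (e in seq_len(n_exons)) {
        iv[e, ] <- c(pos, pos + sizes[e] - 1)
        pos <- iv[e, 2] + sample(200:2000, 1)  # intron gap
      }
      transcript_model(gene = sprintf("GENE%02d", i),
                       chrom = sprintf("chr%02d", i),
                       strand = "+", cds_intervals = iv, cds_sequence = cds)
    })
    names(models) <- vapply(models, `[[`, "", "gene")
    models
  })
}

#' Generate a synthetic targeted-capture variant cohort
#'
#' Emulates a targeted resequencing screen of a handful of patients: each
#' sample carries on the order of a thousand single-nucleotide variants, a
#' stated fraction of which match a known-SNP catalog, lie in coding sequence,
#' and change the encoded amino acid.  Defaults follow the triage proportions
#' of a 6-patient ring-sideroblast capture screen (about 1367 variants per
#' sample; 56% known SNPs; 85% of the new variants non-coding; 58% of the
#' coding remainder synonymous).
#'
#' @param n_samples Number of samples (>= 1).
#' @param per_sample_mean Poisson mean of variants per sample.
#' @param frac_known_snp Probability a variant is in the known-SNP catalog.
#' @param frac_coding Probability a variant falls in coding sequence.
#' @param frac_nonsyn Probability a variant is coding AND non-synonymous;
#'   must not exceed `frac_coding`.
#' @param n_models Number of transcript models to simulate against.
#' @param seed Integer seed.
#'
#' @return A list with `variants` (data.frame of variant records: `chrom`,
#'   `pos`, `ref`, `alt`, `sample`, `genotype`, `id`), `catalog` (a
#'   [snp_catalog()]), `models` (named list of [transcript_model()]), and
#'   `truth` (per-variant `known`/`coding`/`nonsyn` flags plus the planted
#'   missense list).
#' @export
generate_variant_cohort <- function(n_samples = 6,
                                    per_sample_mean = 1367,
                                    frac_known_snp = 0.56,
                                    frac_coding = 0.15,
                                    frac_nonsyn = 0.063,
                                    n_models = 12,
                                    seed = 1) {
  for (nm in c("frac_known_snp", "frac_coding", "frac_nonsyn")) {
    v <- get(nm)
    if (!is.finite(v) || v < 0 || v > 1)
      stop("invalid configuration: `", nm, "` must lie in [0, 1]",
           call. = FALSE)
  }
  if (frac_nonsyn > frac_coding)
    stop("invalid configuration: `frac_nonsyn` exceeds `frac_coding`",
         call. = FALSE)
  if (n_samples < 1 || per_sample_mean < 1)
    stop("invalid configuration: counts must be >= 1", call. = FALSE)
  models <- generate_transcript_models(n_models, seed = seed)
  chrom_len <- 2e5
  withr::with_seed(seed + 1L, {
    sample_ids <- sprintf("S%02d", seq_len(n_samples))
    counts <- stats::rpois(n_samples, per_sample_mean)
    total <- sum(counts)
    sample_col <- rep(sample_ids, counts)
    known <- stats::runif(total) < frac_known_snp
    coding <- stats::runif(total) < frac_coding
    p_nonsyn_given_coding <- if (frac_coding > 0) frac_nonsyn / frac_coding else 0
    nonsyn <- coding & (stats::runif(total) < p_nonsyn_given_coding)
    model_idx <- sample(length(models), total, replace = TRUE)

    chrom <- character(total); pos <- integer(total)
    ref <- character(total); alt <- character(total)
    for (i in seq_len(total)) {
      m <- models[[model_idx[i]]]
      chrom[i] <- m$chrom
      if (coding[i]) {
        v <- .draw_coding_variant(m, want_nonsyn = nonsyn[i])
        pos[i] <- v$pos; ref[i] <- v$ref; alt[i] <- v$alt
      } else {
        in_cds <- TRUE
        while (in_cds) {
          p <- sample.int(chrom_len, 1)
          in_cds <- any(p >= m$cds_intervals[, 1] & p <= m$cds_intervals[, 2])
        }
        pos[i] <- p
        ref[i] <- sample(.BASES, 1)
        alt[i] <- sample(setdiff(.BASES, ref[i]), 1)
      }
    }
    genotype <- sample(c("het", "hom"), total, replace = TRUE,
                       prob = c(0.9, 0.1))
    variants <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                           sample = sample_col, genotype = genotype,
                           id = NA_character_, stringsAsFactors = FALSE)
    # catalog: keys of known-flagged variants plus decoys never generated
    kk <- unique(variants[known, c("chrom", "pos", "alt")])
    kk$id <- sprintf("rs%06d", seq_len(nrow(kk)))
    key <- paste(variants$chrom, variants$pos, variants$alt)
    variants$id[known] <- kk$id[match(key[known], paste(kk$chrom, kk$pos, kk$alt))]
    decoys <- data.frame(chrom = "chr99",
                         pos = sample.int(chrom_len, 50),
                         alt = sample(.BASES, 50, replace = TRUE),
                         id = sprintf("rs9%05d", 1:50))
    catalog <- snp_catalog(rbind(kk, decoys))
    truth <- data.frame(chrom = chrom, pos = pos, alt = alt,
                        sample = sample_col, known = known,
                        coding = coding, nonsyn = nonsyn,
                        stringsAsFactors = FALSE)
    planted <- truth[!known & nonsyn, c("sample", "chrom", "pos", "alt")]
    list(variants = variants, catalog = catalog, models = models,
         truth = list(flags = truth, planted_missense = planted))
  })
}

# Draw a coding SNV on `model` whose consequence class (synonymous vs
# amino-acid-changing) matches `want_nonsyn`; rejection sampling over CDS
# offsets and alternative bases.
.draw_coding_variant <- function(model, want_nonsyn) {
  len <- nchar(model$cds_sequence)
  repeat {
    off <- sample.int(len, 1)
    refb <- substr(model$cds_sequence, off, off)
    ci <- (off - 1) %/% 3
    codon <- substr(model$cds_sequence, ci * 3 + 1, ci * 3 + 3)
    within <- (off - 1) %% 3 + 1
    aa_ref <- .translate_codon(codon)
    for (altb in sample(setdiff(.BASES, refb))) {
      alt_codon <- codon
      substr(alt_codon, within, within) <- altb
      changed <- .translate_codon(alt_codon) != aa_ref
      if (changed == want_nonsyn) {
        return(list(pos = .cds_offset_to_genomic(model, off),
                    ref = refb, alt = altb))
      }
    }
  }
}
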