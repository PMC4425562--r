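# All text IO is TSV, UTF-8, '.'-decimal; gene and sample IDs are opaque
# strings.  Writers can stamp a "# seed=" comment header; readers skip
# comment lines.

#' Write / read an expression cohort as TSV
#'
#' The expression file has a header row of sample IDs and gene IDs in the
#' first column (named `gene`); the companion phenotype file has columns
#' `sample`, `group` and optionally `mutation_status`.
#'
#' @param cohort An [expression_cohort()].
#' @param path,phenotype_path Paths of the expression and phenotype TSVs.
#' @param seed Optional integer recorded as a `# seed=` comment header.
#' @return `write_expression` returns `path` invisibly; `read_expression`
#'   returns an [expression_cohort()].
#' @export
write_expression <- function(cohort, path, phenotype_path, seed = NULL) {
  stopifnot(inherits(cohort, "expression_cohort"))
  con <- file(path, "w")
  if (!is.null(seed)) writeLines(paste0("# seed=", seed), con)
  df <- data.frame(gene = cohort$genes, cohort$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  ph <- data.frame(sample = cohort$samples,
                   group = unname(cohort$groups[cohort$samples]),
                   stringsAsFactors = FALSE)
  if (!is.null(cohort$mutation_status))
    ph$mutation_status <- unname(cohort$mutation_status[cohort$samples])
  con2 <- file(phenotype_path, "w")
  if (!is.null(seed)) writeLines(paste0("# seed=", seed), con2)
  utils::write.table(ph, con2, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con2)
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path, phenotype_path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines)) stop("empty expression file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol_header <- length(fields[[1]])
  ragged <- which(lengths(fields) != ncol_header)
  if (length(ragged))
    stop("ragged row in ", path, " at line ", ragged[1] + 1,
         " (expected ", ncol_header, " fields, got ",
         lengths(fields)[ragged[1]], ")", call. = FALSE)
  samples <- fields[[1]][-1]
  genes <- vapply(fields[-1], `[[`, "", 1)
  if (anyDuplicated(genes))
    stop("duplicate gene ID in ", path, ": ",
         genes[duplicated(genes)][1], call. = FALSE)
  vals <- vapply(fields[-1], function(f) {
    v <- suppressWarnings(as.numeric(f[-1]))
    v
  }, numeric(length(samples)))
  vals <- if (is.null(dim(vals))) matrix(vals, nrow = length(genes))
          else t(vals)
  badcell <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(badcell))
    stop("non-numeric cell in ", path, " at line ", badcell[1, 1] + 1,
         call. = FALSE)
  dimnames(vals) <- list(genes, samples)
  ph <- utils::read.delim(phenotype_path, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% names(ph)))
    stop("phenotype file needs 'sample' and 'group' columns", call. = FALSE)
  unknown <- setdiff(ph$sample, samples)
  if (length(unknown))
    stop("phenotype file lists unknown samples: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  groups <- stats::setNames(ph$group, ph$sample)
  ms <- if ("mutation_status" %in% names(ph))
    stats::setNames(ph$mutation_status, ph$sample) else NULL
  expression_cohort(vals, groups, ms)
}

#' Write / read a gene-set collection in GMT format
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then members.  On reading, duplicated members within a set are dropped
#' with a warning and blank set names are an error; the universe defaults to
#' the union of all members unless supplied.
#'
#' @param collection A [gene_set_collection()].
#' @param path GMT file path.
#' @param universe Optional character vector overriding the universe.
#' @return `read_gmt` returns a [gene_set_collection()].
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(nm)
    paste(c(nm, "na", collection$sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path, universe = NULL) {
  raw <- readLines(path)
  raw <- raw[nzchar(trimws(raw))]
  if (!length(raw))
    return(gene_set_collection(list(),
                               if (is.null(universe)) character(0) else universe))
  first <- vapply(strsplit(raw, "\t", fixed = TRUE), `[[`, "", 1)
  if (any(!nzchar(first)))
    stop("blank set name at GMT line ", which(!nzchar(first))[1],
         call. = FALSE)
  sets <- fgsea::gmtPathways(path)
  sets <- lapply(stats::setNames(names(sets), names(sets)), function(nm) {
    members <- sets[[nm]]
    if (anyDuplicated(members)) {
      warning("duplicate members in set '", nm, "' deduplicated")
      members <- unique(members)
    }
    members
  })
  if (is.null(universe)) universe <- sort(unique(unlist(sets)))
  gene_set_collection(sets, universe)
}

#' Write / read variant records as a VCF v4.2 subset
#'
#' One row per distinct variant; per-sample genotypes are written in a `GT`
#' FORMAT column (`0/1` het, `1/1` hom, `0/0` non-carrier).  Reading uses
#' `vcfR` and returns the long per-sample record form used across the
#' package (carriers only); indel-like records are rejected.
#'
#' @param variants data.frame of variant records (`chrom`, `pos`, `ref`,
#'   `alt`, `sample`, `genotype`, optional `id`).
#' @param path VCF path (uncompressed).
#' @param samples Optional sample column order; defaults to sorted unique
#'   samples present.
#' @param seed Optional integer recorded in a `##source` meta line.
#' @return `read_vcf` returns a variant data.frame.
#' @export
write_vcf <- function(variants, path, samples = NULL, seed = NULL) {
  .check_variants_df(variants)
  if (is.null(samples)) samples <- sort(unique(variants$sample))
  key <- paste(variants$chrom, variants$pos, variants$ref, variants$alt)
  uk <- !duplicated(key)
  uniq <- variants[uk, , drop = FALSE]
  ord <- order(uniq$chrom, uniq$pos)
  uniq <- uniq[ord, , drop = FALSE]
  ukey <- paste(uniq$chrom, uniq$pos, uniq$ref, uniq$alt)
  gt <- matrix("0/0", nrow(uniq), length(samples),
               dimnames = list(NULL, samples))
  for (i in seq_len(nrow(variants))) {
    r <- match(key[i], ukey)
    gt[r, variants$sample[i]] <-
      if (!is.null(variants$genotype) && variants$genotype[i] == "hom")
        "1/1" else "0/1"
  }
  id <- if ("id" %in% names(uniq)) ifelse(is.na(uniq$id), ".", uniq$id)
        else rep(".", nrow(uniq))
  meta <- c("##fileformat=VCFv4.2",
            if (!is.null(seed)) paste0("##source=sideroseq seed=", seed),
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
            paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_len(nrow(uniq)), function(i)
    paste(c(uniq$chrom[i], uniq$pos[i], id[i], uniq$ref[i], uniq$alt[i],
            ".", "PASS", ".", "GT", gt[i, ]), collapse = "\t"), "")
  writeLines(c(meta, body), path)
  invisible(path)
}

#' @rdname write_vcf
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  out <- list()
  for (s in colnames(gt)) {
    carrier <- !is.na(gt[, s]) & gt[, s] %in% c("0/1", "1/0", "1/1",
                                                "0|1", "1|0", "1|1")
    if (!any(carrier)) next
    out[[s]] <- data.frame(
      chrom = fix$CHROM[carrier],
      pos = as.integer(fix$POS[carrier]),
      ref = fix$REF[carrier],
      alt = fix$ALT[carrier],
      sample = s,
      genotype = ifelse(gt[carrier, s] %in% c("1/1", "1|1"), "hom", "het"),
      id = ifelse(fix$ID[carrier] == ".", NA_character_, fix$ID[carrier]),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  .check_variants_df(res)
}

#' Write / read a known-SNP catalog as 3-column TSV
#'
#' Columns `chrom`, `pos`, `alt` and optionally `id`.
#'
#' @param catalog A [snp_catalog()].
#' @param path TSV path.
#' @return `read_snp_catalog` returns a [snp_catalog()].
#' @export
write_snp_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "snp_catalog"))
  utils::write.table(catalog$entries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_snp_catalog
#' @export
read_snp_catalog <- function(path) {
  snp_catalog(utils::read.delim(path, comment.char = "#",
                                stringsAsFactors = FALSE))
}

#' Write / read transcript models as TSV plus a CDS FASTA
#'
#' The TSV has columns `gene`, `chrom`, `strand` and `intervals`
#' (comma-separated `start-end` pairs); the FASTA holds the spliced CDS
#' sequences named by gene.
#'
#' @param models Named list of [transcript_model()] objects.
#' @param tsv_path,fasta_path Output paths.
#' @return `read_transcript_models` returns a named list of models.
#' @export
write_transcript_models <- function(models, tsv_path, fasta_path) {
  df <- do.call(rbind, lapply(models, function(m) data.frame(
    gene = m$gene, chrom = m$chrom, strand = m$strand,
    intervals = paste(sprintf("%d-%d", m$cds_intervals[, 1],
                              m$cds_intervals[, 2]), collapse = ","),
    stringsAsFactors = FALSE)))
  utils::write.table(df, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  seqs <- Biostrings::DNAStringSet(
    stats::setNames(vapply(models, `[[`, "", "cds_sequence"),
                    vapply(models, `[[`, "", "gene")))
  Biostrings::writeXStringSet(seqs, fasta_path)
  invisible(tsv_path)
}

#' @rdname write_transcript_models
#' @export
read_transcript_models <- function(tsv_path, fasta_path) {
  df <- utils::read.delim(tsv_path, comment.char = "#",
                          stringsAsFactors = FALSE)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  models <- lapply(seq_len(nrow(df)), function(i) {
    parts <- strsplit(strsplit(df$intervals[i], ",")[[1]], "-")
    iv <- do.call(rbind, lapply(parts, function(p)
      as.integer(c(p[1], p[2]))))
    if (!df$gene[i] %in% names(seqs))
      stop("no CDS sequence for gene ", df$gene[i], call. = FALSE)
    transcript_model(df$gene[i], df$chrom[i], df$strand[i], iv,
                     as.character(seqs[[df$gene[i]]]))
  })
  stats::setNames(models, df$gene)
}
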