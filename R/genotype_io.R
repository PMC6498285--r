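# Genotype input, minor-allele coding and frequency filters.
#
# The panel container keeps genotypes as alternate-allele dosages (0/1/2,
# NA = missing call); orientation towards the minor allele happens once,
# globally, in code_alleles().

#' Construct a genotype panel
#'
#' A `genotype_panel` holds biallelic SNP records, sample records and the
#' diploid calls as an alternate-allele dosage matrix (`NA` = missing call).
#'
#' @param snps data.frame with columns `snp_id`, `chrom`, `pos` (1-based),
#'   `ref`, `alt`; `snp_id` must be unique.
#' @param samples data.frame with columns `sample_id`, `population`,
#'   `region`; `sample_id` must be unique.
#' @param dosage integer matrix, SNPs x samples, entries 0/1/2 or `NA`.
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(snps, samples, dosage) {
  stopifnot(is.data.frame(snps), is.data.frame(samples))
  req_s <- c("snp_id", "chrom", "pos", "ref", "alt")
  if (!all(req_s %in% names(snps)))
    stop("snps must have columns: ", paste(req_s, collapse = ", "))
  req_m <- c("sample_id", "population", "region")
  if (!all(req_m %in% names(samples)))
    stop("samples must have columns: ", paste(req_m, collapse = ", "))
  if (anyDuplicated(snps$snp_id)) stop("duplicate SNP identifiers")
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample identifiers")
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (nrow(dosage) != nrow(snps) || ncol(dosage) != nrow(samples))
    stop("dosage dimensions do not match snps/samples")
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("dosage entries must be 0, 1, 2 or NA")
  dimnames(dosage) <- list(snps$snp_id, samples$sample_id)
  structure(list(snps = snps, samples = samples, dosage = dosage),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d SNPs x %d samples (%d populations)\n",
              nrow(x$snps), nrow(x$samples),
              length(unique(x$samples$population))))
  nm <- sum(is.na(x$dosage))
  if (nm) cat(sprintf("  missing calls: %d\n", nm))
  invisible(x)
}

#' Read sample metadata
#'
#' Tab-separated file with columns `sample_id`, `population`, `region`.
#'
#' @param path metadata file path.
#' @return data.frame of sample records.
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) stop("sample table not found: ", path)
  md <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  req <- c("sample_id", "population", "region")
  miss <- setdiff(req, names(md))
  if (length(miss))
    stop("sample table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(md$sample_id)) stop("duplicate sample_id in ", path)
  md
}

# GT strings ("0/1", "1|0", ".", "./.") -> alt dosage, NA when any allele
# is missing.  Alleles other than 0/1 must have been filtered upstream.
.gt_to_dosage <- function(gt) {
  gt <- gsub("|", "/", gt, fixed = TRUE)
  parts <- strsplit(gt, "/", fixed = TRUE)
  vapply(parts, function(p) {
    if (!length(p) || any(p == ".")) return(NA_integer_)
    a <- suppressWarnings(as.integer(p))
    if (anyNA(a)) return(NA_integer_)
    sum(a)
  }, integer(1))
}

#' Read a genotype panel from VCF or a plain-text genotype matrix
#'
#' VCF input keeps biallelic SNPs only (multi-allelic and non-SNP records
#' are skipped with a message); genotypes are taken from the GT field,
#' phase ignored. The plain-text dialect is tab-separated with a header row
#' of sample IDs, first column the SNP ID, and entries 0/1/2 or "." for a
#' missing call.
#'
#' @param source path to a `.vcf` file or a plain-text genotype matrix.
#' @param sample_table path to the sample metadata table
#'   (`sample_id`, `population`, `region`).
#' @return A [genotype_panel]. Every sample in the genotype source must
#'   appear in the metadata; a sample without metadata is a hard error.
#' @export
read_genotypes <- function(source, sample_table) {
  if (!file.exists(source)) stop("genotype source not found: ", source)
  md <- read_sample_table(sample_table)
  if (grepl("\\.vcf(\\.gz)?$", source, ignore.case = TRUE)) {
    vcf <- VariantAnnotation::readVcf(source, genome = "unknown")
    gt <- VariantAnnotation::geno(vcf)$GT
    if (is.null(gt)) stop("VCF has no GT genotype field: ", source)
    ref <- as.character(VariantAnnotation::ref(vcf))
    alt_l <- VariantAnnotation::alt(vcf)
    n_alt <- lengths(alt_l)
    alt <- rep(NA_character_, length(n_alt))
    alt[n_alt == 1L] <- as.character(unlist(alt_l[n_alt == 1L]))
    keep <- n_alt == 1L & nchar(ref) == 1L &
      !is.na(alt) & nchar(alt) == 1L & alt != "."
    n_skip <- sum(!keep)
    if (n_skip)
      message(n_skip, " multi-allelic or non-SNP record(s) skipped")
    rr <- SummarizedExperiment::rowRanges(vcf)[keep]
    snps <- data.frame(
      snp_id = names(rr),
      chrom = as.character(GenomicRanges::seqnames(rr)),
      pos = GenomicRanges::start(rr),
      ref = ref[keep], alt = alt[keep],
      stringsAsFactors = FALSE)
    gt <- gt[keep, , drop = FALSE]
    dosage <- matrix(.gt_to_dosage(gt), nrow = nrow(gt),
                     ncol = ncol(gt), dimnames = dimnames(gt))
    sample_ids <- colnames(gt)
  } else {
    tab <- data.table::fread(source, sep = "\t", header = TRUE,
                             na.strings = ".", colClasses = list(
                               character = 1L), data.table = FALSE)
    if (ncol(tab) < 2L) stop("malformed genotype matrix: ", source)
    sample_ids <- colnames(tab)[-1L]
    dosage <- as.matrix(tab[, -1L, drop = FALSE])
    storage.mode(dosage) <- "integer"
    rownames(dosage) <- tab[[1L]]
    snps <- data.frame(
      snp_id = tab[[1L]], chrom = NA_character_, pos = NA_integer_,
      ref = "R", alt = "A", stringsAsFactors = FALSE)
  }
  missing_md <- setdiff(sample_ids, md$sample_id)
  if (length(missing_md))
    stop("sample(s) missing from metadata table: ",
         paste(missing_md, collapse = ", "))
  samples <- md[match(sample_ids, md$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  genotype_panel(snps, samples, dosage)
}

#' Remove SNPs with too many missing calls
#'
#' @param panel a [genotype_panel].
#' @param max_missing_rate maximum tolerated fraction of missing calls per
#'   SNP; the default 0 removes any SNP with a missing call, yielding the
#'   complete-case matrix the downstream coding requires.
#' @return The filtered [genotype_panel].
#' @export
drop_missing <- function(panel, max_missing_rate = 0) {
  stopifnot(inherits(panel, "genotype_panel"),
            max_missing_rate >= 0, max_missing_rate <= 1)
  rate <- rowMeans(is.na(panel$dosage))
  keep <- rate <= max_missing_rate
  genotype_panel(panel$snps[keep, , drop = FALSE], panel$samples,
                 panel$dosage[keep, , drop = FALSE])
}

#' Construct an allele-score matrix
#'
#' Scores count minor-allele copies (0 homozygous major, 1 heterozygous,
#' 2 homozygous minor); per-SNP minor allele frequency is recomputed from
#' the scores so that `maf == rowSums(scores) / (2 * M)` holds by
#' construction.
#'
#' @param scores integer matrix in \{0,1,2\}, SNPs x samples, no missing.
#' @param snp_meta per-row SNP records (with a `minor_allele` column).
#' @param sample_meta per-column sample records.
#' @return An object of class `allele_matrix` with fields `scores`,
#'   `snp_meta`, `sample_meta` and `maf`.
#' @export
allele_matrix <- function(scores, snp_meta, sample_meta) {
  scores <- as.matrix(scores)
  storage.mode(scores) <- "integer"
  if (anyNA(scores)) stop("allele_matrix scores must not contain NA")
  if (length(scores) && (min(scores) < 0L || max(scores) > 2L))
    stop("allele scores must be in {0, 1, 2}")
  if (nrow(scores) != nrow(snp_meta) || ncol(scores) != nrow(sample_meta))
    stop("score dimensions do not match metadata")
  # maf recomputed from the scores; matrices produced by code_alleles()
  # satisfy maf <= 0.5, but a column subset of one (zoom-in) may not,
  # since orientation stays with the global minor allele
  m <- ncol(scores)
  maf <- if (m > 0L) as.numeric(rowSums(scores)) / (2 * m) else numeric(0)
  dimnames(scores) <- list(snp_meta$snp_id, sample_meta$sample_id)
  structure(list(scores = scores, snp_meta = snp_meta,
                 sample_meta = sample_meta, maf = maf),
            class = "allele_matrix")
}

#' @export
print.allele_matrix <- function(x, ...) {
  cat(sprintf("allele_matrix: %d SNPs x %d samples; MAF range [%.3f, %.3f]\n",
              nrow(x$scores), ncol(x$scores),
              if (length(x$maf)) min(x$maf) else NA,
              if (length(x$maf)) max(x$maf) else NA))
  invisible(x)
}

#' @export
dim.allele_matrix <- function(x) dim(x$scores)

#' Code genotypes as minor-allele scores
#'
#' The minor allele of each SNP is determined once over the merged global
#' sample (all columns), so that scores remain comparable across
#' populations. When the alternate-allele frequency exceeds 0.5 the
#' reference allele is minor and the dosage is flipped (`2 - dosage`); at a
#' frequency of exactly 0.5 the alternate allele is designated minor,
#' deterministically.
#'
#' @param panel a complete-case [genotype_panel] (run [drop_missing] first).
#' @return An [allele_matrix].
#' @export
code_alleles <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  d <- panel$dosage
  if (anyNA(d))
    stop("panel contains missing calls; run drop_missing() first")
  m <- ncol(d)
  if (m == 0L) stop("panel has no samples")
  alt_freq <- rowSums(d) / (2 * m)
  flip <- alt_freq > 0.5          # ties at 0.5 stay alt-oriented
  scores <- d
  if (any(flip)) scores[flip, ] <- 2L - d[flip, , drop = FALSE]
  snp_meta <- panel$snps
  snp_meta$minor_allele <- ifelse(flip, snp_meta$ref, snp_meta$alt)
  allele_matrix(scores, snp_meta, panel$samples)
}

#' Filter SNPs by minor allele frequency
#'
#' Retains rows with MAF strictly greater than the threshold; a SNP at
#' exactly the threshold is removed.
#'
#' @param matrix an [allele_matrix].
#' @param threshold MAF cut in `[0, 0.5]`; default 0.05.
#' @return The filtered [allele_matrix].
#' @export
filter_by_maf <- function(matrix, threshold = 0.05) {
  stopifnot(inherits(matrix, "allele_matrix"),
            threshold >= 0, threshold <= 0.5)
  keep <- matrix$maf > threshold
  allele_matrix(matrix$scores[keep, , drop = FALSE],
                matrix$snp_meta[keep, , drop = FALSE],
                matrix$sample_meta)
}

#' Restrict an allele matrix to catalog SNPs
#'
#' @param matrix an [allele_matrix].
#' @param catalog an [association_catalog] (or character vector of SNP IDs).
#' @return The [allele_matrix] restricted, in original row order, to SNPs
#'   present in the catalog. An empty intersection is an error (usually an
#'   identifier-scheme mismatch between panel and catalog).
#' @export
restrict_to_catalog <- function(matrix, catalog) {
  stopifnot(inherits(matrix, "allele_matrix"))
  ids <- if (is.character(catalog)) catalog else catalog_snps(catalog)
  keep <- matrix$snp_meta$snp_id %in% ids
  if (!any(keep))
    stop("no matrix SNP occurs in the catalog; ",
         "check that both use the same identifier scheme")
  allele_matrix(matrix$scores[keep, , drop = FALSE],
                matrix$snp_meta[keep, , drop = FALSE],
                matrix$sample_meta)
}

#' Write an allele matrix in the plain-text genotype dialect
#'
#' Tab-separated; header row of sample IDs, first column `snp_id`, entries
#' 0/1/2. Re-reading with [read_genotypes] plus [code_alleles] reproduces
#' the scores exactly (minor-oriented scores never flip again).
#'
#' @param matrix an [allele_matrix].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_allele_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "allele_matrix"))
  df <- data.frame(snp_id = matrix$snp_meta$snp_id,
                   matrix$scores, check.names = FALSE,
                   stringsAsFactors = FALSE)
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}
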