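# Seeded synthetic multi-population genotype panels with known truth:
# Balding-Nichols differentiated background SNPs plus planted
# disease-annotated minor-allele blocks.

#' Specify a planted SNP block
#'
#' A block is a set of SNPs whose alternate-allele frequency is raised to
#' `freq` in the target population(s) and held at a low baseline
#' elsewhere, annotated with one disease term; this is the structure the
#' portrayal pipeline must recover as a spot.
#'
#' @param size number of SNPs (>= 1).
#' @param pops character vector of target population labels.
#' @param freq elevated alternate-allele frequency in targets.
#' @param term attached disease term identifier.
#' @param genes gene symbols cycled over the block's SNPs.
#' @param baseline_freq frequency outside the targets (default 0.05).
#' @return list of class `syn_block`.
#' @export
syn_block <- function(size, pops, freq, term,
                      genes = paste0("GENE_", term),
                      baseline_freq = 0.05) {
  stopifnot(size >= 1, freq > 0, freq < 1,
            baseline_freq > 0, baseline_freq < 1)
  structure(list(size = as.integer(size), pops = pops, freq = freq,
                 term = term, genes = genes,
                 baseline_freq = baseline_freq),
            class = "syn_block")
}

#' Specification of a synthetic genotype panel
#'
#' Defaults state a panel of 4 populations x 50 samples with 1,800
#' Balding-Nichols background SNPs at Fst 0.1 and four planted blocks of
#' 50 SNPs at elevated frequency 0.6, one per population — 2,000 SNPs in
#' total, the regime the planted-spot recovery checks run in.
#'
#' @param n_pops number of populations.
#' @param samples_per_pop samples per population.
#' @param n_background_snps Balding-Nichols background SNPs.
#' @param fst differentiation parameter in (0, 1).
#' @param blocks list of [syn_block]s; `NULL` gives the default four
#'   blocks, one per population, attached to distinct leaf terms of the
#'   default ontology fixture (see [make_ontology_fixture]).
#' @param ancestral_maf_range ancestral alternate-allele frequency range;
#'   the default (0.05, 0.5] mimics an array panel already screened at
#'   MAF > 0.05.
#' @param background_annotation_rate fraction of background SNPs given a
#'   random (decoy) leaf-term annotation; the default 1 mirrors a panel
#'   in which every SNP is disease-associated.
#' @param seed RNG seed; all randomness flows from it through fixed
#'   per-component offsets.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_pops = 4L, samples_per_pop = 50L,
                           n_background_snps = 1800L, fst = 0.1,
                           blocks = NULL,
                           ancestral_maf_range = c(0.05, 0.5),
                           background_annotation_rate = 1,
                           seed = 1L) {
  stopifnot(n_pops >= 1, samples_per_pop >= 1, fst > 0, fst < 1,
            length(ancestral_maf_range) == 2,
            ancestral_maf_range[1] > 0, ancestral_maf_range[2] <= 0.5,
            ancestral_maf_range[1] <= ancestral_maf_range[2],
            background_annotation_rate >= 0,
            background_annotation_rate <= 1)
  pops <- sprintf("pop%02d", seq_len(n_pops))
  if (is.null(blocks)) {
    onto <- make_ontology_fixture()
    leaves <- .fixture_leaves(onto)
    # spread the planted terms so their level-3 ancestors are distinct
    step <- max(1L, length(leaves) %/% 4L)
    pick <- leaves[seq(1L, by = step, length.out = min(4L, n_pops))]
    blocks <- lapply(seq_len(min(4L, n_pops)), function(i)
      syn_block(50L, pops[i], 0.6, pick[i]))
  }
  stopifnot(all(vapply(blocks, inherits, TRUE, "syn_block")))
  for (b in blocks)
    if (!all(b$pops %in% pops))
      stop("block targets unknown population(s): ",
           paste(setdiff(b$pops, pops), collapse = ", "))
  structure(list(n_pops = as.integer(n_pops),
                 samples_per_pop = as.integer(samples_per_pop),
                 n_background_snps = as.integer(n_background_snps),
                 fst = fst, blocks = blocks, pops = pops,
                 ancestral_maf_range = ancestral_maf_range,
                 background_annotation_rate = background_annotation_rate,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# sub-seed per generation component, kept well below 2^31
.sub_seed <- function(seed, offset) (seed %% 1000000L) * 1000L + offset

#' Generate a synthetic genotype panel with known truth
#'
#' Background SNP i draws an ancestral frequency p uniformly from
#' `ancestral_maf_range`; each population's frequency comes from a Beta
#' distribution with mean p and variance `p (1 - p) fst`
#' (Balding-Nichols), and each diploid genotype is the sum of two
#' independent allele draws. Block SNPs use the block's elevated
#' frequency in target populations and its low baseline elsewhere. The
#' catalog annotates block SNPs with their disease term (and gene), and
#' background SNPs with random decoy leaf terms of the supplied ontology.
#'
#' @param spec a [synthetic_spec].
#' @param ontology an [ontology_graph] supplying decoy leaf terms;
#'   default [make_ontology_fixture].
#' @return list with `panel` ([genotype_panel]), `catalog`
#'   ([association_catalog]), `truth` (list: `snps` data.frame with
#'   per-population frequencies, block membership and term; `samples`
#'   data.frame), and `ontology`.
#' @export
generate_panel <- function(spec, ontology = make_ontology_fixture()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n_block <- sum(vapply(spec$blocks, `[[`, 0L, "size"))
  n_snps <- spec$n_background_snps + n_block
  if (n_block > 0 && n_snps < n_block)
    stop("blocks larger than the requested SNP count")
  n_pops <- spec$n_pops
  m <- n_pops * spec$samples_per_pop
  pop_of_sample <- rep(spec$pops, each = spec$samples_per_pop)

  # population allele frequency matrix, SNPs x pops
  set.seed(.sub_seed(spec$seed, 1L))
  p_anc <- stats::runif(spec$n_background_snps,
                        spec$ancestral_maf_range[1],
                        spec$ancestral_maf_range[2])
  ratio <- (1 - spec$fst) / spec$fst
  freq <- matrix(stats::rbeta(spec$n_background_snps * n_pops,
                              shape1 = rep(p_anc, n_pops) * ratio,
                              shape2 = rep(1 - p_anc, n_pops) * ratio),
                 nrow = spec$n_background_snps, ncol = n_pops)
  freq <- pmin(pmax(freq, 1e-6), 1 - 1e-6)
  block_id <- rep(NA_integer_, n_snps)
  block_term <- rep(NA_character_, n_snps)
  if (length(spec$blocks)) {
    bfreq <- do.call(rbind, lapply(spec$blocks, function(b) {
      row <- ifelse(spec$pops %in% b$pops, b$freq, b$baseline_freq)
      matrix(row, nrow = b$size, ncol = n_pops, byrow = TRUE)
    }))
    freq <- rbind(freq, bfreq)
    bid <- rep(seq_along(spec$blocks),
               vapply(spec$blocks, `[[`, 0L, "size"))
    block_id[(spec$n_background_snps + 1L):n_snps] <- bid
    block_term[(spec$n_background_snps + 1L):n_snps] <-
      vapply(spec$blocks, `[[`, "", "term")[bid]
    p_anc <- c(p_anc, rowMeans(bfreq))
  }

  # genotypes: binomial(2, pop frequency)
  set.seed(.sub_seed(spec$seed, 2L))
  dosage <- matrix(0L, n_snps, m)
  for (k in seq_len(n_pops)) {
    jj <- which(pop_of_sample == spec$pops[k])
    dosage[, jj] <- stats::rbinom(n_snps * length(jj), 2L,
                                  rep(freq[, k], length(jj)))
  }

  set.seed(.sub_seed(spec$seed, 3L))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_snps, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  snps <- data.frame(
    snp_id = sprintf("snp%05d", seq_len(n_snps)),
    chrom = "1", pos = seq_len(n_snps) * 1000L,
    ref = ref, alt = unname(alt), stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = sprintf("ind%04d", seq_len(m)),
    population = pop_of_sample,
    region = sprintf("region%02d",
                     ((match(pop_of_sample, spec$pops) - 1L) %/% 2L) + 1L),
    stringsAsFactors = FALSE)
  panel <- genotype_panel(snps, samples, dosage)

  # association catalog: planted terms for blocks, decoys for background
  set.seed(.sub_seed(spec$seed, 4L))
  leaves <- .fixture_leaves(ontology)
  recs <- list()
  bg_idx <- which(is.na(block_id))
  if (spec$background_annotation_rate > 0 && length(bg_idx)) {
    pick <- bg_idx[stats::runif(length(bg_idx)) <
                     spec$background_annotation_rate]
    if (length(pick))
      recs[[1L]] <- data.frame(
        snp_id = snps$snp_id[pick],
        disease_term_id = sample(leaves, length(pick), replace = TRUE),
        gene = NA_character_, source = "synthetic_background",
        stringsAsFactors = FALSE)
  }
  if (length(spec$blocks)) {
    bi <- which(!is.na(block_id))
    genes <- unlist(lapply(spec$blocks, function(b)
      rep_len(b$genes, b$size)))
    recs[[length(recs) + 1L]] <- data.frame(
      snp_id = snps$snp_id[bi],
      disease_term_id = block_term[bi],
      gene = genes, source = "synthetic_block",
      stringsAsFactors = FALSE)
  }
  catalog <- association_catalog(
    if (length(recs)) do.call(rbind, recs) else
      data.frame(snp_id = character(0),
                 disease_term_id = character(0)))

  truth_snps <- data.frame(snps, ancestral_freq = p_anc,
                           block = block_id, term = block_term,
                           stringsAsFactors = FALSE)
  truth_snps <- cbind(truth_snps,
                      stats::setNames(as.data.frame(freq),
                                      paste0("freq_", spec$pops)))
  list(panel = panel, catalog = catalog,
       truth = list(snps = truth_snps, samples = samples),
       ontology = ontology)
}

#' Deterministic tree-ontology fixture
#'
#' A rooted tree with `branching` children per node down to
#' `depth - 1` levels below the root (root = level 0); term ids are
#' `SYN:<level>.<index>`. With the defaults (depth 5, branching 2) there
#' are 2^3 = 8 level-3 terms and 16 leaves at level 4, so level-3
#' mapping is always exercised. `diamond = TRUE` adds a second parent to
#' the first leaf, giving it two distinct level-3 ancestors.
#'
#' @param depth number of levels including the root (>= 4... the default
#'   5 puts leaves at level 4).
#' @param branching children per internal node.
#' @param diamond add a multi-parent edge for multi-ancestor tests.
#' @return An [ontology_graph] with depths computed.
#' @export
make_ontology_fixture <- function(depth = 5L, branching = 2L,
                                  diamond = FALSE) {
  stopifnot(depth >= 4L, branching >= 1L)
  ids <- "SYN:0.1"; names_ <- "synthetic disease root"
  parents <- list("SYN:0.1" = character(0))
  prev <- "SYN:0.1"
  for (lvl in seq_len(depth - 1L)) {
    cur <- sprintf("SYN:%d.%d", lvl,
                   seq_len(length(prev) * branching))
    par_of <- rep(prev, each = branching)
    for (i in seq_along(cur)) parents[[cur[i]]] <- par_of[i]
    ids <- c(ids, cur)
    names_ <- c(names_, sprintf("synthetic term level %d #%d", lvl,
                                seq_along(cur)))
    prev <- cur
  }
  if (diamond && depth >= 5L) {
    # first leaf gets a second parent one level up, so it has two
    # distinct ancestors at that level
    leaf <- sprintf("SYN:%d.1", depth - 1L)
    lvl_prefix <- sprintf("SYN:%d.", depth - 2L)
    cands <- setdiff(ids[startsWith(ids, lvl_prefix)], parents[[leaf]])
    if (length(cands))
      parents[[leaf]] <- c(parents[[leaf]], cands[1])
  }
  compute_depths(ontology_graph(
    data.frame(id = ids, name = names_, stringsAsFactors = FALSE),
    parents))
}

# leaf terms (no children) of an ontology fixture, in natural index order
.fixture_leaves <- function(graph) {
  all_parents <- unique(unlist(graph$parents, use.names = FALSE))
  leaves <- setdiff(graph$terms$id, all_parents)
  suffix <- suppressWarnings(as.numeric(sub("^.*\\.", "", leaves)))
  if (anyNA(suffix)) sort(leaves) else leaves[order(suffix)]
}

#' Write an ontology as a minimal OBO file
#'
#' @param graph an [ontology_graph]; @param path output file.
#' @return `path`, invisibly.
#' @export
write_obo <- function(graph, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (i in seq_len(nrow(graph$terms))) {
    id <- graph$terms$id[i]
    ps <- graph$parents[[id]]
    is_a <- if (length(ps)) paste0("is_a: ", ps) else character(0)
    writeLines(c("[Term]", paste0("id: ", id),
                 paste0("name: ", graph$terms$name[i]),
                 is_a, ""), con)
  }
  invisible(path)
}

#' Write a synthetic panel to disk
#'
#' Emits `genotypes.vcf`, `samples.tsv`, `associations.tsv`,
#' `ontology.obo` and the truth tables (`truth_snps.tsv`,
#' `truth_samples.tsv`) into a directory; the VCF round-trips through
#' [read_genotypes].
#'
#' @param sim output of [generate_panel].
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_vcf(sim$panel, file.path(dir, "genotypes.vcf"))
  utils::write.table(sim$panel$samples, file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$catalog$records,
                     file.path(dir, "associations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_obo(sim$ontology, file.path(dir, "ontology.obo"))
  utils::write.table(sim$truth$snps, file.path(dir, "truth_snps.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$samples,
                     file.path(dir, "truth_samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Write a genotype panel as VCF 4.2
#'
#' GT-only, unphased; missing calls become `./.`.
#'
#' @param panel a [genotype_panel]; @param path output `.vcf`.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(panel, path) {
  stopifnot(inherits(panel, "genotype_panel"))
  gt_str <- matrix(c("0/0", "0/1", "1/1")[panel$dosage + 1L],
                   nrow = nrow(panel$dosage))
  gt_str[is.na(panel$dosage)] <- "./."
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=sompop-synthetic",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", panel$samples$sample_id),
          collapse = "\t"))
  body <- paste(panel$snps$chrom, panel$snps$pos, panel$snps$snp_id,
                panel$snps$ref, panel$snps$alt, ".", ".", ".", "GT",
                apply(gt_str, 1L, paste, collapse = "\t"),
                sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Add an LD companion to a SNP
#'
#' Duplicates one SNP's genotypes with a per-sample flip probability,
#' emulating a locus in tight linkage disequilibrium (eps = 0: perfect
#' LD, correlated profile; `anti = TRUE` copies `2 - dosage`, the
#' anti-correlated orientation).
#'
#' @param panel a [genotype_panel].
#' @param snp_id SNP to copy.
#' @param eps per-sample flip probability.
#' @param anti copy in the anti-correlated orientation.
#' @param new_id identifier of the companion SNP.
#' @param seed RNG seed for the flips.
#' @return The [genotype_panel] with one extra SNP appended.
#' @export
add_ld_companion <- function(panel, snp_id, eps = 0.05, anti = FALSE,
                             new_id = paste0(snp_id, "_ld"),
                             seed = 1L) {
  stopifnot(inherits(panel, "genotype_panel"))
  i <- match(snp_id, panel$snps$snp_id)
  if (is.na(i)) stop("unknown SNP: ", snp_id)
  d <- panel$dosage[i, ]
  if (anti) d <- 2L - d
  set.seed(seed)
  flip <- stats::runif(length(d)) < eps
  d[flip] <- sample(0:2, sum(flip), replace = TRUE)
  snps <- rbind(panel$snps,
                data.frame(snp_id = new_id,
                           chrom = panel$snps$chrom[i],
                           pos = panel$snps$pos[i] + 1L,
                           ref = panel$snps$ref[i],
                           alt = panel$snps$alt[i],
                           stringsAsFactors = FALSE))
  genotype_panel(snps, panel$samples, rbind(panel$dosage, d))
}
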