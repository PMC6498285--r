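# Shared fixture builders and independent oracles.

# genotype_panel from a dosage matrix; populations assigned round-robin
# unless given explicitly
tiny_panel <- function(dosage, pops = NULL) {
  dosage <- as.matrix(dosage)
  n <- nrow(dosage); m <- ncol(dosage)
  if (is.null(pops)) pops <- rep(c("P1", "P2"), length.out = m)
  snps <- data.frame(snp_id = sprintf("rs%03d", seq_len(n)),
                     chrom = "1", pos = seq_len(n) * 10L,
                     ref = "A", alt = "G", stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = sprintf("S%02d", seq_len(m)),
                        population = pops,
                        region = "R1", stringsAsFactors = FALSE)
  genotype_panel(snps, samples, dosage)
}

# write a VCF with given body lines and matching metadata; returns paths
tiny_vcf <- function(body, sample_ids,
                     dir = withr::local_tempdir(
                       .local_envir = parent.frame())) {
  vcf <- file.path(dir, "g.vcf")
  meta <- file.path(dir, "meta.tsv")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", sample_ids), collapse = "\t"),
    body), vcf)
  writeLines(c("sample_id\tpopulation\tregion",
               paste(sample_ids, "P1", "R1", sep = "\t")), meta)
  list(vcf = vcf, meta = meta)
}

# hand-built som_model with a prescribed assignment (for portrait and
# segmentation tests that need full control over unit membership)
fake_model <- function(rows, cols, assignment, snp_ids = NULL,
                       sample_ids = NULL, n_samples = 4L) {
  k <- rows * cols
  if (is.null(snp_ids))
    snp_ids <- sprintf("rs%03d", seq_along(assignment))
  members <- split(seq_along(assignment),
                   factor(assignment, levels = seq_len(k)))
  structure(list(
    config = som_config(rows, cols, epochs = 1L),
    prototypes = matrix(0, k, n_samples),
    assignment = as.integer(assignment),
    coords = cbind(row = rep(seq_len(rows), each = cols),
                   col = rep(seq_len(cols), times = rows)),
    unit_members = unname(members),
    qe = 0, qe_final = 0,
    snp_ids = snp_ids, sample_ids = sample_ids, snp_means = NULL),
    class = "som_model")
}

# independent one-sided Fisher oracle: exhaustive hypergeometric
# upper-tail sum from log binomial coefficients
oracle_fisher_greater <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  js <- max(0, k - n):min(k, m)
  js <- js[js >= a]
  if (!length(js)) return(0)
  sum(exp(lchoose(m, js) + lchoose(n, k - js) - lchoose(m + n, k)))
}

# brute-force MST total weight by enumerating all labeled spanning trees
# via Pruefer sequences (n^(n-2) trees)
oracle_mst_weight <- function(w) {
  n <- nrow(w)
  if (n == 2) return(w[1, 2])
  prufer_to_edges <- function(seq) {
    degree <- rep(1L, n)
    for (s in seq) degree[s] <- degree[s] + 1L
    edges <- matrix(0L, n - 1, 2)
    ptr <- 1L
    seq2 <- seq
    for (i in seq_along(seq2)) {
      leaf <- which(degree == 1L)[1]
      edges[ptr, ] <- c(leaf, seq2[i]); ptr <- ptr + 1L
      degree[leaf] <- 0L
      degree[seq2[i]] <- degree[seq2[i]] - 1L
    }
    last <- which(degree == 1L)
    edges[ptr, ] <- last
    edges
  }
  combos <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2)))
  best <- Inf
  for (i in seq_len(nrow(combos))) {
    ed <- prufer_to_edges(combos[i, ])
    tw <- sum(w[ed])
    if (tw < best) best <- tw
  }
  best
}

# Chebyshev-free grid distance between two unit indices of a model
grid_distance <- function(model, u, v) {
  sqrt(sum((model$coords[u, ] - model$coords[v, ])^2))
}

# random allele matrix fixture
random_allele_matrix <- function(n, m, seed) {
  set.seed(seed)
  d <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
  code_alleles(tiny_panel(d))
}
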