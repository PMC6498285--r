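test_that("VCF reading keeps biallelic SNPs and joins metadata", {
  f <- tiny_vcf(c("1\t100\trs1\tA\tG\t.\t.\t.\tGT\t0/1\t1/1",
                  "1\t200\trs2\tC\tT,G\t.\t.\t.\tGT\t0/1\t0/0",
                  "1\t300\trs3\tC\tT\t.\t.\t.\tGT\t0|0\t./."),
                c("S1", "S2"))
  expect_message(panel <- read_genotypes(f$vcf, f$meta),
                 "1 multi-allelic")
  expect_equal(panel$snps$snp_id, c("rs1", "rs3"))
  expect_equal(unname(panel$dosage["rs1", ]), c(1L, 2L))
  expect_true(is.na(panel$dosage["rs3", "S2"]))
  expect_equal(panel$samples$population, c("P1", "P1"))
})

test_that("empty VCF body gives an empty panel without error", {
  f <- tiny_vcf(character(0), c("S1", "S2"))
  panel <- read_genotypes(f$vcf, f$meta)
  expect_equal(nrow(panel$snps), 0L)
})

test_that("a sample absent from the metadata is a named hard error", {
  f <- tiny_vcf("1\t100\trs1\tA\tG\t.\t.\t.\tGT\t0/1\t1/1",
                c("S1", "SX"))
  meta2 <- file.path(dirname(f$meta), "meta2.tsv")
  writeLines(c("sample_id\tpopulation\tregion", "S1\tP1\tR1"), meta2)
  expect_error(read_genotypes(f$vcf, meta2), "SX")
})

test_that("plain-text matrix dialect reads scores and missing calls", {
  dir <- withr::local_tempdir()
  gp <- file.path(dir, "m.tsv")
  writeLines(c("snp_id\tS1\tS2\tS3",
               "rsA\t0\t1\t2",
               "rsB\t.\t0\t0"), gp)
  meta <- file.path(dir, "meta.tsv")
  writeLines(c("sample_id\tpopulation\tregion",
               paste0("S", 1:3, "\tP1\tR1")), meta)
  panel <- read_genotypes(gp, meta)
  expect_equal(unname(panel$dosage["rsA", ]), c(0L, 1L, 2L))
  expect_true(is.na(panel$dosage["rsB", "S1"]))
})

test_that("drop_missing removes SNPs above the missing-rate threshold", {
  d <- rbind(c(0, 1, 2, 1, 0), c(NA, 1, 2, 0, 1),
             c(NA, NA, 0, 1, 2))
  panel <- tiny_panel(d)
  expect_equal(nrow(drop_missing(panel, 0)$snps), 1L)
  expect_equal(nrow(drop_missing(panel, 1)$snps), 3L)
  # 20% and 40% missing both tolerated at rate 0.5
  expect_equal(drop_missing(panel, 0.5)$snps$snp_id,
               c("rs001", "rs002", "rs003"))
  expect_equal(drop_missing(panel, 0.3)$snps$snp_id,
               c("rs001", "rs002"))
})

test_that("allele coding matches the 0/1/2 scheme with global minor allele", {
  # alt frequency 0.3: alt is minor; hom minor -> 2, het -> 1
  panel <- tiny_panel(rbind(c(2, 1, 0, 0, 0)))
  am <- code_alleles(panel)
  expect_equal(unname(am$scores[1, ]), c(2L, 1L, 0L, 0L, 0L))
  expect_equal(am$snp_meta$minor_allele, "G")
  # alt frequency 0.8: ref is minor; alt/alt genotype codes to 0
  panel2 <- tiny_panel(rbind(c(2, 2, 2, 1, 1)))
  am2 <- code_alleles(panel2)
  expect_equal(unname(am2$scores[1, ]), c(0L, 0L, 0L, 1L, 1L))
  expect_equal(am2$snp_meta$minor_allele, "A")
  expect_equal(am2$maf, 0.2)
  # frequency tie at 0.5: alternate allele designated minor
  am3 <- code_alleles(tiny_panel(rbind(c(2, 2, 1, 1, 0, 0))))
  expect_equal(am3$snp_meta$minor_allele, "G")
  expect_equal(am3$maf, 0.5)
})

test_that("coding requires a complete-case panel", {
  panel <- tiny_panel(rbind(c(0, NA, 1)))
  expect_error(code_alleles(panel), "drop_missing")
})

test_that("maf identity and score bounds hold on random fixtures", {
  for (seed in 1:25) {
    am <- random_allele_matrix(30, 11, seed)
    expect_true(all(am$scores %in% 0:2))
    expect_equal(am$maf,
                 unname(rowSums(am$scores)) / (2 * ncol(am$scores)))
    # minor-allele copy count is integral
    expect_equal(am$maf * 2 * ncol(am$scores),
                 round(am$maf * 2 * ncol(am$scores)))
    expect_true(all(am$maf <= 0.5))
  }
})

test_that("MAF filter is strict and monotone", {
  # mafs 0.05 and 0.051 constructed exactly: copies / (2 * 500)
  scores <- rbind(c(rep(1L, 50), rep(0L, 450)),     # maf 0.05
                  c(rep(1L, 51), rep(0L, 449)),     # maf 0.051
                  rep(1L, 500))                     # maf 0.5
  am <- code_alleles(tiny_panel(scores))
  expect_equal(am$maf, c(0.05, 0.051, 0.5))
  kept <- filter_by_maf(am, 0.05)
  expect_equal(kept$snp_meta$snp_id, c("rs002", "rs003"))
  # 10 SNPs with mafs 0.01..0.10: strict > 0.05 keeps 5
  sc <- t(sapply(1:10, function(k) c(rep(2L, k), rep(0L, 100 - k))))
  am10 <- code_alleles(tiny_panel(sc))
  expect_equal(am10$maf, (1:10) / 100)
  expect_equal(nrow(filter_by_maf(am10, 0.05)$scores), 5L)
  # monotone: higher threshold keeps a subset
  am_r <- random_allele_matrix(60, 20, 99)
  prev <- am_r$snp_meta$snp_id
  for (t in c(0.1, 0.2, 0.3, 0.4)) {
    cur <- filter_by_maf(am_r, t)$snp_meta$snp_id
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("restrict_to_catalog preserves order and errors on disjoint ids", {
  am <- random_allele_matrix(5, 6, 3)
  cat3 <- association_catalog(data.frame(
    snp_id = c("rs004", "rs001", "rs003"),
    disease_term_id = "D1", stringsAsFactors = FALSE))
  sub <- restrict_to_catalog(am, cat3)
  expect_equal(sub$snp_meta$snp_id, c("rs001", "rs003", "rs004"))
  # superset catalog leaves the matrix unchanged
  catS <- association_catalog(data.frame(
    snp_id = sprintf("rs%03d", 1:9), disease_term_id = "D1"))
  expect_equal(restrict_to_catalog(am, catS)$scores, am$scores)
  catX <- association_catalog(data.frame(
    snp_id = "chr1:55", disease_term_id = "D1"))
  expect_error(restrict_to_catalog(am, catX), "identifier")
})

test_that("allele matrix round-trips through the plain-text dialect", {
  am <- random_allele_matrix(25, 9, 11)
  dir <- withr::local_tempdir()
  gp <- file.path(dir, "scores.tsv")
  write_allele_matrix(am, gp)
  meta <- file.path(dir, "meta.tsv")
  utils::write.table(am$sample_meta, meta, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  am2 <- code_alleles(read_genotypes(gp, meta))
  expect_equal(unname(am2$scores), unname(am$scores))
  expect_equal(am2$maf, am$maf)
  expect_equal(am2$snp_meta$snp_id, am$snp_meta$snp_id)
})
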