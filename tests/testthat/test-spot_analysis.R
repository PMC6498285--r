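# builds a spot_set from a hand-drawn summary grid and an assignment
segment_on <- function(grid, assignment, ...) {
  rows <- nrow(grid); cols <- ncol(grid)
  model <- fake_model(rows, cols, assignment)
  sm <- summary_map(list(portrait(grid, "g", kind = "mean")))
  segment_spots(sm, model, ...)
}

test_that("summary map is the pointwise maximum over group portraits", {
  p1 <- portrait(matrix(c(0, 2), 1), "g1", kind = "mean")
  p2 <- portrait(matrix(c(2, 0), 1), "g2", kind = "mean")
  sm <- summary_map(list(p1, p2))
  expect_equal(sm$grid, matrix(c(2, 2), 1))
  expect_equal(summary_map(list(p1))$grid, p1$grid)
  # dominance over each contributor
  set.seed(1)
  ps <- lapply(1:4, function(i)
    portrait(matrix(runif(12, 0, 2), 3), paste0("g", i), kind = "mean"))
  smr <- summary_map(ps)
  for (p in ps) expect_true(all(smr$grid >= p$grid))
})

test_that("segmentation extracts 8-connected high plateaus", {
  g <- matrix(0.2, 6, 6)
  g[1:2, 1:3] <- 1.8                      # plateau of 6 units
  g[5:6, 4:6] <- c(1.5, 1.5, 1.5, 1.5, 1.5, 1.9)  # second plateau
  # SNPs 1..6 in plateau-1 units, 7..9 elsewhere
  asg <- c(1L, 2L, 3L, 7L, 8L, 9L, 28L, 29L, 36L)
  ss <- segment_on(g, asg, threshold_quantile = 0.5, min_units = 5)
  expect_length(ss$spots, 2L)
  # labels ordered by decreasing peak: second plateau peaks at 1.9
  expect_equal(ss$spots[[1]]$label, "A")
  expect_equal(ss$spots[[1]]$peak, 1.9)
  expect_equal(ss$spots[[2]]$peak, 1.8)
  expect_setequal(ss$spots[[2]]$snp_ids, sprintf("rs%03d", 1:6))
  # unit sets are disjoint and SNPs belong to exactly one spot
  expect_length(intersect(ss$spots[[1]]$unit_idx,
                          ss$spots[[2]]$unit_idx), 0)
  mem <- spot_membership(ss)
  expect_equal(anyDuplicated(mem$snp_id), 0L)
})

test_that("small components and uniform maps yield no spots", {
  g <- matrix(0.2, 6, 6)
  g[1, 1:3] <- 1.8
  ss <- segment_on(g, c(1L, 2L, 3L), threshold_quantile = 0.5,
                   min_units = 5)
  expect_length(ss$spots, 0L)
  # uniform map: nothing exceeds its own quantile strictly
  expect_warning(
    ss2 <- segment_on(matrix(1, 4, 4), 1L, threshold_quantile = 0.9,
                      min_units = 1),
    "no unit")
  expect_length(ss2$spots, 0L)
})

test_that("spot profiles average member SNPs per sample and group", {
  scores <- rbind(c(0L, 2L), c(2L, 0L), c(1L, 1L))
  am <- code_alleles(tiny_panel(scores, pops = c("G1", "G2")))
  spot <- list(label = "A", snp_ids = c("rs001", "rs002"),
               units = cbind(1, 1), peak = 2)
  pr <- spot_profile(spot, am, "population")
  expect_equal(unname(pr$sample_profile), c(1, 1))
  # single member SNP: profile equals that SNP's row
  spot1 <- list(label = "B", snp_ids = "rs003")
  pr1 <- spot_profile(spot1, am, "population")
  expect_equal(unname(pr1$sample_profile), c(1, 1))
  expect_equal(unname(pr1$group_profile[c("G1", "G2")]), c(1, 1))
})

test_that("Fisher p-values match the exhaustive hypergeometric oracle", {
  tables <- rbind(c(8, 12, 20, 160), c(0, 10, 5, 85), c(5, 0, 0, 5),
                  c(3, 7, 2, 8), c(1, 1, 1, 1), c(10, 0, 40, 150))
  for (i in seq_len(nrow(tables))) {
    a <- tables[i, 1]; b <- tables[i, 2]
    c_ <- tables[i, 3]; d <- tables[i, 4]
    expect_equal(sompop:::.fisher_greater(a, b, c_, d),
                 oracle_fisher_greater(a, b, c_, d),
                 tolerance = 1e-12)
  }
  # agreement with stats::fisher.test one-sided greater
  ft <- stats::fisher.test(matrix(c(8, 12, 20, 160), 2, byrow = TRUE),
                           alternative = "greater")
  expect_equal(sompop:::.fisher_greater(8, 12, 20, 160), ft$p.value,
               tolerance = 1e-9)
})

test_that("moving an annotated SNP into the spot never raises p", {
  set.seed(8)
  for (i in 1:50) {
    a <- sample(0:10, 1); b <- sample(1:10, 1)
    c_ <- sample(1:10, 1); d <- sample(0:20, 1)
    p0 <- sompop:::.fisher_greater(a, b, c_, d)
    p1 <- sompop:::.fisher_greater(a + 1, b - 1, c_ - 1, d + 1)
    expect_lte(p1, p0 + 1e-12)
  }
})

test_that("enrichment builds correct tables over the universe", {
  g <- matrix(0.2, 4, 4); g[1, 1:2] <- c(1.8, 1.9)
  # 20 SNPs: 1..6 in spot units (1, 2); rest in unit 11
  asg <- c(rep(1L, 3), rep(2L, 3), rep(11L, 14))
  ss <- segment_on(g, asg, threshold_quantile = 0.5, min_units = 2)
  expect_length(ss$spots, 1L)
  ann <- data.frame(
    snp_id = c(sprintf("rs%03d", 1:5), "rs010", "rs011"),
    term = c(rep("T1", 5), "T1", "T2"))
  res <- enrich_terms(ss, ann, sprintf("rs%03d", 1:20))
  t1 <- res[res$term == "T1", ]
  expect_equal(t1$n_spot_annotated, 5L)
  expect_equal(t1$n_spot_other, 1L)
  expect_equal(t1$n_out_annotated, 1L)
  expect_equal(t1$n_out_other, 13L)
  expect_equal(t1$p_value, oracle_fisher_greater(5, 1, 1, 13),
               tolerance = 1e-12)
  # counts sum to the universe size
  expect_equal(t1$n_spot_annotated + t1$n_spot_other +
                 t1$n_out_annotated + t1$n_out_other, 20L)
  # spot with zero annotated SNPs for a term: one-sided p is 1
  t2 <- res[res$term == "T2", ]
  expect_equal(t2$p_value, 1)
  # duplicate annotations (multi-source) count once
  res_dup <- enrich_terms(ss, rbind(ann, ann[1, ]),
                          sprintf("rs%03d", 1:20))
  expect_equal(res_dup$p_value, res$p_value)
  # BH column present and >= raw p
  expect_true(all(res$p_adjust >= res$p_value - 1e-15))
})

test_that("a concentrated term attains the minimal p in its spot", {
  # spot holding every annotated SNP of T1: no same-margin arrangement
  # can have smaller p
  g <- matrix(0.2, 4, 4); g[1, 1:2] <- 1.9
  asg <- c(rep(1L, 4), rep(12L, 8))
  ss <- segment_on(g, asg, threshold_quantile = 0.5, min_units = 2)
  ann <- data.frame(snp_id = sprintf("rs%03d", 1:4), term = "T1")
  res <- enrich_terms(ss, ann, sprintf("rs%03d", 1:12))
  p_obs <- res$p_value[res$term == "T1"]
  for (a in 0:4) {
    p_a <- oracle_fisher_greater(a, 4 - a, 4 - a, 4 + a)
    expect_lte(p_obs, p_a + 1e-12)
  }
})

test_that("background distribution counts unique universe SNPs per term", {
  ann <- data.frame(snp_id = c("s1", "s1", "s2", "s3"),
                    term = c("T1", "T2", "T1", "T1"))
  bg <- background_distribution(ann, c("s1", "s2"))
  expect_equal(bg[["T1"]], 2L)
  expect_equal(bg[["T2"]], 1L)
  expect_equal(unname(background_distribution(ann, character(0))),
               integer(0))
  # invariant to duplicated rows
  expect_equal(background_distribution(rbind(ann, ann), c("s1", "s2")),
               bg)
})
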