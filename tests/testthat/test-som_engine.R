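test_that("centralize subtracts per-SNP means and keeps them", {
  cz <- centralize(rbind(c(0, 1, 2), c(1, 1, 1), c(0, 0, 2, 2)[1:3]))
  expect_equal(cz$centered[1, ], c(-1, 0, 1))
  expect_equal(cz$centered[2, ], c(0, 0, 0))
  cz2 <- centralize(rbind(c(0, 0, 2, 2)))
  expect_equal(cz2$centered[1, ], c(-1, -1, 1, 1))
  expect_equal(cz2$means, 1.0)
  # row means are zero within tolerance
  cz3 <- centralize(matrix(runif(60), 10))
  expect_true(all(abs(rowMeans(cz3$centered)) < 1e-9))
})

test_that("the grid yields rows * cols prototypes and full assignment", {
  set.seed(1)
  x <- matrix(rnorm(40 * 6), 40)
  model <- train_som(x, som_config(5, 7, epochs = 10))
  expect_equal(dim(model$prototypes), c(35L, 6L))
  expect_equal(length(model$assignment), 40L)
  expect_true(all(model$assignment %in% 1:35))
  expect_equal(sum(lengths(model$unit_members)), 40L)
})

test_that("identical profiles always share a best-matching unit", {
  set.seed(2)
  base <- matrix(rnorm(20 * 8), 20)
  x <- rbind(base, base[3, ], base[17, ])
  model <- train_som(x, som_config(4, 4, epochs = 15))
  expect_equal(model$assignment[21], model$assignment[3])
  expect_equal(model$assignment[22], model$assignment[17])
})

test_that("well-separated clusters occupy distinct units on a 2x2 grid", {
  set.seed(3)
  # square cluster geometry so the 2x2 grid can align to the plane
  centers <- rbind(c(10, 10, 0), c(10, -10, 0), c(-10, 10, 0),
                   c(-10, -10, 0))
  x <- centers[rep(1:4, each = 6), ] + matrix(rnorm(72, sd = 0.05), 24)
  model <- train_som(x, som_config(2, 2, epochs = 40,
                                   radius_start = 1,
                                   radius_end = 0.05))
  cl <- rep(1:4, each = 6)
  bmu_per_cluster <- tapply(model$assignment, cl,
                            function(u) length(unique(u)))
  expect_true(all(bmu_per_cluster == 1))
  expect_equal(length(unique(tapply(model$assignment, cl, unique))),
               4L)
})

test_that("at vanishing radius prototypes converge to member centroids", {
  set.seed(4)
  x <- matrix(rnorm(30 * 5), 30)
  model <- train_som(x, som_config(3, 3, epochs = 60,
                                   radius_start = 2,
                                   radius_end = 0.02))
  for (u in seq_along(model$unit_members)) {
    mem <- model$unit_members[[u]]
    if (!length(mem)) next
    centroid <- colMeans(x[mem, , drop = FALSE])
    expect_lt(max(abs(model$prototypes[u, ] - centroid)), 0.02)
  }
})

test_that("training is deterministic given config and seed", {
  set.seed(5)
  x <- matrix(rnorm(50 * 7), 50)
  m1 <- train_som(x, som_config(4, 5, epochs = 12))
  m2 <- train_som(x, som_config(4, 5, epochs = 12))
  expect_identical(m1$assignment, m2$assignment)
  expect_identical(m1$prototypes, m2$prototypes)
  r1 <- train_som(x, som_config(4, 5, epochs = 12, init = "random",
                                seed = 42))
  r2 <- train_som(x, som_config(4, 5, epochs = 12, init = "random",
                                seed = 42))
  expect_identical(r1$assignment, r2$assignment)
})

test_that("quantization error is non-increasing over the last epochs", {
  set.seed(6)
  x <- matrix(rnorm(80 * 6), 80)
  model <- train_som(x, som_config(5, 5, epochs = 30))
  tail_qe <- utils::tail(model$qe, 10)
  expect_true(all(diff(tail_qe) <= 1e-6))
})

test_that("assign_bmu matches exhaustive distance search and tie rule", {
  set.seed(7)
  x <- matrix(rnorm(25 * 6), 25)
  model <- train_som(x, som_config(3, 4, epochs = 10))
  for (i in c(1, 5, 12)) {
    d <- apply(model$prototypes, 1,
               function(p) sum((p - x[i, ])^2))
    expect_equal(assign_bmu(x[i, ], model), which.min(d))
  }
  # exact prototype returns its own index
  expect_equal(assign_bmu(model$prototypes[7, ], model), 7L)
  # equidistant prototypes: lowest unit index wins
  model$prototypes[3, ] <- model$prototypes[9, ]
  expect_equal(assign_bmu(model$prototypes[9, ], model), 3L)
  expect_error(assign_bmu(c(1, 2), model), "length")
})

test_that("training rejects invalid input", {
  expect_error(train_som(matrix(1, 1, 1), som_config(2, 2, epochs = 2)),
               "two individuals")
  expect_error(train_som(matrix(c(1, NA, 0, 1), 2),
                         som_config(2, 2, epochs = 2)), "finite")
  expect_error(som_config(1, 5), "2 x 2")
  expect_error(som_config(3, 3, epochs = 0), "epochs")
  expect_error(som_config(3, 3, radius_start = 0.5, radius_end = 1),
               "radius")
})

test_that("correlated profiles land closer than anti-correlated ones", {
  # the linkage-disequilibrium co-location property: over seeded
  # two-cluster panels, the grid distance between the BMUs of two
  # positively correlated SNPs is below that of an anti-correlated pair
  hits <- 0L
  n_rep <- 10L
  for (seed in seq_len(n_rep)) {
    set.seed(100 + seed)
    m <- 40
    half <- c(rep(0.9, 20), rep(0.1, 20))
    freq <- rbind(matrix(half, 12, m, byrow = TRUE),
                  matrix(1 - half, 12, m, byrow = TRUE))
    x <- matrix(rbinom(length(freq), 2, freq), nrow(freq))
    cz <- centralize(x)
    model <- train_som(cz$centered, som_config(6, 6, epochs = 30))
    d_corr <- grid_distance(model, model$assignment[1],
                            model$assignment[2])
    d_anti <- grid_distance(model, model$assignment[1],
                            model$assignment[13])
    if (d_anti > d_corr) hits <- hits + 1L
  }
  expect_gte(hits, n_rep - 1L)
})

test_that("SOM model export round-trips", {
  am <- random_allele_matrix(30, 8, 21)
  model <- som_fit(am, som_config(3, 4, epochs = 8))
  dir <- file.path(withr::local_tempdir(), "som")
  write_som(model, dir)
  model2 <- read_som(dir)
  expect_equal(model2$assignment, model$assignment)
  expect_equal(model2$prototypes, model$prototypes, tolerance = 1e-12)
  expect_equal(model2$snp_means, model$snp_means)
  expect_equal(model2$config$rows, model$config$rows)
})
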