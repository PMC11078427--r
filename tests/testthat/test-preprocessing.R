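test_that("read_pgs_table partitions groups and applies complete-case filtering", {
  path <- withr::local_tempfile(fileext = ".tsv")
  tab <- toy_table()
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)

  df <- read_pgs_table(path, outcome_col = "y", group_col = "pop",
                       pgs_cols = c("pgs1", "pgs2"))
  samples <- as_pop_samples(df, "y", "pop", c("pgs1", "pgs2"))
  expect_length(samples, 2L)
  expect_equal(vapply(samples, `[[`, integer(1), "n"), c(3L, 3L))
  expect_equal(vapply(samples, `[[`, character(1), "label"), c("A", "B"))

  # one missing outcome -> that row dropped, group sizes 2 and 3
  tab$y[2] <- NA
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  df2 <- suppressMessages(
    read_pgs_table(path, "y", "pop", c("pgs1", "pgs2")))
  expect_equal(attr(df2, "n_dropped"), 1L)
  samples2 <- as_pop_samples(df2, "y", "pop", c("pgs1", "pgs2"))
  expect_equal(vapply(samples2, `[[`, integer(1), "n"), c(2L, 3L))

  # missing column is a configuration error
  expect_error(read_pgs_table(path, "y", "population", c("pgs1", "pgs2")),
               class = "corcompare_configuration_error")
  # csv auto-detection
  csv <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(toy_table(), csv, row.names = FALSE, quote = FALSE)
  expect_equal(nrow(read_pgs_table(csv, "y", "pop", c("pgs1", "pgs2"))), 6L)
})

test_that("read -> write -> read round-trips population samples", {
  samples <- draw_pair(n = 40, seed = 7)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_samples(samples, path)
  df <- read_pgs_table(path, "outcome", "population", samples[[1]]$pgs_names)
  back <- as_pop_samples(df, "outcome", "population", samples[[1]]$pgs_names)
  for (k in 1:2) {
    expect_equal(back[[k]]$y, samples[[k]]$y, tolerance = 1e-10)
    expect_equal(unname(back[[k]]$X), unname(samples[[k]]$X), tolerance = 1e-10)
    expect_identical(back[[k]]$label, samples[[k]]$label)
  }
})

test_that("standardize centers, scales and preserves correlations", {
  expect_equal(standardize(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(11)
  v <- rnorm(60); w <- rnorm(60)
  z <- standardize(v)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(cor(z, w), cor(v, w), tolerance = 1e-12)
  expect_error(standardize(rep(2, 10)), class = "corcompare_validation_error")
})

test_that("residualize matches the normal-equations solve and is idempotent", {
  set.seed(21)
  n <- 50
  C <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("PC", 1:3)))
  v <- rnorm(n)

  res <- residualize(v, C)
  # brute-force oracle: beta = (D'D)^{-1} D'v
  D <- cbind(1, C)
  beta <- solve(t(D) %*% D, t(D) %*% v)
  expect_equal(res, as.numeric(v - D %*% beta), tolerance = 1e-10)
  # orthogonal to intercept and every covariate
  expect_equal(mean(res), 0, tolerance = 1e-12)
  for (j in 1:3) expect_equal(sum(res * C[, j]), 0, tolerance = 1e-9)
  # idempotent
  expect_equal(residualize(res, C), res, tolerance = 1e-10)

  # empty covariates -> mean-centering; perfect fit -> zeros
  expect_equal(residualize(v, NULL), v - mean(v))
  lin <- 2 + C %*% c(1, -2, 0.5)
  expect_equal(max(abs(residualize(as.numeric(lin), C))), 0, tolerance = 1e-9)
  # collinear design is rejected with the offending column named
  expect_error(residualize(v, cbind(C, PC1b = C[, 1])),
               "PC1b", class = "corcompare_validation_error")
})

test_that("inverse-rank normalization follows the Blom formula with average ranks", {
  # oracle: direct evaluation of qnorm((rank - 3/8)/(n + 1 - 3/4)) at n = 3
  expect_equal(inverse_rank_normalize(c(10, 20, 30)),
               qnorm(c(0.625, 1.625, 2.625) / 3.25), tolerance = 1e-12)
  expect_equal(inverse_rank_normalize(c(10, 20, 30))[2], 0)

  set.seed(31)
  v <- rnorm(40)
  z <- inverse_rank_normalize(v)
  # monotone, symmetric about 0 for distinct values
  expect_true(all(diff(z[order(v)]) > 0))
  expect_equal(sort(z), sort(-z), tolerance = 1e-12)
  # ties map to equal outputs (average ranks)
  zt <- inverse_rank_normalize(c(1, 2, 2, 5))
  expect_equal(zt[2], zt[3])
  # correlations are invariant under increasing affine transforms of input
  w <- rnorm(40)
  expect_equal(cor(inverse_rank_normalize(3 * v + 7), w),
               cor(inverse_rank_normalize(v), w), tolerance = 1e-12)
})

test_that("pop_sample enforces its invariants", {
  expect_error(pop_sample("A", rnorm(5), matrix(rnorm(8), 4, 2)),
               class = "corcompare_validation_error")
  expect_error(pop_sample("A", c(1, NA, 3), matrix(rnorm(6), 3, 2)),
               class = "corcompare_validation_error")
  expect_error(pop_sample("A", rep(1, 5), matrix(rnorm(10), 5, 2)),
               class = "corcompare_validation_error")
  expect_error(pop_sample("A", rnorm(5), cbind(rnorm(5), 2),
                          pgs_names = c("a", "b")),
               class = "corcompare_validation_error")
  expect_error(as_pop_samples(data.frame(y = c(1, 2), pop = c("A", "B"),
                                         s = c(0.5, 1)),
                              "y", "pop", "s"),
               "fewer than 2", class = "corcompare_validation_error")
})
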