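test_that("built-in contrasts have the documented patterns", {
  # within, P = 2, K = 1: the two-dependent-correlations comparison
  w21 <- build_contrast("within", P = 2, K = 1)
  expect_equal(unname(w21$A), matrix(c(1, -1), 1))
  expect_equal(w21$m, 1L)

  # between, P = 3, K = 2: population means contrasted with +-1/P
  b32 <- build_contrast("between", P = 3, K = 2)
  expect_equal(unname(b32$A), matrix(c(rep(1 / 3, 3), rep(-1 / 3, 3)), 1))

  # interaction, P = 3, K = 2: double differences in {-1, 0, 1}
  i32 <- build_contrast("interaction", P = 3, K = 2)
  expect_equal(nrow(i32$A), 2L)
  expect_true(all(i32$A %in% c(-1, 0, 1)))
  expect_equal(rowSums(i32$A), c(0, 0))

  # every built-in row sums to zero; rank equals row count
  for (h in c("within", "between", "interaction")) {
    ct <- build_contrast(h, P = 4, K = 3)
    expect_equal(unname(rowSums(ct$A)), rep(0, nrow(ct$A)), tolerance = 1e-12)
    expect_equal(qr(ct$A)$rank, nrow(ct$A))
    expect_equal(ct$mu0, rep(0, nrow(ct$A)))
  }

  # within averages over populations with weight 1/K
  w32 <- build_contrast("within", P = 3, K = 2)
  expect_equal(unname(w32$A[1, ]), c(0.5, -0.5, 0, 0.5, -0.5, 0))

  # hypotheses undefined for the design refuse to run
  expect_error(build_contrast("between", P = 3, K = 1),
               "K >= 2", class = "corcompare_validation_error")
  expect_error(build_contrast("interaction", P = 3, K = 1),
               class = "corcompare_validation_error")
  expect_error(build_contrast("within", P = 1, K = 2),
               "P >= 2", class = "corcompare_validation_error")
})

test_that("glh_test implements the chi-square quadratic form", {
  samples <- draw_pair(n = 800, delta = 0.05, seed = 17)
  state <- assemble_joint(samples)

  # null point: Au = mu0 exactly gives S = 0, p = 1
  A <- matrix(c(1, -1, 0, 0, 0, 0), 1)
  res0 <- custom_test(state, A, mu0 = drop(A %*% state$u))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)

  # identity contrast with mu0 = u
  resI <- custom_test(state, diag(6), mu0 = state$u)
  expect_equal(resI$statistic, 0, tolerance = 1e-20)

  # estimates carry Au and sqrt(diag(A Sigma A'))
  ct <- build_contrast("within", 3, 2)
  res <- glh_test(state, ct)
  expect_equal(res$estimates$estimate, drop(ct$A %*% state$u))
  expect_equal(res$estimates$se,
               sqrt(diag(ct$A %*% state$Sigma %*% t(ct$A))))
  expect_gte(res$statistic, 0)
  expect_equal(res$df, 2L)
  expect_equal(res$p_value, pchisq(res$statistic, 2, lower.tail = FALSE))

  # custom_test with a built-in matrix reproduces glh_test
  res2 <- custom_test(state, ct$A)
  expect_equal(res2$statistic, res$statistic)
  expect_equal(res2$p_value, res$p_value)
})

test_that("P=2, K=1 within test equals the dependent-correlation z test squared", {
  set.seed(19)
  s <- draw_pair(n = 500, P = 2, delta = 0.08, seed = 19)[[1]]
  state <- assemble_joint(list(s))
  res <- glh_test(state, build_contrast("within", P = 2, K = 1))
  z <- (state$u[1] - state$u[2]) /
    sqrt(state$Sigma[1, 1] + state$Sigma[2, 2] - 2 * state$Sigma[1, 2])
  expect_equal(res$statistic, unname(z^2), tolerance = 1e-12)
  expect_equal(res$p_value, unname(2 * pnorm(-abs(z))), tolerance = 1e-12)
})

test_that("tests are invariant to relabeling and contrast reparameterization", {
  samples <- draw_pair(n = 700, delta = 0.06, seed = 23)
  state <- assemble_joint(samples)
  hyps <- c("within", "between", "interaction")
  base <- lapply(hyps, function(h) glh_test(state, build_contrast(h, 3, 2)))

  # permute score labels consistently across populations
  perm <- c(3, 1, 2)
  relab <- lapply(samples, function(s)
    pop_sample(s$label, s$y, s$X[, perm], pgs_names = s$pgs_names[perm]))
  state_p <- assemble_joint(relab)
  for (i in seq_along(hyps)) {
    alt <- glh_test(state_p, build_contrast(hyps[i], 3, 2))
    expect_equal(alt$statistic, base[[i]]$statistic, tolerance = 1e-9)
  }

  # permute population order
  state_k <- assemble_joint(rev(samples))
  for (i in seq_along(hyps)) {
    alt <- glh_test(state_k, build_contrast(hyps[i], 3, 2))
    expect_equal(alt$statistic, base[[i]]$statistic, tolerance = 1e-9)
  }

  # replace A by MA with invertible M
  ct <- build_contrast("interaction", 3, 2)
  M <- matrix(c(2, 1, 0.5, -1), 2)
  alt <- custom_test(state, M %*% ct$A)
  expect_equal(alt$statistic,
               base[[which(hyps == "interaction")]]$statistic,
               tolerance = 1e-9)
})

test_that("rank-deficient contrasts fall back to the pseudo-inverse", {
  samples <- draw_pair(n = 600, seed = 29)
  state <- assemble_joint(samples)
  ct <- build_contrast("within", 3, 2)
  Adup <- rbind(ct$A, ct$A[1, ])  # duplicated row: rank 2, 3 rows
  # warned twice: once when the contrast is built, once at the
  # pseudo-inverse fallback
  ws <- testthat::capture_warnings(res <- custom_test(state, Adup))
  expect_length(ws, 2L)
  expect_match(ws, "rank|singular", all = TRUE)
  ref <- glh_test(state, ct)
  expect_equal(res$df, 2L)
  expect_equal(res$statistic, ref$statistic, tolerance = 1e-8)
  # an all-zero contrast warns (rank 0) before erroring on zero variance
  expect_error(suppressWarnings(custom_test(state, matrix(0, 1, 6))),
               class = "corcompare_validation_error")
  expect_error(custom_test(state, matrix(1, 1, 4)),
               class = "corcompare_validation_error")
})

test_that("pairwise difference intervals use the joint covariance", {
  samples <- draw_pair(n = 900, delta = 0.05, seed = 31)
  state <- assemble_joint(samples)
  ci <- pairwise_difference_ci(state, 1, 3)
  expect_equal(unname(ci["difference"]), unname(state$u[1] - state$u[3]))
  hw <- qnorm(0.975) * sqrt(state$Sigma[1, 1] + state$Sigma[3, 3] -
                              2 * state$Sigma[1, 3])
  expect_equal(unname(ci["upper"] - ci["difference"]), unname(hw))
  expect_lt(ci["lower"], ci["difference"])

  # cross-population entries are parametrically independent
  ci2 <- pairwise_difference_ci(state, 1, 4)
  hw2 <- qnorm(0.975) * sqrt(state$Sigma[1, 1] + state$Sigma[4, 4])
  expect_equal(unname(ci2["upper"] - ci2["difference"]), unname(hw2))

  # p-value of the single-row contrast agrees with the interval decision
  e <- function(i) replace(numeric(6), i, 1)
  res <- custom_test(state, matrix(e(1) - e(3), 1))
  excludes0 <- ci["lower"] > 0 || ci["upper"] < 0
  expect_equal(unname(res$p_value < 0.05), unname(excludes0))

  expect_error(pairwise_difference_ci(state, 2, 2),
               class = "corcompare_validation_error")
  expect_error(pairwise_difference_ci(state, 1, 99),
               class = "corcompare_validation_error")
  # degenerate: identical entries with identical covariance
  st <- state
  st$Sigma[1, 2] <- st$Sigma[2, 1] <- st$Sigma[1, 1]
  st$Sigma[2, 2] <- st$Sigma[1, 1]
  st$u[2] <- st$u[1]
  expect_warning(ci3 <- pairwise_difference_ci(st, 1, 2),
                 class = "corcompare_degenerate_interval")
  expect_equal(unname(ci3), c(0, 0, 0))
})
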