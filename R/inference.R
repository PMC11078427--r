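#' Build a contrast matrix for the built-in hypotheses
#'
#' Constructs the contrast matrix `A` for one of the three ANOVA-like
#' hypotheses on the stacked correlation vector
#' `u = (r_{1,1},...,r_{P,1}, ..., r_{1,K},...,r_{P,K})` (population-major,
#' score index fastest):
#'
#' * `"within"`: the P scores have equal correlation with the outcome when
#'   averaged over populations — `P - 1` rows contrasting score 1 against
#'   each other score, averaged over the K populations (+1/K and -1/K).
#' * `"between"`: the mean score-outcome correlation is equal across
#'   populations — `K - 1` rows contrasting population 1 against each other
#'   population, averaged over the P scores (+1/P and -1/P).
#' * `"interaction"`: the pattern of score differences is the same in every
#'   population — `(P-1)(K-1)` double-difference rows with entries in
#'   \{+1, -1, 0\}, score 1 and population 1 as references.
#'
#' Score 1 and population 1 anchor the contrasts; by reparameterization
#' invariance of the test statistic the choice of reference does not affect
#' the test. Every row sums to zero and the rows are linearly independent, so
#' the degrees of freedom equal the number of rows. The null value is 0.
#'
#' @param hypothesis One of `"within"`, `"between"`, `"interaction"`.
#' @param P Number of scores (>= 2 for within/interaction).
#' @param K Number of populations (>= 2 for between/interaction).
#' @return An object of class `contrast_matrix`: list with `A`, `mu0`, `m`
#'   (rank = rows) and `hypothesis`.
#' @export
build_contrast <- function(hypothesis = c("within", "between", "interaction"),
                           P, K) {
  hypothesis <- match.arg(hypothesis)
  P <- as.integer(P); K <- as.integer(K)
  if (P * K < 2L) stop_validation("need at least two correlations to contrast")
  if (hypothesis %in% c("within", "interaction") && P < 2L) {
    stop_validation(sprintf(
      "the %s hypothesis compares scores and needs P >= 2 (got P = %d)",
      hypothesis, P))
  }
  if (hypothesis %in% c("between", "interaction") && K < 2L) {
    stop_validation(sprintf(
      "the %s hypothesis compares populations and needs K >= 2 (got K = %d)",
      hypothesis, K))
  }
  pos <- function(p, k) (k - 1L) * P + p
  A <- switch(hypothesis,
    within = {
      A <- matrix(0, P - 1L, P * K)
      for (i in seq_len(P - 1L)) for (k in seq_len(K)) {
        A[i, pos(1L, k)] <- 1 / K
        A[i, pos(i + 1L, k)] <- -1 / K
      }
      A
    },
    between = {
      A <- matrix(0, K - 1L, P * K)
      for (j in seq_len(K - 1L)) {
        A[j, pos(seq_len(P), 1L)] <- 1 / P
        A[j, pos(seq_len(P), j + 1L)] <- -1 / P
      }
      A
    },
    interaction = {
      A <- matrix(0, (P - 1L) * (K - 1L), P * K)
      row <- 0L
      for (j in seq.int(2L, K)) for (i in seq.int(2L, P)) {
        row <- row + 1L
        A[row, pos(1L, 1L)] <- 1
        A[row, pos(i, 1L)] <- -1
        A[row, pos(1L, j)] <- -1
        A[row, pos(i, j)] <- 1
      }
      A
    })
  new_contrast(A, mu0 = rep(0, nrow(A)), hypothesis = hypothesis)
}

new_contrast <- function(A, mu0, hypothesis = "custom") {
  A <- as.matrix(A)
  if (length(mu0) != nrow(A)) {
    stop_validation("mu0 length must equal the number of contrast rows")
  }
  rk <- qr(A)$rank
  if (rk < nrow(A)) {
    warn_class(sprintf(
      "contrast rows are linearly dependent (rank %d < %d rows)", rk, nrow(A)),
      "corcompare_rank_deficient")
  }
  structure(list(A = A, mu0 = as.numeric(mu0), m = rk,
                 hypothesis = hypothesis),
            class = "contrast_matrix")
}

#' @export
print.contrast_matrix <- function(x, ...) {
  cat(sprintf("Contrast matrix (%s): %d row(s), rank %d\n",
              x$hypothesis, nrow(x$A), x$m))
  print(x$A)
  invisible(x)
}

#' General linear hypothesis test on a correlation vector
#'
#' Tests `H0: A u = mu0` with the quadratic-form statistic
#' `S = (Au - mu0)' (A Sigma A')^{-1} (Au - mu0)`, which is asymptotically
#' chi-square with `m = rank(A)` degrees of freedom under the null.
#'
#' When `A Sigma A'` is numerically singular (e.g. nearly collinear scores),
#' the Moore-Penrose pseudo-inverse is used, the degrees of freedom drop to
#' the numerical rank, and a classed warning is emitted.
#'
#' @param state A `correlation_state` (from [assemble_joint()] or
#'   [bootstrap_cov()]).
#' @param contrast A `contrast_matrix` (from [build_contrast()] or
#'   [custom_test()] input).
#' @return An object of class `cor_test`: list with `statistic`, `df`,
#'   `p_value`, `method`, `hypothesis`, `estimates` (a data frame of `Au`
#'   with standard errors) and the input `u`/`Sigma`.
#' @export
glh_test <- function(state, contrast) {
  A <- contrast$A
  if (ncol(A) != length(state$u)) {
    stop_validation(sprintf(
      "contrast has %d columns but u has length %d", ncol(A), length(state$u)))
  }
  d <- drop(A %*% state$u) - contrast$mu0
  M <- A %*% state$Sigma %*% t(A)
  M <- (M + t(M)) / 2
  if (all(M == 0)) {
    stop_validation("A Sigma A' is exactly zero; the contrast has no sampling variance")
  }
  df <- contrast$m
  Minv <- tryCatch({
    if (rcond(M) < 1e-12) stop("near-singular")
    solve(M)
  }, error = function(e) NULL)
  if (is.null(Minv)) {
    pi <- pseudo_inverse(M)
    Minv <- pi$inv
    df <- pi$rank
    warn_class(sprintf(
      "A Sigma A' is numerically singular; using pseudo-inverse with df = %d",
      df), "corcompare_rank_deficient")
  }
  S <- max(0, drop(t(d) %*% Minv %*% d))
  p <- stats::pchisq(S, df = df, lower.tail = FALSE)
  est <- data.frame(estimate = drop(A %*% state$u),
                    se = sqrt(pmax(0, diag(M))),
                    null_value = contrast$mu0)
  structure(
    list(statistic = S, df = df, p_value = p,
         method = state$method, hypothesis = contrast$hypothesis,
         estimates = est, u = state$u, Sigma = state$Sigma),
    class = "cor_test")
}

#' @export
print.cor_test <- function(x, digits = 4, ...) {
  cat(sprintf("Correlation contrast test (%s, %s)\n", x$hypothesis, x$method))
  cat(sprintf("  chi-square = %.*g, df = %d, p = %.3g\n",
              digits, x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Test a user-supplied contrast
#'
#' Same machinery as [glh_test()] but for an arbitrary contrast matrix `A`
#' and null value `mu0`, enabling bespoke comparisons (e.g. one score against
#' the average of several others, or one score across populations).
#'
#' @param state A `correlation_state`.
#' @param A Numeric matrix with `P*K` columns (rows = contrasts). Linearly
#'   dependent rows are rank-reduced with a warning.
#' @param mu0 Null value vector (default all zeros).
#' @return A `cor_test` (see [glh_test()]).
#' @export
custom_test <- function(state, A, mu0 = NULL) {
  A <- as.matrix(A)
  if (ncol(A) != length(state$u)) {
    stop_validation(sprintf(
      "A must have %d columns (P*K); got %d", length(state$u), ncol(A)))
  }
  mu0 <- mu0 %||% rep(0, nrow(A))
  glh_test(state, new_contrast(A, mu0, hypothesis = "custom"))
}

#' Confidence interval for the difference of two correlations
#'
#' Normal-theory interval for `u[idx_a] - u[idx_b]` using the joint
#' covariance: half-width `z * sqrt(Sigma[a,a] + Sigma[b,b] - 2 Sigma[a,b])`.
#' For entries from different populations the parametric cross term is zero.
#'
#' @param state A `correlation_state`.
#' @param idx_a,idx_b Positions in `u` (integer, or names of `u`).
#' @param level Confidence level in (0, 1); default 0.95.
#' @return Named numeric vector `c(difference, lower, upper)`. A degenerate
#'   (zero-variance) difference is returned as `(d, d, d)` with a warning.
#' @export
pairwise_difference_ci <- function(state, idx_a, idx_b, level = 0.95) {
  resolve <- function(i) {
    if (is.character(i)) i <- match(i, names(state$u))
    i <- as.integer(i)
    if (is.na(i) || i < 1L || i > length(state$u)) {
      stop_validation("index out of range of u")
    }
    i
  }
  a <- resolve(idx_a); b <- resolve(idx_b)
  if (a == b) stop_validation("idx_a and idx_b must differ (zero-variance difference)")
  if (level <= 0 || level >= 1) stop_validation("level must be in (0, 1)")
  d <- state$u[a] - state$u[b]
  v <- state$Sigma[a, a] + state$Sigma[b, b] - 2 * state$Sigma[a, b]
  if (v <= 0) {
    warn_class("difference has zero estimated variance; degenerate interval",
               "corcompare_degenerate_interval")
    v <- 0
  }
  hw <- stats::qnorm((1 + level) / 2) * sqrt(v)
  c(difference = unname(d), lower = unname(d - hw), upper = unname(d + hw))
}
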