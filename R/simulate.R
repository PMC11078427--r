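#' Correlation matrices for the three simulation settings
#'
#' Builds the (P+1) x (P+1) joint correlation matrices of
#' `(Y, X_1, ..., X_P)` for two populations A and B. The inter-score block
#' has `phi` off the diagonal in both populations; the outcome row encodes
#' the design:
#'
#' * setting `"I"` (within alternative): in both populations the last score
#'   has outcome correlation `tau + delta`, the others `tau`.
#' * setting `"II"` (between alternative): all scores have `tau` in A and
#'   `tau + delta` in B.
#' * setting `"III"` (interaction alternative): all scores have `tau` in A;
#'   in B the last score has `tau + delta`, the others `tau`.
#' * setting `"null"`: all scores have `tau` in both populations
#'   (equivalent to any setting with `delta = 0`).
#'
#' Both matrices are validated to be positive semi-definite before use;
#' infeasible parameter combinations error rather than being silently
#' adjusted.
#'
#' @param setting One of `"I"`, `"II"`, `"III"`, `"null"`.
#' @param tau Base score-outcome correlation.
#' @param phi Common inter-score correlation.
#' @param delta Correlation perturbation (>= 0).
#' @param P Number of scores (default 3).
#' @return List with elements `A` and `B`, each a correlation matrix.
#' @export
build_setting_matrices <- function(setting = c("I", "II", "III", "null"),
                                   tau, phi, delta = 0, P = 3L) {
  setting <- match.arg(setting)
  if (abs(tau) >= 1 || abs(phi) >= 1) stop_validation("tau and phi must be in (-1, 1)")
  if (delta < 0) stop_validation("delta must be >= 0")
  base_row <- function(last) c(rep(tau, P - 1L), last)
  rows <- switch(setting,
    I    = list(A = base_row(tau + delta), B = base_row(tau + delta)),
    II   = list(A = rep(tau, P),           B = rep(tau + delta, P)),
    III  = list(A = rep(tau, P),           B = base_row(tau + delta)),
    null = list(A = rep(tau, P),           B = rep(tau, P)))
  make <- function(outcome_row, label) {
    R <- matrix(phi, P + 1L, P + 1L)
    diag(R) <- 1
    R[1L, -1L] <- outcome_row
    R[-1L, 1L] <- outcome_row
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-10) {
      stop_validation(sprintf(
        "correlation matrix for population %s is not positive semi-definite (tau=%.3g, phi=%.3g, delta=%.3g)",
        label, tau, phi, delta))
    }
    dimnames(R) <- list(c("Y", paste0("PGS", seq_len(P))),
                        c("Y", paste0("PGS", seq_len(P))))
    R
  }
  list(A = make(rows$A, "A"), B = make(rows$B, "B"))
}

#' Draw one population sample from a correlation structure
#'
#' Draws `n` individuals from the zero-mean, unit-variance multivariate
#' normal with the given correlation matrix. The first coordinate is the
#' outcome, the remaining coordinates are the scores.
#'
#' @param corr (P+1) x (P+1) correlation matrix (outcome first).
#' @param n Sample size (>= 2).
#' @param label Population label for the returned [pop_sample].
#' @return A [pop_sample] with P scores.
#' @export
simulate_population <- function(corr, n, label = "sim") {
  corr <- as.matrix(corr)
  d <- ncol(corr)
  if (n < 2L) stop_validation("n must be >= 2")
  L <- tryCatch(chol(corr), error = function(e) {
    stop_validation("correlation matrix is not positive definite")
  })
  Z <- matrix(stats::rnorm(n * d), n, d) %*% L
  pop_sample(label, y = Z[, 1L], X = Z[, -1L, drop = FALSE],
             pgs_names = colnames(corr)[-1L] %||% paste0("PGS", seq_len(d - 1L)))
}

#' Simulation configuration
#'
#' @param setting Simulation setting (see [build_setting_matrices()]).
#' @param tau,phi,delta Correlation parameters.
#' @param P Number of scores (default 3).
#' @param n Per-population sample size; scalar (equal sizes) or length-2
#'   vector (unequal).
#' @param reps Number of replicates (default 1000).
#' @param alpha Significance level(s); default `c(0.025, 0.05)`.
#' @param seed Integer RNG seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(setting = "I", tau = 0.4, phi = 0.5, delta = 0,
                       P = 3L, n = 1000L, reps = 1000L,
                       alpha = c(0.025, 0.05), seed = 1L) {
  if (any(alpha <= 0 | alpha >= 1)) stop_validation("alpha must be in (0, 1)")
  if (reps < 1L) stop_validation("reps must be >= 1")
  n <- as.integer(n)
  if (length(n) == 1L) n <- rep(n, 2L)
  if (length(n) != 2L) stop_validation("n must be a scalar or length 2 (populations A, B)")
  # validate feasibility up front
  build_setting_matrices(setting, tau, phi, delta, P)
  structure(list(setting = setting, tau = tau, phi = phi, delta = delta,
                 P = as.integer(P), K = 2L, n = n, reps = as.integer(reps),
                 alpha = sort(alpha), seed = as.integer(seed)),
            class = "sim_config")
}

#' Run a replicated simulation experiment
#'
#' For each replicate: draw the two population samples under the configured
#' setting, run the three contrast tests (within, between, interaction), and
#' record whether each rejects at each significance level. Replicate `r` uses
#' a deterministic child seed of `config$seed`, so results are independent of
#' execution order. A failed replicate is recorded and excluded with a
#' warning.
#'
#' @param config A [sim_config()].
#' @param method `"parametric"` (asymptotic covariance) or `"nonparametric"`
#'   (bootstrap covariance + permutation p-values; far slower).
#' @param plan [resampling_plan()] used when `method = "nonparametric"`
#'   (its seed is re-derived per replicate).
#' @return An object of class `sim_result`: list with `rejections` (a
#'   hypothesis x alpha matrix of rejection proportions), `mc_se` (matching
#'   Monte-Carlo standard errors `sqrt(p(1-p)/reps)`), `p_values` (reps x 3
#'   matrix), `statistics`, `n_failed`, and the config echo.
#' @export
run_experiment <- function(config, method = c("parametric", "nonparametric"),
                           plan = resampling_plan(n_boot = 500L, n_perm = 500L)) {
  method <- match.arg(method)
  mats <- build_setting_matrices(config$setting, config$tau, config$phi,
                                 config$delta, config$P)
  hyps <- c("within", "between", "interaction")
  contrasts <- lapply(hyps, build_contrast, P = config$P, K = 2L)
  names(contrasts) <- hyps
  pv <- matrix(NA_real_, config$reps, 3L, dimnames = list(NULL, hyps))
  st <- matrix(NA_real_, config$reps, 3L, dimnames = list(NULL, hyps))
  n_failed <- 0L
  for (r in seq_len(config$reps)) {
    set.seed(child_seed(config$seed, r))
    res <- tryCatch({
      sA <- simulate_population(mats$A, config$n[1L], "A")
      sB <- simulate_population(mats$B, config$n[2L], "B")
      if (method == "parametric") {
        state <- suppressWarnings(assemble_joint(list(sA, sB)))
        lapply(contrasts, function(ct) glh_test(state, ct))
      } else {
        rplan <- resampling_plan(plan$n_boot, plan$n_perm,
                                 child_seed(config$seed, 500000L + r))
        lapply(hyps, function(h)
          permutation_pvalue(list(sA, sB), h, rplan))
      }
    }, error = function(e) NULL)
    if (is.null(res)) {
      n_failed <- n_failed + 1L
      next
    }
    pv[r, ] <- vapply(res, `[[`, numeric(1L), "p_value")
    st[r, ] <- vapply(res, `[[`, numeric(1L), "statistic")
  }
  if (n_failed > 0L) {
    warn_class(sprintf("%d replicate(s) failed and were excluded", n_failed),
               "corcompare_failed_replicates")
  }
  ok <- stats::complete.cases(pv)
  rej <- sapply(config$alpha, function(a) colMeans(pv[ok, , drop = FALSE] < a))
  rej <- matrix(rej, nrow = 3L,
                dimnames = list(hyps, paste0("alpha=", config$alpha)))
  mc_se <- sqrt(rej * (1 - rej) / sum(ok))
  structure(list(rejections = rej, mc_se = mc_se,
                 p_values = pv, statistics = st,
                 n_failed = n_failed, reps_used = sum(ok),
                 method = method, config = config),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, digits = 3, ...) {
  cfg <- x$config
  cat(sprintf(
    "Simulation (%s): setting %s, tau=%.3g, phi=%.3g, delta=%.3g, n=(%d,%d), %d replicate(s)\n",
    x$method, cfg$setting, cfg$tau, cfg$phi, cfg$delta,
    cfg$n[1L], cfg$n[2L], x$reps_used))
  cat("Rejection proportions:\n")
  print(round(x$rejections, digits))
  if (x$n_failed > 0L) cat(sprintf("(%d failed replicate(s) excluded)\n", x$n_failed))
  invisible(x)
}

#' Tidy one simulation result
#'
#' @param x A `sim_result`.
#' @return A data frame with one row per hypothesis x alpha, carrying the
#'   configuration, rejection proportion and Monte-Carlo standard error.
#' @export
as.data.frame.sim_result <- function(x, ...) {
  cfg <- x$config
  grid <- expand.grid(hypothesis = rownames(x$rejections),
                      alpha = cfg$alpha, stringsAsFactors = FALSE)
  data.frame(setting = cfg$setting, tau = cfg$tau, phi = cfg$phi,
             delta = cfg$delta, n_A = cfg$n[1L], n_B = cfg$n[2L],
             reps = x$reps_used, method = x$method, grid,
             rejection = mapply(function(h, a)
               x$rejections[h, paste0("alpha=", a)],
               grid$hypothesis, grid$alpha),
             mc_se = mapply(function(h, a)
               x$mc_se[h, paste0("alpha=", a)],
               grid$hypothesis, grid$alpha),
             row.names = NULL)
}
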