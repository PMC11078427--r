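#' Score-outcome correlation vector for one population
#'
#' Pearson correlations of each polygenic score with the outcome.
#'
#' @param sample A [pop_sample].
#' @return Named numeric vector of length P (one entry per score).
#' @export
pearson_vector <- function(sample) {
  if (sample$n < 3L) {
    stop_validation("need n >= 3 to estimate correlations")
  }
  r <- as.numeric(stats::cor(sample$X, sample$y))
  names(r) <- sample$pgs_names
  r
}

#' Asymptotic covariance of dependent correlations sharing one outcome
#'
#' The large-sample (Olkin-Finn) covariance of the P sample correlations
#' between each score and a common outcome, with the scores themselves
#' correlated. With `r_i` the score-outcome correlations and `phi_ij` the
#' inter-score correlations:
#' \deqn{var(r_i) = (1 - r_i^2)^2 / n}
#' \deqn{cov(r_i, r_j) = [\phi_{ij}(1 - r_i^2 - r_j^2) -
#'   \tfrac12 r_i r_j (1 - r_i^2 - r_j^2 - \phi_{ij}^2)] / n}
#' Population correlations are replaced by their sample plug-in estimates.
#'
#' @param r Numeric vector of P score-outcome correlations, all `|r| < 1`.
#' @param Phi P x P inter-score correlation matrix (unit diagonal).
#' @param n Sample size (>= 3).
#' @return P x P covariance matrix.
#' @export
asymptotic_cov_block <- function(r, Phi, n) {
  P <- length(r)
  Phi <- as.matrix(Phi)
  if (!all(dim(Phi) == P)) {
    stop_validation("Phi must be P x P for P = length(r)")
  }
  if (any(abs(Phi - t(Phi)) > 1e-8) || any(abs(diag(Phi) - 1) > 1e-8)) {
    stop_validation("Phi must be symmetric with unit diagonal")
  }
  if (n < 3L) stop_validation("need n >= 3")
  if (any(abs(r) >= 1)) {
    stop_validation("degenerate variance: |r| = 1 for at least one score")
  }
  V <- matrix(0, P, P)
  for (i in seq_len(P)) {
    V[i, i] <- (1 - r[i]^2)^2
    if (i < P) for (j in seq.int(i + 1L, P)) {
      V[i, j] <- Phi[i, j] * (1 - r[i]^2 - r[j]^2) -
        0.5 * r[i] * r[j] * (1 - r[i]^2 - r[j]^2 - Phi[i, j]^2)
      V[j, i] <- V[i, j]
    }
  }
  V / n
}

#' Assemble the joint correlation state across populations
#'
#' Stacks the per-population score-outcome correlation vectors
#' population-major (score index fastest) into a single vector `u` of length
#' P*K, and builds its covariance. In this parametric mode the populations
#' are independent samples, so `Sigma` is block-diagonal with one
#' [asymptotic_cov_block()] per population and exact zeros between
#' populations.
#'
#' Asymptotic inference on raw correlations is an approximation for large
#' samples; a classed warning (`corcompare_small_sample`) is emitted when any
#' population has fewer than 500 individuals.
#'
#' @param samples List of [pop_sample] objects with identical `pgs_names`.
#' @return An object of class `correlation_state`: list with `u`, `Sigma`,
#'   `P`, `K`, `ns`, `pgs_names`, `pop_names`, `method = "parametric"`.
#' @export
assemble_joint <- function(samples) {
  if (!length(samples)) stop_validation("need at least one population sample")
  pgs <- samples[[1L]]$pgs_names
  for (s in samples) {
    if (!identical(s$pgs_names, pgs)) {
      stop_validation("all populations must have the same scores, in the same order")
    }
  }
  ns <- vapply(samples, function(s) s$n, integer(1L))
  if (any(ns < 500L)) {
    warn_class(paste(
      "parametric (asymptotic) inference with n < 500 in at least one",
      "population; consider the nonparametric mode"),
      "corcompare_small_sample")
  }
  P <- length(pgs)
  K <- length(samples)
  u <- numeric(0)
  Sigma <- matrix(0, P * K, P * K)
  for (k in seq_len(K)) {
    s <- samples[[k]]
    r <- pearson_vector(s)
    Phi <- stats::cor(s$X)
    idx <- (k - 1L) * P + seq_len(P)
    u <- c(u, r)
    Sigma[idx, idx] <- asymptotic_cov_block(r, Phi, s$n)
  }
  pops <- vapply(samples, function(s) s$label, character(1L))
  names(u) <- paste(rep(pgs, K), rep(pops, each = P), sep = ":")
  dimnames(Sigma) <- list(names(u), names(u))
  new_correlation_state(u, Sigma, P, K, ns, pgs, pops, "parametric")
}

new_correlation_state <- function(u, Sigma, P, K, ns, pgs_names, pop_names,
                                  method) {
  Sigma <- check_psd(Sigma, "correlation covariance matrix")
  structure(
    list(u = u, Sigma = Sigma, P = P, K = K, ns = ns,
         pgs_names = pgs_names, pop_names = pop_names, method = method),
    class = "correlation_state")
}

#' @export
print.correlation_state <- function(x, digits = 4, ...) {
  cat(sprintf("Correlation state: %d score(s) x %d population(s), %s covariance\n",
              x$P, x$K, x$method))
  print(round(coef(x), digits))
  invisible(x)
}

#' @export
coef.correlation_state <- function(object, ...) {
  matrix(object$u, object$P, object$K,
         dimnames = list(object$pgs_names, object$pop_names))
}

#' @export
vcov.correlation_state <- function(object, ...) object$Sigma

#' Flag non-positive score-outcome correlations
#'
#' A polygenic score is expected to correlate positively with its intended
#' outcome; a correlation at or below zero often indicates a flipped effect
#' allele in the score computation. This check never alters results.
#'
#' @param state A `correlation_state`.
#' @param warn Emit an R warning listing the flagged entries (default TRUE).
#' @return Character vector of messages, one per entry of `u` that is <= 0
#'   (boundary included); empty if all correlations are positive.
#' @export
check_positive_correlations <- function(state, warn = TRUE) {
  bad <- which(state$u <= 0)
  msgs <- character(0)
  if (length(bad)) {
    pgs <- rep(state$pgs_names, state$K)[bad]
    pop <- rep(state$pop_names, each = state$P)[bad]
    msgs <- sprintf(
      "score '%s' has non-positive correlation (%.4f) with the outcome in population '%s'; check the designated effect alleles",
      pgs, state$u[bad], pop)
    if (warn) warn_class(paste(msgs, collapse = "\n"),
                         "corcompare_nonpositive_correlation")
  }
  msgs
}
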