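#' Resampling plan
#'
#' Bundles the bootstrap/permutation replicate counts and the RNG seed so
#' that nonparametric results are exactly reproducible. Each population gets
#' a deterministic child seed derived from `seed`, so results do not depend
#' on population ordering side effects.
#'
#' @param n_boot Bootstrap replicates for the covariance (default 1000).
#' @param n_perm Permutations for the permutation p-value (default 1000).
#' @param seed Integer RNG seed (default 1).
#' @return An object of class `resampling_plan`.
#' @export
resampling_plan <- function(n_boot = 1000L, n_perm = 1000L, seed = 1L) {
  n_boot <- as.integer(n_boot); n_perm <- as.integer(n_perm)
  if (n_boot < 2L) stop_validation("n_boot must be >= 2")
  if (n_perm < 1L) stop_validation("n_perm must be >= 1")
  structure(list(n_boot = n_boot, n_perm = n_perm, seed = as.integer(seed)),
            class = "resampling_plan")
}

# Correlations of each score with the outcome for a row subset, with a
# zero-variance guard used by the bootstrap redraw logic.
cor_vec_rows <- function(y, X, rows) {
  yy <- y[rows]
  XX <- X[rows, , drop = FALSE]
  if (stats::sd(yy) == 0 || any(apply(XX, 2L, stats::sd) == 0)) return(NULL)
  as.numeric(stats::cor(XX, yy))
}

#' Bootstrap covariance of the stacked correlation vector
#'
#' Resamples individuals with replacement, independently within each
#' population, recomputes the stacked correlation vector for each replicate,
#' and returns the original-sample point estimate `u` together with the
#' replicate covariance matrix (mean-centered, denominator `n_boot - 1`).
#' Unlike the parametric covariance, cross-population blocks are estimated
#' rather than fixed at zero (for independent samples they converge to zero).
#'
#' A replicate in which any resampled column is constant is redrawn (at most
#' 100 retries, then an error).
#'
#' @param samples List of [pop_sample] objects.
#' @param plan A [resampling_plan()].
#' @return A `correlation_state` with `method = "bootstrap"`.
#' @export
bootstrap_cov <- function(samples, plan = resampling_plan()) {
  if (!inherits(plan, "resampling_plan")) stop_validation("plan must be a resampling_plan")
  for (s in samples) if (s$n < 3L) {
    stop_validation("bootstrap needs n >= 3 in every population")
  }
  P <- length(samples[[1L]]$pgs_names)
  K <- length(samples)
  B <- plan$n_boot
  U <- matrix(0, B, P * K)
  for (k in seq_len(K)) {
    s <- samples[[k]]
    set.seed(child_seed(plan$seed, k * 7919L))
    idx <- matrix(sample.int(s$n, s$n * B, replace = TRUE), s$n, B)
    cols <- (k - 1L) * P + seq_len(P)
    for (b in seq_len(B)) {
      r <- cor_vec_rows(s$y, s$X, idx[, b])
      tries <- 0L
      while (is.null(r)) {
        tries <- tries + 1L
        if (tries > 100L) {
          stop_validation(sprintf(
            "population '%s': 100 bootstrap redraws hit a constant column", s$label))
        }
        r <- cor_vec_rows(s$y, s$X, sample.int(s$n, s$n, replace = TRUE))
      }
      U[b, cols] <- r
    }
  }
  Sigma <- stats::cov(U)
  u <- unlist(lapply(samples, pearson_vector), use.names = FALSE)
  pops <- vapply(samples, function(s) s$label, character(1L))
  pgs <- samples[[1L]]$pgs_names
  names(u) <- paste(rep(pgs, K), rep(pops, each = P), sep = ":")
  dimnames(Sigma) <- list(names(u), names(u))
  ns <- vapply(samples, function(s) s$n, integer(1L))
  new_correlation_state(u, Sigma, P, K, ns, pgs, pops, "bootstrap")
}

# One permuted copy of the samples under the null of the given hypothesis.
# between: individuals are pooled and population labels reassigned at random
#   (sizes preserved) -- exchangeable under equal joint distributions.
# within / interaction: the P score labels are shuffled independently for
#   each individual -- exchangeable score columns under the within null with
#   a common inter-score correlation.
permute_samples <- function(samples, hypothesis) {
  K <- length(samples)
  if (hypothesis == "between") {
    ys <- unlist(lapply(samples, `[[`, "y"), use.names = FALSE)
    Xs <- do.call(rbind, lapply(samples, `[[`, "X"))
    ntot <- length(ys)
    ord <- sample.int(ntot)
    starts <- cumsum(c(0L, vapply(samples, `[[`, integer(1L), "n")))
    lapply(seq_len(K), function(k) {
      rows <- ord[seq.int(starts[k] + 1L, starts[k + 1L])]
      list(y = ys[rows], X = Xs[rows, , drop = FALSE])
    })
  } else {
    lapply(samples, function(s) {
      P <- ncol(s$X)
      if (P <= 6L) {
        perms <- all_permutations(P)
        pick <- perms[sample.int(nrow(perms), s$n, replace = TRUE), , drop = FALSE]
        Xp <- matrix(s$X[cbind(rep(seq_len(s$n), P), as.vector(pick))],
                     s$n, P)
      } else {
        Xp <- t(apply(s$X, 1L, sample))
      }
      list(y = s$y, X = Xp)
    })
  }
}

#' Permutation p-value for a built-in hypothesis
#'
#' Computes the observed statistic with the bootstrap covariance of `u`, then
#' builds the null distribution by recomputing the statistic on permuted data
#' (the covariance is held fixed at the observed bootstrap estimate; only the
#' correlation vector is recomputed per permutation). Under the between null,
#' individuals are exchangeable across populations, so population labels are
#' permuted; under the within/interaction null the score columns are
#' exchangeable, so score labels are shuffled per individual. The p-value
#' uses the add-one rule `p = (1 + #\{S_perm >= S_obs\}) / (1 + n_perm)`, so
#' it is never 0 and never exceeds 1.
#'
#' @param samples List of [pop_sample] objects.
#' @param hypothesis One of `"within"`, `"between"`, `"interaction"`.
#' @param plan A [resampling_plan()].
#' @return A `cor_test` with `method = "permutation"` and an extra element
#'   `n_perm`.
#' @export
permutation_pvalue <- function(samples,
                               hypothesis = c("within", "between", "interaction"),
                               plan = resampling_plan()) {
  hypothesis <- match.arg(hypothesis)
  P <- length(samples[[1L]]$pgs_names)
  K <- length(samples)
  contrast <- build_contrast(hypothesis, P = P, K = K)
  state <- bootstrap_cov(samples, plan)
  obs <- glh_test(state, contrast)
  A <- contrast$A
  M <- A %*% state$Sigma %*% t(A)
  M <- (M + t(M)) / 2
  Minv <- tryCatch(solve(M), error = function(e) pseudo_inverse(M)$inv)
  stat_of <- function(perm) {
    u <- unlist(lapply(perm, function(p) as.numeric(stats::cor(p$X, p$y))),
                use.names = FALSE)
    d <- drop(A %*% u) - contrast$mu0
    drop(t(d) %*% Minv %*% d)
  }
  set.seed(child_seed(plan$seed, 104729L))
  S_perm <- vapply(seq_len(plan$n_perm),
                   function(i) stat_of(permute_samples(samples, hypothesis)),
                   numeric(1L))
  p <- (1 + sum(S_perm >= obs$statistic)) / (1 + plan$n_perm)
  obs$method <- "permutation"
  obs$p_value <- p
  obs$n_perm <- plan$n_perm
  obs
}
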