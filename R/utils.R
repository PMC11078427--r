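# Internal helpers: classed conditions, pseudo-inverse, seed streams.

stop_validation <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("corcompare_validation_error", "error")))
}

stop_configuration <- function(msg) {
  stop(errorCondition(msg, class = c("corcompare_configuration_error", "error")))
}

warn_class <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "corcompare_warning")))
}

# Moore-Penrose pseudo-inverse via SVD; returns the inverse and the numerical
# rank (singular values above tol * max(sv)).
pseudo_inverse <- function(M, tol = 1e-12) {
  sv <- svd(M)
  keep <- sv$d > tol * max(sv$d, 0)
  rank <- sum(keep)
  if (rank == 0L) {
    stop_validation("contrast covariance matrix is numerically zero")
  }
  inv <- sv$v[, keep, drop = FALSE] %*%
    (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
  list(inv = inv, rank = rank)
}

# Symmetrize and check for negative eigenvalues beyond numerical noise.
# Plug-in covariance matrices can be numerically indefinite; eigenvalues more
# negative than -1e-10 * lambda_max indicate a genuinely bad matrix.
check_psd <- function(Sigma, label = "covariance matrix") {
  S <- (Sigma + t(Sigma)) / 2
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev))) {
    stop_validation(sprintf(
      "%s is not positive semi-definite (min eigenvalue %.3e)", label, min(ev)))
  }
  S
}

# Deterministic child seed so replicate r (or population k) gets its own
# reproducible stream regardless of evaluation order. Kept below 2^31 - 1.
child_seed <- function(seed, r) {
  as.integer((as.numeric(seed) %% 2147483629 * 48271 + r * 8191) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# All permutations of 1..k, one per row (k small; used for per-individual
# score-label shuffles in the permutation test).
all_permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    rest <- setdiff(seq_len(k), i)
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}
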