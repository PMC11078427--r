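#' Compare polygenic score performance via correlations
#'
#' Fits the correlation-comparison model: computes the Pearson correlation of
#' each score with the outcome in each population, the joint covariance of
#' that stacked correlation vector (asymptotic or bootstrap), and the
#' requested ANOVA-like contrast tests:
#'
#' * **within** — do the scores have equal mean correlation with the outcome,
#'   averaged over populations?
#' * **between** — is the mean score-outcome correlation equal across
#'   populations?
#' * **interaction** — is the pattern of score differences the same in every
#'   population?
#'
#' The model interface is `outcome ~ score1 + score2 + ... | group`; omit
#' `| group` for a single population. Preprocessing mirrors standard
#' polygenic-score evaluation practice: optionally inverse-rank normalize the
#' outcome, then residualize outcome and scores on covariates (e.g. genetic
#' principal components) within each population before correlating.
#'
#' @param formula Model formula `y ~ pgs1 + pgs2 + ... | group` (the part
#'   after `|` names the population-group column; optional).
#' @param data Data frame containing the variables. Rows with a missing value
#'   in any used column (including covariates) are dropped (complete-case).
#' @param covariates Character vector of covariate column names to
#'   residualize on (within each population), or `NULL`.
#' @param int Logical; inverse-rank normalize the outcome before grouping.
#' @param method `"parametric"` (asymptotic covariance, default),
#'   `"bootstrap"` (bootstrap covariance, chi-square p-values) or
#'   `"permutation"` (bootstrap covariance, permutation p-values).
#' @param hypotheses Character vector of built-in hypotheses to test;
#'   defaults to all that are defined for the data (`"within"` needs >= 2
#'   scores; `"between"`/`"interaction"` need >= 2 populations).
#' @param plan A [resampling_plan()] for the nonparametric methods.
#' @return An object of class `corcompare`: list with `samples`, `state`
#'   (the `correlation_state`), `tests` (named list of `cor_test`), `corr`
#'   (per-population full correlation matrices of `(y, scores)`), `ns`,
#'   `flags` (non-positive-correlation messages) and the matched call.
#'   Methods: [print.corcompare()], [summary.corcompare()],
#'   [coef.corcompare()] (P x K correlation matrix), `vcov` (covariance of
#'   the stacked correlations), [plot.corcompare()],
#'   [simulate.corcompare()], [confint.corcompare()].
#' @examples
#' set.seed(1)
#' mats <- build_setting_matrices("I", tau = 0.4, phi = 0.5, delta = 0.1)
#' a <- simulate_population(mats$A, 600, "A")
#' b <- simulate_population(mats$B, 600, "B")
#' df <- rbind(
#'   data.frame(pop = "A", y = a$y, a$X),
#'   data.frame(pop = "B", y = b$y, b$X))
#' fit <- corcompare(y ~ PGS1 + PGS2 + PGS3 | pop, data = df)
#' summary(fit)
#' @export
corcompare <- function(formula, data, covariates = NULL, int = FALSE,
                       method = c("parametric", "bootstrap", "permutation"),
                       hypotheses = NULL, plan = resampling_plan()) {
  method <- match.arg(method)
  spec <- parse_corcompare_formula(formula)
  samples <- as_pop_samples(data, outcome_col = spec$outcome,
                            group_col = spec$group, pgs_cols = spec$pgs,
                            covariate_cols = covariates, int = int)
  fit_corcompare(samples, method = method, hypotheses = hypotheses,
                 plan = plan, call = match.call())
}

# y ~ s1 + s2 + ... | group  ->  list(outcome, pgs, group)
parse_corcompare_formula <- function(formula) {
  if (length(formula) != 3L) {
    stop_configuration("formula must have the form y ~ pgs1 + ... | group")
  }
  outcome <- all.vars(formula[[2L]])
  if (length(outcome) != 1L) {
    stop_configuration("formula must have a single outcome variable")
  }
  rhs <- formula[[3L]]
  group <- NULL
  if (is.call(rhs) && identical(rhs[[1L]], as.name("|"))) {
    group <- all.vars(rhs[[3L]])
    if (length(group) != 1L) {
      stop_configuration("the grouping term after | must be a single variable")
    }
    rhs <- rhs[[2L]]
  }
  pgs <- all.vars(rhs)
  if (!length(pgs)) stop_configuration("no score columns in formula")
  list(outcome = outcome, pgs = pgs, group = group)
}

# Shared by corcompare() and the CLI: samples are already preprocessed.
fit_corcompare <- function(samples, method = "parametric", hypotheses = NULL,
                           plan = resampling_plan(), call = NULL) {
  P <- length(samples[[1L]]$pgs_names)
  K <- length(samples)
  if (is.null(hypotheses)) {
    hypotheses <- c(if (P >= 2L) "within",
                    if (K >= 2L) c("between", "interaction"))
    if (is.null(hypotheses)) {
      stop_validation("nothing to test: a single score in a single population")
    }
  }
  state <- if (method == "parametric") {
    assemble_joint(samples)
  } else {
    bootstrap_cov(samples, plan)
  }
  flags <- check_positive_correlations(state, warn = TRUE)
  tests <- lapply(hypotheses, function(h) {
    if (method == "permutation") {
      permutation_pvalue(samples, h, plan)
    } else {
      glh_test(state, build_contrast(h, P = P, K = K))
    }
  })
  names(tests) <- hypotheses
  corr <- lapply(samples, function(s) stats::cor(cbind(y = s$y, s$X)))
  names(corr) <- vapply(samples, `[[`, character(1L), "label")
  structure(
    list(samples = samples, state = state, tests = tests, corr = corr,
         ns = state$ns, method = method, flags = flags,
         plan = if (method != "parametric") plan else NULL, call = call),
    class = "corcompare")
}

#' @export
print.corcompare <- function(x, digits = 4, ...) {
  cat("Correlation-based polygenic score comparison\n")
  if (!is.null(x$call)) {
    cat("Call: "); print(x$call)
  }
  cat(sprintf("%d score(s), %d population(s) (n = %s), %s covariance\n\n",
              x$state$P, x$state$K, paste(x$ns, collapse = ", "), x$method))
  cat("Score-outcome correlations:\n")
  print(round(coef(x), digits))
  cat("\nTests:\n")
  print(summary_table(x), digits = digits)
  if (length(x$flags)) {
    cat("\nFlags:\n"); cat(paste0("  ", x$flags, collapse = "\n"), "\n")
  }
  invisible(x)
}

summary_table <- function(x) {
  data.frame(
    hypothesis = names(x$tests),
    statistic = vapply(x$tests, `[[`, numeric(1L), "statistic"),
    df = vapply(x$tests, `[[`, numeric(1L), "df"),
    p_value = vapply(x$tests, `[[`, numeric(1L), "p_value"),
    method = vapply(x$tests, `[[`, character(1L), "method"),
    row.names = NULL)
}

#' Summarize a correlation comparison
#'
#' @param object A `corcompare` fit.
#' @param level Confidence level for the per-correlation intervals.
#' @param ... Unused.
#' @return An object of class `summary.corcompare` with the correlation
#'   matrix, per-correlation standard errors and normal-theory intervals,
#'   the test table and sample sizes.
#' @export
summary.corcompare <- function(object, level = 0.95, ...) {
  se <- sqrt(diag(object$state$Sigma))
  z <- stats::qnorm((1 + level) / 2)
  est <- data.frame(
    correlation = names(object$state$u),
    estimate = unname(object$state$u),
    se = unname(se),
    lower = unname(object$state$u - z * se),
    upper = unname(object$state$u + z * se),
    row.names = NULL)
  structure(list(coef = coef(object), estimates = est,
                 tests = summary_table(object), ns = object$ns,
                 method = object$method, flags = object$flags, level = level),
            class = "summary.corcompare")
}

#' @export
print.summary.corcompare <- function(x, digits = 4, ...) {
  cat(sprintf("Score-outcome correlations (%s covariance; n = %s):\n",
              x$method, paste(x$ns, collapse = ", ")))
  print(round(x$coef, digits))
  cat(sprintf("\nEstimates with %g%% normal-theory intervals:\n", 100 * x$level))
  ests <- x$estimates
  ests[-1L] <- round(ests[-1L], digits)
  print(ests, row.names = FALSE)
  cat("\nTests:\n")
  print(x$tests, digits = digits, row.names = FALSE)
  if (length(x$flags)) {
    cat("\nFlags:\n"); cat(paste0("  ", x$flags, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' @describeIn corcompare P x K matrix of score-outcome correlations.
#' @param object,x A `corcompare` fit.
#' @param ... Passed on or ignored.
#' @export
coef.corcompare <- function(object, ...) coef(object$state)

#' @describeIn corcompare Covariance matrix of the stacked correlations.
#' @export
vcov.corcompare <- function(object, ...) object$state$Sigma

#' Confidence intervals for pairwise correlation differences
#'
#' Normal-theory intervals for differences between entries of the stacked
#' correlation vector, using the fitted covariance (see
#' [pairwise_difference_ci()]).
#'
#' @param object A `corcompare` fit.
#' @param parm Optional 2-column matrix (or list of length-2 vectors) of
#'   index pairs into the stacked correlation vector; default all pairs.
#' @param level Confidence level.
#' @param ... Unused.
#' @return Data frame with one row per pair: the two entry names, the
#'   difference and its interval.
#' @export
confint.corcompare <- function(object, parm = NULL, level = 0.95, ...) {
  u <- object$state$u
  if (is.null(parm)) {
    parm <- t(utils::combn(length(u), 2L))
  } else if (is.list(parm)) {
    parm <- do.call(rbind, parm)
  }
  parm <- as.matrix(parm)
  out <- do.call(rbind, lapply(seq_len(nrow(parm)), function(i) {
    ci <- pairwise_difference_ci(object$state, parm[i, 1L], parm[i, 2L],
                                 level = level)
    data.frame(a = names(u)[parm[i, 1L]], b = names(u)[parm[i, 2L]],
               difference = ci[["difference"]], lower = ci[["lower"]],
               upper = ci[["upper"]])
  }))
  out
}

#' Plot score-outcome correlations by population
#'
#' Grouped bar plot of the estimated correlations with normal-theory error
#' bars, one group of bars per population.
#'
#' @param x A `corcompare` fit.
#' @param level Confidence level for the error bars.
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, the bar midpoints.
#' @export
plot.corcompare <- function(x, level = 0.95, ...) {
  est <- coef(x)
  se <- matrix(sqrt(diag(x$state$Sigma)), x$state$P, x$state$K)
  z <- stats::qnorm((1 + level) / 2)
  mids <- graphics::barplot(est, beside = TRUE, legend.text = rownames(est),
                            ylab = "correlation with outcome",
                            xlab = "population",
                            ylim = range(0, est + z * se, est - z * se), ...)
  graphics::arrows(mids, est - z * se, mids, est + z * se,
                   angle = 90, code = 3, length = 0.03)
  invisible(mids)
}

#' Simulate new datasets from a fitted comparison
#'
#' Draws multivariate-normal datasets with each population's plug-in
#' correlation structure (outcome and scores jointly) at the fitted sample
#' sizes — a parametric-bootstrap companion to the asymptotic tests.
#'
#' @param object A `corcompare` fit.
#' @param nsim Number of datasets.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A list of length `nsim`; each element is a list of [pop_sample]
#'   objects (one per population).
#' @export
simulate.corcompare <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  pops <- names(object$corr)
  lapply(seq_len(nsim), function(i) {
    ss <- lapply(seq_along(pops), function(k) {
      simulate_population(object$corr[[k]], object$ns[k], label = pops[k])
    })
    names(ss) <- pops
    ss
  })
}
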