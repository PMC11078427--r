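#' Construct a population sample
#'
#' Bundles the quantitative outcome and the matrix of per-individual polygenic
#' scores for one population group. This is the elementary unit consumed by
#' [assemble_joint()], [bootstrap_cov()] and the fitting function
#' [corcompare()].
#'
#' @param label Population-group identifier (length-1 character).
#' @param y Numeric outcome vector of length `n`.
#' @param X Numeric matrix (`n` rows, one column per polygenic score).
#' @param pgs_names Optional character vector of score names; defaults to the
#'   column names of `X` (or `PGS1, PGS2, ...`).
#' @return An object of class `pop_sample`: a list with elements `label`,
#'   `y`, `X`, `pgs_names` and `n`.
#' @examples
#' s <- pop_sample("EUR", rnorm(50), matrix(rnorm(100), 50, 2))
#' s$n
#' @export
pop_sample <- function(label, y, X, pgs_names = NULL) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (length(y) != nrow(X)) {
    stop_validation("length of y must equal the number of rows of X")
  }
  if (anyNA(y) || anyNA(X)) {
    stop_validation("pop_sample does not accept missing values; filter first")
  }
  n <- length(y)
  if (n < 2L) {
    stop_validation(sprintf("population '%s' has n < 2 after filtering", label))
  }
  pgs_names <- pgs_names %||% colnames(X) %||% paste0("PGS", seq_len(ncol(X)))
  if (anyDuplicated(pgs_names)) {
    stop_validation("pgs_names must be unique")
  }
  if (stats::var(y) <= 0) {
    stop_validation(sprintf("outcome has zero variance in population '%s'", label))
  }
  v <- apply(X, 2L, stats::var)
  if (any(v <= 0)) {
    stop_validation(sprintf(
      "zero-variance score column(s) in population '%s': %s",
      label, paste(pgs_names[v <= 0], collapse = ", ")))
  }
  colnames(X) <- pgs_names
  structure(
    list(label = as.character(label), y = y, X = X,
         pgs_names = pgs_names, n = n),
    class = "pop_sample")
}

#' @export
print.pop_sample <- function(x, ...) {
  cat(sprintf("Population sample '%s': n = %d, %d score(s) [%s]\n",
              x$label, x$n, length(x$pgs_names),
              paste(x$pgs_names, collapse = ", ")))
  invisible(x)
}

#' Read a per-individual score table
#'
#' Reads a delimited text file (CSV or TSV, delimiter auto-detected from the
#' header line unless given) with one row per individual, checks that the
#' named columns exist and are numeric, and applies complete-case filtering
#' over the used columns.
#'
#' @param path Path to the delimited file (with header).
#' @param outcome_col Name of the quantitative outcome column.
#' @param group_col Name of the population-group column, or `NULL` for a
#'   single-population table.
#' @param pgs_cols Character vector of polygenic-score column names.
#' @param covariate_cols Optional character vector of covariate column names
#'   (e.g. genetic principal components).
#' @param delim Field delimiter; `NULL` (default) auto-detects tab vs comma.
#' @return A `data.frame` restricted to the used columns with complete cases;
#'   the number of dropped rows is stored in attribute `"n_dropped"`.
#' @seealso [as_pop_samples()] to convert into `pop_sample` objects with
#'   preprocessing applied.
#' @export
read_pgs_table <- function(path, outcome_col, group_col = NULL, pgs_cols,
                           covariate_cols = NULL, delim = NULL) {
  if (!file.exists(path)) {
    stop_configuration(sprintf("input file not found: %s", path))
  }
  if (is.null(delim)) {
    header <- readLines(path, n = 1L)
    delim <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          stringsAsFactors = FALSE, check.names = FALSE)
  used <- c(outcome_col, group_col, pgs_cols, covariate_cols)
  missing_cols <- setdiff(used, names(df))
  if (length(missing_cols)) {
    stop_configuration(sprintf("column(s) not found in %s: %s",
                               path, paste(missing_cols, collapse = ", ")))
  }
  for (cl in c(outcome_col, pgs_cols, covariate_cols)) {
    if (!is.numeric(df[[cl]])) {
      stop_configuration(sprintf("column '%s' must be numeric", cl))
    }
  }
  df <- df[, used, drop = FALSE]
  keep <- stats::complete.cases(df)
  out <- df[keep, , drop = FALSE]
  attr(out, "n_dropped") <- sum(!keep)
  if (sum(!keep) > 0) {
    message(sprintf("Dropped %d row(s) with missing values (complete-case).",
                    sum(!keep)))
  }
  out
}

#' Split a table into preprocessed population samples
#'
#' Partitions a per-individual table by group label and applies the standard
#' preprocessing used for polygenic-score evaluation: optional inverse-rank
#' normalization of the outcome (applied once, before grouping), then optional
#' residualization of the outcome and of each score on the covariates by
#' linear regression within each group.
#'
#' @inheritParams read_pgs_table
#' @param data A data frame (e.g. from [read_pgs_table()]).
#' @param int Logical; inverse-rank normalize the outcome first.
#' @return A list of [pop_sample] objects, ordered by first appearance of the
#'   group labels (factor levels are respected if `group_col` is a factor).
#' @export
as_pop_samples <- function(data, outcome_col, group_col = NULL, pgs_cols,
                           covariate_cols = NULL, int = FALSE) {
  used <- c(outcome_col, group_col, pgs_cols, covariate_cols)
  missing_cols <- setdiff(used, names(data))
  if (length(missing_cols)) {
    stop_configuration(sprintf("column(s) not found: %s",
                               paste(missing_cols, collapse = ", ")))
  }
  data <- data[stats::complete.cases(data[, used, drop = FALSE]), , drop = FALSE]
  if (int) {
    data[[outcome_col]] <- inverse_rank_normalize(data[[outcome_col]])
  }
  if (is.null(group_col)) {
    groups <- factor(rep("all", nrow(data)))
  } else {
    g <- data[[group_col]]
    groups <- if (is.factor(g)) droplevels(g) else factor(g, levels = unique(g))
  }
  lapply(levels(groups), function(lv) {
    rows <- which(groups == lv)
    if (length(rows) < 2L) {
      stop_validation(sprintf(
        "population '%s' has fewer than 2 complete rows", lv))
    }
    y <- data[[outcome_col]][rows]
    X <- as.matrix(data[rows, pgs_cols, drop = FALSE])
    if (length(covariate_cols)) {
      C <- as.matrix(data[rows, covariate_cols, drop = FALSE])
      y <- residualize(y, C)
      X <- apply(X, 2L, residualize, C = C)
    }
    pop_sample(lv, y, X, pgs_names = pgs_cols)
  })
}

#' Write population samples back to a delimited table
#'
#' Serializes a list of [pop_sample] objects to a TSV for audit; reading the
#' file back with [read_pgs_table()] + [as_pop_samples()] (no preprocessing)
#' reproduces the samples.
#'
#' @param samples List of [pop_sample] objects.
#' @param path Output file path.
#' @param group_col,outcome_col Column names used in the output header.
#' @return `path`, invisibly.
#' @export
write_samples <- function(samples, path, group_col = "population",
                          outcome_col = "outcome") {
  tabs <- lapply(samples, function(s) {
    out <- data.frame(group = s$label, outcome = s$y, check.names = FALSE)
    names(out) <- c(group_col, outcome_col)
    cbind(out, as.data.frame(s$X))
  })
  tab <- do.call(rbind, tabs)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Standardize a vector to mean 0 and standard deviation 1
#'
#' Uses the sample standard deviation (denominator `n - 1`). Pearson
#' correlations are unaffected by this rescaling.
#'
#' @param v Numeric vector, length >= 2, with positive variance.
#' @return Numeric vector with sample mean 0 and sample sd 1.
#' @export
standardize <- function(v) {
  v <- as.numeric(v)
  if (length(v) < 2L) stop_validation("standardize needs length >= 2")
  s <- stats::sd(v)
  if (!is.finite(s) || s <= 0) {
    stop_validation("cannot standardize a constant (zero-variance) vector")
  }
  (v - mean(v)) / s
}

#' Residualize a vector on covariates
#'
#' Returns the residuals of the least-squares regression of `v` on an
#' intercept plus the columns of `C`. With `C` empty this is mean-centering.
#' Residuals are orthogonal to the intercept and to every covariate column.
#'
#' @param v Numeric vector.
#' @param C Covariate matrix with `length(v)` rows, or `NULL`/zero columns.
#' @return Residual vector of the same length as `v`.
#' @export
residualize <- function(v, C = NULL) {
  v <- as.numeric(v)
  if (is.null(C) || NCOL(C) == 0L || length(C) == 0L) {
    return(v - mean(v))
  }
  C <- as.matrix(C)
  if (nrow(C) != length(v)) {
    stop_validation("nrow(C) must equal length(v)")
  }
  D <- cbind(`(Intercept)` = 1, C)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    dropped <- colnames(D)[qrD$pivot[seq.int(qrD$rank + 1L, ncol(D))]]
    stop_validation(sprintf(
      "covariate design is rank-deficient; collinear column(s): %s",
      paste(dropped, collapse = ", ")))
  }
  as.numeric(qr.resid(qrD, v))
}

#' Inverse-rank normalization
#'
#' Maps values to normal quantiles through their ranks:
#' `qnorm((rank - c) / (n - 2c + 1))` with the Blom offset `c = 3/8` by
#' default. Ties receive average ranks (tied inputs map to equal outputs) and
#' the transform is monotone in `v`.
#'
#' @param v Numeric vector, length >= 2.
#' @param offset Rank offset constant `c`; default `3/8` (Blom).
#' @return Numeric vector of normal scores.
#' @export
inverse_rank_normalize <- function(v, offset = 3 / 8) {
  v <- as.numeric(v)
  n <- length(v)
  if (n < 2L) stop_validation("inverse_rank_normalize needs length >= 2")
  r <- rank(v, ties.method = "average")
  stats::qnorm((r - offset) / (n - 2 * offset + 1))
}
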