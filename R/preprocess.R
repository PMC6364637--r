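# Deterministic column transforms with refittable records, so that
# cross-validation can re-apply training-fold statistics to held-out data
# without leakage.

.new_record <- function(transform, constants) {
  structure(list(transform = transform, constants = constants),
            class = "lncass_transform_record")
}

#' @export
print.lncass_transform_record <- function(x, ...) {
  cat(sprintf("<transform record> %s over %d columns\n", x$transform,
              ncol(x$constants)))
  invisible(x)
}

#' Elementwise log(1 + x) transform
#'
#' Used when predictors span several orders of magnitude. All entries must
#' be non-negative.
#'
#' @param X Numeric matrix.
#' @return Transformed matrix.
#' @export
log1p_columns <- function(X) {
  X <- as.matrix(X)
  bad <- which(X < 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("log1p requires non-negative entries; first violation at row %d, column %d",
                 bad[1, 1], bad[1, 2]))
  log1p(X)
}

#' Scale columns to the unit interval
#'
#' Fits `(x - min) / (max - min)` per column, or re-applies a stored
#' record's min/max to new data, clamping out-of-range values into `[0, 1]`
#' (the number of clamped entries is returned).
#'
#' @param X Numeric matrix.
#' @param record Optional `lncass_transform_record` from a previous fit.
#' @return List with `X` (transformed), `record`, `n_clamped`.
#' @export
scale_unit_interval <- function(X, record = NULL) {
  X <- as.matrix(X)
  if (is.null(record)) {
    mins <- apply(X, 2, min); maxs <- apply(X, 2, max)
    const <- which(maxs - mins == 0)
    if (length(const))
      stop("constant column(s) at fit time: ",
           paste(utils::head(const, 5), collapse = ", "))
    record <- .new_record("unit_interval", rbind(min = mins, max = maxs))
  } else {
    stopifnot(inherits(record, "lncass_transform_record"),
              record$transform == "unit_interval")
  }
  mins <- record$constants["min", ]; maxs <- record$constants["max", ]
  out <- sweep(sweep(X, 2, mins, "-"), 2, maxs - mins, "/")
  n_clamped <- sum(out < 0 | out > 1)
  if (n_clamped > 0) {
    warning(n_clamped, " value(s) outside the training range were clamped to [0, 1]")
    out <- pmin(pmax(out, 0), 1)
  }
  list(X = out, record = record, n_clamped = n_clamped)
}

#' Standardize columns (z-score)
#'
#' Fits per-column mean and standard deviation (denominator `n - 1`), or
#' re-applies a stored record's constants to new data.
#'
#' @param X Numeric matrix.
#' @param record Optional `lncass_transform_record` from a previous fit.
#' @return List with `X` (transformed) and `record`.
#' @export
standardize_columns <- function(X, record = NULL) {
  X <- as.matrix(X)
  if (is.null(record)) {
    mu <- colMeans(X)
    sd_ <- apply(X, 2, stats::sd)
    zero <- which(sd_ == 0)
    if (length(zero))
      stop("zero-variance column(s) at fit time: ",
           paste(utils::head(zero, 5), collapse = ", "))
    record <- .new_record("standardize", rbind(mean = mu, sd = sd_))
  } else {
    stopifnot(inherits(record, "lncass_transform_record"),
              record$transform == "standardize")
  }
  out <- sweep(sweep(X, 2, record$constants["mean", ], "-"), 2,
               record$constants["sd", ], "/")
  list(X = out, record = record)
}

#' Serialize / restore a transform record as CSV
#'
#' @param record `lncass_transform_record`.
#' @param path CSV path.
#' @export
write_transform_record <- function(record, path) {
  stopifnot(inherits(record, "lncass_transform_record"))
  df <- as.data.frame(t(record$constants))
  df <- cbind(column = rownames(df), transform = record$transform, df)
  utils::write.csv(format(df, digits = 17), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_transform_record
#' @export
read_transform_record <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  transform <- df$transform[1]
  keep <- setdiff(names(df), c("column", "transform"))
  constants <- t(as.matrix(df[, keep, drop = FALSE]))
  colnames(constants) <- df$column
  .new_record(transform, constants)
}

# ridge-guarded Newton fits of univariate logistic regressions. The
# unit-scale ridge acts like a N(0, 1) prior precision on each coefficient:
# under perfect separation the slope stops at a large finite value whose
# curvature is dominated by the penalty, so |Z| stays large and finite
# instead of degenerating (a vanishing ridge sends the standard error to
# 1/sqrt(ridge) and the Z of a separating predictor to ~0).
.univariate_wald_z <- function(X, y, ridge = 1, max_iter = 50) {
  p <- ncol(X); n <- nrow(X)
  z_scores <- numeric(p)
  for (j in seq_len(p)) {
    xj <- X[, j]
    b <- c(0, 0)   # intercept, slope
    for (it in seq_len(max_iter)) {
      eta <- b[1] + b[2] * xj
      mu <- sigm(eta)
      wgt <- pmax(mu * (1 - mu), 1e-10)
      g <- c(sum(y - mu) - ridge * b[1], sum((y - mu) * xj) - ridge * b[2])
      H <- matrix(c(sum(wgt) + ridge, sum(wgt * xj),
                    sum(wgt * xj), sum(wgt * xj^2) + ridge), 2, 2)
      step <- solve(H, g)
      b <- b + step
      if (max(abs(step)) < 1e-10) break
    }
    eta <- b[1] + b[2] * xj
    wgt <- pmax(sigm(eta) * (1 - sigm(eta)), 1e-10)
    H <- matrix(c(sum(wgt) + ridge, sum(wgt * xj),
                  sum(wgt * xj), sum(wgt * xj^2) + ridge), 2, 2)
    se <- sqrt(solve(H)[2, 2])
    z_scores[j] <- b[2] / se
  }
  z_scores
}

#' Univariate Wald screen
#'
#' Fits a univariate logistic regression (intercept + one predictor) per
#' predictor and ranks predictors by `|Z| = |coefficient / standard
#' error|`, returning the top `k`. Fits carry a unit-scale ridge penalty
#' (equivalent to a standard-normal prior on each coefficient) so perfectly
#' separating predictors receive a large finite `|Z|` instead of a
#' degenerate fit. Ties are broken by lower column index.
#'
#' @param data Binomial `lncass_dataset`.
#' @param k Number of predictors to keep (`k <= p`).
#' @return Data frame with `index`, `predictor`, `z` sorted by `|z|`
#'   descending.
#' @export
wald_screen <- function(data, k) {
  stopifnot(inherits(data, "lncass_dataset"))
  if (data$family != "binomial")
    stop("the Wald screen applies to binomial datasets")
  if (k < 1 || k > data$p) stop("k must be between 1 and ", data$p)
  z <- .univariate_wald_z(data$X, data$y)
  ord <- order(-abs(z), seq_along(z))
  top <- ord[seq_len(k)]
  data.frame(index = top, predictor = data$predictor_names[top], z = z[top],
             row.names = NULL)
}
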