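#' Regression dataset container
#'
#' Bundles a numeric design matrix, a response vector, the model family and
#' predictor names, with validation. The linear model is
#' `y_i = beta0 + X_i beta + eps_i` (gaussian family) or a Bernoulli
#' response with logit link (binomial family).
#'
#' @param X Numeric matrix, rows = observations, no missing values.
#' @param y Response vector: real for `"gaussian"`, 0/1 for `"binomial"`.
#' @param family `"gaussian"` or `"binomial"`.
#' @param predictor_names Optional character vector of length `ncol(X)`;
#'   defaults to `colnames(X)` or `x1..xp`.
#' @return Object of class `lncass_dataset`.
#' @export
regression_dataset <- function(X, y, family = c("gaussian", "binomial"),
                               predictor_names = NULL) {
  family <- match.arg(family)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (anyNA(X) || anyNA(y))
    stop("missing values are not supported; impute upstream before model fitting")
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  if (nrow(X) < 2) stop("need at least 2 observations")
  if (ncol(X) < 1) stop("need at least 1 predictor")
  if (family == "binomial" && !all(y %in% c(0, 1)))
    stop("binomial response must be coded 0/1")
  if (is.null(predictor_names)) {
    predictor_names <- colnames(X)
    if (is.null(predictor_names)) predictor_names <- paste0("x", seq_len(ncol(X)))
  }
  stopifnot(length(predictor_names) == ncol(X))
  colnames(X) <- predictor_names
  structure(
    list(X = X, y = y, family = family, predictor_names = predictor_names,
         n = nrow(X), p = ncol(X)),
    class = "lncass_dataset"
  )
}

#' @export
print.lncass_dataset <- function(x, ...) {
  cat(sprintf("<lncass_dataset> %d observations x %d predictors, family = %s\n",
              x$n, x$p, x$family))
  invisible(x)
}

#' Group structure over predictors
#'
#' Partition of the predictors into named groups for the grouped LN-CASS
#' prior, under which whole groups are excluded first, then included with a
#' shared coefficient, and only then allowed member-specific deviations.
#'
#' @param assignment Character (or factor) vector, one group label per
#'   predictor, in predictor order.
#' @return Object of class `lncass_groups` with fields `assignment`,
#'   `groups` (distinct labels in first-appearance order), `index` (list of
#'   member indices per group).
#' @export
group_structure <- function(assignment) {
  assignment <- as.character(assignment)
  if (length(assignment) < 1) stop("assignment must cover at least one predictor")
  if (anyNA(assignment)) stop("every predictor must be assigned to a group")
  groups <- unique(assignment)
  index <- lapply(groups, function(g) which(assignment == g))
  if (any(lengths(index) == 0)) stop("groups with zero members are not allowed")
  structure(list(assignment = assignment, groups = groups, index = index),
            class = "lncass_groups")
}

#' Read a predictor-to-group map from a two-column CSV
#'
#' The file must have a header and two columns: predictor name, group label.
#' Predictors of `data` not present in the file, or file rows naming unknown
#' predictors, are errors.
#'
#' @param path CSV path.
#' @param data `lncass_dataset` whose predictors the map must cover.
#' @return `lncass_groups` in the dataset's predictor order.
#' @export
read_group_map <- function(path, data) {
  stopifnot(inherits(data, "lncass_dataset"))
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("group map must have two columns: predictor, group")
  pred <- as.character(tab[[1]]); grp <- as.character(tab[[2]])
  unknown <- setdiff(pred, data$predictor_names)
  if (length(unknown))
    stop("group map names unknown predictors: ", paste(unknown, collapse = ", "))
  missing <- setdiff(data$predictor_names, pred)
  if (length(missing))
    stop("group map is missing predictors: ", paste(missing, collapse = ", "))
  group_structure(grp[match(data$predictor_names, pred)])
}

#' GAM basis configuration
#'
#' Knot layout for the piecewise-linear (hinge) basis expansion used by the
#' hierarchical GAM. Default: `n_knots` knots equally spaced at
#' `k / (n_knots + 1)` in (0, 1).
#'
#' @param n_knots Number of interior knots per covariate (>= 0; 0 gives a
#'   purely linear model).
#' @param knot_positions Optional strictly increasing values in (0, 1);
#'   overrides the equal spacing.
#' @return Object of class `lncass_gam_config`.
#' @export
gam_config <- function(n_knots = 5, knot_positions = NULL) {
  stopifnot(is.numeric(n_knots), length(n_knots) == 1, n_knots >= 0)
  n_knots <- as.integer(n_knots)
  if (is.null(knot_positions)) {
    knot_positions <- if (n_knots > 0) seq_len(n_knots) / (n_knots + 1) else numeric(0)
  } else {
    knot_positions <- as.numeric(knot_positions)
    if (length(knot_positions) != n_knots)
      stop("knot_positions length must equal n_knots")
    if (n_knots > 0) {
      if (any(diff(knot_positions) <= 0)) stop("knots must be strictly increasing")
      if (any(knot_positions <= 0 | knot_positions >= 1))
        stop("knots must be interior to [0, 1]")
    }
  }
  structure(list(n_knots = n_knots, knot_positions = knot_positions),
            class = "lncass_gam_config")
}

#' Read a design matrix + response from delimited text
#'
#' Expects a header row; the response column is named by `response`; an
#' optional first id column (non-numeric) is dropped. Separator inferred
#' from the extension (`.tsv` = tab, otherwise comma).
#'
#' @param path CSV/TSV path.
#' @param response Name of the response column.
#' @param family Model family tag for the resulting dataset.
#' @return `lncass_dataset`.
#' @export
read_regression_csv <- function(path, response = "y",
                                family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!response %in% names(tab))
    stop("response column '", response, "' not found in ", path)
  y <- tab[[response]]
  tab[[response]] <- NULL
  non_num <- !vapply(tab, is.numeric, logical(1))
  if (any(non_num)) {
    if (non_num[1] && sum(non_num) == 1) tab[[1]] <- NULL  # id column
    else stop("non-numeric predictor columns: ",
              paste(names(tab)[non_num], collapse = ", "))
  }
  regression_dataset(as.matrix(tab), y, family = family,
                     predictor_names = names(tab))
}
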