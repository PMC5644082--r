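#' Threshold effect families
#'
#' A threshold family describes what happens to the mean function at the
#' change point `e` of the thresholded predictor `x`:
#'
#' * `step`: the mean jumps by `beta1` at `e`, via the indicator `I(x > e)`;
#'   flat on either side.
#' * `hinge`: flat below `e`, linear with slope `beta1` above, via the hinge
#'   function `(x - e)+`; continuous at `e`.
#' * `segmented`: slope `gamma` below `e` and `gamma + beta1` above;
#'   continuous at `e`.
#' * `stegmented`: segmented plus a jump `beta2` at `e` (a fusion of the step
#'   and segmented forms); discontinuous.
#'
#' The family determines `p`, the number of threshold-dependent design
#' columns (`p = 2` for stegmented, `p = 1` otherwise), and whether the raw
#' predictor `x` enters the model linearly (`gamma` term, segmented and
#' stegmented only).
#'
#' @param name one of `"step"`, `"hinge"`, `"segmented"`, `"stegmented"`.
#' @return an object of class `threshold_family` with elements `name`, `p`
#'   and `includes_linear_x`.
#' @examples
#' threshold_family("stegmented")$p  # 2
#' @export
threshold_family <- function(name = c("step", "hinge", "segmented", "stegmented")) {
  name <- match.arg(name)
  structure(
    list(
      name = name,
      p = if (name == "stegmented") 2L else 1L,
      includes_linear_x = name %in% c("segmented", "stegmented")
    ),
    class = "threshold_family"
  )
}

#' @export
print.threshold_family <- function(x, ...) {
  cat(sprintf(
    "threshold family '%s' (p = %d, linear x term: %s)\n",
    x$name, x$p, if (x$includes_linear_x) "yes" else "no"
  ))
  invisible(x)
}

#' Specify a threshold regression model
#'
#' Binds the column names of a dataset to the roles of a threshold
#' regression model: the outcome `y`, the thresholded predictor `x`, and
#' zero or more adjustment covariates `z` that enter linearly and are not
#' subjected to thresholding.
#'
#' @param outcome name of the outcome column. Must hold values in
#'   `{0, 1}` under the logistic link.
#' @param x name of the continuous predictor subjected to thresholding.
#' @param z character vector of adjustment covariate column names (may be
#'   empty).
#' @param family a [threshold_family()] or its name.
#' @param link `"logistic"` for binary outcomes, `"linear"` for continuous.
#' @return an object of class `threshold_spec`.
#' @examples
#' threshold_spec("y", "x", z = "z", family = "hinge", link = "logistic")
#' @export
threshold_spec <- function(outcome, x, z = character(),
                           family = c("step", "hinge", "segmented", "stegmented"),
                           link = c("logistic", "linear")) {
  if (is.character(family)) family <- threshold_family(family)
  stopifnot(inherits(family, "threshold_family"))
  link <- match.arg(link)
  cols <- c(outcome, x, z)
  if (anyDuplicated(cols)) {
    stop("outcome, x and z must name distinct columns", call. = FALSE)
  }
  structure(
    list(outcome = outcome, x = x, z = as.character(z),
         family = family, link = link),
    class = "threshold_spec"
  )
}

#' @export
print.threshold_spec <- function(x, ...) {
  cat(sprintf(
    "threshold model spec: %s ~ threshold(%s; %s)%s, link = %s\n",
    x$outcome, x$x, x$family$name,
    if (length(x$z)) paste0(" + ", paste(x$z, collapse = " + ")) else "",
    x$link
  ))
  invisible(x)
}

#' Threshold-dependent design columns
#'
#' Builds the `n x p` block of design columns that depend on the candidate
#' threshold `e`: `I(x > e)` for the step family, the hinge `(x - e)+` for
#' hinge and segmented, and both (hinge column first) for stegmented.
#' The indicator is strict: ties `x == e` contribute 0, so entries are
#' exactly 0 wherever `x <= e`.
#'
#' @param x numeric vector of predictor values (finite).
#' @param e candidate threshold, finite scalar.
#' @param family a [threshold_family()] or its name.
#' @return numeric matrix with `family$p` columns.
#' @examples
#' threshold_columns(c(5, 8), 7.4, "hinge")      # 0 and 0.6
#' threshold_columns(c(5, 8), 7.4, "stegmented") # cbind(c(0, .6), c(0, 1))
#' @export
threshold_columns <- function(x, e, family) {
  if (is.character(family)) family <- threshold_family(family)
  if (!length(x)) stop("x must be non-empty", call. = FALSE)
  if (!all(is.finite(x))) {
    stop("non-finite values in thresholded predictor", call. = FALSE)
  }
  if (!is.finite(e) || length(e) != 1L) {
    stop("threshold e must be a finite scalar", call. = FALSE)
  }
  ind <- as.numeric(x > e)
  switch(family$name,
    step = matrix(ind, ncol = 1L, dimnames = list(NULL, "I(x>e)")),
    hinge = ,
    segmented = matrix((x - e) * ind, ncol = 1L,
                       dimnames = list(NULL, "(x-e)+")),
    stegmented = cbind(`(x-e)+` = (x - e) * ind, `I(x>e)` = ind)
  )
}

#' Design matrices for a fixed candidate threshold
#'
#' Splits the design of a threshold model at fixed `e` into the
#' threshold-independent block `Z` and the threshold-dependent block `X`.
#' Column order is fixed: `Z = [intercept, z..., x]` (the raw `x` column is
#' present only for segmented/stegmented families) and
#' `X = threshold_columns(x, e, family)`.
#'
#' @param data data frame containing the spec's columns, already validated
#'   (no missing values in used columns).
#' @param spec a [threshold_spec()].
#' @param e candidate threshold.
#' @return list with elements `Z`, `X` (matrices) and `y` (outcome vector).
#' @export
build_design <- function(data, spec, e) {
  stopifnot(inherits(spec, "threshold_spec"))
  used <- c(spec$outcome, spec$x, spec$z)
  missing_cols <- setdiff(used, names(data))
  if (length(missing_cols)) {
    stop("columns missing from data: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  x <- data[[spec$x]]
  if (length(unique(x)) < 2L) {
    stop("thresholded predictor '", spec$x, "' is constant", call. = FALSE)
  }
  Z <- cbind(`(Intercept)` = rep(1, nrow(data)))
  if (length(spec$z)) {
    zm <- as.matrix(data[spec$z])
    storage.mode(zm) <- "double"
    Z <- cbind(Z, zm)
  }
  if (spec$family$includes_linear_x) {
    Z <- cbind(Z, x)
    colnames(Z)[ncol(Z)] <- spec$x
  }
  list(Z = Z, X = threshold_columns(x, e, spec$family), y = data[[spec$outcome]])
}

# Validate the raw columns once per dataset: numeric x/z, binary outcome
# under the logistic link, complete cases only (drop count reported).
validate_data <- function(data, spec, quiet = FALSE) {
  used <- c(spec$outcome, spec$x, spec$z)
  missing_cols <- setdiff(used, names(data))
  if (length(missing_cols)) {
    stop("columns missing from data: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (cl in c(spec$x, spec$z)) {
    if (!is.numeric(data[[cl]])) {
      stop("column '", cl, "' must be numeric", call. = FALSE)
    }
  }
  keep <- stats::complete.cases(data[used])
  dropped <- sum(!keep)
  if (dropped > 0L) {
    if (!quiet) message(dropped, " row(s) with missing values dropped")
    data <- data[keep, , drop = FALSE]
  }
  y <- data[[spec$outcome]]
  if (!is.numeric(y)) stop("outcome must be numeric", call. = FALSE)
  if (spec$link == "logistic" && !all(y %in% c(0, 1))) {
    stop("logistic link requires outcome values in {0, 1}", call. = FALSE)
  }
  if (!all(is.finite(data[[spec$x]]))) {
    stop("non-finite values in thresholded predictor", call. = FALSE)
  }
  attr(data, "n_dropped") <- dropped
  data
}
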