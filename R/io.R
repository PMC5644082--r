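#' Read a delimited data file for threshold modelling
#'
#' Reads a CSV (or TSV, by extension `.tsv`/`.tab`/`.txt`) file with a
#' header row. When a [threshold_spec()] is supplied, the used columns are
#' validated: `x` and `z` must be numeric, the outcome must be 0/1 under the
#' logistic link, and rows with missing values in used columns are dropped
#' with a reported count (attached as attribute `n_dropped`).
#'
#' @param path file path.
#' @param spec optional [threshold_spec()] to validate against.
#' @return a data frame.
#' @export
read_table <- function(path, spec = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.(tsv|tab|txt)$", path, ignore.case = TRUE)) "\t" else ","
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  if (!is.null(spec)) d <- validate_data(d, spec)
  d
}

#' Write a fit record to JSON
#'
#' Serializes a `threshold_fit` (and optionally its confidence intervals) as
#' a machine-readable JSON record: model spec, search method, threshold and
#' coefficient estimates, log-likelihood, convergence flag, seed and package
#' version. The profile trace can be written alongside as TSV, which is the
#' input for a likelihood-versus-candidate plot.
#'
#' @param fit a `threshold_fit`.
#' @param path output JSON path.
#' @param intervals optional `interval_set` to embed.
#' @param seed optional seed to record for provenance.
#' @param profile_path optional TSV path for the profile trace.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path, intervals = NULL, seed = NULL,
                      profile_path = NULL) {
  stopifnot(inherits(fit, "threshold_fit"))
  rec <- list(
    package = "thresholdreg",
    version = as.character(utils::packageVersion("thresholdreg")),
    spec = list(outcome = fit$spec$outcome, x = fit$spec$x, z = fit$spec$z,
                family = fit$spec$family$name, link = fit$spec$link),
    method = fit$method,
    n = fit$n,
    e = fit$e,
    coefficients = as.list(fit$coefficients),
    loglik = fit$loglik,
    converged = fit$converged,
    seed = seed,
    intervals = if (!is.null(intervals)) {
      list(method = intervals$method, level = intervals$level,
           parameters = intervals$intervals)
    }
  )
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  if (!is.null(profile_path) && !is.null(fit$profile)) {
    utils::write.table(fit$profile, profile_path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a fit record written by [write_fit()]
#'
#' @param path JSON path.
#' @return a list mirroring the record, with `coefficients` as a named
#'   numeric vector.
#' @export
read_fit <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  rec$coefficients <- unlist(rec$coefficients)
  rec
}

#' Predict from a threshold regression fit
#'
#' Evaluates the fitted mean structure on new data: the linear predictor,
#' or the expit-transformed risk under the logistic link. For hinge and
#' segmented fits the prediction is continuous in `x` at the threshold; for
#' step fits it takes exactly two values as `x` varies with `z` fixed.
#'
#' @param object a `threshold_fit`.
#' @param newdata data frame containing the predictor columns.
#' @param type `"link"` for the linear predictor, `"response"` for the mean.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.threshold_fit <- function(object, newdata,
                                  type = c("link", "response"), ...) {
  type <- match.arg(type)
  spec <- object$spec
  need <- c(spec$x, spec$z)
  miss <- setdiff(need, names(newdata))
  if (length(miss)) {
    stop("columns missing from newdata: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  x <- newdata[[spec$x]]
  Z <- cbind(`(Intercept)` = rep(1, nrow(newdata)))
  if (length(spec$z)) {
    zm <- as.matrix(newdata[spec$z])
    storage.mode(zm) <- "double"
    Z <- cbind(Z, zm)
  }
  if (spec$family$includes_linear_x) {
    Z <- cbind(Z, x)
    colnames(Z)[ncol(Z)] <- spec$x
  }
  des <- cbind(Z, threshold_columns(x, object$e, spec$family))
  eta <- drop(des %*% object$coefficients)
  if (type == "response" && spec$link == "logistic") stats::plogis(eta) else eta
}
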