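#' Model-based confidence intervals
#'
#' Wald-type intervals whose validity requires the threshold model to be
#' correctly specified. The construction differs by family because the
#' threshold estimate has different asymptotics:
#'
#' * hinge / segmented (continuous at the threshold): all parameters,
#'   including the threshold, converge at the regular `n^{-1/2}` rate. Joint
#'   Wald intervals are taken from the observed information of the full
#'   parameter vector including `e`, computed numerically on the smoothed
#'   likelihood at a large smoothing scale where the model is
#'   differentiable.
#' * step / stegmented (discontinuous): the threshold converges at the
#'   faster `n^{-1}` rate, so Wald theory does not apply to `e`. Coefficient
#'   intervals are Wald at the fixed threshold estimate; the interval for
#'   `e` is the profile-likelihood set
#'   `{e : 2 (loglik(e_hat) - loglik(e)) <= qchisq(level, 1)}` over the
#'   candidate grid, reported as the hull of the set with a flag saying
#'   whether the set was contiguous.
#'
#' If the observed information is numerically singular, the function falls
#' back to the bootstrap ([robust_ci()]) with a warning.
#'
#' @param fit a `threshold_fit`.
#' @param data the data frame the model was fitted to.
#' @param level confidence level in (0, 1), default 0.95.
#' @return an object of class `interval_set`: a data frame of per-parameter
#'   estimate, lower and upper, plus `method`, `level`, and for
#'   discontinuous families `e_profile_contiguous`.
#' @export
model_based_ci <- function(fit, data, level = 0.95) {
  stopifnot(inherits(fit, "threshold_fit"), level > 0, level < 1)
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  spec <- fit$spec
  data <- validate_data(data, spec, quiet = TRUE)
  zq <- stats::qnorm(1 - (1 - level) / 2)
  est <- c(fit$coefficients, e = fit$e)
  k <- length(fit$coefficients)

  if (spec$family$name %in% c("hinge", "segmented")) {
    x <- data[[spec$x]]
    b <- if (!is.null(fit$b)) fit$b else 20 / stats::sd(x)
    d0 <- build_design(data, spec, fit$e)
    A <- d0$Z
    y <- d0$y
    negll <- function(par) {
      des <- cbind(A, smooth_threshold_columns(x, par[k + 1], b, spec$family))
      -smoothed_loglik(y, des, par[seq_len(k)], spec$link)
    }
    H <- pracma::hessian(negll, est)
    vc <- tryCatch(chol2inv(chol(H)), error = function(e) NULL)
    if (is.null(vc) || any(!is.finite(vc))) {
      warning("observed information not positive definite; ",
              "falling back to bootstrap intervals", call. = FALSE)
      return(robust_ci(fit, data, level = level))
    }
    se <- sqrt(diag(vc))
    out <- data.frame(parameter = names(est), estimate = unname(est),
                      lower = unname(est - zq * se),
                      upper = unname(est + zq * se))
    return(structure(list(intervals = out, method = "wald_model",
                          level = level),
                     class = "interval_set"))
  }

  # discontinuous families: coefficients at fixed e_hat, profile set for e
  se <- sqrt(diag(fit$glm$vcov))
  out <- data.frame(parameter = names(fit$coefficients),
                    estimate = unname(fit$coefficients),
                    lower = unname(fit$coefficients - zq * se),
                    upper = unname(fit$coefficients + zq * se))
  prof <- fit$profile
  if (is.null(prof) || is.null(prof$loglik)) {
    grid <- candidate_grid(data[[spec$x]], fit$config)
    prof <- data.frame(e = grid, loglik = profile_loglik(data, spec, grid))
  }
  in_set <- 2 * (max(prof$loglik) - prof$loglik) <= stats::qchisq(level, 1)
  idx <- which(in_set)
  contiguous <- all(diff(idx) == 1L)
  out <- rbind(out, data.frame(parameter = "e", estimate = fit$e,
                               lower = min(prof$e[in_set]),
                               upper = max(prof$e[in_set])))
  structure(list(intervals = out, method = "wald_model", level = level,
                 e_profile_contiguous = contiguous),
            class = "interval_set")
}

#' Model-robust confidence intervals
#'
#' Intervals designed to retain coverage even when the data-generating model
#' is not truly a threshold model. Offered for the continuous families
#' (hinge and segmented), whose parameters keep the regular `n^{-1/2}` rate
#' under misspecification.
#'
#' The default is a nonparametric case-resampling bootstrap with percentile
#' intervals for all parameters including the threshold; replicates whose
#' refit fails are dropped (with an error if more than 20% fail). The
#' `"sandwich"` variant gives robust (heteroskedasticity-consistent) Wald
#' intervals for the regression coefficients at the fixed threshold
#' estimate; it does not produce an interval for `e`.
#'
#' @param fit a `threshold_fit` for a hinge or segmented model.
#' @param data the data frame the model was fitted to.
#' @param level confidence level in (0, 1).
#' @param n_boot number of bootstrap replicates (default 1000; must be
#'   positive for the bootstrap type).
#' @param seed integer seed for the resampling stream.
#' @param type `"bootstrap"` (percentile, all parameters) or `"sandwich"`
#'   (coefficients only).
#' @return an `interval_set`; for the bootstrap, the per-replicate estimates
#'   are attached as `$replicates`.
#' @export
robust_ci <- function(fit, data, level = 0.95, n_boot = 1000L, seed = 1L,
                      type = c("bootstrap", "sandwich")) {
  stopifnot(inherits(fit, "threshold_fit"), level > 0, level < 1)
  type <- match.arg(type)
  spec <- fit$spec
  if (!spec$family$name %in% c("hinge", "segmented")) {
    stop("model-robust intervals are only offered for the continuous ",
         "threshold families (hinge, segmented)", call. = FALSE)
  }
  data <- validate_data(data, spec, quiet = TRUE)
  est <- c(fit$coefficients, e = fit$e)

  if (type == "sandwich") {
    d0 <- build_design(data, spec, fit$e)
    des <- cbind(d0$Z, d0$X)
    r <- d0$y - fit$glm$fitted_mean
    if (spec$link == "logistic") {
      bread_inv <- crossprod(des, des * fit$glm$irls_weights)
    } else {
      bread_inv <- crossprod(des) / fit$glm$sigma2
      r <- r / fit$glm$sigma2
    }
    bread <- chol2inv(chol(bread_inv))
    meat <- crossprod(des * r)
    vc <- bread %*% meat %*% bread
    se <- sqrt(diag(vc))
    zq <- stats::qnorm(1 - (1 - level) / 2)
    cf <- fit$coefficients
    out <- data.frame(parameter = names(cf), estimate = unname(cf),
                      lower = unname(cf - zq * se),
                      upper = unname(cf + zq * se))
    return(structure(list(intervals = out, method = "wald_robust",
                          level = level),
                     class = "interval_set"))
  }

  n_boot <- as.integer(n_boot)
  if (n_boot < 1L) stop("n_boot must be positive", call. = FALSE)
  n <- nrow(data)
  set.seed(seed)
  reps <- matrix(NA_real_, n_boot, length(est),
                 dimnames = list(NULL, names(est)))
  for (bb in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    bf <- tryCatch(suppressWarnings(
      if (fit$method == "smooth") {
        fit_smooth(data[idx, , drop = FALSE], spec,
                   smooth_settings(b = fit$b), fit$config)
      } else {
        fit_exact(data[idx, , drop = FALSE], spec, fit$config)
      }
    ), error = function(e) NULL)
    if (!is.null(bf) && bf$converged) {
      reps[bb, ] <- c(bf$coefficients, bf$e)
    }
  }
  ok <- stats::complete.cases(reps)
  n_failed <- sum(!ok)
  if (n_failed > 0.2 * n_boot) {
    stop("more than 20% of bootstrap replicates failed (", n_failed, "/",
         n_boot, ")", call. = FALSE)
  }
  if (n_failed > 0L) {
    message(n_failed, " bootstrap replicate(s) dropped (refit failure)")
  }
  qs <- apply(reps[ok, , drop = FALSE], 2, stats::quantile,
              probs = c((1 - level) / 2, 1 - (1 - level) / 2))
  out <- data.frame(parameter = names(est), estimate = unname(est),
                    lower = unname(qs[1, ]), upper = unname(qs[2, ]))
  structure(list(intervals = out, method = "bootstrap", level = level,
                 n_boot = n_boot, n_failed = n_failed,
                 replicates = reps[ok, , drop = FALSE]),
            class = "interval_set")
}

#' @export
print.interval_set <- function(x, digits = 4, ...) {
  cat(sprintf("%s confidence intervals, level = %.2f\n", x$method, x$level))
  print(cbind(x$intervals[1], round(x$intervals[-1], digits)))
  invisible(x)
}
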