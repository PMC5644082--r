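#' Simulation scenario for threshold regression studies
#'
#' Describes a data-generating threshold model: the family, link, true
#' parameters, sample size and covariate distributions. The covariate
#' defaults are `z ~ N(0, 1)` and `x ~ N(4.7, 1.6)` with the true threshold
#' at the center of the `x` distribution, so candidate grids have
#' observations on both sides of the truth. Default effect sizes (hinge and
#' segmented slope `-0.92`, intercept giving roughly a one-third event rate
#' under the logistic link) are documented in the methods vignette; a null
#' scenario is obtained by setting the threshold-effect coefficients to 0
#' (`beta1 = 0`, and `beta2 = 0` for stegmented).
#'
#' @param family a [threshold_family()] or its name.
#' @param link `"logistic"` or `"linear"`.
#' @param n sample size.
#' @param alpha1 intercept; `NULL` (default) calibrates it so the marginal
#'   event rate under the logistic link is about one third (deterministic
#'   quadrature over the covariate distributions). Ignored calibration for
#'   the linear link, where the default is `-0.3`.
#' @param alpha2 coefficient on `z`.
#' @param gamma slope on raw `x` (segmented/stegmented only).
#' @param beta1 threshold-effect coefficient (on `I(x>e)` for step, on
#'   `(x-e)+` otherwise); default 1 for step, -0.92 otherwise.
#' @param beta2 jump coefficient (stegmented only).
#' @param e true threshold.
#' @param x_mean,x_sd,z_sd covariate distribution parameters.
#' @param resid_sd residual standard deviation for the linear link.
#' @param seed integer seed.
#' @return an object of class `sim_scenario`.
#' @export
sim_scenario <- function(family = c("step", "hinge", "segmented", "stegmented"),
                         link = c("logistic", "linear"), n = 250L,
                         alpha1 = NULL, alpha2 = 0.5, gamma = 0.5,
                         beta1 = NULL, beta2 = 0.5, e = 4.7,
                         x_mean = 4.7, x_sd = 1.6, z_sd = 1, resid_sd = 1,
                         seed = 1L) {
  if (is.character(family)) family <- threshold_family(match.arg(family))
  link <- match.arg(link)
  if (is.null(beta1)) beta1 <- if (family$name == "step") 1 else -0.92
  stopifnot(n >= 10, x_sd > 0, z_sd > 0, resid_sd > 0)
  if (is.null(alpha1)) {
    alpha1 <- if (link == "linear") {
      -0.3
    } else {
      calibrate_intercept(family, alpha2, gamma, beta1, beta2, e,
                          x_mean, x_sd, z_sd, target = 1 / 3)
    }
  }
  structure(
    list(family = family, link = link, n = as.integer(n),
         alpha1 = alpha1, alpha2 = alpha2,
         gamma = if (family$includes_linear_x) gamma else NULL,
         beta1 = beta1,
         beta2 = if (family$name == "stegmented") beta2 else NULL,
         e = e, x_mean = x_mean, x_sd = x_sd, z_sd = z_sd,
         resid_sd = resid_sd, seed = as.integer(seed)),
    class = "sim_scenario"
  )
}

# Intercept giving a target marginal event rate under the logistic link,
# by Gauss-Hermite quadrature over the Gaussian covariates (deterministic).
calibrate_intercept <- function(family, alpha2, gamma, beta1, beta2, e,
                                x_mean, x_sd, z_sd, target = 1 / 3) {
  gh_n <- 32L
  gh <- pracma::gaussHermite(gh_n)
  zs <- sqrt(2) * z_sd * gh$x
  xs <- x_mean + sqrt(2) * x_sd * gh$x
  wz <- gh$w / sqrt(pi)
  wx <- gh$w / sqrt(pi)
  tc <- threshold_columns(xs, e, family)
  beta <- beta1
  if (family$name == "stegmented") beta <- c(beta, beta2)
  wx_part <- drop(tc %*% beta)
  if (family$includes_linear_x) wx_part <- wx_part + gamma * xs
  grid2 <- expand.grid(i = seq_len(gh_n), j = seq_len(gh_n))
  eta0 <- alpha2 * zs[grid2$i] + wx_part[grid2$j]
  w2 <- wz[grid2$i] * wx[grid2$j]
  rate <- function(a1) sum(w2 * stats::plogis(a1 + eta0)) - target
  stats::uniroot(rate, c(-30, 30), tol = 1e-10)$root
}

# True parameter vector in design-column order, threshold last.
true_parameters <- function(scenario) {
  fam <- scenario$family
  beta <- scenario$beta1
  names(beta) <- if (fam$name == "step") "I(x>e)" else "(x-e)+"
  if (fam$name == "stegmented") beta <- c(beta, `I(x>e)` = scenario$beta2)
  out <- c(`(Intercept)` = scenario$alpha1, z = scenario$alpha2)
  if (fam$includes_linear_x) out <- c(out, x = scenario$gamma)
  c(out, beta, e = scenario$e)
}

#' Generate data from a threshold regression scenario
#'
#' Draws `z ~ N(0, z_sd)`, `x ~ N(x_mean, x_sd)`, forms the linear predictor
#' of the scenario's threshold family, and draws the outcome: Bernoulli with
#' expit success probability under the logistic link, Gaussian with standard
#' deviation `resid_sd` under the linear link. A fixed seed reproduces the
#' table exactly.
#'
#' @param scenario a [sim_scenario()].
#' @param seed optional override of the scenario's seed.
#' @return data frame with columns `z`, `x`, `y`.
#' @export
gen_data <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  set.seed(if (is.null(seed)) scenario$seed else seed)
  n <- scenario$n
  z <- stats::rnorm(n, 0, scenario$z_sd)
  x <- stats::rnorm(n, scenario$x_mean, scenario$x_sd)
  tc <- threshold_columns(x, scenario$e, scenario$family)
  beta <- scenario$beta1
  if (scenario$family$name == "stegmented") beta <- c(beta, scenario$beta2)
  eta <- scenario$alpha1 + scenario$alpha2 * z + drop(tc %*% beta)
  if (scenario$family$includes_linear_x) eta <- eta + scenario$gamma * x
  y <- if (scenario$link == "logistic") {
    stats::rbinom(n, 1L, stats::plogis(eta))
  } else {
    eta + stats::rnorm(n, 0, scenario$resid_sd)
  }
  data.frame(z = z, x = x, y = y)
}

spec_from_scenario <- function(scenario) {
  threshold_spec("y", "x", z = "z", family = scenario$family,
                 link = scenario$link)
}

# Shared replicate engine: per-replicate seeds are drawn once from the
# master seed, so results are deterministic regardless of evaluation order.
run_replicates <- function(scenario, reps, method = c("exact", "smooth"),
                           config = grid_config()) {
  method <- match.arg(method)
  stopifnot(reps >= 1)
  set.seed(scenario$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, reps)
  spec <- spec_from_scenario(scenario)
  truth <- true_parameters(scenario)
  est <- matrix(NA_real_, reps, length(truth),
                dimnames = list(NULL, names(truth)))
  for (r in seq_len(reps)) {
    d <- gen_data(scenario, seed = seeds[r])
    f <- tryCatch(suppressWarnings(
      if (method == "exact") fit_exact(d, spec, config)
      else fit_smooth(d, spec, config = config)
    ), error = function(e) NULL)
    if (!is.null(f) && f$converged) est[r, ] <- c(f$coefficients, f$e)
  }
  list(estimates = est, truth = truth,
       n_failed = sum(!stats::complete.cases(est)))
}

new_study_report <- function(table, estimates, scenario, reps, method,
                             n_failed, kind) {
  structure(
    list(table = table, estimates = estimates, scenario = scenario,
         reps = reps, method = method, n_failed = n_failed,
         flagged = n_failed > 0.05 * reps, kind = kind),
    class = "study_report"
  )
}

#' @export
print.study_report <- function(x, digits = 4, ...) {
  cat(sprintf("%s study: %s model, n = %d, %d replicates (%s search)\n",
              x$kind, if (!is.null(x$scenario$family)) x$scenario$family$name
              else "multiple", if (!is.null(x$scenario$n)) x$scenario$n else NA,
              x$reps, x$method))
  if (x$n_failed > 0) {
    cat(sprintf("  %d replicate(s) failed%s\n", x$n_failed,
                if (x$flagged) " [FLAGGED: > 5%]" else ""))
  }
  print(round(x$table, digits))
  invisible(x)
}

#' Monte Carlo bias study
#'
#' Repeatedly simulates from the scenario, fits the threshold model, and
#' reports the relative bias of each coefficient — (Monte Carlo mean minus
#' truth) / truth — and the raw bias of the threshold estimate. For the
#' stegmented family the Monte Carlo mean is replaced by the median, because
#' the sampling distributions of its parameters are markedly skewed.
#' Per-replicate estimates are retained so every summary is re-derivable.
#'
#' @param scenario a [sim_scenario()] with nonzero true coefficients.
#' @param reps number of Monte Carlo replicates (>= 100 recommended).
#' @param method `"exact"` or `"smooth"` search.
#' @param config a [grid_config()].
#' @return a `study_report` whose `table` has rows `relative_bias` (raw bias
#'   for `e`) per parameter; `$estimates` holds the replicate-level fits.
#' @export
bias_table <- function(scenario, reps = 2000L, method = c("exact", "smooth"),
                       config = grid_config()) {
  res <- run_replicates(scenario, reps, method, config)
  est <- res$estimates[stats::complete.cases(res$estimates), , drop = FALSE]
  if (!nrow(est)) stop("all replicates failed", call. = FALSE)
  center <- if (scenario$family$name == "stegmented") {
    apply(est, 2, stats::median)
  } else {
    colMeans(est)
  }
  truth <- res$truth
  tab <- (center - truth) / truth
  tab["e"] <- center["e"] - truth["e"]  # raw bias for the threshold
  new_study_report(tab, res$estimates, scenario, reps, match.arg(method),
                   res$n_failed, "bias")
}

#' Monte Carlo interquartile-range study
#'
#' Same replicate engine as [bias_table()], reporting the Monte Carlo
#' interquartile range of every parameter estimate (a robust spread measure;
#' it shrinks as the sample size grows).
#'
#' @inheritParams bias_table
#' @return a `study_report` whose `table` holds per-parameter IQRs.
#' @export
iqr_table <- function(scenario, reps = 2000L, method = c("exact", "smooth"),
                      config = grid_config()) {
  if (reps < 2) stop("IQR is undefined for fewer than 2 replicates",
                     call. = FALSE)
  res <- run_replicates(scenario, reps, method, config)
  est <- res$estimates[stats::complete.cases(res$estimates), , drop = FALSE]
  if (nrow(est) < 2) stop("too few successful replicates", call. = FALSE)
  tab <- apply(est, 2, stats::IQR)
  new_study_report(tab, res$estimates, scenario, reps, match.arg(method),
                   res$n_failed, "IQR")
}

#' Type-1-error study for the maximal tests
#'
#' Simulates null data (threshold-effect coefficients 0) for each requested
#' family, runs the maximal score and maximal LR tests on every replicate,
#' and reports the fraction of replicates with p-value at or below the
#' nominal level. The score test is unavailable for the stegmented family
#' (its null has two parameters) and is reported as `NA` there.
#'
#' Both tests share one score decomposition and one Monte Carlo draw stream
#' per replicate, halving the cost of the calibration.
#'
#' @param families character vector of family names.
#' @param n sample size per replicate (default 250).
#' @param reps number of null replicates per family.
#' @param B Monte Carlo draws for the null calibration of each test.
#' @param seed master seed; per-replicate data and draw seeds derive from it.
#' @param level nominal level (default 0.05).
#' @param link model link.
#' @param config a [grid_config()].
#' @return a `study_report` whose `table` is a families x {score, lr} matrix
#'   of rejection rates; `$pvalues` holds all per-replicate p-values.
#' @export
type1_table <- function(families = c("step", "hinge", "segmented", "stegmented"),
                        n = 250L, reps = 1000L, B = 1000L, seed = 1L,
                        level = 0.05, link = "logistic",
                        config = grid_config()) {
  stopifnot(reps >= 1, B >= 1)
  tab <- matrix(NA_real_, length(families), 2,
                dimnames = list(families, c("score", "lr")))
  pvals <- list()
  for (fam in families) {
    scenario <- sim_scenario(fam, link = link, n = n, beta1 = 0, beta2 = 0,
                             seed = seed)
    set.seed(seed)
    seeds <- matrix(sample.int(.Machine$integer.max - 1L, 2L * reps), reps, 2L)
    spec <- spec_from_scenario(scenario)
    p <- spec$family$p
    pm <- matrix(NA_real_, reps, 2, dimnames = list(NULL, c("score", "lr")))
    for (r in seq_len(reps)) {
      d <- gen_data(scenario, seed = seeds[r, 1])
      res <- tryCatch(suppressWarnings({
        grid <- candidate_grid(d$x, config)
        dec <- score_process(d, spec, grid)
        q_lr <- lr_process(d, spec, dec$grid)
        draws <- mc_null_distribution(dec, B, seed = seeds[r, 2])
        c(score = if (p == 1L) mean(draws > max(dec$T)) else NA_real_,
          lr = mean(draws > max(q_lr, na.rm = TRUE)))
      }), error = function(e) c(score = NA_real_, lr = NA_real_))
      pm[r, ] <- res
    }
    pvals[[fam]] <- pm
    tab[fam, "score"] <- if (p == 1L) mean(pm[, "score"] <= level, na.rm = TRUE)
      else NA_real_
    tab[fam, "lr"] <- mean(pm[, "lr"] <= level, na.rm = TRUE)
  }
  n_failed <- sum(vapply(pvals, function(p) sum(is.na(p[, "lr"])), numeric(1)))
  rep_obj <- new_study_report(tab, NULL, list(n = n), reps, "score/lr",
                              n_failed, "type-1 error")
  rep_obj$pvalues <- pvals
  rep_obj$level <- level
  rep_obj$B <- B
  rep_obj
}
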