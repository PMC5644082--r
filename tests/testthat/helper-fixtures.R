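# Shared fixtures: everything is generated in code, no stored data.

spec_for <- function(family, link = "logistic", z = "z") {
  threshold_spec("y", "x", z = z, family = family, link = link)
}

# Small logistic dataset with a known hinge structure, deterministic.
toy_logistic <- function(n = 60, seed = 42, beta1 = -1.5, e = 0) {
  set.seed(seed)
  z <- rnorm(n)
  x <- rnorm(n)
  eta <- 0.2 + 0.5 * z + beta1 * pmax(x - e, 0)
  data.frame(z = z, x = x, y = rbinom(n, 1, plogis(eta)))
}

# Brute-force exact-search oracle: enumerate every eligible distinct value,
# refit, return the maximizer. Independent of profile_core.
brute_force_exact <- function(data, spec, config) {
  x <- data[[spec$x]]
  qs <- quantile(x, c(config$lower_quantile, config$upper_quantile),
                 names = FALSE)
  cands <- sort(unique(x[x >= qs[1] & x <= qs[2]]))
  best <- list(e = NA_real_, loglik = -Inf)
  for (e in cands) {
    des <- build_design(data, spec, e)
    f <- tryCatch(fit_glm(des$y, cbind(des$Z, des$X), spec$link),
                  error = function(err) NULL)
    if (!is.null(f) && f$converged && f$loglik > best$loglik) {
      best <- list(e = e, loglik = f$loglik)
    }
  }
  best
}
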