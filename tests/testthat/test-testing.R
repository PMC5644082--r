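test_that("score statistics are non-negative with unit-diagonal correlation", {
  sc <- sim_scenario("hinge", n = 200, seed = 19)
  d <- gen_data(sc)
  g <- candidate_grid(d$x, grid_config(max_grid = 50))
  dec <- score_process(d, spec_for("hinge"), g)
  expect_true(all(dec$T >= 0))
  expect_equal(diag(dec$R), rep(1, dec$M))
  expect_true(isSymmetric(dec$R))
  expect_equal(dec$p, 1L)
  # stegmented decomposition has p = 2 and 2M-dimensional correlation
  dec2 <- score_process(d, spec_for("stegmented"), g)
  expect_equal(dec2$p, 2L)
  expect_equal(nrow(dec2$R), 2L * dec2$M)
  expect_true(all(dec2$T >= 0))
})

test_that("the correlation matrix is invariant to affine rescaling of x and z", {
  d <- toy_logistic(n = 150, seed = 29)
  spec <- spec_for("hinge")
  g <- candidate_grid(d$x, grid_config(max_grid = 25))
  dec <- score_process(d, spec, g)
  d2 <- data.frame(z = 5 * d$z - 2, x = 3 * d$x + 10, y = d$y)
  dec2 <- score_process(d2, spec, 3 * g + 10)
  expect_equal(dec2$R, dec$R, tolerance = 1e-7)
  expect_equal(dec2$T, dec$T, tolerance = 1e-7)
})

test_that("partialling out vanishes when z is orthogonal to the design", {
  # linear link; z constructed orthogonal to the intercept and the hinge
  # column, so the efficient information reduces to the centered information
  set.seed(61)
  x <- seq(-2, 2, length.out = 40)
  e <- 0.3
  h <- pmax(x - e, 0)
  z <- residuals(lm(rnorm(40) ~ cbind(1, h)))
  y <- rnorm(40)
  d <- data.frame(z = z, x = x, y = y)
  spec <- threshold_spec("y", "x", "z", "hinge", "linear")
  dec <- score_process(d, spec, e)
  nf <- fit_glm(y, cbind(1, z), "linear")
  info_centered <- (sum(h^2) - sum(h)^2 / 40) / nf$sigma2
  expect_equal(dec$V[1, 1], info_centered, tolerance = 1e-8)
})

test_that("LR statistics are non-negative and dominated by their maximum", {
  d <- toy_logistic(n = 150, seed = 37)
  for (fam in c("hinge", "stegmented")) {
    spec <- spec_for(fam)
    g <- candidate_grid(d$x, grid_config(max_grid = 30))
    q <- suppressWarnings(lr_process(d, spec, g))
    expect_true(all(q >= 0, na.rm = TRUE))
    tst <- suppressWarnings(max_test(d, spec, "lr", grid = g, B = 300, seed = 2))
    expect_true(all(tst$stat_max >= tst$Q, na.rm = TRUE))
    expect_gte(tst$p_value, 0)
    expect_lte(tst$p_value, 1)
  }
})

test_that("LR and squared-score statistics agree asymptotically at a fixed e", {
  # null hinge data, single candidate: the two statistics share the same
  # asymptotic representation
  lrs <- numeric(20); scs <- numeric(20)
  spec <- spec_for("hinge")
  for (i in 1:20) {
    sc <- sim_scenario("hinge", n = 1000, beta1 = 0, seed = 500 + i)
    d <- gen_data(sc)
    dec <- score_process(d, spec, 4.7)
    lrs[i] <- lr_process(d, spec, 4.7)
    scs[i] <- dec$T[1]
  }
  expect_gt(cor(lrs, scs), 0.98)
  expect_lt(mean(abs(lrs - scs)), 0.2)
})

test_that("Monte Carlo null draws reproduce the chi-squared limit at M = 1", {
  dec1 <- structure(list(R = matrix(1, 1, 1), p = 1L),
                    class = "score_decomposition")
  draws <- mc_null_distribution(dec1, B = 10000, seed = 4)
  ks <- suppressWarnings(ks.test(draws, pchisq, df = 1))
  expect_lt(unname(ks$statistic), 0.02)
  # determinism: same seed gives the identical stream
  expect_identical(draws, mc_null_distribution(dec1, B = 10000, seed = 4))
  expect_warning(mc_null_distribution(dec1, B = 50, seed = 1), "unstable")
})

test_that("perfectly correlated candidates collapse to a single statistic", {
  decp <- structure(list(R = matrix(1, 4, 4), p = 1L),
                    class = "score_decomposition")
  draws <- mc_null_distribution(decp, B = 4000, seed = 9)
  # all four tuples are identical within a draw, so the max is chi-squared(1)
  ks <- suppressWarnings(ks.test(draws, pchisq, df = 1))
  expect_lt(unname(ks$statistic), 0.03)
})

test_that("maximal tests reject reliably under a strong threshold effect", {
  hits <- 0
  spec <- spec_for("hinge")
  for (i in 1:10) {
    sc <- sim_scenario("hinge", n = 500, beta1 = -2.5, alpha1 = 1.5,
                       seed = 700 + i)
    d <- gen_data(sc)
    tst <- max_test(d, spec, "score", B = 1000, seed = i)
    hits <- hits + (tst$p_value < 0.01)
  }
  expect_gte(hits, 9)
})

test_that("unsupported and conservative options behave as documented", {
  d <- toy_logistic(n = 100, seed = 43)
  expect_error(max_test(d, spec_for("stegmented"), "score"),
               "single-parameter")
  t1 <- max_test(d, spec_for("hinge"), "score", B = 500, seed = 3)
  t2 <- max_test(d, spec_for("hinge"), "score", B = 500, seed = 3,
                 conservative = TRUE)
  expect_equal(t2$p_value, (1 + t1$p_value * 500) / 501, tolerance = 1e-12)
})

test_that("model-based and empirical score covariances are close under the null", {
  sc <- sim_scenario("hinge", n = 800, beta1 = 0, seed = 53)
  d <- gen_data(sc)
  g <- candidate_grid(d$x, grid_config(max_grid = 15))
  dm <- score_process(d, spec_for("hinge"), g, v_type = "model")
  de <- score_process(d, spec_for("hinge"), g, v_type = "empirical")
  # the empirical information is a root-n perturbation of the model-based one
  expect_gt(cor(dm$T, de$T), 0.95)
  expect_lt(max(abs(dm$R - de$R)), 0.15)
})
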