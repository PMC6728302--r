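test_that("CR cdf matches hand evaluations and behaves like a cdf", {
  expect_equal(pcompray(0, 1, 1), 0)
  expect_equal(pcompray(1, 1, 1), 0.5)             # 1 - (1+1)^(-1)
  expect_equal(pcompray(sqrt(3), 2, 1), 0.9375)    # 1 - 4^(-2)
  x <- seq(0, 50, length.out = 500)
  p <- pcompray(x, 1.7, 0.8)
  expect_true(all(diff(p) >= 0))
  expect_true(all(p >= 0 & p < 1))
  expect_equal(pcompray(1e8, 1.7, 0.8), 1, tolerance = 1e-10)
  expect_error(pcompray(-1, 1, 1), "nonnegative")
  expect_error(pcompray(1, -1, 1), "alpha")
})

test_that("CR pdf matches hand evaluation, integrates to 1, and is d/dx of the cdf", {
  expect_equal(dcompray(0, 1, 1), 0)
  expect_equal(dcompray(1, 1, 1), 0.5)             # 2 * 2^(-2)
  for (par in list(c(1, 1), c(2.5, 0.4), c(0.7, 3))) {
    mass <- integrate(function(x) dcompray(x, par[1], par[2]), 0, Inf,
                      rel.tol = 1e-9)$value
    expect_equal(mass, 1, tolerance = 1e-6)
  }
  h <- 1e-6
  x <- c(0.3, 1.1, 2.7)
  num <- (pcompray(x + h, 1.6, 0.9) - pcompray(x - h, 1.6, 0.9)) / (2 * h)
  expect_equal(dcompray(x, 1.6, 0.9), num, tolerance = 1e-6)
  expect_error(dcompray(-0.1, 1, 1), "nonnegative")
})

test_that("quantile function inverts the cdf", {
  expect_equal(qcompray(0, 1, 1), 0)
  expect_equal(qcompray(0.5, 1, 1), 1)
  u <- seq(0.001, 0.999, by = 0.002)
  for (par in list(c(1, 1), c(3, 0.2), c(0.4, 5))) {
    expect_equal(pcompray(qcompray(u, par[1], par[2]), par[1], par[2]), u,
                 tolerance = 1e-10)
  }
  expect_error(qcompray(1, 1, 1), "\\[0, 1\\)")
  expect_error(qcompray(-0.1, 1, 1), "\\[0, 1\\)")
})

test_that("CR sampler is seed-reproducible and distributionally correct", {
  x1 <- rcompray(100, 1, 1, seed = 11)
  x2 <- rcompray(100, 1, 1, seed = 11)
  expect_identical(x1, x2)
  x <- rcompray(1e5, 1, 1, seed = 12)
  ks <- suppressWarnings(
    ks.test(x, function(q) pcompray(q, 1, 1))$statistic)
  expect_lt(unname(ks), 0.01)                       # Glivenko-Cantelli
  expect_equal(median(x), 1, tolerance = 0.02)      # qcompray(0.5) = 1
})

test_that("log(1 + X^2/beta) is exponential with rate alpha", {
  alpha <- 1.7; beta <- 0.6
  v <- log1p(rcompray(1e5, alpha, beta, seed = 13)^2 / beta)
  expect_equal(mean(v), 1 / alpha, tolerance = 0.02)
  expect_equal(var(v), 1 / alpha^2, tolerance = 0.05)
})

test_that("alternative samplers use the documented parameterizations", {
  expect_equal(mean(ralt(alt_spec("exponential"), 1e5, seed = 21)), 1.5,
               tolerance = 0.02)
  expect_equal(mean(ralt(alt_spec("gamma"), 1e5, seed = 22)), 3,
               tolerance = 0.05)                     # k * theta = 1.5 * 2
  expect_equal(mean(ralt(alt_spec("chi_square"), 1e5, seed = 23)), 4,
               tolerance = 0.05)                     # mean = df
  expect_error(alt_spec("weibull"), "arg")
  expect_error(alt_spec("gamma", rate = 2), "unknown parameter")
  expect_error(alt_spec("chi_square", df = 2.5), "integer")
})

test_that("comparison cdfs match hand values and the ER/Rayleigh identity", {
  expect_equal(palt(alt_spec("rayleigh", sigma = 2), 0), 0)
  expect_equal(palt(alt_spec("exponentiated_rayleigh", lambda = 1, theta = 2), 1),
               (1 - exp(-1))^2, tolerance = 1e-12)   # ~0.39958
  ## ER with theta = 1 is a Rayleigh with sigma = 1/sqrt(2 lambda)
  x <- seq(0.1, 4, by = 0.3)
  lam <- 0.7
  expect_equal(palt(alt_spec("exponentiated_rayleigh", lambda = lam, theta = 1), x),
               palt(alt_spec("rayleigh", sigma = 1 / sqrt(2 * lam)), x),
               tolerance = 1e-12)
  ## inverse-transform samplers agree with their cdfs
  for (fam in c("rayleigh", "exponentiated_rayleigh")) {
    spec <- alt_spec(fam)
    x <- ralt(spec, 2e4, seed = 24)
    ks <- suppressWarnings(ks.test(x, function(q) palt(spec, q))$statistic)
    expect_lt(unname(ks), 0.02)
  }
})
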