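test_that("censored_sample validates and sorts its input", {
  s <- censored_sample(c(2.1, 0.5, 1.3), n = 10)
  expect_identical(s$x, c(0.5, 1.3, 2.1))
  expect_identical(c(s$n, s$r), c(10L, 3L))
  expect_error(censored_sample(c(1, -1)), "positive")
  expect_error(censored_sample(c(1, 2), n = 1), "n >= length")
  expect_error(censored_sample(numeric(0)), "nonempty")
})

test_that("v-transform matches hand values and preserves order", {
  expect_equal(cr_vtransform(censored_sample(1), 1), log(2))
  s <- censored_sample(c(0.4, 1.1, 2.2), n = 5)
  v <- cr_vtransform(s, 0.7)
  expect_equal(v, log1p(s$x^2 / 0.7))
  expect_true(all(diff(v) >= 0))
  expect_error(cr_vtransform(s, -1), "beta")
})

test_that("log-likelihood matches hand value and the product-form oracle", {
  ## r = n = 1, x = 1, alpha = beta = 1: -2 log 2
  expect_equal(cr_loglik(censored_sample(1), 1, 1), -2 * log(2))
  ## independent product-form oracle: sum log f + (n-r) log S(x_r), minus
  ## the r log 2 absorbed into the package's likelihood convention
  set.seed(31)
  for (k in 1:10) {
    n <- sample(4:12, 1); r <- sample(2:n, 1)
    s <- synth_dataset(cr_spec(1.3, 0.8), n, r, seed = 300 + k)
    a <- runif(1, 0.3, 3); b <- runif(1, 0.2, 2)
    oracle <- sum(dcompray(s$x, a, b, log = TRUE)) +
      (n - r) * pcompray(s$x[r], a, b, lower.tail = FALSE, log.p = TRUE) -
      r * log(2)
    expect_equal(cr_loglik(s, a, b), oracle, tolerance = 1e-10)
  }
  ## censoring an extra item at fixed x_r changes the value by -alpha * v_r
  s1 <- censored_sample(c(0.5, 1.2), n = 4)
  s2 <- censored_sample(c(0.5, 1.2), n = 5)
  vr <- log1p(1.2^2 / 0.8)
  expect_equal(cr_loglik(s2, 1.4, 0.8) - cr_loglik(s1, 1.4, 0.8),
               -1.4 * vr, tolerance = 1e-12)
})

test_that("score matches central finite differences of the log-likelihood", {
  set.seed(32)
  for (k in 1:20) {
    n <- sample(4:15, 1); r <- sample(2:n, 1)
    s <- synth_dataset(cr_spec(1, 0.5), n, r, seed = 400 + k)
    a <- runif(1, 0.3, 3); b <- runif(1, 0.2, 2)
    sc <- cr_score(s, a, b)
    h <- 1e-6
    fd_a <- (cr_loglik(s, a + h, b) - cr_loglik(s, a - h, b)) / (2 * h)
    fd_b <- (cr_loglik(s, a, b + h) - cr_loglik(s, a, b - h)) / (2 * h)
    expect_equal(sc[["alpha"]], fd_a, tolerance = 1e-5)
    expect_equal(sc[["beta"]], fd_b, tolerance = 1e-5)
  }
})

test_that("closed-form shape MLE matches hand values and the grid maximizer", {
  expect_equal(cr_alpha_mle(censored_sample(c(1, 1)), 1), 1 / log(2))
  expect_equal(cr_alpha_mle(censored_sample(1, n = 2), 1), 1 / (2 * log(2)))
  set.seed(33)
  for (k in 1:5) {
    s <- synth_dataset(cr_spec(1.5, 0.7), 12, 8, seed = 500 + k)
    b <- runif(1, 0.3, 2)
    a_hat <- cr_alpha_mle(s, b)
    ## alpha-score is exactly zero at the closed form
    expect_equal(cr_score(s, a_hat, b)[["alpha"]], 0, tolerance = 1e-10)
    ## brute-force grid search of the fixed-beta likelihood
    grid <- seq(a_hat / 3, a_hat * 3, length.out = 20001)
    ll <- vapply(grid, function(a) cr_loglik(s, a, b), numeric(1))
    expect_equal(grid[which.max(ll)], a_hat, tolerance = 1e-3)
    expect_true(all(ll <= cr_loglik(s, a_hat, b) + 1e-12))
  }
})

test_that("joint profile MLE is a stationary local maximum matching 2-D grid search", {
  set.seed(34)
  for (k in 1:5) {
    s <- synth_dataset(cr_spec(2, 1), 40, seed = 600 + k)
    fit <- cr_mle(s)
    expect_true(fit$converged)
    if (fit$boundary) next   # Rayleigh-limit fit: no interior stationary point
    sc <- cr_score(s, fit$alpha, fit$beta)
    expect_lt(abs(sc[["alpha"]]) * fit$alpha / s$r, 1e-6)
    expect_lt(abs(sc[["beta"]]) * fit$beta / s$r, 1e-6)
    ## negative-definite numerical Hessian in (log alpha, log beta)
    h <- 1e-4
    f <- function(la, lb) cr_loglik(s, exp(la), exp(lb))
    la <- log(fit$alpha); lb <- log(fit$beta)
    H <- matrix(c(
      (f(la + h, lb) - 2 * f(la, lb) + f(la - h, lb)) / h^2,
      rep((f(la + h, lb + h) - f(la + h, lb - h) -
           f(la - h, lb + h) + f(la - h, lb - h)) / (4 * h^2), 2),
      (f(la, lb + h) - 2 * f(la, lb) + f(la, lb - h)) / h^2), 2, 2)
    expect_true(all(eigen(H, symmetric = TRUE)$values < 0))
    ## coarse 2-D lattice never beats the profile maximizer
    lattice <- expand.grid(a = fit$alpha * 2^seq(-2, 2, by = 0.1),
                           b = fit$beta * 2^seq(-2, 2, by = 0.1))
    ll <- mapply(function(a, b) cr_loglik(s, a, b), lattice$a, lattice$b)
    expect_true(all(ll <= fit$loglik + 1e-9))
  }
})

test_that("shape MLE is scale-equivariant and order-invariant", {
  s <- synth_dataset(cr_spec(1.2, 0.4), 15, 10, seed = 41)
  fit <- cr_mle(s)
  ## x -> c x with beta -> c^2 beta leaves v, hence alpha-hat, unchanged
  for (cc in c(0.1, 3, 25)) {
    expect_equal(cr_alpha_mle(censored_sample(cc * s$x, n = s$n), cc^2 * 0.4),
                 cr_alpha_mle(s, 0.4), tolerance = 1e-12)
    fit_c <- cr_mle(censored_sample(cc * s$x, n = s$n))
    expect_equal(fit_c$alpha, fit$alpha, tolerance = 1e-5)
    expect_equal(fit_c$beta, cc^2 * fit$beta, tolerance = 1e-4)
  }
  shuffled <- censored_sample(rev(s$x), n = s$n)
  expect_equal(cr_mle(shuffled)$alpha, fit$alpha, tolerance = 1e-12)
})

test_that("fixed-beta fit reports the fixed scale and converges trivially", {
  s <- synth_dataset(cr_spec(1, 0.5), 20, 12, seed = 42)
  fit <- cr_mle(s, beta = 0.5)
  expect_equal(fit$beta_fixed, 0.5)
  expect_equal(fit$alpha, cr_alpha_mle(s, 0.5))
  expect_true(fit$converged)
  expect_error(cr_mle(censored_sample(c(1, 1))), "distinct")
})

test_that("estimation error shrinks with sample size (median absolute error)", {
  ## median-based so the occasional Rayleigh-limit boundary fit at small n
  ## (legitimate, but with a huge nominal alpha) cannot dominate
  mae <- function(n) {
    a <- b <- numeric(60)
    for (k in 1:60) {
      f <- cr_mle(synth_dataset(cr_spec(2, 1), n, seed = 7000 + 17 * n + k))
      a[k] <- f$alpha; b[k] <- f$beta
    }
    c(median(abs(a - 2)), median(abs(b - 1)))
  }
  e <- vapply(c(50, 200, 800), mae, numeric(2))
  expect_true(all(diff(e[1, ]) < 0))
  expect_true(all(diff(e[2, ]) < 0))
})
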