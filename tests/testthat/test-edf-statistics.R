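test_that("uniformize applies the fitted cdf, clips, and preserves order", {
  us <- uniformize(censored_sample(1), 1, 1)
  expect_equal(us$u, 0.5)
  s <- synth_dataset(cr_spec(1, 0.5), 15, 10, seed = 51)
  us <- uniformize(s, 1.3, 0.7)
  expect_true(all(diff(us$u) >= 0))
  expect_true(all(us$u > 0 & us$u < 1))
  expect_equal(us$u, pmin(pmax(pcompray(s$x, 1.3, 0.7), 1e-12), 1 - 1e-12))
  ## probability-integral transform: u under the true parameters is uniform
  x <- rcompray(1e4, 1.5, 0.8, seed = 52)
  u <- uniformize(censored_sample(x), 1.5, 0.8)$u
  expect_gt(suppressWarnings(ks.test(u, "punif")$p.value), 0.01)
})

test_that("single-observation statistics match hand evaluations", {
  us <- structure(list(u = 0.5, n = 1L, r = 1L), class = "uniformized_sample")
  expect_equal(ks_stat(us), 0.5)
  expect_equal(cvm_stat(us), 1 / 24)
  expect_equal(ad_stat(us), log(2) - 0.5)
})

test_that("KS statistic equals the enumeration and sup-distance oracle", {
  ## regular complete-sample configuration, direct enumeration
  n <- 10
  u <- seq_len(n) / (n + 1)
  us <- structure(list(u = u, n = n, r = n), class = "uniformized_sample")
  i <- seq_len(n)
  expect_equal(ks_stat(us),
               max(pmax(i / n - u, u - (i - 1) / n)))
  ## randomized censored instances vs the knot-enumeration sup oracle
  set.seed(53)
  for (k in 1:50) {
    us <- random_uniformized()
    expect_equal(ks_stat(us), oracle_ks(us$u, us$n), tolerance = 1e-12)
  }
})

test_that("CvM statistic equals the integral oracle on random censored samples", {
  set.seed(54)
  for (k in 1:50) {
    us <- random_uniformized()
    expect_equal(cvm_stat(us), oracle_cvm(us$u, us$n), tolerance = 1e-8)
  }
  ## complete sample with u_(n) -> 1: classical W^2 recovered
  n <- 8
  u <- c(sort(runif(n - 1)) * 0.9, 1 - 1e-9)
  us <- structure(list(u = u, n = n, r = n), class = "uniformized_sample")
  i <- seq_len(n)
  w2 <- sum((u - (2 * i - 1) / (2 * n))^2) + 1 / (12 * n)
  expect_equal(cvm_stat(us), w2, tolerance = 1e-7)
})

test_that("AD statistic equals the weighted-integral oracle and is tail-sensitive", {
  set.seed(55)
  for (k in 1:50) {
    us <- random_uniformized()
    expect_equal(ad_stat(us), oracle_ad(us$u, us$n), tolerance = 1e-6)
  }
  ## pushing the smallest u toward 0 inflates the statistic
  base <- structure(list(u = c(0.2, 0.5, 0.8), n = 5L, r = 3L),
                    class = "uniformized_sample")
  shifted <- base
  vals <- vapply(c(0.2, 0.02, 0.002, 2e-4), function(u1) {
    shifted$u[1] <- u1
    ad_stat(shifted)
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("combined statistics are reorder-invariant, scale-invariant, and censor-aware", {
  s <- synth_dataset(cr_spec(1, 0.5), 20, 14, seed = 56)
  st <- cr_gof_stats(s, 1.2, 0.6)
  expect_identical(names(st), c("ks", "cvm", "ad"))
  ## duplicate-preserving reordering of the input
  expect_equal(cr_gof_stats(censored_sample(sample(s$x), n = s$n), 1.2, 0.6), st)
  ## monotone rescaling x -> c x with beta -> c^2 beta leaves u unchanged
  expect_equal(cr_gof_stats(censored_sample(10 * s$x, n = s$n), 1.2, 100 * 0.6),
               st, tolerance = 1e-12)
  ## censored statistics use only the first r order statistics
  full <- synth_dataset(cr_spec(1, 0.5), 12, seed = 57)
  st_r <- cr_gof_stats(censored_sample(full$x[1:11], n = 12), 1.1, 0.5)
  st_n <- cr_gof_stats(full, 1.1, 0.5)
  expect_false(isTRUE(all.equal(st_r, st_n)))
})
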