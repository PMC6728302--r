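# Independent oracles for the modified EDF statistics, computed from the
# definition (distance between the step EDF of the uniformized values and
# the identity over [0, u_(r)]), not from the closed forms in the package.

# Step EDF of u at t: #{u_i <= t} / n
edf_at <- function(t, u, n) vapply(t, function(tt) sum(u <= tt), numeric(1)) / n

# sup distance by enumeration at the knots (the sup of |G - t| over
# [0, u_(r)] is attained at a knot or its left limit)
oracle_ks <- function(u, n) {
  r <- length(u)
  cand <- c(abs(seq_len(r) / n - u),          # at u_(i), G = i/n
            abs(u - (seq_len(r) - 1) / n))    # left limit, G = (i-1)/n
  max(cand)
}

# n * integral of (G - t)^2 over [0, u_(r)], segment-by-segment quadrature
oracle_cvm <- function(u, n) {
  knots <- c(0, u)
  total <- 0
  for (j in seq_along(u)) {
    g <- (j - 1) / n
    total <- total + integrate(function(t) (g - t)^2, knots[j], knots[j + 1],
                               rel.tol = 1e-12, abs.tol = 1e-14)$value
  }
  n * total
}

# n * integral of (G - t)^2 / (t (1 - t)) over [0, u_(r)]
oracle_ad <- function(u, n) {
  knots <- c(0, u)
  total <- 0
  for (j in seq_along(u)) {
    g <- (j - 1) / n
    total <- total + integrate(function(t) (g - t)^2 / (t * (1 - t)),
                               knots[j], knots[j + 1],
                               rel.tol = 1e-11, abs.tol = 1e-13)$value
  }
  n * total
}

# random censored uniformized sample for property tests
random_uniformized <- function(n_max = 12) {
  n <- sample(3:n_max, 1)
  r <- sample(2:n, 1)
  u <- sort(runif(n))[seq_len(r)]
  structure(list(u = u, n = n, r = r), class = "uniformized_sample")
}

cr_spec <- function(alpha = 1, beta = 0.5)
  alt_spec("compound_rayleigh", alpha = alpha, beta = beta)
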