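## Modified EDF goodness-of-fit statistics for type-II censored samples.
##
## With u_(i) = F(x_(i); alpha_hat, beta_hat) the probability-integral
## transform of the observed order statistics, the censored statistics are
##
##   D+ = max_i (i/n - u_(i)),  D- = max_i (u_(i) - (i-1)/n),  D = max(D+, D-)
##   C  = sum (u_(i) - (2i-1)/(2n))^2 + r/(12 n^2) + (n/3)(u_(r) - r/n)^3
##   A  = -(1/n) sum (2i-1)[log u_(i) - log(1-u_(i))] - 2 sum log(1-u_(i))
##        - (1/n)[(r-n)^2 log(1-u_(r)) - r^2 log u_(r) + n^2 u_(r)]
##
## C and A are exactly n * int_0^{u_(r)} (G_n(u)-u)^2 [w(u)] du with
## w = 1 and w = 1/(u(1-u)) respectively, where G_n is the EDF of the u's
## with steps of height 1/n (checked against quadrature in the tests).

#' Probability-integral transform of a censored sample
#'
#' Maps the observed order statistics through the fitted Compound Rayleigh
#' cdf: \eqn{\hat u_{(i)} = F(x_{(i)}; \alpha, \beta)}.  Values are clipped
#' to `[eps, 1 - eps]` (`eps = 1e-12`) so that the logarithms in the
#' Anderson-Darling statistic are always finite.
#'
#' @inheritParams cr_loglik
#' @return an object of class `"uniformized_sample"`: a list with the
#'   clipped nondecreasing vector `u` and the censoring counts `n`, `r`.
#' @examples
#' uniformize(censored_sample(1), alpha = 1, beta = 1)$u   # 0.5
#' @export
uniformize <- function(s, alpha, beta) {
  s <- as_censored_sample(s)
  check_cr_params(alpha, beta)
  eps <- 1e-12
  u <- pmin(pmax(pcompray(s$x, alpha, beta), eps), 1 - eps)
  structure(list(u = u, n = s$n, r = s$r), class = "uniformized_sample")
}

as_uniformized <- function(us) {
  if (inherits(us, "uniformized_sample")) return(us)
  stop("expected a 'uniformized_sample' (see uniformize())", call. = FALSE)
}

#' Modified Kolmogorov-Smirnov statistic for censored samples
#'
#' \eqn{\hat D = \max(\hat D^+, \hat D^-)} with
#' \eqn{\hat D^+ = \max_{i \le r}(i/n - \hat u_{(i)})} and
#' \eqn{\hat D^- = \max_{i \le r}(\hat u_{(i)} - (i-1)/n)}, each floored at
#' zero so the statistic is the (nonnegative) supremum distance between the
#' EDF and the fitted cdf over the observed range.
#'
#' @param us a `"uniformized_sample"` from [uniformize()].
#' @return the statistic, in `[0, 1]`.
#' @export
ks_stat <- function(us) {
  us <- as_uniformized(us)
  i <- seq_len(us$r)
  dplus <- max(pmax(i / us$n - us$u, 0))
  dminus <- max(pmax(us$u - (i - 1) / us$n, 0))
  max(dplus, dminus)
}

#' Modified Cramer-von Mises statistic for censored samples
#'
#' \deqn{\hat C = \sum_{i=1}^r \Big[\hat u_{(i)} - \frac{2i-1}{2n}\Big]^2
#'   + \frac{r}{12 n^2} + \frac{n}{3}\Big[\hat u_{(r)} - \frac{r}{n}\Big]^3.}
#' For a complete sample with \eqn{\hat u_{(n)} \to 1} the cubic term
#' vanishes and the classical \eqn{W^2} is recovered.
#'
#' @inheritParams ks_stat
#' @return the statistic (nonnegative).
#' @export
cvm_stat <- function(us) {
  us <- as_uniformized(us)
  i <- seq_len(us$r)
  n <- us$n
  sum((us$u - (2 * i - 1) / (2 * n))^2) + us$r / (12 * n^2) +
    (n / 3) * (us$u[us$r] - us$r / n)^3
}

#' Modified Anderson-Darling statistic for censored samples
#'
#' \deqn{\hat A = -\frac{1}{n}\sum_{i=1}^r (2i-1)
#'   [\log\hat u_{(i)} - \log(1-\hat u_{(i)})]
#'   - 2 \sum_{i=1}^r \log(1-\hat u_{(i)})
#'   - \frac{1}{n}\big[(r-n)^2 \log(1-\hat u_{(r)})
#'   - r^2\log\hat u_{(r)} + n^2 \hat u_{(r)}\big].}
#'
#' @inheritParams ks_stat
#' @return the statistic.
#' @export
ad_stat <- function(us) {
  us <- as_uniformized(us)
  u <- us$u
  if (any(u <= 0) || any(u >= 1))
    stop("uniformized values must lie strictly inside (0, 1)", call. = FALSE)
  i <- seq_len(us$r)
  n <- us$n
  r <- us$r
  -(1 / n) * sum((2 * i - 1) * (log(u) - log1p(-u))) -
    2 * sum(log1p(-u)) -
    (1 / n) * ((r - n)^2 * log1p(-u[r]) - r^2 * log(u[r]) + n^2 * u[r])
}

#' All three modified statistics at a given parameter pair
#'
#' Convenience wrapper: uniformizes the sample at `(alpha, beta)` and
#' returns the modified KS, CvM and AD statistics.
#'
#' @inheritParams cr_loglik
#' @return named numeric vector `c(ks = , cvm = , ad = )`.
#' @examples
#' x <- rcompray(50, 1, 1, seed = 3)
#' fit <- cr_mle(censored_sample(x))
#' cr_gof_stats(fit$sample, fit$alpha, fit$beta)
#' @export
cr_gof_stats <- function(s, alpha, beta) {
  us <- uniformize(s, alpha, beta)
  c(ks = ks_stat(us), cvm = cvm_stat(us), ad = ad_stat(us))
}
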