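## Compound Rayleigh distribution and the alternative families used in the
## power study.  All cdf/pdf evaluation goes through log1p/expm1 so that
## extreme shapes (large alpha) do not overflow.

check_cr_params <- function(alpha, beta) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0)
    stop("'alpha' must be a single positive number", call. = FALSE)
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta <= 0)
    stop("'beta' must be a single positive number", call. = FALSE)
  invisible(TRUE)
}

#' The Compound Rayleigh distribution
#'
#' Density, distribution function, quantile function and random generation
#' for the Compound Rayleigh (CR) distribution with shape `alpha` and scale
#' `beta`:
#' \deqn{F(x) = 1 - (1 + x^2/\beta)^{-\alpha}, \qquad
#'       f(x) = \frac{2\alpha x}{\beta}\,(1 + x^2/\beta)^{-(\alpha+1)},
#'       \quad x \ge 0.}
#' Equivalently, \eqn{X^2} follows a Lomax (Pareto type II) distribution
#' with shape \eqn{\alpha} and scale \eqn{\beta}, and
#' \eqn{\log(1 + X^2/\beta)} is exponential with rate \eqn{\alpha} -- the
#' identity behind the closed-form shape estimator used throughout the
#' package.
#'
#' `beta` carries the units of \eqn{x^2}; `alpha` is dimensionless.
#'
#' @param x,q vector of nonnegative quantiles.
#' @param p vector of probabilities in `[0, 1)`.
#' @param n number of draws.
#' @param alpha positive shape parameter.
#' @param beta positive scale parameter (units of `x^2`).
#' @param log,log.p logical; if `TRUE`, probabilities/densities are returned
#'   on the log scale.
#' @param lower.tail logical; if `TRUE` (default), probabilities are
#'   \eqn{P(X \le x)}.
#' @param seed optional integer; when supplied, the generator is seeded
#'   locally so the draw is reproducible and the caller's RNG stream is not
#'   advanced.
#'
#' @return `dcompray` gives the density, `pcompray` the distribution
#'   function, `qcompray` the quantile function and `rcompray` generates
#'   random deviates by inverse transform.
#'
#' @examples
#' pcompray(1, alpha = 1, beta = 1)        # 0.5
#' qcompray(0.5, alpha = 1, beta = 1)      # 1
#' x <- rcompray(10, alpha = 2, beta = 0.5, seed = 1)
#' @name compound_rayleigh
NULL

#' @rdname compound_rayleigh
#' @export
dcompray <- function(x, alpha, beta, log = FALSE) {
  check_cr_params(alpha, beta)
  if (any(!is.finite(x)) || any(x < 0))
    stop("'x' must be finite and nonnegative", call. = FALSE)
  ld <- ifelse(x == 0, -Inf,
               log(2 * alpha) + log(x) - log(beta) -
                 (alpha + 1) * log1p(x^2 / beta))
  if (log) ld else exp(ld)
}

#' @rdname compound_rayleigh
#' @export
pcompray <- function(q, alpha, beta, lower.tail = TRUE, log.p = FALSE) {
  check_cr_params(alpha, beta)
  if (any(!is.finite(q)) || any(q < 0))
    stop("'q' must be finite and nonnegative", call. = FALSE)
  lsurv <- -alpha * log1p(q^2 / beta)   # log S(q)
  if (lower.tail) {
    if (log.p) log(-expm1(lsurv)) else -expm1(lsurv)
  } else {
    if (log.p) lsurv else exp(lsurv)
  }
}

#' @rdname compound_rayleigh
#' @export
qcompray <- function(p, alpha, beta) {
  check_cr_params(alpha, beta)
  if (any(!is.finite(p)) || any(p < 0) || any(p >= 1))
    stop("'p' must lie in [0, 1)", call. = FALSE)
  sqrt(beta * expm1(-log1p(-p) / alpha))
}

#' @rdname compound_rayleigh
#' @export
rcompray <- function(n, alpha, beta, seed = NULL) {
  check_cr_params(alpha, beta)
  if (length(n) != 1L || n < 1) stop("'n' must be a positive integer", call. = FALSE)
  with_seed(seed, qcompray(runif(n), alpha, beta))
}

## Run expr under a local seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

## Deterministic per-replicate sub-seeds derived from a master seed.
make_subseeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}

#' Specify an alternative lifetime distribution
#'
#' Constructs a validated specification of one of the lifetime families used
#' for power simulation and comparative fitting.  Parameterizations:
#' \describe{
#'   \item{`exponential`}{mean `theta`; density
#'     \eqn{(1/\theta)\exp(-x/\theta)}.  Default `theta = 1.5`.}
#'   \item{`gamma`}{shape `k`, scale `theta`.  Default `k = 1.5`,
#'     `theta = 2`.}
#'   \item{`chi_square`}{degrees of freedom `df` (positive integer).
#'     Default `df = 4`.}
#'   \item{`rayleigh`}{scale `sigma`; \eqn{F(x)=1-\exp(-x^2/(2\sigma^2))}.}
#'   \item{`exponentiated_rayleigh`}{rate `lambda`, exponent `theta`;
#'     \eqn{F(x)=(1-\exp(-\lambda x^2))^{\theta}}.}
#'   \item{`compound_rayleigh`}{shape `alpha`, scale `beta` as in
#'     [pcompray()].}
#' }
#'
#' @param family one of `"exponential"`, `"gamma"`, `"chi_square"`,
#'   `"rayleigh"`, `"exponentiated_rayleigh"`, `"compound_rayleigh"`.
#' @param ... named family parameters overriding the defaults above.
#'
#' @return an object of class `"alt_spec"`: a list with elements `family`
#'   and `params`.
#' @examples
#' alt_spec("exponential")            # theta = 1.5
#' alt_spec("gamma", k = 2, theta = 1)
#' @export
alt_spec <- function(family, ...) {
  family <- match.arg(family, c("exponential", "gamma", "chi_square",
                                "rayleigh", "exponentiated_rayleigh",
                                "compound_rayleigh"))
  defaults <- switch(family,
    exponential            = list(theta = 1.5),
    gamma                  = list(k = 1.5, theta = 2),
    chi_square             = list(df = 4),
    rayleigh               = list(sigma = 1),
    exponentiated_rayleigh = list(lambda = 1, theta = 1),
    compound_rayleigh      = list(alpha = 1, beta = 0.5))
  override <- list(...)
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown))
    stop("unknown parameter(s) for family '", family, "': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  params <- utils::modifyList(defaults, override)
  for (nm in names(params)) {
    v <- params[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("parameter '", nm, "' must be a single positive number", call. = FALSE)
  }
  if (family == "chi_square" && params$df != round(params$df))
    stop("'df' must be a positive integer", call. = FALSE)
  structure(list(family = family, params = params), class = "alt_spec")
}

#' @export
print.alt_spec <- function(x, ...) {
  cat("Alternative distribution: ", x$family, "(",
      paste(names(x$params), unlist(x$params), sep = " = ", collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' Sample from an alternative lifetime distribution
#'
#' Seeded random generation from a family specified by [alt_spec()].  All
#' continuous families without a native R generator use inverse-transform
#' sampling.
#'
#' @param spec an [alt_spec()] object (or a family name, passed through
#'   `alt_spec()` with default parameters).
#' @param n number of draws.
#' @param seed optional integer seed (local, see [rcompray()]).
#' @return numeric vector of `n` nonnegative draws.
#' @examples
#' ralt(alt_spec("gamma"), 5, seed = 1)
#' @export
ralt <- function(spec, n, seed = NULL) {
  if (is.character(spec)) spec <- alt_spec(spec)
  stopifnot(inherits(spec, "alt_spec"))
  if (length(n) != 1L || n < 1) stop("'n' must be a positive integer", call. = FALSE)
  p <- spec$params
  with_seed(seed, switch(spec$family,
    exponential            = rexp(n, rate = 1 / p$theta),
    gamma                  = rgamma(n, shape = p$k, scale = p$theta),
    chi_square             = rchisq(n, df = p$df),
    rayleigh               = p$sigma * sqrt(-2 * log1p(-runif(n))),
    exponentiated_rayleigh = sqrt(-log1p(-runif(n)^(1 / p$theta)) / p$lambda),
    compound_rayleigh      = qcompray(runif(n), p$alpha, p$beta)))
}

#' Distribution function of an alternative family
#'
#' Evaluates the cdf of a family specified by [alt_spec()], used for
#' comparative fitting reports.
#'
#' @inheritParams ralt
#' @param x vector of nonnegative quantiles.
#' @return vector of probabilities.
#' @examples
#' palt(alt_spec("rayleigh", sigma = 1), 1)   # 1 - exp(-1/2)
#' @export
palt <- function(spec, x) {
  if (is.character(spec)) spec <- alt_spec(spec)
  stopifnot(inherits(spec, "alt_spec"))
  if (any(!is.finite(x)) || any(x < 0))
    stop("'x' must be finite and nonnegative", call. = FALSE)
  p <- spec$params
  switch(spec$family,
    exponential            = pexp(x, rate = 1 / p$theta),
    gamma                  = pgamma(x, shape = p$k, scale = p$theta),
    chi_square             = pchisq(x, df = p$df),
    rayleigh               = -expm1(-x^2 / (2 * p$sigma^2)),
    exponentiated_rayleigh = (-expm1(-p$lambda * x^2))^p$theta,
    compound_rayleigh      = pcompray(x, p$alpha, p$beta))
}
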