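#' Type-II censored sample container
#'
#' Bundles the `r` smallest order statistics observed in a life test of `n`
#' items.  A complete sample is the special case `r = n`.  Values are sorted
#' on construction, so downstream estimators and statistics are invariant to
#' the input ordering.
#'
#' @param x numeric vector of observed (uncensored) lifetimes; all values
#'   must be positive and finite.
#' @param n total number of items on test.  Defaults to `length(x)`
#'   (complete sample); must be at least `length(x)`.
#'
#' @return an object of class `"censored_sample"`: a list with elements
#'   `x` (sorted observed values), `n` and `r = length(x)`.
#' @examples
#' censored_sample(c(2.1, 0.5, 1.3))           # complete, n = r = 3
#' censored_sample(c(2.1, 0.5, 1.3), n = 10)   # 7 items still running
#' @export
censored_sample <- function(x, n = length(x)) {
  if (!is.numeric(x) || length(x) < 1L)
    stop("'x' must be a nonempty numeric vector", call. = FALSE)
  if (any(!is.finite(x)) || any(x <= 0))
    stop("all observed lifetimes must be positive and finite", call. = FALSE)
  r <- length(x)
  if (!is.numeric(n) || length(n) != 1L || n != round(n) || n < r)
    stop("'n' must be a single integer with n >= length(x)", call. = FALSE)
  structure(list(x = sort(x), n = as.integer(n), r = as.integer(r)),
            class = "censored_sample")
}

is_complete <- function(s) s$r == s$n

as_censored_sample <- function(x, n = NULL) {
  if (inherits(x, "censored_sample")) return(x)
  censored_sample(x, n = if (is.null(n)) length(x) else n)
}

#' @export
print.censored_sample <- function(x, ...) {
  cat("Type-II censored sample: r =", x$r, "observed of n =", x$n,
      if (is_complete(x)) "(complete)\n" else "\n")
  cat("  range [", format(min(x$x)), ", ", format(max(x$x)), "]\n", sep = "")
  invisible(x)
}
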