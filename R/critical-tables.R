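## Monte Carlo critical values for the modified statistics.
##
## Each replicate draws a complete CR sample of size n, keeps the first r
## order statistics, re-estimates the parameters (shape only when the scale
## is treated as known; both by profile likelihood otherwise), and records
## the three statistics.  The empirical null distribution so produced is the
## reference distribution of a Lilliefors-type test: parameters estimated,
## censoring applied.

#' Simulate the null distribution of the modified statistics
#'
#' Runs the Monte Carlo procedure for one `(n, r)` cell: draw a complete
#' Compound Rayleigh sample, sort, truncate to the first `r` order
#' statistics, estimate the parameters (`"beta_known"`: shape by
#' [cr_alpha_mle()] at the generating scale; `"both_unknown"`: joint profile
#' fit), and evaluate the three statistics.  Replicates use independent
#' sub-seeds derived deterministically from `seed`.  A replicate whose fit
#' fails numerically (non-finite estimates) is redrawn with a fresh
#' sub-seed; redraws are counted, and a failure rate above 1% aborts with a
#' diagnostic.  Rayleigh-limit boundary fits (see [cr_mle()]) are legitimate
#' fits, not failures.
#'
#' In the `"beta_known"` case the null distribution provably does not depend
#' on the generating shape `alpha`: the transformed values
#' \eqn{v_i = \log(1 + x_i^2/\beta)} are exponential with rate \eqn{\alpha}
#' and the closed-form estimator is scale-equivariant in `v`, so the
#' uniformized values are shape-free.
#'
#' @param n complete-sample size.
#' @param r number of observed order statistics (`r = n` for complete).
#' @param case `"beta_known"` or `"both_unknown"`.
#' @param alpha,beta generating parameters (in the `"beta_known"` case
#'   `beta` is also the value held fixed during estimation).
#' @param reps number of Monte Carlo replicates.
#' @param seed integer master seed.
#' @return an object of class `"cr_null_sim"`: a list with `draws` (a
#'   `reps` x 3 matrix, columns `ks`, `cvm`, `ad`), the cell metadata, and
#'   `redraws`, the number of redrawn replicates.
#' @examples
#' sim <- simulate_null(10, 10, "beta_known", reps = 200, seed = 1)
#' colMeans(sim$draws)
#' @export
simulate_null <- function(n, r = n, case = c("both_unknown", "beta_known"),
                          alpha = 1, beta = 0.5, reps = 5000, seed = NULL) {
  case <- match.arg(case)
  if (r < 1 || r > n) stop("need 1 <= r <= n", call. = FALSE)
  if (reps < 1) stop("'reps' must be at least 1", call. = FALSE)
  check_cr_params(alpha, beta)
  subseeds <- make_subseeds(seed, reps)
  draws <- matrix(NA_real_, reps, 3, dimnames = list(NULL, c("ks", "cvm", "ad")))
  redraws <- 0L
  max_redraws <- max(1L, ceiling(0.01 * reps))
  for (k in seq_len(reps)) {
    attempt <- 0L
    repeat {
      x <- sort(rcompray(n, alpha, beta, seed = subseeds[k] + attempt))[seq_len(r)]
      s <- censored_sample(x, n = n)
      st <- tryCatch({
        fit <- if (case == "beta_known") cr_mle(s, beta = beta) else cr_mle(s)
        if (!all(is.finite(c(fit$alpha, fit$beta)))) stop("non-finite fit")
        cr_gof_stats(s, fit$alpha, fit$beta)
      }, error = function(e) NULL)
      if (!is.null(st) && all(is.finite(st))) break
      attempt <- attempt + 1L
      redraws <- redraws + 1L
      if (redraws > max_redraws)
        stop("estimation failure rate exceeded 1% during null simulation",
             call. = FALSE)
    }
    draws[k, ] <- st
  }
  structure(list(draws = draws, n = as.integer(n), r = as.integer(r),
                 case = case, alpha = alpha, beta = beta,
                 reps = as.integer(reps), seed = seed, redraws = redraws),
            class = "cr_null_sim")
}

#' @export
print.cr_null_sim <- function(x, ...) {
  cat(sprintf("Null simulation: n = %d, r = %d, case = %s, reps = %d\n",
              x$n, x$r, x$case, x$reps))
  print(round(apply(x$draws, 2, quantile, c(0.5, 0.9, 0.95, 0.99)), 5))
  invisible(x)
}

#' Extract critical values from a null simulation
#'
#' Empirical quantiles of the simulated null distributions, by the
#' interpolation-free order-statistic rule: under the default `"upper"`
#' convention the critical value at level `gamma` is the
#' `ceiling((1-gamma)*B)`-th smallest draw (reject for large statistics);
#' the `"lower"` convention returns the `ceiling(gamma*B)`-th smallest draw
#' and exists only to emulate published tables that tabulate the opposite
#' tail.
#'
#' @param sim a `"cr_null_sim"` from [simulate_null()].
#' @param gammas significance levels in `(0, 1)`.
#' @param convention `"upper"` (default) or `"lower"`.
#' @return a data frame with columns `statistic`, `n`, `r`, `gamma`,
#'   `critical_value`.
#' @examples
#' sim <- simulate_null(10, 10, "beta_known", reps = 200, seed = 1)
#' critical_values(sim, gammas = c(0.05, 0.10))
#' @export
critical_values <- function(sim, gammas = c(0.01, 0.02, 0.05, 0.10, 0.20),
                            convention = c("upper", "lower")) {
  stopifnot(inherits(sim, "cr_null_sim"))
  convention <- match.arg(convention)
  if (any(gammas <= 0) || any(gammas >= 1))
    stop("'gammas' must lie strictly inside (0, 1)", call. = FALSE)
  B <- sim$reps
  rows <- expand.grid(statistic = colnames(sim$draws), gamma = gammas,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows$critical_value <- mapply(function(stat, g) {
    ranked <- sort(sim$draws[, stat])
    idx <- if (convention == "upper") ceiling((1 - g) * B) else ceiling(g * B)
    ranked[max(1L, idx)]
  }, rows$statistic, rows$gamma)
  data.frame(statistic = rows$statistic, n = sim$n, r = sim$r,
             gamma = rows$gamma, critical_value = rows$critical_value,
             row.names = NULL)
}

#' Default simulation size grid
#'
#' The `(n, r)` cells used for the packaged critical-value tables:
#' complete samples at `n = 5, 10, 15, 20, 30, 40, 50` and the censored
#' pairs `5(3), 10(6), 15(9), 20(12), 30(22), 40(32), 50(42)`.
#'
#' @param censored logical; return the censored pairs instead of the
#'   complete-sample sizes.
#' @return data frame with columns `n` and `r`.
#' @export
default_size_grid <- function(censored = FALSE) {
  n <- c(5L, 10L, 15L, 20L, 30L, 40L, 50L)
  r <- if (censored) c(3L, 6L, 9L, 12L, 22L, 32L, 42L) else n
  data.frame(n = n, r = r)
}

#' Generate a full critical-value table
#'
#' Runs [simulate_null()] and [critical_values()] over a grid of `(n, r)`
#' cells and binds the rows into one table carrying full provenance
#' (case, generating parameters, reps, master seed, convention) as
#' attributes, which [write_cv_table()] stores in a metadata sidecar.
#' Each cell gets its own deterministic sub-seed.
#'
#' @param sizes data frame with columns `n`, `r`; defaults to both the
#'   complete and censored grids of [default_size_grid()].
#' @inheritParams simulate_null
#' @inheritParams critical_values
#' @return a data frame of class `"cr_cv_table"` (columns `statistic`, `n`,
#'   `r`, `gamma`, `critical_value`) with metadata attributes.
#' @examples
#' tab <- cr_critical_tables(sizes = data.frame(n = 10, r = 10),
#'                           case = "beta_known", reps = 200, seed = 1)
#' subset(tab, gamma == 0.05)
#' @export
cr_critical_tables <- function(sizes = rbind(default_size_grid(FALSE),
                                             default_size_grid(TRUE)),
                               case = c("both_unknown", "beta_known"),
                               alpha = 1, beta = 0.5, reps = 5000,
                               seed = NULL,
                               gammas = c(0.01, 0.02, 0.05, 0.10, 0.20),
                               convention = c("upper", "lower")) {
  case <- match.arg(case)
  convention <- match.arg(convention)
  stopifnot(is.data.frame(sizes), all(c("n", "r") %in% names(sizes)))
  cell_seeds <- make_subseeds(seed, nrow(sizes))
  out <- do.call(rbind, lapply(seq_len(nrow(sizes)), function(i) {
    sim <- simulate_null(sizes$n[i], sizes$r[i], case = case,
                         alpha = alpha, beta = beta, reps = reps,
                         seed = cell_seeds[i])
    critical_values(sim, gammas = gammas, convention = convention)
  }))
  structure(out, class = c("cr_cv_table", "data.frame"),
            case = case, alpha = alpha, beta = beta, reps = reps,
            seed = seed, convention = convention)
}

cv_lookup <- function(table, statistic, n, r, gamma) {
  hit <- table$statistic == statistic & table$n == n & table$r == r &
    abs(table$gamma - gamma) < 1e-12
  if (sum(hit) != 1L)
    stop(sprintf("no critical value for (%s, n=%d, r=%d, gamma=%g) in table",
                 statistic, n, r, gamma), call. = FALSE)
  table$critical_value[hit]
}
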