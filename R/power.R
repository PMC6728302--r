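## Power of the three modified tests against non-CR lifetime alternatives.

#' Estimate power of the modified tests against one alternative
#'
#' For each replicate: draw a size-`n` sample from the alternative, sort,
#' keep the first `r` order statistics, fit the Compound Rayleigh model
#' (same estimation case as the critical-value table), compute the three
#' modified statistics, and reject when a statistic exceeds its
#' upper-convention critical value.  Power is the rejection fraction.
#'
#' @param alt an [alt_spec()] (or family name).  Using
#'   `alt_spec("compound_rayleigh", ...)` here measures the empirical size
#'   of the test instead of power.
#' @param n,r sample size and observed count.
#' @param level significance level; a `(statistic, n, r, level)` row must
#'   exist in `table`.
#' @param table a `"cr_cv_table"` from [cr_critical_tables()] built under
#'   the `"upper"` convention.
#' @param case estimation case, matching the table's.
#' @param beta scale held fixed in the `"beta_known"` case.
#' @param reps number of replicates.
#' @param seed integer master seed.
#' @return an object of class `"cr_power"`: list with `power` (named vector
#'   over statistics), the configuration, and `table_meta` provenance.
#' @examples
#' tab <- cr_critical_tables(sizes = data.frame(n = 10, r = 10),
#'                           case = "beta_known", reps = 200, seed = 1)
#' estimate_power(alt_spec("exponential"), n = 10, r = 10, level = 0.05,
#'                table = tab, case = "beta_known", reps = 100, seed = 2)
#' @export
estimate_power <- function(alt, n, r = n, level = 0.05, table,
                           case = c("both_unknown", "beta_known"),
                           beta = 0.5, reps = 10000, seed = NULL) {
  if (is.character(alt)) alt <- alt_spec(alt)
  stopifnot(inherits(alt, "alt_spec"))
  case <- match.arg(case)
  if (reps < 1) stop("'reps' must be at least 1", call. = FALSE)
  if (!identical(attr(table, "convention", exact = TRUE), "upper") &&
      !is.null(attr(table, "convention", exact = TRUE)))
    stop("power estimation requires an 'upper'-convention table", call. = FALSE)
  crit <- vapply(c("ks", "cvm", "ad"),
                 function(st) cv_lookup(table, st, n, r, level), numeric(1))
  subseeds <- make_subseeds(seed, reps)
  rejections <- c(ks = 0L, cvm = 0L, ad = 0L)
  for (k in seq_len(reps)) {
    x <- sort(ralt(alt, n, seed = subseeds[k]))[seq_len(r)]
    s <- censored_sample(x, n = n)
    fit <- if (case == "beta_known") cr_mle(s, beta = beta) else cr_mle(s)
    st <- cr_gof_stats(s, fit$alpha, fit$beta)
    rejections <- rejections + (st > crit)
  }
  structure(list(power = rejections / reps, alt = alt, n = as.integer(n),
                 r = as.integer(r), level = level, case = case,
                 reps = as.integer(reps), seed = seed,
                 critical_values = crit,
                 table_meta = attributes(table)[c("case", "alpha", "beta",
                                                  "reps", "seed", "convention")]),
            class = "cr_power")
}

#' @export
print.cr_power <- function(x, ...) {
  cat(sprintf("Power vs %s (n = %d, r = %d, level = %g, case = %s, reps = %d)\n",
              x$alt$family, x$n, x$r, x$level, x$case, x$reps))
  print(round(x$power, 4))
  invisible(x)
}

#' Power table over alternatives and sample sizes
#'
#' Runs [estimate_power()] over the cross of alternatives and `(n, r)`
#' cells, generating a matching critical-value table first (so the
#' experiment is internally consistent: same estimation case, same
#' convention, stated reps and seeds).
#'
#' @param alternatives list of [alt_spec()] objects (or family names).
#'   Defaults to the exponential (mean 1.5), gamma (shape 1.5, scale 2) and
#'   chi-square (4 df) alternatives.
#' @param sizes data frame with columns `n`, `r`; defaults to complete and
#'   censored cells at `n = 5, 15, 30` (`r = 3, 9, 22` censored).
#' @param level significance level.
#' @param case estimation case for both tables and power runs.
#' @param beta scale held fixed in the `"beta_known"` case.
#' @param table_reps,power_reps Monte Carlo sizes for the two stages.
#' @param seed integer master seed (split deterministically between stages).
#' @return a data frame of class `"cr_power_table"` with one row per
#'   (alternative, n, r, statistic): columns `alternative`, `n`, `r`,
#'   `statistic`, `level`, `power`, plus provenance attributes.
#' @export
power_table <- function(alternatives = list(alt_spec("exponential"),
                                            alt_spec("gamma"),
                                            alt_spec("chi_square")),
                        sizes = data.frame(n = c(5L, 15L, 30L, 5L, 15L, 30L),
                                           r = c(5L, 15L, 30L, 3L, 9L, 22L)),
                        level = 0.05,
                        case = c("both_unknown", "beta_known"),
                        beta = 0.5, table_reps = 5000, power_reps = 10000,
                        seed = NULL) {
  case <- match.arg(case)
  alternatives <- lapply(alternatives,
                         function(a) if (is.character(a)) alt_spec(a) else a)
  seeds <- make_subseeds(seed, 1L + length(alternatives) * nrow(sizes))
  tab <- cr_critical_tables(sizes = unique(sizes[c("n", "r")]), case = case,
                            beta = beta, reps = table_reps, seed = seeds[1L],
                            gammas = level, convention = "upper")
  k <- 1L
  rows <- list()
  for (alt in alternatives) {
    for (i in seq_len(nrow(sizes))) {
      k <- k + 1L
      pw <- estimate_power(alt, n = sizes$n[i], r = sizes$r[i], level = level,
                           table = tab, case = case, beta = beta,
                           reps = power_reps, seed = seeds[k])
      rows[[length(rows) + 1L]] <-
        data.frame(alternative = alt$family, n = sizes$n[i], r = sizes$r[i],
                   statistic = names(pw$power), level = level,
                   power = unname(pw$power), row.names = NULL)
    }
  }
  structure(do.call(rbind, rows),
            class = c("cr_power_table", "data.frame"),
            case = case, beta = beta, table_reps = table_reps,
            power_reps = power_reps, seed = seed, level = level)
}
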