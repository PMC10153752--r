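#' Perkins genetic map distance from tetrad counts
#'
#' The Perkins estimator corrects for double crossovers using the
#' nonparental-ditype class:
#' \deqn{cM = 50 (TT + 6\,NPD) / (PD + TT + NPD).}
#' It is unbounded and may exceed 50 cM. The standard error is the
#' multinomial delta-method SE of [perkins_se()].
#'
#' @param counts An [interval_counts()] object (or anything with fields
#'   `PD`, `TT`, `NPD`).
#' @return A `map_estimate`: list with `cM`, `se` (both centimorgans) and `n`.
#' @examples
#' perkins_distance(interval_counts(PD = 80, TT = 20, NPD = 0))  # 10 cM
#' @export
perkins_distance <- function(counts) {
  n <- counts$PD + counts$TT + counts$NPD
  if (n <= 0) stop("cannot estimate a map distance from zero tetrads")
  cM <- 50 * (counts$TT + 6 * counts$NPD) / n
  structure(list(interval = counts$interval, cM = cM,
                 se = perkins_se(counts), n = as.integer(n)),
            class = "map_estimate")
}

#' Delta-method standard error of the Perkins distance
#'
#' Each tetrad contributes a score X: 0 for PD, 1/2 for TT, 3 for NPD, so the
#' Perkins distance is 100 times the mean score. The SE is the multinomial
#' (delta-method) standard error of that mean at the observed class
#' frequencies: \eqn{100\sqrt{(E[X^2]-E[X]^2)/n}}. It matches a
#' nonparametric bootstrap over tetrads closely for moderate n, and is 0 when
#' all tetrads fall in one class.
#'
#' @inheritParams perkins_distance
#' @return Standard error in centimorgans.
#' @export
perkins_se <- function(counts) {
  n <- counts$PD + counts$TT + counts$NPD
  if (n <= 0) stop("cannot estimate a standard error from zero tetrads")
  p <- c(counts$PD, counts$TT, counts$NPD) / n
  x <- c(0, 0.5, 3)
  m1 <- sum(p * x)
  m2 <- sum(p * x^2)
  100 * sqrt(max(m2 - m1^2, 0) / n)
}

#' @export
print.map_estimate <- function(x, ...) {
  lbl <- if (is.na(x$interval)) "" else paste0(x$interval, ": ")
  cat(sprintf("%s%.1f +/- %.1f cM (n=%d tetrads)\n", lbl, x$cM, x$se, x$n))
  invisible(x)
}

#' Single-spore recombination frequency with exact confidence interval
#'
#' Recombination frequency among single spores, as a percentage:
#' `100 * recombinant / (parental + recombinant)`, with a two-sided
#' Clopper-Pearson exact binomial confidence interval.
#'
#' @param parental,recombinant Spore counts.
#' @param conf_level Confidence level (default 0.95).
#' @return List with `rf` (percent), `lower`, `upper` (percent bounds),
#'   `n`, and `conf_level`.
#' @export
single_spore_rf <- function(parental, recombinant, conf_level = 0.95) {
  n <- parental + recombinant
  if (n <= 0) stop("cannot estimate a frequency from zero spores")
  x <- recombinant
  alpha <- 1 - conf_level
  # Clopper-Pearson bounds via the beta quantile form of the exact interval
  lower <- if (x == 0) 0 else qbeta(alpha / 2, x, n - x + 1)
  upper <- if (x == n) 1 else qbeta(1 - alpha / 2, x + 1, n - x)
  structure(list(rf = 100 * x / n, lower = 100 * lower, upper = 100 * upper,
                 n = as.integer(n), conf_level = conf_level),
            class = "spore_rf")
}

#' @export
print.spore_rf <- function(x, ...) {
  cat(sprintf("RF = %.1f%% (%d%% CI %.1f-%.1f, n=%d spores)\n",
              x$rf, round(100 * x$conf_level), x$lower, x$upper, x$n))
  invisible(x)
}
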