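#' Log-likelihood-ratio (G) test of a contingency table
#'
#' Computes the plain G statistic \eqn{G = 2\sum O \ln(O/E)} over cells with
#' a positive observed count, expected counts from the row/column marginals.
#' No Williams or continuity correction is applied. Columns with a zero total
#' are dropped before computing the degrees of freedom
#' `(rows - 1) * (remaining cols - 1)`; if no degrees of freedom remain, the
#' p-value is 1 with a warning.
#'
#' @param tab Non-negative integer matrix (typically 2x3: the PD/TT/NPD
#'   distribution of one interval in two subsets of tetrads).
#' @return List with `G`, `df` and `p` (chi-square upper tail).
#' @export
g_test <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || sum(tab) <= 0)
    stop("g_test needs a non-negative table with a positive total")
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  pos <- tab > 0
  G <- 2 * sum(tab[pos] * log(tab[pos] / E[pos]))
  if (df < 1L) {
    warning("no degrees of freedom left after dropping empty columns; p = 1")
    return(list(G = G, df = 0L, p = 1))
  }
  list(G = G, df = df, p = pchisq(G, df, lower.tail = FALSE))
}

# Perkins distance of one margin of the joint table within the subset of
# tetrads that are recombinant ("present") or non-recombinant ("absent") in
# the reference margin. reference = 1 partitions on interval X and measures Y.
malkova_direction <- function(joint, reference, alpha) {
  m <- unclass(joint)
  if (reference == 2L) m <- t(m)
  absent <- m["PD", ]              # no recombination event in the reference
  present <- m["TT", ] + m["NPD", ]
  sub <- function(v, lab) interval_counts(v[["PD"]], v[["TT"]], v[["NPD"]],
                                          interval = lab)
  out <- list(reference = attr(joint, "intervals")[reference],
              measured = attr(joint, "intervals")[3L - reference],
              cM_present = NULL, cM_absent = NULL, ratio = NA_real_,
              G = NA_real_, df = NA_integer_, p = NA_real_,
              flag = NA_character_)
  if (sum(present) == 0 || sum(absent) == 0) {
    out$flag <- "empty subset"
    return(out)
  }
  out$cM_present <- perkins_distance(sub(present, "present"))
  out$cM_absent <- perkins_distance(sub(absent, "absent"))
  gt <- g_test(rbind(absent = absent, present = present))
  out[c("G", "df", "p")] <- gt
  if (out$cM_absent$cM == 0) {
    out$flag <- "cM_absent = 0"
  } else {
    out$ratio <- out$cM_present$cM / out$cM_absent$cM
  }
  out
}

#' Malkova crossover-interference ratio for an adjacent interval pair
#'
#' Partitions the tetrads by the presence or absence of a recombination event
#' (TT or NPD class) in a reference interval, estimates the Perkins map
#' distance of the adjacent interval in each subset, and reports the ratio
#' distance(crossover present) / distance(crossover absent). The computation
#' is done in both directions (each interval in turn as reference) and
#' `mean_ratio` is the arithmetic mean of the two directional ratios. A ratio
#' below 1 indicates positive interference: a crossover in the reference
#' interval shrinks the effective map of its neighbour. Significance of the
#' difference in tetrad-class distribution between the two subsets is
#' assessed per direction with a [g_test()] on the 2x3 (or, with
#' `collapse = TRUE`, the 2x2 recombinant/non-recombinant) table.
#'
#' @param joint A [joint_counts()] table (see [joint_tally()]).
#' @param alpha Significance level for the interference call.
#' @param collapse Collapse the compared distributions to
#'   recombinant/non-recombinant before the G test (2x2 instead of 2x3).
#' @return A `malkova_result`: the pair id, the two directional results
#'   (reference interval, subset map estimates, ratio, G, df, p, flags),
#'   `mean_ratio`, and the interference `call` from [interference_call()].
#' @export
malkova <- function(joint, alpha = 0.05, collapse = FALSE) {
  stopifnot(inherits(joint, "joint_counts"))
  if (attr(joint, "n") <= 0) stop("empty joint table")
  j <- joint
  dirs <- lapply(1:2, malkova_direction, joint = j, alpha = alpha)
  if (collapse) {
    # redo each G test on the 2x2 recombinant/non-recombinant fold
    dirs <- lapply(1:2, function(ref) {
      d <- dirs[[ref]]
      m <- unclass(j); if (ref == 2L) m <- t(m)
      absent <- m["PD", ]; present <- m["TT", ] + m["NPD", ]
      if (sum(absent) > 0 && sum(present) > 0) {
        tab <- rbind(absent, present)
        tab <- cbind(nonrec = tab[, "PD"], rec = tab[, "TT"] + tab[, "NPD"])
        d[c("G", "df", "p")] <- g_test(tab)
      }
      d
    })
  }
  ratios <- vapply(dirs, `[[`, numeric(1), "ratio")
  mean_ratio <- if (anyNA(ratios)) NA_real_ else mean(ratios)
  res <- structure(list(pair = attr(joint, "pair"), directions = dirs,
                        mean_ratio = mean_ratio, alpha = alpha,
                        collapse = collapse, call = NA_character_),
                   class = "malkova_result")
  res$call <- interference_call(res, alpha)
  res
}

#' Coefficient of coincidence for an interval pair
#'
#' Tetrad-level coefficient of coincidence: the observed number of tetrads
#' recombinant (TT or NPD) in both intervals divided by the number expected
#' under independence, `n * fX * fY`, where `fX` and `fY` are the marginal
#' recombinant-tetrad frequencies. COC below 1 indicates positive
#' interference; COC is undefined (flagged `NA`) when either marginal
#' frequency is zero.
#'
#' @param joint A [joint_counts()] table.
#' @return A `coc_result`: `observed_dco`, `expected_dco`, `coc`, marginal
#'   recombinant frequencies `fX`, `fY`, and `n`.
#' @export
coc <- function(joint) {
  stopifnot(inherits(joint, "joint_counts"))
  m <- unclass(joint)
  n <- sum(m)
  if (n <= 0) stop("empty joint table")
  recX <- rowSums(m)[c("TT", "NPD")]
  recY <- colSums(m)[c("TT", "NPD")]
  fX <- sum(recX) / n
  fY <- sum(recY) / n
  observed <- sum(m[c("TT", "NPD"), c("TT", "NPD")])
  expected <- n * fX * fY
  structure(list(pair = attr(joint, "pair"),
                 observed_dco = as.integer(observed), expected_dco = expected,
                 coc = if (expected > 0) observed / expected else NA_real_,
                 fX = fX, fY = fY, n = as.integer(n)),
            class = "coc_result")
}

#' Interference call from a Malkova result
#'
#' Applies the published decision rule: positive interference when the mean
#' ratio is below 1 and at least one directional G test has p below `alpha`;
#' a negative-interference candidate when the mean ratio is above 1 with at
#' least one significant G test; otherwise no detectable interference.
#' Results whose ratios are undefined (empty subset or zero denominator) are
#' "not evaluable".
#'
#' @param result A `malkova_result` from [malkova()].
#' @param alpha Significance level.
#' @return One of `"positive interference"`, `"no detectable interference"`,
#'   `"negative-interference candidate"`, `"not evaluable"`.
#' @export
interference_call <- function(result, alpha = 0.05) {
  stopifnot(inherits(result, "malkova_result"))
  if (is.na(result$mean_ratio)) return("not evaluable")
  ps <- vapply(result$directions, `[[`, numeric(1), "p")
  sig <- any(!is.na(ps) & ps < alpha)
  if (result$mean_ratio < 1 && sig) "positive interference"
  else if (result$mean_ratio > 1 && sig) "negative-interference candidate"
  else "no detectable interference"
}

#' @export
print.malkova_result <- function(x, ...) {
  cat("Malkova interference analysis, pair", x$pair, "\n")
  for (d in x$directions) {
    if (is.na(d$ratio)) {
      cat(sprintf("  ref %s: ratio undefined (%s)\n", d$reference, d$flag))
    } else {
      cat(sprintf(
        "  ref %s: %s %.1f cM (CO present) / %.1f cM (CO absent) = %.2f; G=%.2f, df=%d, p=%.3g\n",
        d$reference, d$measured, d$cM_present$cM, d$cM_absent$cM, d$ratio,
        d$G, d$df, d$p))
    }
  }
  if (!is.na(x$mean_ratio))
    cat(sprintf("  mean ratio %.2f -> %s\n", x$mean_ratio, x$call))
  else cat("  ", x$call, "\n")
  invisible(x)
}

#' @export
print.coc_result <- function(x, ...) {
  cat(sprintf(
    "COC, pair %s: observed DCO %d / expected %.2f = %s (n=%d)\n",
    x$pair, x$observed_dco, x$expected_dco,
    if (is.na(x$coc)) "undefined" else sprintf("%.2f", x$coc), x$n))
  invisible(x)
}

#' Interference summary across adjacent interval pairs
#'
#' Runs [malkova()] and [coc()] on every adjacent interval pair of a map and
#' returns one summary row per pair.
#'
#' @inheritParams classify_interval
#' @param alpha Significance level for interference calls.
#' @return A data frame with columns `pair`, `n`, `ratio_ref_X`,
#'   `ratio_ref_Y`, `mean_ratio`, `p_ref_X`, `p_ref_Y`, `coc`, `call`.
#' @export
interference_summary <- function(tetrads, map, parental_phase = c(0, 0),
                                 alpha = 0.05) {
  iv <- intervals(map)
  if (nrow(iv) < 2L) stop("need at least 2 intervals for interference analysis")
  rows <- lapply(seq_len(nrow(iv) - 1L), function(i) {
    j <- joint_tally(tetrads, map, iv$interval[i], iv$interval[i + 1L],
                     parental_phase)
    mk <- malkova(j, alpha)
    cc <- coc(j)
    data.frame(pair = attr(j, "pair"), n = attr(j, "n"),
               ratio_ref_X = mk$directions[[1]]$ratio,
               ratio_ref_Y = mk$directions[[2]]$ratio,
               mean_ratio = mk$mean_ratio,
               p_ref_X = mk$directions[[1]]$p,
               p_ref_Y = mk$directions[[2]]$p,
               coc = cc$coc, call = mk$call, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
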