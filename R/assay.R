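#' Spore-autonomous fluorescence assay counts
#'
#' The fluorescence assay scores tetrads, without dissection, as tetratype
#' (one crossover between the linked reporters) or parental ditype; double
#' crossover classes are not scored, so the data model carries only TT and
#' PD counts.
#'
#' @param TT,PD Non-negative integer tetrad counts.
#' @param strain Strain or condition label.
#' @return An `assay_counts` object.
#' @export
assay_counts <- function(TT, PD, strain = NA_character_) {
  if (any(c(TT, PD) < 0) || any(c(TT, PD) != round(c(TT, PD))))
    stop("TT and PD must be non-negative integers")
  structure(list(strain = strain, TT = as.integer(TT), PD = as.integer(PD)),
            class = "assay_counts")
}

#' Tetratype fraction of an assay count
#'
#' @param counts An [assay_counts()] object (or list with `TT`, `PD`).
#' @return `TT / (TT + PD)`, a fraction in `[0, 1]`.
#' @export
tetratype_fraction <- function(counts) {
  n <- counts$TT + counts$PD
  if (n <= 0) stop("cannot compute a tetratype fraction from zero tetrads")
  counts$TT / n
}

#' Two-tailed Fisher's exact test for two assay counts
#'
#' Exact hypergeometric test on the 2x2 table of (TT, PD) counts of two
#' strains. The two-sided p-value uses the probability-mass convention: the
#' sum of the probabilities of all tables (at the observed marginals) whose
#' probability does not exceed that of the observed table, with the standard
#' 1e-7 relative tolerance for ties.
#'
#' @param a,b Two [assay_counts()] objects.
#' @return Two-tailed p-value.
#' @export
fisher_2x2 <- function(a, b) {
  if (a$TT + a$PD <= 0 || b$TT + b$PD <= 0)
    stop("both strains need a positive tetrad total")
  fisher_p(a$TT, a$PD, b$TT, b$PD)
}

# probability-mass two-sided Fisher p for table [[x11,x12],[x21,x22]]
fisher_p <- function(x11, x12, x21, x22) {
  m <- x11 + x12          # row 1 total
  n <- x21 + x22          # row 2 total
  k <- x11 + x21          # column 1 total
  support <- max(0, k - n):min(k, m)
  d <- stats::dhyper(support, m, n, k)
  min(1, sum(d[d <= stats::dhyper(x11, m, n, k) * (1 + 1e-7)]))
}

#' Pearson chi-square test for two assay counts
#'
#' Plain 2x2 Pearson chi-square, one degree of freedom, no continuity
#' correction. If any expected cell count is zero the p-value is undefined
#' and `NA` is returned with a warning.
#'
#' @inheritParams fisher_2x2
#' @return List with `statistic`, `df` and `p`.
#' @export
chi2_2x2 <- function(a, b) {
  if (a$TT + a$PD <= 0 || b$TT + b$PD <= 0)
    stop("both strains need a positive tetrad total")
  tab <- rbind(c(a$TT, a$PD), c(b$TT, b$PD))
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(E == 0)) {
    warning("zero expected cell count; chi-square p undefined")
    return(list(statistic = NA_real_, df = 1L, p = NA_real_))
  }
  stat <- sum((tab - E)^2 / E)
  list(statistic = stat, df = 1L, p = pchisq(stat, 1L, lower.tail = FALSE))
}

#' Benjamini-Hochberg adjustment of a family of p-values
#'
#' Standard step-up adjusted p-values (monotone-enforced), with rejection
#' where the adjusted p-value is at or below the stated false discovery
#' rate. The family is the set of comparisons passed in one call; families
#' from different experiments/panels should not be pooled.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @param fdr False discovery rate (default 0.05).
#' @param comparison Optional labels, one per p-value.
#' @return A data frame with columns `comparison`, `p`, `p_adj`, `reject`.
#' @export
bh_adjust <- function(p, fdr = 0.05, comparison = NULL) {
  if (!length(p))
    return(data.frame(comparison = character(), p = numeric(),
                      p_adj = numeric(), reject = logical()))
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  if (is.null(comparison)) comparison <- paste0("test_", seq_along(p))
  p_adj <- stats::p.adjust(p, method = "BH")
  data.frame(comparison = comparison, p = p, p_adj = p_adj,
             reject = p_adj <= fdr, stringsAsFactors = FALSE)
}

#' Classify a mutant phenotype against wild-type and null controls
#'
#' Tests the mutant's tetratype counts against a wild-type control and a null
#' control; both raw p-values enter one Benjamini-Hochberg family.
#' "Distinguishable" means rejected after adjustment at the given FDR. A
#' strain distinguishable from the null only is wild-type-like (`"+"`), from
#' wild-type only is null-like (`"-"`), from both is intermediate (`"INT"`),
#' and from neither is `"indeterminate"` (typically underpowered counts).
#'
#' @param mutant,wt,null [assay_counts()] for the test strain and the two
#'   controls.
#' @param fdr False discovery rate for the two-test family.
#' @param test `"fisher"` (default, two-tailed exact) or `"chi2"`.
#' @return A `phenotype_call`: list with `call`, the per-comparison `records`
#'   data frame (raw and adjusted p), `test` and `fdr`.
#' @export
classify_phenotype <- function(mutant, wt, null, fdr = 0.05,
                               test = c("fisher", "chi2")) {
  test <- match.arg(test)
  pfun <- function(a, b)
    if (test == "fisher") fisher_2x2(a, b) else chi2_2x2(a, b)$p
  p <- c(pfun(mutant, wt), pfun(mutant, null))
  rec <- bh_adjust(p, fdr, comparison = c("vs_wt", "vs_null"))
  dist_wt <- rec$reject[1L]
  dist_null <- rec$reject[2L]
  call <- if (dist_null && !dist_wt) "+"
          else if (dist_wt && !dist_null) "-"
          else if (dist_wt && dist_null) "INT"
          else "indeterminate"
  structure(list(strain = mutant$strain, call = call, records = rec,
                 test = test, fdr = fdr),
            class = "phenotype_call")
}

#' @export
print.phenotype_call <- function(x, ...) {
  cat(sprintf("Phenotype call%s: %s (%s test, BH at %.0f%% FDR)\n",
              if (is.na(x$strain)) "" else paste0(" for ", x$strain),
              x$call, x$test, 100 * x$fdr))
  print(x$records, row.names = FALSE)
  invisible(x)
}

#' Analyse a table of fluorescence-assay counts
#'
#' Computes the tetratype fraction for every strain and, for rows with
#' `role == "test"`, tests against the `wt_control` and `null_control` rows.
#' All comparisons in the call form one Benjamini-Hochberg family.
#'
#' @param counts Data frame with columns `strain`, `TT`, `PD` and `role`
#'   (`test`, `wt_control` or `null_control`; exactly one of each control).
#' @param fdr False discovery rate.
#' @param test `"fisher"` or `"chi2"`.
#' @return A data frame with one row per test strain: tetratype percentages,
#'   raw and BH-adjusted p-values against each control, and the `+`/`-`/
#'   `INT`/`indeterminate` call; the statistical options used are attached
#'   as attributes `test` and `fdr`.
#' @export
assay_analysis <- function(counts, fdr = 0.05, test = c("fisher", "chi2")) {
  test <- match.arg(test)
  need <- c("strain", "TT", "PD", "role")
  if (!all(need %in% names(counts)))
    stop("assay table lacks column(s): ",
         paste(setdiff(need, names(counts)), collapse = ", "))
  getrow <- function(role) {
    i <- which(counts$role == role)
    if (length(i) != 1L) stop("need exactly one ", role, " row")
    assay_counts(counts$TT[i], counts$PD[i], counts$strain[i])
  }
  wt <- getrow("wt_control")
  null <- getrow("null_control")
  tests <- which(counts$role == "test")
  pfun <- function(a, b)
    if (test == "fisher") fisher_2x2(a, b) else chi2_2x2(a, b)$p
  p <- unlist(lapply(tests, function(i) {
    m <- assay_counts(counts$TT[i], counts$PD[i], counts$strain[i])
    c(pfun(m, wt), pfun(m, null))
  }))
  labs <- as.vector(rbind(paste0(counts$strain[tests], "_vs_wt"),
                          paste0(counts$strain[tests], "_vs_null")))
  rec <- bh_adjust(p, fdr, comparison = labs)
  out <- do.call(rbind, lapply(seq_along(tests), function(k) {
    i <- tests[k]
    r_wt <- rec[2L * k - 1L, ]
    r_null <- rec[2L * k, ]
    call <- if (r_null$reject && !r_wt$reject) "+"
            else if (r_wt$reject && !r_null$reject) "-"
            else if (r_wt$reject && r_null$reject) "INT"
            else "indeterminate"
    data.frame(strain = counts$strain[i],
               pct_tetratype = 100 * counts$TT[i] / (counts$TT[i] + counts$PD[i]),
               n = counts$TT[i] + counts$PD[i],
               p_vs_wt = r_wt$p, p_adj_vs_wt = r_wt$p_adj,
               p_vs_null = r_null$p, p_adj_vs_null = r_null$p_adj,
               call = call, stringsAsFactors = FALSE)
  }))
  structure(out, test = test, fdr = fdr,
            wt_pct = 100 * tetratype_fraction(wt),
            null_pct = 100 * tetratype_fraction(null))
}
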