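#' @importFrom stats pchisq qbeta rgamma rpois runif rbinom setNames
#' @importFrom utils read.delim write.table
NULL

TETRAD_CLASSES <- c("PD", "TT", "NPD", "UNSCORABLE")

# Columns of a tetrad table that are not marker calls.
TETRAD_ID_COLS <- c("tetrad_id", "spore_id", "viable")

# Validate a tetrad table against a map and return the marker column matrix.
# Every tetrad must have exactly 4 spores; alleles are 0/1/NA.
check_tetrad_table <- function(tetrads, map) {
  missing_cols <- setdiff(TETRAD_ID_COLS, names(tetrads))
  if (length(missing_cols))
    stop("tetrad table lacks column(s): ", paste(missing_cols, collapse = ", "))
  missing_mk <- setdiff(map$name, names(tetrads))
  if (length(missing_mk))
    stop("tetrad table lacks marker column(s): ",
         paste(missing_mk, collapse = ", "))
  sizes <- table(tetrads$tetrad_id)
  if (any(sizes != 4L))
    stop("tetrad(s) without exactly 4 spores: ",
         paste(names(sizes)[sizes != 4L], collapse = ", "))
  invisible(tetrads)
}

# Normalize a parental phase declaration for one interval: the two parental
# two-allele combinations. With biallelic 0/1 calls the phase reduces to the
# parity of the parental combination: phase c(0,0) (default) means (0,0) and
# (1,1) are parental; c(0,1) means (0,1) and (1,0) are.
phase_parity <- function(parental_phase) {
  if (is.null(parental_phase)) return(0L)
  if (length(parental_phase) != 2L || !all(parental_phase %in% c(0, 1)))
    stop("parental_phase must be a pair of allele codes in {0,1}")
  as.integer(xor(parental_phase[1L], parental_phase[2L]))
}

#' Classify tetrads into ditype classes for one interval
#'
#' For each four-spore tetrad, counts spores whose two-marker allele
#' combination is non-parental. Zero recombinant spores is a parental ditype
#' (PD), two a tetratype (TT), four a nonparental ditype (NPD). Tetrads with
#' any inviable spore, a missing allele call at either marker, or a
#' recombinant spore count of 1 or 3 (non-2:2 segregation, a putative gene
#' conversion) are UNSCORABLE.
#'
#' @param tetrads Tetrad table: a data frame with columns `tetrad_id`,
#'   `spore_id`, `viable` (logical or 0/1) and one 0/1/`NA` column per marker.
#' @param map A [marker_map()] giving marker order.
#' @param interval Marker pair, as `c("M1","M2")` or the id `"M1-M2"`.
#' @param parental_phase The two parental allele combinations, given as one of
#'   them (a length-2 vector of 0/1 codes); the other is its complement.
#'   Default `c(0,0)`: allele code 0 at both markers is parental. Set
#'   `infer_phase = TRUE` to take the majority combination as parental instead.
#' @param infer_phase Infer the parental phase as the majority two-marker
#'   combination among viable, fully scored spores. Off by default: phase is
#'   a property of the cross and should normally be declared.
#'
#' @return A character vector, one class per tetrad (in order of first
#'   appearance of `tetrad_id`), with values in `PD`, `TT`, `NPD`,
#'   `UNSCORABLE`; tetrad ids as names.
#' @seealso [tally()], [joint_tally()]
#' @export
classify_interval <- function(tetrads, map, interval, parental_phase = c(0, 0),
                              infer_phase = FALSE) {
  check_tetrad_table(tetrads, map)
  interval <- resolve_interval(map, interval)
  a1 <- as.integer(tetrads[[interval[1L]]])
  a2 <- as.integer(tetrads[[interval[2L]]])
  viable <- as.logical(tetrads$viable)
  parity <- if (infer_phase) {
    ok <- viable & !is.na(a1) & !is.na(a2)
    if (!any(ok)) stop("cannot infer parental phase: no scorable spores")
    obs <- xor(a1[ok], a2[ok])
    as.integer(mean(obs) > 0.5)
  } else {
    phase_parity(parental_phase)
  }
  recomb <- as.integer(xor(a1, a2) != parity)   # NA propagates missing calls

  id <- factor(tetrads$tetrad_id, levels = unique(tetrads$tetrad_id))
  nrec <- tapply(recomb, id, function(x) if (anyNA(x)) NA_integer_ else sum(x))
  all_viable <- tapply(viable, id, all)

  cls <- rep("UNSCORABLE", nlevels(id))
  scorable <- all_viable & !is.na(nrec) & nrec %in% c(0L, 2L, 4L)
  cls[scorable] <- c(`0` = "PD", `2` = "TT", `4` = "NPD")[
    as.character(nrec[scorable])]
  setNames(cls, levels(id))
}

#' Tally PD/TT/NPD counts for one interval
#'
#' Classifies every tetrad with [classify_interval()] and counts the scorable
#' classes; UNSCORABLE tetrads are excluded from `n` and reported separately.
#'
#' @inheritParams classify_interval
#' @return An [interval_counts()] object.
#' @export
tally <- function(tetrads, map, interval, parental_phase = c(0, 0),
                  infer_phase = FALSE) {
  interval <- resolve_interval(map, interval)
  cls <- classify_interval(tetrads, map, interval, parental_phase, infer_phase)
  tab <- table(factor(cls, levels = TETRAD_CLASSES))
  interval_counts(PD = tab[["PD"]], TT = tab[["TT"]], NPD = tab[["NPD"]],
                  interval = paste(interval, collapse = "-"),
                  unscorable = tab[["UNSCORABLE"]])
}

#' PD/TT/NPD counts for one genetic interval
#'
#' @param PD,TT,NPD Non-negative integer tetrad counts.
#' @param interval Interval id (optional label).
#' @param unscorable Count of tetrads excluded as unscorable.
#' @return An `interval_counts` object with fields `PD`, `TT`, `NPD`,
#'   `n = PD + TT + NPD`, `interval`, `unscorable`.
#' @export
interval_counts <- function(PD, TT, NPD, interval = NA_character_,
                            unscorable = 0L) {
  counts <- c(PD = PD, TT = TT, NPD = NPD)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("PD, TT and NPD must be non-negative integers")
  structure(list(interval = interval, PD = as.integer(PD), TT = as.integer(TT),
                 NPD = as.integer(NPD), n = as.integer(PD + TT + NPD),
                 unscorable = as.integer(unscorable)),
            class = "interval_counts")
}

#' @export
print.interval_counts <- function(x, ...) {
  cat(sprintf("Interval %s: PD=%d TT=%d NPD=%d (n=%d, %d unscorable)\n",
              x$interval, x$PD, x$TT, x$NPD, x$n, x$unscorable))
  invisible(x)
}

#' Joint 3x3 tally for a pair of intervals
#'
#' Cross-tabulates the ditype classes of two intervals over the tetrads that
#' are scorable in both; this table is the input to all interference
#' statistics. Row and column marginals reproduce each interval's
#' [tally()] restricted to the both-scorable subset.
#'
#' @inheritParams classify_interval
#' @param intervalX,intervalY Two distinct marker intervals. Interference
#'   statistics are conventionally computed for adjacent intervals sharing a
#'   middle marker; non-adjacent pairs are accepted with a warning.
#' @return A `joint_counts` object: a 3x3 integer matrix with rows indexed by
#'   the class in interval X and columns by interval Y, plus attributes
#'   `pair`, `intervals`, `n` and `unscorable`.
#' @export
joint_tally <- function(tetrads, map, intervalX, intervalY,
                        parental_phase = c(0, 0), infer_phase = FALSE) {
  intervalX <- resolve_interval(map, intervalX)
  intervalY <- resolve_interval(map, intervalY)
  if (identical(intervalX, intervalY))
    stop("the two intervals must be distinct")
  if (!length(intersect(intervalX, intervalY)))
    warning("intervals ", paste(intervalX, collapse = "-"), " and ",
            paste(intervalY, collapse = "-"),
            " are not adjacent; interference statistics are usually computed",
            " for adjacent intervals sharing a middle marker")
  cx <- classify_interval(tetrads, map, intervalX, parental_phase, infer_phase)
  cy <- classify_interval(tetrads, map, intervalY, parental_phase, infer_phase)
  both <- cx != "UNSCORABLE" & cy != "UNSCORABLE"
  lev <- TETRAD_CLASSES[1:3]
  m <- table(factor(cx[both], levels = lev), factor(cy[both], levels = lev))
  joint_counts(unclass(m),
               pair = paste(paste(intervalX, collapse = "-"),
                            paste(intervalY, collapse = "-"), sep = " / "),
               intervals = c(paste(intervalX, collapse = "-"),
                             paste(intervalY, collapse = "-")),
               unscorable = sum(!both))
}

#' Construct a joint 3x3 count object
#'
#' @param m 3x3 non-negative integer matrix, rows = class in interval X
#'   (PD, TT, NPD), columns = class in interval Y.
#' @param pair Pair label.
#' @param intervals Character vector of the two interval ids.
#' @param unscorable Number of tetrads excluded (unscorable in either
#'   interval).
#' @return A `joint_counts` object.
#' @export
joint_counts <- function(m, pair = NA_character_, intervals = c("X", "Y"),
                         unscorable = 0L) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(3L, 3L)) || any(m < 0) || any(m != round(m)))
    stop("joint counts must be a 3x3 non-negative integer matrix")
  storage.mode(m) <- "integer"
  dimnames(m) <- list(X = TETRAD_CLASSES[1:3], Y = TETRAD_CLASSES[1:3])
  structure(m, pair = pair, intervals = intervals,
            n = sum(m), unscorable = as.integer(unscorable),
            class = c("joint_counts", "matrix", "array"))
}

# Marginal interval_counts of a joint table (1 = interval X, 2 = interval Y).
marginal_counts <- function(joint, margin) {
  v <- apply(unclass(joint), margin, sum)
  interval_counts(v[["PD"]], v[["TT"]], v[["NPD"]],
                  interval = attr(joint, "intervals")[margin])
}

#' @export
print.joint_counts <- function(x, ...) {
  cat("Joint tetrad-class counts, pair", attr(x, "pair"),
      sprintf("(n=%d, %d unscorable)\n", attr(x, "n"), attr(x, "unscorable")))
  print(unclass(x))
  invisible(x)
}

#' Spore-viability profile of a tetrad collection
#'
#' @param tetrads Tetrad table (see [classify_interval()]); only `tetrad_id`
#'   and `viable` are used.
#' @return A `viability_profile`: counts of tetrads with exactly 4, 3, 2, 1
#'   and 0 viable spores, the number of tetrads, and the overall fraction of
#'   viable spores.
#' @export
viability_profile <- function(tetrads) {
  if (!all(c("tetrad_id", "viable") %in% names(tetrads)))
    stop("tetrad table lacks tetrad_id/viable columns")
  id <- factor(tetrads$tetrad_id, levels = unique(tetrads$tetrad_id))
  k <- tapply(as.logical(tetrads$viable), id, sum)
  counts <- table(factor(k, levels = 4:0))
  structure(list(counts = setNames(as.integer(counts), 4:0),
                 n_tetrads = nlevels(id),
                 overall_viability = sum(k) / (4 * nlevels(id))),
            class = "viability_profile")
}

#' @export
print.viability_profile <- function(x, ...) {
  cat(sprintf("Viability profile over %d tetrads (%.1f%% spores viable)\n",
              x$n_tetrads, 100 * x$overall_viability))
  pct <- 100 * x$counts / max(x$n_tetrads, 1L)
  for (k in names(x$counts))
    cat(sprintf("  %s viable spores: %d (%.1f%%)\n", k, x$counts[[k]], pct[[k]]))
  invisible(x)
}
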