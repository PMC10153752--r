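#' Configuration of a synthetic meiosis experiment
#'
#' The simulator places crossovers on a four-chromatid bivalent along genetic
#' distance. Interfering (class I) crossovers follow a stationary gamma
#' renewal process with shape `nu` (`nu = 1` is Poisson, i.e. no
#' interference; larger `nu` gives more evenly spaced, interfering
#' crossovers). A fraction `p2` of crossover activity comes from an
#' independent, non-interfering (class II) Poisson process. Rates are set so
#' the expected number of bivalent crossovers is 2 per Morgan regardless of
#' `nu` and `p2` — each crossover involves 2 of the 4 chromatids, so this
#' preserves the configured per-chromatid map length. Chromatid choice is
#' uniform and independent per event (no chromatid interference).
#'
#' @param map A [marker_map()] with genetic positions for every marker.
#' @param n_tetrads Number of tetrads to simulate.
#' @param nu Gamma shape for class I interference, `>= 1`.
#' @param p2 Fraction of crossover activity that is non-interfering class II,
#'   in `[0, 1]`.
#' @param p_death Independent per-spore inviability probability.
#' @param p_ndj Meiosis-I nondisjunction probability for bivalents with zero
#'   crossovers (kills the two spores of the pole that receives no copy).
#' @param seed Optional RNG seed for reproducible datasets.
#' @return A `sim_config` object.
#' @export
sim_config <- function(map, n_tetrads, nu = 1, p2 = 0, p_death = 0,
                       p_ndj = 0, seed = NULL) {
  stopifnot(inherits(map, "marker_map"))
  if (anyNA(map$position_cM))
    stop("the simulator needs genetic positions for every marker")
  if (n_tetrads < 0 || n_tetrads != round(n_tetrads))
    stop("n_tetrads must be a non-negative integer")
  if (nu < 1) stop("nu must be >= 1")
  probs <- c(p2 = p2, p_death = p_death, p_ndj = p_ndj)
  if (any(probs < 0 | probs > 1))
    stop("p2, p_death and p_ndj must lie in [0, 1]")
  structure(list(map = map, n_tetrads = as.integer(n_tetrads), nu = nu,
                 p2 = p2, p_death = p_death, p_ndj = p_ndj, seed = seed),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "Meiosis simulation: %d tetrads, %d markers over %.1f cM, nu=%.3g, p2=%.3g, p_death=%.3g, p_ndj=%.3g%s\n",
    x$n_tetrads, nrow(x$map),
    diff(range(x$map$position_cM)), x$nu, x$p2, x$p_death, x$p_ndj,
    if (is.null(x$seed)) "" else paste0(", seed=", x$seed)))
  invisible(x)
}

# Draw from the equilibrium (length-biased forward recurrence) distribution
# of a Gamma(shape = nu, rate = beta) renewal process. For integer nu the
# equilibrium distribution is an equal mixture of Gamma(k, beta), k = 1..nu;
# otherwise invert the closed-form equilibrium CDF
#   Fe(x) = (beta/nu) * x * (1 - pgamma(x, nu, beta)) + pgamma(x, nu + 1, beta)
req_equilibrium <- function(n, nu, beta) {
  if (abs(nu - round(nu)) < 1e-9) {
    k <- sample.int(round(nu), n, replace = TRUE)
    return(rgamma(n, shape = k, rate = beta))
  }
  Fe <- function(x) (beta / nu) * x * stats::pgamma(x, nu, beta,
                                                    lower.tail = FALSE) +
    stats::pgamma(x, nu + 1, beta)
  u <- runif(n)
  hi <- (nu / beta) * 50
  vapply(u, function(ui)
    stats::uniroot(function(x) Fe(x) - ui, c(0, hi), tol = 1e-10)$root,
    numeric(1))
}

# Place crossover events for n bivalents over a region of L Morgans.
# Returns a data frame (meiosis, pos) with events in (0, L], unsorted.
draw_crossover_positions <- function(n, L, nu, p2) {
  ev_id <- integer(0); ev_pos <- numeric(0)
  if (L > 0 && p2 < 1) {
    beta <- 2 * nu * (1 - p2)       # mean class I spacing 1/(2(1-p2)) Morgans
    idx <- seq_len(n)
    cur <- req_equilibrium(n, nu, beta)
    while (length(idx)) {
      keep <- cur <= L
      idx <- idx[keep]; cur <- cur[keep]
      if (!length(idx)) break
      ev_id <- c(ev_id, idx); ev_pos <- c(ev_pos, cur)
      cur <- cur + rgamma(length(idx), shape = nu, rate = beta)
    }
  }
  if (L > 0 && p2 > 0) {
    m2 <- rpois(n, 2 * p2 * L)
    ev_id <- c(ev_id, rep.int(seq_len(n), m2))
    ev_pos <- c(ev_pos, runif(sum(m2), 0, L))
  }
  data.frame(meiosis = ev_id, pos = ev_pos)
}

#' Simulate crossover events for bivalents
#'
#' Draws the crossover positions and chromatid assignments for `n` meioses
#' under a [sim_config()]. Positions are in Morgans along the region spanned
#' by the map; each event exchanges the distal segments of one uniformly
#' chosen chromatid of each parent.
#'
#' @param config A [sim_config()].
#' @param n Number of meioses (defaults to `config$n_tetrads`).
#' @return A list of `n` data frames, each with columns `pos` (Morgans,
#'   ascending), `ca` (chromatid 1 or 2 of parent 1) and `cb` (chromatid 3
#'   or 4 of parent 2).
#' @export
simulate_crossovers <- function(config, n = config$n_tetrads) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  L <- diff(range(config$map$position_cM)) / 100
  ev <- draw_crossover_positions(n, L, config$nu, config$p2)
  ev$ca <- sample.int(2L, nrow(ev), replace = TRUE)
  ev$cb <- sample.int(2L, nrow(ev), replace = TRUE) + 2L
  ord <- order(ev$meiosis, ev$pos)
  ev <- ev[ord, , drop = FALSE]
  out <- split(ev[c("pos", "ca", "cb")],
               factor(ev$meiosis, levels = seq_len(n)))
  names(out) <- NULL
  lapply(out, function(d) { rownames(d) <- NULL; d })
}

#' Resolve crossover events into a four-spore tetrad
#'
#' Starts from two chromatids per parent (origins 0,0,1,1), applies each
#' crossover in order of position by exchanging the distal segments of the
#' chosen chromatid pair, and reads the marker alleles off the four resulting
#' chromatids, which become the four spores.
#'
#' @param events Data frame of events as produced by [simulate_crossovers()]
#'   (columns `pos`, `ca`, `cb`; sorted by `pos`).
#' @param map A [marker_map()] with positions.
#' @return A 4 x markers integer matrix of allele origins (0/1), one row per
#'   spore, columns named by marker.
#' @export
resolve_tetrad <- function(events, map) {
  mpos <- (map$position_cM - map$position_cM[1L]) / 100
  resolve_tetrad_at(events, mpos, map$name)
}

resolve_tetrad_at <- function(events, mpos, mnames) {
  M <- length(mpos)
  geno <- matrix(NA_integer_, 4L, M, dimnames = list(NULL, mnames))
  parent <- c(0L, 0L, 1L, 1L)   # parental origin of the 4 bivalent strands
  strand <- 1:4                 # strand each spore currently follows
  nev <- if (is.null(events)) 0L else nrow(events)
  j <- 1L
  for (e in seq_len(nev)) {
    x <- events$pos[e]
    while (j <= M && mpos[j] < x) { geno[, j] <- parent[strand]; j <- j + 1L }
    # the event joins original strands ca and cb: spores tracking them switch
    ia <- match(events$ca[e], strand)
    ib <- match(events$cb[e], strand)
    strand[c(ia, ib)] <- strand[c(ib, ia)]
  }
  while (j <= M) { geno[, j] <- parent[strand]; j <- j + 1L }
  geno
}

#' Expected tetrad-class frequencies without interference
#'
#' Closed-form oracle: for an interval of `d` Morgans under a Poisson
#' crossover process (no crossover or chromatid interference), mixes the
#' k-crossover class distribution over `k ~ Poisson(2d)`. Per event the class
#' evolves as PD -> TT; TT -> PD w.p. 1/4, TT w.p. 1/2, NPD w.p. 1/4;
#' NPD -> TT, starting from PD. The series is truncated at relative error
#' below 1e-12.
#'
#' @param d Interval length in Morgans (`>= 0`).
#' @return Named numeric vector `c(PD=, TT=, NPD=)` summing to 1.
#' @export
mather_frequencies <- function(d) {
  if (length(d) != 1L || is.na(d) || d < 0)
    stop("d must be a single non-negative interval length in Morgans")
  Tm <- matrix(c(0, 1, 0,
                 1 / 4, 1 / 2, 1 / 4,
                 0, 1, 0), nrow = 3, byrow = TRUE)
  lambda <- 2 * d
  K <- max(20L, stats::qpois(1 - 1e-14, lambda) + 10L)
  v <- c(1, 0, 0)
  acc <- stats::dpois(0, lambda) * v
  for (k in seq_len(K)) {
    v <- as.vector(v %*% Tm)
    acc <- acc + stats::dpois(k, lambda) * v
  }
  setNames(acc / sum(acc), c("PD", "TT", "NPD"))
}

#' Apply the viability model to simulated tetrads
#'
#' Each spore dies independently with probability `p_death`. Additionally,
#' a bivalent with zero crossovers undergoes meiosis-I nondisjunction with
#' probability `p_ndj`: both homologs travel to one pole, and the two spores
#' derived from the empty pole are inviable. With zero crossovers, spores
#' 1,2 and 3,4 are the two sister pairs, so one of those pairs (chosen
#' uniformly) is killed.
#'
#' @param viable Logical matrix (n x 4) of current viability flags.
#' @param zero_co Logical vector: did the bivalent have zero crossovers?
#' @param config A [sim_config()].
#' @return Updated logical n x 4 viability matrix.
#' @export
apply_viability <- function(viable, zero_co, config) {
  n <- nrow(viable)
  if (config$p_death > 0)
    viable <- viable & matrix(runif(4L * n) >= config$p_death, n, 4L)
  ndj <- zero_co & (runif(n) < config$p_ndj)
  if (any(ndj)) {
    pole <- sample(c(0L, 2L), sum(ndj), replace = TRUE)
    rows <- which(ndj)
    for (k in seq_along(rows))
      viable[rows[k], pole[k] + 1:2] <- FALSE
  }
  viable
}

#' Simulate a tetrad dataset
#'
#' Runs the full generative model of [sim_config()]: crossover placement,
#' resolution to four spores, and the viability model; returns a tetrad
#' table in the dialect consumed by [classify_interval()] and
#' [read_tetrad_table()]. Parent-1 alleles are coded 0, so the parental
#' phase of every interval is the default `c(0, 0)`.
#'
#' @param config A [sim_config()].
#' @return A data frame with columns `tetrad_id`, `spore_id`, `viable` and
#'   one 0/1 column per marker, 4 rows per tetrad.
#' @export
simulate_tetrads <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_tetrads
  map <- config$map
  M <- nrow(map)
  events <- simulate_crossovers(config, n)
  mpos <- (map$position_cM - map$position_cM[1L]) / 100
  G <- matrix(NA_integer_, 4L * n, M)
  base <- matrix(rep(c(0L, 0L, 1L, 1L), M), 4L, M)  # zero-crossover genotype
  for (i in seq_len(n)) {
    ev <- events[[i]]
    rows <- (4L * (i - 1L) + 1L):(4L * i)
    G[rows, ] <- if (nrow(ev) == 0L) base else resolve_tetrad_at(ev, mpos, NULL)
  }
  zero_co <- vapply(events, nrow, integer(1)) == 0L
  viable <- apply_viability(matrix(TRUE, n, 4L), zero_co, config)
  out <- data.frame(
    tetrad_id = rep(sprintf("t%05d", seq_len(n)), each = 4L),
    spore_id = rep(c("a", "b", "c", "d"), times = n),
    viable = as.integer(t(viable)),
    stringsAsFactors = FALSE)
  for (m in seq_len(M)) out[[map$name[m]]] <- G[, m]
  out
}

#' Simulate a dataset and write it with its ground truth
#'
#' Writes the tetrad table as TSV plus a JSON truth record (marker map with
#' configured positions and interval lengths, `nu`, `p2`, `p_death`,
#' `p_ndj`, `n_tetrads`, `seed`) for parameter-recovery tests. With the same
#' seed the output files are byte-identical across runs.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if absent).
#' @param prefix File-name prefix.
#' @return Invisibly, a list with the written `tetrads` and `truth` paths.
#' @export
simulate_dataset <- function(config, dir, prefix = "sim") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tet <- simulate_tetrads(config)
  tet_path <- file.path(dir, paste0(prefix, "_tetrads.tsv"))
  truth_path <- file.path(dir, paste0(prefix, "_truth.json"))
  write_tetrad_table(tet, tet_path)
  truth <- list(
    markers = config$map$name,
    position_cM = config$map$position_cM,
    interval_cM = setNames(as.list(intervals(config$map)$length_cM),
                           intervals(config$map)$interval),
    n_tetrads = config$n_tetrads, nu = config$nu, p2 = config$p2,
    p_death = config$p_death, p_ndj = config$p_ndj,
    seed = if (is.null(config$seed)) NA else config$seed)
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(list(tetrads = tet_path, truth = truth_path))
}

#' Read a simulation configuration from YAML
#'
#' The file holds `markers` (as in [read_marker_map()]) plus any of
#' `n_tetrads`, `nu`, `p2`, `p_death`, `p_ndj`, `seed`.
#'
#' @param path Path to the YAML file.
#' @param n_tetrads,seed Optional overrides of the file's values.
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path, n_tetrads = NULL, seed = NULL) {
  doc <- yaml::read_yaml(path)
  map <- read_marker_map(path)
  pick <- function(field, default) {
    if (!is.null(doc[[field]])) doc[[field]] else default
  }
  sim_config(map,
             n_tetrads = if (!is.null(n_tetrads)) n_tetrads
                         else pick("n_tetrads", 1000L),
             nu = pick("nu", 1), p2 = pick("p2", 0),
             p_death = pick("p_death", 0), p_ndj = pick("p_ndj", 0),
             seed = if (!is.null(seed)) seed else doc$seed)
}
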