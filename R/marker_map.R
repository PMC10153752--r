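#' Construct an ordered genetic marker map
#'
#' A marker map is an ordered set of markers along one chromosome. Genetic
#' positions (in centimorgans) are required by the meiosis simulator but may
#' be absent (`NA`) for observed data, where only marker order matters.
#'
#' @param name Character vector of unique marker names.
#' @param chromosome Chromosome label, recycled to the number of markers.
#' @param position_cM Numeric vector of genetic positions in centimorgans,
#'   strictly increasing where present, or `NULL`/`NA` when unknown.
#'
#' @return A `marker_map` object: a data frame with columns `name`,
#'   `chromosome`, `position_cM` and `index` (0-based order).
#' @examples
#' chrXV <- marker_map(c("URA3", "LEU2", "LYS2", "ADE2", "HIS3"), "XV",
#'                     c(0, 20.4, 41.4, 77.3, 104.9))
#' intervals(chrXV)
#' @export
marker_map <- function(name, chromosome = "chr", position_cM = NULL) {
  name <- as.character(name)
  if (length(name) < 2L)
    stop("a marker map needs at least 2 markers")
  if (anyDuplicated(name))
    stop("marker names must be unique: ", name[duplicated(name)][1L])
  if (is.null(position_cM)) position_cM <- rep(NA_real_, length(name))
  position_cM <- as.numeric(position_cM)
  if (length(position_cM) != length(name))
    stop("position_cM must match the number of markers")
  pos <- position_cM[!is.na(position_cM)]
  if (length(pos) > 1L && any(diff(pos) <= 0))
    stop("positions must be strictly increasing along the chromosome")
  structure(
    data.frame(name = name,
               chromosome = rep_len(as.character(chromosome), length(name)),
               position_cM = position_cM,
               index = seq_along(name) - 1L,
               stringsAsFactors = FALSE),
    class = c("marker_map", "data.frame"))
}

#' Consecutive marker intervals of a map
#'
#' @param map A [marker_map()].
#' @return A data frame with one row per consecutive marker pair: `interval`
#'   (id of the form `"M1-M2"`), `left`, `right`, and `length_cM` (`NA` when
#'   positions are absent).
#' @export
intervals <- function(map) {
  stopifnot(inherits(map, "marker_map"))
  i <- seq_len(nrow(map) - 1L)
  data.frame(interval = paste0(map$name[i], "-", map$name[i + 1L]),
             left = map$name[i], right = map$name[i + 1L],
             length_cM = map$position_cM[i + 1L] - map$position_cM[i],
             stringsAsFactors = FALSE)
}

# Resolve an interval given as c("M1","M2") or "M1-M2" to marker names,
# validating that both exist in the map.
resolve_interval <- function(map, interval) {
  if (is.character(interval) && length(interval) == 1L && grepl("-", interval)) {
    parts <- strsplit(interval, "-", fixed = TRUE)[[1L]]
    if (length(parts) != 2L)
      stop("cannot parse interval id: ", interval)
    interval <- parts
  }
  if (length(interval) != 2L)
    stop("an interval is a pair of marker names")
  missing <- setdiff(interval, map$name)
  if (length(missing))
    stop("unknown marker name: ", paste(missing, collapse = ", "))
  as.character(interval)
}

#' Bundled example marker maps
#'
#' `chrXV_map()` returns the five-marker chromosome XV map
#' (URA3-LEU2-LYS2-ADE2-HIS3) with wild-type interval lengths of
#' 20.4, 21.0, 35.9 and 27.6 cM; `cen8_thr1_map()` returns the two-marker
#' 20 cM CEN8-THR1 interval on chromosome VIII used by the spore-autonomous
#' fluorescence assay.
#'
#' @return A [marker_map()].
#' @export
chrXV_map <- function() {
  marker_map(c("URA3", "LEU2", "LYS2", "ADE2", "HIS3"), "XV",
             c(0, 20.4, 41.4, 77.3, 104.9))
}

#' @rdname chrXV_map
#' @export
cen8_thr1_map <- function() {
  marker_map(c("CEN8", "THR1"), "VIII", c(0, 20))
}

#' Read a marker map from a YAML file
#'
#' The file holds a `markers` sequence; each entry has `name`, optional
#' `chromosome`, and optional `position_cM`.
#'
#' @param path Path to the YAML file.
#' @return A [marker_map()].
#' @export
read_marker_map <- function(path) {
  doc <- yaml::read_yaml(path)
  mk <- doc$markers
  if (is.null(mk)) stop("no 'markers' entry in ", path)
  name <- vapply(mk, function(m) as.character(m$name), character(1))
  chromosome <- vapply(mk, function(m)
    if (is.null(m$chromosome)) "chr" else as.character(m$chromosome), character(1))
  pos <- vapply(mk, function(m)
    if (is.null(m$position_cM)) NA_real_ else as.numeric(m$position_cM), numeric(1))
  marker_map(name, chromosome, pos)
}

#' @export
print.marker_map <- function(x, ...) {
  cat("Marker map:", nrow(x), "markers on chromosome",
      unique(x$chromosome), "\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
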