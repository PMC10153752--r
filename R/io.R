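#' Read a tetrad genotype table
#'
#' Reads the tab-delimited tetrad dialect: header row, columns `tetrad_id`,
#' `spore_id`, `viable` (0/1), then one column per marker with values 0, 1 or
#' `NA` (0 = parent-1 allele). Marker order is taken from the map, not the
#' file. Malformed rows are reported with their line numbers; tetrads without
#' exactly four spores are rejected with a warning and excluded.
#'
#' @param path Path to the TSV file.
#' @param map A [marker_map()].
#' @return A validated tetrad table (data frame), ready for
#'   [classify_interval()] and friends.
#' @export
read_tetrad_table <- function(path, map) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   check.names = FALSE)
  missing_cols <- setdiff(c(TETRAD_ID_COLS, map$name), names(df))
  if (length(missing_cols))
    stop(path, ": missing column(s): ", paste(missing_cols, collapse = ", "))
  line <- seq_len(nrow(df)) + 1L   # header is line 1
  dup <- duplicated(df[c("tetrad_id", "spore_id")])
  if (any(dup))
    stop(path, ": duplicate (tetrad_id, spore_id) at line(s) ",
         paste(line[dup], collapse = ", "))
  for (col in map$name) {
    bad <- !is.na(df[[col]]) & !(df[[col]] %in% c(0, 1))
    if (any(bad))
      stop(path, ": non-binary allele call in column ", col, " at line(s) ",
           paste(line[bad], collapse = ", "))
    df[[col]] <- as.integer(df[[col]])
  }
  bad_v <- is.na(df$viable) | !(df$viable %in% c(0, 1))
  if (any(bad_v))
    stop(path, ": viable must be 0/1; offending line(s) ",
         paste(line[bad_v], collapse = ", "))
  sizes <- table(df$tetrad_id)
  incomplete <- names(sizes)[sizes != 4L]
  if (length(incomplete)) {
    warning(path, ": rejecting tetrad(s) without exactly 4 spores: ",
            paste(incomplete, collapse = ", "))
    df <- df[!(df$tetrad_id %in% incomplete), , drop = FALSE]
  }
  df[c(TETRAD_ID_COLS, map$name)]
}

#' Write a tetrad table as TSV
#'
#' @param tetrads Tetrad table data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_tetrad_table <- function(tetrads, path) {
  write.table(tetrads, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read a pre-tallied interval count table
#'
#' TSV with columns `interval`, `PD`, `NPD`, `TT` (one row per interval).
#'
#' @param path Path to the TSV file.
#' @return A named list of [interval_counts()], one per row.
#' @export
read_counts_table <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("interval", "PD", "NPD", "TT")
  if (!all(need %in% names(df)))
    stop(path, ": missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  out <- lapply(seq_len(nrow(df)), function(i)
    interval_counts(df$PD[i], df$TT[i], df$NPD[i], interval = df$interval[i]))
  setNames(out, df$interval)
}

#' Read a joint 3x3 tetrad-class table
#'
#' TSV with a `class` column holding PD/TT/NPD row labels (interval X) and
#' columns `PD`, `TT`, `NPD` (interval Y).
#'
#' @param path Path to the TSV file.
#' @param pair Pair label (defaults to the file name).
#' @return A [joint_counts()] object.
#' @export
read_joint_table <- function(path, pair = basename(path)) {
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("class", "PD", "TT", "NPD")
  if (!all(need %in% names(df)))
    stop(path, ": missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  if (!identical(sort(df$class), sort(c("PD", "TT", "NPD"))))
    stop(path, ": class column must hold PD, TT and NPD exactly once each")
  m <- as.matrix(df[match(c("PD", "TT", "NPD"), df$class), c("PD", "TT", "NPD")])
  joint_counts(m, pair = pair)
}

#' Read a fluorescence-assay count table
#'
#' TSV with columns `strain`, `TT`, `PD` and optional `role`
#' (`test`/`wt_control`/`null_control`).
#'
#' @param path Path to the TSV file.
#' @return Data frame suitable for [assay_analysis()].
#' @export
read_assay_table <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("strain", "TT", "PD")
  if (!all(need %in% names(df)))
    stop(path, ": missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  if (is.null(df$role)) df$role <- "test"
  df
}

# Provenance block embedded in every emitted result file: options used and
# md5 digests of the inputs that produced it.
provenance <- function(inputs = character(), options = list()) {
  digests <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  list(package = "tetradkit",
       version = as.character(utils::packageVersion("tetradkit")),
       options = options, input_md5 = digests)
}

write_results_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(path)
}
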