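# Builders for small hand-made tetrad tables.

# Two-marker map used by most classification fixtures.
map2 <- function() marker_map(c("M1", "M2"), "chr", c(0, 20))

# One tetrad: `spores` is a list of 4 allele vectors (one per spore).
make_tetrad <- function(spores, id = "t1", viable = rep(1L, 4),
                        markers = paste0("M", seq_along(spores[[1]]))) {
  stopifnot(length(spores) == 4L)
  df <- data.frame(tetrad_id = id, spore_id = c("a", "b", "c", "d"),
                   viable = viable, stringsAsFactors = FALSE)
  al <- do.call(rbind, spores)
  for (m in seq_along(markers)) df[[markers[m]]] <- al[, m]
  df
}

# Stack several tetrads (lists of 4 allele vectors) into one table.
make_tetrads <- function(..., markers = NULL) {
  sp <- list(...)
  if (is.null(markers)) markers <- paste0("M", seq_along(sp[[1]][[1]]))
  do.call(rbind, lapply(seq_along(sp), function(i)
    make_tetrad(sp[[i]], id = sprintf("t%03d", i), markers = markers)))
}

# Canonical two-marker tetrads by class (phase: 0,0 / 1,1 parental)
pd_spores <- function() list(c(0, 0), c(0, 0), c(1, 1), c(1, 1))
tt_spores <- function() list(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
npd_spores <- function() list(c(0, 1), c(0, 1), c(1, 0), c(1, 0))

# n identical tetrads of one class
rep_tetrads <- function(spores, n, markers = c("M1", "M2")) {
  do.call(rbind, lapply(seq_len(n), function(i)
    make_tetrad(spores, id = sprintf("t%03d", i), markers = markers)))
}

# Build a joint_counts object directly from a 3x3 matrix (rows = interval X)
jc <- function(m, pair = "X / Y") joint_counts(m, pair = pair)
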