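#' Run an analysis pipeline end to end
#'
#' Drives the package's stages from a single configuration: `simulate`
#' (write a synthetic dataset), `map` (classify, tally and estimate Perkins
#' distances for every interval), `interference` (Malkova and COC for every
#' adjacent pair), `viability` (spore-viability profile) and `assay`
#' (fluorescence-assay analysis). Results are written as JSON (and TSV where
#' tabular) into `out_dir`; each result file embeds the statistical options
#' and the md5 digests of its inputs. Warnings (unscorable tetrads,
#' undefined ratios) never abort a run; malformed input always does.
#'
#' @param analysis One of `"simulate"`, `"map"`, `"interference"`,
#'   `"viability"`, `"assay"`.
#' @param out_dir Output directory, created if absent.
#' @param tetrads_path Tetrad TSV (for map/interference/viability).
#' @param map Marker map object, or path to a marker-map YAML.
#' @param assay_path Assay count TSV (for `assay`).
#' @param sim YAML path or [sim_config()] (for `simulate`).
#' @param parental_phase Parental phase passed to the classifiers.
#' @param test,fdr,alpha Statistical options: assay test choice
#'   (`"fisher"`/`"chi2"`), false discovery rate, interference significance
#'   level.
#' @param seed Seed forwarded to `simulate`.
#' @return Invisibly, the list of computed results.
#' @export
run_pipeline <- function(analysis = c("map", "interference", "viability",
                                      "assay", "simulate"),
                         out_dir = ".", tetrads_path = NULL, map = NULL,
                         assay_path = NULL, sim = NULL,
                         parental_phase = c(0, 0),
                         test = c("fisher", "chi2"), fdr = 0.05,
                         alpha = 0.05, seed = NULL) {
  analysis <- match.arg(analysis)
  test <- match.arg(test)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (is.character(map)) map <- read_marker_map(map)

  if (analysis == "simulate") {
    if (is.character(sim)) sim <- read_sim_config(sim, seed = seed)
    if (!inherits(sim, "sim_config")) stop("simulate needs a sim config")
    if (!is.null(seed)) sim$seed <- seed
    paths <- simulate_dataset(sim, out_dir)
    return(invisible(paths))
  }

  if (analysis == "assay") {
    if (is.null(assay_path)) stop("assay analysis needs an assay table")
    counts <- read_assay_table(assay_path)
    res <- assay_analysis(counts, fdr = fdr, test = test)
    write.table(res, file.path(out_dir, "assay_results.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_results_json(
      list(provenance = provenance(assay_path,
                                   list(test = test, fdr = fdr)),
           results = res),
      file.path(out_dir, "assay_results.json"))
    return(invisible(res))
  }

  if (is.null(tetrads_path) || is.null(map))
    stop(analysis, " analysis needs a tetrad table and a marker map")
  tetrads <- read_tetrad_table(tetrads_path, map)
  if (!nrow(tetrads)) stop("no usable tetrads in ", tetrads_path)

  if (analysis == "viability") {
    vp <- viability_profile(tetrads)
    write_results_json(
      list(provenance = provenance(tetrads_path),
           counts_by_viable_spores = as.list(vp$counts),
           n_tetrads = vp$n_tetrads,
           overall_viability = vp$overall_viability),
      file.path(out_dir, "viability.json"))
    return(invisible(vp))
  }

  if (analysis == "map") {
    iv <- intervals(map)
    ests <- lapply(iv$interval, function(id) {
      ct <- tally(tetrads, map, id, parental_phase)
      est <- perkins_distance(ct)
      list(interval = id, PD = ct$PD, TT = ct$TT, NPD = ct$NPD,
           n = ct$n, unscorable = ct$unscorable,
           cM = est$cM, se = est$se)
    })
    tab <- do.call(rbind, lapply(ests, as.data.frame))
    write.table(tab, file.path(out_dir, "map_results.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_results_json(
      list(provenance = provenance(tetrads_path,
                                   list(parental_phase = parental_phase,
                                        se_method = "multinomial delta")),
           intervals = ests,
           total_cM = sum(tab$cM)),
      file.path(out_dir, "map_results.json"))
    return(invisible(tab))
  }

  # interference
  res <- interference_summary(tetrads, map, parental_phase, alpha)
  write.table(res, file.path(out_dir, "interference_results.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_results_json(
    list(provenance = provenance(tetrads_path,
                                 list(alpha = alpha,
                                      parental_phase = parental_phase)),
         pairs = res),
    file.path(out_dir, "interference_results.json"))
  invisible(res)
}
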