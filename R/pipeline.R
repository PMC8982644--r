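#' Run configuration for an end-to-end pipeline run
#'
#' All parameters are serialized into the output manifest so a run can be
#' reproduced exactly from its output directory.
#'
#' @param input `"synthetic"` (generate traces) or a character vector of
#'   trace CSV paths.
#' @param n_cells number of synthetic cells (when `input = "synthetic"`).
#' @param generator named list of [generator_params] overrides.
#' @param v_detect,min_isi,tisi0,mad_mult detection parameters.
#' @param include_slow_tau include the slow-AHP time constant in the pooled
#'   burst models?
#' @param out_dir output directory (`NULL` = keep results in memory only).
#' @param seed master seed; per-cell generator seeds derive from it.
#' @return list of class `run_config`.
#' @export
run_config <- function(input = "synthetic", n_cells = 5,
                       generator = list(), v_detect = -23, min_isi = 1,
                       tisi0 = 90, mad_mult = 4, include_slow_tau = TRUE,
                       out_dir = NULL, seed = 1) {
  structure(as.list(environment()), class = "run_config")
}

cell_seed <- function(seed, k) (as.integer(seed) * 1009L + k) %% 2147483647L

#' Analyse one trace end to end
#'
#' @param trace a [vm_trace].
#' @param cfg a [run_config] (detection parameters are taken from it).
#' @return the [extract_cell_features] bundle.
#' @export
analyze_trace <- function(trace, cfg = run_config()) {
  extract_cell_features(trace, v_detect = cfg$v_detect,
                        min_isi = cfg$min_isi, tisi0 = cfg$tisi0,
                        mad_mult = cfg$mad_mult)
}

#' Generate-and-analyse a synthetic cohort
#'
#' Generates `n_cells` synthetic recordings (per-cell seeds derived from the
#' master seed), runs detection and feature extraction on each, and fits the
#' within-cell threshold-versus-pre-AP regressions.
#'
#' @param cfg a [run_config].
#' @return list with `cells` (per-cell feature bundles plus ground truth),
#'   `ap_table`, `burst_table` (pooled), `fits` (per-cell
#'   [within_cell_fit] of first-AP threshold on pre-AP hyperpolarization
#'   depth), `population` (summary of the per-cell slopes, reported per mV
#'   of hyperpolarization so the generator's default corresponds to -0.37).
#' @export
analyze_synthetic_cohort <- function(cfg = run_config()) {
  cells <- vector("list", cfg$n_cells)
  for (k in seq_len(cfg$n_cells)) {
    gp <- do.call(generator_params,
                  modifyList(list(seed = cell_seed(cfg$seed, k)),
                             cfg$generator))
    rec <- generate_cell_recording(gp)
    rec$trace$cell_id <- sprintf("cell%02d", k)
    feats <- analyze_trace(rec$trace, cfg)
    cells[[k]] <- c(feats, list(truth = rec$truth, params = gp))
  }
  ap_table <- do.call(rbind, lapply(cells, `[[`, "ap_table"))
  burst_table <- do.call(rbind, lapply(cells, function(x) {
    bt <- x$burst_table
    if (nrow(bt)) bt$slow_tau <- x$slow_fit$tau
    bt
  }))
  fits <- lapply(cells, function(x) {
    bt <- x$burst_table
    ok <- !bt$excluded & is.finite(bt$first_pre_ap) &
      is.finite(bt$first_threshold)
    # threshold regressed on the pre-AP potential itself (as in the
    # recordings' analysis); the slope per mV of *hyperpolarization* is the
    # sign flip, so the generator default corresponds to -0.37
    within_cell_fit(bt$first_pre_ap[ok], bt$first_threshold[ok],
                    cell_id = bt$cell_id[1])
  })
  slopes <- -vapply(fits, `[[`, numeric(1), "slope")
  p_raw <- vapply(fits, `[[`, numeric(1), "p_raw")
  pop <- if (sum(is.finite(slopes)) >= 2) population_summary(slopes) else NULL
  list(cells = cells, ap_table = ap_table, burst_table = burst_table,
       fits = fits, slopes = slopes,
       p_holm = holm_correction(p_raw[is.finite(p_raw)]),
       population = pop)
}

#' Run the full pipeline and write a report bundle
#'
#' Synthetic generation (or CSV ingestion), detection, feature extraction,
#' QC, within-cell and pooled statistics; writes tidy CSV tables, JSON
#' summaries and a machine-readable manifest when `out_dir` is set. On a
#' stage failure the partial outputs written so far are retained alongside a
#' failure manifest.
#'
#' @param cfg a [run_config].
#' @return list with the cohort analysis, `qc`, `burst_models`, and
#'   `manifest`; invisibly when writing to disk.
#' @export
run_pipeline <- function(cfg = run_config()) {
  manifest <- list(package = "ahpburst",
                   version = as.character(utils::packageVersion("ahpburst")),
                   seed = cfg$seed,
                   parameters = cfg[setdiff(names(cfg), "out_dir")],
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  emit <- function(res, failed = NULL) {
    manifest$failed <- failed
    manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
    res$manifest <- manifest
    if (!is.null(cfg$out_dir)) {
      dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
      wr <- function(d, f) utils::write.csv(d, file.path(cfg$out_dir, f),
                                            row.names = FALSE)
      if (!is.null(res$cohort)) {
        wr(res$cohort$ap_table, "ap_table.csv")
        wr(res$cohort$burst_table, "burst_table.csv")
        fits <- do.call(rbind, lapply(res$cohort$fits, function(f)
          data.frame(cell_id = f$cell_id, slope = f$slope, r = f$r,
                     p_raw = f$p_raw, n = f$n_points)))
        fits$p_holm <- holm_correction(ifelse(is.finite(fits$p_raw),
                                              fits$p_raw, 1))
        wr(fits, "within_cell_fits.csv")
        if (!is.null(res$cohort$population))
          jsonlite::write_json(unclass(res$cohort$population),
                               file.path(cfg$out_dir, "population.json"),
                               auto_unbox = TRUE, digits = NA)
      }
      if (!is.null(res$qc))
        wr(res$qc$dropped, "qc_dropped.csv")
      jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
    }
    if (is.null(failed)) res else {
      warning("pipeline stage failed: ", failed)
      res
    }
  }
  res <- list()
  cohort <- tryCatch(
    if (identical(cfg$input, "synthetic")) analyze_synthetic_cohort(cfg)
    else {
      traces <- lapply(cfg$input, read_vm_csv)
      cells <- lapply(traces, function(tr)
        c(analyze_trace(tr, cfg), list(truth = NULL)))
      list(cells = cells,
           ap_table = do.call(rbind, lapply(cells, `[[`, "ap_table")),
           burst_table = do.call(rbind, lapply(cells, function(x) {
             bt <- x$burst_table
             if (nrow(bt)) bt$slow_tau <- x$slow_fit$tau
             bt
           })),
           fits = NULL, population = NULL)
    },
    error = function(e) e)
  if (inherits(cohort, "error"))
    return(invisible(emit(res, failed = conditionMessage(cohort))))
  res$cohort <- cohort

  summaries <- do.call(rbind, lapply(cohort$cells, function(x)
    data.frame(cell_id = x$ap_table$cell_id[1] %||% NA,
               n_bursts = length(x$segmentation$bursts),
               has_rest_interval = !all(x$burst_table$excluded %||% TRUE))))
  res$qc <- qc_filter_cells(summaries)
  kept <- res$qc$kept
  res$burst_models <- tryCatch({
    bt <- cohort$burst_table[cohort$burst_table$cell_id %in% kept, ]
    fit_burst_models(bt, include_slow_tau = cfg$include_slow_tau)
  }, error = function(e) NULL)
  if (!is.null(cfg$out_dir)) invisible(emit(res)) else emit(res)
}
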