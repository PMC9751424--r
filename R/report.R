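# Report stage: CSV tables mirroring the usual clinical reporting layout
# (contrast table, morphology-parameter table, follow-up stratification)
# plus a JSON run manifest. Output is a pure function of the metrics table
# and the supplied seed/config, so fixed inputs give byte-identical files.

#' Build report tables from a cohort metrics table
#'
#' Writes three CSV tables and a JSON manifest into `out_dir`:
#' \describe{
#'   \item{table_vagueness.csv}{vagueness value by eyelid level, research vs
#'     control, with the paired test's p-value.}
#'   \item{table_parameters.csv}{height, width, tortuosity and density at
#'     upper/lower/both eyelid levels.}
#'   \item{table_by_interval.csv}{the four morphology parameters stratified
#'     by follow-up-interval bin (months).}
#'   \item{manifest.json}{seed, subject count, package version and an MD5
#'     digest of the configuration, for reproducibility audits.}
#' }
#'
#' @param metrics Metrics data frame (standard schema; aggregate rows are
#'   used).
#' @param out_dir Output directory (created if needed).
#' @param seed Optional root seed recorded in the manifest.
#' @param config Optional `cohort_config` recorded (hashed) in the
#'   manifest.
#' @param adjust_p Apply Benjamini-Hochberg adjustment within each table.
#'   Default `FALSE` (unadjusted p-values, as customarily reported).
#' @return Invisibly, a list of the three tables.
#' @export
build_report <- function(metrics, out_dir, seed = NULL, config = NULL,
                         adjust_p = FALSE) {
  metrics <- as.data.frame(metrics)
  if (nrow(metrics[metrics$gland_id == "AGGREGATE", ]) == 0L)
    mgm_stop("empty cohort: no aggregate metric rows")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  tab_vag <- compare_table(metrics, parameters = "vagueness")
  tab_par <- compare_table(metrics,
                           parameters = c("height", "width", "tortuosity", "density"))
  tab_int <- do.call(rbind, lapply(
    c("height", "width", "tortuosity", "density"),
    function(p) stratify_by_interval(metrics, p, level = "both")))
  rownames(tab_int) <- NULL
  if (adjust_p) {
    tab_vag$p_adjusted <- stats::p.adjust(tab_vag$p_value, "BH")
    tab_par$p_adjusted <- stats::p.adjust(tab_par$p_value, "BH")
    tab_int$p_adjusted <- stats::p.adjust(tab_int$p_value, "BH")
  }
  utils::write.csv(tab_vag, file.path(out_dir, "table_vagueness.csv"), row.names = FALSE)
  utils::write.csv(tab_par, file.path(out_dir, "table_parameters.csv"), row.names = FALSE)
  utils::write.csv(tab_int, file.path(out_dir, "table_by_interval.csv"), row.names = FALSE)

  cfg_hash <- NA_character_
  if (!is.null(config)) {
    tf <- tempfile(fileext = ".json")
    jsonlite::write_json(unclass(config), tf, auto_unbox = TRUE, digits = NA)
    cfg_hash <- unname(tools::md5sum(tf))
    unlink(tf)
  }
  manifest <- list(
    seed = seed,
    n_subjects = length(unique(metrics$subject_id)),
    n_rows = nrow(metrics),
    config_md5 = cfg_hash,
    package = "meibomorph",
    package_version = as.character(utils::packageVersion("meibomorph"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(vagueness = tab_vag, parameters = tab_par, by_interval = tab_int))
}
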