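#' Run the full spectrum-effect pipeline
#'
#' Chains the stages end to end: common-peak matching across batches,
#' optional relative quantities and fingerprint QC against a reference peak,
#' grey relational analysis of peak areas against every activity index, one
#' OPLS model per index, and the joint VIP/coefficient screening rule. Every
#' threshold and the seed are echoed in the returned `log` so a run can be
#' regenerated from its report alone.
#'
#' @param tables List of [peak_table()]s (or a `common_peak_matrix` to skip
#'   matching).
#' @param activity An [activity_table()] (or data frame with `batch_id` plus
#'   numeric index columns) covering the same batches.
#' @param time_window Matching window in minutes; default 0.1.
#' @param reference_peak Optional common-peak id; when given, GRA and OPLS
#'   run on relative areas and a [fingerprint_summary()] is included,
#'   otherwise raw areas are used.
#' @param rho,normalization GRA settings; defaults 0.5 and `"mean"`.
#' @param n_orthogonal OPLS orthogonal components; default 1.
#' @param vip_threshold,near_miss_slack Screening rule settings; defaults 1
#'   and 0.1.
#' @param identities Optional peak-to-compound map for the rendered report.
#' @param seed Recorded in the log (the pipeline itself draws no random
#'   numbers; generators are seeded upstream).
#' @return List of class `specfx_pipeline`: `common`, `fingerprint` (or
#'   `NULL`), `areas` (matrix fed to GRA/OPLS), `gra`, `opls` (per-assay
#'   list), `screening`, `document`, `config`, `log`.
#' @examples
#' gen <- generate(synthetic_spec(n_batches = 12, seed = 7))
#' run <- run_pipeline(gen$tables, gen$activity)
#' run$screening$core_set
#' @export
run_pipeline <- function(tables, activity, time_window = 0.1,
                         reference_peak = NULL, rho = 0.5,
                         normalization = "mean", n_orthogonal = 1,
                         vip_threshold = 1, near_miss_slack = 0.1,
                         identities = NULL, seed = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  common <- if (inherits(tables, "common_peak_matrix")) tables else
    stage("fingerprint", match_common_peaks(tables, time_window = time_window))

  act <- stage("bioassay", {
    if (!is.data.frame(activity)) stop("activity must be a data frame")
    if (!"batch_id" %in% names(activity)) stop("activity lacks `batch_id`")
    if (!setequal(activity$batch_id, common$batch_ids))
      stop("activity batches do not match the peak tables")
    activity[match(common$batch_ids, activity$batch_id), , drop = FALSE]
  })

  fp <- NULL
  areas <- common$areas
  if (!is.null(reference_peak)) {
    fp <- stage("fingerprint", fingerprint_summary(common, reference_peak))
    areas <- fp$relative_areas
  }
  colnames(areas) <- common$peak_ids

  idx_cols <- setdiff(names(act)[vapply(act, is.numeric, logical(1))],
                      c("sd_dpph", "sd_taoc"))
  g <- stage("gra", gra(areas, act, rho = rho, normalization = normalization))
  models <- stage("opls", {
    ms <- lapply(idx_cols, function(cn)
      fit_opls1(areas, act[[cn]], n_orthogonal = n_orthogonal))
    stats::setNames(ms, idx_cols)
  })
  sc <- stage("screening",
              screen(models, gra = g, vip_threshold = vip_threshold,
                     near_miss_slack = near_miss_slack))
  doc <- stage("screening", report(sc, identities = identities))

  config <- list(time_window = time_window, reference_peak = reference_peak,
                 rho = rho, normalization = normalization,
                 n_orthogonal = n_orthogonal, vip_threshold = vip_threshold,
                 near_miss_slack = near_miss_slack, seed = seed)
  log <- sprintf("%s = %s", names(config),
                 vapply(config, function(v)
                   if (is.null(v)) "NULL" else paste(format(v), collapse = ","),
                   character(1)))
  structure(list(common = common, fingerprint = fp, areas = areas, gra = g,
                 opls = models, screening = sc, document = doc,
                 config = config, log = log),
            class = "specfx_pipeline")
}

#' @export
print.specfx_pipeline <- function(x, ...) {
  cat(sprintf("<specfx_pipeline: %d batches, %d common peaks, %d assay(s)>\n",
              length(x$common$batch_ids), length(x$common$peak_ids),
              length(x$opls)))
  print(x$screening)
  invisible(x)
}

#' Write the pipeline's artifact bundle
#'
#' Writes the common-peak matrices, GRA table, per-assay OPLS summaries, the
#' screening report (markdown + JSON), and a run log to a directory.
#'
#' @param run A [run_pipeline()] result.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_pipeline <- function(run, dir) {
  stopifnot(inherits(run, "specfx_pipeline"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_csv(run$common$areas, file.path(dir, "areas.csv"))
  write_matrix_csv(run$common$rts, file.path(dir, "rts.csv"))
  if (!is.null(run$fingerprint)) {
    write_matrix_csv(run$fingerprint$relative_areas,
                     file.path(dir, "relative_areas.csv"))
    write_matrix_csv(run$fingerprint$relative_rts,
                     file.path(dir, "relative_rts.csv"))
    write_matrix_csv(run$fingerprint$similarity,
                     file.path(dir, "similarity.csv"))
  }
  utils::write.csv(run$gra$degrees, file.path(dir, "gra.csv"),
                   row.names = FALSE, quote = FALSE)
  for (a in names(run$opls)) {
    m <- run$opls[[a]]
    utils::write.csv(data.frame(peak = m$peaks,
                                coefficient_scaled = unname(m$coefficients_scaled),
                                vip = unname(m$vip)),
                     file.path(dir, sprintf("opls_%s.csv", a)),
                     row.names = FALSE, quote = FALSE)
  }
  write_screening_report(run$document, dir)
  writeLines(run$log, file.path(dir, "run_log.txt"))
  invisible(dir)
}
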