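#' Joint active-component screening rule
#'
#' Combines per-assay OPLS outcomes into the screening rule for candidate
#' active components: within each assay, a peak is a candidate when its VIP
#' exceeds the threshold *and* its (standardized) regression coefficient is
#' positive; the core set is the intersection of the per-assay candidate
#' sets. Peaks whose VIP falls just short of the threshold (within
#' `near_miss_slack`) with a positive coefficient in at least one assay are
#' surfaced as near-misses, so the expert-judgement step that typically
#' follows the rule is transparent rather than automated. GRA degrees and
#' ranks, when supplied, are reported alongside and never thresholded.
#'
#' @param models Named list, one element per assay: either a fitted
#'   [fit_opls1()] model or a data frame with columns `peak`, `vip`,
#'   `coefficient`. All assays must cover the same peak set.
#' @param gra Optional [gra()] result (or its `$degrees` data frame) over the
#'   same peaks.
#' @param vip_threshold VIP cut-off; default 1.
#' @param near_miss_slack Width of the near-miss band below the threshold;
#'   default 0.1.
#' @return Object of class `screening_report`: list with `table` (per peak:
#'   per-assay VIP/coefficient/pass flags, `in_core`, `near_miss`, GRA
#'   columns when available), `core_set`, `per_assay` (candidate sets),
#'   `flagged_set` (near-misses), `thresholds`. Sets are ordered by
#'   minimum-across-assays VIP, descending.
#' @examples
#' a <- data.frame(peak = 1:3, vip = c(1.5, 1.2, 0.4), coefficient = c(1, 1, 1))
#' b <- data.frame(peak = 1:3, vip = c(0.3, 1.6, 1.4), coefficient = c(1, 1, -1))
#' screen(list(A = a, B = b))$core_set  # 2
#' @export
screen <- function(models, gra = NULL, vip_threshold = 1, near_miss_slack = 0.1) {
  stopifnot(is.list(models), length(models) >= 1L)
  if (is.null(names(models)) || any(!nzchar(names(models))))
    names(models) <- paste0("assay", seq_along(models))
  per <- lapply(models, function(m) {
    if (inherits(m, "opls"))
      data.frame(peak = m$peaks, vip = unname(m$vip),
                 coefficient = unname(m$coefficients_scaled),
                 stringsAsFactors = FALSE)
    else {
      stopifnot(all(c("peak", "vip", "coefficient") %in% names(m)))
      data.frame(peak = as.character(m$peak), vip = m$vip,
                 coefficient = m$coefficient, stringsAsFactors = FALSE)
    }
  })
  peaks <- per[[1L]]$peak
  for (m in per) if (!setequal(m$peak, peaks))
    stop("assays cover different peak sets", call. = FALSE)
  per <- lapply(per, function(m) m[match(peaks, m$peak), ])

  passes <- vapply(per, function(m)
    m$vip > vip_threshold & m$coefficient > 0, logical(length(peaks)))
  near <- vapply(per, function(m)
    m$vip >= vip_threshold - near_miss_slack & m$vip <= vip_threshold &
      m$coefficient > 0, logical(length(peaks)))
  if (length(peaks) == 1L) {        # vapply returns vectors for one peak
    passes <- matrix(passes, 1L); near <- matrix(near, 1L)
  }
  in_core <- apply(passes, 1L, all)
  near_miss <- apply(near, 1L, any) & !in_core
  min_vip <- do.call(pmin, lapply(per, `[[`, "vip"))

  tab <- data.frame(peak = peaks, stringsAsFactors = FALSE)
  for (a in names(per)) {
    tab[[paste0("vip_", a)]] <- per[[a]]$vip
    tab[[paste0("coef_", a)]] <- per[[a]]$coefficient
    tab[[paste0("pass_", a)]] <- passes[, a]
  }
  tab$min_vip <- min_vip
  tab$in_core <- in_core
  tab$near_miss <- near_miss
  if (!is.null(gra)) {
    deg <- if (inherits(gra, "gra_result")) gra$degrees else gra
    for (a in unique(deg$assay)) {
      d_a <- deg[deg$assay == a, ]
      i <- match(peaks, as.character(d_a$peak))
      tab[[paste0("gra_degree_", a)]] <- d_a$degree[i]
      tab[[paste0("gra_rank_", a)]] <- d_a$rank[i]
    }
  }
  by_vip <- function(sel) peaks[sel][order(-min_vip[sel])]
  structure(list(
    table = tab,
    core_set = by_vip(in_core),
    per_assay = lapply(names(per), function(a) by_vip(passes[, a])) |>
      stats::setNames(names(per)),
    flagged_set = by_vip(near_miss),
    thresholds = list(vip_threshold = vip_threshold,
                      near_miss_slack = near_miss_slack)),
    class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf("<screening_report: %d peaks, VIP > %g with positive coefficient in all %d assays>\n",
              nrow(x$table), x$thresholds$vip_threshold, length(x$per_assay)))
  cat(sprintf("  core set: %s\n",
              if (length(x$core_set)) paste(x$core_set, collapse = ", ") else "(none)"))
  if (length(x$flagged_set))
    cat(sprintf("  near misses: %s\n", paste(x$flagged_set, collapse = ", ")))
  invisible(x)
}

#' Render a screening report
#'
#' Produces a human-readable markdown document and a JSON-serializable list
#' from a [screen()] result, optionally annotating peaks with compound
#' identities established from reference standards.
#'
#' @param screening A `screening_report`.
#' @param identities Optional named list or character vector mapping peak id
#'   to compound name (unknown peaks warn).
#' @return List with `markdown` (character scalar) and `data` (list ready for
#'   [jsonlite::toJSON()]); class `screening_document`.
#' @export
report <- function(screening, identities = NULL) {
  stopifnot(inherits(screening, "screening_report"))
  peaks <- screening$table$peak
  ids <- unlist(identities) %||% character(0)
  ann <- function(p) {
    nm <- ids[match(as.character(p), names(ids))]
    if (is.na(nm)) as.character(p) else sprintf("%s (%s)", p, nm)
  }
  if (!is.null(identities)) {
    unknown <- setdiff(names(identities), as.character(peaks))
    if (length(unknown))
      warning(sprintf("identity map names unknown peak(s): %s",
                      paste(unknown, collapse = ", ")), call. = FALSE)
  }
  md <- c("# Active-component screening report", "",
          sprintf("Rule: VIP > %g and positive regression coefficient in every assay (near-miss slack %g).",
                  screening$thresholds$vip_threshold,
                  screening$thresholds$near_miss_slack), "")
  md <- c(md, if (length(screening$core_set))
    c("## Core candidates", "",
      paste0("- peak ", vapply(screening$core_set, ann, character(1))))
    else "No peak passed the rule in every assay.")
  if (length(screening$flagged_set))
    md <- c(md, "", "## Near misses", "",
            paste0("- peak ", vapply(screening$flagged_set, ann, character(1))))
  for (a in names(screening$per_assay))
    md <- c(md, "", sprintf("- %s candidates: %s", a,
                            paste(screening$per_assay[[a]], collapse = ", ")))
  data <- list(thresholds = screening$thresholds,
               core_set = as.character(screening$core_set),
               flagged_set = as.character(screening$flagged_set),
               per_assay = lapply(screening$per_assay, as.character),
               identities = as.list(identities %||% stats::setNames(list(), character(0))),
               table = screening$table)
  structure(list(markdown = paste(md, collapse = "\n"), data = data),
            class = "screening_document")
}

#' Write a screening report to disk
#'
#' Writes `screening_report.md` and `screening_report.json` (readable back
#' with [jsonlite::fromJSON()]).
#'
#' @param doc A [report()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
write_screening_report <- function(doc, dir) {
  stopifnot(inherits(doc, "screening_document"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  md_path <- file.path(dir, "screening_report.md")
  json_path <- file.path(dir, "screening_report.json")
  writeLines(doc$markdown, md_path)
  jsonlite::write_json(doc$data, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(c(md_path, json_path))
}
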