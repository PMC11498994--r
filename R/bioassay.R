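#' Fit a linear standard curve
#'
#' Ordinary least-squares line through calibration points, absorbance against
#' concentration, as used for the DPPH standard series and the iron-based
#' total-antioxidant-capacity kit calibrant.
#'
#' @param concentrations Numeric vector (mg/mL or umol/mL), at least two
#'   distinct values.
#' @param absorbances Numeric vector, same length.
#' @return Object of class `standard_curve`: list with `slope`, `intercept`,
#'   `r_squared`, `n_points`.
#' @examples
#' fit_standard_curve(1:5, 2 * (1:5) + 0.1)
#' @export
fit_standard_curve <- function(concentrations, absorbances) {
  stopifnot(length(concentrations) == length(absorbances),
            length(concentrations) >= 2L)
  if (length(unique(concentrations)) < 2L)
    stop("need at least two distinct concentrations", call. = FALSE)
  fit <- stats::lm(absorbances ~ concentrations)
  ss_tot <- sum((absorbances - mean(absorbances))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = r2,
                 n_points = length(concentrations)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("<standard_curve: A = %.4f c + %.4f, r2 = %.4f, n = %d>\n",
              x$slope, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}

#' DPPH radical scavenging rate
#'
#' Percent scavenging of the DPPH radical's 517-nm absorbance:
#' `100 * (1 - (a_sample - a_control) / a_standard)`, where `a_sample` is
#' sample + DPPH, `a_control` is sample + solvent (colour correction), and
#' `a_standard` is solvent + DPPH. Values outside `[0, 100]` are possible
#' (e.g. pro-oxidant behaviour or absorbance noise) and are flagged with a
#' warning, never clamped, so downstream modelling sees the raw numbers.
#'
#' @param a_sample,a_control,a_standard Absorbances (vectors recycle);
#'   `a_standard` must be positive.
#' @return Scavenging rate(s) in percent.
#' @examples
#' dpph_scavenging_rate(0.5, 0.1, 0.8)  # 50
#' @export
dpph_scavenging_rate <- function(a_sample, a_control, a_standard) {
  if (any(a_standard <= 0))
    stop("`a_standard` must be positive", call. = FALSE)
  rate <- 100 * (1 - (a_sample - a_control) / a_standard)
  out <- which(rate < 0 | rate > 100)
  if (length(out))
    warning(sprintf("%d scavenging rate(s) outside [0, 100]%%; reported unclamped",
                    length(out)), call. = FALSE)
  rate
}

#' Total antioxidant capacity from a linear calibration
#'
#' Converts a blank-corrected 593-nm absorbance to concentration through an
#' inverted standard curve and a dilution factor:
#' `((a_sample - a_blank) - intercept) / slope * dilution_factor`.
#' The default dilution factor 34 reflects a plate layout of 180 uL reaction
#' mixture + 18 uL water + 6 uL sample (204/6). Negative capacities are
#' flagged, not clamped.
#'
#' @param a_sample,a_blank Absorbances (vectors recycle).
#' @param calibration A [fit_standard_curve()] result with non-zero slope.
#' @param dilution_factor Positive scalar; default 34.
#' @return Capacity in the calibrant's concentration units (umol/mL).
#' @export
t_aoc <- function(a_sample, a_blank, calibration, dilution_factor = 34) {
  stopifnot(inherits(calibration, "standard_curve"))
  if (calibration$slope == 0)
    stop("calibration slope must be non-zero", call. = FALSE)
  if (dilution_factor <= 0)
    stop("`dilution_factor` must be positive", call. = FALSE)
  val <- ((a_sample - a_blank) - calibration$intercept) /
    calibration$slope * dilution_factor
  if (any(val < 0))
    warning(sprintf("%d negative capacity value(s); reported unclamped",
                    sum(val < 0)), call. = FALSE)
  val
}

#' Replicate mean and standard deviation
#'
#' @param values Numeric vector, length >= 1.
#' @return List with `mean` and `sd` (sample SD; `NA` for a single value).
#' @export
summarize_replicates <- function(values) {
  stopifnot(length(values) >= 1L)
  list(mean = mean(values),
       sd = if (length(values) > 1L) stats::sd(values) else NA_real_)
}

#' Assemble a per-batch activity table
#'
#' The dependent-variable side of a spectrum-effect analysis: one row per
#' batch with the two efficacy indices.
#'
#' @param batch_id Character vector of batch ids (unique).
#' @param dpph_pct DPPH scavenging rates in percent.
#' @param t_aoc Total antioxidant capacities in umol/mL.
#' @param sd_dpph,sd_taoc Optional replicate SDs.
#' @return `data.frame` of class `activity_table`.
#' @export
activity_table <- function(batch_id, dpph_pct, t_aoc,
                           sd_dpph = NA_real_, sd_taoc = NA_real_) {
  batch_id <- as.character(batch_id)
  stopifnot(!anyDuplicated(batch_id),
            length(dpph_pct) == length(batch_id),
            length(t_aoc) == length(batch_id))
  out <- data.frame(batch_id = batch_id, dpph_pct = as.numeric(dpph_pct),
                    t_aoc = as.numeric(t_aoc),
                    sd_dpph = as.numeric(sd_dpph),
                    sd_taoc = as.numeric(sd_taoc),
                    stringsAsFactors = FALSE)
  class(out) <- c("activity_table", "data.frame")
  out
}

#' Compute per-batch activities from a plate reading
#'
#' Reduces a long-format plate table (columns `well`, `role`, `absorbance`,
#' optional `batch_id`) to one activity value per batch. Roles: `sample`
#' (sample + reagent), `control` (sample + solvent, DPPH mode only),
#' `standard` (solvent + reagent, DPPH mode only), `blank` (T-AOC mode), and
#' `calibrant:<conc>` rows defining the standard curve (T-AOC mode).
#' Replicate wells are averaged per batch/role.
#'
#' @param plate Data frame as above.
#' @param mode `"dpph"` or `"taoc"`.
#' @param dilution_factor Passed to [t_aoc()] in T-AOC mode.
#' @return Data frame `batch_id`, `value`, `sd` (replicate SD of the computed
#'   value via per-replicate evaluation).
#' @export
plate_activity <- function(plate, mode = c("dpph", "taoc"),
                           dilution_factor = 34) {
  mode <- match.arg(mode)
  stopifnot(all(c("role", "absorbance") %in% names(plate)))
  if (is.null(plate$batch_id)) plate$batch_id <- "sample"
  role_mean <- function(r, b = NULL) {
    sel <- plate$role == r & (if (is.null(b)) TRUE else plate$batch_id == b)
    if (!any(sel)) stop(sprintf("plate has no '%s' wells", r), call. = FALSE)
    mean(plate$absorbance[sel])
  }
  batches <- unique(plate$batch_id[plate$role %in% c("sample")])
  if (mode == "dpph") {
    a_std <- role_mean("standard")
    vals <- vapply(batches, function(b) {
      per <- dpph_scavenging_rate(plate$absorbance[plate$role == "sample" &
                                                     plate$batch_id == b],
                                  role_mean("control", b), a_std)
      c(mean(per), if (length(per) > 1L) stats::sd(per) else NA_real_)
    }, numeric(2))
  } else {
    cal_rows <- grepl("^calibrant:", plate$role)
    if (!any(cal_rows)) stop("plate has no calibrant wells", call. = FALSE)
    conc <- as.numeric(sub("^calibrant:", "", plate$role[cal_rows]))
    curve <- fit_standard_curve(conc, plate$absorbance[cal_rows])
    a_blank <- role_mean("blank")
    vals <- vapply(batches, function(b) {
      per <- t_aoc(plate$absorbance[plate$role == "sample" &
                                      plate$batch_id == b],
                   a_blank, curve, dilution_factor)
      c(mean(per), if (length(per) > 1L) stats::sd(per) else NA_real_)
    }, numeric(2))
  }
  data.frame(batch_id = batches, value = vals[1L, ], sd = vals[2L, ],
             row.names = NULL, stringsAsFactors = FALSE)
}
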