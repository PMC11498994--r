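#' Read per-batch peak tables from CSV
#'
#' Reads the pinned peak-table dialect — UTF-8, comma separator, '.' decimal,
#' mandatory header `batch_id,peak_id,rt_min,area` — from one long file or a
#' directory of such files, and splits into one [peak_table()] per batch.
#' Batch ids are opaque strings.
#'
#' @param path A CSV file, a directory of CSV files, or a character vector of
#'   files.
#' @return Named list of `peak_table`s.
#' @export
read_peak_tables <- function(path) {
  files <- if (length(path) == 1L && dir.exists(path))
    list.files(path, pattern = "\\.csv$", full.names = TRUE) else path
  if (!length(files)) stop("no CSV files found", call. = FALSE)
  long <- do.call(rbind, lapply(files, function(f) {
    df <- utils::read.csv(f, stringsAsFactors = FALSE)
    need <- c("batch_id", "peak_id", "rt_min", "area")
    if (!all(need %in% names(df)))
      stop(sprintf("%s: missing column(s) %s", f,
                   paste(setdiff(need, names(df)), collapse = ", ")),
           call. = FALSE)
    df[, need]
  }))
  lapply(split(long, long$batch_id), function(d)
    peak_table(d$batch_id[1L], d$rt_min, d$area, d$peak_id))
}

#' Write peak tables to a single long CSV
#'
#' @param tables List of [peak_table()]s.
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_peak_tables <- function(tables, file) {
  long <- do.call(rbind, lapply(tables, as.data.frame))
  utils::write.csv(long, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read and write activity tables
#'
#' CSV dialect `batch_id,dpph_pct,t_aoc[,sd_dpph,sd_taoc]`.
#'
#' @param file Path.
#' @return [read_activity_table()]: an [activity_table()].
#' @export
read_activity_table <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("batch_id", "dpph_pct", "t_aoc")
  if (!all(need %in% names(df)))
    stop(sprintf("activity CSV missing column(s): %s",
                 paste(setdiff(need, names(df)), collapse = ", ")),
         call. = FALSE)
  activity_table(df$batch_id, df$dpph_pct, df$t_aoc,
                 df$sd_dpph %||% NA_real_, df$sd_taoc %||% NA_real_)
}

#' @rdname read_activity_table
#' @param table An [activity_table()].
#' @export
write_activity_table <- function(table, file) {
  utils::write.csv(as.data.frame(table), file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read a plate CSV
#'
#' Dialect `well,role,absorbance[,batch_id]` with roles `sample`, `control`,
#' `standard`, `blank`, or `calibrant:<conc>`; see [plate_activity()].
#'
#' @param file Path.
#' @return Data frame.
#' @export
read_plate <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!all(c("well", "role", "absorbance") %in% names(df)))
    stop("plate CSV needs columns well, role, absorbance", call. = FALSE)
  df
}

#' Write a labelled matrix as CSV
#'
#' Used for the relative-rt/relative-area/similarity artifacts; the first
#' column holds row labels under the name `id`.
#'
#' @param m Matrix with dimnames.
#' @param file Path.
#' @export
write_matrix_csv <- function(m, file) {
  df <- data.frame(id = rownames(m) %||% seq_len(nrow(m)), m,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(file) {
  df <- utils::read.csv(file, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}
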