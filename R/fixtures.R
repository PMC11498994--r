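#' Packaged reference tables
#'
#' The package ships the published data of a ten-batch Yiwei Decoction (YWD)
#' antioxidant study, transcribed to CSV so every pipeline stage can be
#' exercised against real numbers: relative retention times and relative
#' peak areas of the 15 common peaks (with the published per-row RSD
#' column), the published fingerprint similarity matrix, the per-batch DPPH
#' scavenging rates and total antioxidant capacities, and the published grey
#' relational degrees and ranks. Files are checksum-pinned and validated at
#' load so transcription errors cannot pass silently.
#'
#' Note: the published RSD for peak 11 of the relative-area table (28.412)
#' is inconsistent with the RSD of its own printed row values (23.76); all
#' other rows agree to within 0.3 percentage points. The transcription
#' carries the printed value verbatim.
#'
#' @name fixtures
NULL

.fixture_registry <- list(
  table2 = list(file = "table2_relative_rt.csv",
                md5 = "e3827356f108758b0011130a8ff878ad"),
  table3 = list(file = "table3_relative_area.csv",
                md5 = "3c8e9b8b98b12e92a1d0575641e27ad2"),
  table4 = list(file = "table4_similarity.csv",
                md5 = "7b22253bc2bb389611879d5ae0509d4e"),
  table5 = list(file = "table5_activity.csv",
                md5 = "c4508ca40cdebe63c0dbeb57e856c786"),
  table6 = list(file = "table6_gra.csv",
                md5 = "0a69e61f6f01b199e387d41d7f0d6d07"))

#' Load a packaged reference table
#'
#' @param name One of `"table2"` (relative retention times), `"table3"`
#'   (relative peak areas), `"table4"` (published similarity matrix),
#'   `"table5"` (per-batch activities), `"table6"` (published GRA degrees
#'   and ranks).
#' @return A validated data frame. For `table2`/`table3` the columns are
#'   `peak`, `S1`...`S10`, `rsd_printed`; use [fixture_matrix()] for the
#'   batches x peaks matrix form. `table4` returns the full symmetric
#'   similarity matrix (rows/columns `S1`...`S10`, `Control`).
#' @examples
#' load_fixture("table5")$dpph_pct
#' @export
load_fixture <- function(name) {
  entry <- .fixture_registry[[name]]
  if (is.null(entry))
    stop(sprintf("unknown fixture '%s'; available: %s", name,
                 paste(names(.fixture_registry), collapse = ", ")),
         call. = FALSE)
  path <- system.file("extdata", entry$file, package = "specfx",
                      mustWork = TRUE)
  if (!identical(unname(tools::md5sum(path)), entry$md5))
    stop(sprintf("fixture '%s' failed its integrity check", name),
         call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  batches <- paste0("S", 1:10)
  if (name %in% c("table2", "table3")) {
    stopifnot(nrow(df) == 15L, all(batches %in% names(df)))
    if (!all(unlist(df[df$peak == 9L, batches]) == 1))
      stop("fixture reference-peak row is not all 1.000", call. = FALSE)
  } else if (name == "table5") {
    stopifnot(nrow(df) == 10L,
              identical(df$batch_id, batches))
  } else if (name == "table6") {
    stopifnot(nrow(df) == 15L,
              setequal(df$dpph_rank, 1:15), setequal(df$taoc_rank, 1:15))
  } else if (name == "table4") {
    m <- as.matrix(df[, -1L])
    rownames(m) <- df$batch
    m[upper.tri(m)] <- t(m)[upper.tri(m)]
    stopifnot(all(diag(m) == 1))
    return(m)
  }
  df
}

#' Batches x peaks matrix form of a packaged peak table
#'
#' @param fixture A `table2` or `table3` data frame from [load_fixture()],
#'   or the fixture name itself.
#' @return 10 x 15 numeric matrix, rows `S1`...`S10`, columns the peak
#'   numbers.
#' @export
fixture_matrix <- function(fixture) {
  if (is.character(fixture)) fixture <- load_fixture(fixture)
  m <- t(as.matrix(fixture[, paste0("S", 1:10)]))
  colnames(m) <- fixture$peak
  m
}

#' Compound identities of the chemically identified peaks
#'
#' The three common peaks identified against reference standards.
#'
#' @return Named character vector (peak number to compound name).
#' @export
peak_identities <- function() {
  c("9" = "vitexin", "11" = "verbascoside", "15" = "psoralen")
}
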