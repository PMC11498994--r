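#' Match common peaks across batches
#'
#' Clusters peaks from several batches by retention time and keeps the
#' clusters shared by a sufficient fraction of batches ("common peaks", in the
#' fingerprinting sense: occupancy 1 means the peak is present in every
#' batch). Clustering is agglomerative on retention time: starting from
#' singletons, adjacent clusters merge (closest median gap first) as long as
#' every member of the merged cluster stays within the window of the merged
#' cluster's median. Anchoring to the median makes the result independent
#' of batch order and of within-batch peak order. When a batch contributes
#' more than one peak to a cluster, the peak nearest the cluster median is
#' kept (ties broken toward the earlier retention time, with a warning).
#'
#' @param tables List of [peak_table()] objects (or data frames with columns
#'   `batch_id`, `peak_id`, `rt_min`, `area`), one per batch; at least two.
#' @param time_window Maximum distance (minutes) between a peak and its
#'   cluster's median retention time; default 0.1 min.
#' @param min_occupancy Minimum fraction of batches a cluster must cover to be
#'   reported; default 1 (strict common peaks).
#' @return An object of class `common_peak_matrix`: a list with `batch_ids`,
#'   `peak_ids` (1..K in median-retention-time order), `areas` and `rts`
#'   (batches x peaks matrices, `NA` where a batch lacks the peak),
#'   `occupancy` (per-peak fraction of batches), `median_rt`, and
#'   `reference_peak_id` (filled by [relative_to_reference()]).
#' @examples
#' a <- peak_table("S1", c(5.00, 10.00), c(1, 2))
#' b <- peak_table("S2", c(5.04, 10.30), c(1, 2))
#' match_common_peaks(list(a, b), time_window = 0.1)$peak_ids  # one cluster
#' @export
match_common_peaks <- function(tables, time_window = 0.1, min_occupancy = 1) {
  if (!is.list(tables) || length(tables) < 2L)
    stop("need at least two peak tables", call. = FALSE)
  stopifnot(time_window > 0, min_occupancy > 0, min_occupancy <= 1)
  pool <- do.call(rbind, lapply(tables, function(tb)
    as.data.frame(tb)[, c("batch_id", "peak_id", "rt_min", "area")]))
  batch_ids <- unique(vapply(tables, function(tb) tb$batch_id[1L], character(1)))
  if (anyDuplicated(batch_ids))
    stop("duplicate batch ids across tables", call. = FALSE)
  # stable pool order: by rt, then batch id, then peak id (never by list order)
  pool <- pool[order(pool$rt_min, pool$batch_id, pool$peak_id), , drop = FALSE]

  # agglomeration over rt-sorted peaks: clusters are contiguous segments of
  # the sorted rt vector; adjacent segments merge (smallest median gap first)
  # while every member stays within the window of the pooled median
  rt <- pool$rt_min
  n <- length(rt)
  med_of <- function(i, j) {                 # O(1) median of sorted rt[i..j]
    L <- j - i + 1L
    (rt[i + (L - 1L) %/% 2L] + rt[i + L %/% 2L]) / 2
  }
  starts <- seq_len(n)                       # segment start indices
  repeat {
    k <- length(starts)
    if (k < 2L) break
    ends <- c(starts[-1L] - 1L, n)
    i <- starts[-k]; j <- ends[-1L]          # pooled adjacent-pair ranges
    pm <- med_of(i, j)
    ok <- pmax(pm - rt[i], rt[j] - pm) <= time_window
    if (!any(ok)) break
    gaps <- med_of(starts[-1L], ends[-1L]) - med_of(starts[-k], ends[-k])
    best <- which(ok)[which.min(gaps[ok])]
    starts <- starts[-(best + 1L)]
  }
  ends <- c(starts[-1L] - 1L, n)
  cluster <- rep.int(seq_along(starts), ends - starts + 1L)
  members <- lapply(seq_along(starts), function(s) rt[starts[s]:ends[s]])

  # one peak per batch per cluster: nearest to the cluster median, earlier rt on ties
  keep <- rep(TRUE, nrow(pool))
  med <- vapply(members, stats::median, numeric(1))
  for (k in seq_along(members)) {
    idx <- which(cluster == k)
    for (b in unique(pool$batch_id[idx])) {
      ib <- idx[pool$batch_id[idx] == b]
      if (length(ib) > 1L) {
        d <- abs(pool$rt_min[ib] - med[k])
        best <- ib[order(d, pool$rt_min[ib])][1L]
        drop <- setdiff(ib, best)
        keep[drop] <- FALSE
        warning(sprintf(
          "batch %s contributed %d peaks to the %.3f-min cluster; kept %s",
          b, length(ib), med[k], pool$peak_id[best]), call. = FALSE)
      }
    }
  }
  pool <- pool[keep, , drop = FALSE]
  cluster <- cluster[keep]

  occ <- vapply(seq_along(members), function(k)
    length(unique(pool$batch_id[cluster == k])) / length(batch_ids), numeric(1))
  common <- which(occ >= min_occupancy - 1e-12)
  common <- common[order(med[common])]
  K <- length(common)

  areas <- matrix(NA_real_, length(batch_ids), K,
                  dimnames = list(batch_ids, seq_len(K)))
  rts <- areas
  for (j in seq_len(K)) {
    idx <- which(cluster == common[j])
    areas[pool$batch_id[idx], j] <- pool$area[idx]
    rts[pool$batch_id[idx], j] <- pool$rt_min[idx]
  }
  structure(list(batch_ids = batch_ids, peak_ids = seq_len(K),
                 areas = areas, rts = rts,
                 occupancy = stats::setNames(occ[common], seq_len(K)),
                 median_rt = stats::setNames(med[common], seq_len(K)),
                 reference_peak_id = NULL),
            class = "common_peak_matrix")
}

#' @export
print.common_peak_matrix <- function(x, ...) {
  cat(sprintf("<common_peak_matrix: %d batches x %d peaks, occupancy %s>\n",
              length(x$batch_ids), length(x$peak_ids),
              paste(range(round(x$occupancy, 2)), collapse = "-")))
  invisible(x)
}

#' Relative retention times and areas against a reference peak
#'
#' Divides every batch's retention times and areas by that batch's value for
#' the chosen reference peak (a well-resolved common peak; peak 9 in the
#' packaged ten-batch dataset). The reference column of both outputs is
#' exactly 1.
#'
#' @param matrix A `common_peak_matrix` from [match_common_peaks()].
#' @param reference_peak_id One of `matrix$peak_ids`.
#' @return List with `relative_rts`, `relative_areas` (batches x peaks), and
#'   `reference_peak_id`.
#' @export
relative_to_reference <- function(matrix, reference_peak_id) {
  stopifnot(inherits(matrix, "common_peak_matrix"))
  j <- match(reference_peak_id, matrix$peak_ids)
  if (is.na(j))
    stop("reference peak not among the common peaks", call. = FALSE)
  ref_rt <- matrix$rts[, j]
  ref_area <- matrix$areas[, j]
  bad <- which(!is.finite(ref_rt) | ref_rt <= 0 | !is.finite(ref_area) |
                 ref_area <= 0)
  if (length(bad))
    stop(sprintf("reference peak %s has non-positive rt or area in batch %s",
                 reference_peak_id,
                 paste(matrix$batch_ids[bad], collapse = ", ")), call. = FALSE)
  rel_rt <- sweep(matrix$rts, 1L, ref_rt, "/")
  rel_area <- sweep(matrix$areas, 1L, ref_area, "/")
  rel_rt[, j] <- 1
  rel_area[, j] <- 1
  list(relative_rts = rel_rt, relative_areas = rel_area,
       reference_peak_id = reference_peak_id)
}

#' Relative standard deviation (percent)
#'
#' The repeatability/precision metric of fingerprint methodology checks:
#' `100 * sd(x) / mean(x)` with the sample (n-1) standard deviation.
#'
#' @param values Numeric vector, length >= 2, non-zero mean.
#' @return RSD in percent.
#' @examples
#' rsd(c(1, 2, 3))  # 50
#' @export
rsd <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("RSD needs at least two values", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("RSD undefined for zero mean", call. = FALSE)
  100 * stats::sd(values) / m
}

#' Consensus reference fingerprint
#'
#' Component-wise median (default) or mean across batches, the "median
#' method" used to build a control fingerprint from matched batches.
#'
#' @param x Batches x features numeric matrix (e.g. `$areas` of a
#'   `common_peak_matrix`), a `common_peak_matrix`, or a list of
#'   [chromatogram()]s (resampled to a shared grid first).
#' @param method `"median"` or `"mean"`.
#' @return Numeric vector, one value per feature.
#' @export
reference_fingerprint <- function(x, method = c("median", "mean")) {
  method <- match.arg(method)
  x <- as_batch_matrix(x)
  f <- if (method == "median") stats::median else mean
  apply(x, 2L, f)
}

# common_peak_matrix / chromatogram list / matrix -> batches x features matrix
as_batch_matrix <- function(x) {
  if (inherits(x, "common_peak_matrix")) return(x$areas)
  if (is.list(x) && length(x) && inherits(x[[1L]], "chromatogram"))
    return(resample_chromatograms(x))
  if (is.matrix(x)) return(x)
  stop("expected a matrix, common_peak_matrix, or list of chromatograms",
       call. = FALSE)
}

#' Cosine similarity of two vectors
#'
#' `dot(a, b) / (|a| |b|)`; lies in `[0, 1]` for the non-negative vectors of
#' chromatographic data.
#'
#' @param a,b Numeric vectors of equal length, neither all-zero.
#' @return Similarity in `[-1, 1]`.
#' @examples
#' cosine_similarity(c(1, 1, 0), c(1, 0, 0))  # 0.7071
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b) || length(a) < 1L)
    stop("vectors must have equal positive length", call. = FALSE)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    stop("cosine similarity undefined for an all-zero vector", call. = FALSE)
  sum(a * b) / (na * nb)
}

#' Pairwise fingerprint similarity matrix
#'
#' All pairwise similarities between batch vectors, optionally augmented with
#' the consensus (median) reference fingerprint as an extra row/column —
#' the layout of published fingerprint-similarity tables. Cosine on
#' common-peak area vectors is the default; Pearson correlation is available
#' since the reference similarity software's exact algorithm is unpublished.
#'
#' @inheritParams reference_fingerprint
#' @param include_reference Append the median reference fingerprint as a
#'   final `"reference"` row/column (default `TRUE`).
#' @param method `"cosine"` (default) or `"pearson"`.
#' @return Symmetric matrix with unit diagonal, labelled by batch id.
#' @export
similarity_matrix <- function(x, include_reference = TRUE,
                              method = c("cosine", "pearson")) {
  method <- match.arg(method)
  m <- as_batch_matrix(x)
  if (nrow(m) < 2L) stop("need at least two batches", call. = FALSE)
  if (include_reference) {
    m <- rbind(m, reference = reference_fingerprint(m))
    if (is.null(rownames(m))) rownames(m) <- c(seq_len(nrow(m) - 1L), "reference")
  }
  n <- nrow(m)
  sim <- diag(1, n)
  dimnames(sim) <- list(rownames(m), rownames(m))
  fun <- if (method == "cosine") cosine_similarity else stats::cor
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    sim[i, j] <- sim[j, i] <- fun(m[i, ], m[j, ])
  }
  sim
}

#' Fingerprint QC summary
#'
#' Per-peak RSDs of relative retention time and relative area, the similarity
#' matrix, and the consensus reference vector — the quantities a fingerprint
#' methodology section reports.
#'
#' @param matrix A `common_peak_matrix` with full occupancy.
#' @param reference_peak_id Reference peak for the relative quantities.
#' @param similarity `"cosine"` or `"pearson"`, passed to
#'   [similarity_matrix()].
#' @return Object of class `fingerprint_summary`: list with `relative_rts`,
#'   `relative_areas`, `rsd_rt`, `rsd_area` (percent, per peak),
#'   `similarity`, `reference_fingerprint`, `reference_peak_id`.
#' @export
fingerprint_summary <- function(matrix, reference_peak_id,
                                similarity = c("cosine", "pearson")) {
  rel <- relative_to_reference(matrix, reference_peak_id)
  structure(list(
    relative_rts = rel$relative_rts,
    relative_areas = rel$relative_areas,
    rsd_rt = apply(rel$relative_rts, 2L, rsd),
    rsd_area = apply(rel$relative_areas, 2L, function(v)
      if (stats::sd(v) == 0) 0 else rsd(v)),
    similarity = similarity_matrix(matrix, method = match.arg(similarity)),
    reference_fingerprint = reference_fingerprint(matrix),
    reference_peak_id = reference_peak_id), class = "fingerprint_summary")
}

#' @export
print.fingerprint_summary <- function(x, ...) {
  cat(sprintf(
    "<fingerprint_summary: %d peaks, reference peak %s>\n",
    length(x$rsd_rt), x$reference_peak_id))
  cat(sprintf("  relative-RT RSD: %.3f-%.3f%%; relative-area RSD: %.1f-%.1f%%\n",
              min(x$rsd_rt), max(x$rsd_rt), min(x$rsd_area), max(x$rsd_area)))
  off <- x$similarity[lower.tri(x$similarity)]
  cat(sprintf("  similarity: %.3f-%.3f\n", min(off), max(off)))
  invisible(x)
}
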