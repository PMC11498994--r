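#' Grey relational analysis
#'
#' Deng's grey relational analysis scores how closely each subsequence (a
#' common peak's area profile over batches) tracks a parent sequence (an
#' efficacy index over the same batches). After dimensionless normalization,
#' per-point absolute differences `D[i, k] = |x0(k) - xi(k)|` are turned into
#' relational coefficients
#' `xi[i, k] = (m + rho * M) / (D[i, k] + rho * M)`,
#' with `m` and `M` the minimum and maximum of `D` over *all* subsequences
#' and points jointly (two-level extrema, one run per parent sequence), and
#' `rho` the resolution coefficient. The unweighted row mean is the
#' relational degree, in (0, 1], with 1 attained only by a subsequence
#' identical to the parent after normalization.
#'
#' @name gra-module
NULL

#' Mean normalization
#'
#' Divides a series by its mean, removing scale so sequences with different
#' units are comparable; the output has mean exactly 1.
#'
#' @param series Numeric vector with non-zero mean.
#' @return Normalized vector.
#' @examples
#' mean_normalize(c(1, 2, 3))  # 0.5 1.0 1.5
#' @export
mean_normalize <- function(series) {
  m <- mean(series)
  if (!is.finite(m) || m == 0)
    stop("mean normalization undefined: series mean is zero or non-finite",
         call. = FALSE)
  series / m
}

normalize_series <- function(series, method) {
  switch(method,
         mean = mean_normalize(series),
         initial = {
           if (series[1L] == 0)
             stop("initial-value normalization undefined: first value is zero",
                  call. = FALSE)
           series / series[1L]
         },
         minmax = {
           r <- range(series)
           if (diff(r) == 0)
             stop("min-max normalization undefined: constant series",
                  call. = FALSE)
           (series - r[1L]) / diff(r)
         },
         stop("unknown normalization method", call. = FALSE))
}

#' Grey relational coefficients
#'
#' @param parent Numeric parent sequence (efficacy index per batch).
#' @param children Matrix with one column per subsequence (batches x peaks),
#'   or a single numeric vector.
#' @param rho Resolution coefficient in (0, 1]; default 0.5.
#' @param normalization `"mean"` (default), `"initial"`, or `"minmax"`.
#' @param normalize_parent Normalize the parent with the same method
#'   (default `TRUE`).
#' @return Matrix of coefficients, one row per subsequence, one column per
#'   point; all values in (0, 1].
#' @examples
#' relational_coefficients(c(1, 2, 3), c(3, 2, 1))  # 1/3, 1, 1/3
#' @export
relational_coefficients <- function(parent, children, rho = 0.5,
                                    normalization = c("mean", "initial", "minmax"),
                                    normalize_parent = TRUE) {
  normalization <- match.arg(normalization)
  if (!is.matrix(children)) children <- matrix(children, ncol = 1L)
  n <- length(parent)
  if (n < 2L || nrow(children) != n)
    stop("parent and subsequences must share length >= 2", call. = FALSE)
  stopifnot(rho > 0, rho <= 1)
  x0 <- if (normalize_parent) normalize_series(parent, normalization) else parent
  xi <- apply(children, 2L, normalize_series, method = normalization)
  D <- abs(xi - x0)                   # recycles x0 down each column
  m <- min(D); M <- max(D)
  if (M == 0) {
    warning("all subsequences identical to the parent after normalization; ",
            "coefficients are all 1", call. = FALSE)
    return(matrix(1, ncol(children), n,
                  dimnames = list(colnames(children), names(parent))))
  }
  t((m + rho * M) / (D + rho * M))
}

#' Grey relational degree
#'
#' Unweighted mean of a subsequence's relational coefficients.
#'
#' @param coefficients_row Numeric vector (one row of
#'   [relational_coefficients()]) or a matrix, in which case row means are
#'   returned.
#' @return Degree(s) in (0, 1].
#' @export
relational_degree <- function(coefficients_row) {
  if (is.matrix(coefficients_row)) return(rowMeans(coefficients_row))
  if (!length(coefficients_row)) stop("empty coefficient row", call. = FALSE)
  mean(coefficients_row)
}

#' Rank relational degrees
#'
#' Rank 1 is the highest degree; ties are broken by subsequence index
#' ascending (with a warning), matching the "Sort" column convention of
#' published GRA tables.
#'
#' @param degrees Numeric vector.
#' @return Integer ranks, a permutation of `1:length(degrees)`.
#' @export
rank_degrees <- function(degrees) {
  if (!length(degrees)) stop("no degrees to rank", call. = FALSE)
  if (anyDuplicated(degrees))
    warning("tied relational degrees; ties broken by index ascending",
            call. = FALSE)
  as.integer(rank(-degrees, ties.method = "first"))
}

#' Grey relational analysis of peak areas against activities
#'
#' One GRA run per efficacy index: each activity column is the parent
#' sequence and every peak's area profile is a subsequence, with two-level
#' extrema computed within the run (the layout of a published GRA table with
#' one block per index).
#'
#' @param areas Batches x peaks numeric matrix (relative or raw areas), or a
#'   `common_peak_matrix`.
#' @param activity An [activity_table()] or data frame with `batch_id` plus
#'   one numeric column per index, or a named numeric matrix/data.frame of
#'   parents (batches x indices). Batches must match `areas` rows when both
#'   are labelled.
#' @param rho Resolution coefficient; default 0.5.
#' @param normalization Passed to [relational_coefficients()].
#' @param normalize_parent Passed to [relational_coefficients()].
#' @return Object of class `gra_result`: list with `degrees` (data frame
#'   `assay`, `peak`, `degree`, `rank`), `coefficients` (list of per-assay
#'   matrices), `rho`, `normalization`.
#' @examples
#' X <- cbind(p1 = c(1, 2, 3, 4), p2 = c(4, 3, 2, 1))
#' y <- data.frame(batch_id = 1:4, dpph_pct = c(1.1, 2.1, 2.9, 4.2))
#' gra(X, y)$degrees
#' @export
gra <- function(areas, activity, rho = 0.5,
                normalization = c("mean", "initial", "minmax"),
                normalize_parent = TRUE) {
  normalization <- match.arg(normalization)
  X <- as_batch_matrix(areas)
  if (is.data.frame(activity)) {
    ids <- activity[["batch_id"]]
    act <- as.matrix(activity[vapply(activity, is.numeric, logical(1)) &
                                !names(activity) %in% c("sd_dpph", "sd_taoc")])
    if (!is.null(ids)) rownames(act) <- ids
  } else act <- as.matrix(activity)
  if (nrow(act) != nrow(X))
    stop("areas and activity cover different numbers of batches", call. = FALSE)
  if (!is.null(rownames(act)) && !is.null(rownames(X))) {
    if (!setequal(rownames(act), rownames(X)))
      stop("areas and activity batch ids do not match", call. = FALSE)
    act <- act[rownames(X), , drop = FALSE]
  }
  peaks <- colnames(X) %||% as.character(seq_len(ncol(X)))
  assays <- colnames(act) %||% paste0("assay", seq_len(ncol(act)))
  coefs <- list()
  deg <- do.call(rbind, lapply(seq_along(assays), function(a) {
    xi <- relational_coefficients(act[, a], X, rho = rho,
                                  normalization = normalization,
                                  normalize_parent = normalize_parent)
    rownames(xi) <- peaks
    coefs[[assays[a]]] <<- xi
    d <- relational_degree(xi)
    data.frame(assay = assays[a], peak = peaks, degree = unname(d),
               rank = rank_degrees(d), stringsAsFactors = FALSE)
  }))
  structure(list(degrees = deg, coefficients = coefs, rho = rho,
                 normalization = normalization), class = "gra_result")
}

#' @export
print.gra_result <- function(x, ...) {
  cat(sprintf("<gra_result: %d subsequences x %d parent sequences, rho = %g, %s normalization>\n",
              length(unique(x$degrees$peak)), length(x$coefficients), x$rho,
              x$normalization))
  top <- x$degrees[x$degrees$rank <= 3L, ]
  cat("  top degrees:\n")
  for (a in unique(top$assay)) {
    t_a <- top[top$assay == a, ]
    t_a <- t_a[order(t_a$rank), ]
    cat(sprintf("    %s: %s\n", a,
                paste(sprintf("%s (%.3f)", t_a$peak, t_a$degree), collapse = ", ")))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
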